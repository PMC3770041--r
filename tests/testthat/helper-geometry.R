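# rasterized reference shapes used across tests

mk_disk <- function(R, cx = 0, cy = 0, pad = 3) {
  n <- ceiling(R + max(abs(cx), abs(cy))) + pad
  xs <- (-n):n
  outer(xs, xs, function(y, x) as.integer((x - cx)^2 + (y - cy)^2 <= R^2))
}

mk_square <- function(side, pad = 3) {
  m <- matrix(0L, side + 2 * pad, side + 2 * pad)
  m[(pad + 1):(pad + side), (pad + 1):(pad + side)] <- 1L
  m
}

mk_ellipse <- function(a, b, theta = 0, cx = 0, cy = 0, pad = 4) {
  n <- ceiling(a) + pad
  xs <- (-n):n
  ct <- cos(theta); st <- sin(theta)
  outer(xs, xs, function(y, x) {
    u <- (x - cx) * ct + (y - cy) * st
    v <- -(x - cx) * st + (y - cy) * ct
    as.integer((u / a)^2 + (v / b)^2 <= 1)
  })
}

# a small, fast cohort configuration for pipeline-level tests; note the tiny
# field can saturate at tumour densities, so generation may warn
small_cohort_config <- function(seed = 11L, n_samples = 2L,
                                fields_per_sample = 2L) {
  specs <- default_group_specs()
  for (i in seq_along(specs)) specs[[i]]$n_samples <- n_samples
  cohort_config(specs, fields_per_sample = fields_per_sample,
                field_width_um = 120, field_height_um = 100, seed = seed)
}

# generate a small cohort quietly (saturation warnings are expected there)
quiet_cohort <- function(cfg, render = TRUE)
  suppressWarnings(generate_cohort(cfg, render = render))

# independent point-in-polygon oracle (winding angle method)
winding_inside <- function(px, py, xy) {
  x <- xy[, 1] - px; y <- xy[, 2] - py
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  ang <- atan2(x * yn - xn * y, x * xn + y * yn)
  abs(sum(ang)) > pi
}
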