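#' Group-level simulation parameters
#'
#' A \code{group_spec} describes one cohort arm (controls, low-grade or
#' high-grade gliomas): how many cases it has, the admissible WHO grade codes
#' and their mixing proportions, the between-sample distribution of mean
#' nuclear area, the nucleus-level spread, the nucleus placement intensity,
#' and the shape parameters of its nuclei.
#'
#' The between-sample mean/SD pairs are the quantities a study would report in
#' its group summary table; nucleus-level spread within a sample
#' (\code{within_sample_cv}) and field-to-field heterogeneity
#' (\code{field_effect_cv}) are not usually printed and are exposed as knobs.
#'
#' @param label group label, one of \code{"CG"}, \code{"LGG"}, \code{"HGG"}.
#' @param n_samples number of cases in the group (>= 1).
#' @param grade_codes integer WHO grade codes admissible for the group
#'   (controls use 0).
#' @param grade_probs mixing proportions for \code{grade_codes}; must sum to 1.
#' @param na_mean_um2,na_sd_um2 mean and SD (between samples) of the
#'   per-sample mean nuclear area, in um^2.
#' @param within_sample_cv coefficient of variation of nucleus areas around
#'   their sample mean.
#' @param density_mean_per_mm2,density_sd_per_mm2 mean and SD (between
#'   samples) of the nucleus placement intensity, per mm^2.
#' @param aspect_ratio_mean target major/minor axis ratio of nuclei (>= 1).
#' @param irregularity boundary perturbation amplitude in [0, 0.5); larger
#'   values give more pleomorphic (less round) nuclei.
#' @param irregularity_sd between-sample jitter of the irregularity.
#' @param field_effect_cv coefficient of variation of per-field mean-area
#'   multipliers within a sample (multipliers are renormalised to mean 1 so
#'   the sample mean is unaffected); models intratumoral field-to-field
#'   heterogeneity and makes pooled tumour area distributions mixtures.
#' @return An object of class \code{group_spec}.
#' @export
group_spec <- function(label, n_samples, grade_codes, grade_probs,
                       na_mean_um2, na_sd_um2, within_sample_cv,
                       density_mean_per_mm2, density_sd_per_mm2,
                       aspect_ratio_mean, irregularity,
                       irregularity_sd = 0.02, field_effect_cv = 0) {
  if (!label %in% c("CG", "LGG", "HGG"))
    stop("group label must be one of CG, LGG, HGG")
  if (n_samples < 1) stop("group sizes must be >= 1")
  if (length(grade_codes) != length(grade_probs))
    stop("grade_codes and grade_probs must have equal length")
  if (abs(sum(grade_probs) - 1) > 1e-8)
    stop("grade mixing proportions must sum to 1")
  if (na_mean_um2 <= 0 || density_mean_per_mm2 <= 0)
    stop("means must be > 0")
  if (na_sd_um2 < 0 || density_sd_per_mm2 < 0) stop("SDs must be >= 0")
  if (within_sample_cv < 0 || field_effect_cv < 0) stop("CVs must be >= 0")
  if (aspect_ratio_mean < 1) stop("aspect_ratio_mean must be >= 1")
  if (irregularity < 0 || irregularity >= 0.5)
    stop("irregularity must be in [0, 0.5)")
  structure(list(
    label = label, n_samples = as.integer(n_samples),
    grade_codes = as.integer(grade_codes), grade_probs = as.numeric(grade_probs),
    na_mean_um2 = na_mean_um2, na_sd_um2 = na_sd_um2,
    within_sample_cv = within_sample_cv,
    density_mean_per_mm2 = density_mean_per_mm2,
    density_sd_per_mm2 = density_sd_per_mm2,
    aspect_ratio_mean = aspect_ratio_mean,
    irregularity = irregularity, irregularity_sd = irregularity_sd,
    field_effect_cv = field_effect_cv
  ), class = "group_spec")
}

#' Default cohort arms calibrated to the reference glioma study
#'
#' Three \code{\link{group_spec}}s — 10 controls (CG), 14 low-grade (LGG) and
#' 16 high-grade (HGG) gliomas — whose between-sample nuclear-area and density
#' distributions follow the reference group summaries
#' (\code{\link{reference_summary}}), whose grade mixtures follow the reported
#' case spectrum (all LGG are WHO grade II; HGG are 13 glioblastoma grade IV
#' and 3 anaplastic astrocytoma grade III), and whose aspect ratio and
#' irregularity are calibrated so mean analytic roundness lands near the
#' reported group means (about 65.5 / 61.5 / 59.8).
#'
#' @return Named list of three \code{group_spec}s.
#' @export
default_group_specs <- function() {
  list(
    CG = group_spec("CG", 10, 0L, 1,
                    na_mean_um2 = 23.44, na_sd_um2 = 4.01,
                    within_sample_cv = 0.15,
                    density_mean_per_mm2 = 1107, density_sd_per_mm2 = 138,
                    aspect_ratio_mean = 6.96 / 4.62, irregularity = 0.35,
                    field_effect_cv = 0.05),
    LGG = group_spec("LGG", 14, 2L, 1,
                     na_mean_um2 = 42.62, na_sd_um2 = 7.26,
                     within_sample_cv = 0.30,
                     density_mean_per_mm2 = 3232, density_sd_per_mm2 = 1596,
                     aspect_ratio_mean = 9.41 / 6.34, irregularity = 0.385,
                     field_effect_cv = 0.25),
    HGG = group_spec("HGG", 16, c(3L, 4L), c(3 / 16, 13 / 16),
                     na_mean_um2 = 55.22, na_sd_um2 = 13.48,
                     within_sample_cv = 0.30,
                     density_mean_per_mm2 = 4350, density_sd_per_mm2 = 1089,
                     aspect_ratio_mean = 10.73 / 7.11, irregularity = 0.40,
                     field_effect_cv = 0.25)
  )
}

#' Cohort simulation configuration
#'
#' @param group_specs list of \code{\link{group_spec}}s.
#' @param fields_per_sample number of high-power fields recorded per case
#'   (default 5).
#' @param field_width_um,field_height_um physical field size in um. The
#'   default 346 x 260 um (~0.09 mm^2) is a typical 400x digital camera field.
#' @param microns_per_pixel raster calibration (default 0.25 um/px).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(group_specs = default_group_specs(),
                          fields_per_sample = 5L,
                          field_width_um = 346, field_height_um = 260,
                          microns_per_pixel = 0.25, seed = 1L) {
  if (fields_per_sample < 1) stop("fields_per_sample must be >= 1")
  if (field_width_um <= 0 || field_height_um <= 0 || microns_per_pixel <= 0)
    stop("all physical dimensions must be > 0")
  if (!all(vapply(group_specs, inherits, TRUE, "group_spec")))
    stop("group_specs must be a list of group_spec objects")
  structure(list(
    group_specs = group_specs,
    fields_per_sample = as.integer(fields_per_sample),
    field_width_um = field_width_um, field_height_um = field_height_um,
    microns_per_pixel = microns_per_pixel, seed = as.integer(seed)
  ), class = "cohort_config")
}

field_dims_px <- function(config) {
  c(h = as.integer(round(config$field_height_um / config$microns_per_pixel)),
    w = as.integer(round(config$field_width_um / config$microns_per_pixel)))
}

field_area_mm2_of <- function(config) {
  d <- field_dims_px(config)
  d[["h"]] * d[["w"]] * config$microns_per_pixel^2 / 1e6
}

rtrunc_norm_pos <- function(n, mean, sd, lower = 0) {
  # rejection sampling from Normal(mean, sd) truncated to (lower, Inf)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x > lower
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# minimum boundary gap (um) used by placement and enforced by render_field
placement_gap_um <- function(config) config$microns_per_pixel

max_radius <- function(poly) {
  v <- poly$vertices
  sqrt(max(v[, 1]^2 + v[, 2]^2))
}

# min distance between two vertex clouds, with a chord-sag allowance
boundary_clearance <- function(v1, v2) {
  d2 <- outer(v1[, 1], v2[, 1], "-")^2 + outer(v1[, 2], v2[, 2], "-")^2
  sqrt(min(d2))
}

chord_slack <- function(poly) {
  # half the longest edge: bound on how far the true boundary can stray
  # from the vertex sample
  v <- poly$vertices
  dx <- diff(c(v[, 1], v[1, 1])); dy <- diff(c(v[, 2], v[1, 2]))
  0.5 * max(sqrt(dx^2 + dy^2))
}

#' Place nuclei in a field by rejection sampling
#'
#' Draws uniform positions, rejecting any candidate whose boundary comes
#' closer than one pixel to an already placed nucleus or to the field border.
#' After \code{max_attempts} failed draws for a nucleus the field is emitted
#' with fewer nuclei and a warning (density saturation).
#'
#' @param polygons list of \code{nucleus_polygon}s (centred at the origin).
#' @param config a \code{\link{cohort_config}}.
#' @param max_attempts rejection cap per nucleus (default 1000).
#' @return List of polygons with an added \code{centroid} element (um); its
#'   \code{vertices} are translated to field coordinates.
#' @keywords internal
place_nuclei <- function(polygons, config, max_attempts = 1000L) {
  gap <- placement_gap_um(config)
  w <- config$field_width_um; h <- config$field_height_um
  placed <- list()
  if (!length(polygons)) return(placed)
  cx <- numeric(0); cy <- numeric(0); rmax <- numeric(0); slk <- numeric(0)
  sub_cache <- list()
  dropped <- 0L
  for (poly in polygons) {
    r <- max_radius(poly)
    slack <- chord_slack(poly)
    lox <- r + gap; hix <- w - r - gap
    loy <- r + gap; hiy <- h - r - gap
    if (hix <= lox || hiy <= loy) { dropped <- dropped + 1L; next }
    v0x <- poly$vertices[, 1]; v0y <- poly$vertices[, 2]
    csub <- seq(1, length(v0x), by = 4L)      # coarse vertex subsample
    sagc <- 4 * slack                         # sag bound of the subsample
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      px <- stats::runif(1, lox, hix)
      py <- stats::runif(1, loy, hiy)
      if (length(cx)) {
        cd2 <- (cx - px)^2 + (cy - py)^2
        near <- which(cd2 < (rmax + r + gap + 2 * slack)^2)
        if (length(near)) {
          # clearance, coarse to fine: a sparse vertex subsample settles
          # clearly-far and clearly-clashing neighbours; only borderline
          # pairs get the full vertex-cloud distance
          clash <- FALSE
          for (j in near) {
            vj <- placed[[j]]$vertices
            vjs <- sub_cache[[j]]
            lim <- gap + slack + slk[j]
            d2c <- outer(v0x[csub] + px, vjs[, 1], "-")^2 +
              outer(v0y[csub] + py, vjs[, 2], "-")^2
            mc <- min(d2c)
            if (mc < lim^2) { clash <- TRUE; break }
            band <- lim + sagc + 4 * slk[j]
            if (mc >= band^2) next
            d2 <- outer(v0x + px, vj[, 1], "-")^2 +
              outer(v0y + py, vj[, 2], "-")^2
            if (min(d2) < lim^2) { clash <- TRUE; break }
          }
          if (clash) next
        }
      }
      poly$centroid <- c(px, py)
      poly$vertices <- cbind(v0x + px, v0y + py)
      placed[[length(placed) + 1L]] <- poly
      sub_cache[[length(placed)]] <- poly$vertices[csub, , drop = FALSE]
      cx <- c(cx, px); cy <- c(cy, py); rmax <- c(rmax, r)
      slk <- c(slk, slack)
      ok <- TRUE
      break
    }
    if (!ok) dropped <- dropped + 1L
  }
  if (dropped > 0L)
    warning(sprintf("field saturated: %d of %d nuclei could not be placed",
                    dropped, length(polygons)))
  placed
}

rasterize_polygon <- function(xy, dims, mpp, center = NULL, rot = NULL) {
  # pixel-center-in-polygon membership; 0-based pixel (i, j) has its center at
  # physical (x = j * mpp, y = i * mpp). When the polygon is star-convex with
  # vertices on a uniform angular grid about `center` (rotated by `rot`), the
  # exact membership test reduces to: find the angular sector of the pixel,
  # then check which side of that sector's boundary chord it falls on.
  jlo <- max(0L, as.integer(floor(min(xy[, 1]) / mpp)))
  jhi <- min(dims[["w"]] - 1L, as.integer(ceiling(max(xy[, 1]) / mpp)))
  ilo <- max(0L, as.integer(floor(min(xy[, 2]) / mpp)))
  ihi <- min(dims[["h"]] - 1L, as.integer(ceiling(max(xy[, 2]) / mpp)))
  if (jhi < jlo || ihi < ilo) return(NULL)
  px <- (jlo:jhi) * mpp
  py <- (ilo:ihi) * mpp
  nr <- length(py); nc <- length(px)
  gx <- rep(px, each = nr)
  gy <- rep(py, times = nc)
  n <- nrow(xy)
  if (!is.null(center) && !is.null(rot)) {
    dx <- gx - center[1]; dy <- gy - center[2]
    t <- (atan2(dy, dx) - rot) %% (2 * pi)
    j <- pmin(floor(t * n / (2 * pi)) + 1L, n)
    jn <- j %% n + 1L
    ax <- xy[j, 1]; ay <- xy[j, 2]
    inside <- (xy[jn, 1] - ax) * (gy - ay) - (xy[jn, 2] - ay) * (gx - ax) >= 0
  } else {
    inside <- rep(FALSE, nr * nc)
    x1 <- xy[, 1]; y1 <- xy[, 2]
    x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
    for (e in seq_len(n)) {
      if (y1[e] == y2[e]) next
      cross <- ((y1[e] > gy) != (y2[e] > gy)) &
        (gx < x1[e] + (gy - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e]))
      inside <- xor(inside, cross)
    }
  }
  idx <- which(inside)
  if (!length(idx)) return(NULL)
  ri <- ((idx - 1L) %% nr) + ilo + 1L   # 1-based row in full raster
  ci <- ((idx - 1L) %/% nr) + jlo + 1L
  cbind(row = ri, col = ci)
}

#' Render a field of placed nuclei to a label image
#'
#' Produces an integer raster in which pixel centers inside the i-th polygon
#' get label i and background stays 0, together with the aligned ground-truth
#' table. Polygons must lie within the field and keep a minimum boundary
#' clearance of one pixel; violations raise a placement-rejection error.
#'
#' @param nuclei list of placed \code{nucleus_polygon}s (as returned by
#'   \code{place_nuclei}: vertices in field coordinates, \code{centroid} set).
#' @param config a \code{\link{cohort_config}}.
#' @return List with \code{image} (integer matrix, rows = y) and
#'   \code{ground_truth} (data frame, one row per label).
#' @export
render_field <- function(nuclei, config) {
  dims <- field_dims_px(config)
  mpp <- config$microns_per_pixel
  if (length(nuclei) > 65535L)
    stop("label count exceeds 16-bit raster capacity")
  img <- matrix(0L, dims[["h"]], dims[["w"]])
  if (!length(nuclei)) {
    return(list(image = img, ground_truth = empty_ground_truth()))
  }
  half <- mpp / 2
  for (k in seq_along(nuclei)) {
    v <- nuclei[[k]]$vertices
    if (min(v[, 1]) < -half || max(v[, 1]) > (dims[["w"]] - 0.5) * mpp ||
        min(v[, 2]) < -half || max(v[, 2]) > (dims[["h"]] - 0.5) * mpp)
      stop("placement rejection: polygon outside field bounds")
  }
  gap <- placement_gap_um(config)
  ctr <- t(vapply(nuclei, function(p) p$centroid, numeric(2)))
  rmax <- vapply(nuclei, function(p) {
    v <- sweep(p$vertices, 2, p$centroid)
    sqrt(max(v[, 1]^2 + v[, 2]^2))
  }, numeric(1))
  for (k in seq_along(nuclei)) {
    if (k == 1L) next
    j_near <- which(sqrt((ctr[1:(k - 1L), 1] - ctr[k, 1])^2 +
                           (ctr[1:(k - 1L), 2] - ctr[k, 2])^2) <
                      rmax[1:(k - 1L)] + rmax[k] + gap)
    for (j in j_near) {
      cl <- boundary_clearance(nuclei[[k]]$vertices, nuclei[[j]]$vertices)
      if (cl < gap) stop("placement rejection: nuclei overlap or touch")
    }
  }
  gt <- vector("list", length(nuclei))
  for (k in seq_along(nuclei)) {
    pix <- rasterize_polygon(nuclei[[k]]$vertices, dims, mpp,
                             center = nuclei[[k]]$centroid,
                             rot = nuclei[[k]]$radial_rot)
    if (!is.null(pix)) img[pix] <- k
    p <- nuclei[[k]]
    gt[[k]] <- data.frame(
      label_id = k,
      centroid_x_um = p$centroid[1], centroid_y_um = p$centroid[2],
      true_area_um2 = p$true_area_um2, true_perimeter_um = p$true_perimeter_um,
      true_majx_um = p$true_majx_um, true_minx_um = p$true_minx_um,
      true_nr = p$true_nr
    )
  }
  list(image = img, ground_truth = do.call(rbind, gt))
}

empty_ground_truth <- function() {
  data.frame(label_id = integer(0), centroid_x_um = numeric(0),
             centroid_y_um = numeric(0), true_area_um2 = numeric(0),
             true_perimeter_um = numeric(0), true_majx_um = numeric(0),
             true_minx_um = numeric(0), true_nr = numeric(0))
}

draw_sample_parameters <- function(spec) {
  list(
    mean_area = rtrunc_norm_pos(1, spec$na_mean_um2, spec$na_sd_um2),
    density   = rtrunc_norm_pos(1, spec$density_mean_per_mm2,
                                spec$density_sd_per_mm2),
    grade     = spec$grade_codes[
      sample.int(length(spec$grade_codes), 1, prob = spec$grade_probs)],
    irregularity = min(max(stats::rnorm(1, spec$irregularity,
                                        spec$irregularity_sd), 0), 0.45)
  )
}

draw_field_multipliers <- function(spec, k) {
  if (spec$field_effect_cv <= 0) return(rep(1, k))
  m <- rtrunc_norm_pos(k, 1, spec$field_effect_cv, lower = 0.1)
  m / mean(m)  # renormalise so the sample mean area is preserved
}

draw_nucleus_areas <- function(n, mean_area, cv) {
  if (n == 0L) return(numeric(0))
  rtrunc_norm_pos(n, mean_area, cv * mean_area)
}

#' Generate a full synthetic cohort
#'
#' For each sample: a per-sample mean nuclear area and placement density are
#' drawn from the group's truncated-normal between-sample distributions and a
#' WHO grade code from its grade mixture; for each field, the nucleus count is
#' Poisson(density x field area), nucleus areas are normal around the
#' field-adjusted sample mean (truncated positive), outlines come from
#' \code{\link{generate_nucleus_polygon}}, and nuclei are placed without
#' overlap. Everything drawn is recorded in the manifest, and the whole cohort
#' is reproducible from \code{config$seed}.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param render logical; if TRUE (default) each field's label image is
#'   rasterized, otherwise only polygons and ground truth are kept.
#' @return An object of class \code{glioma_cohort}: list with \code{config},
#'   \code{samples} (each with \code{fields}: placed nuclei, ground truth and
#'   optionally \code{image}) and \code{manifest} (data frame of all drawn
#'   per-sample/per-field parameters).
#' @export
generate_cohort <- function(config, render = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  area_mm2 <- field_area_mm2_of(config)
  samples <- list()
  manifest <- list()
  for (spec in config$group_specs) {
    for (i in seq_len(spec$n_samples)) {
      sample_id <- sprintf("%s%02d", spec$label, i)
      par <- draw_sample_parameters(spec)
      mult <- draw_field_multipliers(spec, config$fields_per_sample)
      fields <- list()
      for (f in seq_len(config$fields_per_sample)) {
        n_f <- stats::rpois(1, par$density * area_mm2)
        areas <- draw_nucleus_areas(n_f, par$mean_area * mult[f],
                                    spec$within_sample_cv)
        polys <- lapply(areas, function(a)
          generate_nucleus_polygon(a, spec$aspect_ratio_mean,
                                   par$irregularity))
        placed <- place_nuclei(polys, config)
        fld <- list(field_id = f, n_drawn = n_f, nuclei = placed)
        if (render) {
          r <- render_field(placed, config)
          fld$image <- r$image
          fld$ground_truth <- r$ground_truth
        } else {
          fld$ground_truth <- if (length(placed)) do.call(rbind, lapply(
            seq_along(placed), function(k) {
              p <- placed[[k]]
              data.frame(label_id = k, centroid_x_um = p$centroid[1],
                         centroid_y_um = p$centroid[2],
                         true_area_um2 = p$true_area_um2,
                         true_perimeter_um = p$true_perimeter_um,
                         true_majx_um = p$true_majx_um,
                         true_minx_um = p$true_minx_um, true_nr = p$true_nr)
            })) else empty_ground_truth()
        }
        if (nrow(fld$ground_truth)) {
          fld$ground_truth <- cbind(sample_id = sample_id, field_id = f,
                                    fld$ground_truth)
        }
        fields[[f]] <- fld
        manifest[[length(manifest) + 1L]] <- data.frame(
          sample_id = sample_id, group = spec$label, grade_code = par$grade,
          field_id = f, drawn_mean_area_um2 = par$mean_area,
          drawn_density_per_mm2 = par$density,
          drawn_irregularity = par$irregularity,
          field_area_multiplier = mult[f],
          n_drawn = n_f, n_placed = length(placed)
        )
      }
      samples[[sample_id]] <- list(sample_id = sample_id, group = spec$label,
                                   grade_code = par$grade, fields = fields)
    }
  }
  structure(list(config = config, samples = samples,
                 manifest = do.call(rbind, manifest)),
            class = "glioma_cohort")
}

#' @export
print.glioma_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<glioma_cohort> %d samples, %d fields, %d nuclei placed (seed %d)\n",
              length(x$samples), nrow(m), sum(m$n_placed), x$config$seed))
  for (g in unique(m$group)) {
    mg <- m[m$group == g, ]
    cat(sprintf("  %-3s: %2d samples, mean %.0f nuclei/field\n", g,
                length(unique(mg$sample_id)), mean(mg$n_placed)))
  }
  invisible(x)
}

#' Pooled ground-truth table of a cohort
#'
#' @param cohort a \code{glioma_cohort}.
#' @return Data frame with one row per generated nucleus.
#' @export
cohort_ground_truth <- function(cohort) {
  stopifnot(inherits(cohort, "glioma_cohort"))
  rows <- list()
  for (s in cohort$samples) for (f in s$fields)
    if (nrow(f$ground_truth)) rows[[length(rows) + 1L]] <- f$ground_truth
  if (!length(rows)) return(empty_ground_truth())
  do.call(rbind, rows)
}
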