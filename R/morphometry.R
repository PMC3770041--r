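#' Calibration of a label image
#'
#' @param microns_per_pixel physical size of one pixel side, in um (> 0).
#' @return Object of class \code{calibration}.
#' @export
calibration <- function(microns_per_pixel) {
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1 ||
      microns_per_pixel <= 0)
    stop("microns_per_pixel must be a positive scalar")
  structure(list(microns_per_pixel = microns_per_pixel), class = "calibration")
}

image_area_mm2 <- function(img, cal) {
  nrow(img) * ncol(img) * cal$microns_per_pixel^2 / 1e6
}

as_mask <- function(pixel_set) {
  if (!is.matrix(pixel_set)) stop("pixel_set must be a matrix")
  pixel_set != 0
}

#' Nuclear area (NA) of a pixel region
#'
#' @param pixel_set matrix; nonzero entries are the region's pixels.
#' @param cal a \code{\link{calibration}}.
#' @return Area in um^2: pixel count x microns_per_pixel^2.
#' @export
nucleus_area <- function(pixel_set, cal) {
  m <- as_mask(pixel_set)
  n <- sum(m)
  if (n == 0) stop("empty region")
  n * cal$microns_per_pixel^2
}

mask_connected <- function(m) {
  # 8-connectivity via iterative dilation from the first foreground pixel
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) return(TRUE)
  nr <- nrow(m); nc <- ncol(m)
  vis <- matrix(FALSE, nr, nc)
  vis[idx[1, 1], idx[1, 2]] <- TRUE
  repeat {
    grown <- vis
    grown[-1, ]  <- grown[-1, ]  | vis[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | vis[-1, ]
    grown[, -1]  <- grown[, -1]  | vis[, -nc]
    grown[, -nc] <- grown[, -nc] | vis[, -1]
    grown[-1, -1]   <- grown[-1, -1]   | vis[-nr, -nc]
    grown[-nr, -nc] <- grown[-nr, -nc] | vis[-1, -1]
    grown[-1, -nc]  <- grown[-1, -nc]  | vis[-nr, -1]
    grown[-nr, -1]  <- grown[-nr, -1]  | vis[-1, -nc]
    grown <- grown & m
    if (all(grown == vis)) break
    vis <- grown
  }
  all(vis[m])
}

#' Nuclear perimeter (NP) of a pixel region
#'
#' Boundary length via the calibrated multi-directional configuration-count
#' estimator (see \code{\link{digital-perimeter}}); for a rasterized disk of
#' radius >= 20 px the relative error against 2*pi*r is below 2%. A single
#' pixel measures 1.7656 x microns_per_pixel.
#'
#' @inheritParams nucleus_area
#' @return Perimeter in um.
#' @export
nucleus_perimeter <- function(pixel_set, cal) {
  m <- as_mask(pixel_set)
  if (sum(m) == 0) stop("empty region")
  if (!mask_connected(m)) stop("disconnected region")
  perimeter_from_features(perimeter_features(m), cal$microns_per_pixel)
}

#' Major and minor axis (MAJX, MINX) of a pixel region
#'
#' Axis lengths of the moment-equivalent ellipse:
#' \code{4 * sqrt(eigenvalues)} of the covariance matrix of pixel-center
#' coordinates, scaled to um. Exact for ideal filled ellipses and stable
#' under rotation (unlike Feret diameters).
#'
#' @inheritParams nucleus_area
#' @return Named vector \code{c(majx_um, minx_um)}, \code{majx >= minx}.
#' @export
nucleus_axes <- function(pixel_set, cal) {
  m <- as_mask(pixel_set)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) < 3) stop("region must have >= 3 pixels")
  x <- idx[, 2]; y <- idx[, 1]
  n <- length(x)
  cxx <- sum((x - mean(x))^2) / n
  cyy <- sum((y - mean(y))^2) / n
  cxy <- sum((x - mean(x)) * (y - mean(y))) / n
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE,
              only.values = TRUE)$values
  if (ev[2] <= 1e-12) stop("degenerate region: pixels are collinear")
  c(majx_um = 4 * sqrt(ev[1]), minx_um = 4 * sqrt(ev[2])) *
    cal$microns_per_pixel
}

#' Nuclear roundness (NR)
#'
#' Shape factor \code{(4 * pi * na / np^2) * 100}: 100 for a perfect circle,
#' smaller for irregular outlines (isoperimetric inequality).
#'
#' @param na nuclear area in um^2 (> 0).
#' @param np nuclear perimeter in um (> 0).
#' @return Roundness in percent.
#' @examples
#' nuclear_roundness(pi, 2 * pi)  # unit circle: 100
#' nuclear_roundness(1, 4)        # unit square: 78.54
#' @export
nuclear_roundness <- function(na, np) {
  if (any(np == 0)) stop("division error: zero perimeter")
  if (any(na < 0) || any(np < 0)) stop("invalid parameter: negative input")
  4 * pi * na / np^2 * 100
}

label_pixels <- function(label_image, label_id) {
  which(label_image == label_id, arr.ind = TRUE)
}

crop_mask <- function(label_image, label_id, pad = 2L) {
  idx <- label_pixels(label_image, label_id)
  if (nrow(idx) == 0) return(NULL)
  r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(label_image), max(idx[, 1]) + pad)
  c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(ncol(label_image), max(idx[, 2]) + pad)
  label_image[r0:r1, c0:c1] == label_id
}

#' Measure one nucleus in a label image
#'
#' Composes area, perimeter, axes and roundness for a single label, and sets
#' the \code{border_touching} flag (any member pixel on the raster edge) and
#' the \code{separated} flag (no member pixel 8-adjacent to a different
#' nonzero label).
#'
#' @param label_id integer label to measure.
#' @param label_image integer label matrix (0 = background).
#' @param cal a \code{\link{calibration}}.
#' @param sample_id,field_id optional identifiers carried into the record.
#' @return One-row data frame: identifiers, \code{majx_um}, \code{minx_um},
#'   \code{na_um2}, \code{np_um}, \code{nr_pct}, \code{border_touching},
#'   \code{separated}.
#' @export
measure_nucleus <- function(label_id, label_image, cal,
                            sample_id = NA_character_, field_id = NA_integer_) {
  idx <- label_pixels(label_image, label_id)
  if (nrow(idx) == 0) stop(sprintf("label %s not found", label_id))
  m <- crop_mask(label_image, label_id)
  na <- nucleus_area(m, cal)
  np <- perimeter_from_features(perimeter_features(m), cal$microns_per_pixel)
  ax <- if (nrow(idx) >= 3) tryCatch(nucleus_axes(m, cal), error = function(e)
    c(majx_um = NA_real_, minx_um = NA_real_)) else
      c(majx_um = NA_real_, minx_um = NA_real_)
  border <- any(idx[, 1] == 1L | idx[, 1] == nrow(label_image) |
                  idx[, 2] == 1L | idx[, 2] == ncol(label_image))
  data.frame(
    sample_id = sample_id, field_id = field_id, label_id = label_id,
    majx_um = unname(ax[1]), minx_um = unname(ax[2]),
    na_um2 = na, np_um = np, nr_pct = nuclear_roundness(na, np),
    border_touching = border,
    separated = label_separated(label_image, label_id)
  )
}

label_separated <- function(label_image, label_id) {
  idx <- label_pixels(label_image, label_id)
  nr <- nrow(label_image); nc <- ncol(label_image)
  for (dd in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                  c(0, 1), c(1, -1), c(1, 0), c(1, 1))) {
    r <- idx[, 1] + dd[1]; c <- idx[, 2] + dd[2]
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- label_image[cbind(r[ok], c[ok])]
    if (any(v != 0 & v != label_id)) return(FALSE)
  }
  TRUE
}

#' Measure every nucleus in a field
#'
#' Vectorised whole-field measurement: per-label pixel counts, centroids and
#' second moments via grouped sums, perimeters via per-label configuration
#' counts (with a per-label fallback for nuclei that touch another label),
#' plus the field-level quantities: nucleus count, nuclear density
#' ND = count / field area (mm^-2) and percent total nuclear area
#' \%TNA = 100 x nonzero pixels / total pixels. All nuclei are included in
#' ND and \%TNA regardless of separation or border flags.
#'
#' @param label_image integer label matrix (0 = background).
#' @param cal a \code{\link{calibration}}.
#' @param sample_id,field_id optional identifiers.
#' @return Object of class \code{field_record}: list with \code{field_id},
#'   \code{nucleus_count}, \code{nd_per_mm2}, \code{tna_pct} and
#'   \code{nuclei} (per-nucleus data frame as in
#'   \code{\link{measure_nucleus}}).
#' @export
measure_field <- function(label_image, cal, sample_id = NA_character_,
                          field_id = NA_integer_) {
  if (!is.matrix(label_image) || nrow(label_image) == 0 || ncol(label_image) == 0)
    stop("zero-sized image")
  mpp <- cal$microns_per_pixel
  area_mm2 <- image_area_mm2(label_image, cal)
  storage.mode(label_image) <- "integer"
  idx <- which(label_image != 0L)
  if (!length(idx)) {
    return(structure(list(
      field_id = field_id, nucleus_count = 0L, nd_per_mm2 = 0,
      tna_pct = 0, field_area_mm2 = area_mm2,
      nuclei = measure_nucleus_empty()), class = "field_record"))
  }
  lab <- label_image[idx]
  nrr <- nrow(label_image)
  rows <- ((idx - 1L) %% nrr) + 1L
  cols <- ((idx - 1L) %/% nrr) + 1L
  K <- max(lab)
  cnt <- tabulate(lab, nbins = K)
  present <- which(cnt > 0L)

  sx <- rowsum_by(cols, lab, K); sy <- rowsum_by(rows, lab, K)
  sxx <- rowsum_by(cols^2, lab, K); syy <- rowsum_by(rows^2, lab, K)
  sxy <- rowsum_by(cols * rows, lab, K)
  mx <- sx / cnt; my <- sy / cnt
  cxx <- sxx / cnt - mx^2
  cyy <- syy / cnt - my^2
  cxy <- sxy / cnt - mx * my
  tr <- cxx + cyy
  dt <- cxx * cyy - cxy^2
  disc <- sqrt(pmax(tr^2 / 4 - dt, 0))
  ev1 <- pmax(tr / 2 + disc, 0); ev2 <- pmax(tr / 2 - disc, 0)
  majx <- 4 * sqrt(ev1) * mpp
  minx <- 4 * sqrt(ev2) * mpp

  border_lab <- unique(c(label_image[1, ], label_image[nrr, ],
                         label_image[, 1], label_image[, ncol(label_image)]))
  border <- seq_len(K) %in% setdiff(border_lab, 0L)
  nonsep <- nonseparated_labels(label_image, K)

  fe <- label_perimeter_features(label_image, K)
  np <- as.vector(fe %*% perimeter_weights[colnames(fe)]) * mpp
  # labels touching another label: per-mask recompute of the binary perimeter
  for (L in which(nonsep)) {
    m <- crop_mask(label_image, L)
    np[L] <- perimeter_from_features(perimeter_features(m), mpp)
  }

  na <- cnt * mpp^2
  nuclei <- data.frame(
    sample_id = sample_id, field_id = field_id, label_id = present,
    majx_um = ifelse(cnt[present] >= 3, majx[present], NA_real_),
    minx_um = ifelse(cnt[present] >= 3, minx[present], NA_real_),
    na_um2 = na[present], np_um = np[present],
    nr_pct = 4 * pi * na[present] / np[present]^2 * 100,
    border_touching = border[present],
    separated = !nonsep[present]
  )
  structure(list(
    field_id = field_id, nucleus_count = length(present),
    nd_per_mm2 = length(present) / area_mm2,
    tna_pct = 100 * length(idx) / length(label_image),
    field_area_mm2 = area_mm2,
    nuclei = nuclei
  ), class = "field_record")
}

measure_nucleus_empty <- function() {
  data.frame(sample_id = character(0), field_id = integer(0),
             label_id = integer(0), majx_um = numeric(0), minx_um = numeric(0),
             na_um2 = numeric(0), np_um = numeric(0), nr_pct = numeric(0),
             border_touching = logical(0), separated = logical(0))
}

rowsum_by <- function(v, g, K) {
  out <- numeric(K)
  rs <- rowsum(as.numeric(v), g)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

nonseparated_labels <- function(img, K) {
  ns <- logical(K)
  nr <- nrow(img); nc <- ncol(img)
  pairs <- list(
    list(img[, -nc], img[, -1]), list(img[-nr, ], img[-1, ]),
    list(img[-nr, -nc], img[-1, -1]), list(img[-nr, -1], img[-1, -nc]))
  for (pr in pairs) {
    a <- pr[[1]]; b <- pr[[2]]
    sel <- a != b & a != 0L & b != 0L
    if (any(sel)) ns[unique(c(a[sel], b[sel]))] <- TRUE
  }
  ns
}

#' @export
print.field_record <- function(x, ...) {
  cat(sprintf("<field_record> field %s: %d nuclei | ND %.0f /mm^2 | %%TNA %.2f\n",
              x$field_id, x$nucleus_count, x$nd_per_mm2, x$tna_pct))
  invisible(x)
}

#' Select the most cellular fields
#'
#' Keeps the \code{k} fields with the highest nucleus count (the "maximum
#' cellularity" rule), ties broken by field id order. If fewer than \code{k}
#' fields exist, all are returned with a warning.
#'
#' @param fields list of \code{field_record}s.
#' @param k number of fields to keep (default 5).
#' @return List of \code{field_record}s.
#' @export
select_fields <- function(fields, k = 5L) {
  if (!length(fields)) stop("empty field list")
  counts <- vapply(fields, function(f) as.numeric(f$nucleus_count), numeric(1))
  ids <- vapply(fields, function(f) as.integer(f$field_id), integer(1))
  if (length(fields) < k) {
    warning(sprintf("only %d fields available (requested %d); using all",
                    length(fields), k))
    return(fields[order(ids)])
  }
  fields[order(-counts, ids)[seq_len(k)]]
}

#' Select nuclei for shape/size statistics
#'
#' Operationalises "clearly separated and relatively larger in size": keeps
#' nuclei with \code{separated = TRUE} and \code{border_touching = FALSE},
#' sorts by area descending (ties by field then label id) and takes the first
#' \code{n}. Fewer than \code{n} eligible nuclei yields all of them with a
#' warning. Note the deliberate size bias: this mirrors the manual convention
#' of choosing larger nuclei, and is documented as a caveat.
#'
#' @param records per-nucleus data frame (rows from \code{\link{measure_field}}).
#' @param n number of nuclei to keep (default 100).
#' @return Filtered, ordered data frame.
#' @export
select_nuclei <- function(records, n = 100L) {
  eligible <- records[records$separated & !records$border_touching, ,
                      drop = FALSE]
  if (nrow(eligible) == 0) {
    warning("no eligible nuclei (all border-touching or not separated)")
    return(eligible)
  }
  ord <- order(-eligible$na_um2, eligible$field_id, eligible$label_id)
  eligible <- eligible[ord, , drop = FALSE]
  if (nrow(eligible) < n) {
    warning(sprintf("only %d eligible nuclei (requested %d); using all",
                    nrow(eligible), n))
    return(eligible)
  }
  eligible[seq_len(n), , drop = FALSE]
}

#' Per-sample parameter means
#'
#' MAJX, MINX, NA, NP and NR are averaged over the selected nuclei; ND and
#' \%TNA over the selected fields.
#'
#' @param sample_id,group,grade identifiers for the case.
#' @param fields list of \code{field_record}s (the selected fields).
#' @param selected_nuclei data frame from \code{\link{select_nuclei}}.
#' @return One-row data frame of per-sample means.
#' @export
summarize_sample <- function(sample_id, group, grade, fields, selected_nuclei) {
  if (!length(fields)) stop("no fields to summarize")
  if (!nrow(selected_nuclei)) stop("no nuclei to summarize")
  data.frame(
    sample_id = sample_id, group = group, grade_code = as.integer(grade),
    n_nuclei = nrow(selected_nuclei), n_fields = length(fields),
    mean_majx = mean(selected_nuclei$majx_um),
    mean_minx = mean(selected_nuclei$minx_um),
    mean_na = mean(selected_nuclei$na_um2),
    mean_np = mean(selected_nuclei$np_um),
    mean_nr = mean(selected_nuclei$nr_pct),
    mean_nd = mean(vapply(fields, function(f) f$nd_per_mm2, numeric(1))),
    mean_tna = mean(vapply(fields, function(f) f$tna_pct, numeric(1)))
  )
}

#' Measure an entire cohort
#'
#' Runs \code{\link{measure_field}} on every rendered field of every sample,
#' applies the field- and nucleus-selection rules and summarises each sample.
#'
#' @param cohort a \code{glioma_cohort} generated with \code{render = TRUE}.
#' @param fields_per_sample number of most-cellular fields to keep (default 5).
#' @param nuclei_per_sample number of nuclei for shape statistics (default 100).
#' @return List with \code{samples} (per-sample means), \code{fields}
#'   (per-field rows) and \code{nuclei} (per-nucleus rows from all measured
#'   fields, with a \code{selected} flag).
#' @export
measure_cohort <- function(cohort, fields_per_sample = 5L,
                           nuclei_per_sample = 100L) {
  stopifnot(inherits(cohort, "glioma_cohort"))
  cal <- calibration(cohort$config$microns_per_pixel)
  sample_rows <- list(); field_rows <- list(); nuc_rows <- list()
  for (s in cohort$samples) {
    frecs <- lapply(s$fields, function(f) {
      if (is.null(f$image)) stop("cohort was generated with render = FALSE")
      measure_field(f$image, cal, sample_id = s$sample_id,
                    field_id = f$field_id)
    })
    sel_fields <- select_fields(frecs, fields_per_sample)
    sel_ids <- vapply(sel_fields, function(f) as.integer(f$field_id),
                      integer(1))
    nuc <- do.call(rbind, lapply(frecs, function(f) f$nuclei))
    nuc$in_selected_field <- nuc$field_id %in% sel_ids
    chosen <- select_nuclei(nuc[nuc$in_selected_field, , drop = FALSE],
                            nuclei_per_sample)
    nuc$selected <- interaction(nuc$field_id, nuc$label_id) %in%
      interaction(chosen$field_id, chosen$label_id) & nuc$in_selected_field
    sample_rows[[s$sample_id]] <- summarize_sample(
      s$sample_id, s$group, s$grade_code, sel_fields, chosen)
    field_rows[[s$sample_id]] <- data.frame(
      sample_id = s$sample_id,
      field_id = vapply(frecs, function(f) as.integer(f$field_id), integer(1)),
      nucleus_count = vapply(frecs, function(f) f$nucleus_count, integer(1)),
      nd_per_mm2 = vapply(frecs, function(f) f$nd_per_mm2, numeric(1)),
      tna_pct = vapply(frecs, function(f) f$tna_pct, numeric(1)),
      selected = vapply(frecs, function(f) as.integer(f$field_id), integer(1))
        %in% sel_ids)
    nuc_rows[[s$sample_id]] <- nuc
  }
  list(samples = do.call(rbind, c(sample_rows, list(make.row.names = FALSE))),
       fields = do.call(rbind, c(field_rows, list(make.row.names = FALSE))),
       nuclei = do.call(rbind, c(nuc_rows, list(make.row.names = FALSE))))
}
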