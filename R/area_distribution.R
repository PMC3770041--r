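#' Observed nuclear-area histogram
#'
#' Uniform left-closed/right-open bins over the data (padded outward to bin
#' boundaries) or over an explicit range. The default 5 um^2 bin width suits
#' nuclear areas in the 10-100 um^2 range.
#'
#' @param areas numeric vector of nuclear areas (um^2), length >= 1.
#' @param bin_width bin width in um^2 (> 0).
#' @param range optional c(lo, hi); data outside it are dropped.
#' @return Object of class \code{area_distribution}: \code{bin_edges},
#'   \code{observed_counts}, \code{expected_counts} (NULL until a Gaussian
#'   model is attached), \code{n}, \code{mean}, \code{sd}.
#' @export
area_histogram <- function(areas, bin_width = 5, range = NULL) {
  if (!length(areas)) stop("empty input")
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (is.null(range)) {
    lo <- floor(min(areas) / bin_width) * bin_width
    hi <- ceiling(max(areas) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
  } else {
    lo <- range[1]; hi <- range[2]
    areas <- areas[areas >= lo & areas < hi]
  }
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, edges[length(edges)] + bin_width)
  counts <- as.integer(table(cut(areas, edges, right = FALSE,
                                 include.lowest = FALSE)))
  structure(list(bin_edges = edges, observed_counts = counts,
                 expected_counts = NULL, n = length(areas),
                 mean = mean(areas), sd = stats::sd(areas)),
            class = "area_distribution")
}

#' Expected Gaussian bin counts
#'
#' The "calculated Gaussian distribution" overlay: expected count per bin is
#' \code{n * (pnorm(hi; mean, sd) - pnorm(lo; mean, sd))}.
#'
#' @param mean,sd Gaussian parameters (sd > 0), um^2.
#' @param n number of nuclei the model is scaled to.
#' @param bin_edges strictly increasing bin edges.
#' @return Numeric vector of expected counts, one per bin.
#' @export
gaussian_expected_counts <- function(mean, sd, n, bin_edges) {
  if (sd <= 0) stop("sd must be > 0")
  if (n < 1) stop("n must be >= 1")
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  k <- length(bin_edges)
  n * (stats::pnorm(bin_edges[-1], mean, sd) -
         stats::pnorm(bin_edges[-k], mean, sd))
}

#' Attach a Gaussian model to an observed distribution
#'
#' @param dist an \code{area_distribution}.
#' @param mean,sd model parameters; default to the distribution's own.
#' @return The distribution with \code{expected_counts} filled in.
#' @export
add_gaussian_model <- function(dist, mean = dist$mean, sd = dist$sd) {
  stopifnot(inherits(dist, "area_distribution"))
  dist$expected_counts <- gaussian_expected_counts(mean, sd, dist$n,
                                                   dist$bin_edges)
  dist
}

#' Departure of an area distribution from Gaussianity
#'
#' One-sample Kolmogorov-Smirnov distance of the raw areas against
#' Normal(mean, sd) with the parameters estimated from the same data (so the
#' P value is approximate and anti-conservative; it is reported as such),
#' plus two descriptors of the qualitative pattern seen in tumours: the
#' observed-to-Gaussian peak-height ratio and the observed range as a
#' fraction of mean +/- 3 sd.
#'
#' @param areas numeric vector of nuclear areas, length >= 20.
#' @param bin_width bin width used for the peak-height descriptor.
#' @return List of class \code{gaussian_deviation}: \code{statistic} (KS
#'   distance), \code{p_value} (approximate), \code{peak_ratio} (> 1 when the
#'   observed mode is sharper than the Gaussian, < 1 when flatter),
#'   \code{range_ratio} (> 1 when the observed range exceeds 6 sd).
#' @export
gaussian_deviation <- function(areas, bin_width = 5) {
  if (length(areas) < 20) stop("insufficient data: need >= 20 areas")
  m <- mean(areas); s <- stats::sd(areas)
  if (s == 0) stop("sd must be > 0")
  ks <- suppressWarnings(stats::ks.test(areas, "pnorm", m, s))
  h <- area_histogram(areas, bin_width)
  expected <- gaussian_expected_counts(m, s, h$n, h$bin_edges)
  structure(list(
    statistic = unname(ks$statistic),
    p_value = ks$p.value,
    peak_ratio = max(h$observed_counts) / max(expected),
    range_ratio = diff(range(areas)) / (6 * s),
    n = length(areas)
  ), class = "gaussian_deviation")
}

#' @export
print.gaussian_deviation <- function(x, ...) {
  cat(sprintf(
    "KS distance %.4f (approx p = %.3g, n = %d); peak ratio %.2f; range/6sd %.2f\n",
    x$statistic, x$p_value, x$n, x$peak_ratio, x$range_ratio))
  invisible(x)
}

#' Group-level Gaussian model curves
#'
#' Expected-count curves for each group from its summary mean/SD, scaled to
#' \code{n} nuclei — the model overlay comparing groups: because the SDs
#' order CG < LGG < HGG, the peak heights order CG > LGG > HGG.
#'
#' @param summary data frame with columns \code{group}, \code{mean},
#'   \code{sd} (one row per group), e.g. the \code{na} rows of
#'   \code{\link{reference_summary}}.
#' @param n nuclei per curve (default 100).
#' @param bin_width bin width in um^2.
#' @param range range spanned by the curves; defaults to covering all groups
#'   at mean +/- 4 sd.
#' @return Data frame: \code{group}, \code{bin_lo}, \code{bin_hi},
#'   \code{expected}.
#' @export
group_model_curves <- function(summary, n = 100, bin_width = 5, range = NULL) {
  stopifnot(all(c("group", "mean", "sd") %in% names(summary)))
  if (is.null(range)) {
    lo <- floor(min(summary$mean - 4 * summary$sd) / bin_width) * bin_width
    hi <- ceiling(max(summary$mean + 4 * summary$sd) / bin_width) * bin_width
    range <- c(max(lo, 0), hi)
  }
  edges <- seq(range[1], range[2], by = bin_width)
  out <- lapply(seq_len(nrow(summary)), function(i) {
    data.frame(group = summary$group[i], bin_lo = edges[-length(edges)],
               bin_hi = edges[-1],
               expected = gaussian_expected_counts(summary$mean[i],
                                                   summary$sd[i], n, edges))
  })
  do.call(rbind, out)
}

#' Export an area distribution as a data frame
#'
#' @param x an \code{area_distribution}.
#' @param ... ignored.
#' @return Data frame: \code{bin_lo}, \code{bin_hi}, \code{observed},
#'   \code{expected} (NA when no model attached).
#' @export
as.data.frame.area_distribution <- function(x, ...) {
  k <- length(x$bin_edges)
  data.frame(bin_lo = x$bin_edges[-k], bin_hi = x$bin_edges[-1],
             observed = x$observed_counts,
             expected = if (is.null(x$expected_counts)) NA_real_
                        else x$expected_counts)
}

#' @export
print.area_distribution <- function(x, ...) {
  cat(sprintf("<area_distribution> n = %d, mean %.2f, sd %.2f, %d bins [%g, %g)\n",
              x$n, x$mean, x$sd, length(x$observed_counts),
              x$bin_edges[1], x$bin_edges[length(x$bin_edges)]))
  invisible(x)
}

#' Plot an observed distribution with its Gaussian overlay
#'
#' @param x an \code{area_distribution}.
#' @param ... passed to \code{barplot}.
#' @export
plot.area_distribution <- function(x, ...) {
  k <- length(x$bin_edges)
  mids <- (x$bin_edges[-k] + x$bin_edges[-1]) / 2
  bp <- graphics::barplot(x$observed_counts, names.arg = round(mids, 1),
                          xlab = "nuclear area (um^2)", ylab = "count", ...)
  if (!is.null(x$expected_counts))
    graphics::lines(bp, x$expected_counts, col = "firebrick", lwd = 2)
  invisible(x)
}
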