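#' Reference group summary statistics
#'
#' Published per-group summaries (mean, SD, range, n) of age and the seven
#' nuclear parameters for a 40-case glioma morphometry cohort: 10 controls
#' (CG), 14 low-grade (LGG) and 16 high-grade (HGG) diffusely infiltrating
#' gliomas. These drive the default synthetic-cohort calibration and can be
#' fed directly to \code{\link{t_tests_from_summary}} to reproduce the
#' published pairwise P values.
#'
#' @return Data frame with columns \code{parameter}, \code{group}, \code{n},
#'   \code{mean}, \code{sd}, \code{min}, \code{max}.
#' @export
reference_summary <- function() {
  p <- c("age", "majx", "minx", "na", "np", "nr", "nd", "tna")
  rbind(
    data.frame(parameter = p, group = "CG", n = 10L,
               mean = c(46.3, 6.96, 4.62, 23.44, 21.54, 65.55, 1107, 2.32),
               sd   = c(3.5, 0.59, 0.35, 4.01, 2.11, 4.34, 138, 0.54),
               min  = c(40, 6.23, 4.18, 19.42, 18.84, 59.85, 849, 1.65),
               max  = c(53, 8.07, 5.30, 30.33, 25.33, 73.48, 1282, 3.33)),
    data.frame(parameter = p, group = "LGG", n = 14L,
               mean = c(39.1, 9.41, 6.34, 42.62, 29.79, 61.53, 3232, 9.98),
               sd   = c(14.1, 0.81, 0.70, 7.26, 2.80, 5.42, 1596, 4.34),
               min  = c(9, 7.51, 4.98, 27.15, 23.34, 48.99, 1456, 3.63),
               max  = c(62, 10.30, 7.56, 55.23, 32.74, 70.43, 5633, 17.35)),
    data.frame(parameter = p, group = "HGG", n = 16L,
               mean = c(54.6, 10.73, 7.11, 55.22, 34.24, 59.78, 4350, 15.88),
               sd   = c(16.8, 1.33, 0.94, 13.48, 4.49, 5.80, 1089, 7.48),
               min  = c(27, 8.90, 4.66, 30.26, 28.92, 48.94, 1941, 6.64),
               max  = c(79, 12.87, 8.70, 76.90, 41.91, 70.40, 6360, 35.33))
  )
}

#' Summary statistics of one group of values
#'
#' @param values numeric vector (length >= 2).
#' @param name parameter name carried into the result.
#' @return One-row data frame: \code{parameter}, \code{n}, \code{mean},
#'   \code{sd} (sample SD, n-1 denominator), \code{min}, \code{max}.
#' @export
group_summary <- function(values, name = "parameter") {
  if (length(values) < 2) stop("insufficient data: need >= 2 values")
  data.frame(parameter = name, n = length(values), mean = mean(values),
             sd = stats::sd(values), min = min(values), max = max(values))
}

#' Pooled-variance two-sided Student t-test from summary statistics
#'
#' Computes \code{sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)},
#' \code{t = (m2 - m1) / (sp * sqrt(1/n1 + 1/n2))} and the two-sided P value
#' on \code{n1+n2-2} degrees of freedom. Because only means, SDs and sizes
#' enter, published summary tables can be tested directly. Welch's unequal
#' variance form is available via \code{welch = TRUE} but is not the default:
#' the pooled form is the one that reproduces the reference study's printed
#' P values.
#'
#' @param m1,s1,n1 mean, sample SD and size of group 1.
#' @param m2,s2,n2 mean, sample SD and size of group 2.
#' @param welch use the Welch unequal-variance test instead of pooling.
#' @param alpha significance level for the \code{significant} flag.
#' @return List of class \code{t_test_result}: \code{t_statistic}, \code{df},
#'   \code{p_value}, \code{significant}.
#' @examples
#' # LGG vs HGG nuclear area from the reference summaries
#' t_test_pooled(42.62, 7.26, 14, 55.22, 13.48, 16)$p_value  # ~0.0042
#' @export
t_test_pooled <- function(m1, s1, n1, m2, s2, n2, welch = FALSE,
                          alpha = 0.05) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (s1 < 0 || s2 < 0) stop("SDs must be >= 0")
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2) {
      return(structure(list(t_statistic = 0, df = n1 + n2 - 2, p_value = 1,
                            significant = FALSE), class = "t_test_result"))
    }
    warning("zero pooled variance with unequal means: P = 0")
    return(structure(list(t_statistic = sign(m2 - m1) * Inf, df = n1 + n2 - 2,
                          p_value = 0, significant = TRUE),
                     class = "t_test_result"))
  }
  if (welch) {
    se2 <- s1^2 / n1 + s2^2 / n2
    t <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    t <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(t_statistic = t, df = df, p_value = p,
                 significant = p < alpha), class = "t_test_result")
}

#' Pooled t-test from raw per-sample vectors
#'
#' Computes the summaries internally and delegates to
#' \code{\link{t_test_pooled}}; identical to the summary-statistic path to
#' machine precision.
#'
#' @param x,y numeric vectors for the two groups.
#' @inheritParams t_test_pooled
#' @export
t_test_pooled_xy <- function(x, y, welch = FALSE, alpha = 0.05) {
  t_test_pooled(mean(x), stats::sd(x), length(x),
                mean(y), stats::sd(y), length(y), welch = welch, alpha = alpha)
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t = %.4f, df = %.5g, p = %.4g%s\n", x$t_statistic, x$df,
              x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Pearson correlation with a two-sided P value
#'
#' Standard Pearson r with P from \code{t = r * sqrt((n-2) / (1-r^2))} on
#' n-2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, both nonconstant.
#' @return List of class \code{correlation_result}: \code{r}, \code{p_value},
#'   \code{n}.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need >= 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  r <- stats::cor(x, y)
  n <- length(x)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  structure(list(r = r, p_value = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (n = %d), p = %.4g\n", x$r, x$n, x$p_value))
  invisible(x)
}

#' Least-squares regression line
#'
#' @param x,y numeric vectors of equal length >= 3; \code{x} nonconstant.
#' @return List with \code{slope} and \code{intercept}.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need >= 3 paired values")
  if (stats::sd(x) == 0) stop("constant x: regression undefined")
  slope <- stats::cov(x, y) / stats::var(x)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' WHO grade code of a diagnosis
#'
#' Controls are coded 0; tumours take their WHO grade: diffuse astrocytoma
#' (DA) and oligoastrocytoma (OA) grade II, anaplastic astrocytoma (AA)
#' grade III, glioblastoma multiforme (GBM) grade IV.
#'
#' @param group group or diagnosis label: \code{"CG"} (or \code{"control"}),
#'   \code{"DA"}, \code{"OA"}, \code{"AA"}, \code{"GBM"}, or \code{"LGG"} /
#'   \code{"HGG"} together with \code{who_grade}.
#' @param who_grade WHO grade (2-4), required when \code{group} is a group
#'   label rather than a diagnosis.
#' @return Integer grade code in \{0, 2, 3, 4\}.
#' @export
grade_code <- function(group, who_grade = NULL) {
  map <- c(CG = 0L, control = 0L, DA = 2L, OA = 2L, AA = 3L, GBM = 4L)
  if (group %in% names(map)) return(unname(map[group]))
  if (group %in% c("LGG", "HGG")) {
    if (is.null(who_grade)) stop("who_grade required for group labels")
    g <- as.integer(who_grade)
    if (group == "LGG" && g != 2L) stop("LGG cases are WHO grade 2")
    if (group == "HGG" && !g %in% c(3L, 4L)) stop("HGG cases are WHO grade 3 or 4")
    return(g)
  }
  stop(sprintf("unknown diagnosis label: %s", group))
}

morpho_parameters <- c("majx", "minx", "na", "np", "nr", "nd", "tna")

#' Group-level statistical analysis of per-sample means
#'
#' For each of the seven nuclear parameters (plus age if present): per-group
#' summaries (mean, sample SD, range), the three pairwise pooled-variance
#' t-tests (CG/LGG, CG/HGG, LGG/HGG) and the Pearson correlation plus
#' regression line against WHO grade code; additionally the correlations of
#' nuclear density with nuclear area and perimeter across all samples. No
#' multiple-testing correction is applied (a documented limitation of the
#' reproduced analysis).
#'
#' @param samples per-sample data frame with columns \code{sample_id},
#'   \code{group} (CG/LGG/HGG), \code{grade_code} and \code{mean_majx},
#'   \code{mean_minx}, \code{mean_na}, \code{mean_np}, \code{mean_nr},
#'   \code{mean_nd}, \code{mean_tna}; optionally \code{age_years}.
#' @param alpha significance level for flags (default 0.05).
#' @return Object of class \code{glioma_group_analysis}: list with
#'   \code{summaries}, \code{t_tests}, \code{grade_correlations},
#'   \code{density_correlations} data frames and the input \code{samples}.
#' @export
run_group_analysis <- function(samples, alpha = 0.05) {
  need <- c("sample_id", "group", "grade_code",
            paste0("mean_", morpho_parameters))
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  groups <- c("CG", "LGG", "HGG")
  absent <- setdiff(groups, unique(samples$group))
  if (length(absent))
    stop("missing groups: ", paste(absent, collapse = ", "))
  for (g in groups)
    if (sum(samples$group == g) < 2)
      stop(sprintf("group %s needs >= 2 samples", g))

  params <- morpho_parameters
  cols <- paste0("mean_", params)
  if ("age_years" %in% names(samples)) {
    params <- c(params, "age"); cols <- c(cols, "age_years")
  }

  summaries <- list(); tt <- list(); gc <- list()
  pairs <- list(c("CG", "LGG"), c("CG", "HGG"), c("LGG", "HGG"))
  for (i in seq_along(params)) {
    p <- params[i]; v <- samples[[cols[i]]]
    for (g in groups) {
      s <- group_summary(v[samples$group == g], p)
      s$group <- g
      summaries[[length(summaries) + 1L]] <- s
    }
    for (pr in pairs) {
      r <- t_test_pooled_xy(v[samples$group == pr[1]],
                            v[samples$group == pr[2]], alpha = alpha)
      tt[[length(tt) + 1L]] <- data.frame(
        parameter = p, group_pair = paste(pr, collapse = "/"),
        t_statistic = r$t_statistic, df = r$df, p_value = r$p_value,
        significant = r$significant)
    }
    cr <- pearson_with_p(samples$grade_code, v)
    fit <- linear_fit(samples$grade_code, v)
    gc[[length(gc) + 1L]] <- data.frame(
      parameter = p, r = cr$r, p_value = cr$p_value,
      slope = fit$slope, intercept = fit$intercept)
  }
  dc <- lapply(c(na = "mean_na", np = "mean_np"), function(cn) {
    cr <- pearson_with_p(samples[[cn]], samples$mean_nd)
    fit <- linear_fit(samples[[cn]], samples$mean_nd)
    data.frame(parameter = sub("mean_", "", cn), r = cr$r,
               p_value = cr$p_value, slope = fit$slope,
               intercept = fit$intercept)
  })
  structure(list(
    summaries = do.call(rbind, summaries),
    t_tests = do.call(rbind, tt),
    grade_correlations = do.call(rbind, gc),
    density_correlations = do.call(rbind, unname(dc)),
    samples = samples, alpha = alpha
  ), class = "glioma_group_analysis")
}

#' Pairwise t-tests straight from a published summary table
#'
#' Consumes group summaries (parameter, group, n, mean, sd) — for example
#' \code{\link{reference_summary}} or a user CSV — and computes the three
#' pairwise pooled-variance t-tests per parameter without any raw data.
#'
#' @param summary data frame with columns \code{parameter}, \code{group},
#'   \code{n}, \code{mean}, \code{sd}.
#' @param alpha significance level.
#' @return Data frame: parameter, group_pair, t_statistic, df, p_value,
#'   significant.
#' @export
t_tests_from_summary <- function(summary, alpha = 0.05) {
  need <- c("parameter", "group", "n", "mean", "sd")
  missing_cols <- setdiff(need, names(summary))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  pairs <- list(c("CG", "LGG"), c("CG", "HGG"), c("LGG", "HGG"))
  out <- list()
  for (p in unique(summary$parameter)) {
    sp <- summary[summary$parameter == p, ]
    for (pr in pairs) {
      a <- sp[sp$group == pr[1], ]; b <- sp[sp$group == pr[2], ]
      if (nrow(a) != 1 || nrow(b) != 1) next
      r <- t_test_pooled(a$mean, a$sd, a$n, b$mean, b$sd, b$n, alpha = alpha)
      out[[length(out) + 1L]] <- data.frame(
        parameter = p, group_pair = paste(pr, collapse = "/"),
        t_statistic = r$t_statistic, df = r$df, p_value = r$p_value,
        significant = r$significant)
    }
  }
  if (!length(out)) stop("need >= 2 groups with matching parameters")
  do.call(rbind, out)
}

#' @export
print.glioma_group_analysis <- function(x, digits = 4, ...) {
  cat("Group analysis of nuclear morphometric parameters\n")
  cat(sprintf("  %d samples: %s\n\n", nrow(x$samples),
              paste(sprintf("%s n=%d", c("CG", "LGG", "HGG"),
                            table(factor(x$samples$group,
                                         c("CG", "LGG", "HGG")))),
                    collapse = ", ")))
  for (p in unique(x$summaries$parameter)) {
    s <- x$summaries[x$summaries$parameter == p, ]
    t <- x$t_tests[x$t_tests$parameter == p, ]
    cat(sprintf("%-5s ", toupper(p)))
    cat(paste(sprintf("%s %.4g +/- %.3g", s$group, s$mean, s$sd),
              collapse = " | "))
    cat(sprintf("\n      P: %s\n",
                paste(sprintf("%s %.4g%s", t$group_pair, t$p_value,
                              ifelse(t$significant, "", " (ns)")),
                      collapse = ", ")))
  }
  cat("\nCorrelation with WHO grade:\n")
  g <- x$grade_correlations
  cat(paste(sprintf("  %-5s r = %+.3f (p = %.3g)", toupper(g$parameter), g$r,
                    g$p_value), collapse = "\n"), "\n")
  d <- x$density_correlations
  cat(sprintf("ND vs NA r = %.3f; ND vs NP r = %.3f\n",
              d$r[d$parameter == "na"], d$r[d$parameter == "np"]))
  invisible(x)
}

#' @export
summary.glioma_group_analysis <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' Scatter plots of parameters against WHO grade
#'
#' One panel per parameter with the fitted regression line, plus panels of
#' nuclear density against nuclear area and perimeter.
#'
#' @param x a \code{glioma_group_analysis}.
#' @param ... passed to \code{plot}.
#' @export
plot.glioma_group_analysis <- function(x, ...) {
  s <- x$samples
  old <- graphics::par(mfrow = c(3, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in morpho_parameters) {
    v <- s[[paste0("mean_", p)]]
    graphics::plot(s$grade_code, v, xlab = "WHO grade code",
                   ylab = toupper(p), pch = 19,
                   col = c(CG = "forestgreen", LGG = "orange",
                           HGG = "firebrick")[s$group], ...)
    g <- x$grade_correlations[x$grade_correlations$parameter == p, ]
    graphics::abline(g$intercept, g$slope, lty = 2)
    graphics::mtext(sprintf("r = %.2f", g$r), side = 3, cex = 0.7)
  }
  for (cn in c("mean_na", "mean_np")) {
    graphics::plot(s[[cn]], s$mean_nd, xlab = toupper(sub("mean_", "", cn)),
                   ylab = "ND (per mm^2)", pch = 19,
                   col = c(CG = "forestgreen", LGG = "orange",
                           HGG = "firebrick")[s$group], ...)
    d <- x$density_correlations[
      x$density_correlations$parameter == sub("mean_", "", cn), ]
    graphics::abline(d$intercept, d$slope, lty = 2)
    graphics::mtext(sprintf("r = %.2f", d$r), side = 3, cex = 0.7)
  }
  invisible(x)
}
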