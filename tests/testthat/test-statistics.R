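test_that("group_summary gives mean, sample SD and range", {
  s <- group_summary(c(1, 2, 3), "x")
  expect_equal(s$mean, 2); expect_equal(s$sd, 1)
  expect_equal(s$min, 1); expect_equal(s$max, 3)
  expect_equal(group_summary(rep(5, 4))$sd, 0)
  expect_error(group_summary(1), "insufficient")
})

test_that("pooled t-test matches an independent implementation", {
  # {1,2,3} vs {4,5,6}: closed form t = 3/sqrt(2/3)
  r <- t_test_pooled_xy(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t_statistic, 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 0.021312, tolerance = 1e-4)
  # cross-check against stats::t.test with var.equal = TRUE
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), mean = runif(1))
    mine <- t_test_pooled_xy(x, y)
    ref <- t.test(y, x, var.equal = TRUE)
    expect_equal(mine$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("summary-statistic and raw-vector t-test paths are identical", {
  set.seed(9)
  x <- rnorm(14, 42, 7); y <- rnorm(16, 55, 13)
  a <- t_test_pooled_xy(x, y)
  b <- t_test_pooled(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
  expect_identical(a$t_statistic, b$t_statistic)
  expect_identical(a$p_value, b$p_value)
})

test_that("t-test symmetry and degenerate cases behave", {
  a <- t_test_pooled(10, 2, 8, 14, 3, 9)
  b <- t_test_pooled(14, 3, 9, 10, 2, 8)
  expect_equal(a$t_statistic, -b$t_statistic)
  expect_equal(a$p_value, b$p_value)
  same <- t_test_pooled(5, 1, 6, 5, 1, 6)
  expect_equal(same$t_statistic, 0); expect_equal(same$p_value, 1)
  ident <- t_test_pooled(5, 0, 6, 5, 0, 6)
  expect_equal(ident$p_value, 1)
  expect_warning(zero <- t_test_pooled(5, 0, 6, 7, 0, 6), "P = 0")
  expect_equal(zero$p_value, 0)
  expect_error(t_test_pooled(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("reference-summary t-tests reproduce the published cells", {
  tt <- t_tests_from_summary(reference_summary())
  cell <- function(p, pair) tt$p_value[tt$parameter == p & tt$group_pair == pair]
  expect_equal(cell("na", "LGG/HGG"), 0.0042, tolerance = 0.0002 / 0.0042)
  expect_equal(cell("majx", "LGG/HGG"), 0.0032, tolerance = 0.0005 / 0.0032)
  expect_equal(cell("np", "LGG/HGG"), 0.0034, tolerance = 0.0005 / 0.0034)
  expect_equal(cell("nr", "CG/HGG"), 0.0125, tolerance = 0.0005 / 0.0125)
  # the pooled (not Welch) choice is what matches the published value
  welch <- t_test_pooled(42.62, 7.26, 14, 55.22, 13.48, 16, welch = TRUE)
  expect_equal(welch$p_value, 0.0035, tolerance = 0.03)
  expect_gt(abs(welch$p_value - 0.0042), abs(cell("na", "LGG/HGG") - 0.0042))
})

test_that("pearson correlation and p-value match the covariance oracle", {
  x <- c(0, 1, 2, 3, 4); y <- c(0, 1, 2, 3, 0)
  r <- pearson_with_p(x, y)
  # brute-force covariance formula
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r$r, r_oracle, tolerance = 1e-12)
  ref <- cor.test(x, y)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(pearson_with_p(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearson_with_p(1:5, -(1:5))$r, -1)
  expect_error(pearson_with_p(rep(1, 5), 1:5), "constant")
  expect_error(pearson_with_p(1:4, 1:5), "equal length")
})

test_that("pearson r is invariant under positive affine transforms", {
  set.seed(10)
  x <- rnorm(20); y <- rnorm(20) + 0.5 * x
  r0 <- pearson_with_p(x, y)$r
  expect_equal(pearson_with_p(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_with_p(x, 0.1 * y - 2)$r, r0, tolerance = 1e-12)
})

test_that("least-squares line matches lm and its residuals are orthogonal", {
  x <- 1:10
  f <- linear_fit(x, 3 * x - 2)
  expect_equal(f$slope, 3); expect_equal(f$intercept, -2)
  set.seed(11)
  xr <- rnorm(10); yr <- rnorm(10)
  fr <- linear_fit(xr, yr)
  res <- yr - (fr$intercept + fr$slope * xr)
  expect_equal(sum(res * xr), 0, tolerance = 1e-10)
  expect_equal(sum(res), 0, tolerance = 1e-10)
  ref <- coef(lm(yr ~ xr))
  expect_equal(fr$intercept, unname(ref[1]), tolerance = 1e-10)
  expect_equal(fr$slope, unname(ref[2]), tolerance = 1e-10)
  expect_error(linear_fit(rep(2, 5), 1:5), "constant x")
})

test_that("grade codes map diagnoses to WHO grades", {
  expect_identical(grade_code("CG"), 0L)
  expect_identical(grade_code("control"), 0L)
  expect_identical(grade_code("DA"), 2L)
  expect_identical(grade_code("OA"), 2L)
  expect_identical(grade_code("AA"), 3L)
  expect_identical(grade_code("GBM"), 4L)
  expect_identical(grade_code("HGG", 4), 4L)
  expect_error(grade_code("HGG", 2), "grade 3 or 4")
  expect_error(grade_code("oligodendroglioma"), "unknown diagnosis")
})

make_samples <- function(n = c(CG = 4, LGG = 5, HGG = 5), jitter = 0.05,
                         seed = 1) {
  set.seed(seed)
  base <- list(CG = c(0, 7, 4.6, 23, 21, 66, 1100, 2.3),
               LGG = c(2, 9.4, 6.3, 43, 30, 62, 3200, 10),
               HGG = c(4, 10.7, 7.1, 55, 34, 60, 4350, 16))
  rows <- list()
  for (g in names(n)) for (i in seq_len(n[[g]])) {
    b <- base[[g]]
    rows[[paste0(g, i)]] <- data.frame(
      sample_id = paste0(g, i), group = g, grade_code = b[1],
      mean_majx = b[2] * (1 + rnorm(1, 0, jitter)),
      mean_minx = b[3] * (1 + rnorm(1, 0, jitter)),
      mean_na = b[4] * (1 + rnorm(1, 0, jitter)),
      mean_np = b[5] * (1 + rnorm(1, 0, jitter)),
      mean_nr = b[6] * (1 + rnorm(1, 0, jitter)),
      mean_nd = b[7] * (1 + rnorm(1, 0, jitter)),
      mean_tna = b[8] * (1 + rnorm(1, 0, jitter)))
  }
  do.call(rbind, rows)
}

test_that("run_group_analysis produces the full report shape", {
  an <- run_group_analysis(make_samples())
  expect_s3_class(an, "glioma_group_analysis")
  expect_identical(nrow(an$summaries), 7L * 3L)
  expect_identical(nrow(an$t_tests), 7L * 3L)
  expect_identical(nrow(an$grade_correlations), 7L)
  expect_identical(nrow(an$density_correlations), 2L)
  expect_true(all(abs(an$grade_correlations$r) <= 1))
  expect_output(print(an), "Correlation with WHO grade")
})

test_that("identical groups give p = 1 and monotone parameters r ~ 1", {
  s <- make_samples(jitter = 0)
  # zero within-group variance, exactly linear in grade code
  s$mean_na <- 20 + 8 * s$grade_code
  an <- suppressWarnings(run_group_analysis(s))
  inc <- an$grade_correlations[an$grade_correlations$parameter == "na", ]
  expect_gt(inc$r, 0.99)
  # two identical groups: copy CG onto LGG
  s2 <- make_samples(n = c(CG = 4, LGG = 4, HGG = 4), jitter = 0.03, seed = 2)
  for (cn in grep("^mean_", names(s2), value = TRUE))
    s2[[cn]][s2$group == "LGG"] <- s2[[cn]][s2$group == "CG"]
  an2 <- run_group_analysis(s2)
  cg_lgg <- an2$t_tests[an2$t_tests$group_pair == "CG/LGG", ]
  expect_true(all(abs(cg_lgg$p_value - 1) < 1e-10))
})

test_that("run_group_analysis validates structure", {
  s <- make_samples()
  expect_error(run_group_analysis(s[s$group != "LGG", ]), "missing groups")
  expect_error(run_group_analysis(s[, -which(names(s) == "mean_nr")]),
               "missing columns")
})
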