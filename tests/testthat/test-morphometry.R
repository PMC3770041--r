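cal1 <- calibration(1)
cal025 <- calibration(0.25)

test_that("nuclear area is pixel count times squared calibration", {
  expect_equal(nucleus_area(mk_square(10), cal1), 100)
  # rasterized disk of radius 20 px at 0.25 um/px vs analytic pi * 5^2
  expect_equal(nucleus_area(mk_disk(20), cal025), pi * 5^2,
               tolerance = 0.01)
  expect_error(nucleus_area(matrix(0L, 5, 5), cal1), "empty region")
})

test_that("digital perimeter meets its disk and square error contracts", {
  # disk radius 40 px at 0.25 um/px: true circumference 2 pi 10 um
  expect_equal(nucleus_perimeter(mk_disk(40), cal025), 2 * pi * 10,
               tolerance = 0.02)
  for (R in c(20, 30, 60, 100)) {
    expect_equal(nucleus_perimeter(mk_disk(R), cal1), 2 * pi * R,
                 tolerance = 0.02)
  }
  # 10x10 px square at 1 um/px: 40 um within 2 um
  expect_equal(nucleus_perimeter(mk_square(10), cal1), 40, tolerance = 2 / 40)
  # single pixel: documented estimator constant
  one <- matrix(0L, 5, 5); one[3, 3] <- 1L
  expect_equal(nucleus_perimeter(one, cal1), 1.7656, tolerance = 1e-3)
  expect_gt(nucleus_perimeter(one, cal1), 0)
  # errors: empty and disconnected regions
  expect_error(nucleus_perimeter(matrix(0L, 4, 4), cal1), "empty")
  two <- matrix(0L, 7, 7); two[2, 2] <- 1L; two[6, 6] <- 1L
  expect_error(nucleus_perimeter(two, cal1), "disconnected")
})

test_that("moment axes recover ellipse diameters and are rotation-stable", {
  # semi-axes 40 and 20 px at 0.25 um/px -> MAJX 20 um, MINX 10 um
  ax <- nucleus_axes(mk_ellipse(40, 20), cal025)
  expect_equal(unname(ax["majx_um"]), 20, tolerance = 0.02)
  expect_equal(unname(ax["minx_um"]), 10, tolerance = 0.02)
  # disk: both axes equal within 2%
  axd <- nucleus_axes(mk_disk(25), cal1)
  expect_equal(unname(axd["majx_um"] / axd["minx_um"]), 1, tolerance = 0.02)
  # 90 degree rotation leaves axes unchanged within 1%
  m <- mk_ellipse(30, 12, theta = pi / 7)
  ax1 <- nucleus_axes(m, cal1)
  ax2 <- nucleus_axes(t(m), cal1)
  expect_equal(unname(ax1), unname(ax2), tolerance = 0.01)
  expect_gte(ax1[["majx_um"]], ax1[["minx_um"]])
  # collinear region is degenerate
  line <- matrix(0L, 5, 9); line[3, 2:8] <- 1L
  expect_error(nucleus_axes(line, cal1), "collinear")
  expect_error(nucleus_axes(matrix(c(1L, 1L), 1, 2), cal1), ">= 3 pixels")
})

test_that("nuclear roundness follows its closed form", {
  expect_equal(nuclear_roundness(pi, 2 * pi), 100)
  expect_equal(nuclear_roundness(1, 4), 400 * pi / 16)
  expect_error(nuclear_roundness(1, 0), "division")
  expect_error(nuclear_roundness(-1, 2), "invalid parameter")
})

test_that("roundness of rasterized disks stays in the calibration band", {
  set.seed(9)
  for (R in seq(10, 100, by = 10)) {
    for (off in list(c(0, 0), c(0.5, 0.5), runif(2) - 0.5)) {
      m <- mk_disk(R, off[1], off[2])
      nr <- nuclear_roundness(nucleus_area(m, cal1),
                              nucleus_perimeter(m, cal1))
      expect_gte(nr, 98); expect_lte(nr, 102)
    }
  }
})

test_that("shape factor is scale invariant while size parameters scale", {
  nr_of <- function(m, cal) nuclear_roundness(nucleus_area(m, cal),
                                              nucleus_perimeter(m, cal))
  m1 <- mk_ellipse(20, 12); m2 <- mk_ellipse(60, 36)
  expect_equal(nr_of(m1, cal1), nr_of(m2, cal1), tolerance = 0.01)
  expect_gt(nucleus_area(m2, cal1), nucleus_area(m1, cal1))
  # calibration rescale: NA, NP scale, NR unchanged
  expect_equal(nr_of(m1, cal1), nr_of(m1, cal025), tolerance = 1e-12)
  expect_equal(nucleus_area(m1, cal025), nucleus_area(m1, cal1) / 16)
})

test_that("measure_nucleus composes measures and sets flags", {
  img <- matrix(0L, 30, 40)
  img[10:20, 5:15] <- 1L            # interior square nucleus
  img[1:4, 25:30] <- 2L             # touches the top border
  img[10:14, 20:24] <- 3L           # 8-adjacent pair
  img[10:14, 25:29] <- 4L
  cal <- calibration(1)
  r1 <- measure_nucleus(1L, img, cal)
  expect_equal(r1$na_um2, 121)
  expect_false(r1$border_touching); expect_true(r1$separated)
  expect_true(measure_nucleus(2L, img, cal)$border_touching)
  expect_false(measure_nucleus(3L, img, cal)$separated)
  expect_false(measure_nucleus(4L, img, cal)$separated)
  expect_error(measure_nucleus(9L, img, cal), "not found")
})

test_that("measure_field computes counts, density and %TNA", {
  img <- matrix(0L, 100, 100)
  img[2:6, 2:51] <- 1L   # 250 pixels
  cal <- calibration(1)  # 100x100 um = 0.01 mm^2
  f <- measure_field(img, cal)
  expect_identical(f$nucleus_count, 1L)
  expect_equal(f$nd_per_mm2, 1 / 0.01)
  expect_equal(f$tna_pct, 2.5)
  # all-zero image
  f0 <- measure_field(matrix(0L, 10, 10), cal)
  expect_identical(f0$nucleus_count, 0L)
  expect_equal(f0$nd_per_mm2, 0); expect_equal(f0$tna_pct, 0)
  expect_error(measure_field(matrix(0L, 0, 0), cal), "zero-sized")
})

test_that("whole-field measurement agrees with the single-nucleus path", {
  set.seed(12)
  cfg <- cohort_config(fields_per_sample = 1L, field_width_um = 80,
                       field_height_um = 60, seed = 12L)
  polys <- lapply(runif(12, 25, 70), function(a)
    generate_nucleus_polygon(a, 1.5, 0.3))
  env <- asNamespace("gliomorph")
  placed <- env$place_nuclei(polys, cfg)
  img <- render_field(placed, cfg)$image
  cal <- calibration(0.25)
  f <- measure_field(img, cal)
  for (k in seq_len(nrow(f$nuclei))) {
    single <- measure_nucleus(f$nuclei$label_id[k], img, cal)
    expect_equal(f$nuclei$na_um2[k], single$na_um2)
    expect_equal(f$nuclei$np_um[k], single$np_um, tolerance = 1e-10)
    expect_equal(f$nuclei$majx_um[k], single$majx_um, tolerance = 1e-6)
    expect_equal(f$nuclei$border_touching[k], single$border_touching)
    expect_equal(f$nuclei$separated[k], single$separated)
  }
  # label count conservation
  expect_identical(f$nucleus_count, length(placed))
})

test_that("field selection keeps the k most cellular fields", {
  mk_f <- function(id, count) structure(
    list(field_id = id, nucleus_count = count, nd_per_mm2 = 0, tna_pct = 0,
         nuclei = NULL), class = "field_record")
  fields <- lapply(1:8, function(i) mk_f(i, i * 10))
  sel <- select_fields(fields, 5)
  expect_setequal(vapply(sel, function(f) f$nucleus_count, numeric(1)),
                  c(40, 50, 60, 70, 80))
  expect_warning(sel3 <- select_fields(fields[1:3], 5), "only 3")
  expect_length(sel3, 3)
  # tie at the cutoff: lower field id retained
  tied <- list(mk_f(1, 10), mk_f(2, 5), mk_f(3, 5))
  sel2 <- select_fields(tied, 2)
  expect_setequal(vapply(sel2, function(f) f$field_id, numeric(1)), c(1, 2))
  expect_error(select_fields(list(), 5), "empty")
})

test_that("nucleus selection filters flags then takes the largest", {
  rec <- data.frame(
    sample_id = "s", field_id = rep(1:3, each = 50), label_id = rep(1:50, 3),
    na_um2 = runif(150, 10, 90), np_um = 1, nr_pct = 50,
    majx_um = 1, minx_um = 1,
    border_touching = rep(c(FALSE, TRUE), c(140, 10)),
    separated = rep(c(TRUE, FALSE), c(130, 20)))
  sel <- select_nuclei(rec, 100)
  expect_identical(nrow(sel), 100L)
  eligible <- rec[rec$separated & !rec$border_touching, ]
  expect_equal(sort(sel$na_um2, decreasing = TRUE),
               sort(eligible$na_um2, decreasing = TRUE)[1:100])
  expect_warning(select_nuclei(rec[1:40, ], 100), "only")
  allbad <- rec; allbad$border_touching <- TRUE
  expect_warning(s0 <- select_nuclei(allbad, 100), "no eligible")
  expect_identical(nrow(s0), 0L)
})

test_that("sample summaries are means over nuclei and fields", {
  nuc <- data.frame(sample_id = "s", field_id = 1, label_id = 1:2,
                    majx_um = c(8, 10), minx_um = c(5, 7),
                    na_um2 = c(30, 50), np_um = c(20, 26),
                    nr_pct = c(90, 80), border_touching = FALSE,
                    separated = TRUE)
  f <- structure(list(field_id = 1, nucleus_count = 2L, nd_per_mm2 = 1500,
                      tna_pct = 4, nuclei = nuc), class = "field_record")
  s <- summarize_sample("s", "CG", 0, list(f), nuc)
  expect_equal(s$mean_na, 40); expect_equal(s$mean_nr, 85)
  expect_equal(s$mean_nd, 1500); expect_equal(s$mean_tna, 4)
  # duplicating every nucleus leaves means unchanged
  s2 <- summarize_sample("s", "CG", 0, list(f), rbind(nuc, nuc))
  expect_equal(s2$mean_na, s$mean_na); expect_equal(s2$mean_majx, s$mean_majx)
  expect_error(summarize_sample("s", "CG", 0, list(), nuc), "no fields")
  expect_error(summarize_sample("s", "CG", 0, list(f), nuc[0, ]), "no nuclei")
})
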