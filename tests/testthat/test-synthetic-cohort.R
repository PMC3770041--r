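test_that("rasterization matches a pixel-center-in-polygon oracle", {
  cfg <- cohort_config(fields_per_sample = 1L, field_width_um = 30,
                       field_height_um = 25, microns_per_pixel = 0.25)
  # 10 um x 10 um square at 0.25 um/px: ~1600 pixels
  sq <- list(vertices = cbind(c(10, 20, 20, 10), c(8, 8, 18, 18)),
             centroid = c(15, 13), true_area_um2 = 100,
             true_perimeter_um = 40, true_majx_um = NA, true_minx_um = NA,
             true_nr = NA)
  r <- render_field(list(sq), cfg)
  expect_equal(sum(r$image == 1L), 1600, tolerance = 80 / 1600)
  # irregular triangle vs independent winding-number oracle (vertices off
  # the pixel-center lattice so no center lies exactly on an edge)
  tri <- list(vertices = cbind(c(5.13, 21.87, 12.29), c(4.21, 7.03, 19.77)),
              centroid = c(13, 10.33), true_area_um2 = 1,
              true_perimeter_um = 1, true_majx_um = NA, true_minx_um = NA,
              true_nr = NA)
  r2 <- render_field(list(tri), cfg)
  dims <- dim(r2$image)
  for (k in 1:300) {
    i <- sample(dims[1], 1); j <- sample(dims[2], 1)
    inside <- winding_inside((j - 1) * 0.25, (i - 1) * 0.25, tri$vertices)
    expect_identical(r2$image[i, j] == 1L, inside)
  }
})

test_that("empty fields and overlap violations are handled", {
  cfg <- cohort_config(fields_per_sample = 1L, field_width_um = 30,
                       field_height_um = 25)
  r <- render_field(list(), cfg)
  expect_true(all(r$image == 0L))
  expect_identical(nrow(r$ground_truth), 0L)
  set.seed(5)
  p1 <- generate_nucleus_polygon(50, 1, 0)
  p2 <- generate_nucleus_polygon(50, 1, 0)
  place_at <- function(p, x, y) {
    p$centroid <- c(x, y); p$vertices <- sweep(p$vertices, 2, c(-x, -y)); p
  }
  expect_error(render_field(list(place_at(p1, 12, 12), place_at(p2, 13, 12)),
                            cfg), "placement rejection")
  expect_error(render_field(list(place_at(p1, 2, 2)), cfg),
               "placement rejection")
})

test_that("cohort generation is seed-reproducible and seed-sensitive", {
  cfg <- small_cohort_config(seed = 21L)
  c1 <- quiet_cohort(cfg)
  c2 <- quiet_cohort(cfg)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$samples$CG01$fields[[1]]$image,
                   c2$samples$CG01$fields[[1]]$image)
  cfg2 <- small_cohort_config(seed = 22L)
  c3 <- quiet_cohort(cfg2)
  expect_false(identical(c1$manifest$drawn_mean_area_um2,
                         c3$manifest$drawn_mean_area_um2))
})

test_that("written cohorts are byte-identical across reruns", {
  cfg <- small_cohort_config(seed = 31L, n_samples = 1L,
                             fields_per_sample = 1L)
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  write_cohort(quiet_cohort(cfg), d1)
  write_cohort(quiet_cohort(cfg), d2)
  for (f in c("CG01_f1.tif", "ground_truth.csv", "manifest.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("per-sample mean areas track the group-level target", {
  # CG spec, 10 samples: grand mean of drawn per-sample means should sit
  # within ~3 standard errors (4.01/sqrt(10) = 1.27) of 23.44
  specs <- default_group_specs()
  cfg <- cohort_config(list(CG = specs$CG), fields_per_sample = 1L,
                       field_width_um = 60, field_height_um = 50, seed = 41L)
  coh <- generate_cohort(cfg, render = FALSE)
  per_sample <- unique(coh$manifest[, c("sample_id", "drawn_mean_area_um2")])
  expect_equal(mean(per_sample$drawn_mean_area_um2), 23.44, tolerance = 4 / 23.44)
})

test_that("grade mixtures follow the case spectrum", {
  specs <- default_group_specs()
  grades <- integer(0)
  for (seed in 1:8) {
    cfg <- cohort_config(list(HGG = specs$HGG), fields_per_sample = 1L,
                         field_width_um = 40, field_height_um = 30,
                         seed = 100L + seed)
    coh <- quiet_cohort(cfg, render = FALSE)
    grades <- c(grades, unique(coh$manifest[, c("sample_id", "grade_code")])$grade_code)
  }
  expect_true(all(grades %in% c(3L, 4L)))
  # 13/16 glioblastoma: proportion of grade 4 over many draws
  expect_equal(mean(grades == 4L), 13 / 16, tolerance = 0.12)
  cfgc <- cohort_config(list(CG = default_group_specs()$CG),
                        fields_per_sample = 1L, field_width_um = 40,
                        field_height_um = 30, seed = 7L)
  expect_true(all(quiet_cohort(cfgc, render = FALSE)$manifest$grade_code == 0L))
})

test_that("group_spec and cohort_config validate their inputs", {
  expect_error(group_spec("XX", 5, 0L, 1, 20, 2, 0.1, 1000, 100, 1.5, 0.1),
               "label")
  expect_error(group_spec("CG", 5, c(0L, 2L), c(0.5, 0.6), 20, 2, 0.1,
                          1000, 100, 1.5, 0.1), "sum to 1")
  expect_error(group_spec("CG", 5, 0L, 1, -20, 2, 0.1, 1000, 100, 1.5, 0.1),
               "> 0")
  expect_error(group_spec("CG", 5, 0L, 1, 20, 2, 0.1, 1000, 100, 1.5, 0.6),
               "irregularity")
  expect_error(cohort_config(fields_per_sample = 0), "fields_per_sample")
  expect_error(cohort_config(field_width_um = -1), "dimensions")
})

test_that("generated ground truth respects the isoperimetric bound", {
  cfg <- small_cohort_config(seed = 51L, n_samples = 1L,
                             fields_per_sample = 1L)
  gt <- cohort_ground_truth(quiet_cohort(cfg, render = FALSE))
  expect_true(all(gt$true_nr <= 100))
  expect_true(all(gt$true_nr > 0))
  expect_true(all(gt$true_majx_um >= gt$true_minx_um))
})
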