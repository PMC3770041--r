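#' Pipeline stages: simulate, measure, analyze
#'
#' The pipeline's stage boundaries are files (TIFF label images and CSV
#' tables), so each stage is independently runnable, testable and
#' replaceable. Each stage writes a JSON run manifest recording the seed,
#' package version and MD5 hashes of its outputs; rerunning a stage with an
#' identical configuration reproduces identical data files byte for byte.
#'
#' @name pipeline
NULL

stage_manifest <- function(dir, stage, config_snapshot, seed, files) {
  mf <- list(
    stage = stage,
    tool = "gliomorph",
    version = as.character(utils::packageVersion("gliomorph")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config_snapshot,
    outputs = as.list(tools::md5sum(sort(files)))
  )
  path <- file.path(dir, sprintf("run_manifest_%s.json", stage))
  jsonlite::write_json(mf, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Simulate stage: generate a cohort onto disk
#'
#' @param config a \code{\link{cohort_config}} or path to a YAML config.
#' @param out_dir output directory.
#' @param seed optional override of the config seed.
#' @return Invisibly, the output directory.
#' @export
cmd_simulate <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_cohort_config(config)
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cohort <- generate_cohort(config)
  files <- write_cohort(cohort, out_dir)
  stage_manifest(out_dir, "simulate", config_to_list(config), config$seed,
                 files)
  message(sprintf("simulate: %d samples, %d fields -> %s",
                  length(cohort$samples), nrow(cohort$manifest), out_dir))
  invisible(out_dir)
}

#' Measure stage: label images to feature tables
#'
#' Reads every \code{<sample>_f<k>.tif}/\code{.png} in \code{in_dir},
#' measures it, applies the 5-field / 100-nucleus selection rules per sample
#' and writes \code{nuclei.csv}, \code{fields.csv} and \code{samples.csv}.
#' Group and grade columns are joined from \code{manifest.csv} when present.
#' Corrupt image files are reported and skipped; the run continues.
#'
#' @param in_dir directory of label images.
#' @param microns_per_pixel calibration (um per pixel).
#' @param out_dir output directory for the CSVs.
#' @param fields_per_sample,nuclei_per_sample selection rule sizes.
#' @return Invisibly, the per-sample data frame.
#' @export
cmd_measure <- function(in_dir, microns_per_pixel, out_dir,
                        fields_per_sample = 5L, nuclei_per_sample = 100L) {
  if (missing(microns_per_pixel) || is.null(microns_per_pixel))
    stop("calibration missing: supply microns_per_pixel")
  paths <- list.files(in_dir, pattern = "_f[0-9]+\\.(tif|tiff|png)$",
                      full.names = TRUE)
  if (!length(paths)) stop("no label images found in ", in_dir)
  cal <- calibration(microns_per_pixel)
  ids <- sub("_f[0-9]+\\.(tif|tiff|png)$", "", basename(paths))
  fid <- as.integer(sub(".*_f([0-9]+)\\.(tif|tiff|png)$", "\\1",
                        basename(paths)))
  failed <- character(0)

  meta <- NULL
  mpath <- file.path(in_dir, "manifest.csv")
  if (file.exists(mpath)) {
    mm <- utils::read.csv(mpath)
    if (all(c("sample_id", "group", "grade_code") %in% names(mm)))
      meta <- unique(mm[, c("sample_id", "group", "grade_code")])
  }

  sample_rows <- list(); field_rows <- list(); nuc_rows <- list()
  for (sid in unique(ids)) {
    sel <- which(ids == sid)
    frecs <- list()
    for (k in sel) {
      rec <- tryCatch(
        measure_field(read_label_image(paths[k]), cal, sample_id = sid,
                      field_id = fid[k]),
        error = function(e) {
          failed <<- c(failed, sprintf("%s: %s", basename(paths[k]),
                                       conditionMessage(e)))
          NULL
        })
      if (!is.null(rec)) frecs[[length(frecs) + 1L]] <- rec
    }
    if (!length(frecs)) next
    sel_fields <- select_fields(frecs, fields_per_sample)
    sel_ids <- vapply(sel_fields, function(f) as.integer(f$field_id),
                      integer(1))
    nuc <- do.call(rbind, lapply(frecs, function(f) f$nuclei))
    chosen <- select_nuclei(nuc[nuc$field_id %in% sel_ids, , drop = FALSE],
                            nuclei_per_sample)
    grp <- NA_character_; grd <- NA_integer_
    if (!is.null(meta) && sid %in% meta$sample_id) {
      grp <- meta$group[meta$sample_id == sid][1]
      grd <- meta$grade_code[meta$sample_id == sid][1]
    }
    sample_rows[[sid]] <- summarize_sample(sid, grp, grd, sel_fields, chosen)
    field_rows[[sid]] <- data.frame(
      sample_id = sid,
      field_id = vapply(frecs, function(f) as.integer(f$field_id), integer(1)),
      nucleus_count = vapply(frecs, function(f) f$nucleus_count, integer(1)),
      nd_per_mm2 = vapply(frecs, function(f) f$nd_per_mm2, numeric(1)),
      tna_pct = vapply(frecs, function(f) f$tna_pct, numeric(1)))
    nuc_rows[[sid]] <- nuc
  }
  if (length(failed))
    warning(sprintf("%d image(s) could not be measured:\n  %s",
                    length(failed), paste(failed, collapse = "\n  ")))
  if (!length(sample_rows)) stop("no measurable samples")

  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  samples <- do.call(rbind, c(sample_rows, list(make.row.names = FALSE)))
  out <- c(samples = file.path(out_dir, "samples.csv"),
           fields = file.path(out_dir, "fields.csv"),
           nuclei = file.path(out_dir, "nuclei.csv"))
  utils::write.csv(samples, out["samples"], row.names = FALSE)
  utils::write.csv(do.call(rbind, c(field_rows, list(make.row.names = FALSE))),
                   out["fields"], row.names = FALSE)
  utils::write.csv(do.call(rbind, c(nuc_rows, list(make.row.names = FALSE))),
                   out["nuclei"], row.names = FALSE)
  stage_manifest(out_dir, "measure",
                 list(in_dir = in_dir, microns_per_pixel = microns_per_pixel,
                      fields_per_sample = fields_per_sample,
                      nuclei_per_sample = nuclei_per_sample),
                 NA, unname(out))
  message(sprintf("measure: %d samples -> %s", nrow(samples), out_dir))
  invisible(samples)
}

#' Analyze stage: statistical reports
#'
#' In the default mode, consumes a per-sample CSV (from \code{cmd_measure})
#' and writes the group summary/t-test table, the grade and density
#' correlations and per-sample area-distribution exports. With
#' \code{from_summary = TRUE} the input is a published-style summary CSV
#' (parameter, group, n, mean, sd) and only the pairwise t-tests are
#' computed — no raw data or images needed.
#'
#' @param input path to a CSV, or a data frame.
#' @param out_dir output directory.
#' @param from_summary logical; treat input as group summaries.
#' @param nuclei optional per-nucleus CSV path or data frame (for
#'   area-distribution exports when \code{input} is per-sample).
#' @return Invisibly, the \code{glioma_group_analysis} (or the t-test data
#'   frame in summary mode).
#' @export
cmd_analyze <- function(input, out_dir, from_summary = FALSE, nuclei = NULL) {
  df <- if (is.character(input)) utils::read.csv(input) else input
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  if (from_summary) {
    tt <- t_tests_from_summary(df)
    path <- file.path(out_dir, "t_tests.csv")
    utils::write.csv(tt, path, row.names = FALSE)
    stage_manifest(out_dir, "analyze", list(mode = "summary"), NA, path)
    message(sprintf("analyze (summary mode): %d tests -> %s", nrow(tt), path))
    return(invisible(tt))
  }
  an <- run_group_analysis(df)
  files <- c(file.path(out_dir, "group_summaries.csv"),
             file.path(out_dir, "t_tests.csv"),
             file.path(out_dir, "grade_correlations.csv"),
             file.path(out_dir, "density_correlations.csv"))
  utils::write.csv(an$summaries, files[1], row.names = FALSE)
  utils::write.csv(an$t_tests, files[2], row.names = FALSE)
  utils::write.csv(an$grade_correlations, files[3], row.names = FALSE)
  utils::write.csv(an$density_correlations, files[4], row.names = FALSE)
  if (!is.null(nuclei)) {
    nd <- if (is.character(nuclei)) utils::read.csv(nuclei) else nuclei
    dist_rows <- list()
    for (sid in unique(nd$sample_id)) {
      a <- nd$na_um2[nd$sample_id == sid]
      if (length(a) < 2) next
      d <- as.data.frame(add_gaussian_model(area_histogram(a)))
      d <- cbind(sample_id = sid, d)
      dist_rows[[sid]] <- d
    }
    if (length(dist_rows)) {
      f <- file.path(out_dir, "area_distributions.csv")
      utils::write.csv(do.call(rbind, c(dist_rows,
                                        list(make.row.names = FALSE))),
                       f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  gm <- merge(stats::aggregate(mean_na ~ group, df, mean),
              stats::aggregate(mean_na ~ group, df, stats::sd),
              by = "group", suffixes = c(".m", ".s"))
  curves <- group_model_curves(data.frame(group = gm$group,
                                          mean = gm$mean_na.m,
                                          sd = gm$mean_na.s))
  f <- file.path(out_dir, "group_model_curves.csv")
  utils::write.csv(curves, f, row.names = FALSE)
  files <- c(files, f)
  stage_manifest(out_dir, "analyze", list(mode = "samples"), NA, files)
  message(sprintf("analyze: %d samples -> %s", nrow(df), out_dir))
  invisible(an)
}
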