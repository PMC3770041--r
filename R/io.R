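#' Label image I/O
#'
#' Label rasters are stored as 16-bit single-channel TIFF (integer labels
#' 0..65535, background 0), written and read losslessly. 8- or 16-bit
#' single-channel PNG is accepted on input; PNG output is 8-bit (labels up
#' to 255) because the PNG writer does not support greater depth — use TIFF
#' for denser fields.
#'
#' @param img integer matrix of labels.
#' @param path output file; extension selects the format (.tif/.tiff/.png).
#' @return \code{path}, invisibly.
#' @export
write_label_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (max(img) > 65535L) stop("label count exceeds 16-bit capacity")
    tiff::writeTIFF(img / 65535, path, bits.per.sample = 16,
                    compression = "none")
  } else if (ext == "png") {
    if (max(img) > 255L)
      stop("label count exceeds 8-bit PNG capacity; write TIFF instead")
    png::writePNG(img / 255, path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    v <- png::readPNG(path)
    # readPNG rescales to [0, 1] by the source bit depth; recover integers
    # (8-bit: x * 255 integral; 16-bit: x * 65535 integral)
    if (length(dim(v)) == 3L) v <- v[, , 1]
    v8 <- v * 255
    if (max(abs(v8 - round(v8))) < 1e-9) round(v8) else round(v * 65535)
  } else stop("unsupported image format: ", ext)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  storage.mode(m) <- "integer"
  m
}

config_to_list <- function(config) {
  list(
    fields_per_sample = config$fields_per_sample,
    field_width_um = config$field_width_um,
    field_height_um = config$field_height_um,
    microns_per_pixel = config$microns_per_pixel,
    seed = config$seed,
    groups = lapply(unname(config$group_specs), unclass)
  )
}

#' Read / write a cohort configuration as YAML
#'
#' The YAML mirrors \code{\link{cohort_config}} fields, with one block per
#' group mirroring \code{\link{group_spec}}.
#'
#' @param config a \code{cohort_config}.
#' @param path YAML file path.
#' @return For \code{read_cohort_config}, a \code{cohort_config}.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  for (key in c("fields_per_sample", "field_width_um", "field_height_um",
                "microns_per_pixel", "seed", "groups"))
    if (is.null(x[[key]]))
      stop(sprintf("config validation error: missing key '%s'", key))
  specs <- lapply(x$groups, function(g) {
    need <- c("label", "n_samples", "grade_codes", "grade_probs",
              "na_mean_um2", "na_sd_um2", "within_sample_cv",
              "density_mean_per_mm2", "density_sd_per_mm2",
              "aspect_ratio_mean", "irregularity")
    for (key in need)
      if (is.null(g[[key]]))
        stop(sprintf("config validation error: missing group key '%s'", key))
    group_spec(g$label, g$n_samples, g$grade_codes, g$grade_probs,
               g$na_mean_um2, g$na_sd_um2, g$within_sample_cv,
               g$density_mean_per_mm2, g$density_sd_per_mm2,
               g$aspect_ratio_mean, g$irregularity,
               irregularity_sd = g$irregularity_sd %||% 0.02,
               field_effect_cv = g$field_effect_cv %||% 0)
  })
  names(specs) <- vapply(specs, function(s) s$label, character(1))
  cohort_config(specs, x$fields_per_sample, x$field_width_um,
                x$field_height_um, x$microns_per_pixel, x$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a generated cohort to disk
#'
#' One 16-bit TIFF per field (\code{<sample>_f<k>.tif}), the pooled
#' ground-truth table and the manifest as CSV, and the configuration as YAML.
#' Output is byte-stable for a fixed config (no timestamps in data files).
#'
#' @param cohort a \code{glioma_cohort} (rendered).
#' @param dir output directory (created if needed).
#' @return Character vector of written files, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "glioma_cohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  files <- character(0)
  for (s in cohort$samples) for (f in s$fields) {
    if (is.null(f$image)) stop("cohort was generated with render = FALSE")
    p <- file.path(dir, sprintf("%s_f%d.tif", s$sample_id, f$field_id))
    write_label_image(f$image, p)
    files <- c(files, p)
  }
  gt <- file.path(dir, "ground_truth.csv")
  utils::write.csv(cohort_ground_truth(cohort), gt, row.names = FALSE)
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(cohort$manifest, mf, row.names = FALSE)
  cf <- file.path(dir, "config.yaml")
  write_cohort_config(cohort$config, cf)
  invisible(c(files, gt, mf, cf))
}
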