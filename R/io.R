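# File interchange: 16-bit single-channel TIFFs for images, CSV for tables,
# YAML for configs and fitted transforms.

#' Read and write single-channel 16-bit TIFF images
#'
#' Images are stored one file per channel as 16-bit grayscale TIFF. In
#' memory an image is a numeric matrix indexed `[x, y]` in camera counts
#' (0-65535); on disk the usual row-major raster layout is used.
#'
#' @param path file path.
#' @param img image matrix in counts.
#' @return `readChannelImage`: image matrix in counts.
#' @export
readChannelImage <- function(path) {
  raster <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(raster)) == 3L) raster <- raster[, , 1]
  t(raster) * 65535
}

#' @rdname readChannelImage
#' @export
writeChannelImage <- function(img, path) {
  tiff::writeTIFF(t(clampCounts(round(img))) / 65535, path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Write a simulated assay to a directory
#'
#' Writes one 16-bit TIFF per chip channel (`chip_<channel>.tif`), the
#' membrane pair (`membrane_imprint.tif`, `membrane_psa.tif`), the ground
#' truth and calibration standards as CSV, the configuration as YAML and a
#' `manifest.yaml` recording the seed and file inventory.
#'
#' @param assay a [NanowellAssay-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeAssay <- function(assay, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (ch in names(assay@chipImages)) {
    f <- file.path(dir, paste0("chip_", ch, ".tif"))
    writeChannelImage(assay@chipImages[[ch]], f)
    files <- c(files, basename(f))
  }
  writeChannelImage(assay@imprintImage, file.path(dir, "membrane_imprint.tif"))
  writeChannelImage(assay@psaImage, file.path(dir, "membrane_psa.tif"))
  utils::write.csv(assay@truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(assay@standards, file.path(dir, "standards.csv"),
                   row.names = FALSE)
  writeAssayConfig(assay@config, file.path(dir, "config.yaml"))
  writeGridTransform(assay@transform, file.path(dir, "true_transform.yaml"))
  yaml::write_yaml(list(seed = assay@config@seed,
                        files = c(files, "membrane_imprint.tif",
                                  "membrane_psa.tif", "ground_truth.csv",
                                  "standards.csv", "config.yaml",
                                  "true_transform.yaml")),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Serialize assay configurations and fitted transforms to YAML
#'
#' @param config an [AssayConfig-class].
#' @param transform a [GridTransform-class].
#' @param path file path.
#' @return read functions return the reconstructed object; write functions
#'   return `path` invisibly.
#' @export
writeAssayConfig <- function(config, path) {
  yaml::write_yaml(list(
    n_rows = config@nRows, n_cols = config@nCols, pitch_um = config@pitchUm,
    um_per_px = config@umPerPx, well_radius_um = config@wellRadiusUm,
    imprint_radius_um = config@imprintRadiusUm, n_cells = config@nCells,
    phenotype_mix = as.list(config@phenotypeMix),
    intensity_sdlog = config@intensitySdLog,
    secretion_pg_range = config@secretionPgRange,
    spot_radius_range_um = config@spotRadiusRangeUm,
    calib_slope = config@calibSlope, calib_intercept = config@calibIntercept,
    chip_background = config@chipBackground,
    membrane_background = config@membraneBackground,
    noise_sd = config@noiseSd, imprint_contrast = config@imprintContrast,
    transform_scale = config@transformScale,
    transform_rotation_deg = config@transformRotationDeg,
    transform_translation_px = config@transformTranslationPx,
    seed = config@seed), path)
  invisible(path)
}

#' @rdname writeAssayConfig
#' @export
readAssayConfig <- function(path) {
  v <- yaml::read_yaml(path)
  assayConfig(n_rows = v$n_rows, n_cols = v$n_cols, pitch_um = v$pitch_um,
              um_per_px = v$um_per_px, well_radius_um = v$well_radius_um,
              imprint_radius_um = v$imprint_radius_um, n_cells = v$n_cells,
              phenotype_mix = unlist(v$phenotype_mix),
              intensity_sdlog = v$intensity_sdlog,
              secretion_pg_range = v$secretion_pg_range,
              spot_radius_range_um = v$spot_radius_range_um,
              calib_slope = v$calib_slope,
              calib_intercept = v$calib_intercept,
              chip_background = v$chip_background,
              membrane_background = v$membrane_background,
              noise_sd = v$noise_sd, imprint_contrast = v$imprint_contrast,
              transform_scale = v$transform_scale,
              transform_rotation_deg = v$transform_rotation_deg,
              transform_translation_px = v$transform_translation_px,
              seed = v$seed)
}

#' @rdname writeAssayConfig
#' @export
writeGridTransform <- function(transform, path) {
  yaml::write_yaml(list(scale = transform@scale,
                        rotation_deg = transform@rotationDeg,
                        tx = transform@translationPx[1],
                        ty = transform@translationPx[2],
                        rms = transform@rmsResidual,
                        n_support = transform@nSupport), path)
  invisible(path)
}

#' @rdname writeAssayConfig
#' @export
readGridTransform <- function(path) {
  v <- yaml::read_yaml(path)
  gridTransform(scale = v$scale, rotation_deg = v$rotation_deg,
                translation_px = c(v$tx, v$ty),
                rms_residual = if (is.null(v$rms)) NA_real_ else v$rms,
                n_support = if (is.null(v$n_support)) 0L else v$n_support)
}

#' Read a calibration-standards CSV
#'
#' Expected columns: `concentration_ug_per_ml`, `volume_ul`, `area_um2`,
#' `normalized_intensity`.
#'
#' @param path CSV file path.
#' @return data.frame of standards.
#' @export
readCalibrationStandards <- function(path) {
  std <- utils::read.csv(path)
  stopIfMissingCols(std, c("concentration_ug_per_ml", "volume_ul",
                           "area_um2", "normalized_intensity"),
                    "standards CSV")
  std
}

#' Read an enumeration event table CSV
#'
#' Expected columns: `ck_intensity`, `psma_intensity` and logical
#' `dapi_positive`/`cd45_positive` (or numeric `cd45_intensity`).
#'
#' @param path CSV file path.
#' @return data.frame of events.
#' @export
readEventTable <- function(path) {
  ev <- utils::read.csv(path)
  stopIfMissingCols(ev, c("ck_intensity", "psma_intensity"), "event CSV")
  ev
}
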