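#' @import methods
NULL

PHENOTYPES <- c("psma_pos_secretor", "psma_neg_secretor",
                "psma_pos_nonsecretor", "psma_neg_nonsecretor",
                "leukocyte")

CHIP_CHANNELS <- c("calcein", "psma", "cd45")

#' Well lattice geometry of a nanowell chip scan
#'
#' `WellLayout` describes the regular square lattice of wells in pixel
#' coordinates of the chip scan: lattice dimensions, pitch, origin (center of
#' the first well, i.e. row 1 / column 1), and the radius of the disc over
#' which per-well intensities are averaged. Well ids are row-major starting
#' at 1: `well_id = (row - 1) * n_cols + col`.
#'
#' @slot nRows,nCols integer lattice dimensions.
#' @slot pitchPx center-to-center well spacing in pixels.
#' @slot originPx numeric length-2, pixel position `(x, y)` of well 1's center.
#' @slot wellRadiusPx radius in pixels of the well measurement disc.
#' @export
setClass("WellLayout",
  representation(nRows = "integer", nCols = "integer", pitchPx = "numeric",
                 originPx = "numeric", wellRadiusPx = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@nRows < 1L || object@nCols < 1L)
      msg <- c(msg, "nRows and nCols must be >= 1")
    if (length(object@originPx) != 2L)
      msg <- c(msg, "originPx must have length 2")
    if (object@pitchPx <= 0) msg <- c(msg, "pitchPx must be > 0")
    if (object@wellRadiusPx <= 0) msg <- c(msg, "wellRadiusPx must be > 0")
    if (object@wellRadiusPx > object@pitchPx / 2)
      msg <- c(msg, "wellRadiusPx must not exceed pitchPx/2 (wells overlap)")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a [WellLayout-class]
#'
#' @param n_rows,n_cols lattice dimensions.
#' @param pitch_px well pitch in pixels.
#' @param origin_px pixel center `(x, y)` of well 1 (row 1, column 1).
#' @param well_radius_px measurement-disc radius in pixels.
#' @return a `WellLayout` object.
#' @examples
#' wellLayout(80, 80, pitch_px = 50)
#' @export
wellLayout <- function(n_rows, n_cols, pitch_px,
                       origin_px = c(pitch_px / 2, pitch_px / 2),
                       well_radius_px = pitch_px / 4) {
  new("WellLayout", nRows = as.integer(n_rows), nCols = as.integer(n_cols),
      pitchPx = as.numeric(pitch_px), originPx = as.numeric(origin_px),
      wellRadiusPx = as.numeric(well_radius_px))
}

#' Chip-to-membrane similarity transform
#'
#' A 2D similarity transform `p' = scale * R(rotation) %*% p + translation`
#' mapping chip-scan pixel coordinates to membrane-image pixel coordinates,
#' together with the fit diagnostics reported by [fitGridTransform()].
#'
#' @slot scale unitless isotropic scale factor (> 0).
#' @slot rotationDeg rotation angle in degrees, counter-clockwise.
#' @slot translationPx numeric length-2 translation `(tx, ty)` in pixels.
#' @slot rmsResidual root-mean-square registration residual in membrane
#'   pixels (`NA` for analytically constructed transforms).
#' @slot nSupport number of lattice points supporting the fit.
#' @export
setClass("GridTransform",
  representation(scale = "numeric", rotationDeg = "numeric",
                 translationPx = "numeric", rmsResidual = "numeric",
                 nSupport = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@scale <= 0) msg <- c(msg, "scale must be > 0")
    if (length(object@translationPx) != 2L)
      msg <- c(msg, "translationPx must have length 2")
    if (!is.na(object@rmsResidual) && object@rmsResidual < 0)
      msg <- c(msg, "rmsResidual must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a [GridTransform-class]
#'
#' @param scale isotropic scale factor.
#' @param rotation_deg rotation in degrees (counter-clockwise).
#' @param translation_px translation `(tx, ty)` in pixels.
#' @param rms_residual,n_support fit diagnostics (optional).
#' @return a `GridTransform` object.
#' @examples
#' gridTransform(rotation_deg = 2, translation_px = c(12.3, -7.8))
#' @export
gridTransform <- function(scale = 1, rotation_deg = 0,
                          translation_px = c(0, 0),
                          rms_residual = NA_real_, n_support = 0L) {
  new("GridTransform", scale = as.numeric(scale),
      rotationDeg = as.numeric(rotation_deg),
      translationPx = as.numeric(translation_px),
      rmsResidual = as.numeric(rms_residual),
      nSupport = as.integer(n_support))
}

#' Linear standard-curve model for secretion spots
#'
#' Linear map between normalized spot intensity (fold over membrane
#' background) and antigen surface density in pg/um^2, fitted from a
#' dilution series with [fitCalibration()].
#'
#' @slot slope normalized-intensity units per (pg/um^2); must be > 0 for a
#'   usable model.
#' @slot intercept normalized intensity at zero density.
#' @slot rSquared coefficient of determination of the fit.
#' @slot densityRange range of standard densities (pg/um^2) the model was
#'   fitted on; quantification outside it is extrapolation.
#' @slot nStandards number of standards used.
#' @export
setClass("CalibrationModel",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", densityRange = "numeric",
                 nStandards = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@densityRange) != 2L)
      msg <- c(msg, "densityRange must have length 2")
    if (!is.na(object@rSquared) &&
        (object@rSquared < 0 || object@rSquared > 1))
      msg <- c(msg, "rSquared must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Configuration of the synthetic nanowell secretion assay
#'
#' Bundles every parameter of the synthetic data generator: chip geometry,
#' optics scale, cell load and phenotype mixture, per-phenotype marker
#' intensities, secretion range and spot geometry, the membrane standard
#' curve, noise level, and the chip-to-membrane transform. The `seed` fully
#' determines all generated outputs. Use [assayConfig()] to construct.
#'
#' @slot nRows,nCols well lattice dimensions (default 80 x 80 = 6,400 wells).
#' @slot pitchUm well pitch in micrometers (default 100, i.e. an 8 x 8 mm
#'   field under the defaults).
#' @slot umPerPx image scale in micrometers per pixel.
#' @slot wellRadiusUm radius of the well footprint in micrometers.
#' @slot imprintRadiusUm radius of a membrane imprint spot in micrometers.
#' @slot nCells number of cells seeded (at most one per well).
#' @slot phenotypeMix named proportions over the five phenotypes
#'   (PSMA+/- secretor, PSMA+/- non-secretor, leukocyte), summing to 1.
#' @slot intensityMeans 5 x 3 matrix of mean marker intensities (counts) per
#'   phenotype (rows) and channel calcein/psma/cd45 (columns).
#' @slot intensitySdLog log-normal spread (sdlog) of per-cell intensities.
#' @slot secretionPgRange range (pg/cell) secretion is drawn from, uniformly,
#'   for secretors.
#' @slot spotRadiusRangeUm range (um) secretion-spot radii are drawn from,
#'   independently of the secreted amount.
#' @slot calibSlope,calibIntercept true standard curve: normalized intensity
#'   `NI = calibIntercept + calibSlope * density(pg/um^2)`.
#' @slot chipBackground,membraneBackground background level (counts) of chip
#'   and membrane images.
#' @slot noiseSd additive Gaussian noise sd (counts) on all images.
#' @slot imprintContrast imprint spot intensity above membrane background.
#' @slot transformScale,transformRotationDeg,transformTranslationPx
#'   chip-to-membrane transform: scale and rotation about the chip center,
#'   then translation (pixels).
#' @slot seed integer RNG seed determining all generated outputs.
#' @export
setClass("AssayConfig",
  representation(nRows = "integer", nCols = "integer", pitchUm = "numeric",
                 umPerPx = "numeric", wellRadiusUm = "numeric",
                 imprintRadiusUm = "numeric", nCells = "integer",
                 phenotypeMix = "numeric", intensityMeans = "matrix",
                 intensitySdLog = "numeric", secretionPgRange = "numeric",
                 spotRadiusRangeUm = "numeric", calibSlope = "numeric",
                 calibIntercept = "numeric", chipBackground = "numeric",
                 membraneBackground = "numeric", noiseSd = "numeric",
                 imprintContrast = "numeric", transformScale = "numeric",
                 transformRotationDeg = "numeric",
                 transformTranslationPx = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
    if (object@nCells > object@nRows * object@nCols)
      msg <- c(msg, "nCells exceeds the number of wells")
    if (!identical(sort(names(object@phenotypeMix)), sort(PHENOTYPES)))
      msg <- c(msg, paste("phenotypeMix must be named with:",
                          paste(PHENOTYPES, collapse = ", ")))
    if (any(object@phenotypeMix < 0) ||
        abs(sum(object@phenotypeMix) - 1) > 1e-8)
      msg <- c(msg, "phenotypeMix proportions must be >= 0 and sum to 1")
    if (!all(PHENOTYPES %in% rownames(object@intensityMeans)) ||
        !all(CHIP_CHANNELS %in% colnames(object@intensityMeans)))
      msg <- c(msg, "intensityMeans must have phenotype rows and channel columns")
    if (object@transformScale <= 0)
      msg <- c(msg, "transformScale must be > 0 (degenerate transform)")
    if (abs(object@transformRotationDeg) > 10)
      msg <- c(msg, "|transformRotationDeg| must be <= 10 degrees")
    if (any(abs(object@transformTranslationPx) >
            object@pitchUm / object@umPerPx))
      msg <- c(msg, "|transformTranslationPx| must be <= one pitch")
    if (diff(object@secretionPgRange) < 0 || any(object@secretionPgRange < 0))
      msg <- c(msg, "secretionPgRange must be a non-negative interval")
    if (any(object@spotRadiusRangeUm <= 0))
      msg <- c(msg, "spotRadiusRangeUm must be positive")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' A fully simulated nanowell secretion assay
#'
#' Container returned by [simulateAssay()]: the generating configuration,
#' the chip [WellLayout-class], the ground-truth cell table, rendered chip
#' channel images, the membrane imprint/secretion image pair, the true
#' chip-to-membrane [GridTransform-class], and the calibration-standard
#' dilution table.
#'
#' @slot config the generating [AssayConfig-class].
#' @slot layout chip [WellLayout-class] in chip-scan pixels.
#' @slot truth data.frame, one row per occupied well: `well_id`, `row`,
#'   `col`, `phenotype`, true `calcein`/`psma`/`cd45` intensities,
#'   `secretion_pg` (0 for non-secretors), `spot_radius_um` (NA for
#'   non-secretors).
#' @slot chipImages named list of chip channel matrices (brightfield,
#'   calcein, psma, cd45).
#' @slot imprintImage,psaImage membrane image pair (imprint lattice; captured
#'   secretion spots).
#' @slot transform true chip-to-membrane [GridTransform-class].
#' @slot standards calibration dilution table (see
#'   [makeCalibrationStandards()]).
#' @export
setClass("NanowellAssay",
  representation(config = "AssayConfig", layout = "WellLayout",
                 truth = "data.frame", chipImages = "list",
                 imprintImage = "matrix", psaImage = "matrix",
                 transform = "GridTransform", standards = "data.frame"))
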