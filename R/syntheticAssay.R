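# Synthetic nanowell secretion assay: ground truth, chip channel renders,
# membrane imprint/secretion renders and calibration dilution tables, all
# fully determined by (config, seed). The generator stands in for patient
# leukapheresis material: no raw images are deposited with such studies, so
# every downstream module is validated against this annotated emulation.

defaultPhenotypeMix <- function() {
  # Subpopulation frequencies representative of DLA-derived samples in
  # metastatic castration-naive prostate cancer: ~72% of captured cells
  # PSMA+, ~31% secreting (23% PSMA+, 8% PSMA-), small leukocyte carryover.
  c(psma_pos_secretor = 0.23, psma_neg_secretor = 0.08,
    psma_pos_nonsecretor = 0.49, psma_neg_nonsecretor = 0.15,
    leukocyte = 0.05)
}

defaultIntensityMeans <- function() {
  m <- rbind(
    psma_pos_secretor    = c(5000, 4000,   30),
    psma_neg_secretor    = c(5000,   50,   30),
    psma_pos_nonsecretor = c(5000, 4000,   30),
    psma_neg_nonsecretor = c(5000,   50,   30),
    leukocyte            = c(2000,   50, 5000))
  colnames(m) <- CHIP_CHANNELS
  m
}

#' Configure the synthetic nanowell secretion assay
#'
#' Builds an [AssayConfig-class] with defaults emulating the real assay: a
#' 6,400-well chip (80 x 80 lattice at 100 um pitch, an 8 x 8 mm field)
#' imaged at 2 um/px, sparse single-cell occupancy, per-phenotype marker
#' intensities (calcein viability, PSMA-PE, CD45-APC), uniform secretion in
#' `secretion_pg_range` for secretors, disc-shaped secretion spots whose
#' radius is drawn independently of the secreted amount (so surface density
#' and area vary separately), a linear intensity-density standard curve, and
#' a within-tolerance chip-to-membrane similarity transform.
#'
#' @param n_rows,n_cols well lattice dimensions.
#' @param pitch_um well pitch (um).
#' @param um_per_px image scale (um per pixel).
#' @param well_radius_um well footprint radius (um).
#' @param imprint_radius_um membrane imprint spot radius (um).
#' @param n_cells number of seeded cells (one per well at most).
#' @param phenotype_mix named proportions over the five phenotypes.
#' @param intensity_means 5 x 3 matrix of mean channel intensities.
#' @param intensity_sdlog log-normal spread of per-cell intensities.
#' @param secretion_pg_range secretion interval (pg/cell) for secretors.
#' @param spot_radius_range_um secretion-spot radius interval (um).
#' @param calib_slope,calib_intercept true standard curve (normalized
#'   intensity per pg/um^2; normalized intensity at zero density).
#' @param chip_background,membrane_background image background (counts).
#' @param noise_sd additive Gaussian noise sd (counts).
#' @param imprint_contrast imprint spot brightness above background (counts).
#' @param transform_scale,transform_rotation_deg,transform_translation_px
#'   chip-to-membrane similarity transform (rotation/scale about the chip
#'   center, then translation).
#' @param seed integer seed; fully determines all generated outputs.
#' @return an [AssayConfig-class].
#' @examples
#' cfg <- assayConfig(n_rows = 12, n_cols = 12, n_cells = 20, seed = 1)
#' @export
assayConfig <- function(n_rows = 80, n_cols = 80, pitch_um = 100,
                        um_per_px = 2, well_radius_um = 24,
                        imprint_radius_um = 10, n_cells = 100,
                        phenotype_mix = defaultPhenotypeMix(),
                        intensity_means = defaultIntensityMeans(),
                        intensity_sdlog = 0.25,
                        secretion_pg_range = c(2, 15),
                        spot_radius_range_um = c(15, 25),
                        calib_slope = 200, calib_intercept = 1,
                        chip_background = 300, membrane_background = 2000,
                        noise_sd = 40, imprint_contrast = 4000,
                        transform_scale = 1.005,
                        transform_rotation_deg = 1.5,
                        transform_translation_px = c(8, -5),
                        seed = 1L) {
  new("AssayConfig", nRows = as.integer(n_rows), nCols = as.integer(n_cols),
      pitchUm = pitch_um, umPerPx = um_per_px, wellRadiusUm = well_radius_um,
      imprintRadiusUm = imprint_radius_um, nCells = as.integer(n_cells),
      phenotypeMix = phenotype_mix[PHENOTYPES],
      intensityMeans = intensity_means, intensitySdLog = intensity_sdlog,
      secretionPgRange = as.numeric(secretion_pg_range),
      spotRadiusRangeUm = as.numeric(spot_radius_range_um),
      calibSlope = calib_slope, calibIntercept = calib_intercept,
      chipBackground = chip_background,
      membraneBackground = membrane_background, noiseSd = noise_sd,
      imprintContrast = imprint_contrast, transformScale = transform_scale,
      transformRotationDeg = transform_rotation_deg,
      transformTranslationPx = as.numeric(transform_translation_px),
      seed = as.integer(seed))
}

#' Draw the ground-truth cell table for a synthetic assay
#'
#' Samples `n_cells` wells without replacement, assigns phenotypes from the
#' configured mixture, draws per-cell marker intensities (log-normal around
#' the phenotype means), uniform secretion over `secretion_pg_range` for
#' secretors (0 for non-secretors and leukocytes) and an independent spot
#' radius per secretor. Deterministic given `config@seed`.
#'
#' @param config an [AssayConfig-class].
#' @return list with `truth` (data.frame: `well_id`, `row`, `col`,
#'   `phenotype`, `calcein`, `psma`, `cd45`, `secretion_pg`,
#'   `spot_radius_um`) and `layout` (the chip [WellLayout-class]).
#' @export
makeGroundTruth <- function(config) {
  validObject(config)
  layout <- layoutFromConfig(config)
  n <- config@nCells
  truth <- withSeed(config@seed, {
    ids <- sort(sample.int(nWells(layout), n))
    phen <- if (n > 0L) {
      sample(PHENOTYPES, n, replace = TRUE, prob = config@phenotypeMix)
    } else character(0)
    mu <- config@intensityMeans[phen, , drop = FALSE]
    draw <- function(m) stats::rlnorm(n, meanlog = log(m),
                                      sdlog = config@intensitySdLog)
    secretor <- phen %in% c("psma_pos_secretor", "psma_neg_secretor")
    pg <- numeric(n)
    pg[secretor] <- stats::runif(sum(secretor),
                                 config@secretionPgRange[1],
                                 config@secretionPgRange[2])
    radius <- rep(NA_real_, n)
    radius[secretor] <- stats::runif(sum(secretor),
                                     config@spotRadiusRangeUm[1],
                                     config@spotRadiusRangeUm[2])
    rc <- if (n > 0L) wellIdToRowCol(layout, ids) else
      cbind(row = integer(0), col = integer(0))
    data.frame(well_id = as.integer(ids), row = rc[, "row"], col = rc[, "col"],
               phenotype = phen,
               calcein = if (n > 0L) draw(mu[, "calcein"]) else numeric(0),
               psma = if (n > 0L) draw(mu[, "psma"]) else numeric(0),
               cd45 = if (n > 0L) draw(mu[, "cd45"]) else numeric(0),
               secretion_pg = pg, spot_radius_um = radius)
  })
  list(truth = truth, layout = layout)
}

#' Render the multi-channel chip scan of a synthetic assay
#'
#' Produces one 16-bit-range raster per channel (brightfield, calcein,
#' psma, cd45): flat background plus additive Gaussian noise, with a disc of
#' the cell's true channel intensity at each occupied well center (cells
#' fill the well footprint at this scale; brightfield shows wells as darker
#' discs). Deterministic given `config@seed`.
#'
#' @param truth ground-truth table from [makeGroundTruth()].
#' @param layout the matching [WellLayout-class].
#' @param config the generating [AssayConfig-class].
#' @return named list of channel matrices (`[x, y]`, counts).
#' @export
renderChipImages <- function(truth, layout, config) {
  if (nrow(truth) > 0L && any(truth$well_id > nWells(layout)))
    stop("truth is inconsistent with the layout")
  dims <- chipFieldDims(layout)
  r <- layout@wellRadiusPx
  centers <- wellCenters(layout)
  withSeed(config@seed + 1L, {
    imgs <- list()
    bf <- backgroundField(dims["nx"], dims["ny"], 20000, config@noiseSd)
    for (i in seq_len(nrow(centers)))  # wells appear dark in brightfield
      bf <- addDisc(bf, centers[i, 1], centers[i, 2], r, -4000)
    imgs$brightfield <- clampCounts(bf)
    for (ch in CHIP_CHANNELS) {
      img <- backgroundField(dims["nx"], dims["ny"], config@chipBackground,
                             config@noiseSd)
      for (i in seq_len(nrow(truth))) {
        ctr <- centers[truth$well_id[i], ]
        img <- addDisc(img, ctr[1], ctr[2], r, truth[[ch]][i])
      }
      imgs[[ch]] <- clampCounts(img)
    }
    imgs
  })
}

# Chip-to-membrane transform in absolute pixel coordinates. The configured
# rotation/scale act about the chip center; a margin shift keeps the whole
# transformed lattice inside the membrane raster.
membraneTransform <- function(layout, config) {
  dims <- chipFieldDims(layout)
  ctr <- dims / 2
  th <- config@transformRotationDeg * pi / 180
  s <- config@transformScale
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t0 <- as.numeric(ctr - s * R %*% ctr) + config@transformTranslationPx
  tf <- gridTransform(s, config@transformRotationDeg, t0)
  mapped <- applyTransform(tf, wellCenters(layout))
  margin <- layout@pitchPx / 2
  shift <- pmax(0, margin - apply(mapped, 2, min))
  tf <- gridTransform(s, config@transformRotationDeg, t0 + shift)
  mapped <- applyTransform(tf, wellCenters(layout))
  dims_m <- as.numeric(ceiling(apply(mapped, 2, max) + margin))
  list(transform = tf, dims = c(nx = dims_m[1], ny = dims_m[2]))
}

#' Render the membrane image pair of a synthetic assay
#'
#' The imprint (PE) image carries one bright spot per well pore at the
#' transformed lattice position; the secretion (FITC) image carries one disc
#' per secreting cell at its transformed well position, rendered at
#' `NI * membrane_background` where the normalized intensity follows the
#' true standard curve `NI = intercept + slope * (pg / spot_area_um2)`.
#' Non-secretors contribute nothing. Deterministic given `config@seed`.
#'
#' @inheritParams renderChipImages
#' @return list with `imprint` and `psa` image matrices and `transform`, the
#'   true chip-to-membrane [GridTransform-class] (absolute pixel frame,
#'   including the margin shift that keeps the lattice inside the raster).
#' @export
renderMembraneImages <- function(truth, layout, config) {
  if (config@transformScale <= 0) stop("degenerate transform: scale <= 0")
  mt <- membraneTransform(layout, config)
  tf <- mt$transform
  dims <- mt$dims
  mapped_all <- applyTransform(tf, wellCenters(layout))
  r_imp <- config@imprintRadiusUm / config@umPerPx
  bgM <- config@membraneBackground
  withSeed(config@seed + 2L, {
    imprint <- backgroundField(dims["nx"], dims["ny"], bgM, config@noiseSd)
    for (i in seq_len(nrow(mapped_all)))
      imprint <- addDisc(imprint, mapped_all[i, 1], mapped_all[i, 2], r_imp,
                         config@imprintContrast)
    psa <- backgroundField(dims["nx"], dims["ny"], bgM, config@noiseSd)
    sec <- truth[truth$secretion_pg > 0, , drop = FALSE]
    for (i in seq_len(nrow(sec))) {
      ctr <- mapped_all[sec$well_id[i], ]
      r_px <- sec$spot_radius_um[i] / config@umPerPx
      area_um2 <- pi * sec$spot_radius_um[i]^2
      ni <- config@calibIntercept +
        config@calibSlope * sec$secretion_pg[i] / area_um2
      psa <- addDisc(psa, ctr[1], ctr[2], r_px, (ni - 1) * bgM)
    }
    list(imprint = clampCounts(imprint), psa = clampCounts(psa),
         transform = tf)
  })
}

#' Generate a calibration-standard dilution table
#'
#' Emulates spotting 2 uL drops of a two-fold antigen dilution series
#' (default 500 down to 31.25 ug/mL) onto the capture membrane: each
#' standard's surface density is `concentration x volume / spot area` in
#' pg/um^2 and its normalized intensity follows the configured standard
#' curve, optionally with additive Gaussian noise expressed as a fraction of
#' the intensity range. Drop areas vary around `area_um2` (sd 10%),
#' reflecting spreading variability. Deterministic given `config@seed`.
#'
#' @param config an [AssayConfig-class] (supplies the true curve and seed).
#' @param concentrations_ug_per_ml dilution series (ug/mL).
#' @param volume_ul drop volume (uL).
#' @param area_um2 mean drop footprint on the membrane (um^2); 2 uL spreads
#'   to roughly a 5 mm diameter disc on PVDF.
#' @param n_replicates spots per dilution.
#' @param noise_frac sd of added intensity noise as a fraction of the
#'   intensity range of the series (0 = noiseless table).
#' @return data.frame: `concentration_ug_per_ml`, `volume_ul`, `area_um2`,
#'   `normalized_intensity`, `true_density_pg_um2`.
#' @export
makeCalibrationStandards <- function(config,
                                     concentrations_ug_per_ml =
                                       500 / 2^(0:4),
                                     volume_ul = 2, area_um2 = 2e7,
                                     n_replicates = 3, noise_frac = 0) {
  conc <- rep(concentrations_ug_per_ml, each = n_replicates)
  withSeed(config@seed + 3L, {
    areas <- stats::rnorm(length(conc), mean = area_um2, sd = 0.1 * area_um2)
    areas <- pmax(areas, 0.5 * area_um2)
    dens <- conc * volume_ul * 1000 / areas  # ug/mL * uL -> ng; ng = 1e3 pg
    ni <- config@calibIntercept + config@calibSlope * dens
    if (noise_frac > 0)
      ni <- ni + stats::rnorm(length(ni), sd = noise_frac * diff(range(ni)))
    data.frame(concentration_ug_per_ml = conc, volume_ul = volume_ul,
               area_um2 = areas, normalized_intensity = ni,
               true_density_pg_um2 = dens)
  })
}

#' Simulate a complete synthetic assay
#'
#' Convenience wrapper chaining [makeGroundTruth()], [renderChipImages()],
#' [renderMembraneImages()] and [makeCalibrationStandards()] into a
#' [NanowellAssay-class].
#'
#' @param config an [AssayConfig-class].
#' @param standards_noise_frac intensity noise fraction for the standards
#'   table (see [makeCalibrationStandards()]).
#' @return a [NanowellAssay-class].
#' @examples
#' assay <- simulateAssay(assayConfig(n_rows = 10, n_cols = 10,
#'                                    n_cells = 15, seed = 7))
#' assay
#' @export
simulateAssay <- function(config, standards_noise_frac = 0) {
  gt <- makeGroundTruth(config)
  chip <- renderChipImages(gt$truth, gt$layout, config)
  mem <- renderMembraneImages(gt$truth, gt$layout, config)
  std <- makeCalibrationStandards(config, noise_frac = standards_noise_frac)
  new("NanowellAssay", config = config, layout = gt$layout, truth = gt$truth,
      chipImages = chip, imprintImage = mem$imprint, psaImage = mem$psa,
      transform = mem$transform, standards = std)
}

#' @rdname accessors
#' @export
setMethod("assayTruth", "NanowellAssay", function(object) object@truth)

#' @rdname accessors
#' @export
setMethod("chipImages", "NanowellAssay", function(object) object@chipImages)

setMethod("show", "NanowellAssay", function(object) {
  cat("NanowellAssay:", object@layout@nRows, "x", object@layout@nCols,
      "wells,", nrow(object@truth), "cells seeded\n")
  tab <- table(factor(object@truth$phenotype, levels = PHENOTYPES))
  cat("  phenotypes:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = ", "), "\n")
  cat("  secretors:", sum(object@truth$secretion_pg > 0), "; chip field",
      nrow(object@chipImages[[1]]), "x", ncol(object@chipImages[[1]]),
      "px\n")
  invisible(NULL)
})

setMethod("show", "AssayConfig", function(object) {
  cat("AssayConfig:", object@nRows, "x", object@nCols, "wells at",
      object@pitchUm, "um pitch,", object@umPerPx, "um/px\n")
  cat("  cells:", object@nCells, "; secretion",
      object@secretionPgRange[1], "-", object@secretionPgRange[2],
      "pg/cell; noise sd", object@noiseSd, "; seed", object@seed, "\n")
  invisible(NULL)
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel: NI = %.4g + %.4g * density(pg/um^2)\n",
              object@intercept, object@slope))
  cat(sprintf("  R^2 = %.4f over %d standards, density %.3g-%.3g pg/um^2\n",
              object@rSquared, object@nStandards,
              object@densityRange[1], object@densityRange[2]))
  invisible(NULL)
})
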