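# End-to-end analysis of one chip/membrane pair.

#' Analyse a chip/membrane assay end to end
#'
#' Runs the full quantification chain on one patient's data: per-well
#' intensity measurement and phenotype gating on the chip scan, imprint
#' detection and similarity-transform registration on the membrane PE
#' image, secretion-spot segmentation on the membrane FITC image, matching
#' of spots to wells, intensity normalization against leukocyte/no-cell
#' wells, standard-curve calibration, conversion to pg/cell, and assembly
#' into per-cell records and a patient summary.
#'
#' Background wells for normalization are picked deterministically: evenly
#' spaced over the wells classified empty or leukocyte (the protocol uses
#' 50 of them).
#'
#' @param chip_images named list of chip channel matrices (calcein, psma,
#'   cd45; brightfield optional).
#' @param imprint_image,psa_image membrane image pair.
#' @param layout the chip [WellLayout-class].
#' @param standards calibration dilution table (see [fitCalibration()]).
#' @param um_per_px image scale (um per pixel).
#' @param patient_id identifier for the output records.
#' @param chip_thresholds list from [chipThresholds()].
#' @param spot_threshold,spot_absolute threshold settings for
#'   [segmentSpots()].
#' @param min_area,max_area,roundness_range spot filters (see
#'   [segmentSpots()]).
#' @param n_background background wells used for normalization.
#' @param min_pg minimum pg/cell for a PSA+ call.
#' @param serum_psa,screening_ctc patient metadata carried into the summary.
#' @return list: `cells` (per-cell records), `summary` (one-row patient
#'   summary), `observations`, `spots`, `secretion`, `transform`,
#'   `calibration`.
#' @examples
#' assay <- simulateAssay(assayConfig(n_rows = 16, n_cols = 16,
#'                                    n_cells = 30, seed = 11))
#' res <- analyzeAssay(chipImages(assay), assay@imprintImage,
#'                     assay@psaImage, assay@layout, assay@standards,
#'                     um_per_px = assay@config@umPerPx, patient_id = "p1")
#' res$summary
#' @export
analyzeAssay <- function(chip_images, imprint_image, psa_image, layout,
                         standards, um_per_px, patient_id = "patient",
                         chip_thresholds = chipThresholds(),
                         spot_threshold = "background", spot_absolute = NULL,
                         min_area = 10, max_area = 1e4,
                         roundness_range = c(0.64, 1),
                         n_background = 50, min_pg = 0,
                         serum_psa = NA_real_, screening_ctc = NA_real_) {
  obs <- measureWells(chip_images, layout)
  obs <- classifyWells(obs, chip_thresholds)

  centroids <- detectImprintSpots(imprint_image)
  transform <- fitGridTransform(centroids, layout)

  spots <- segmentSpots(psa_image, threshold = spot_threshold,
                        absolute = spot_absolute, min_area = min_area,
                        max_area = max_area,
                        roundness_range = roundness_range)
  spots <- matchSpotsToWells(spots, transform, layout)
  matched <- spots[!is.na(spots$matched_well), , drop = FALSE]

  bg_ids <- obs$well_id[obs$phenotype %in% c("empty", "leukocyte")]
  bg_ids <- setdiff(bg_ids, matched$matched_well)
  if (length(bg_ids) > n_background)
    bg_ids <- bg_ids[round(seq(1, length(bg_ids), length.out = n_background))]
  bg <- measureMembraneBackground(psa_image, transform, layout, bg_ids)

  calibration <- fitCalibration(standards)
  secretion <- if (nrow(matched) > 0L) {
    matched <- normalizeIntensities(matched, bg, n_background = length(bg_ids))
    quantifySpots(matched, calibration, um_per_px)
  } else {
    data.frame(well_id = integer(0), normalized_intensity = numeric(0),
               density_pg_um2 = numeric(0), area_um2 = numeric(0),
               pg_per_cell = numeric(0), clamped = logical(0))
  }

  cells <- assembleCells(obs, secretion, patient_id, min_pg = min_pg)
  summary <- summarizePatient(cells, serum_psa = serum_psa,
                              screening_ctc = screening_ctc)
  list(cells = cells, summary = summary, observations = obs, spots = spots,
       secretion = secretion, transform = transform,
       calibration = calibration)
}
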