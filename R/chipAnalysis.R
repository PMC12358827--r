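# Chip-scan analysis: per-well channel intensities and phenotype calls.

#' Measure per-well channel intensities on a chip scan
#'
#' For every well of the layout, averages each channel over the well disc
#' and subtracts a robust per-channel background, the median over well-free
#' pixels (pixels at least `bg_exclusion` well-radii from any well center).
#' Well localisation uses the known layout: the chip is imaged in a fixed
#' frame, so no registration of the scan itself is needed.
#'
#' @param images named list of channel matrices (same dimensions); a
#'   `brightfield` channel, if present, is ignored for measurement.
#' @param layout the chip [WellLayout-class]; must fit inside the images.
#' @param bg_exclusion background pixels must be at least this many well
#'   radii from every well center.
#' @return data.frame with one row per well: `well_id`, `row`, `col`, and
#'   one background-subtracted mean intensity column per measured channel.
#' @examples
#' assay <- simulateAssay(assayConfig(n_rows = 8, n_cols = 8, n_cells = 6,
#'                                    seed = 2))
#' obs <- measureWells(chipImages(assay), assay@layout)
#' head(obs)
#' @export
measureWells <- function(images, layout, bg_exclusion = 1) {
  channels <- setdiff(names(images), "brightfield")
  if (length(channels) == 0L) stop("no measurable channels in `images`")
  dims <- dim(images[[1]])
  for (ch in channels)
    if (!identical(dim(images[[ch]]), dims))
      stop("all channels must have identical dimensions")
  centers <- wellCenters(layout)
  r <- layout@wellRadiusPx
  if (any(centers[, 1] - r < 0.5) || any(centers[, 2] - r < 0.5) ||
      any(centers[, 1] + r > dims[1] + 0.5) ||
      any(centers[, 2] + r > dims[2] + 0.5))
    stop("layout exceeds image bounds")

  # Background mask: distance to the nearest well center, computed
  # analytically from the lattice (clamped at the lattice edge).
  px <- seq_len(dims[1]); py <- seq_len(dims[2])
  nearest_cx <- layout@originPx[1] + layout@pitchPx *
    pmin(pmax(round((px - layout@originPx[1]) / layout@pitchPx), 0),
         layout@nCols - 1)
  nearest_cy <- layout@originPx[2] + layout@pitchPx *
    pmin(pmax(round((py - layout@originPx[2]) / layout@pitchPx), 0),
         layout@nRows - 1)
  dx2 <- (px - nearest_cx)^2
  dy2 <- (py - nearest_cy)^2
  bg_mask <- outer(dx2, dy2, `+`) >= (bg_exclusion * r)^2

  disc_idx <- lapply(seq_len(nrow(centers)), function(i)
    discPixels(centers[i, 1], centers[i, 2], r, dims[1], dims[2]))
  rc <- wellIdToRowCol(layout, seq_len(nWells(layout)))
  out <- data.frame(well_id = seq_len(nWells(layout)),
                    row = rc[, "row"], col = rc[, "col"])
  for (ch in channels) {
    img <- images[[ch]]
    bg <- stats::median(img[bg_mask])
    out[[ch]] <- vapply(disc_idx, function(ix) mean(img[ix]), numeric(1)) - bg
  }
  out
}

#' Chip-side phenotype gating thresholds
#'
#' Positivity cutoffs applied to background-subtracted well intensities.
#' The real assay sets these by eye against an intensity bar; the defaults
#' here are calibrated on the synthetic generator's intensity scale (live
#' cells several thousand counts above background vs. tens of counts for
#' negative markers).
#'
#' @param calcein,psma,cd45 positivity thresholds (counts, inclusive >=).
#' @return named list of thresholds.
#' @export
chipThresholds <- function(calcein = 500, psma = 500, cd45 = 500) {
  if (any(c(calcein, psma, cd45) < 0)) stop("thresholds must be >= 0")
  list(calcein = calcein, psma = psma, cd45 = cd45)
}

#' Call per-well occupancy and phenotype from measured intensities
#'
#' Gating mirrors the viability-based identification of candidate tumor
#' cells: CD45-positive wells hold leukocytes regardless of the other
#' markers; calcein-positive CD45-negative wells hold candidate CTCs,
#' subdivided into PSMA+ and PSMA- by the PSMA threshold; wells negative
#' for calcein and CD45 are empty (debris without viable staining is not
#' distinguished from empty at this level).
#'
#' @param observations data.frame from [measureWells()] (columns `well_id`,
#'   `calcein`, `psma`, `cd45`).
#' @param thresholds list from [chipThresholds()].
#' @return the input with `phenotype` (one of `"psma_pos_ctc"`,
#'   `"psma_neg_ctc"`, `"leukocyte"`, `"empty"`) and `occupancy`
#'   (`"cell"`/`"empty"`) columns appended.
#' @export
classifyWells <- function(observations, thresholds = chipThresholds()) {
  stopIfMissingCols(observations, c("well_id", "calcein", "psma", "cd45"),
                    "well observations")
  cd45_pos <- observations$cd45 >= thresholds$cd45
  calcein_pos <- observations$calcein >= thresholds$calcein
  psma_pos <- observations$psma >= thresholds$psma
  phenotype <- rep("empty", nrow(observations))
  phenotype[cd45_pos] <- "leukocyte"
  phenotype[!cd45_pos & calcein_pos & psma_pos] <- "psma_pos_ctc"
  phenotype[!cd45_pos & calcein_pos & !psma_pos] <- "psma_neg_ctc"
  observations$phenotype <- phenotype
  observations$occupancy <- ifelse(phenotype == "empty", "empty", "cell")
  observations
}

#' Recovery rate of seeded cells
#'
#' Fraction of sorted cells that were recovered on the chip, in percent:
#' `100 * cells_detected / cells_sorted`.
#'
#' @param cells_detected number of occupied wells detected on the chip.
#' @param cells_sorted number of cells sorted onto the chip.
#' @return recovery rate in percent.
#' @export
recoveryRate <- function(cells_detected, cells_sorted) {
  if (cells_sorted <= 0) stop("cells_sorted must be > 0")
  100 * cells_detected / cells_sorted
}
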