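#' @rdname accessors
#' @export
setMethod("nWells", "WellLayout", function(object) {
  object@nRows * object@nCols
})

#' @rdname accessors
#' @export
setMethod("wellCenters", "WellLayout", function(object) {
  ids <- seq_len(nWells(object))
  rc <- wellIdToRowCol(object, ids)
  centers <- cbind(
    x = object@originPx[1] + (rc[, "col"] - 1) * object@pitchPx,
    y = object@originPx[2] + (rc[, "row"] - 1) * object@pitchPx)
  rownames(centers) <- ids
  centers
})

#' Convert between well ids and (row, col) lattice positions
#'
#' Well ids are row-major from 1: `well_id = (row - 1) * n_cols + col`.
#'
#' @param layout a [WellLayout-class].
#' @param well_id integer vector of well ids in `[1, nWells]`.
#' @param row,col integer vectors of lattice positions (1-based).
#' @return `wellIdToRowCol`: integer matrix with columns `row`, `col`;
#'   `rowColToWellId`: integer vector of well ids.
#' @examples
#' ly <- wellLayout(80, 80, 50)
#' wellIdToRowCol(ly, c(1, 81, 6400))
#' rowColToWellId(ly, 2, 1)
#' @export
wellIdToRowCol <- function(layout, well_id) {
  well_id <- as.integer(well_id)
  if (any(well_id < 1L | well_id > nWells(layout)))
    stop("well_id out of range [1, ", nWells(layout), "]")
  cbind(row = (well_id - 1L) %/% layout@nCols + 1L,
        col = (well_id - 1L) %% layout@nCols + 1L)
}

#' @rdname wellIdToRowCol
#' @export
rowColToWellId <- function(layout, row, col) {
  row <- as.integer(row); col <- as.integer(col)
  if (any(row < 1L | row > layout@nRows | col < 1L | col > layout@nCols))
    stop("row/col outside the lattice")
  (row - 1L) * layout@nCols + col
}

#' Derive the pixel-space well layout from an assay configuration
#'
#' @param config an [AssayConfig-class].
#' @return a [WellLayout-class] in chip-scan pixel coordinates.
#' @export
layoutFromConfig <- function(config) {
  pitch_px <- config@pitchUm / config@umPerPx
  wellLayout(config@nRows, config@nCols, pitch_px,
             origin_px = c(pitch_px / 2, pitch_px / 2),
             well_radius_px = config@wellRadiusUm / config@umPerPx)
}

# Pixel dimensions of the chip field implied by a layout (margin = pitch/2
# beyond the last well center on each side).
chipFieldDims <- function(layout) {
  c(nx = ceiling(layout@originPx[1] + (layout@nCols - 1) * layout@pitchPx +
                   layout@pitchPx / 2),
    ny = ceiling(layout@originPx[2] + (layout@nRows - 1) * layout@pitchPx +
                   layout@pitchPx / 2))
}

setMethod("show", "WellLayout", function(object) {
  dims <- chipFieldDims(object)
  cat("WellLayout:", object@nRows, "x", object@nCols, "wells (",
      nWells(object), "total )\n")
  cat("  pitch:", object@pitchPx, "px; well radius:", object@wellRadiusPx,
      "px; origin: (", object@originPx[1], ",", object@originPx[2], ")\n")
  cat("  field:", dims["nx"], "x", dims["ny"], "px\n")
  invisible(NULL)
})
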