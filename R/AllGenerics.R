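#' Accessors for nanospot S4 classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `wellCenters()` returns the pixel centers of all wells (row-major well id
#' order), `nWells()` the lattice size, `calSlope()`/`calIntercept()` the
#' standard-curve coefficients, `assayTruth()` the ground-truth table of a
#' simulated assay and `chipImages()` its channel stack.
#'
#' @param object a nanospot S4 object.
#' @return `wellCenters`: an n-by-2 matrix of `(x, y)` pixel centers with
#'   `well_id` rownames; `nWells`: integer; `calSlope`, `calIntercept`:
#'   numeric scalars; `assayTruth`: data.frame; `chipImages`: named list of
#'   matrices.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wellCenters", function(object) standardGeneric("wellCenters"))

#' @rdname accessors
#' @export
setGeneric("nWells", function(object) standardGeneric("nWells"))

#' @rdname accessors
#' @export
setGeneric("calSlope", function(object) standardGeneric("calSlope"))

#' @rdname accessors
#' @export
setGeneric("calIntercept", function(object) standardGeneric("calIntercept"))

#' @rdname accessors
#' @export
setGeneric("assayTruth", function(object) standardGeneric("assayTruth"))

#' @rdname accessors
#' @export
setGeneric("chipImages", function(object) standardGeneric("chipImages"))
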