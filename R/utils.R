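# Internal helpers shared across modules.
#
# Image convention: a channel image is a numeric matrix indexed [x, y]
# (EBImage convention), intensities in camera counts (0..65535, stored as
# doubles; quantisation happens only at TIFF IO). A point is c(x, y) in
# pixel units with pixel centers at integer coordinates starting at 1.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Disc rasterisation helpers
#'
#' `discPixels` lists the pixel indices whose centers fall inside the disc
#' `(cx, cy, r)`, clipped to an `nx`-by-`ny` image; `addDisc` adds `value`
#' to that footprint. Used by the synthetic renderer and handy for building
#' test images.
#'
#' @param cx,cy disc center in pixels.
#' @param r disc radius in pixels.
#' @param nx,ny image dimensions.
#' @param img image matrix (`[x, y]`).
#' @param value intensity added over the disc footprint.
#' @return `discPixels`: two-column integer matrix of `(x, y)` indices;
#'   `addDisc`: the modified image.
#' @examples
#' img <- addDisc(matrix(0, 50, 50), 25, 25, 10, 100)
#' sum(img > 0)  # ~ pi * 10^2
#' @export
discPixels <- function(cx, cy, r, nx, ny) {
  xs <- max(1L, ceiling(cx - r)):min(nx, floor(cx + r))
  if (length(xs) == 0L || xs[1] > nx) return(cbind(x = integer(0), y = integer(0)))
  out_x <- integer(0); out_y <- integer(0)
  for (x in xs) {
    half <- r * r - (x - cx)^2
    if (half < 0) next
    half <- sqrt(half)
    ys <- max(1L, ceiling(cy - half)):min(ny, floor(cy + half))
    if (length(ys) == 0L) next
    out_x <- c(out_x, rep.int(x, length(ys)))
    out_y <- c(out_y, ys)
  }
  cbind(x = out_x, y = out_y)
}

#' @rdname discPixels
#' @export
addDisc <- function(img, cx, cy, r, value) {
  px <- discPixels(cx, cy, r, nrow(img), ncol(img))
  if (nrow(px) > 0L) img[px] <- img[px] + value
  img
}

# Flat background field with optional additive Gaussian noise.
backgroundField <- function(nx, ny, level, noise_sd) {
  if (noise_sd > 0) {
    matrix(stats::rnorm(nx * ny, mean = level, sd = noise_sd), nx, ny)
  } else {
    matrix(level, nx, ny)
  }
}

clampCounts <- function(img, max_count = 65535) {
  img[img < 0] <- 0
  img[img > max_count] <- max_count
  img
}

stopIfMissingCols <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
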