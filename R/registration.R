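# Membrane registration: detect the anti-IgG imprint lattice printed through
# the well pores, fit the chip-to-membrane similarity transform, and map
# membrane coordinates back to well ids.

#' Apply or invert a chip-to-membrane similarity transform
#'
#' The forward transform maps chip-scan pixel coordinates to membrane pixel
#' coordinates: `p' = scale * R(rotation) %*% p + translation`.
#'
#' @param transform a [GridTransform-class].
#' @param points numeric n-by-2 matrix (or length-2 vector) of `(x, y)`
#'   points.
#' @return an n-by-2 matrix of transformed points (`applyTransform`), or the
#'   inverse `GridTransform` (`invertTransform`).
#' @examples
#' tf <- gridTransform(rotation_deg = 90, translation_px = c(10, 0))
#' applyTransform(tf, c(1, 0))
#' @export
applyTransform <- function(transform, points) {
  points <- rbind2cols(points)
  th <- transform@rotationDeg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out <- transform@scale * points %*% t(R)
  out[, 1] <- out[, 1] + transform@translationPx[1]
  out[, 2] <- out[, 2] + transform@translationPx[2]
  colnames(out) <- c("x", "y")
  out
}

#' @rdname applyTransform
#' @export
invertTransform <- function(transform) {
  th <- transform@rotationDeg * pi / 180
  s <- transform@scale
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t_inv <- -(1 / s) * t(R) %*% transform@translationPx
  gridTransform(scale = 1 / s, rotation_deg = -transform@rotationDeg,
                translation_px = as.numeric(t_inv),
                rms_residual = transform@rmsResidual,
                n_support = transform@nSupport)
}

rbind2cols <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  if (ncol(points) != 2L) stop("points must be (x, y) pairs")
  points
}

# Automatic global threshold for bright objects on a flat background.
# "otsu": Otsu's method on a 256-bin histogram (EBImage); "background":
# robust background model median + k * MAD; "absolute": user value.
autoThreshold <- function(img, method = c("otsu", "background", "absolute"),
                          absolute = NULL, k = 5) {
  method <- match.arg(method)
  switch(method,
    otsu = {
      rng <- range(img)
      if (diff(rng) <= 0) return(Inf)
      EBImage::otsu(EBImage::Image(img), range = rng, levels = 256L)
    },
    background = stats::median(img) + k * stats::mad(img),
    absolute = {
      if (is.null(absolute)) stop("absolute threshold requested but not given")
      absolute
    })
}

#' Detect imprint spots on the membrane lattice image
#'
#' Thresholds the anti-IgG imprint image, labels connected components
#' (8-connectivity) and returns their centroids, filtered to a plausible
#' spot-size window so dust and noise pixels are rejected.
#'
#' @param img single-channel membrane imprint image (matrix, `[x, y]`).
#' @param threshold `"otsu"` (default), `"background"` (median + 5 MAD), or
#'   `"absolute"`.
#' @param absolute threshold value when `threshold = "absolute"`.
#' @param min_area,max_area retained component pixel-area window.
#' @return data.frame with one row per spot: `x`, `y` (binary centroid, px)
#'   and `pixel_area`.
#' @seealso [fitGridTransform()]
#' @export
detectImprintSpots <- function(img, threshold = "otsu", absolute = NULL,
                               min_area = 4, max_area = 2500) {
  thr <- autoThreshold(img, threshold, absolute = absolute)
  mask <- img > thr
  if (!any(mask)) stop("no imprint found: no pixels above threshold")
  lab <- EBImage::bwlabel(mask)
  lab_v <- as.integer(lab)
  keep <- lab_v > 0L
  lab_v <- lab_v[keep]
  xy <- arrayInd(which(keep), dim(img))
  n_px <- tabulate(lab_v)
  cx <- rowsum(as.numeric(xy[, 1]), lab_v)[, 1] / n_px
  cy <- rowsum(as.numeric(xy[, 2]), lab_v)[, 1] / n_px
  ok <- n_px >= min_area & n_px <= max_area
  if (!any(ok)) stop("no imprint found: all components outside the size window")
  data.frame(x = cx[ok], y = cy[ok], pixel_area = n_px[ok])
}

# Closed-form 2D similarity fit (least squares, no reflection): finds
# (s, R, t) minimising sum || y_i - (s R x_i + t) ||^2.
fitSimilarity <- function(X, Y) {
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  S <- crossprod(Yc, Xc) / nrow(X)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, d))
  R <- sv$u %*% D %*% t(sv$v)
  var_x <- mean(rowSums(Xc^2))
  s <- sum(sv$d * c(1, d)) / var_x
  t_vec <- my - s * as.numeric(R %*% mx)
  list(scale = s, rotation_deg = atan2(R[2, 1], R[1, 1]) * 180 / pi,
       translation = t_vec)
}

# Coarse lattice orientation/scale estimate from nearest-neighbour vectors
# (angles fold into (-45, 45] deg modulo the square-lattice symmetry).
latticeInit <- function(P, pitch_px, max_sample = 300L) {
  n <- nrow(P)
  if (n < 4L) return(list(rotation_deg = 0, scale = 1))
  idx <- if (n > max_sample)
    round(seq(1L, n, length.out = max_sample)) else seq_len(n)
  angles <- numeric(length(idx))
  dists <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    d2 <- (P[, 1] - P[i, 1])^2 + (P[, 2] - P[i, 2])^2
    d2[i] <- Inf
    j <- which.min(d2)
    ang <- atan2(P[j, 2] - P[i, 2], P[j, 1] - P[i, 1]) * 180 / pi
    ang <- ang %% 90
    if (ang > 45) ang <- ang - 90
    angles[k] <- ang
    dists[k] <- sqrt(d2[j])
  }
  list(rotation_deg = stats::median(angles),
       scale = stats::median(dists) / pitch_px)
}

# Nearest lattice well (analytic, exploiting the regular grid) for points in
# chip-frame pixels. Ties between equidistant wells resolve to the lowest
# well id because the floor candidate wins on equality.
nearestWell <- function(layout, points) {
  u <- (points[, 1] - layout@originPx[1]) / layout@pitchPx  # col - 1
  v <- (points[, 2] - layout@originPx[2]) / layout@pitchPx  # row - 1
  snap <- function(f, n) {
    lo <- floor(f)
    cand <- ifelse(f - lo <= (lo + 1 - f), lo, lo + 1)  # ties -> lower index
    pmin(pmax(cand, 0), n - 1)
  }
  col <- snap(u, layout@nCols) + 1
  row <- snap(v, layout@nRows) + 1
  cx <- layout@originPx[1] + (col - 1) * layout@pitchPx
  cy <- layout@originPx[2] + (row - 1) * layout@pitchPx
  dist <- sqrt((points[, 1] - cx)^2 + (points[, 2] - cy)^2)
  data.frame(well_id = (as.integer(row) - 1L) * layout@nCols + as.integer(col),
             center_x = cx, center_y = cy, dist_px = dist)
}

#' Fit the chip-to-membrane similarity transform from imprint centroids
#'
#' Registers detected imprint-spot centroids against the known well lattice
#' by iterated nearest-neighbor matching and closed-form least-squares
#' similarity fitting (scale, rotation, translation). At each iteration the
#' centroids are mapped back to the chip frame under the current estimate,
#' matched to their nearest lattice point, and pairs with residuals beyond
#' `reject_factor` x pitch are discarded before refitting; this makes the fit
#' robust to spurious detections and to initially mismatched edge spots under
#' rotation.
#'
#' @param centroids data.frame or matrix of spot centroids with columns
#'   `x`, `y` (membrane pixels), e.g. from [detectImprintSpots()].
#' @param layout the chip [WellLayout-class].
#' @param iterations number of match/fit refinement iterations.
#' @param reject_factor inlier radius as a fraction of the pitch.
#' @param max_rms registration is declared failed when the final RMS residual
#'   exceeds `max_rms` x pitch.
#' @return a [GridTransform-class] with `rmsResidual` (membrane px) and
#'   `nSupport` (inlier lattice points) filled in.
#' @examples
#' ly <- wellLayout(10, 10, 50)
#' tf <- gridTransform(rotation_deg = 2, translation_px = c(12.3, -7.8))
#' fitGridTransform(applyTransform(tf, wellCenters(ly)), ly)
#' @export
fitGridTransform <- function(centroids, layout, iterations = 5,
                             reject_factor = 0.4, max_rms = 0.25) {
  if (is.data.frame(centroids)) {
    stopIfMissingCols(centroids, c("x", "y"), "centroids")
    P <- cbind(centroids$x, centroids$y)
  } else P <- rbind2cols(centroids)
  if (nrow(P) < 3L) stop("at least 3 imprint centroids are required")
  centers <- wellCenters(layout)

  # Initial estimate from the lattice structure itself: nearest-neighbour
  # vectors between imprint spots run along the (rotated) grid axes, so
  # their angles folded into (-45, 45] degrees estimate the rotation and
  # their lengths the scaled pitch. This makes the refinement loop start
  # close enough that nearest-well matching is correct over the whole chip
  # for any rotation within the supported range.
  init <- latticeInit(P, layout@pitchPx)
  est <- list(scale = init$scale, rotation_deg = init$rotation_deg,
              translation = NULL)
  th0 <- init$rotation_deg * pi / 180
  R0 <- matrix(c(cos(th0), sin(th0), -sin(th0), cos(th0)), 2, 2)
  est$translation <- colMeans(P) -
    init$scale * as.numeric(R0 %*% colMeans(centers))

  pitch <- layout@pitchPx
  match_tab <- NULL
  for (it in seq_len(iterations)) {
    tf <- gridTransform(est$scale, est$rotation_deg, est$translation)
    chipP <- applyTransform(invertTransform(tf), P)
    nn <- nearestWell(layout, chipP)
    nn$spot <- seq_len(nrow(P))
    nn <- nn[nn$dist_px <= reject_factor * pitch, , drop = FALSE]
    if (nrow(nn) > 0L) {  # one centroid per well: keep the closest
      nn <- nn[order(nn$well_id, nn$dist_px), , drop = FALSE]
      nn <- nn[!duplicated(nn$well_id), , drop = FALSE]
    }
    if (nrow(nn) < 3L)
      stop("registration failed: fewer than 3 inlier lattice points")
    est <- fitSimilarity(cbind(nn$center_x, nn$center_y),
                         P[nn$spot, , drop = FALSE])
    match_tab <- nn
  }
  tf <- gridTransform(est$scale, est$rotation_deg, est$translation)
  pred <- applyTransform(tf, cbind(match_tab$center_x, match_tab$center_y))
  res <- P[match_tab$spot, , drop = FALSE] - pred
  rms <- sqrt(mean(rowSums(res^2)))
  if (rms > max_rms * pitch)
    stop(sprintf("registration failed: rms residual %.2f px exceeds %.2f px",
                 rms, max_rms * pitch))
  gridTransform(est$scale, est$rotation_deg, est$translation,
                rms_residual = rms, n_support = nrow(match_tab))
}

#' Map membrane coordinates to well ids
#'
#' Inverse-transforms membrane points to the chip frame and assigns each to
#' its nearest well center when within the assignment radius (a fraction of
#' the pitch). Points beyond the radius, or off the chip footprint, map to
#' `NA`. A point exactly equidistant between wells resolves to the lowest
#' well id (documented tie-break; unreachable in the presence of noise).
#'
#' @param transform the chip-to-membrane [GridTransform-class].
#' @param layout the chip [WellLayout-class].
#' @param points n-by-2 matrix or data.frame (`x`, `y`) in membrane pixels.
#' @param assignment_radius maximum chip-frame distance to the well center,
#'   as a fraction of the pitch (default 0.5).
#' @return integer vector of well ids (`NA` where unassigned).
#' @export
mapPointToWell <- function(transform, layout, points,
                           assignment_radius = 0.5) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  points <- rbind2cols(points)
  chipP <- applyTransform(invertTransform(transform), points)
  nn <- nearestWell(layout, chipP)
  ids <- nn$well_id
  ids[nn$dist_px > assignment_radius * layout@pitchPx] <- NA_integer_
  as.integer(ids)
}

setMethod("show", "GridTransform", function(object) {
  cat(sprintf("GridTransform: scale %.4f, rotation %.3f deg, translation (%.2f, %.2f) px\n",
              object@scale, object@rotationDeg,
              object@translationPx[1], object@translationPx[2]))
  if (!is.na(object@rmsResidual))
    cat(sprintf("  rms residual %.3f px over %d lattice points\n",
                object@rmsResidual, object@nSupport))
  invisible(NULL)
})
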