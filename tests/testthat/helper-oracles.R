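# Independent oracles used to check the implementation. These deliberately
# avoid the package's own code paths (EBImage labelling, lm, the disc
# rasteriser's internals).

# Analytic mask of a rotated filled ellipse: pixel centers (i, j) inside
# ((x')/a)^2 + ((y')/b)^2 <= 1 with x', y' the coordinates rotated by
# -theta about (cx, cy). theta in radians.
ellipseMask <- function(nx, ny, cx, cy, a, b, theta = 0) {
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  dx <- xs - cx; dy <- ys - cy
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  (u / a)^2 + (v / b)^2 <= 1
}

# Brute-force flood fill (8-connectivity) of a logical mask; returns the
# pixel count of every connected component. Queue-based, O(n) but slow R;
# for small oracle images only.
floodFillAreas <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  seen <- matrix(FALSE, nx, ny)
  areas <- integer(0)
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (!mask[i, j] || seen[i, j]) next
    queue <- matrix(c(i, j), ncol = 2)
    seen[i, j] <- TRUE
    count <- 0L
    while (nrow(queue) > 0L) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      count <- count + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ny &&
            mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
    areas <- c(areas, count)
  }
  areas
}

# Normal-equations OLS oracle for y ~ x.
olsOracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# Closed-form 2D similarity transform application.
similarityOracle <- function(points, scale, rot_deg, trans) {
  th <- rot_deg * pi / 180
  cbind(scale * (cos(th) * points[, 1] - sin(th) * points[, 2]) + trans[1],
        scale * (sin(th) * points[, 1] + cos(th) * points[, 2]) + trans[2])
}
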