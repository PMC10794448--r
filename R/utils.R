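# Internal helpers: classed conditions and planar polygon primitives.
# Polygons are open rings: an n x 2 matrix of vertices, implicitly closed,
# counter-clockwise (CCW) after normalization.

ptStop <- function(subclass, msg, call. = FALSE) {
  cnd <- structure(
    class = c(paste0("plaquetrend_", subclass), "plaquetrend_error",
              "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cnd)
}

# Signed area by the shoelace formula; positive for CCW rings.
polySignedArea <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

polyPerimeter <- function(pts) {
  d <- pts[c(seq_len(nrow(pts))[-1L], 1L), , drop = FALSE] - pts
  sum(sqrt(rowSums(d^2)))
}

# Area centroid of a simple polygon (not the vertex mean).
polyCentroid <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100)
    return(colMeans(pts))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Algebraic (Kasa) least-squares circle fit; returns center and radius.
fitCircle <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  coef <- unname(qr.solve(A, b))
  cx <- -coef[1L] / 2
  cy <- -coef[2L] / 2
  r2 <- cx^2 + cy^2 - coef[3L]
  if (!is.finite(r2) || r2 <= 0)
    ptStop("invalid_contour", "degenerate vertex set: circle fit failed")
  c(cx = cx, cy = cy, r = sqrt(r2))
}

# Even-odd point-in-polygon test; boundary points (within tol) count as inside.
pointInPolygon <- function(p, pts, tol = 1e-12) {
  as.logical(.pointsInPolyCpp(matrix(p, 1L, 2L), pts, tol))
}

# vectorized variant over a matrix of points
pointsInPolygon <- function(P, pts, tol = 1e-12) {
  as.logical(.pointsInPolyCpp(P, pts, tol))
}

# All-pairs proper segment-intersection test for polygon simplicity.
# O(n^2) vectorized; adequate for annotated IVUS contours (n <= ~1000).
isSimplePolygon <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(FALSE)
  p1 <- pts
  p2 <- pts[c(2:n, 1L), , drop = FALSE]
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  adjacent <- (j - i == 1L) | (i == 1L & j == n)
  i <- i[!adjacent]; j <- j[!adjacent]
  if (!length(i)) return(TRUE)
  a1 <- p1[i, , drop = FALSE]; a2 <- p2[i, , drop = FALSE]
  b1 <- p1[j, , drop = FALSE]; b2 <- p2[j, , drop = FALSE]
  d1 <- a2 - a1; d2 <- b2 - b1
  cr <- function(u, v) u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  denom <- cr(d1, d2)
  w <- b1 - a1
  t <- cr(w, d2) / denom
  s <- cr(w, d1) / denom
  hit <- is.finite(t) & is.finite(s) & t > 0 & t < 1 & s > 0 & s < 1
  # collinear overlapping segments (denom == 0) with touching bounding boxes
  col <- denom == 0 & cr(w, d1) == 0
  if (any(col)) {
    k <- which(col)
    ov <- pmin(pmax(a1[k, 1L], a2[k, 1L]), pmax(b1[k, 1L], b2[k, 1L])) >=
      pmax(pmin(a1[k, 1L], a2[k, 1L]), pmin(b1[k, 1L], b2[k, 1L])) &
      pmin(pmax(a1[k, 2L], a2[k, 2L]), pmax(b1[k, 2L], b2[k, 2L])) >=
      pmax(pmin(a1[k, 2L], a2[k, 2L]), pmin(b1[k, 2L], b2[k, 2L]))
    if (any(ov)) return(FALSE)
  }
  !any(hit)
}

# Resample a closed ring to n points equally spaced in (chord) arclength,
# starting at vertex 1. Coordinates are interpolated with a periodic cubic
# spline through the vertices: annotated anatomic boundaries are smooth, and
# chordwise-linear resampling aliases the vertex grid against the resample
# grid, which makes curvature integrals of coarse polygons non-convergent.
# Returns list(points, step) where step = P/n and P is the chord perimeter.
resampleClosed <- function(pts, n) {
  closed <- rbind(pts, pts[1L, ])
  seg <- sqrt(rowSums((closed[-1L, , drop = FALSE] -
                       closed[-nrow(closed), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  P <- s[length(s)]
  t <- seq(0, P, length.out = n + 1L)[-(n + 1L)]
  x <- spline(s, closed[, 1L], xout = t, method = "periodic")$y
  y <- spline(s, closed[, 2L], xout = t, method = "periodic")$y
  list(points = cbind(x, y), step = P / n)
}

# Per-vertex signed curvature of a closed, uniformly resampled ring:
# central finite differences of the unwrapped tangent angle over arclength.
closedCurvature <- function(pts, step) {
  n <- nrow(pts)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  dx <- (pts[nxt, 1L] - pts[prv, 1L]) / 2
  dy <- (pts[nxt, 2L] - pts[prv, 2L]) / 2
  theta <- atan2(dy, dx)
  dtheta <- theta[nxt] - theta[prv]
  dtheta <- (dtheta + pi) %% (2 * pi) - pi   # wrap to (-pi, pi]
  dtheta / (2 * step)
}

# Distances from `origin` to the polygon boundary along unit directions.
# first = TRUE returns the nearest crossing; otherwise each ray must cross
# the boundary exactly once (vertex-grazing duplicates collapsed).
rayDistances <- function(pts, origin, angles, first = TRUE) {
  d <- .rayCastCpp(pts, as.numeric(origin), as.numeric(angles), first)
  if (anyNA(d)) {
    if (first)
      ptStop("geometry_inconsistency",
             "a ray from the anchor does not intersect the contour")
    ptStop("geometry_inconsistency",
           "a ray intersects the contour boundary more than once (or never)")
  }
  d
}
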