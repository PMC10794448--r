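# Frame-wise geometric descriptors of one lumen/vessel contour pair.
#
# Conventions fixed across the package:
#  * ray-cast quantities use M uniformly spaced directions (default 360);
#  * xi diameters run through the catheter anchor (image origin), psi
#    diameters through the contour's own centroid, so xi is catheter-relative
#    and psi intrinsic;
#  * plaque thickness is measured along rays from the lumen centroid;
#  * curvature is estimated on an arclength-resampled copy (N = 256 points)
#    by central differences of the unwrapped tangent angle.

.M_DEFAULT <- 360L
.N_RESAMPLE <- 256L

#' Basic polygon metrics of a contour
#'
#' Area (shoelace formula), perimeter (vertex-chain length), area centroid,
#' and the radius of the least-squares best-fit circle.
#'
#' @param contour a [Contour-class].
#' @return list with \code{A} (mm^2), \code{P} (mm), \code{centroid}
#'   (length-2, mm) and \code{rFit} (mm).
#' @examples
#' sq <- Contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), "lumen")
#' contourMetrics(sq)  # A = 1, P = 4, centroid (0.5, 0.5)
#' @export
contourMetrics <- function(contour) {
  stopifnot(is(contour, "Contour"))
  pts <- contour@points
  list(A = polySignedArea(pts), P = polyPerimeter(pts),
       centroid = polyCentroid(pts), rFit = unname(fitCircle(pts)["r"]))
}

#' Cross-sectional areas and plaque burden
#'
#' Lumen area, vessel area, plaque area (vessel minus lumen) and plaque
#' burden PB = 100 * plaqueA / vesselA. The lumen must be contained in the
#' vessel (equality allowed: a plaque-free frame has PB = 0).
#'
#' @param lumen,vessel [Contour-class] objects of matching roles.
#' @return list with \code{lumenA}, \code{vesselA}, \code{plaqueA} (mm^2)
#'   and \code{PB} (%).
#' @export
frameAreas <- function(lumen, vessel) {
  aL <- polySignedArea(lumen@points)
  aV <- polySignedArea(vessel@points)
  if (aL > aV + 1e-12 * max(aV, 1))
    ptStop("geometry_inconsistency", "lumen area exceeds vessel area")
  inside <- pointsInPolygon(lumen@points, vessel@points, tol = 1e-9)
  if (!all(inside))
    ptStop("geometry_inconsistency",
           "lumen contour is not contained in the vessel contour")
  plaqueA <- max(aV - aL, 0)
  list(lumenA = aL, vesselA = aV, plaqueA = plaqueA,
       PB = 100 * plaqueA / aV)
}

#' Extreme diameters through an anchor point
#'
#' For M uniformly spaced directions theta in [0, pi), the chord through
#' \code{anchor} at angle theta is cast against the contour boundary on both
#' sides; the diameter d(theta) is the sum of the two first-hit distances.
#' Returns the minimum and maximum over directions.
#'
#' @param contour a [Contour-class].
#' @param anchor length-2 point, strictly inside the contour.
#' @param M number of directions (default 360).
#' @return list with \code{dMin}, \code{dMax} (mm).
#' @export
diameterExtremes <- function(contour, anchor, M = .M_DEFAULT) {
  pts <- contour@points
  if (!pointInPolygon(anchor, pts))
    ptStop("anchor_error", "anchor point lies outside the contour")
  th <- seq(0, pi, length.out = M + 1L)[seq_len(M)]
  fwd <- rayDistances(pts, anchor, th, first = TRUE)
  bwd <- rayDistances(pts, anchor, th + pi, first = TRUE)
  d <- fwd + bwd
  list(dMin = min(d), dMax = max(d))
}

#' Eccentricity-type descriptors of a lumen/vessel pair
#'
#' \code{xiL}/\code{xiV}: max/min diameter ratio through the catheter anchor;
#' \code{xiP}: centroid offset between lumen and vessel normalised by the
#' mean of the lumen extreme diameters (taken through the lumen centroid, so
#' xiP does not depend on the catheter position); \code{psiL}/\code{psiV}:
#' ellipse eccentricity sqrt(1 - (min/max)^2) with diameters taken through
#' the contour's own centroid.
#'
#' @inheritParams frameAreas
#' @param anchor catheter position (image origin), inside both contours.
#' @param M number of ray directions.
#' @return list with \code{xiL}, \code{xiV}, \code{xiP}, \code{psiL},
#'   \code{psiV}.
#' @export
eccentricityFeatures <- function(lumen, vessel, anchor, M = .M_DEFAULT) {
  dL <- diameterExtremes(lumen, anchor, M)
  dV <- diameterExtremes(vessel, anchor, M)
  cL <- polyCentroid(lumen@points)
  cV <- polyCentroid(vessel@points)
  dLc <- diameterExtremes(lumen, cL, M)
  dVc <- diameterExtremes(vessel, cV, M)
  list(
    xiL = dL$dMax / dL$dMin,
    xiV = dV$dMax / dV$dMin,
    xiP = sqrt(sum((cL - cV)^2)) / ((dLc$dMin + dLc$dMax) / 2),
    psiL = sqrt(max(0, 1 - (dLc$dMin / dLc$dMax)^2)),
    psiV = sqrt(max(0, 1 - (dVc$dMin / dVc$dMax)^2))
  )
}

#' Circumferential plaque-distribution descriptors
#'
#' At M uniformly spaced angles around the lumen centroid, rays are cast to
#' both boundaries; plaque thickness is the vessel-hit distance minus the
#' lumen-hit distance. \code{rhoL}/\code{rhoV} give the percentage of angles
#' at which thickness over the respective radius exceeds 0.2, and
#' \code{varrho} the maximum over mean thickness ratio (defined as 1 on
#' plaque-free frames).
#'
#' @inheritParams frameAreas
#' @param M number of angles.
#' @return list with \code{rhoL}, \code{rhoV} (% of circumference) and
#'   \code{varrho} (dimensionless, >= 1).
#' @export
plaqueDistributionFeatures <- function(lumen, vessel, M = .M_DEFAULT) {
  cL <- polyCentroid(lumen@points)
  if (!pointInPolygon(cL, lumen@points))
    ptStop("geometry_inconsistency",
           "lumen centroid lies outside the lumen contour")
  th <- seq(0, 2 * pi, length.out = M + 1L)[seq_len(M)]
  rl <- rayDistances(lumen@points, cL, th, first = FALSE)
  rv <- rayDistances(vessel@points, cL, th, first = FALSE)
  thick <- rv - rl
  if (any(thick < -1e-9))
    ptStop("geometry_inconsistency",
           "negative plaque thickness: lumen outside vessel along a ray")
  thick <- pmax(thick, 0)
  mt <- mean(thick)
  list(
    rhoL = 100 * mean(thick / rl > 0.2),
    rhoV = 100 * mean(thick / rv > 0.2),
    varrho = if (mt <= 1e-12) 1 else max(thick) / mt
  )
}

#' Shape-complexity descriptors of a single contour
#'
#' Circularity phi = 4*pi*A/P^2 (1 for a circle, < 1 otherwise), curvature
#' irregularity tau = max(k) - min(k), and curvature roughness
#' kappa = sqrt((r/2*pi) * sum(k^2 * dl)), where k is the per-point signed
#' curvature of the arclength-resampled contour, dl the arclength step and r
#' the best-fit circle radius. A perfect circle has kappa = 1.
#'
#' @param contour a [Contour-class].
#' @param nResample number of equally spaced arclength points used for the
#'   curvature estimate (default 256).
#' @return list with \code{phi}, \code{tau} (1/mm), \code{kappa}.
#' @export
shapeComplexityFeatures <- function(contour, nResample = .N_RESAMPLE) {
  m <- contourMetrics(contour)
  rs <- resampleClosed(contour@points, nResample)
  k <- closedCurvature(rs$points, rs$step)
  list(
    phi = 4 * pi * m$A / m$P^2,
    tau = max(k) - min(k),
    kappa = sqrt(m$rFit / (2 * pi) * sum(k^2) * rs$step)
  )
}

#' Curvature profile of a contour
#'
#' Per-point signed local curvature and local segment lengths on the
#' arclength-resampled contour; the segment lengths sum to the contour
#' perimeter.
#'
#' @inheritParams shapeComplexityFeatures
#' @return list with \code{varkappa} (1/mm) and \code{deltaL} (mm), both of
#'   length \code{nResample}.
#' @export
curvatureProfile <- function(contour, nResample = .N_RESAMPLE) {
  rs <- resampleClosed(contour@points, nResample)
  list(varkappa = closedCurvature(rs$points, rs$step),
       deltaL = rep(rs$step, nResample))
}

.FRAME_FEATURES <- c("lumenA", "vesselA", "plaqueA", "PB",
                     "xiL", "xiV", "xiP", "psiL", "psiV",
                     "rhoL", "rhoV", "varrho",
                     "phiL", "phiV", "tauL", "tauV", "kappaL", "kappaV")

#' All 18 frame-wise geometric descriptors
#'
#' Assembles areas and plaque burden, eccentricity descriptors,
#' plaque-distribution descriptors and per-contour shape complexity into a
#' single named list for one frame.
#'
#' @inheritParams eccentricityFeatures
#' @param nResample resampling resolution for curvature estimates.
#' @return named list with elements
#'   \code{lumenA, vesselA, plaqueA, PB, xiL, xiV, xiP, psiL, psiV,
#'   rhoL, rhoV, varrho, phiL, phiV, tauL, tauV, kappaL, kappaV}.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 65)[-65]
#' lum <- Contour(cbind(cos(th), sin(th)), "lumen")
#' ves <- Contour(cbind(2 * cos(th), 2 * sin(th)), "vessel")
#' f <- computeFrameFeatures(lum, ves, anchor = c(0, 0))
#' f$PB       # 75% plaque burden for the 1/2 radius annulus
#' @export
computeFrameFeatures <- function(lumen, vessel, anchor = c(0, 0),
                                 M = .M_DEFAULT, nResample = .N_RESAMPLE) {
  ar <- frameAreas(lumen, vessel)
  ec <- eccentricityFeatures(lumen, vessel, anchor, M)
  pd <- plaqueDistributionFeatures(lumen, vessel, M)
  scL <- shapeComplexityFeatures(lumen, nResample)
  scV <- shapeComplexityFeatures(vessel, nResample)
  out <- list(
    lumenA = ar$lumenA, vesselA = ar$vesselA, plaqueA = ar$plaqueA,
    PB = ar$PB,
    xiL = ec$xiL, xiV = ec$xiV, xiP = ec$xiP,
    psiL = ec$psiL, psiV = ec$psiV,
    rhoL = pd$rhoL, rhoV = pd$rhoV, varrho = pd$varrho,
    phiL = scL$phi, phiV = scV$phi,
    tauL = scL$tau, tauV = scV$tau,
    kappaL = scL$kappa, kappaV = scV$kappa
  )
  stopifnot(identical(names(out), .FRAME_FEATURES))
  out
}
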