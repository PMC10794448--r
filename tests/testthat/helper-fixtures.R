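# Shared fixtures and independent oracles. Everything is generated in code;
# expensive cohorts are memoised for reuse across test files.

.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(key, builder) {
  if (!exists(key, .fixtureCache)) assign(key, builder(), .fixtureCache)
  get(key, .fixtureCache)
}

regularPolygon <- function(n, radius = 1, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1L] + radius * cos(th), center[2L] + radius * sin(th))
}

circleContour <- function(radius = 1, n = 256L, center = c(0, 0),
                          role = "lumen") {
  Contour(regularPolygon(n, radius, center), role = role)
}

ellipseContour <- function(a = 2, b = 1, n = 256L, role = "lumen") {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  Contour(cbind(a * cos(th), b * sin(th)), role = role)
}

# Independent ray-cast oracle: plain per-angle loop over edge crossings,
# nearest hit. Kept separate from the package's compiled path.
oracleRayCast <- function(pts, origin, angles) {
  n <- nrow(pts)
  p2 <- pts[c(2:n, 1L), , drop = FALSE]
  ex <- p2[, 1L] - pts[, 1L]; ey <- p2[, 2L] - pts[, 2L]
  bx <- pts[, 1L] - origin[1L]; by <- pts[, 2L] - origin[2L]
  vapply(angles, function(th) {
    dx <- cos(th); dy <- sin(th)
    dxe <- dx * ey - dy * ex
    t <- (bx * ey - by * ex) / dxe
    s <- (dy * bx - dx * by) / dxe
    t <- t[is.finite(t) & is.finite(s) & t > 1e-12 & s > -1e-9 & s < 1 + 1e-9]
    if (!length(t)) return(NA_real_)
    min(t)
  }, numeric(1))
}

# dense-sampling oracle for the diameter extremes through an anchor
oracleDiameters <- function(contour, anchor, M = 3600L) {
  th <- seq(0, pi, length.out = M + 1L)[seq_len(M)]
  pts <- contourPoints(contour)
  d <- oracleRayCast(pts, anchor, th) + oracleRayCast(pts, anchor, th + pi)
  list(dMin = min(d), dMax = max(d))
}

# dense angular oracle for the plaque-distribution features
oraclePlaqueDistribution <- function(lumen, vessel, M = 3600L) {
  cL <- plaquetrend:::polyCentroid(contourPoints(lumen))
  th <- seq(0, 2 * pi, length.out = M + 1L)[seq_len(M)]
  rl <- oracleRayCast(contourPoints(lumen), cL, th)
  rv <- oracleRayCast(contourPoints(vessel), cL, th)
  thick <- pmax(rv - rl, 0)
  mt <- mean(thick)
  list(rhoL = 100 * mean(thick / rl > 0.2),
       rhoV = 100 * mean(thick / rv > 0.2),
       varrho = if (mt <= 1e-12) 1 else max(thick) / mt)
}

# a random valid lumen/vessel frame pair around the catheter origin
randomFramePair <- function(nVertices = 128L) {
  ves <- simulateContour(areaTarget = runif(1, 8, 18),
                         eccentricity = runif(1, 0, 0.4),
                         perturbAmp = 0.05, nVertices = nVertices,
                         role = "vessel")
  theta <- seq(0, 2 * pi, length.out = nVertices + 1L)[seq_len(nVertices)]
  rv <- sqrt(rowSums(contourPoints(ves)^2))
  pb <- runif(1, 20, 80)
  lumenA <- contourMetrics(ves)$A * (1 - pb / 100)
  rl <- plaquetrend:::.lumenProfile(rv, theta, lumenA, runif(1, 0, 0.25),
                                    runif(1, 0, 2 * pi))
  lum <- Contour(cbind(rl * cos(theta), rl * sin(theta)), role = "lumen")
  list(lumen = lum, vessel = ves, PB = pb)
}

# small cohort shared by io/pipeline tests
tinySim <- function() memoFixture("tinySim", function() {
  simulateCohort(cohortConfig(nPatients = 4L, nArteries = 6L,
                              lengthRangeMm = c(12, 18), seed = 101))
})

# a ChPAV feature dataset on a slightly larger cohort, shared by the
# ml-pipeline and determinism/SHAP acceptance tests
smallChpavDataset <- function() memoFixture("smallChpav", function() {
  sim <- simulateCohort(cohortConfig(nPatients = 8L, nArteries = 12L,
                                     lengthRangeMm = c(15, 25), seed = 202))
  ds <- buildRoiDataset(sim$cohort, criterion = "ChPAV", setId = "Sd")
  list(sim = sim, ds = ds,
       groupDPAV = setNames(ds$pullbacks$dPAV_fp, ds$pullbacks$pullback_id))
})

# uniform-grid signal helper
gridSignal <- function(values, name = "f") {
  LongitudinalSignal(values, originMm = 0, name = name)
}

expect_roi <- function(rois, starts, ends) {
  expect_equal(rois$start, as.integer(starts))
  expect_equal(rois$end, as.integer(ends))
}
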