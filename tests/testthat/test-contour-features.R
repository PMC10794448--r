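# Frame-wise geometric descriptors: closed forms, dense ray-cast oracles,
# invariants, convergence and scale behaviour.

test_that("basic polygon metrics match closed forms", {
  sq <- Contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), "lumen")
  m <- contourMetrics(sq)
  expect_equal(m$A, 1)
  expect_equal(m$P, 4)
  expect_equal(m$centroid, c(0.5, 0.5))

  # regular 360-gon, circumradius 1: A = (n/2) sin(2 pi / n)
  g <- Contour(regularPolygon(360), "lumen")
  expect_equal(contourMetrics(g)$A, 180 * sin(2 * pi / 360), tolerance = 1e-12)
  expect_equal(contourMetrics(g)$rFit, 1, tolerance = 1e-6)

  expect_error(Contour(cbind(c(0, 1), c(0, 1)), "lumen"),
               class = "plaquetrend_invalid_contour")
  # self-intersecting bow tie
  expect_error(Contour(cbind(c(0, 1, 1, 0), c(0, 1, 0, 1)), "lumen"),
               class = "plaquetrend_invalid_contour")
})

test_that("orientation is normalised and vertices validated", {
  cw <- Contour(cbind(c(0, 0, 1, 1), c(0, 1, 1, 0)), "lumen")  # clockwise in
  expect_gt(plaquetrend:::polySignedArea(contourPoints(cw)), 0)
  expect_error(Contour(cbind(c(0, 1, NA), c(0, 0, 1)), "lumen"),
               class = "plaquetrend_invalid_contour")
})

test_that("frame areas and plaque burden follow the area definitions", {
  lum <- circleContour(1, 128)
  ves <- circleContour(2, 128, role = "vessel")
  ar <- frameAreas(lum, ves)
  expect_equal(ar$plaqueA, ar$vesselA - ar$lumenA)
  expect_equal(ar$PB, 100 * ar$plaqueA / ar$vesselA)
  expect_equal(ar$PB, 75, tolerance = 1e-3)

  # degenerate no-plaque frame: lumen identical to vessel
  same <- frameAreas(circleContour(1, 64), circleContour(1, 64, role = "vessel"))
  expect_equal(same$plaqueA, 0)
  expect_equal(same$PB, 0)

  expect_error(frameAreas(circleContour(2, 64), circleContour(1, 64, role = "vessel")),
               class = "plaquetrend_geometry_inconsistency")
})

test_that("diameter extremes match circle/ellipse geometry and the dense oracle", {
  circ <- circleContour(1, 720)
  d <- diameterExtremes(circ, c(0, 0))
  expect_equal(d$dMin, 2, tolerance = 1e-4)
  expect_equal(d$dMax, 2, tolerance = 1e-4)

  ell <- ellipseContour(2, 1, 720)
  d <- diameterExtremes(ell, c(0, 0))
  oracle <- oracleDiameters(ell, c(0, 0), M = 3600L)
  expect_equal(d$dMin, oracle$dMin, tolerance = 1e-3)
  expect_equal(d$dMax, oracle$dMax, tolerance = 1e-3)
  expect_equal(d$dMin, 2, tolerance = 1e-3)
  expect_equal(d$dMax, 4, tolerance = 1e-3)

  expect_error(diameterExtremes(circ, c(5, 0)),
               class = "plaquetrend_anchor_error")
})

test_that("eccentricity features: symmetry, offset arithmetic, ellipse closed form", {
  lum <- circleContour(1, 360)
  ves <- circleContour(2, 360, role = "vessel")
  ec <- eccentricityFeatures(lum, ves, c(0, 0))
  expect_equal(ec$xiL, 1, tolerance = 1e-4)
  expect_equal(ec$xiV, 1, tolerance = 1e-4)
  expect_equal(ec$xiP, 0, tolerance = 1e-9)
  expect_lt(ec$psiL, 0.02)
  expect_lt(ec$psiV, 0.02)

  # lumen circle r=1 at (0.5, 0) inside vessel r=2: xiP = 0.5 / 2
  lum2 <- circleContour(1, 360, center = c(0.5, 0))
  ec2 <- eccentricityFeatures(lum2, ves, c(0, 0))
  expect_equal(ec2$xiP, 0.25, tolerance = 1e-4)

  # 2:1 ellipse: psi = sqrt(1 - (1/2)^2) = sqrt(3)/2
  ell <- ellipseContour(2, 1, 720)
  ec3 <- eccentricityFeatures(ell, circleContour(3, 360, role = "vessel"),
                              c(0, 0))
  expect_equal(ec3$psiL, sqrt(3) / 2, tolerance = 1e-3)
})

test_that("plaque distribution features: annuli and dense oracle", {
  lum <- circleContour(1, 256)
  ves <- circleContour(2, 256, role = "vessel")
  pd <- plaqueDistributionFeatures(lum, ves)
  expect_equal(pd$rhoL, 100)
  expect_equal(pd$varrho, 1, tolerance = 1e-4)  # polygon discretization

  thin <- circleContour(1.1, 256, role = "vessel")
  expect_equal(plaqueDistributionFeatures(lum, thin)$rhoL, 0)

  # eccentric lumen: r=1 offset by 0.5 inside vessel r=2
  lumOff <- circleContour(1, 256, center = c(0.5, 0))
  pd2 <- plaqueDistributionFeatures(lumOff, ves)
  oracle <- oraclePlaqueDistribution(lumOff, ves, M = 3600L)
  expect_equal(pd2$varrho, oracle$varrho, tolerance = 0.01)
  expect_lt(abs(pd2$rhoL - oracle$rhoL), 1)
  expect_lt(abs(pd2$rhoV - oracle$rhoV), 1)
})

test_that("shape complexity: circle roughness 1, square circularity pi/4", {
  circ <- Contour(regularPolygon(720, 2), "lumen")
  sc <- shapeComplexityFeatures(circ)
  expect_equal(sc$kappa, 1, tolerance = 1e-3)
  expect_equal(sc$phi, 1, tolerance = 1e-4)
  expect_lt(sc$tau, 0.05)

  sq <- Contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), "lumen")
  expect_equal(shapeComplexityFeatures(sq)$phi, pi / 4, tolerance = 1e-12)

  prof <- curvatureProfile(circ)
  expect_length(prof$varkappa, 256L)
  expect_equal(sum(prof$deltaL), contourMetrics(circ)$P, tolerance = 1e-9)
  expect_equal(mean(prof$varkappa), 0.5, tolerance = 1e-3)  # 1/r, r = 2
})

test_that("shape features converge monotonically for n-gon circles beyond n = 32", {
  ns <- c(32, 64, 128, 256, 512)
  vals <- t(vapply(ns, function(n) {
    cc <- Contour(regularPolygon(n, 2), "lumen")
    sc <- shapeComplexityFeatures(cc)
    d <- diameterExtremes(cc, c(0, 0))
    c(phi = abs(sc$phi - 1), kappa = abs(sc$kappa - 1), tau = sc$tau,
      psi = sqrt(max(0, 1 - (d$dMin / d$dMax)^2)))
  }, numeric(4)))
  for (k in colnames(vals)) {
    expect_true(all(diff(vals[, k]) <= 1e-5),
                info = sprintf("%s not monotonically decreasing", k))
    expect_lt(vals[nrow(vals), k], 0.02)
  }
})

test_that("frame feature invariants hold on random synthetic frames", {
  set.seed(11)
  for (i in 1:200) {
    fp <- randomFramePair()
    f <- computeFrameFeatures(fp$lumen, fp$vessel, c(0, 0))
    expect_equal(f$plaqueA, f$vesselA - f$lumenA, tolerance = 1e-9)
    expect_gte(f$plaqueA, 0)
    expect_true(f$PB >= 0 && f$PB < 100)
    expect_gte(f$xiL, 1); expect_gte(f$xiV, 1)
    expect_true(f$psiL >= 0 && f$psiL < 1)
    expect_true(f$psiV >= 0 && f$psiV < 1)
    expect_true(f$phiL > 0 && f$phiL <= 1)
    expect_true(f$phiV > 0 && f$phiV <= 1)
    expect_gte(f$tauL, 0); expect_gte(f$tauV, 0)
    expect_gt(f$kappaL, 0); expect_gt(f$kappaV, 0)
    expect_true(f$rhoL >= 0 && f$rhoL <= 100)
    expect_true(f$rhoV >= 0 && f$rhoV <= 100)
    expect_gte(f$varrho, 1)
  }
})

test_that("dimensionless features are scale invariant; tau scales as 1/length", {
  set.seed(21)
  fp <- randomFramePair()
  f1 <- computeFrameFeatures(fp$lumen, fp$vessel, c(0, 0))
  s <- 2.7
  lum2 <- Contour(contourPoints(fp$lumen) * s, "lumen", checkSimple = FALSE)
  ves2 <- Contour(contourPoints(fp$vessel) * s, "vessel", checkSimple = FALSE)
  f2 <- computeFrameFeatures(lum2, ves2, c(0, 0))
  for (k in c("PB", "xiL", "xiV", "xiP", "psiL", "psiV", "phiL", "phiV",
              "rhoL", "rhoV", "varrho", "kappaL", "kappaV"))
    expect_equal(f2[[k]], f1[[k]], tolerance = 1e-9, info = k)
  expect_equal(f2$tauL, f1$tauL / s, tolerance = 1e-9)
  expect_equal(f2$lumenA, f1$lumenA * s^2, tolerance = 1e-9)
})

test_that("degenerate plaque-free frame reports varrho = 1", {
  lum <- circleContour(1.5, 128)
  ves <- circleContour(1.5, 128, role = "vessel")
  f <- computeFrameFeatures(lum, ves, c(0, 0))
  expect_equal(f$plaqueA, 0)
  expect_equal(f$PB, 0)
  expect_equal(f$varrho, 1)
  expect_equal(f$rhoL, 0)
})
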