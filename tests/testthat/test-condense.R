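# Region-wise condensation and feature-set assembly.

test_that("order statistics follow the linear-interpolation convention", {
  cs <- condenseStatistics(1:101)
  expect_equal(cs$MED, 51)
  expect_equal(cs$IQR, 50)
  expect_equal(cs$ICR, 80)

  const <- condenseStatistics(rep(3.3, 40))
  expect_equal(const$MED, 3.3)
  expect_equal(const$IQR, 0)
  expect_equal(const$ICR, 0)

  expect_error(condenseStatistics(numeric(0)),
               class = "plaquetrend_empty_input")
})

test_that("Shannon entropy matches a brute-force histogram oracle", {
  expect_equal(shannonEntropy(rep(7, 50)), 0)
  # 16 equally filled bins: H = log2(16) = 4 bits
  expect_equal(shannonEntropy(rep(1:16, each = 5), nBins = 16L), 4)

  set.seed(5)
  for (i in 1:20) {
    seg <- rnorm(200)
    nb <- sample(c(8L, 16L, 32L), 1L)
    lo <- min(seg); hi <- max(seg)
    bins <- pmin(nb, floor((seg - lo) / (hi - lo) * nb) + 1L)
    p <- as.numeric(table(factor(bins, levels = 1:nb))) / length(seg)
    p <- p[p > 0]
    expect_equal(shannonEntropy(seg, nb), -sum(p * log2(p)), tolerance = 1e-12)
    expect_gte(shannonEntropy(seg, nb), 0)
    expect_lte(shannonEntropy(seg, nb), log2(nb))
  }
})

test_that("first Fourier harmonic magnitude/phase follow the direct DFT", {
  n <- 64L
  t <- 0:(n - 1)
  fh <- fftFirstHarmonic(cos(2 * pi * t / n))
  expect_equal(fh$FFTm, 1, tolerance = 1e-9)
  expect_equal(fh$FFTp, 0, tolerance = 1e-9)

  fh2 <- fftFirstHarmonic(sin(2 * pi * t / n))
  expect_equal(fh2$FFTp, -pi / 2, tolerance = 1e-9)
  expect_equal(fh2$FFTm, 1, tolerance = 1e-9)

  const <- fftFirstHarmonic(rep(4, 32))
  expect_equal(const$FFTm, 0, tolerance = 1e-12)
  expect_equal(const$FFTp, 0)

  # against R's FFT as an independent oracle
  set.seed(6)
  v <- rnorm(50)
  x1 <- fft(v)[2L]
  fh3 <- fftFirstHarmonic(v)
  expect_equal(fh3$FFTm, 2 * Mod(x1) / 50, tolerance = 1e-12)
  expect_equal(fh3$FFTp, Arg(x1), tolerance = 1e-12)

  expect_error(fftFirstHarmonic(1), class = "plaquetrend_too_short")
})

test_that("permutation invariance holds for order/entropy stats but not Fourier", {
  set.seed(7)
  seg <- rnorm(120)
  perm <- sample(seg)
  a <- condenseSegment(seg); b <- condenseSegment(perm)
  expect_equal(a$MED, b$MED); expect_equal(a$IQR, b$IQR)
  expect_equal(a$ICR, b$ICR); expect_equal(a$H, b$H)
  expect_false(isTRUE(all.equal(a$FFTp, b$FFTp)))
})

makeBlSignals <- function(n = 120L, seed = 8) {
  set.seed(seed)
  feats <- plaquetrend:::.FRAME_FEATURES
  sigs <- lapply(feats, function(nm) gridSignal(rnorm(n, 10, 2), nm))
  names(sigs) <- feats
  der <- lapply(sigs, signalDerivative)
  names(der) <- paste0("d", feats)
  c(sigs, der)
}

clinRow <- function() {
  as.data.frame(setNames(as.list(c(60, 1, 27, 1.1, 3.4, rep(0, 9), 1,
                                   1, 0, 1, 1, 1)),
                         c("AGE", "MSX", "BMI", "HDL", "LDL", "DIA", "HYT",
                           "HYC", "CSK", "FHC", "RFL", "PMI", "PPI", "STA",
                           "ASP", "PRA", "CLO", "DAPT", "BB", "ACE")))
}

test_that("feature sets assemble with the exact schema sizes", {
  roi <- data.frame(start = 10L, end = 90L, length_mm = 80 / 60)
  vols <- list(TLV_BL = 10, TVV_BL = 20, TAV_BL = 10, PAV_BL = 50)
  sigs <- makeBlSignals()

  fa <- assembleFeatures(roi, clinical = clinRow(), setId = "Sa")
  expect_length(fa, 20L)

  fb <- assembleFeatures(roi, clinical = clinRow(), volumes = vols,
                         setId = "Sb")
  expect_length(fb, 24L)
  expect_equal(fb$PAV, 50)

  fd <- assembleFeatures(roi, blSignals = sigs, clinical = clinRow(),
                         volumes = vols, artery = "LAD", setId = "Sd")
  expect_length(fd, 242L)  # 20 clinical + 4 volumes + 216 condensed + 2 macro
  expect_equal(fd$artery, "LAD")
  expect_equal(fd$len_mm, 80 / 60)
  expect_true(all(vapply(fd[setdiff(names(fd), "artery")], is.finite,
                         logical(1))))

  # condensed values agree with direct condensation of the segment
  seg <- signalValues(sigs$PB)[11:90]
  expect_equal(fd$MED_PB, condenseStatistics(seg)$MED)
  expect_equal(fd$FFTm_dPB,
               fftFirstHarmonic(signalValues(sigs$dPB)[11:90])$FFTm)
})

test_that("missing clinical data is an error, never imputed", {
  roi <- data.frame(start = 0L, end = 60L, length_mm = 1)
  cr <- clinRow(); cr$HDL <- NULL
  expect_error(assembleFeatures(roi, clinical = cr, setId = "Sa"),
               class = "plaquetrend_missing_data")
  cr2 <- clinRow(); cr2$AGE <- NA
  expect_error(assembleFeatures(roi, clinical = cr2, setId = "Sa"),
               class = "plaquetrend_missing_data")
})

test_that("condensed feature name grid is stable and complete", {
  nms <- condensedFeatureNames()
  expect_length(nms, 216L)
  expect_true(all(c("MED_PB", "FFTp_dPB", "H_kappaL", "ICR_dvarrho") %in% nms))
  expect_false(anyDuplicated(nms) > 0)
})
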