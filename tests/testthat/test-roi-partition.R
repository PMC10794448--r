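# ROI criteria hand-traces, purity invariants, and the dPAV target.

pbOf <- function(v) gridSignal(v, "PB")

test_that("ChPAV partitioning follows the sign-run rules", {
  base <- rep(40, 60)
  # +1% for 30 frames then -1% for 30 frames: two ROIs
  d <- c(rep(1, 30), rep(-1, 30))
  rois <- partitionChPAV(pbOf(base), pbOf(base + d))
  expect_roi(rois, c(0, 30), c(30, 60))

  # sub-threshold everywhere: discarded
  expect_equal(nrow(partitionChPAV(pbOf(base), pbOf(base + 0.3))), 0L)

  # short +run inside a -background: the 10-frame run dropped, flanks kept
  d2 <- c(rep(-1, 25), rep(1, 10), rep(-1, 25))
  rois2 <- partitionChPAV(pbOf(rep(40, 60)), pbOf(rep(40, 60) + d2))
  expect_roi(rois2, c(0, 35), c(25, 60))

  # zero difference breaks runs
  d3 <- c(rep(1, 20), rep(0, 5), rep(1, 20))
  rois3 <- partitionChPAV(pbOf(rep(40, 45)), pbOf(rep(40, 45) + d3))
  expect_roi(rois3, c(0, 25), c(20, 45))

  # runs shorter than 15 frames are discarded even above threshold
  d4 <- c(rep(1, 14), rep(-1, 46))
  rois4 <- partitionChPAV(pbOf(rep(40, 60)), pbOf(rep(40, 60) + d4))
  expect_roi(rois4, 14, 60)

  expect_error(partitionChPAV(pbOf(base), pbOf(base[1:30])),
               class = "plaquetrend_alignment_error")
})

test_that("ChPAV ROIs are sign-pure", {
  set.seed(9)
  for (rep in 1:20) {
    d <- as.numeric(stats::filter(rnorm(400, 0, 2), rep(1 / 8, 8),
                                  circular = TRUE))
    rois <- partitionChPAV(pbOf(rep(40, 400)), pbOf(40 + d))
    for (i in seq_len(nrow(rois))) {
      seg <- d[(rois$start[i] + 1):rois$end[i]]
      expect_true(all(seg > 0) || all(seg < 0))
      expect_gte(max(abs(seg)), 0.5)
      expect_gte(rois$end[i] - rois$start[i], 15L)
    }
    if (nrow(rois) > 1L)
      expect_true(all(rois$start[-1] >= rois$end[-nrow(rois)]))
  }
})

test_that("PBR partitioning uses the printed bins and run rules", {
  pb <- c(rep(20, 20), rep(40, 20), rep(70, 20))
  rois <- partitionPBR(pbOf(pb))
  expect_roi(rois, c(0, 20, 40), c(20, 40, 60))
  expect_equal(rois$category, c(0L, 1L, 2L))

  # single category spans the pullback
  one <- partitionPBR(pbOf(rep(50, 120)))
  expect_roi(one, 0, 120)

  # bin edge 30.0 goes to the upper bin (half-open convention)
  edge <- partitionPBR(pbOf(c(rep(29.9, 20), rep(30.0, 20))))
  expect_roi(edge, c(0, 20), c(20, 40))
  expect_equal(edge$category, c(0L, 1L))

  # PB = 60 and PB = 100 belong to the top bin
  top <- partitionPBR(pbOf(c(rep(60, 20), rep(100, 20))))
  expect_roi(top, 0, 40)
  expect_equal(top$category, 2L)

  expect_error(partitionPBR(pbOf(c(50, 101, 50))),
               class = "plaquetrend_invalid_signal")
})

test_that("window partitioning enumerates pooled offset grids", {
  # length 100, window 30, offsets 0/10/20: 3 + 3 + 2 windows
  rois <- partitionWindows(100L, 30L)
  expect_equal(nrow(rois), 8L)
  expect_equal(rois$start[rois$offset_id == 0L], c(0L, 30L, 60L))
  expect_equal(rois$start[rois$offset_id == 1L], c(10L, 40L, 70L))
  expect_equal(rois$start[rois$offset_id == 2L], c(20L, 50L))
  expect_true(all(rois$end - rois$start == 30L))

  expect_equal(nrow(partitionWindows(29L, 30L)), 0L)
  expect_equal(nrow(partitionWindows(240L, 120L, offsets = 0L)), 2L)
  expect_equal(sort(unique(partitionWindows(400L, 120L)$offset_id)), 0:5)
  expect_error(partitionWindows(100L, 0L), class = "plaquetrend_config_error")

  # per-offset windows are disjoint and window-sized
  w <- partitionWindows(500L, 60L)
  for (o in unique(w$offset_id)) {
    wo <- w[w$offset_id == o, ]
    expect_true(all(wo$start[-1] == wo$end[-nrow(wo)]))
  }
})

test_that("full-pullback criterion and dispatch", {
  expect_roi(partitionFullPullback(600L), 0, 600)
  expect_roi(partitionFullPullback(15L), 0, 15)
  expect_error(partitionFullPullback(10L), class = "plaquetrend_config_error")

  pb <- pbOf(rep(45, 200))
  expect_equal(partitionROIs("FP", pb)$criterion, "FP")
  expect_equal(unique(partitionROIs("W30O10", pb)$criterion), "W30O10")
  expect_error(partitionROIs("ChPAV", pb), class = "plaquetrend_config_error")
  expect_error(partitionROIs("nope", pb), class = "plaquetrend_config_error")
})

areasOf <- function(lum, ves) {
  list(lumenA = gridSignal(lum, "lumenA"), vesselA = gridSignal(ves, "vesselA"),
       plaqueA = gridSignal(ves - lum, "plaqueA"))
}

test_that("roiTarget arithmetic, tie class and quadrature accuracy", {
  n <- 121L
  bl <- areasOf(rep(5, n), rep(10, n))     # PAV 50
  fu <- areasOf(rep(6, n), rep(10, n))     # PAV 40
  roi <- data.frame(start = 0L, end = n)
  tgt <- roiTarget(roi, bl, fu)
  expect_equal(tgt$PAV_BL, 50)
  expect_equal(tgt$PAV_FU, 40)
  expect_equal(tgt$dPAV, -10)
  expect_equal(tgt$class, "regression")
  expect_equal(tgt$TVV_BL, 10 * (n - 1) / 60, tolerance = 1e-12)

  # identical phases: dPAV = 0, tie assigned to regression
  tgt0 <- roiTarget(roi, bl, bl)
  expect_equal(tgt0$dPAV, 0)
  expect_equal(tgt0$class, "regression")

  # linearly varying areas against a dense Simpson oracle
  x <- (0:(n - 1)) / 60
  lum <- 4 + 0.3 * x; ves <- 11 + 0.1 * x
  tgt2 <- roiTarget(roi, areasOf(lum, ves), areasOf(lum, ves))
  simpson <- function(f, a, b, m = 2000L) {
    xs <- seq(a, b, length.out = 2L * m + 1L)
    h <- (b - a) / (2 * m)
    w <- c(1, rep(c(4, 2), m - 1L), 4, 1)
    sum(w * f(xs)) * h / 3
  }
  tavOracle <- simpson(function(x) (11 + 0.1 * x) - (4 + 0.3 * x), 0, (n - 1) / 60)
  tvvOracle <- simpson(function(x) 11 + 0.1 * x, 0, (n - 1) / 60)
  expect_equal(tgt2$PAV_BL, 100 * tavOracle / tvvOracle, tolerance = 1e-6)

  expect_error(roiTarget(data.frame(start = 0L, end = n + 50L), bl, fu),
               class = "plaquetrend_range_error")
})

test_that("integrals are conserved over disjoint exhaustive partitions", {
  set.seed(13)
  n <- 241L
  lum <- 5 + cumsum(rnorm(n, 0, 0.02)); ves <- lum + 4 + abs(rnorm(n, 1, 0.2))
  bl <- areasOf(lum, ves); fu <- areasOf(lum * 0.95, ves)
  whole <- roiTarget(data.frame(start = 0L, end = n), bl, fu)
  cuts <- c(0L, 60L, 150L, 200L, n)
  parts <- lapply(seq_len(length(cuts) - 1L), function(i)
    roiTarget(data.frame(start = cuts[i], end = cuts[i + 1L]), bl, fu))
  expect_equal(sum(vapply(parts, `[[`, numeric(1), "TAV_BL")), whole$TAV_BL,
               tolerance = 1e-9)
  expect_equal(sum(vapply(parts, `[[`, numeric(1), "TVV_BL")), whole$TVV_BL,
               tolerance = 1e-9)
  expect_equal(sum(vapply(parts, `[[`, numeric(1), "TLV_FU")), whole$TLV_FU,
               tolerance = 1e-9)
})
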