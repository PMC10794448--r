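# Folds, standardization, MI selection, metrics, leakage guards, post-hoc
# indices.

test_that("repeated stratified folds partition groups with balanced classes", {
  set.seed(41)
  ids <- sprintf("PB%02d", 1:40)
  dpav <- c(rnorm(16, 2, 1), rnorm(24, -2, 1))  # 16 progression, 24 regression
  folds <- makeFolds(ids, dpav, nFolds = 5L, nRepeats = 20L, seed = 3L)
  expect_equal(nrow(folds), 40L * 20L)
  expect_equal(length(unique(folds$repeat_id)) * 5L, 100L)  # 100 models

  cls <- ifelse(dpav > 0, "P", "R")
  names(cls) <- ids
  for (r in unique(folds$repeat_id)) {
    fr <- folds[folds$repeat_id == r, ]
    expect_setequal(fr$group, ids)           # partition: every group once
    tab <- table(fr$fold_id, cls[fr$group])
    # per-fold class counts within 1 of proportional
    expect_true(all(abs(tab[, "P"] - 16 / 5) <= 1))
    expect_true(all(abs(tab[, "R"] - 24 / 5) <= 1))
    expect_equal(sum(tab), 40)
  }
  # every group tested exactly nRepeats times, determinism under the seed
  expect_true(all(table(folds$group) == 20L))
  folds2 <- makeFolds(ids, dpav, nFolds = 5L, nRepeats = 20L, seed = 3L)
  expect_identical(folds, folds2)
  folds3 <- makeFolds(ids, dpav, nFolds = 5L, nRepeats = 20L, seed = 4L)
  expect_false(identical(folds, folds3))

  expect_error(makeFolds(ids[1:3], dpav[1:3], nFolds = 5L),
               class = "plaquetrend_config_error")
})

test_that("standardization uses train-side population parameters", {
  tr <- matrix(c(1, 2, 3, 5, 5, 5), 3, 2)
  colnames(tr) <- c("x", "z")
  te <- matrix(c(2, 4, 5, 9), 2, 2)
  colnames(te) <- c("x", "z")
  std <- standardizeFeatures(tr, te)
  expect_equal(std$train[, "x"], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  expect_equal(std$train[, "z"], c(0, 0, 0))       # zero-variance guard
  expect_equal(std$apply[, "z"], c(0, 0))
  expect_equal(std$apply[, "x"], (c(2, 4) - 2) / sqrt(2 / 3), tolerance = 1e-9)
  # a test row equal to the train mean maps to zero
  expect_equal(unname(standardizeFeatures(tr, tr[2, , drop = FALSE])$apply[1, "x"]),
               0)
})

test_that("leakage guard: pooled-data parameters differ from train-only", {
  set.seed(42)
  tr <- matrix(rnorm(50, 3), 50, 1); te <- matrix(rnorm(20, 8), 20, 1)
  colnames(tr) <- colnames(te) <- "x"
  trainOnly <- standardizeFeatures(tr, te)
  pooled <- standardizeFeatures(rbind(tr, te))
  expect_gt(abs(trainOnly$center["x"] - pooled$center["x"]), 0.5)
  expect_false(isTRUE(all.equal(trainOnly$apply[, "x"],
                                pooled$train[51:70, "x"])))
})

test_that("mutual information ranks a label-identical feature first", {
  set.seed(43)
  y <- rep(c(TRUE, FALSE), each = 100)
  perfect <- as.numeric(y)
  noise <- rnorm(200)
  expect_gt(mutualInfo(perfect + rnorm(200, 0, 1e-6), y),
            mutualInfo(noise, y) + 0.3)
  expect_gte(mutualInfo(noise, y), 0)
})

test_that("k-best selection recovers planted informative features", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(1000 + s)
    n <- 2000L
    y <- rbinom(n, 1L, 0.5) == 1L
    info <- sapply(1:5, function(i) as.numeric(y) * (0.5 + 0.1 * i) +
                                    rnorm(n, 0, 0.6))
    noise <- matrix(rnorm(n * 50L), n, 50L)
    X <- cbind(info, noise)
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    sel <- selectKBest(X, y, k = 8L)
    if (sum(sel <= 5L) >= 4L) hits <- hits + 1L
  }
  expect_gte(hits, 19L)  # >= 4 of 5 informative picked in >= 95% of runs

  set.seed(44)
  X <- matrix(rnorm(100 * 6), 100, 6)
  expect_equal(selectKBest(X, X[, 1] > 0, k = 6L), 1:6)
  expect_error(selectKBest(X, X[, 1] > 0, k = 0L),
               class = "plaquetrend_config_error")
  expect_error(selectKBest(X, X[, 1] > 0, k = 7L),
               class = "plaquetrend_config_error")
  # the label-identical feature is always selected
  y <- X[, 3] > 0
  X2 <- cbind(X, lab = as.numeric(y))
  set.seed(45)
  expect_true(7L %in% selectKBest(X2, y, k = 2L))
})

test_that("metrics match hand-computed confusion arithmetic", {
  perfect <- evaluatePredictions(c(-1, 2, -3, 4), c(-1, 2, -3, 4))
  expect_equal(perfect$MAE, 0); expect_equal(perfect$MSE, 0)
  expect_equal(perfect$ACC, 1); expect_equal(perfect$MCC, 1)
  expect_equal(perfect$F1a, 1)

  # TP=2, FP=1, FN=1, TN=3: ACC = 5/7, MCC = 5/12
  truth <- c(1, 1, 1, -1, -1, -1, -1)
  pred <- c(1, 1, -1, 1, -1, -1, -1)
  m <- evaluatePredictions(pred, truth)
  expect_equal(m$ACC, 5 / 7)
  expect_equal(m$MCC, 5 / 12)
  expect_equal(m$F1pos, 2 * 2 / (2 * 2 + 1 + 1))
  expect_equal(m$F1neg, 2 * 3 / (2 * 3 + 1 + 1))
  expect_equal(m$F1a, (m$F1pos + m$F1neg) / 2)

  # single-class truth with mixed predictions: MCC guard at 0
  g <- evaluatePredictions(c(1, -1, 1), c(1, 1, 1))
  expect_equal(g$MCC, 0)
  expect_equal(g$ACC, 2 / 3)
  # constant predictions: r guard at 0
  expect_equal(evaluatePredictions(c(1, 1, 1), c(1, -1, 2))$r, 0)

  expect_error(evaluatePredictions(numeric(0), numeric(0)),
               class = "plaquetrend_data_error")
})

test_that("experiments keep groups intact and reproduce bit-identically", {
  fix <- smallChpavDataset()
  cfg <- experimentConfig(nFolds = 3L, nRepeats = 4L, seed = 9L,
                          kSelect = 8L, nEstimators = 32L, maxDepth = 6L,
                          computeShap = FALSE)
  res <- runExperiment(fix$ds$features, fix$groupDPAV, cfg)
  expect_equal(nrow(res@metrics), 12L)

  # group integrity: no pullback on both sides of one model
  pr <- modelPredictions(res)
  folds <- res@folds
  for (mid in unique(pr$model_id)) {
    sub <- pr[pr$model_id == mid, ]
    r <- sub$repeat_id[1]; f <- sub$fold_id[1]
    testPbs <- folds$group[folds$repeat_id == r & folds$fold_id == f]
    expect_true(all(sub$pullback_id %in% testPbs))
  }

  res2 <- runExperiment(fix$ds$features, fix$groupDPAV, cfg)
  expect_identical(modelPredictions(res2)$y_pred, pr$y_pred)
  expect_identical(metricsSummary(res2), metricsSummary(res))
})

test_that("SHAP summary weights selection ratio and zeroes unselected features", {
  fix <- smallChpavDataset()
  cfg <- experimentConfig(nFolds = 3L, nRepeats = 2L, seed = 5L,
                          kSelect = 8L, nEstimators = 32L, maxDepth = 6L,
                          computeShap = TRUE)
  res <- runExperiment(fix$ds$features, fix$groupDPAV, cfg)
  ss <- shapSummary(res)
  expect_setequal(ss$feature, res@featureNames)
  never <- ss[ss$selection_count == 0L, ]
  expect_true(all(never$weighted_shap == 0))
  expect_true(all(ss$selection_ratio == ss$selection_count / 6))
  picked <- ss[ss$selection_count > 0L, ]
  expect_equal(picked$weighted_shap,
               picked$selection_ratio * picked$sum_mean_abs_shap)
})

test_that("post-hoc CCR and CCL follow their length-weighted definitions", {
  # synthetic bookkeeping: 2 pullbacks x 2 ROIs, 2 repeats of 1 "fold"
  pred <- do.call(rbind, lapply(1:2, function(r) data.frame(
    model_id = r, repeat_id = r, fold_id = 1L,
    roi_id = c("a1", "a2", "b1", "b2"),
    pullback_id = c("A", "A", "B", "B"),
    y_true = c(2, -1, 3, -2),
    y_pred = c(1.5, 1.0, -0.5, -1.0),  # a1 right, a2 wrong, b1 wrong, b2 right
    stringsAsFactors = FALSE)))
  res <- new("ExperimentResult",
             config = experimentConfig(nFolds = 2L, nRepeats = 2L),
             folds = data.frame(), predictions = pred,
             metrics = data.frame(model_id = 1:2, repeat_id = 1:2,
                                  fold_id = 1L),
             selection = list(), shap = list(), featureNames = character(0))
  lens <- c(a1 = 3, a2 = 1, b1 = 1, b2 = 1)
  ph <- posthocIndices(res, lens)
  expect_equal(ph$roi$CCR[ph$roi$roi_id == "a1"], 1)
  expect_equal(ph$roi$CCR[ph$roi$roi_id == "a2"], 0)
  expect_equal(ph$roi$appearances, rep(2L, 4))
  # pullback A: lengths 3 (correct) + 1 (wrong) -> CCL = 0.75 in every model
  expect_equal(ph$pullback$CCL_mean[ph$pullback$pullback_id == "A"], 0.75)
  expect_equal(ph$pullback$CCL_sd[ph$pullback$pullback_id == "A"], 0)
  expect_equal(ph$pullback$CCL_mean[ph$pullback$pullback_id == "B"], 0.5)
  expect_false(ph$pullback$correct[ph$pullback$pullback_id == "B"])

  expect_error(posthocIndices(res, lens[1:2]),
               class = "plaquetrend_bookkeeping_error")
})

test_that("one-hot artery expansion is numeric and level-stable", {
  df <- data.frame(x = 1:3, artery = c("LAD", "RCA", "LAD"),
                   stringsAsFactors = FALSE)
  oh <- oneHotArtery(df, levels = c("LAD", "LCx", "RCA"))
  expect_setequal(names(oh), c("x", "A_LAD", "A_LCx", "A_RCA"))
  expect_equal(oh$A_LAD, c(1, 0, 1))
  expect_equal(oh$A_LCx, c(0, 0, 0))
})
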