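# Cross-validated dPAV regression/classification: repeated stratified k-fold
# at the pullback level, train-side standardization and mutual-information
# k-best selection, gradient-boosted trees, metrics, SHAP summaries and
# post-hoc CCR/CCL indices.

#' Experiment configuration
#'
#' @param nFolds folds per repeat (default 5).
#' @param nRepeats repeats (default 20), for nFolds x nRepeats models.
#' @param seed integer seed controlling fold assignment and selector
#'   tie-breaking.
#' @param kSelect number of features kept by mutual-information selection;
#'   0 disables selection. Typical values: 0, 8, 32.
#' @param nEstimators,maxDepth,eta,minLeaf,lambda booster settings (defaults:
#'   256 trees, depth 12, squared error via residual fitting, learning rate
#'   0.3, L2 leaf regularization 1).
#' @param groupBy \code{"pullback"} (default, the operative protocol) or
#'   \code{"patient"}.
#' @param computeShap compute TreeSHAP attributions on every test fold.
#' @return a named list of settings.
#' @export
experimentConfig <- function(nFolds = 5L, nRepeats = 20L, seed = 1L,
                             kSelect = 0L, nEstimators = 256L,
                             maxDepth = 12L, eta = 0.3, minLeaf = 1L,
                             lambda = 1,
                             groupBy = c("pullback", "patient"),
                             computeShap = TRUE) {
  groupBy <- match.arg(groupBy)
  stopifnot(nFolds >= 2L, nRepeats >= 1L, kSelect >= 0L, nEstimators >= 1L,
            maxDepth >= 1L, eta > 0, lambda >= 0)
  list(nFolds = as.integer(nFolds), nRepeats = as.integer(nRepeats),
       seed = as.integer(seed), kSelect = as.integer(kSelect),
       nEstimators = as.integer(nEstimators), maxDepth = as.integer(maxDepth),
       eta = eta, minLeaf = as.integer(minLeaf), lambda = lambda,
       groupBy = groupBy, computeShap = isTRUE(computeShap))
}

#' Repeated stratified group-level fold assignment
#'
#' Folds partition the groups (pullbacks) within each repeat; stratification
#' is by the sign of the group-level dPAV (progression iff dPAV > 0), with
#' per-fold class counts within 1 of proportional. Deterministic given the
#' seed.
#'
#' @param groupIds character/factor vector of group identifiers (one entry
#'   per group).
#' @param groupDPAV group-level dPAV used for stratification.
#' @param nFolds,nRepeats,seed see [experimentConfig()].
#' @return data.frame with columns \code{repeat_id}, \code{fold_id},
#'   \code{group}, giving each group's test fold per repeat.
#' @export
makeFolds <- function(groupIds, groupDPAV, nFolds = 5L, nRepeats = 20L,
                      seed = 1L) {
  groupIds <- as.character(groupIds)
  if (anyDuplicated(groupIds))
    ptStop("config_error", "group ids must be unique")
  if (length(groupIds) < nFolds)
    ptStop("config_error", "fewer groups than folds")
  cls <- ifelse(groupDPAV > 0, "progression", "regression")
  set.seed(seed)
  rows <- list()
  for (r in seq_len(nRepeats)) {
    fold <- integer(length(groupIds))
    for (cl in unique(cls)) {
      members <- which(cls == cl)
      nc <- length(members)
      cnt <- rep(nc %/% nFolds, nFolds)
      extra <- nc %% nFolds
      if (extra > 0L) {
        lucky <- sample.int(nFolds, extra)
        cnt[lucky] <- cnt[lucky] + 1L
      }
      labels <- rep(seq_len(nFolds), times = cnt)
      fold[members[sample.int(nc)]] <- labels
    }
    rows[[r]] <- data.frame(repeat_id = r, fold_id = fold,
                            group = groupIds, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' One-hot expansion of the arterial label
#'
#' Expands the categorical \code{artery} column of a feature data.frame into
#' 0/1 indicator columns \code{A_<label>} over a fixed level set, leaving all
#' other columns untouched.
#'
#' @param features ROI feature data.frame.
#' @param levels label universe; defaults to the labels present, sorted.
#' @return numeric data.frame.
#' @export
oneHotArtery <- function(features, levels = NULL) {
  if (!"artery" %in% names(features)) return(features)
  lab <- as.character(features$artery)
  if (is.null(levels)) levels <- sort(unique(lab))
  oh <- vapply(levels, function(l) as.numeric(lab == l),
               numeric(length(lab)))
  oh <- as.data.frame(oh)
  names(oh) <- paste0("A_", levels)
  cbind(features[setdiff(names(features), "artery")], oh)
}

#' Train-parameter standardization
#'
#' Centres and scales every column to train mean 0 and population (divide by
#' n) standard deviation 1; zero-variance columns map to all zeros. The
#' apply-side matrix is always transformed with the TRAIN parameters. One-hot
#' indicator columns (names starting \code{A_}) pass through unchanged.
#'
#' @param train numeric matrix or data.frame.
#' @param apply optional matrix transformed with the train parameters.
#' @return list with \code{train}, \code{apply} (matrices) and
#'   \code{center}, \code{scale} vectors.
#' @export
standardizeFeatures <- function(train, apply = NULL) {
  train <- as.matrix(train)
  passthrough <- startsWith(colnames(train), "A_")
  ctr <- colMeans(train)
  n <- nrow(train)
  sdev <- sqrt(colMeans(train^2) - ctr^2)
  sdev[sdev < 1e-12] <- NA_real_  # zero-variance guard: column -> zeros
  ctr[passthrough] <- 0
  sdev[passthrough] <- 1
  tf <- function(m) {
    m <- sweep(m, 2L, ctr, "-")
    m <- sweep(m, 2L, sdev, "/")
    m[, is.na(sdev)] <- 0
    m
  }
  out <- list(train = tf(train), center = ctr, scale = sdev)
  if (!is.null(apply)) out$apply <- tf(as.matrix(apply))
  out
}

#' Nearest-neighbour mutual information with a binary label
#'
#' Ross-type estimator for a continuous feature against a discrete class:
#' for each sample, the distance to its k-th nearest neighbour within its own
#' class defines a radius; counting all-sample neighbours inside that radius
#' gives the digamma-based estimate
#' \eqn{\hat I = \psi(N) + \psi(k) - \langle\psi(N_c)\rangle -
#' \langle\psi(m)\rangle}, clipped at 0. A tiny seeded jitter (1e-10 of the
#' feature scale) breaks ties, so the estimate is deterministic given the
#' seed.
#'
#' @param x numeric feature.
#' @param y binary labels (two levels).
#' @param k neighbour order (default 3).
#' @return non-negative MI estimate (nats).
#' @export
mutualInfo <- function(x, y, k = 3L) {
  y <- as.integer(factor(y))
  N <- length(x)
  keepCls <- as.integer(names(which(table(y) > k)))
  use <- y %in% keepCls
  if (sum(use) < 2L * (k + 1L)) return(0)
  x <- x[use]; y <- y[use]; N <- length(x)
  ordAll <- sort(x)
  radius <- numeric(N)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    xs <- sort(x[idx])
    nc <- length(xs)
    kk <- min(k, nc - 1L)
    d <- rep(Inf, nc)
    for (l in 0:kk) {
      r <- kk - l
      lo <- seq_len(nc) - l
      hi <- seq_len(nc) + r
      okw <- lo >= 1L & hi <= nc
      cand <- rep(Inf, nc)
      cand[okw] <- pmax(xs[seq_len(nc)[okw]] - xs[lo[okw]],
                        xs[hi[okw]] - xs[seq_len(nc)[okw]])
      d <- pmin(d, cand)
    }
    # map back to original order within the class
    radius[idx[order(x[idx])]] <- d
  }
  r <- radius * (1 - 1e-12)
  m <- findInterval(x + r, ordAll) - findInterval(x - r, ordAll,
                                                  left.open = TRUE)
  m <- pmax(m, 1L)  # includes the point itself
  nC <- table(y)[as.character(y)]
  mi <- digamma(N) + digamma(k) - mean(digamma(as.numeric(nC))) -
    mean(digamma(m))
  max(0, mi)
}

#' k-best feature selection by mutual information with the class label
#'
#' Scores every column of the training matrix by [mutualInfo()] against the
#' binary progression/regression label (sign of dPAV) and keeps the top k;
#' ties break by column order. Jitter for tie-breaking is drawn once from the
#' seeded RNG, so selection is deterministic given the seed.
#'
#' @param train numeric matrix.
#' @param classLabels binary vector (e.g. \code{dPAV > 0}).
#' @param k number of features to keep.
#' @param k_nn neighbour order of the MI estimator.
#' @return integer indices of the selected columns, in column order.
#' @export
selectKBest <- function(train, classLabels, k, k_nn = 3L) {
  if (k <= 0L)
    ptStop("config_error", "k must be positive")
  p <- ncol(train)
  if (k > p)
    ptStop("config_error", "k exceeds the number of features")
  jitter <- matrix(rnorm(length(train)), nrow(train), p)
  scale <- apply(train, 2L, function(c) max(sd(c), 1e-300))
  xj <- train + sweep(jitter, 2L, scale * 1e-10, "*")
  scores <- vapply(seq_len(p), function(j)
    mutualInfo(xj[, j], classLabels, k = k_nn), numeric(1))
  sort(order(-scores)[seq_len(k)])
}

#' Train the dPAV regressor
#'
#' Thin wrapper over [gbtFit()] using the configuration's booster settings.
#'
#' @param train standardized, selected feature matrix.
#' @param y training dPAV values.
#' @param config an [experimentConfig()].
#' @return a \code{"gbtModel"}.
#' @export
trainRegressor <- function(train, y, config = experimentConfig()) {
  gbtFit(train, y, nEstimators = config$nEstimators,
         maxDepth = config$maxDepth, eta = config$eta,
         minLeaf = config$minLeaf, lambda = config$lambda)
}

.safeDiv <- function(num, den) if (!is.finite(den) || den == 0) 0 else num / den

#' Regression and classification metrics of one model
#'
#' Regression metrics (MAE, MSE, Pearson r) on raw dPAV values;
#' classification metrics after thresholding prediction and truth at 0
#' (dPAV <= 0 is the regression class): accuracy, Matthews correlation
#' coefficient, F1 of each class and their average. MCC, r and F1 are
#' defined as 0 when their denominator vanishes.
#'
#' @param predicted,truth numeric vectors of equal length.
#' @return named list of metrics: \code{MAE, MSE, r, ACC, MCC, F1neg, F1pos,
#'   F1a}.
#' @export
evaluatePredictions <- function(predicted, truth) {
  if (!length(predicted) || length(predicted) != length(truth))
    ptStop("data_error", "predictions and truth must be equal-length, non-empty")
  err <- predicted - truth
  predPos <- predicted > 0
  truePos <- truth > 0
  tp <- sum(predPos & truePos); tn <- sum(!predPos & !truePos)
  fp <- sum(predPos & !truePos); fn <- sum(!predPos & truePos)
  mcc <- .safeDiv(tp * tn - fp * fn,
                  sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
  r <- if (sd(predicted) == 0 || sd(truth) == 0) 0 else cor(predicted, truth)
  f1pos <- .safeDiv(2 * tp, 2 * tp + fp + fn)
  f1neg <- .safeDiv(2 * tn, 2 * tn + fn + fp)
  list(MAE = mean(abs(err)), MSE = mean(err^2), r = r,
       ACC = (tp + tn) / length(truth), MCC = mcc,
       F1neg = f1neg, F1pos = f1pos, F1a = (f1neg + f1pos) / 2)
}

#' Run a full repeated cross-validated experiment
#'
#' For every (repeat, fold): the test pullbacks' ROIs are held out; the
#' arterial label is one-hot expanded; standardization and (optional)
#' mutual-information selection parameters are computed on the training side
#' only; a gradient-boosted tree regressor is fitted and applied to the test
#' side; regression/classification metrics, selected features and
#' (optionally) TreeSHAP attributions are recorded. Group integrity (no
#' pullback on both sides of one model) is asserted on every fold.
#'
#' @param features ROI feature data.frame: metadata columns
#'   \code{roi_id, pullback_id, patient_id, dPAV} plus feature columns
#'   (including a categorical \code{artery} for Sd).
#' @param groupDPAV named numeric: group-level dPAV per pullback (or per
#'   patient under \code{groupBy = "patient"}) used for stratification;
#'   typically the full-pullback dPAV.
#' @param config an [experimentConfig()].
#' @return an [ExperimentResult-class].
#' @export
runExperiment <- function(features, groupDPAV, config = experimentConfig()) {
  meta <- c("roi_id", "pullback_id", "patient_id", "dPAV")
  if (!all(meta %in% names(features)))
    ptStop("data_error", paste("features needs columns:",
                               paste(meta, collapse = ", ")))
  groupCol <- if (config$groupBy == "patient") "patient_id" else "pullback_id"
  groups <- unique(as.character(features[[groupCol]]))
  if (!all(groups %in% names(groupDPAV)))
    ptStop("data_error", "groupDPAV must cover every group")

  X <- oneHotArtery(features[setdiff(names(features), meta)])
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- features$dPAV
  g <- as.character(features[[groupCol]])

  folds <- makeFolds(groups, groupDPAV[groups], config$nFolds,
                     config$nRepeats, config$seed)
  set.seed(config$seed + 1L)  # selector jitter stream

  predRows <- list(); metRows <- list()
  selection <- list(); shap <- list()
  modelId <- 0L
  for (r in seq_len(config$nRepeats)) {
    fr <- folds[folds$repeat_id == r, ]
    for (f in seq_len(config$nFolds)) {
      modelId <- modelId + 1L
      testGroups <- fr$group[fr$fold_id == f]
      testIdx <- g %in% testGroups
      stopifnot(!any(g[testIdx] %in% g[!testIdx]))  # group integrity
      if (!any(testIdx) || sum(!testIdx) < 2L)
        ptStop("config_error", "a fold has an empty train or test side")
      std <- standardizeFeatures(X[!testIdx, , drop = FALSE],
                                 X[testIdx, , drop = FALSE])
      selIdx <- seq_len(ncol(X))
      if (config$kSelect > 0L)
        selIdx <- selectKBest(std$train, y[!testIdx] > 0, config$kSelect)
      tr <- std$train[, selIdx, drop = FALSE]
      te <- std$apply[, selIdx, drop = FALSE]
      model <- trainRegressor(tr, y[!testIdx], config)
      pred <- predict(model, te)
      met <- evaluatePredictions(pred, y[testIdx])
      metRows[[modelId]] <- data.frame(model_id = modelId, repeat_id = r,
                                       fold_id = f, as.data.frame(met))
      predRows[[modelId]] <- data.frame(
        model_id = modelId, repeat_id = r, fold_id = f,
        roi_id = features$roi_id[testIdx],
        pullback_id = features$pullback_id[testIdx],
        y_true = y[testIdx], y_pred = pred, stringsAsFactors = FALSE)
      selection[[modelId]] <- colnames(X)[selIdx]
      if (config$computeShap) {
        sh <- gbtShap(model, te)
        shap[[modelId]] <- list(
          meanAbs = colMeans(abs(sh$phi)),
          expected = sh$expected,
          additivityGap = max(abs(rowSums(sh$phi) + sh$expected - pred)))
      }
    }
  }
  new("ExperimentResult", config = config, folds = folds,
      predictions = do.call(rbind, predRows),
      metrics = do.call(rbind, metRows),
      selection = selection, shap = shap, featureNames = colnames(X))
}

#' Aggregate metric summary of an experiment
#'
#' Mean, standard deviation, minimum and maximum of every metric over the
#' models, mirroring the mean (std) [min, max] reporting format.
#'
#' @param object an [ExperimentResult-class].
#' @return data.frame with columns \code{metric, mean, sd, min, max}.
#' @export
metricsSummary <- function(object) {
  m <- object@metrics
  metrics <- setdiff(names(m), c("model_id", "repeat_id", "fold_id"))
  data.frame(
    metric = metrics,
    mean = vapply(metrics, function(k) mean(m[[k]]), numeric(1)),
    sd = vapply(metrics, function(k) sd(m[[k]]), numeric(1)),
    min = vapply(metrics, function(k) min(m[[k]]), numeric(1)),
    max = vapply(metrics, function(k) max(m[[k]]), numeric(1)),
    row.names = NULL)
}

#' Selection counts and SR-weighted mean |SHAP| per feature
#'
#' Counts how often each feature was selected across the models, the
#' selection ratio SR = count / n_models, and the SR-weighted total mean
#' absolute SHAP attribution (SR times the sum over models of the feature's
#' mean |SHAP| on that model's test set). Never-selected features score
#' exactly 0.
#'
#' @param object an [ExperimentResult-class] run with
#'   \code{computeShap = TRUE}.
#' @return data.frame with columns \code{feature, selection_count,
#'   selection_ratio, sum_mean_abs_shap, weighted_shap}, sorted by
#'   \code{weighted_shap} decreasing.
#' @export
shapSummary <- function(object) {
  if (!length(object@shap))
    ptStop("capability_error", "experiment was run without SHAP")
  nModels <- nrow(object@metrics)
  feats <- object@featureNames
  cnt <- setNames(numeric(length(feats)), feats)
  tot <- setNames(numeric(length(feats)), feats)
  for (i in seq_along(object@selection)) {
    sel <- object@selection[[i]]
    cnt[sel] <- cnt[sel] + 1
    ma <- object@shap[[i]]$meanAbs
    tot[names(ma)] <- tot[names(ma)] + ma
  }
  sr <- cnt / nModels
  out <- data.frame(feature = feats, selection_count = as.integer(cnt),
                    selection_ratio = sr, sum_mean_abs_shap = tot,
                    weighted_shap = sr * tot, row.names = NULL)
  out[order(-out$weighted_shap, out$feature), ]
}

#' Post-hoc correct-classification indices
#'
#' Every ROI appears in the test set of \code{nRepeats} models; CCR is the
#' fraction of those appearances in which the sign of the prediction matched
#' the sign of the truth (threshold 0, dPAV <= 0 is the regression class).
#' CCL for a pullback and one model is the length-weighted fraction of its
#' ROIs that the model classified correctly; per pullback the mean and sd
#' over its test models are reported.
#'
#' @param object an [ExperimentResult-class].
#' @param roiLengths named numeric: ROI length in mm per \code{roi_id}.
#' @return list with \code{roi} (roi_id, appearances, CCR, mean_pred,
#'   mean_abs_err, correct = CCR > 0.5) and \code{pullback} (pullback_id,
#'   CCL_mean, CCL_sd, correct = CCL_mean > 0.5) data.frames.
#' @export
posthocIndices <- function(object, roiLengths) {
  pr <- object@predictions
  if (!all(as.character(pr$roi_id) %in% names(roiLengths)))
    ptStop("bookkeeping_error", "roiLengths must cover every ROI")
  pr$correct <- (pr$y_pred > 0) == (pr$y_true > 0)
  nRep <- object@config$nRepeats
  app <- tapply(pr$correct, pr$roi_id, length)
  if (any(app != nRep))
    ptStop("bookkeeping_error",
           "every ROI must appear in exactly nRepeats test sets")
  roi <- data.frame(
    roi_id = names(app),
    appearances = as.integer(app),
    CCR = as.numeric(tapply(pr$correct, pr$roi_id, mean)),
    mean_pred = as.numeric(tapply(pr$y_pred, pr$roi_id, mean)),
    mean_abs_err = as.numeric(tapply(abs(pr$y_pred - pr$y_true), pr$roi_id,
                                     mean)),
    stringsAsFactors = FALSE)
  roi$correct <- roi$CCR > 0.5

  pr$len <- roiLengths[as.character(pr$roi_id)]
  key <- interaction(pr$pullback_id, pr$model_id, drop = TRUE)
  cclPerModel <- tapply(pr$correct * pr$len, key, sum) /
    tapply(pr$len, key, sum)
  pbOfKey <- as.character(tapply(as.character(pr$pullback_id), key, `[`, 1L))
  cclMean <- tapply(cclPerModel, pbOfKey, mean)
  pullback <- data.frame(
    pullback_id = names(cclMean),
    CCL_mean = as.numeric(cclMean),
    CCL_sd = as.numeric(tapply(cclPerModel, pbOfKey, sd)),
    stringsAsFactors = FALSE)
  pullback$correct <- pullback$CCL_mean > 0.5
  list(roi = roi, pullback = pullback)
}

#' Write the aggregate metrics of an experiment as CSV
#'
#' Fixed-format (6 significant digits, "." decimal separator) so identical
#' experiments produce byte-identical files.
#'
#' @param object an [ExperimentResult-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMetricsCsv <- function(object, path) {
  ms <- metricsSummary(object)
  lines <- c("metric,mean,sd,min,max",
             sprintf("%s,%.6g,%.6g,%.6g,%.6g", ms$metric, ms$mean, ms$sd,
                     ms$min, ms$max))
  writeLines(lines, path)
  invisible(path)
}
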