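# R front-end of the package-internal gradient-boosted tree regressor.

#' Fit a gradient-boosted regression-tree ensemble
#'
#' Squared-error gradient boosting: each tree is a greedy CART regression
#' tree fit to the current residuals (variance-reduction splits, deterministic
#' tie-breaking by feature order and leftmost split), added with shrinkage
#' \code{eta}. The base score is the training-target mean, so a constant
#' target is reproduced exactly. The procedure uses no randomness: identical
#' inputs give an identical model.
#'
#' @param X numeric matrix (rows = samples).
#' @param y numeric response (here: dPAV in %).
#' @param nEstimators number of trees (default 256).
#' @param maxDepth maximum tree depth (default 12).
#' @param eta learning rate (default 0.3).
#' @param minLeaf minimum samples per leaf (default 1).
#' @param lambda L2 regularization on leaf values (default 1): a leaf over m
#'   samples takes value sum(residuals) / (m + lambda) and split gains use
#'   the regularized scores, matching the defaults of standard
#'   gradient-boosting libraries.
#' @return an object of class \code{"gbtModel"}.
#' @export
gbtFit <- function(X, y, nEstimators = 256L, maxDepth = 12L, eta = 0.3,
                   minLeaf = 1L, lambda = 1) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) == 0L || length(y) == 0L)
    ptStop("data_error", "empty training set")
  if (nrow(X) != length(y))
    ptStop("data_error", "X and y differ in length")
  fit <- .gbtFitCpp(X, as.numeric(y), as.integer(nEstimators),
                    as.integer(maxDepth), as.numeric(eta),
                    as.integer(minLeaf), as.numeric(lambda))
  structure(list(trees = fit$trees, base = fit$base, eta = fit$eta,
                 p = fit$p, featureNames = colnames(X),
                 nEstimators = as.integer(nEstimators),
                 maxDepth = as.integer(maxDepth)),
            class = "gbtModel")
}

#' @export
print.gbtModel <- function(x, ...) {
  cat(sprintf("gbtModel: %d trees, max depth %d, eta %.3g, %d features\n",
              x$nEstimators, x$maxDepth, x$eta, x$p))
  invisible(x)
}

#' Predict from a gradient-boosted tree model
#'
#' @param object a \code{"gbtModel"}.
#' @param newdata numeric matrix with the training columns.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gbtModel <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object$p)
    ptStop("data_error", "newdata has the wrong number of columns")
  as.numeric(.gbtPredictCpp(object$trees, object$base, object$eta, newdata))
}

#' Exact TreeSHAP attributions of a gradient-boosted tree model
#'
#' Path-dependent TreeSHAP with training-cover weighting: per sample, the
#' per-feature attributions plus the expected model output equal the model
#' prediction exactly (additivity).
#'
#' @param model a \code{"gbtModel"}.
#' @param X numeric matrix of samples to explain.
#' @return list with \code{phi} (samples x features attribution matrix,
#'   named columns) and \code{expected} (the cover-weighted expected model
#'   output).
#' @export
gbtShap <- function(model, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != model$p)
    ptStop("data_error", "X has the wrong number of columns")
  out <- .gbtShapCpp(model$trees, model$base, model$eta, X)
  colnames(out$phi) <- model$featureNames
  out
}
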