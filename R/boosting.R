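#' Fit a gradient-boosted tree classifier
#'
#' Binary classifier trained by gradient boosting with logistic loss and
#' depth-limited regression trees. Splits and leaf weights use the
#' second-order (gain-based) formulation with L2 regularization `lambda`:
#' a split's gain is
#' `0.5 * (GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda))`
#' and a leaf's weight is `-G/(H+lambda)` scaled by `learning_rate`, where
#' `G`/`H` are the sums of loss gradients and Hessians in the node. Feature
#' importance is the total split gain accumulated per feature.
#'
#' The fit is fully deterministic: no subsampling, features scanned in column
#' order, ties in gain resolved in favor of the first candidate found.
#'
#' @param x Numeric matrix, samples in rows, features in columns.
#' @param y Binary labels (see [auc_score()] for accepted encodings).
#' @param n_trees Number of boosting rounds.
#' @param max_depth Maximum tree depth (1 = stumps).
#' @param learning_rate Shrinkage applied to each leaf weight.
#' @param lambda L2 regularization on leaf weights.
#' @param min_obs Minimum samples per child node.
#' @param colsample Fraction of features visible to each tree (column
#'   subsampling). `1` scans all columns and the fit is RNG-free; below 1
#'   each tree draws its own feature subset, which spreads importance over
#'   correlated informative features. The per-tree subset never drops
#'   below `min(p, 50)` features, so small problems are not starved.
#' @param seed Integer seed for the column subsampler. When `NULL` it is
#'   drawn from R's RNG stream, so fits are reproducible under
#'   `set.seed()`; ignored when `colsample = 1`.
#' @return An object of class `gbt_model` with elements `trees`,
#'   `base_score`, `importance` (named by column) and `n_features`.
#' @export
gbt_fit <- function(x, y, n_trees = 100L, max_depth = 2L,
                    learning_rate = 0.1, lambda = 1, min_obs = 2L,
                    colsample = 1, seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  yb <- as_binary_labels(y)
  if (any(!is.finite(x))) stop("x must be finite")
  if (colsample <= 0 || colsample > 1) stop("colsample must be in (0, 1]")
  colsample <- max(colsample, min(ncol(x), 50L) / ncol(x))
  if (is.null(seed))
    seed <- if (colsample < 1) sample.int(2147483000L, 1L) else 0L
  fit <- .gbt_fit_cpp(x, as.numeric(yb), as.integer(n_trees),
                      as.integer(max_depth), learning_rate, lambda,
                      as.integer(min_obs), colsample, as.integer(seed))
  names(fit$importance) <- colnames(x)
  class(fit) <- "gbt_model"
  fit
}

#' Predict from a gradient-boosted tree classifier
#'
#' @param object A `gbt_model` from [gbt_fit()].
#' @param newdata Numeric matrix with the same columns (in order) as training.
#' @param type `"link"` for raw margins, `"response"` for probabilities.
#' @param ... Unused.
#' @return Numeric vector of scores.
#' @export
predict.gbt_model <- function(object, newdata, type = c("link", "response"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object$n_features)
    stop("newdata has ", ncol(newdata), " features; model expects ",
         object$n_features)
  m <- .gbt_predict_cpp(unclass(object), newdata)
  if (type == "response") 1 / (1 + exp(-m)) else m
}

#' @export
print.gbt_model <- function(x, ...) {
  cat("Gradient-boosted tree classifier:", length(x$trees), "trees,",
      x$n_features, "features\n")
  invisible(x)
}
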