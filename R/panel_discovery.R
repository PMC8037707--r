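#' Configuration for gradient-boosting panel discovery
#'
#' Defaults follow the modeling protocol this package implements: an 80/20
#' stratified hold-out with 5-fold stratified cross-validation over the
#' training partition to pick boosting hyperparameters from a small fixed
#' grid, repeated 10 times with test ROC AUCs averaged; stability selection
#' over stratified subsamples; and a 1000-reshuffle label-permutation test.
#'
#' @param train_fraction Training share of each hold-out split.
#' @param cv_folds Stratified CV folds on the training partition.
#' @param n_repeats Hold-out repetitions whose test AUCs are averaged.
#' @param n_subsamples Stability-selection subsample draws.
#' @param subsample_fraction Fraction of samples per stability draw
#'   (stratified, without replacement).
#' @param top_q_per_subsample Features marked selected per draw (default
#'   `2 * panel_size`).
#' @param n_permutations Label reshuffles for the permutation test.
#' @param perm_repeats Hold-out repetitions per permutation (default 1 for
#'   desk-scale runtime; set to `n_repeats` for the full protocol).
#' @param perm_cv_select If `TRUE` each permutation re-runs hyperparameter
#'   CV; default `FALSE` uses `fixed_params`.
#' @param panel_size Panel size K (top-K features reported).
#' @param grid Data frame of candidate hyperparameters (`max_depth`,
#'   `n_trees`, `learning_rate`).
#' @param fixed_params Single-row hyperparameters for stability selection
#'   and (by default) permutations.
#' @param colsample Per-tree column-subsampling fraction handed to
#'   [gbt_fit()] (default 0.05, with `gbt_fit()`'s 50-feature floor): each
#'   tree sees a random feature subset so importance spreads over
#'   correlated discriminative metabolites instead of collapsing onto one
#'   representative.
#' @param seed Seed from which all per-stage seeds are derived.
#' @return A `model_config` list, validated.
#' @export
model_config <- function(train_fraction = 0.8, cv_folds = 5L, n_repeats = 10L,
                         n_subsamples = 100L, subsample_fraction = 0.8,
                         top_q_per_subsample = NULL, n_permutations = 1000L,
                         perm_repeats = 1L, perm_cv_select = FALSE,
                         panel_size = 30L,
                         grid = data.frame(max_depth = c(2L, 2L, 3L, 3L),
                                           n_trees = c(100L, 300L, 100L, 300L),
                                           learning_rate = 0.1),
                         fixed_params = NULL, colsample = 0.05, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  if (cv_folds < 2L) stop("cv_folds must be >= 2")
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  if (is.null(top_q_per_subsample)) top_q_per_subsample <- 2L * panel_size
  if (is.null(fixed_params))
    fixed_params <- data.frame(max_depth = 2L, n_trees = 300L,
                               learning_rate = 0.1)
  structure(list(train_fraction = train_fraction, cv_folds = as.integer(cv_folds),
                 n_repeats = as.integer(n_repeats),
                 n_subsamples = as.integer(n_subsamples),
                 subsample_fraction = subsample_fraction,
                 top_q_per_subsample = as.integer(top_q_per_subsample),
                 n_permutations = as.integer(n_permutations),
                 perm_repeats = as.integer(perm_repeats),
                 perm_cv_select = isTRUE(perm_cv_select),
                 panel_size = as.integer(panel_size), grid = grid,
                 fixed_params = fixed_params, colsample = colsample,
                 seed = as.integer(seed)),
            class = "model_config")
}

# Extract the feature x sample matrix (samples in rows for the learner) and
# binary labels for a two-group contrast from a zscore_matrix.
contrast_data <- function(z, groups) {
  cols <- contrast_columns(z, groups)
  x <- t(z$z[, c(cols[[1L]], cols[[2L]]), drop = FALSE])
  y <- c(rep(0L, length(cols[[1L]])), rep(1L, length(cols[[2L]])))
  if (any(!is.finite(x))) stop("features must be finite")
  list(x = x, y = y)
}

fit_one <- function(x, y, params, colsample = 1) {
  gbt_fit(x, y, n_trees = params$n_trees, max_depth = params$max_depth,
          learning_rate = params$learning_rate, colsample = colsample)
}

# 5-fold stratified CV over the training partition: mean validation AUC per
# grid row; the first row attaining the maximum wins (deterministic). The
# fold models of the winning row are part of the classifier ensemble, so
# their summed importances are returned alongside the selection.
cv_select_params <- function(x, y, config) {
  fold <- stratified_folds(y, config$cv_folds)
  fold_imp <- vector("list", nrow(config$grid))
  cv_auc <- vapply(seq_len(nrow(config$grid)), function(g) {
    imp <- numeric(ncol(x))
    aucs <- vapply(seq_len(config$cv_folds), function(f) {
      tr <- fold != f
      if (length(unique(y[!tr])) < 2L) return(NA_real_)
      fit <- fit_one(x[tr, , drop = FALSE], y[tr], config$grid[g, ],
                     config$colsample)
      imp <<- imp + fit$importance
      auc_score(predict(fit, x[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
    fold_imp[[g]] <<- imp
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(cv_auc)
  list(params = config$grid[best, , drop = FALSE],
       fold_importance = fold_imp[[best]])
}

#' Repeated stratified hold-out evaluation of the boosting classifier
#'
#' For each repeat: a stratified 80/20 train/test split; stratified CV on
#' the training partition selects boosting hyperparameters from the config
#' grid; the model is refit on the full training partition; ROC AUC is
#' computed on the held-out samples and per-feature importances are taken
#' from the refit model. Test AUCs are averaged over repeats for the final
#' test ROC AUC. Deterministic for a fixed config seed.
#'
#' @param z A `zscore_matrix` (merged or single-run).
#' @param groups Length-2 character: reference group, case group.
#' @param config A [model_config()].
#' @param seed Overrides `config$seed` when given.
#' @return List: `mean_auc`, `aucs` (per repeat), `importances` (repeat x
#'   feature matrix of raw gain importances), `params` (chosen
#'   hyperparameters per repeat).
#' @export
repeated_holdout_auc <- function(z, groups = c("control", "AS_pre"),
                                 config = model_config(), seed = NULL) {
  dat <- contrast_data(z, groups)
  if (min(table(dat$y)) < 2L) stop("each class needs >= 2 samples")
  seed <- if (is.null(seed)) config$seed else seed
  with_seed(derive_seed(seed, "holdout"), {
    p <- ncol(dat$x)
    aucs <- numeric(config$n_repeats)
    imp <- matrix(0, config$n_repeats, p,
                  dimnames = list(NULL, colnames(dat$x)))
    params <- vector("list", config$n_repeats)
    for (r in seq_len(config$n_repeats)) {
      sp <- stratified_split(dat$y, config$train_fraction)
      xtr <- dat$x[sp$train, , drop = FALSE]
      ytr <- dat$y[sp$train]
      sel <- cv_select_params(xtr, ytr, config)
      fit <- fit_one(xtr, ytr, sel$params, config$colsample)
      aucs[r] <- auc_score(predict(fit, dat$x[sp$test, , drop = FALSE]),
                           dat$y[sp$test])
      # ensemble importance: refit model plus the winning config's CV fold
      # models, averaged per model
      imp[r, ] <- (fit$importance + sel$fold_importance) / (config$cv_folds + 1)
      params[[r]] <- sel$params
    }
    list(mean_auc = mean(aucs), aucs = aucs, importances = imp,
         params = do.call(rbind, params))
  })
}

#' Stability selection of discriminative features
#'
#' Repeatedly refits the boosting classifier on stratified subsamples drawn
#' without replacement and records, per feature, how often it ranks within
#' the `top_q_per_subsample` features by importance. The resulting selection
#' frequency measures robustness of a feature's importance to sampling.
#'
#' @inheritParams repeated_holdout_auc
#' @return Named numeric vector of selection frequencies in `[0, 1]`.
#' @export
stability_select <- function(z, groups = c("control", "AS_pre"),
                             config = model_config(), seed = NULL) {
  dat <- contrast_data(z, groups)
  n <- length(dat$y)
  if (ceiling(config$subsample_fraction * n) < length(unique(dat$y)))
    stop("subsample smaller than the number of classes")
  seed <- if (is.null(seed)) config$seed else seed
  with_seed(derive_seed(seed, "stability"), {
    p <- ncol(dat$x)
    q <- min(config$top_q_per_subsample, p)
    hits <- stats::setNames(numeric(p), colnames(dat$x))
    for (b in seq_len(config$n_subsamples)) {
      idx <- stratified_sample(dat$y, config$subsample_fraction)
      if (length(unique(dat$y[idx])) < 2L)
        stop("stratification failure in stability subsample")
      fit <- fit_one(dat$x[idx, , drop = FALSE], dat$y[idx],
                     config$fixed_params, config$colsample)
      nnz <- sum(fit$importance > 0)
      top <- order(-fit$importance, colnames(dat$x))[seq_len(min(q, nnz))]
      hits[top] <- hits[top] + 1
    }
    hits / config$n_subsamples
  })
}

#' Rank features into a panel by importance and stability
#'
#' Composite score = mean gain importance across hold-out repeats times the
#' stability-selection frequency, rescaled so the top feature scores exactly
#' 100 (relative variable importance, %). The top-K panel is extracted with
#' a deterministic tie rule: score descending, then feature name ascending.
#'
#' @param holdout Result of [repeated_holdout_auc()].
#' @param frequencies Result of [stability_select()].
#' @param panel_size Panel size K.
#' @return A `panel_result` list: `table` (feature, importance,
#'   stability_frequency, rank for all features, sorted), `panel` (top-K
#'   feature names), `mean_auc`, `aucs`.
#' @export
rank_variable_importance <- function(holdout, frequencies, panel_size = 30L) {
  mi <- colMeans(holdout$importances)
  if (!identical(names(mi), names(frequencies)))
    frequencies <- frequencies[names(mi)]
  score <- mi * frequencies
  if (all(score == 0)) stop("degenerate model: all composite importances are zero")
  rel <- score / max(score) * 100
  o <- order(-rel, names(rel))
  tab <- data.frame(feature = names(rel)[o],
                    importance = rel[o],
                    mean_gain = mi[o],
                    stability_frequency = frequencies[o],
                    rank = seq_along(rel),
                    row.names = NULL, stringsAsFactors = FALSE)
  k <- min(panel_size, nrow(tab))
  structure(list(table = tab, panel = tab$feature[seq_len(k)],
                 panel_size = k, mean_auc = holdout$mean_auc,
                 aucs = holdout$aucs),
            class = "panel_result")
}

#' @export
print.panel_result <- function(x, ...) {
  cat("Panel of", x$panel_size, "features; mean test ROC AUC =",
      sprintf("%.3f", x$mean_auc), "\n")
  print(utils::head(x$table, x$panel_size))
  invisible(x)
}

#' Label-permutation validity test of the discrimination pipeline
#'
#' The outcome labels are reshuffled uniformly at random `n_permutations`
#' times while the feature profiles are kept intact; the hold-out AUC
#' pipeline is re-run per reshuffle. For exchangeability with the null
#' draws, the observed statistic is recomputed under the same reduced
#' settings used for the permutations (`perm_repeats` repeats and, unless
#' `perm_cv_select`, the fixed hyperparameters). The empirical p-value uses
#' the add-one estimator `(1 + #\{permuted >= observed\}) / (N + 1)`, so it
#' is never zero.
#'
#' @inheritParams repeated_holdout_auc
#' @return A `permutation_result` list: `observed_auc`, `permuted_aucs`,
#'   `p_value`, `n_permutations`.
#' @export
permutation_test <- function(z, groups = c("control", "AS_pre"),
                             config = model_config(), seed = NULL) {
  if (config$n_permutations < 1L) stop("n_permutations must be >= 1")
  dat <- contrast_data(z, groups)
  seed <- if (is.null(seed)) config$seed else seed

  perm_config <- config
  perm_config$n_repeats <- config$perm_repeats
  if (!config$perm_cv_select)
    perm_config$grid <- config$fixed_params

  eval_auc <- function(y, eseed) {
    with_seed(eseed, {
      aucs <- numeric(perm_config$n_repeats)
      for (r in seq_len(perm_config$n_repeats)) {
        sp <- stratified_split(y, perm_config$train_fraction)
        xtr <- dat$x[sp$train, , drop = FALSE]
        best <- if (nrow(perm_config$grid) > 1L)
          cv_select_params(xtr, y[sp$train], perm_config)$params
        else perm_config$grid
        fit <- fit_one(xtr, y[sp$train], best, perm_config$colsample)
        aucs[r] <- auc_score(predict(fit, dat$x[sp$test, , drop = FALSE]),
                             y[sp$test])
      }
      mean(aucs)
    })
  }

  observed <- eval_auc(dat$y, derive_seed(seed, "perm_observed"))
  permuted <- with_seed(derive_seed(seed, "perm_labels"), {
    lapply(seq_len(config$n_permutations), function(i)
      list(y = sample(dat$y), seed = sample.int(2147483000, 1L)))
  })
  permuted_aucs <- vapply(permuted, function(pp) eval_auc(pp$y, pp$seed),
                          numeric(1))
  p <- (1 + sum(permuted_aucs >= observed)) / (config$n_permutations + 1)
  structure(list(observed_auc = observed, permuted_aucs = permuted_aucs,
                 p_value = p, n_permutations = config$n_permutations),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: observed mean AUC %.3f, p = %.4g (N = %d)\n",
              x$observed_auc, x$p_value, x$n_permutations))
  invisible(x)
}

#' Discover a biomarker panel end to end
#'
#' Convenience wrapper running [repeated_holdout_auc()],
#' [stability_select()], [rank_variable_importance()] and (optionally)
#' [permutation_test()] on one contrast.
#'
#' @inheritParams repeated_holdout_auc
#' @param run_permutation Whether to run the permutation test.
#' @return A `panel_result` with an extra `permutation` element (or NULL).
#' @export
discover_panel <- function(z, groups = c("control", "AS_pre"),
                           config = model_config(), run_permutation = TRUE) {
  ho <- repeated_holdout_auc(z, groups, config)
  fr <- stability_select(z, groups, config)
  res <- rank_variable_importance(ho, fr, config$panel_size)
  res$permutation <- if (run_permutation) permutation_test(z, groups, config)
  res
}
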