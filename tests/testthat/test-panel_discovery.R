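sep_zmatrix <- function(seed = 1, n_per = 10, p = 30, d = 4) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per * p), 2 * n_per, p,
              dimnames = list(NULL, sprintf("F%03d", seq_len(p))))
  y <- rep(0:1, each = n_per)
  x[, 1] <- x[, 1] + d * y
  list(z = toy_zmatrix(x, y), y = y)
}

fast_config <- function(n_subsamples = 30L, n_permutations = 30L, ...) {
  model_config(grid = data.frame(max_depth = 2L, n_trees = 50L,
                                 learning_rate = 0.1),
               n_subsamples = n_subsamples,
               n_permutations = n_permutations, ...)
}

test_that("perfect separation yields mean test AUC 1 and top importance on the signal", {
  set.seed(1)
  x <- matrix(rnorm(19 * 20), 19, 20,
              dimnames = list(NULL, sprintf("F%03d", 1:20)))
  y <- c(rep(0L, 9), rep(1L, 10))
  x[, 5] <- y * 10 + rnorm(19, 0, 0.01) # perfectly separated feature
  z <- toy_zmatrix(x, y)
  ho <- repeated_holdout_auc(z, config = fast_config(seed = 2, colsample = 1))
  expect_equal(ho$mean_auc, 1)
  expect_length(ho$aucs, 10L)
  expect_true(all(colMeans(ho$importances)["F005"] >=
                    colMeans(ho$importances)[-5]))
})

test_that("two-feature toy: only the informative feature earns importance, every repeat", {
  set.seed(3)
  x <- cbind(F1 = c(rnorm(10, 0), rnorm(10, 5)), F2 = rnorm(20))
  y <- rep(0:1, each = 10)
  ho <- repeated_holdout_auc(toy_zmatrix(x, y),
                             config = fast_config(seed = 4, colsample = 1))
  expect_true(all(ho$importances[, "F1"] > ho$importances[, "F2"]))
})

test_that("null labels give chance-level AUC on average", {
  set.seed(5)
  aucs <- vapply(1:6, function(s) {
    x <- matrix(rnorm(20 * 40), 20, 40,
                dimnames = list(NULL, sprintf("F%03d", 1:40)))
    y <- rep(0:1, each = 10)
    repeated_holdout_auc(toy_zmatrix(x, y),
                         config = fast_config(seed = s))$mean_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("repeated_holdout_auc is bit-reproducible for a fixed seed", {
  sz <- sep_zmatrix(seed = 6)
  a <- repeated_holdout_auc(sz$z, config = fast_config(seed = 11))
  b <- repeated_holdout_auc(sz$z, config = fast_config(seed = 11))
  expect_identical(a$aucs, b$aucs)
  expect_identical(a$importances, b$importances)
  c2 <- repeated_holdout_auc(sz$z, config = fast_config(seed = 12))
  expect_false(identical(a$aucs, c2$aucs) && identical(a$importances,
                                                       c2$importances))
})

test_that("stability selection: signal frequency 1, bounded bookkeeping", {
  sz <- sep_zmatrix(seed = 7, d = 6)
  cfg <- fast_config(seed = 8, top_q_per_subsample = 5L)
  fr <- stability_select(sz$z, config = cfg)
  expect_equal(unname(fr["F001"]), 1)
  expect_true(all(fr >= 0 & fr <= 1))
  # at most top_q selections per draw on average
  expect_lte(sum(fr), 5)
  expect_error(stability_select(sz$z, config = fast_config(
    subsample_fraction = 0.01)), "subsample")
})

test_that("rank_variable_importance rescales to 100, ties break alphabetically", {
  feats <- c("ZZ_dup", "Mid", "AA_dup", "Low")
  ho <- list(mean_auc = 0.9, aucs = rep(0.9, 3),
             importances = matrix(rep(c(4, 2, 4, 1), each = 3), 3, 4,
                                  dimnames = list(NULL, feats)))
  fr <- setNames(c(0.5, 0.8, 0.5, 0.1), feats)
  pr <- rank_variable_importance(ho, fr, panel_size = 3L)
  expect_equal(max(pr$table$importance), 100)
  expect_identical(pr$table$importance[1], 100)
  expect_length(pr$panel, 3L)
  # equal composite scores (4 * 0.5) tie-break alphabetically
  expect_identical(pr$table$feature, c("AA_dup", "ZZ_dup", "Mid", "Low"))
  expect_equal(pr$table$importance[1], pr$table$importance[2])
  # single informative feature scores exactly 100
  solo <- rank_variable_importance(
    list(mean_auc = 1, aucs = 1,
         importances = matrix(c(3, 0), 1, 2,
                              dimnames = list(NULL, c("sig", "noise")))),
    setNames(c(1, 0), c("sig", "noise")), panel_size = 1L)
  expect_identical(solo$panel, "sig")
  expect_equal(solo$table$importance[1], 100)

  ho0 <- ho; ho0$importances[] <- 0
  expect_error(rank_variable_importance(ho0, fr), "degenerate")
})

test_that("permutation test: boundary behavior and add-one estimator", {
  sz <- sep_zmatrix(seed = 13, d = 8)
  pt <- permutation_test(sz$z, config = fast_config(seed = 14,
                                                    n_permutations = 19L))
  expect_length(pt$permuted_aucs, 19L)
  expect_identical(pt$p_value,
                   (1 + sum(pt$permuted_aucs >= pt$observed_auc)) / 20)
  expect_gt(pt$p_value, 0)
  expect_lte(pt$p_value, 1)
  expect_error(model_config(n_permutations = 0L), "n_permutations")
})

test_that("permutation test with the full repeat protocol detects a planted effect", {
  st <- small_study(seed = 31, n_peaks = 120, n_planted = 15, n_reversing = 5)
  zm <- harmonized(st)
  cfg <- fast_config(seed = 15, n_permutations = 59L, perm_repeats = 10L)
  pt <- permutation_test(zm, config = cfg)
  expect_lte(pt$p_value, 0.05)
})

test_that("discover_panel recovers planted features on a generated study", {
  st <- small_study(seed = 37, n_peaks = 150, n_planted = 15, n_reversing = 5)
  zm <- harmonized(st)
  res <- discover_panel(zm, config = fast_config(seed = 16),
                        run_permutation = FALSE)
  found <- features_matching(res$panel, st$truth$planted_feature_names)
  expect_gte(sum(!is.na(found)), 12)
  expect_gte(res$mean_auc, 0.9)
})
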