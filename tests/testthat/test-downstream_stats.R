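test_that("bh_adjust matches the brute-force step-up oracle and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.2)),
               c(0.05, 0.05, 0.05, 0.05, 0.2))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  set.seed(6)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    got <- bh_adjust(p)
    expect_equal(got, oracle_bh(p))
    expect_equal(got, p.adjust(p, "BH"))
    expect_true(all(got >= p))
  }
  # NAs are passed through and excluded from m
  p <- c(0.01, NA, 0.04)
  expect_equal(bh_adjust(p), c(0.02, NA, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("paired one-tailed t matches the closed form and t.test to 1e-10", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(3:15, 1)
    pre <- rnorm(n); post <- pre + rnorm(n, 0.3)
    for (dir in c("less", "greater")) {
      got <- paired_one_tailed_t(pre, post, dir)
      ref <- t.test(post, pre, paired = TRUE, alternative = dir)
      expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(got$p, ref$p.value, tolerance = 1e-10)
      d <- post - pre
      expect_equal(got$t, mean(d) / (sd(d) / sqrt(n)), tolerance = 1e-12)
    }
    # one-tailed p is half the two-tailed p in the effect's direction
    two <- t.test(post, pre, paired = TRUE)$p.value
    dir_eff <- if (mean(post - pre) > 0) "greater" else "less"
    expect_equal(paired_one_tailed_t(pre, post, dir_eff)$p, two / 2,
                 tolerance = 1e-10)
  }
})

test_that("paired t edge cases: strong consistent shift, null center, zero variance", {
  # oracle: d = {1,1,1,2}, t = 1.25 / (0.5 / 2) = 5, df 3
  got <- paired_one_tailed_t(rep(0, 4), c(1, 1, 1, 2), "greater")
  expect_equal(got$t, 5)
  expect_equal(got$p, pt(5, 3, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(got$p, 0.01)
  set.seed(8)
  sym <- replicate(40, {
    pre <- rnorm(8); post <- pre + sample(c(-1, 1), 8, TRUE) * 0.5
    paired_one_tailed_t(pre, post, "greater")$p
  })
  expect_lt(abs(mean(sym) - 0.5), 0.15)
  zv <- paired_one_tailed_t(c(0, 0, 0), c(1, 1, 1), "greater")
  expect_identical(zv$p, 0)
  expect_true(zv$flag)
  expect_identical(paired_one_tailed_t(c(0, 0, 0), c(1, 1, 1), "less")$p, 1)
})

test_that("group_difference_tests: null features flat, planted features significant", {
  st <- small_study(seed = 41, n_peaks = 120, n_planted = 15, n_reversing = 5)
  zm <- harmonized(st)
  gs <- group_difference_tests(zm)
  expect_true(all(gs$p_adj >= gs$p, na.rm = TRUE))
  planted <- features_matching(gs$feature, st$truth$planted_feature_names)
  ip <- gs$feature %in% planted
  # planted d=2 features mostly clear FDR; null features mostly do not
  expect_gte(mean(gs$p_adj[ip] < 0.05), 0.8)
  expect_lte(mean(gs$p_adj[!ip] < 0.05), 0.1)
  expect_true(all(is.finite(gs$neg_log10_p_adj[!gs$degenerate])))

  # identical distributions: p in the null region
  x <- matrix(rnorm(18 * 5), 18, 5, dimnames = list(NULL, paste0("F", 1:5)))
  z0 <- toy_zmatrix(x, rep(0:1, each = 9))
  gs0 <- group_difference_tests(z0)
  expect_true(all(gs0$p > 0.001))

  # degenerate feature flagged, excluded from adjustment
  x[, 2] <- 1
  zd <- toy_zmatrix(x, rep(0:1, each = 9))
  gsd <- group_difference_tests(zd)
  expect_true(gsd$degenerate[2])
  expect_true(is.na(gsd$p_adj[2]))
})

test_that("classify_reversal implements the class rule on forced cases", {
  gs <- data.frame(feature = c("up_rev", "up_further", "flat"),
                   mean_ref = c(0, 0, 0), mean_case = c(2, 2, 0.01))
  paired <- data.frame(feature = c("up_rev", "up_further", "flat"),
                       mean_diff = c(-2, 1.5, 0.001),
                       p = c(0.01, 0.99, 0.5))
  cls <- classify_reversal(gs, paired)
  expect_identical(cls$class,
                   c("reversal_toward_control", "further_deviation",
                     "no_significant_change"))
  expect_identical(cls$direction_pre, c(1, 1, 1))
  expect_identical(cls$direction_change, c(-1, 1, 1))
})

test_that("reversal classes recover the planted reversing set on a generated study", {
  st <- small_study(seed = 43, n_peaks = 120, n_planted = 16, n_reversing = 8)
  zm <- harmonized(st)
  gs <- group_difference_tests(zm)
  pr <- paired_stats(zm)
  cls <- classify_reversal(gs, pr)
  rev_feats <- features_matching(cls$feature, st$truth$reversing_feature_names)
  nonrev <- setdiff(st$truth$planted_feature_names,
                    st$truth$reversing_feature_names)
  nonrev_feats <- features_matching(cls$feature, nonrev)
  expect_gte(mean(cls$class[cls$feature %in% rev_feats] ==
                    "reversal_toward_control"), 0.85)
  expect_gte(mean(cls$class[cls$feature %in% nonrev_feats] %in%
                    c("further_deviation", "no_significant_change")), 0.85)
})

test_that("clinical correlations: exact cases and monotone invariance", {
  set.seed(9)
  n <- 16
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("mono", "lin", "noise")))
  z <- toy_zmatrix(x, rep(0:1, n / 2))
  clinical <- data.frame(sample_id = z$meta$sample_id,
                         LVMi = exp(x[, "mono"]),      # monotone in feature
                         MEEi = 2 * x[, "lin"] + 1)    # exactly linear
  co <- correlate_clinical(z, clinical)
  expect_equal(co$rho[co$feature == "mono" & co$covariate == "LVMi"], 1)
  expect_equal(co$r_squared[co$feature == "lin" & co$covariate == "MEEi"], 1)
  expect_true(all(co$p_adj >= co$p, na.rm = TRUE))
  expect_true(all(abs(co$rho) <= 1, na.rm = TRUE))

  # Spearman rho invariant under strictly monotone transforms of either side
  rho0 <- co$rho[co$feature == "noise" & co$covariate == "LVMi"]
  z2 <- z; z2$z["noise", ] <- exp(z$z["noise", ] / 2)
  co2 <- correlate_clinical(z2, clinical)
  expect_equal(co2$rho[co2$feature == "noise" & co2$covariate == "LVMi"], rho0)

  # constant covariate flagged
  clinical$MEEi <- 5
  co3 <- correlate_clinical(z, clinical)
  expect_true(all(co3$flag[co3$covariate == "MEEi"]))
})

test_that("planted covariate links are recovered as significant correlations", {
  st <- small_study(seed = 47, n_peaks = 100, n_planted = 10, n_reversing = 5)
  zm <- harmonized(st)
  links <- st$truth$covariate_linked
  feats <- features_matching(rownames(zm$z),
                             st$metabolite_db$name[
                               match(links$id, st$metabolite_db$id)])
  co <- correlate_clinical(zm, st$clinical, features = unname(feats))
  for (k in seq_len(nrow(links))) {
    hit <- co[co$feature == feats[k] & co$covariate == links$covariate[k], ]
    expect_gt(abs(hit$rho), 0.3)
    expect_true(hit$significant)
  }
})
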