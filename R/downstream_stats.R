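#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard step-up procedure: with p-values sorted ascending,
#' `adjusted_i = min_{j >= i} p_j * m / j`, capped at 1, returned in the
#' original input order. NAs propagate and do not count toward `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(out)
  o <- order(pv)
  adj <- rev(cummin(rev(pv[o] * m / seq_len(m))))
  adj <- pmin(adj, 1)
  out[ok][o] <- adj
  out
}

#' Per-feature two-group difference tests with FDR correction
#'
#' Welch's two-sided t-test (default) or Mann-Whitney per feature between
#' two groups of Z-scores, BH-adjusted across features, reported with
#' `-log10(adjusted p)` as the per-metabolite discrimination capacity.
#' Features with zero variance in both groups get an undefined p (NA),
#' are excluded from the adjustment, and are flagged.
#'
#' @param z A `zscore_matrix`.
#' @param groups Length-2 character vector (reference, case).
#' @param test `"welch"` or `"wilcoxon"`.
#' @return A data frame per feature: group means/sds, `p`, `p_adj`,
#'   `neg_log10_p_adj`, `degenerate` flag.
#' @export
group_difference_tests <- function(z, groups = c("control", "AS_pre"),
                                   test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  cols <- contrast_columns(z, groups)
  a <- z$z[, cols[[1L]], drop = FALSE]
  b <- z$z[, cols[[2L]], drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L) stop("each group needs >= 2 samples")
  p <- vapply(seq_len(nrow(a)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) return(NA_real_)
    if (test == "welch") stats::t.test(x, y)$p.value
    else stats::wilcox.test(x, y, exact = FALSE)$p.value
  }, numeric(1))
  p_adj <- bh_adjust(p)
  # cap at the smallest representable p so -log10 stays finite
  p_floor <- pmax(p_adj, .Machine$double.xmin)
  data.frame(feature = rownames(z$z),
             mean_ref = rowMeans(a), sd_ref = apply(a, 1L, stats::sd),
             mean_case = rowMeans(b), sd_case = apply(b, 1L, stats::sd),
             p = p, p_adj = p_adj,
             neg_log10_p_adj = ifelse(is.na(p_adj), NA_real_, -log10(p_floor)),
             degenerate = is.na(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-tailed paired t-test on pre/post differences
#'
#' Closed form on complete pairs: `t = mean(d) / (sd(d) / sqrt(n))` with
#' `d = post - pre`, p from the t distribution tail in the stated
#' direction (`"less"`: alternative mean(d) < 0; `"greater"`: > 0).
#' Zero-variance differences give p 0 or 1 by the sign of the (non-zero)
#' mean difference and are flagged; all-zero differences give p = NA.
#'
#' @param pre,post Numeric vectors, matched by position (complete pairs).
#' @param direction `"less"` or `"greater"`, the alternative for
#'   `mean(post - pre)`.
#' @return List: `estimate` (mean difference), `t`, `df`, `p`, `flag`.
#' @export
paired_one_tailed_t <- function(pre, post, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  if (length(pre) != length(post)) stop("pre and post must be paired")
  ok <- is.finite(pre) & is.finite(post)
  d <- (post - pre)[ok]
  n <- length(d)
  if (n < 2L) stop("need >= 2 complete pairs")
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    p <- if (md == 0) NA_real_
    else if ((md < 0) == (direction == "less")) 0 else 1
    return(list(estimate = md, t = NA_real_, df = n - 1L, p = p, flag = TRUE))
  }
  t <- md / (sdd / sqrt(n))
  p <- if (direction == "less") stats::pt(t, n - 1L)
  else stats::pt(t, n - 1L, lower.tail = FALSE)
  list(estimate = md, t = t, df = n - 1L, p = p, flag = FALSE)
}

#' Paired pre/post statistics for every feature
#'
#' Runs the one-tailed paired t-test per feature on the within-run
#' pre/post contrast. The tested direction per feature is "change toward
#' the control mean": the alternative's sign is the sign of
#' `control mean - case-pre mean` (a post-intervention normalization test).
#'
#' @param z A merged `zscore_matrix` containing control, pre and post groups.
#' @param alpha Significance level for the `significant` flag.
#' @param groups Character, names of the control / pre / post groups.
#' @return Data frame per feature: `mean_diff` (post - pre), `t`, `p`,
#'   `direction` tested, `significant`.
#' @export
paired_stats <- function(z, alpha = 0.05,
                         groups = c(control = "control", pre = "AS_pre",
                                    post = "AS_post")) {
  m <- z$meta
  cc <- contrast_columns(z, unname(groups[c("pre", "post")]))
  pre_cols <- cc[[1L]]; post_cols <- cc[[2L]]
  pre_meta <- m[match(pre_cols, m$column), ]
  post_meta <- m[match(post_cols, m$column), ]
  post_cols <- post_cols[match(pre_meta$pair_id, post_meta$pair_id)]
  if (any(is.na(post_cols))) stop("pair ids do not link pre and post samples")
  ctrl_cols <- m$column[m$group == groups[["control"]]]

  pre_m <- z$z[, pre_cols, drop = FALSE]
  post_m <- z$z[, post_cols, drop = FALSE]
  ctrl_mean <- rowMeans(z$z[, ctrl_cols, drop = FALSE])

  res <- lapply(seq_len(nrow(z$z)), function(i) {
    dir <- if (ctrl_mean[i] < mean(pre_m[i, ])) "less" else "greater"
    tt <- paired_one_tailed_t(pre_m[i, ], post_m[i, ], dir)
    data.frame(feature = rownames(z$z)[i], mean_diff = tt$estimate,
               t = tt$t, p = tt$p, direction = dir,
               significant = !is.na(tt$p) && tt$p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Classify post-intervention reversal toward control
#'
#' A feature is `reversal_toward_control` iff its paired pre/post change is
#' significant and the change opposes the pre-intervention deviation from
#' controls; a significant change in the same direction as the deviation is
#' `further_deviation`; anything else is `no_significant_change`. The
#' away-from-control tail uses the complement of the toward-control
#' one-tailed p.
#'
#' @param group_stats Result of [group_difference_tests()] (control vs pre).
#' @param paired Result of [paired_stats()] on the same features.
#' @param alpha Significance level (default 0.05).
#' @return Data frame: `feature`, `direction_pre` (sign of pre deviation),
#'   `direction_change` (sign of post - pre), `class`.
#' @export
classify_reversal <- function(group_stats, paired, alpha = 0.05) {
  if (!setequal(group_stats$feature, paired$feature))
    stop("group and paired statistics cover different features")
  paired <- paired[match(group_stats$feature, paired$feature), ]
  dir_pre <- sign(group_stats$mean_case - group_stats$mean_ref)
  dir_chg <- sign(paired$mean_diff)
  p_toward <- paired$p
  p_away <- 1 - paired$p
  cls <- ifelse(is.na(p_toward), "no_significant_change",
         ifelse(p_toward < alpha & dir_chg == -dir_pre & dir_chg != 0,
                "reversal_toward_control",
         ifelse(p_away < alpha & dir_chg == dir_pre & dir_chg != 0,
                "further_deviation", "no_significant_change")))
  data.frame(feature = group_stats$feature, direction_pre = dir_pre,
             direction_change = dir_chg, class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlate panel features with clinical covariates
#'
#' Spearman correlation (average ranks on ties) of each feature's Z-scores
#' with each clinical covariate over the pooled control + case-pre samples,
#' BH-adjusted across the whole feature x covariate family; effect size
#' reported as the least-squares R-squared of covariate on Z-score.
#' Significance is called at adjusted p below `fdr_cutoff` (default 0.1).
#'
#' @param z A `zscore_matrix`.
#' @param clinical Data frame with `sample_id` and the covariate columns.
#' @param features Feature names to correlate (e.g. the panel); default all.
#' @param covariates Covariate column names (default LVMi, MEEi).
#' @param groups Sample groups pooled for the correlation.
#' @param fdr_cutoff FDR significance cutoff.
#' @return Data frame per (feature, covariate): `rho`, `p`, `p_adj`,
#'   `r_squared`, `significant`, `flag` (constant input).
#' @export
correlate_clinical <- function(z, clinical, features = NULL,
                               covariates = c("LVMi", "MEEi"),
                               groups = c("control", "AS_pre"),
                               fdr_cutoff = 0.1) {
  if (is.null(features)) features <- rownames(z$z)
  miss <- setdiff(features, rownames(z$z))
  if (length(miss)) stop("unknown features: ", paste(miss, collapse = ", "))
  cols <- unlist(contrast_columns(z, groups))
  m <- z$meta[match(cols, z$meta$column), ]
  cl <- clinical[match(m$sample_id, clinical$sample_id), ]
  if (nrow(cl) < 3L) stop("need >= 3 observations per correlation")

  rows <- list()
  for (f in features) {
    x <- z$z[f, cols]
    for (cv in covariates) {
      y <- cl[[cv]]
      if (is.null(y)) stop("covariate ", cv, " missing from clinical table")
      ok <- is.finite(x) & is.finite(y)
      flag <- stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0
      if (flag || sum(ok) < 3L) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature = f, covariate = cv, rho = NA_real_, p = NA_real_,
          r_squared = NA_real_, flag = TRUE, stringsAsFactors = FALSE)
        next
      }
      ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman"))
      # simple-regression R^2 equals the squared Pearson correlation
      r2 <- stats::cor(x[ok], y[ok])^2
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, covariate = cv, rho = unname(ct$estimate),
        p = ct$p.value, r_squared = r2, flag = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- !is.na(out$p_adj) & out$p_adj < fdr_cutoff
  rownames(out) <- NULL
  out[, c("feature", "covariate", "rho", "p", "p_adj", "r_squared",
          "significant", "flag")]
}
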