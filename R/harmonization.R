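#' Log10-transform an intensity matrix
#'
#' MS peak intensities are approximately log-normal, so parametric
#' statistics downstream of Z-scoring operate on the log10 scale. Zeros are
#' floored at half the smallest positive intensity before taking logs
#' (half-minimum imputation).
#'
#' @param m Non-negative intensity matrix.
#' @return `log10(m)` with the zero floor applied.
#' @export
log_intensities <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("intensities must be non-negative")
  pos <- m[m > 0]
  if (length(pos) == 0L) stop("all intensities are zero")
  log10(pmax(m, min(pos) / 2))
}

#' Anchored Z-score harmonization of a run's intensity matrix
#'
#' Standardizes every feature within each MS run against the mean and sample
#' standard deviation (n-1 denominator) of an anchor group measured in every
#' run: `z = (x - mean_anchor) / sd_anchor`. Z-score units are standard
#' deviations away from the anchor group's mean, which makes samples
#' comparable across runs that share the anchor group. Features whose anchor
#' sd is zero in a run are dropped (Z-scoring is undefined there) with a
#' warning, not an error.
#'
#' @param matrix Numeric matrix, features x samples (colnames = sample ids).
#' @param meta Data frame with one row per sample: `sample_id`, `group`,
#'   `run` (single- or multi-run input), optional `pair_id`.
#' @param anchor_group Group standardized to mean 0 / sd 1 within each run
#'   (default `"AS_pre"`, the group acquired in both runs of the study
#'   design this package targets).
#' @return A `zscore_matrix` list: `z` (features x columns), `meta` (with a
#'   `column` key naming `z`'s columns), `anchor_group`, `anchor_stats`
#'   (per-run per-feature anchor mean/sd), `dropped` (zero-sd feature names).
#' @export
anchor_zscore <- function(matrix, meta, anchor_group = "AS_pre") {
  matrix <- as.matrix(matrix)
  req <- c("sample_id", "group", "run")
  if (!all(req %in% names(meta))) stop("meta needs columns ", paste(req, collapse = ", "))
  if (is.null(colnames(matrix))) stop("matrix must have sample column names")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  miss <- setdiff(colnames(matrix), meta$sample_id)
  if (length(miss)) stop("samples missing from meta: ", paste(miss, collapse = ", "))
  meta <- meta[match(colnames(matrix), meta$sample_id), , drop = FALSE]

  runs <- unique(meta$run)
  z <- matrix * NA_real_
  drop_all <- character(0)
  anchor_stats <- list()
  for (r in runs) {
    cols <- which(meta$run == r)
    anc <- cols[meta$group[cols] == anchor_group]
    if (length(anc) < 2L)
      stop("anchor group '", anchor_group, "' needs >= 2 samples in run '", r, "'")
    mu <- rowMeans(matrix[, anc, drop = FALSE])
    sd <- apply(matrix[, anc, drop = FALSE], 1L, stats::sd)
    zero <- sd == 0
    if (any(zero)) drop_all <- union(drop_all, rownames(matrix)[zero])
    z[, cols] <- (matrix[, cols, drop = FALSE] - mu) / sd
    anchor_stats[[as.character(r)]] <- data.frame(
      feature = rownames(matrix), mean = mu, sd = sd,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (length(drop_all)) {
    warning(length(drop_all), " feature(s) dropped: zero anchor sd")
    keep <- !(rownames(z) %in% drop_all)
    z <- z[keep, , drop = FALSE]
  }
  if (!("pair_id" %in% names(meta))) meta$pair_id <- NA_character_
  meta$column <- meta$sample_id
  structure(list(z = z, meta = meta, anchor_group = anchor_group,
                 anchor_stats = anchor_stats, dropped = drop_all,
                 n_features_dropped_on_merge = 0L),
            class = "zscore_matrix")
}

#' Merge two anchored Z-score matrices into one comparable matrix
#'
#' Inner join on feature labels; features missing from either run are
#' dropped and counted. Samples measured in both runs (the anchor group)
#' keep one column per run: merged columns are named `"<sample_id>@<run>"`
#' so each within-run copy stays addressable — contrasts are later taken
#' within the run that contains both groups being compared.
#'
#' @param z1,z2 `zscore_matrix` objects anchored on the same group.
#' @return A merged `zscore_matrix`; `n_features_dropped_on_merge` records
#'   how many feature labels were not shared.
#' @export
merge_runs <- function(z1, z2) {
  if (!inherits(z1, "zscore_matrix") || !inherits(z2, "zscore_matrix"))
    stop("inputs must be zscore_matrix objects")
  if (!identical(z1$anchor_group, z2$anchor_group))
    stop("runs are anchored on different groups")
  feats <- intersect(rownames(z1$z), rownames(z2$z))
  if (length(feats) == 0L) stop("disjoint feature sets: nothing to merge")
  dropped <- (nrow(z1$z) - length(feats)) + (nrow(z2$z) - length(feats))

  relabel <- function(zm) {
    m <- zm$meta
    m$column <- paste0(m$sample_id, "@", m$run)
    zz <- zm$z[feats, , drop = FALSE]
    colnames(zz) <- m$column
    list(z = zz, meta = m)
  }
  a <- relabel(z1); b <- relabel(z2)
  structure(list(z = cbind(a$z, b$z),
                 meta = rbind(a$meta, b$meta),
                 anchor_group = z1$anchor_group,
                 anchor_stats = c(z1$anchor_stats, z2$anchor_stats),
                 dropped = union(z1$dropped, z2$dropped),
                 n_features_dropped_on_merge = dropped),
            class = "zscore_matrix")
}

#' @export
print.zscore_matrix <- function(x, ...) {
  cat("Z-score matrix:", nrow(x$z), "features x", ncol(x$z), "samples;",
      "anchor =", x$anchor_group,
      sprintf("(runs: %s)\n", paste(unique(x$meta$run), collapse = ", ")))
  invisible(x)
}

# Columns for a two-group contrast, taken within a single run. If a group
# was acquired in several runs, the copy from the run shared with the other
# group is used (e.g. anchor samples: run-1 copy vs controls, run-2 copy vs
# post-intervention samples); ties resolved by lowest run id.
contrast_columns <- function(zm, groups) {
  stopifnot(inherits(zm, "zscore_matrix"), length(groups) == 2L)
  m <- zm$meta
  runs1 <- unique(m$run[m$group == groups[1L]])
  runs2 <- unique(m$run[m$group == groups[2L]])
  shared <- intersect(runs1, runs2)
  if (length(shared) == 0L)
    stop("groups ", groups[1L], " and ", groups[2L], " share no run")
  r <- sort(shared)[1L]
  lapply(groups, function(g) m$column[m$group == g & m$run == r])
}
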