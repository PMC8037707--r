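# Shared fixture builders: everything is generated in code at test time.

# A small complete synthetic study (both runs), sized for fast tests.
small_study <- function(seed = 7, n_peaks = 150, n_planted = 15,
                        n_reversing = 8, effect_size = 2, ...) {
  simulate_study(study_design(
    n_peaks = n_peaks, n_planted_discriminative = n_planted,
    n_planted_reversing = n_reversing, effect_size = effect_size,
    seed = seed, ...))
}

# Annotate + harmonize a study into a merged zscore_matrix (log10 scale,
# as in the pipeline's harmonize stage).
harmonized <- function(study, tolerance_ppm = 2) {
  meta <- study$clinical[, c("sample_id", "group", "run", "pair_id")]
  a1 <- annotate_peaks(average_triplicates(study$run1_peaks),
                       study$metabolite_db, tolerance_ppm)
  a2 <- annotate_peaks(average_triplicates(study$run2_peaks),
                       study$metabolite_db, tolerance_ppm)
  merge_runs(
    anchor_zscore(log_intensities(a1$matrix), meta[meta$run == "run1", ]),
    anchor_zscore(log_intensities(a2$matrix), meta[meta$run == "run2", ]))
}

# Hand-built zscore_matrix around a samples x features matrix (one run).
toy_zmatrix <- function(x, labels,
                        groups = c("control", "AS_pre")) {
  stopifnot(length(labels) == nrow(x))
  ids <- sprintf("S%03d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("F%03d", seq_len(ncol(x)))
  structure(list(
    z = structure(t(x), dimnames = list(colnames(x), ids)),
    meta = data.frame(sample_id = ids, group = groups[labels + 1L],
                      run = "run1", pair_id = NA_character_, column = ids,
                      stringsAsFactors = FALSE),
    anchor_group = "AS_pre", anchor_stats = list(),
    dropped = character(0), n_features_dropped_on_merge = 0L),
    class = "zscore_matrix")
}

# Feature labels of a harmonized study that carry a given metabolite name
# (composite isobar labels count as carrying each member).
features_matching <- function(feature_labels, names) {
  vapply(names, function(nm) {
    hit <- feature_labels[grepl(nm, feature_labels, fixed = TRUE)]
    if (length(hit)) hit[1L] else NA_character_
  }, character(1))
}

# Brute-force annotation oracle: exhaustive double loop over every
# (peak, record) pair, returning the match index set per peak.
oracle_match_sets <- function(mz, db, tolerance_ppm = 2, adduct_offset = 0) {
  lapply(mz, function(m) {
    hits <- integer(0)
    for (j in seq_len(nrow(db))) {
      if (abs((m - adduct_offset - db$mass[j]) / db$mass[j] * 1e6) <=
          tolerance_ppm)
        hits <- c(hits, j)
    }
    hits
  })
}

# Brute-force BH step-up oracle straight from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    adj[o[i]] <- min(pmin(p[o[js]] * m / js, 1))
  }
  adj
}
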