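#' Rank-based ROC AUC
#'
#' Computes the area under the ROC curve via the Mann-Whitney U statistic,
#' `AUC = U / (n1 * n0)`, with average ranks on tied scores. By construction
#' the value is invariant under any strictly monotone transform of `scores`.
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param labels Binary labels (0/1, logical, or a two-level factor whose
#'   second level is the positive class).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Coerce labels to 0/1 integer. Factors use the second level as positive.
as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
    return(as.integer(labels == levels(labels)[2L]))
  }
  if (is.logical(labels)) return(as.integer(labels))
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1))) stop("numeric labels must be 0/1")
  as.integer(labels)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed from a parent seed and a label,
# staying below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

# Stratified sample of indices: draws round(frac * n_g) per stratum
# (at least 1), without replacement. RNG state is the caller's.
stratified_sample <- function(strata, frac) {
  idx <- integer(0)
  for (g in unique(strata)) {
    gi <- which(strata == g)
    k <- max(1L, round(frac * length(gi)))
    idx <- c(idx, if (length(gi) == 1L) gi else sample(gi, k))
  }
  sort(idx)
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into `k` folds, keeping class balance per fold.
stratified_folds <- function(labels, k) {
  y <- as_binary_labels(labels)
  fold <- integer(length(y))
  for (cls in c(0L, 1L)) {
    ci <- which(y == cls)
    if (length(ci) < 1L) stop("stratification failure: class ", cls, " absent")
    fold[sample(ci)] <- rep_len(seq_len(k), length(ci))
  }
  fold
}

# Stratified train/test split: `frac` of each class to the training set.
stratified_split <- function(labels, frac) {
  y <- as_binary_labels(labels)
  train <- integer(0)
  for (cls in c(0L, 1L)) {
    ci <- which(y == cls)
    k <- round(frac * length(ci))
    if (k < 1L || k >= length(ci))
      stop("stratification failure: class ", cls,
           " would be absent from the train or test partition")
    train <- c(train, sample(ci, k))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

# Plain TSV writers/readers used for all pipeline artifacts.
write_tsv <- function(x, path, row_label = NULL) {
  df <- as.data.frame(x, check.names = FALSE)
  if (!is.null(row_label)) {
    df <- cbind(stats::setNames(data.frame(rownames(df), stringsAsFactors = FALSE),
                                row_label), df)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

read_tsv_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}
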