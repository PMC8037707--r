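#' Average technical replicates into per-sample mean intensities
#'
#' DI-HRMS acquisitions are run as technical triplicates; downstream analysis
#' uses the arithmetic mean intensity per sample and peak.
#'
#' @param peaks Numeric matrix of intensities, peaks in rows (rownames are
#'   the observed m/z as character), one column per sample x replicate named
#'   `"<sample>.<replicate>"` (e.g. `"C01.1"`, `"C01.2"`, `"C01.3"`).
#' @param sample_ids Optional character vector mapping each column to its
#'   sample id; by default parsed from column names as everything before the
#'   final `.<digits>` suffix.
#' @return Numeric matrix, peaks x samples, arithmetic mean over replicates.
#' @export
average_triplicates <- function(peaks, sample_ids = NULL) {
  peaks <- as.matrix(peaks)
  if (is.null(sample_ids)) {
    if (is.null(colnames(peaks))) stop("peaks must have replicate column names")
    sample_ids <- sub("\\.[0-9]+$", "", colnames(peaks))
  }
  if (length(sample_ids) != ncol(peaks))
    stop("sample_ids length must match the number of replicate columns")
  reps <- table(sample_ids)
  if (length(unique(reps)) != 1L)
    stop("missing replicate column: samples have unequal replicate counts (",
         paste(names(reps)[reps != max(reps)], collapse = ", "), ")")
  samples <- unique(sample_ids)
  out <- matrix(vapply(samples, function(s)
    rowMeans(peaks[, sample_ids == s, drop = FALSE]), numeric(nrow(peaks))),
    nrow = nrow(peaks), dimnames = list(rownames(peaks), samples))
  out
}

#' Relative mass error in parts per million
#'
#' `ppm = (observed - theoretical) / theoretical * 1e6`. The theoretical
#' mass sits in the denominator (convention choice, stated here).
#'
#' @param observed Observed m/z (Da), positive.
#' @param theoretical Theoretical monoisotopic mass (Da), positive.
#' @return Signed ppm error; vectorized.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(observed <= 0) || any(theoretical <= 0))
    stop("masses must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Annotate mass peaks against a metabolite database
#'
#' Matches each observed peak m/z (optionally shifted by a single adduct
#' offset) to every database record within `tolerance_ppm`. All matches are
#' retained: isobaric records produce a composite label with names joined by
#' `"/"` in ascending alphabetical order. Peaks with no match are excluded
#' from the annotated matrix but counted and listed.
#'
#' @param means Numeric matrix of per-sample mean intensities, peaks in rows;
#'   rownames are observed m/z (coercible to numeric).
#' @param db Data frame with columns `id`, `name`, `mass` (Da).
#' @param tolerance_ppm Match window in ppm (default 2).
#' @param adduct_offset Constant mass offset (Da) subtracted from observed
#'   m/z before matching (e.g. 1.007276 for \[M+H\]+ against neutral masses);
#'   default 0 = direct mass matching.
#' @return An `annotation_result` list: `matrix` (annotated peaks x samples,
#'   rownames = composite labels), `report` (data frame: peak m/z, label,
#'   matched ids/names/ppm errors, n_matches), `unmatched` (m/z of peaks with
#'   no match), `n_peaks`, `n_annotated_peaks`.
#' @export
annotate_peaks <- function(means, db, tolerance_ppm = 2, adduct_offset = 0) {
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be positive")
  if (!all(c("id", "name", "mass") %in% names(db)))
    stop("db must have columns id, name, mass")
  if (nrow(db) == 0L) stop("empty metabolite database")
  means <- as.matrix(means)
  mz <- as.numeric(rownames(means))
  if (any(is.na(mz)) || any(mz <= 0))
    stop("rownames(means) must be positive numeric m/z values")

  neutral <- mz - adduct_offset
  if (any(neutral <= 0)) stop("adduct offset exceeds an observed m/z")
  # all-pairs ppm scan, vectorized: |obs - mass| <= tol * mass / 1e6
  tol_da <- db$mass * tolerance_ppm / 1e6
  o <- order(db$mass)
  mass_s <- db$mass[o]
  lo <- findInterval(neutral - max(tol_da), mass_s) # conservative lower bound
  matches <- vector("list", length(mz))
  for (k in seq_along(mz)) {
    j <- lo[k] + 1L
    hits <- integer(0)
    while (j <= length(mass_s) && mass_s[j] <= neutral[k] + max(tol_da)) {
      if (abs(neutral[k] - mass_s[j]) <= mass_s[j] * tolerance_ppm / 1e6)
        hits <- c(hits, o[j])
      j <- j + 1L
    }
    matches[[k]] <- hits
  }

  n_matches <- lengths(matches)
  keep <- which(n_matches > 0L)
  lab <- vapply(matches[keep], function(h)
    paste(sort(as.character(db$name[h])), collapse = "/"), character(1))
  ids <- vapply(matches[keep], function(h)
    paste(as.character(db$id[h])[order(as.character(db$name[h]))],
          collapse = "/"), character(1))
  ppm <- vapply(seq_along(keep), function(i) {
    h <- matches[[keep[i]]]
    paste(sprintf("%.4f", ppm_error(neutral[keep[i]], db$mass[h])[
      order(as.character(db$name[h]))]), collapse = "/")
  }, character(1))

  amat <- means[keep, , drop = FALSE]
  # labels can collide (each member of an isobar pair yields a peak matching
  # the whole pair); disambiguate deterministically by ascending m/z
  labu <- lab
  dup <- ave(seq_along(lab), lab, FUN = seq_along)
  ndup <- ave(seq_along(lab), lab, FUN = length)
  mzo <- order(mz[keep])
  rk <- integer(length(lab)); rk[mzo] <- seq_along(mzo)
  for (g in unique(lab[ndup > 1L])) {
    gi <- which(lab == g)
    gi <- gi[order(rk[gi])]
    labu[gi] <- paste0(g, " (", seq_along(gi), ")")
  }
  rownames(amat) <- labu

  report <- data.frame(
    mz = mz[keep], feature = labu, label = lab, ids = ids,
    ppm_errors = ppm, n_matches = n_matches[keep],
    stringsAsFactors = FALSE)
  report <- report[order(report$mz), , drop = FALSE]
  rownames(report) <- NULL

  structure(list(
    matrix = amat[order(mz[keep]), , drop = FALSE],
    report = report,
    unmatched = mz[n_matches == 0L],
    n_peaks = length(mz),
    n_annotated_peaks = length(keep)
  ), class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cnt <- collapse_unique_masses(x)
  cat("Annotation:", x$n_annotated_peaks, "of", x$n_peaks,
      "peaks annotated;", cnt[["n_annotated_metabolites"]],
      "metabolite annotations over", cnt[["n_unique_masses"]],
      "unique masses\n")
  invisible(x)
}

#' Count metabolite annotations and unique annotated masses
#'
#' One peak matched by several isobaric records contributes several
#' metabolite annotations but a single unique mass, so the annotation count
#' is always at least the unique-mass count.
#'
#' @param result An `annotation_result` from [annotate_peaks()].
#' @return Named numeric vector `c(n_annotated_metabolites, n_unique_masses)`:
#'   total (peak, metabolite) matches and number of distinct annotated peaks.
#' @export
collapse_unique_masses <- function(result) {
  if (!inherits(result, "annotation_result"))
    stop("result must come from annotate_peaks()")
  c(n_annotated_metabolites = sum(result$report$n_matches),
    n_unique_masses = nrow(result$report))
}
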