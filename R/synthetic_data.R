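#' Specify a synthetic DI-HRMS study design
#'
#' Captures the study world the generator emulates: a case/control serum
#' cohort (default 9 controls, 10 cases with paired pre/post-intervention
#' samples) acquired in two MS runs that share the case-pre group, with
#' log-normal peak intensities, technical triplicates, a planted subset of
#' case-discriminative metabolites, a planted subset that reverses toward
#' the control mean after intervention, and clinical covariates linked to
#' chosen metabolites.
#'
#' @param n_control Healthy control subjects (run 1 only).
#' @param n_as Case subjects; each contributes a pre sample (both runs) and
#'   a post sample (run 2).
#' @param n_peaks Total mass peaks, including decoys.
#' @param n_planted_discriminative Features shifted in case-pre vs control.
#' @param effect_size Standardized mean difference (Cohen's d) of planted
#'   features on the log10 scale.
#' @param n_planted_reversing Subset of planted features whose case-post
#'   mean returns to the control mean (the rest keep their case-pre mean).
#' @param triplicate_cv Coefficient of variation of technical replicates.
#' @param batch_shift_sd SD (log10) of the per-feature multiplicative run-2
#'   batch factor.
#' @param between_subject_sd Between-subject SD on the log10 scale.
#' @param n_replicates Technical replicates per sample.
#' @param isobar_fraction Fraction of database records paired with an
#'   isobaric twin (see [generate_metabolite_db()]).
#' @param decoy_fraction Fraction of peaks placed >5 ppm from every database
#'   mass, exercising the unannotated path.
#' @param mass_range Metabolite monoisotopic mass range (Da).
#' @param covariate_links Data frame (`feature` index among planted features,
#'   `covariate` in `c("LVMi","MEEi")`, `r` target Pearson correlation), or
#'   NULL for the default: planted feature 1 -> LVMi (r 0.7), planted
#'   feature 2 -> MEEi (r 0.7).
#' @param seed Random seed; the design is fully deterministic given it.
#' @return A `study_design` list, validated.
#' @export
study_design <- function(n_control = 9L, n_as = 10L, n_peaks = 2000L,
                         n_planted_discriminative = 30L, effect_size = 2,
                         n_planted_reversing = 14L, triplicate_cv = 0.1,
                         batch_shift_sd = 0.2, between_subject_sd = 0.5,
                         n_replicates = 3L, isobar_fraction = 0.05,
                         decoy_fraction = 0.05, mass_range = c(60, 1000),
                         covariate_links = NULL, seed = 1L) {
  d <- list(n_control = as.integer(n_control), n_as = as.integer(n_as),
            n_peaks = as.integer(n_peaks),
            n_planted_discriminative = as.integer(n_planted_discriminative),
            effect_size = effect_size,
            n_planted_reversing = as.integer(n_planted_reversing),
            triplicate_cv = triplicate_cv, batch_shift_sd = batch_shift_sd,
            between_subject_sd = between_subject_sd,
            n_replicates = as.integer(n_replicates),
            isobar_fraction = isobar_fraction,
            decoy_fraction = decoy_fraction, mass_range = mass_range,
            covariate_links = covariate_links, seed = as.integer(seed))
  if (is.null(d$covariate_links)) {
    k <- min(2L, d$n_planted_discriminative)
    d$covariate_links <- data.frame(
      feature = seq_len(k), covariate = c("LVMi", "MEEi")[seq_len(k)],
      r = rep(0.7, k), stringsAsFactors = FALSE)
  }
  validate_study_design(d)
  structure(d, class = "study_design")
}

validate_study_design <- function(d) {
  stopifnot(d$n_control > 0L, d$n_as > 0L, d$n_peaks > 0L,
            d$n_planted_discriminative > 0L, d$n_replicates >= 1L)
  if (d$n_as < 2L)
    stop("n_as must be >= 2 so the harmonization anchor is computable")
  if (d$n_planted_reversing > d$n_planted_discriminative)
    stop("n_planted_reversing must not exceed n_planted_discriminative")
  if (d$n_planted_discriminative > d$n_peaks)
    stop("n_planted_discriminative must not exceed n_peaks")
  if (d$effect_size < 0) stop("effect_size must be >= 0")
  if (d$triplicate_cv < 0 || d$batch_shift_sd < 0)
    stop("noise parameters must be >= 0")
  if (any(d$covariate_links$r < -1 | d$covariate_links$r > 1))
    stop("target correlations must lie in [-1, 1]")
  if (!all(d$covariate_links$covariate %in% c("LVMi", "MEEi")))
    stop("covariate links must target LVMi or MEEi")
  if (max(d$covariate_links$feature) > d$n_planted_discriminative)
    stop("covariate links must point at planted features")
  invisible(d)
}

#' Generate a synthetic metabolite mass database
#'
#' Stands in for a real metabolite mass database. Base masses are drawn
#' uniformly over `mass_range` and kept mutually >10 ppm apart; a fraction
#' of records then receives an isobaric twin within +/-1 ppm, producing
#' exactly `floor(isobar_fraction * n)` two-membered isobar groups that
#' exercise ambiguous (composite) annotation downstream.
#'
#' @param n Number of records.
#' @param mass_range Mass interval (Da), within (50, 1500).
#' @param isobar_fraction Fraction of records belonging to an isobar pair's
#'   twin slot; `2 * floor(isobar_fraction * n)` records end up in pairs.
#' @param seed Random seed.
#' @return Data frame `id`, `name`, `mass` (sorted by mass) with attribute
#'   `"isobar_groups"`: a list of id pairs.
#' @export
generate_metabolite_db <- function(n, mass_range = c(60, 1000),
                                   isobar_fraction = 0, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  if (mass_range[1] <= 50 || mass_range[2] >= 1500 ||
      mass_range[1] >= mass_range[2])
    stop("mass_range must be an increasing interval within (50, 1500) Da")
  k <- floor(isobar_fraction * n)
  if (2L * k > n)
    stop("impossible isobar fraction: ", isobar_fraction,
         " would require more than n records")
  with_seed(seed, {
    n_base <- n - k
    base <- sort(stats::runif(n_base, mass_range[1], mass_range[2]))
    # enforce >10 ppm mutual separation by redrawing collisions
    repeat {
      gap_ppm <- diff(base) / base[-length(base)] * 1e6
      bad <- which(gap_ppm <= 10)
      if (length(bad) == 0L || n_base == 1L) break
      base[bad + 1L] <- stats::runif(length(bad), mass_range[1], mass_range[2])
      base <- sort(base)
    }
    twin_of <- if (k > 0L) sort(sample.int(n_base, k)) else integer(0)
    twins <- base[twin_of] * (1 + stats::runif(k, -1, 1) * 1e-6)
    mass <- c(base, twins)
    src <- c(seq_len(n_base), twin_of) # base index each record derives from
    o <- order(mass)
    mass <- mass[o]; src <- src[o]
    db <- data.frame(
      id = sprintf("M%05d", seq_len(n)),
      name = sprintf("Metabolite_%05d", seq_len(n)),
      mass = mass, stringsAsFactors = FALSE)
    groups <- lapply(twin_of, function(b) db$id[src == b])
    attr(db, "isobar_groups") <- groups
    db
  })
}

#' Simulate a complete two-run DI-HRMS study with known ground truth
#'
#' Intensities are log-normal: log10 values are Gaussian with
#' between-subject SD `between_subject_sd` around a per-feature baseline.
#' Planted features are shifted by `effect_size * between_subject_sd` (a
#' random sign per feature) in case-pre samples; reversing features have
#' their case-post mean back at the control mean, non-reversing planted
#' features keep the case-pre mean. Each database record generates exactly
#' one peak at its mass perturbed by <1.5 ppm (shared across runs); decoy
#' peaks sit >5 ppm from every database mass. Run 2 intensities carry a
#' per-feature multiplicative batch factor of SD `batch_shift_sd` (log10).
#' Case-pre samples appear in both runs with independent technical noise.
#' Clinical covariates (LVMi in g/m2, MEEi) are linear in the linked planted
#' features' standardized log-intensities plus Gaussian noise, calibrated to
#' the requested Pearson correlation over controls + case-pre subjects.
#'
#' @param design A [study_design()].
#' @return A `simulated_study` list: `run1_peaks`, `run2_peaks` (peak x
#'   sample.replicate intensity matrices, rownames = m/z), `metabolite_db`,
#'   `clinical` (sample_id, group, run, pair_id, LVMi, MEEi), `truth`
#'   (ground-truth list), `design`.
#' @export
simulate_study <- function(design) {
  if (!inherits(design, "study_design")) design <- do.call(study_design, design)
  validate_study_design(design)
  d <- design
  with_seed(d$seed, {
    n_decoy <- floor(d$decoy_fraction * d$n_peaks)
    n_db <- d$n_peaks - n_decoy
    if (n_db < d$n_planted_discriminative)
      stop("too many decoys: fewer database peaks than planted features")
    db <- generate_metabolite_db(n_db, d$mass_range, d$isobar_fraction,
                                 seed = derive_seed(d$seed, "db"))
    iso_ids <- unlist(attr(db, "isobar_groups"))
    singles <- setdiff(db$id, iso_ids)
    if (length(singles) < d$n_planted_discriminative)
      stop("not enough isobar-free records to plant features in")
    planted <- sort(sample(singles, d$n_planted_discriminative))
    reversing <- sort(sample(planted, d$n_planted_reversing))

    # per-feature generative parameters (db features then decoys)
    p_all <- d$n_peaks
    mu <- stats::runif(p_all, 4, 7)          # log10 baseline
    s <- d$between_subject_sd
    sign_f <- numeric(p_all)
    ip <- match(planted, db$id)
    sign_f[ip] <- sample(c(-1, 1), length(ip), replace = TRUE)
    delta <- d$effect_size * s * sign_f      # case-pre shift, log10

    rev_mask <- logical(p_all)
    rev_mask[match(reversing, db$id)] <- TRUE

    # peak m/z: db masses perturbed <1.5 ppm; decoys >5 ppm from all masses
    mz_db <- db$mass * (1 + stats::runif(n_db, -1.5, 1.5) * 1e-6)
    mz_decoy <- numeric(n_decoy)
    i <- 0L
    while (i < n_decoy) {
      cand <- stats::runif(1, d$mass_range[1], d$mass_range[2])
      if (min(abs(cand - db$mass) / db$mass) * 1e6 > 5) {
        i <- i + 1L
        mz_decoy[i] <- cand
      }
    }
    mz <- c(mz_db, mz_decoy)
    mz_lab <- sprintf("%.6f", mz)
    # isobar twins can collide at 6 decimals; nudge by 1e-6 Da (< 0.02 ppm,
    # negligible against the 2 ppm window) until labels are unique
    while (anyDuplicated(mz_lab)) {
      dup <- duplicated(mz_lab)
      mz[dup] <- mz[dup] + 1e-6
      mz_lab <- sprintf("%.6f", mz)
    }

    controls <- sprintf("C%02d", seq_len(d$n_control))
    cases <- sprintf("AS%02d", seq_len(d$n_as))
    pre <- paste0(cases, "_pre")
    post <- paste0(cases, "_post")

    # subject-level log10 matrices (features x subjects)
    draw <- function(n_sub, shift) {
      mu + shift + matrix(stats::rnorm(p_all * n_sub, 0, s), p_all, n_sub)
    }
    log_ctrl <- draw(d$n_control, 0)
    log_pre <- draw(d$n_as, delta)
    log_post <- draw(d$n_as, ifelse(rev_mask, 0, delta))
    colnames(log_ctrl) <- controls
    colnames(log_pre) <- pre
    colnames(log_post) <- post

    batch2 <- stats::rnorm(p_all, 0, d$batch_shift_sd) # log10 run-2 offset

    replicate_expand <- function(logm, batch_offset) {
      x <- 10^(logm + batch_offset)
      reps <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
        noise <- matrix(stats::rnorm(p_all * d$n_replicates, 0,
                                     d$triplicate_cv), p_all)
        out <- x[, j] * (1 + noise)
        colnames(out) <- paste0(colnames(x)[j], ".", seq_len(d$n_replicates))
        out
      }))
      pmax(reps, 0)
    }
    run1 <- replicate_expand(cbind(log_ctrl, log_pre), 0)
    run2 <- replicate_expand(cbind(log_pre, log_post), batch2)
    rownames(run1) <- rownames(run2) <- mz_lab

    # clinical covariates linked to planted features over controls + case-pre
    subj_ids <- c(controls, cases)
    lv <- stats::rnorm(length(subj_ids))
    me <- stats::rnorm(length(subj_ids))
    links <- d$covariate_links
    links$id <- planted[links$feature]
    for (k in seq_len(nrow(links))) {
      fi <- match(links$id[k], db$id)
      v <- c(log_ctrl[fi, ], log_pre[fi, ])
      zf <- (v - mean(v)) / stats::sd(v)
      r <- links$r[k]
      mixed <- r * zf + sqrt(1 - r^2) * stats::rnorm(length(zf))
      if (links$covariate[k] == "LVMi") lv <- mixed else me <- mixed
    }
    lvmi <- 100 + 30 * lv   # g/m2 scale
    meei <- 10 + 2 * me
    clinical <- data.frame(
      sample_id = c(controls, pre, pre, post),
      group = c(rep("control", d$n_control), rep("AS_pre", d$n_as),
                rep("AS_pre", d$n_as), rep("AS_post", d$n_as)),
      run = c(rep("run1", d$n_control + d$n_as), rep("run2", 2 * d$n_as)),
      pair_id = c(rep(NA_character_, d$n_control), cases, cases, cases),
      LVMi = c(lvmi, lvmi[d$n_control + seq_len(d$n_as)],
               lvmi[d$n_control + seq_len(d$n_as)]),
      MEEi = c(meei, meei[d$n_control + seq_len(d$n_as)],
               meei[d$n_control + seq_len(d$n_as)]),
      stringsAsFactors = FALSE)
    clinical <- clinical[!duplicated(paste(clinical$sample_id, clinical$run)), ]
    rownames(clinical) <- NULL

    # synthetic metabolite -> gene mapping and differential expression
    pl_names <- db$name[match(planted, db$id)]
    gene_map <- data.frame(
      metabolite = rep(pl_names, each = 2L),
      gene = sprintf("GENE%04d", seq_len(2L * length(pl_names))),
      pathway = NA_character_, stringsAsFactors = FALSE)
    de_table <- data.frame(
      gene = gene_map$gene,
      log2fc = round(stats::rnorm(nrow(gene_map), 0, 1), 3),
      p = round(stats::runif(nrow(gene_map)), 4),
      stringsAsFactors = FALSE)

    truth <- list(
      planted_feature_ids = planted,
      planted_feature_names = pl_names,
      reversing_feature_ids = reversing,
      reversing_feature_names = db$name[match(reversing, db$id)],
      covariate_linked = links[, c("id", "covariate", "r")],
      peak_map = data.frame(mz = mz_lab,
                            metabolite_id = c(db$id, rep("decoy", n_decoy)),
                            stringsAsFactors = FALSE),
      n_db_peaks = n_db, n_decoy_peaks = n_decoy)

    structure(list(run1_peaks = run1, run2_peaks = run2,
                   metabolite_db = db, clinical = clinical,
                   gene_map = gene_map, de_table = de_table,
                   truth = truth, design = d),
              class = "simulated_study")
  })
}

#' @export
print.simulated_study <- function(x, ...) {
  d <- x$design
  cat("Simulated DI-HRMS study:", d$n_control, "controls +", d$n_as,
      "cases (pre/post);", d$n_peaks, "peaks,",
      d$n_planted_discriminative, "planted (d =", d$effect_size, "),",
      d$n_planted_reversing, "reversing\n")
  invisible(x)
}

#' Write a simulated study to plain-text fixtures
#'
#' Emits TSV tables for both runs' peak intensities, the metabolite
#' database, the clinical table and the synthetic gene mapping/differential
#' expression fixtures, plus the ground truth and design as JSON. Numeric
#' values are written with 17 significant digits so the files round-trip
#' losslessly through [read_fixtures()] and are byte-identical for a fixed
#' seed.
#'
#' @param study A `simulated_study`.
#' @param directory Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixtures <- function(study, directory) {
  if (!inherits(study, "simulated_study")) stop("study must be a simulated_study")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory)
  fm <- function(m) {
    df <- as.data.frame(apply(m, 2L, function(col) sprintf("%.17g", col)),
                        check.names = FALSE, stringsAsFactors = FALSE)
    cbind(data.frame(mz = rownames(m), stringsAsFactors = FALSE), df)
  }
  paths <- c(run1_peaks = file.path(directory, "run1_peaks.tsv"),
             run2_peaks = file.path(directory, "run2_peaks.tsv"),
             metabolite_db = file.path(directory, "metabolite_db.tsv"),
             clinical = file.path(directory, "clinical.tsv"),
             gene_map = file.path(directory, "gene_map.tsv"),
             de_table = file.path(directory, "de_table.tsv"),
             truth = file.path(directory, "truth.json"),
             design = file.path(directory, "design.json"))
  write_tsv(fm(study$run1_peaks), paths[["run1_peaks"]])
  write_tsv(fm(study$run2_peaks), paths[["run2_peaks"]])
  db <- study$metabolite_db
  db$mass <- sprintf("%.17g", db$mass)
  write_tsv(db, paths[["metabolite_db"]])
  cl <- study$clinical
  cl$LVMi <- sprintf("%.17g", cl$LVMi)
  cl$MEEi <- sprintf("%.17g", cl$MEEi)
  write_tsv(cl, paths[["clinical"]])
  write_tsv(study$gene_map, paths[["gene_map"]])
  write_tsv(study$de_table, paths[["de_table"]])
  jsonlite::write_json(study$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(study$design), paths[["design"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read study fixtures written by [write_fixtures()]
#'
#' @param directory Directory containing the fixture files.
#' @return A `simulated_study` (the `design` element is a plain list).
#' @export
read_fixtures <- function(directory) {
  rm_ <- function(p) {
    # first column read as character so m/z row labels round-trip verbatim
    df <- utils::read.table(p, sep = "\t", header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE, comment.char = "",
                            colClasses = "character")
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- df[[1]]
    m
  }
  truth <- jsonlite::read_json(file.path(directory, "truth.json"),
                               simplifyVector = TRUE)
  truth$covariate_linked <- as.data.frame(truth$covariate_linked,
                                          stringsAsFactors = FALSE)
  structure(list(
    run1_peaks = rm_(file.path(directory, "run1_peaks.tsv")),
    run2_peaks = rm_(file.path(directory, "run2_peaks.tsv")),
    metabolite_db = read_tsv(file.path(directory, "metabolite_db.tsv")),
    clinical = read_tsv(file.path(directory, "clinical.tsv")),
    gene_map = read_tsv(file.path(directory, "gene_map.tsv")),
    de_table = read_tsv(file.path(directory, "de_table.tsv")),
    truth = truth,
    design = jsonlite::read_json(file.path(directory, "design.json"),
                                 simplifyVector = TRUE)
  ), class = "simulated_study")
}
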