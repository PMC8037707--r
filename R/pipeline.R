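#' Pipeline configuration
#'
#' Exactly one of `synthetic` (a [study_design()] for fully synthetic mode)
#' or `inputs` (named file paths: `run1_peaks`, `run2_peaks`,
#' `metabolite_db`, `clinical`, and optionally `gene_map`, `de_table`) must
#' be supplied.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param synthetic A [study_design()], or NULL.
#' @param inputs Named list/vector of input TSV paths, or NULL.
#' @param model A [model_config()].
#' @param tolerance_ppm Annotation window (ppm).
#' @param adduct_offset Constant adduct mass offset (Da) for annotation.
#' @param anchor_group Harmonization anchor group.
#' @param alpha Significance level for paired/reversal calls.
#' @param fdr_cutoff FDR cutoff for clinical correlations.
#' @param de_p_threshold Significance threshold for gene direction labels.
#' @param seed Global seed; per-stage seeds are derived from it by stage
#'   name so stages are independently reproducible.
#' @return A `pipeline_config` list, validated.
#' @export
pipeline_config <- function(out_dir, synthetic = NULL, inputs = NULL,
                            model = model_config(), tolerance_ppm = 2,
                            adduct_offset = 0, anchor_group = "AS_pre",
                            alpha = 0.05, fdr_cutoff = 0.1,
                            de_p_threshold = 0.05, seed = 1L) {
  if (is.null(synthetic) == is.null(inputs))
    stop("supply exactly one of `synthetic` (a study_design) or `inputs` (paths)")
  if (alpha <= 0 || alpha >= 1 || fdr_cutoff <= 0 || fdr_cutoff >= 1)
    stop("thresholds must lie in (0, 1)")
  if (!is.null(inputs)) {
    req <- c("run1_peaks", "run2_peaks", "metabolite_db", "clinical")
    if (!all(req %in% names(inputs)))
      stop("inputs must name ", paste(req, collapse = ", "))
  }
  structure(list(out_dir = out_dir, synthetic = synthetic, inputs = inputs,
                 model = model, tolerance_ppm = tolerance_ppm,
                 adduct_offset = adduct_offset, anchor_group = anchor_group,
                 alpha = alpha, fdr_cutoff = fdr_cutoff,
                 de_p_threshold = de_p_threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Serialize a config to canonical JSON (for hashing and the manifest).
# out_dir is omitted: the same study run into two directories must hash
# identically so manifests can be compared byte for byte.
config_json <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  x$model <- unclass(x$model)
  if (!is.null(x$synthetic)) x$synthetic <- unclass(x$synthetic)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the full pipeline
#'
#' Executes simulate (synthetic mode) or load, annotate, harmonize,
#' discover, stats and map-genes in order, writing each stage's artifacts
#' under `config$out_dir` before the next stage starts. Failures abort with
#' the stage name and cause. A run manifest (config hash, seed, per-stage
#' output checksums, package version) is written as `manifest.json`; wall
#' clock timings go to `run.log` so the manifest itself is byte-identical
#' across reruns with the same config and seed.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return List: `manifest`, `panel` (a `panel_result`), `group_stats`,
#'   `paired`, `reversal`, `correlations`, `gene_report`, `annotation`
#'   (per-run counts), invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  cat("", file = log_path)
  t_all <- list()
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, fn) {
    say("[", name, "]")
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    t_all[[name]] <<- proc.time()[["elapsed"]] - t0
    cat(sprintf("%s\t%.2fs\n", name, t_all[[name]]), file = log_path,
        append = TRUE)
    res
  }
  artifacts <- list()
  record <- function(stage_name, paths) {
    artifacts[[stage_name]] <<- unname(unlist(paths))
    invisible(paths)
  }

  writeLines(config_json(config), file.path(out, "config.json"))

  study <- if (!is.null(config$synthetic)) {
    stage("simulate", function() {
      d <- config$synthetic
      d$seed <- derive_seed(config$seed, "simulate")
      st <- simulate_study(d)
      record("simulate", write_fixtures(st, file.path(out, "inputs")))
      st
    })
  } else {
    stage("load", function() {
      ip <- config$inputs
      st <- list(
        run1_peaks = read_tsv_matrix(ip[["run1_peaks"]]),
        run2_peaks = read_tsv_matrix(ip[["run2_peaks"]]),
        metabolite_db = read_tsv(ip[["metabolite_db"]]),
        clinical = read_tsv(ip[["clinical"]]),
        gene_map = if (!is.null(ip[["gene_map"]])) read_tsv(ip[["gene_map"]]),
        de_table = if (!is.null(ip[["de_table"]])) read_tsv(ip[["de_table"]])
      )
      record("load", unlist(ip))
      st
    })
  }

  ann <- stage("annotate", function() {
    res <- lapply(list(run1 = study$run1_peaks, run2 = study$run2_peaks),
                  function(pk) {
      annotate_peaks(average_triplicates(pk), study$metabolite_db,
                     tolerance_ppm = config$tolerance_ppm,
                     adduct_offset = config$adduct_offset)
    })
    for (r in names(res)) {
      write_tsv(res[[r]]$report, file.path(out, paste0("annotation_", r, ".tsv")))
      write_tsv(signif(res[[r]]$matrix, 10),
                file.path(out, paste0("annotated_", r, ".tsv")),
                row_label = "feature")
    }
    record("annotate", file.path(out, c("annotation_run1.tsv",
                                        "annotated_run1.tsv",
                                        "annotation_run2.tsv",
                                        "annotated_run2.tsv")))
    res
  })

  z <- stage("harmonize", function() {
    # intensities are log-normal: standardize on the log10 scale
    meta <- study$clinical[, c("sample_id", "group", "run", "pair_id")]
    z1 <- anchor_zscore(log_intensities(ann$run1$matrix),
                        meta[meta$run == "run1", ], config$anchor_group)
    z2 <- anchor_zscore(log_intensities(ann$run2$matrix),
                        meta[meta$run == "run2", ], config$anchor_group)
    zm <- merge_runs(z1, z2)
    write_tsv(signif(zm$z, 10), file.path(out, "zscores.tsv"),
              row_label = "feature")
    write_tsv(zm$meta, file.path(out, "zscore_meta.tsv"))
    record("harmonize", file.path(out, c("zscores.tsv", "zscore_meta.tsv")))
    zm
  })

  panel <- stage("discover", function() {
    mc <- config$model
    mc$seed <- derive_seed(config$seed, "discover")
    res <- discover_panel(z, c("control", "AS_pre"), mc)
    write_tsv(res$table, file.path(out, "panel.tsv"))
    jsonlite::write_json(
      list(observed_auc = res$permutation$observed_auc,
           p_value = res$permutation$p_value,
           n_permutations = res$permutation$n_permutations,
           mean_test_auc = res$mean_auc),
      file.path(out, "permutation.json"), auto_unbox = TRUE, digits = NA)
    # plot-ready radar table: top-15 features x group mean Z-scores
    top15 <- res$panel[seq_len(min(15L, length(res$panel)))]
    gm <- vapply(c("control", "AS_pre", "AS_post"), function(g) {
      cols <- z$meta$column[z$meta$group == g]
      rowMeans(z$z[top15, cols, drop = FALSE])
    }, numeric(length(top15)))
    write_tsv(data.frame(feature = top15, gm, check.names = FALSE),
              file.path(out, "radar_top15.tsv"))
    record("discover", file.path(out, c("panel.tsv", "permutation.json",
                                        "radar_top15.tsv")))
    res
  })

  st <- stage("stats", function() {
    gs <- group_difference_tests(z, c("control", "AS_pre"))
    zp <- z
    zp$z <- z$z[panel$panel, , drop = FALSE]
    pr <- paired_stats(zp, alpha = config$alpha)
    rv <- classify_reversal(gs[match(panel$panel, gs$feature), ], pr,
                            alpha = config$alpha)
    co <- correlate_clinical(z, study$clinical, features = panel$panel,
                             fdr_cutoff = config$fdr_cutoff)
    write_tsv(gs, file.path(out, "group_stats.tsv"))
    write_tsv(pr, file.path(out, "paired_stats.tsv"))
    write_tsv(rv, file.path(out, "reversal.tsv"))
    write_tsv(co, file.path(out, "correlations.tsv"))
    record("stats", file.path(out, c("group_stats.tsv", "paired_stats.tsv",
                                     "reversal.tsv", "correlations.tsv")))
    list(group_stats = gs, paired = pr, reversal = rv, correlations = co)
  })

  gene_report <- if (!is.null(study$gene_map) && !is.null(study$de_table)) {
    stage("map_genes", function() {
      mm <- map_metabolites_to_genes(panel$panel, study$gene_map)
      gr <- join_expression(mm, study$de_table, config$de_p_threshold)
      write_tsv(gr, file.path(out, "gene_report.tsv"))
      record("map_genes", file.path(out, "gene_report.tsv"))
      gr
    })
  }

  manifest <- stage("manifest", function() {
    files <- sort(unname(unlist(artifacts)))
    sums <- tools::md5sum(files)
    mf <- list(
      config_hash = unname(tools::md5sum(file.path(out, "config.json"))),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("metabpanel")),
      stages = lapply(artifacts, function(fp)
        as.list(stats::setNames(unname(tools::md5sum(fp)), basename(fp)))))
    jsonlite::write_json(mf, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    mf
  })

  invisible(list(manifest = manifest, panel = panel,
                 group_stats = st$group_stats, paired = st$paired,
                 reversal = st$reversal, correlations = st$correlations,
                 gene_report = gene_report,
                 annotation = lapply(ann, collapse_unique_masses)))
}
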