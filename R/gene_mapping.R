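#' Map panel metabolites to candidate interacting genes
#'
#' Offline join of panel features against a user-supplied metabolite-to-gene
#' mapping table (e.g. exported from a pathway resource). Matching is
#' case-insensitive on metabolite names, and composite isobar labels are
#' expanded: `"A/B"` matches mapping rows for A or for B. A trailing
#' disambiguation suffix `" (k)"` on a feature label is ignored.
#'
#' @param panel Character vector of panel feature labels.
#' @param mapping Data frame with columns `metabolite`, `gene` and optional
#'   `pathway`.
#' @return List: `matched` (data frame `feature`, `metabolite`, `gene`,
#'   `pathway`), `unmatched` (panel entries with no mapping row).
#' @export
map_metabolites_to_genes <- function(panel, mapping) {
  if (length(panel) == 0L) stop("panel must be non-empty")
  if (!all(c("metabolite", "gene") %in% names(mapping)))
    stop("mapping must have columns metabolite and gene")
  if (nrow(mapping) == 0L) stop("empty mapping table")
  mapping$gene <- toupper(trimws(mapping$gene))
  if (!("pathway" %in% names(mapping))) mapping$pathway <- NA_character_
  mapping <- mapping[!duplicated(mapping[, c("metabolite", "gene")]), ]
  key <- tolower(trimws(mapping$metabolite))

  rows <- list()
  unmatched <- character(0)
  for (f in panel) {
    parts <- strsplit(sub(" \\([0-9]+\\)$", "", f), "/", fixed = TRUE)[[1]]
    hit <- which(key %in% tolower(trimws(parts)))
    if (length(hit) == 0L) {
      unmatched <- c(unmatched, f)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, metabolite = mapping$metabolite[hit],
        gene = mapping$gene[hit], pathway = mapping$pathway[hit],
        stringsAsFactors = FALSE)
    }
  }
  matched <- if (length(rows)) do.call(rbind, rows)
  else data.frame(feature = character(0), metabolite = character(0),
                  gene = character(0), pathway = character(0),
                  stringsAsFactors = FALSE)
  rownames(matched) <- NULL
  list(matched = matched, unmatched = unmatched)
}

#' Annotate mapped genes with differential-expression evidence
#'
#' Left join of the matched metabolite-gene rows against a differential
#' expression table, labeling each gene `up` (p below threshold, positive
#' log2 fold change), `down` (p below threshold, negative log2FC) or `ns`;
#' genes absent from the expression table are flagged `not measured`.
#'
#' @param matched `matched` data frame from [map_metabolites_to_genes()]
#'   (or the whole list).
#' @param de_table Data frame with columns `gene`, `log2fc`, `p`.
#' @param p_threshold Significance threshold for direction labels.
#' @return Data frame: `feature`, `metabolite`, `gene`, `log2fc`, `p`,
#'   `direction` (`up`/`down`/`ns`), `measured`.
#' @export
join_expression <- function(matched, de_table, p_threshold = 0.05) {
  if (is.list(matched) && !is.data.frame(matched)) matched <- matched$matched
  if (!all(c("gene", "log2fc", "p") %in% names(de_table)))
    stop("de_table must have columns gene, log2fc, p")
  if (any(de_table$p < 0 | de_table$p > 1, na.rm = TRUE))
    stop("de_table p-values must lie in [0, 1]")
  de_table$gene <- toupper(trimws(de_table$gene))
  de_table <- de_table[!duplicated(de_table$gene), ]
  i <- match(matched$gene, de_table$gene)
  lfc <- de_table$log2fc[i]
  p <- de_table$p[i]
  measured <- !is.na(i)
  direction <- ifelse(!measured | is.na(p), "ns",
               ifelse(p < p_threshold & lfc > 0, "up",
               ifelse(p < p_threshold & lfc < 0, "down", "ns")))
  data.frame(feature = matched$feature, metabolite = matched$metabolite,
             gene = matched$gene, log2fc = lfc, p = p,
             direction = direction, measured = measured,
             row.names = NULL, stringsAsFactors = FALSE)
}
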