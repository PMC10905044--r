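# Cell-type signature construction and enrichment scoring.

#' Build extended and combined cell-type signatures
#'
#' Merges per-source single-cell-derived signature sets into two levels:
#' the extended level unites gene sets of the same cell-type name across
#' sources, retaining per-source provenance counts; the combined level
#' additionally unites extended cell types into broader groups given by
#' `merge_map` (e.g. goblet + enterocyte -> epithelial).
#'
#' @param sources List of [signature_set()]s, one per source dataset, all
#'   at the extended level.
#' @param merge_map Named list: combined cell-type name -> character vector
#'   of extended cell-type names. Referencing an unknown extended cell type
#'   is an error.
#' @return List with `extended` and `combined` ([signature_set()]s) and
#'   `provenance` (data frame cell_type, source, n_genes).
#' @export
build_signatures <- function(sources, merge_map) {
  if (!length(sources)) stop("need at least one source signature set")
  all_names <- sort(unique(unlist(lapply(sources, names))))
  ext_sets <- stats::setNames(lapply(all_names, function(nm) {
    sort(unique(unlist(lapply(sources, function(s)
      if (nm %in% names(s)) s[[nm]]$genes else character()))))
  }), all_names)
  provenance <- do.call(rbind, lapply(seq_along(sources), function(i) {
    s <- sources[[i]]
    src <- if (!is.null(names(sources))) names(sources)[i] else
      s[[1L]]$source
    data.frame(cell_type = names(s), source = src,
               n_genes = lengths(lapply(s, `[[`, "genes")),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  extended <- signature_set(ext_sets, sources = "merged", level = "extended")
  unknown <- setdiff(unlist(merge_map), all_names)
  if (length(unknown))
    stop("merge_map references unknown cell type(s): ",
         paste(unknown, collapse = ", "))
  comb_sets <- lapply(merge_map, function(members)
    sort(unique(unlist(ext_sets[members]))))
  combined <- signature_set(comb_sets, sources = "merged", level = "combined")
  list(extended = extended, combined = combined, provenance = provenance)
}

#' Score cell-type signatures against a differential table
#'
#' Maps the (already significance-filtered) differential features onto each
#' cell-type signature and summarizes the spread of their log2 fold
#' changes. Enrichment is descriptive: the call is the sign of the median
#' (positive above zero, negative below, neutral at exactly zero), the way
#' violin-plot deconvolution reads protein changes as cell-population
#' shifts. A Wilcoxon signed-rank p against zero is emitted for reference
#' but takes no part in the call. Features mapping to several signatures
#' contribute to each.
#'
#' @param t A significant-only [differential_table()].
#' @param sig A [signature_set()].
#' @param min_mapped Minimum mapped features for a signature to be scored
#'   (default 3).
#' @return Data frame of class `celltype_enrichment`: cell_type, n_mapped,
#'   median_log2fc, direction, p_wilcoxon; mapped features in attribute
#'   `"mapped"`.
#' @export
score_celltypes <- function(t, sig, min_mapped = 3L) {
  fc <- tapply(t$log2fc, t$gene_symbol, function(x) x[1L])
  mapped <- lapply(sig, function(s) intersect(s$genes, names(fc)))
  keep <- lengths(mapped) >= min_mapped
  rows <- lapply(names(sig)[keep], function(nm) {
    v <- fc[mapped[[nm]]]
    med <- stats::median(v)
    pw <- tryCatch(
      suppressWarnings(stats::wilcox.test(v, mu = 0)$p.value),
      error = function(e) NA_real_)
    data.frame(cell_type = nm, n_mapped = length(v), median_log2fc = med,
               direction = if (med > 0) "positive" else
                 if (med < 0) "negative" else "neutral",
               p_wilcoxon = pw, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_type = character(), n_mapped = integer(),
               median_log2fc = numeric(), direction = character(),
               p_wilcoxon = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "mapped") <- mapped[keep]
  class(out) <- c("celltype_enrichment", "data.frame")
  out
}

#' Write a cell-type enrichment table to TSV
#' @param ce A `celltype_enrichment` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_celltype_enrichment <- function(ce, path) {
  utils::write.table(as.data.frame(ce), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
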