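# Ligand-receptor lookups and matrisomal-ligand -> DE-receptor mapping.

#' Interactor profiles of query genes
#'
#' For each query, collects its interaction partners on either side of the
#' pair set (the pair set is typed ligand -> receptor, but interactor
#' counting is direction-agnostic: a query appearing on the receptor side
#' still reports its ligand partners), and flags the subset differential in
#' the given comparison. A query absent from the interaction set yields an
#' empty profile and a message.
#'
#' @param queries Nonempty character vector of gene symbols (e.g. SLRPs).
#' @param db An [interaction_db()].
#' @param t Optional [differential_table()] used to flag differential
#'   interactors.
#' @param q_max Significance threshold for the differential flag
#'   (default 0.05, strict).
#' @return List of `interactor_profile` objects: `query_symbol`,
#'   `interactors`, `de_interactors`, `n_interactors`, `n_de_interactors`.
#' @export
interactors_of <- function(queries, db, t = NULL, q_max = 0.05) {
  if (!length(queries)) stop("empty query set")
  de_genes <- if (!is.null(t))
    unique(filter_significant(t, q_max)$gene_symbol) else character()
  lapply(stats::setNames(queries, queries), function(g) {
    partners <- sort(unique(c(db$pairs$receptor[db$pairs$ligand == g],
                              db$pairs$ligand[db$pairs$receptor == g])))
    if (!length(partners))
      message("query '", g, "' has no interactors in the database")
    de <- intersect(partners, de_genes)
    structure(list(query_symbol = g, interactors = partners,
                   de_interactors = de,
                   n_interactors = length(partners),
                   n_de_interactors = length(de)),
              class = "interactor_profile")
  })
}

#' Summarize interactor profiles as a data frame
#'
#' @param profiles List returned by [interactors_of()].
#' @return Data frame: query_symbol, n_interactors, n_de_interactors.
#' @export
interactor_counts <- function(profiles) {
  data.frame(query_symbol = vapply(profiles, `[[`, "", "query_symbol"),
             n_interactors = vapply(profiles, `[[`, 0L, "n_interactors"),
             n_de_interactors = vapply(profiles, `[[`, 0L, "n_de_interactors"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Map differential matrisomal ligands to differential receptors
#'
#' The integrative filter chain: keep proteins that are annotated
#' matrisomal, typed as ligands, and significant in the protein comparison
#' (q-value threshold); keep genes typed as receptors and significant in
#' the transcript comparison (adjusted-p threshold); emit every
#' ligand-receptor pair of the interaction set whose endpoints both
#' survive. The receptor filter is transcriptomic only.
#'
#' @param prot Protein [differential_table()] (significance = q-value).
#' @param rna Transcript [differential_table()] (significance = adjusted p).
#' @param ann An [annotation_db()].
#' @param db An [interaction_db()].
#' @param q_max Protein q-value threshold (default 0.05, strict).
#' @param padj_max Transcript adjusted-p threshold (default 0.05, strict).
#' @param check_comparisons Require matching `comparison_id` between the
#'   two tables (default `TRUE`).
#' @return Data frame of class `lr_edges` with columns ligand, receptor,
#'   ligand_log2fc, ligand_q, receptor_log2fc, receptor_padj; per-ligand
#'   and per-receptor edge counts in attributes `"ligand_counts"` /
#'   `"receptor_counts"`.
#' @export
ligand_receptor_map <- function(prot, rna, ann, db, q_max = 0.05,
                                padj_max = 0.05, check_comparisons = TRUE) {
  if (check_comparisons && nrow(prot) && nrow(rna) &&
      !identical(prot$comparison_id[1L], rna$comparison_id[1L]))
    stop("comparison-id mismatch: protein table is '",
         prot$comparison_id[1L], "', transcript table is '",
         rna$comparison_id[1L], "'")
  matri <- matrisomal_genes(ann)
  ligand_type <- names(db$protein_type)[db$protein_type == "ligand"]
  receptor_type <- names(db$protein_type)[db$protein_type == "receptor"]
  sp <- filter_significant(prot, q_max)
  sr <- filter_significant(rna, padj_max)
  lig <- sp[sp$gene_symbol %in% intersect(matri, ligand_type), ]
  rec <- sr[sr$gene_symbol %in% receptor_type, ]
  lig_fc <- tapply(lig$log2fc, lig$gene_symbol, function(x) x[1L])
  lig_q <- tapply(lig$significance, lig$gene_symbol, function(x) x[1L])
  rec_fc <- tapply(rec$log2fc, rec$gene_symbol, function(x) x[1L])
  rec_p <- tapply(rec$significance, rec$gene_symbol, function(x) x[1L])
  p <- db$pairs
  keep <- p$ligand %in% names(lig_fc) & p$receptor %in% names(rec_fc)
  edges <- data.frame(
    ligand = p$ligand[keep], receptor = p$receptor[keep],
    ligand_log2fc = unname(lig_fc[p$ligand[keep]]),
    ligand_q = unname(lig_q[p$ligand[keep]]),
    receptor_log2fc = unname(rec_fc[p$receptor[keep]]),
    receptor_padj = unname(rec_p[p$receptor[keep]]),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$ligand, edges$receptor), ]
  rownames(edges) <- NULL
  attr(edges, "ligand_counts") <- if (nrow(edges))
    sort(table(edges$ligand), decreasing = TRUE) else table(character())
  attr(edges, "receptor_counts") <- if (nrow(edges))
    sort(table(edges$receptor), decreasing = TRUE) else table(character())
  class(edges) <- c("lr_edges", "data.frame")
  edges
}

#' Write a ligand-receptor edge list to TSV
#' @param edges An `lr_edges` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lr_edges <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
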