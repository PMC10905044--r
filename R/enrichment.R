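# SLRP pathway enrichment scoring.

#' SLRP pathway enrichment scores
#'
#' For each pathway P, let I be the union over all query SLRPs of their
#' interactors that fall in P, and DE the subset of I differential in the
#' given comparison. The score is
#'
#'   ES = ES_interactors * (N_de_interactors / N_interactors)
#'
#' where `ES_interactors = mean(log2fc) * mean(q)` over the averaging set,
#' `N_de_interactors = |DE|` and `N_interactors = |I|`. The printed formula
#' says the averages run over "all interactors found in the pathway", but
#' only tested (differential) interactors carry a fold change and q-value
#' in a comparison-specific table, so the default averaging set is the DE
#' subset (`mode = "de_only"`); `mode = "all_with_values"` averages over
#' every in-pathway interactor present in the table. Pathways with no
#' in-pathway interactor are omitted; pathways whose interactors are all
#' non-differential get ES = 0 with `flag = "no_de_interactors"`.
#' Interactor sets are sets: a gene shared by two SLRPs' interactor lists
#' counts once. Multiplying by the average q-value shrinks strongly
#' significant sets toward zero; this is implemented exactly as defined,
#' not "improved".
#'
#' @param slrps Character vector of SLRP symbols.
#' @param profiles List from [interactors_of()] covering every SLRP.
#' @param t [differential_table()] of the relevant comparison
#'   (significance = q-value).
#' @param pathways A [signature_set()].
#' @param q_max Differential threshold (default 0.05, strict).
#' @param mode Averaging set: `"de_only"` (default) or `"all_with_values"`.
#' @return Data frame of class `pathway_scores`: pathway, es,
#'   es_interactors, n_de_interactors, n_interactors, flag.
#' @export
slrp_pathway_scores <- function(slrps, profiles, t, pathways, q_max = 0.05,
                                mode = c("de_only", "all_with_values")) {
  mode <- match.arg(mode)
  if (!length(pathways)) stop("empty pathway set")
  miss <- setdiff(slrps, vapply(profiles, `[[`, "", "query_symbol"))
  if (length(miss))
    stop("no interactor profile for: ", paste(miss, collapse = ", "))
  profiles <- profiles[vapply(profiles, `[[`, "", "query_symbol") %in% slrps]
  interactors <- sort(unique(unlist(lapply(profiles, `[[`, "interactors"))))
  fc <- tapply(t$log2fc, t$gene_symbol, function(x) x[1L])
  qv <- tapply(t$significance, t$gene_symbol, function(x) x[1L])
  de_genes <- unique(filter_significant(t, q_max)$gene_symbol)
  rows <- lapply(names(pathways), function(nm) {
    I <- intersect(interactors, pathways[[nm]]$genes)
    if (!length(I)) return(NULL)
    de <- intersect(I, de_genes)
    avg_set <- if (mode == "de_only") de else intersect(I, names(fc))
    flag <- ""
    if (length(de) == 0L || length(avg_set) == 0L) {
      es_int <- 0
      flag <- "no_de_interactors"
    } else {
      es_int <- mean(fc[avg_set]) * mean(qv[avg_set])
    }
    data.frame(pathway = nm,
               es = es_int * (length(de) / length(I)),
               es_interactors = es_int,
               n_de_interactors = length(de),
               n_interactors = length(I),
               flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pathway = character(), es = numeric(),
                      es_interactors = numeric(),
                      n_de_interactors = integer(),
                      n_interactors = integer(), flag = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pathway_scores", "data.frame")
  out
}

#' Write a pathway score table to TSV
#' @param ps A `pathway_scores` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathway_scores <- function(ps, path) {
  utils::write.table(as.data.frame(ps), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Chord-diagram links from SLRPs to enriched pathways
#'
#' Two-column link list (SLRP, pathway) restricted to the pathways ranking
#' in the top `top_n` by `|ES|`, with one link per (SLRP, pathway) pair
#' whose interactors overlap the pathway. Deterministic ordering (pathway,
#' then SLRP).
#'
#' @param scores A `pathway_scores` data frame.
#' @param profiles List from [interactors_of()].
#' @param pathways The [signature_set()] used for scoring.
#' @param top_n Number of pathways kept by the `|ES|` rank cut
#'   (default all).
#' @return Data frame: source (SLRP), target (pathway), weight
#'   (number of in-pathway interactors of that SLRP).
#' @export
slrp_pathway_links <- function(scores, profiles, pathways, top_n = Inf) {
  keep <- scores$pathway[order(-abs(scores$es))]
  keep <- utils::head(keep, top_n)
  rows <- list()
  for (pw in sort(keep)) {
    pg <- pathways[[pw]]$genes
    for (pr in profiles) {
      k <- length(intersect(pr$interactors, pg))
      if (k > 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          source = pr$query_symbol, target = pw, weight = k,
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(), target = character(),
               weight = integer(), stringsAsFactors = FALSE)
  out[order(out$target, out$source), , drop = FALSE]
}
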