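# Shared fixture builders: everything is generated in code at test time.

tiny_cfg <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, n_proteins = 200L, n_samples_per_group = 4L,
                   n_cell_types = 4L, n_pathways = 5L, n_planted_triples = 6L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# random differential table (already symbol-split)
random_table <- function(n, seed, comparison_id = "A", prefix = "t") {
  set.seed(seed)
  differential_table(
    feature_id = sprintf("%s%04d", prefix, seq_len(n)),
    gene_symbol = sprintf("%sg%04d", prefix, sample(seq_len(n))),
    log2fc = round(rnorm(n, 0, 2), 3),
    significance = round(runif(n), 4),
    comparison_id = comparison_id, split = FALSE)
}

# paired abundance matrix from an explicit matrix of log2 values
matrix_from_log2 <- function(log2_case, log2_ctrl, gene_symbols = NULL,
                             n_unique_peptides = NULL) {
  stopifnot(identical(dim(log2_case), dim(log2_ctrl)))
  n <- nrow(log2_case); k <- ncol(log2_case)
  v <- 2^cbind(log2_case, log2_ctrl)
  rownames(v) <- sprintf("PG%03d", seq_len(n))
  colnames(v) <- c(sprintf("case_m%02d", seq_len(k)),
                   sprintf("ctrl_m%02d", seq_len(k)))
  samples <- data.frame(
    sample_id = colnames(v),
    group = rep(c("case", "ctrl"), each = k),
    pair = rep(sprintf("m%02d", seq_len(k)), 2L))
  abundance_matrix(
    v, samples,
    gene_symbols = gene_symbols %||% sprintf("Gene%03d", seq_len(n)),
    n_unique_peptides = n_unique_peptides %||% rep(3L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent hypergeometric tail by exhaustive enumeration (oracle)
enum_hyper_tail <- function(k, K, N, n, upper = TRUE) {
  probs <- vapply(0:min(K, n), function(x)
    choose(K, x) * choose(N - K, n - x) / choose(N, n), 0)
  idx <- 0:min(K, n)
  if (upper) sum(probs[idx >= k]) else sum(probs[idx <= k])
}

# independent SLRP score oracle: literal evaluation of the printed formula
oracle_slrp_score <- function(profiles, t, pathway_genes, q_max = 0.05) {
  interactors <- unique(unlist(lapply(profiles, function(p) p$interactors)))
  I <- intersect(interactors, pathway_genes)
  if (!length(I)) return(NULL)
  fc <- t$log2fc[match(I, t$gene_symbol)]
  qv <- t$significance[match(I, t$gene_symbol)]
  de <- !is.na(qv) & qv < q_max
  if (!any(de)) return(list(es = 0, n_de = 0, n_int = length(I)))
  es_int <- mean(fc[de]) * mean(qv[de])
  list(es = es_int * (sum(de) / length(I)), n_de = sum(de),
       n_int = length(I))
}
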