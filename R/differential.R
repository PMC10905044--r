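# Differential abundance testing, QC, filtering, signature derivation,
# and overrepresentation analysis.

#' Storey q-values
#'
#' Positive-FDR-controlling q-values. The proportion of true nulls `pi0` is
#' estimated either at a single fixed lambda (default 0.5,
#' `pi0 = #\{p > lambda\} / (m (1 - lambda))`, truncated to `(0, 1]`) or by
#' the natural-spline smoother over a lambda grid evaluated at its right
#' end. The q-value of the i-th smallest p is
#' `min_{j >= i} pi0 * m * p_(j) / j`, i.e. pi0 times the
#' Benjamini-Hochberg running minimum.
#'
#' @param p Numeric vector of p-values in `[0, 1]`, no `NA`.
#' @param lambda Tuning parameter for the fixed-lambda estimator.
#' @param pi0_method `"fixed"` (default) or `"smoother"`.
#' @return Numeric vector of q-values, same order as `p`, with the
#'   estimated `pi0` attached as attribute `"pi0"`.
#' @export
storey_qvalues <- function(p, lambda = 0.5,
                           pi0_method = c("fixed", "smoother")) {
  pi0_method <- match.arg(pi0_method)
  if (!length(p)) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  m <- length(p)
  pi0 <- if (pi0_method == "fixed") {
    mean(p > lambda) / (1 - lambda)
  } else {
    grid <- seq(0.05, 0.9, by = 0.05)
    pi0_l <- vapply(grid, function(l) mean(p > l) / (1 - l), 0)
    fit <- stats::smooth.spline(grid, pi0_l, df = 3)
    stats::predict(fit, x = max(grid))$y
  }
  pi0 <- min(1, max(pi0, 1 / m))
  o <- order(p, decreasing = TRUE)
  q_sorted <- pmin(1, cummin(pi0 * m * p[o] / (m:1)))
  q <- numeric(m)
  q[o] <- q_sorted
  structure(q, pi0 = pi0)
}

#' Paired differential abundance test
#'
#' Per-protein paired t-test on log2 abundances between two groups matched
#' by the pairing key, following summed-intensity DIA practice: the log2
#' fold change is the mean of paired log2 differences, p-values come from
#' the two-sided paired t-test, and q-values from [storey_qvalues()]
#' computed over all tested proteins. Protein groups with fewer than 2
#' unique peptides are excluded before testing; pairs with a missing value
#' on either side are dropped per protein (pairwise-complete), and proteins
#' left with fewer than `min_pairs` complete pairs are skipped and logged.
#' A zero-variance, zero-difference protein gets p = 1 (no evidence); a
#' constant nonzero difference leaves p undefined (`NA`).
#'
#' @param m An [abundance_matrix()].
#' @param contrast Character pair `c(case_group, control_group)`; log2fc is
#'   case minus control.
#' @param min_pairs Minimum complete pairs (default 2).
#' @param min_peptides Unique-peptide filter (default 2).
#' @return A [differential_table()] with one record per tested gene symbol
#'   (multi-symbol groups split), `comparison_id = "case_vs_control"`.
#'   Skipped proteins are reported in attribute `"skipped"`.
#' @export
differential_test <- function(m, contrast, min_pairs = 2L, min_peptides = 2L) {
  stopifnot(length(contrast) == 2L)
  if (!all(contrast %in% m$samples$group))
    stop("contrast groups absent from sample table: ",
         paste(setdiff(contrast, m$samples$group), collapse = ", "))
  keep <- m$n_unique_peptides >= min_peptides
  v <- log2(m$values[keep, , drop = FALSE])
  symbols <- m$gene_symbols[keep]
  case_s <- m$samples[m$samples$group == contrast[1L], ]
  ctrl_s <- m$samples[m$samples$group == contrast[2L], ]
  common_pairs <- intersect(case_s$pair, ctrl_s$pair)
  if (length(common_pairs) < min_pairs)
    stop("fewer than ", min_pairs, " matched pairs between groups")
  case_cols <- case_s$sample_id[match(common_pairs, case_s$pair)]
  ctrl_cols <- ctrl_s$sample_id[match(common_pairs, ctrl_s$pair)]
  d <- v[, case_cols, drop = FALSE] - v[, ctrl_cols, drop = FALSE]
  res <- t(apply(d, 1L, function(di) {
    di <- di[is.finite(di)]
    if (length(di) < min_pairs) return(c(NA_real_, NA_real_, length(di)))
    if (stats::sd(di) == 0) {
      p <- if (mean(di) == 0) 1 else NA_real_
      return(c(mean(di), p, length(di)))
    }
    ht <- stats::t.test(di)
    c(mean(di), ht$p.value, length(di))
  }))
  n_pairs <- res[, 3L]
  skipped <- rownames(v)[n_pairs < min_pairs]
  if (length(skipped))
    message(length(skipped), " protein group(s) skipped: < ", min_pairs,
            " complete pairs")
  tested <- is.finite(res[, 2L]) | (!is.na(res[, 2L]))
  ok <- n_pairs >= min_pairs
  q <- rep(NA_real_, nrow(res))
  has_p <- ok & !is.na(res[, 2L])
  if (any(has_p)) q[has_p] <- storey_qvalues(res[has_p, 2L])
  out <- differential_table(
    feature_id = rownames(v)[ok],
    gene_symbol = symbols[ok],
    log2fc = res[ok, 1L],
    significance = q[ok],
    comparison_id = paste0(contrast[1L], "_vs_", contrast[2L]))
  attr(out, "skipped") <- skipped
  attr(out, "pvalues") <- stats::setNames(res[ok, 2L], rownames(v)[ok])
  out
}

#' Within-group replicate correlation
#'
#' All pairwise Pearson correlations between samples of one group, computed
#' on the log2 abundances of proteins quantified in both members of each
#' pair. A sample is flagged as an outlier when its median correlation to
#' its group-mates falls below `min_r` (default 0.85, the usual
#' within-group reproducibility bar for summed-intensity replicates).
#'
#' @param m An [abundance_matrix()].
#' @param group Group label.
#' @param min_r Outlier threshold on the median within-group r.
#' @return List: `pairs` (data frame sample_a, sample_b, r), `median_r`
#'   (named per sample), `outliers` (character).
#' @export
replicate_correlation <- function(m, group, min_r = 0.85) {
  ids <- m$samples$sample_id[m$samples$group == group]
  if (length(ids) < 2L) stop("need >= 2 samples in group '", group, "'")
  v <- log2(m$values[, ids, drop = FALSE])
  cmb <- utils::combn(ids, 2L)
  r <- apply(cmb, 2L, function(ab)
    stats::cor(v[, ab[1L]], v[, ab[2L]], use = "pairwise.complete.obs"))
  pairs <- data.frame(sample_a = cmb[1L, ], sample_b = cmb[2L, ], r = r,
                      stringsAsFactors = FALSE)
  med <- vapply(ids, function(s)
    stats::median(pairs$r[pairs$sample_a == s | pairs$sample_b == s]), 0)
  list(pairs = pairs, median_r = med, outliers = names(med)[med < min_r])
}

#' Filter a differential table on significance and fold change
#'
#' Keeps records whose significance passes `q_max` and, when
#' `abs_log2fc_min` is given, whose `|log2fc|` strictly exceeds it. The
#' significance comparator defaults to strict (`significance < q_max`);
#' `comparator = "le"` gives the inclusive variant used by
#' Spectronaut-style initial significance calls.
#'
#' @param t A [differential_table()].
#' @param q_max Significance threshold (default 0.05).
#' @param abs_log2fc_min Optional absolute log2 fold-change threshold.
#' @param comparator `"lt"` (strict, default) or `"le"`.
#' @return Filtered `differential_table` (records with `NA` significance
#'   are dropped).
#' @export
filter_significant <- function(t, q_max = 0.05, abs_log2fc_min = NULL,
                               comparator = c("lt", "le")) {
  comparator <- match.arg(comparator)
  s <- t$significance
  keep <- !is.na(s) & if (comparator == "lt") s < q_max else s <= q_max
  if (!is.null(abs_log2fc_min))
    keep <- keep & abs(t$log2fc) > abs_log2fc_min
  out <- t[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(t)
  out
}

#' Top-N most significant features
#'
#' Features sorted by ascending significance; ties broken by larger
#' `|log2fc|`, then lexicographic gene symbol, so the output is
#' deterministic.
#'
#' @param t A [differential_table()].
#' @param n Number of features (e.g. 200 for a disease signature).
#' @return `differential_table` of the first `n` rows; when `n` exceeds the
#'   table size, the whole sorted table is returned with a warning.
#' @export
top_n_signature <- function(t, n) {
  if (n < 1L) stop("n must be >= 1")
  o <- order(t$significance, -abs(t$log2fc), t$gene_symbol)
  out <- t[o, , drop = FALSE]
  if (n > nrow(out)) {
    warning("n = ", n, " exceeds table size ", nrow(out),
            "; returning the whole table")
    n <- nrow(out)
  }
  out <- out[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(t)
  out
}

#' Direction-aware Venn partition of two comparisons
#'
#' Splits the union of significant features of two comparisons into four
#' disjoint sets: significant only in A, only in B, significant in both
#' with the same direction of change, and significant in both with
#' opposite direction. A log2fc of exactly zero counts as its own sign, so
#' it is direction-discordant with both positive and negative changes.
#'
#' @param tA,tB [differential_table()]s over the same symbol space.
#' @param q_max Significance threshold (default 0.05, strict).
#' @param comparator Passed to [filter_significant()].
#' @return Object of class `venn_partition`: list with `only_A`, `only_B`,
#'   `shared_same_direction`, `shared_opposite_direction` (character
#'   vectors of gene symbols) and `comparisons`.
#' @export
venn_direction_partition <- function(tA, tB, q_max = 0.05,
                                     comparator = "lt") {
  sA <- filter_significant(tA, q_max, comparator = comparator)
  sB <- filter_significant(tB, q_max, comparator = comparator)
  fA <- tapply(sA$log2fc, sA$gene_symbol, function(x) x[1L])
  fB <- tapply(sB$log2fc, sB$gene_symbol, function(x) x[1L])
  both <- intersect(names(fA), names(fB))
  same <- both[sign(fA[both]) == sign(fB[both])]
  out <- list(only_A = sort(setdiff(names(fA), both)),
              only_B = sort(setdiff(names(fB), both)),
              shared_same_direction = sort(same),
              shared_opposite_direction = sort(setdiff(both, same)),
              comparisons = c(A = tA$comparison_id[1L],
                              B = tB$comparison_id[1L]))
  class(out) <- "venn_partition"
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("venn_partition: only_A %d | only_B %d | shared same %d | shared opposite %d\n",
              length(x$only_A), length(x$only_B),
              length(x$shared_same_direction),
              length(x$shared_opposite_direction)))
  invisible(x)
}

#' Write a Venn partition to TSV
#'
#' Long format: columns `gene_symbol`, `subset`.
#' @param vp A `venn_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_venn_partition <- function(vp, path) {
  subsets <- c("only_A", "only_B", "shared_same_direction",
               "shared_opposite_direction")
  df <- do.call(rbind, lapply(subsets, function(s)
    if (length(vp[[s]])) data.frame(gene_symbol = vp[[s]], subset = s,
                                    stringsAsFactors = FALSE)))
  if (is.null(df)) df <- data.frame(gene_symbol = character(),
                                    subset = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-matrisome-category fold-change summary
#'
#' Groups the (already significance-filtered) differential records by
#' matrisome category and compares category log2fc distributions with all
#' pairwise Welch t-tests. P-values are reported unadjusted. Categories
#' with fewer than 2 members are kept in the summary but excluded from
#' testing.
#'
#' @param t A significant-only [differential_table()].
#' @param ann An [annotation_db()].
#' @return List: `summary` (category, n, mean/median log2fc), `tests`
#'   (category_a, category_b, p), `values` (per-category log2fc lists).
#' @export
category_fc_summary <- function(t, ann) {
  idx <- match(t$gene_symbol, ann$gene_symbol)
  cat_ <- ann$matrisome_category[idx]
  keep <- !is.na(cat_) & cat_ != "none"
  vals <- split(t$log2fc[keep], cat_[keep])
  summary <- data.frame(
    category = names(vals),
    n = lengths(vals),
    mean_log2fc = vapply(vals, mean, 0),
    median_log2fc = vapply(vals, stats::median, 0),
    stringsAsFactors = FALSE, row.names = NULL)
  testable <- names(vals)[lengths(vals) >= 2L]
  tests <- NULL
  if (length(testable) >= 2L) {
    cmb <- utils::combn(testable, 2L)
    tests <- data.frame(
      category_a = cmb[1L, ], category_b = cmb[2L, ],
      p = apply(cmb, 2L, function(ab) {
        a <- vals[[ab[1L]]]; b <- vals[[ab[2L]]]
        if (stats::sd(c(a, b)) == 0) return(1)
        stats::t.test(a, b)$p.value
      }),
      stringsAsFactors = FALSE)
  }
  list(summary = summary, tests = tests, values = vals)
}

#' Hypergeometric overrepresentation analysis
#'
#' Tests each pathway for over- and under-representation of a candidate
#' gene set against a background universe, with Storey q-values computed
#' over pathways (separately for each direction) and log2 fold enrichment
#' `log2((k / n_cand) / (K / n_bg))` where `k` and `K` are the candidate
#' and background overlaps. A pathway is called significant only when all
#' four filters pass: direction q-value below `q_max` (default 0.01),
#' background overlap >= `min_background` (default 5), candidate overlap >=
#' `min_candidates` (default 2), and `|log2 fold enrichment|` > 1.
#'
#' @param candidates Character vector, a subset of `background`.
#' @param background Character vector, the tested universe.
#' @param pathways A [signature_set()].
#' @param q_max,min_background,min_candidates,min_abs_log2fe Filter values.
#' @return Data frame: pathway, n_background_overlap, n_candidate_overlap,
#'   p_over, p_under, q_over, q_under, log2_fold_enrichment, direction,
#'   passes_filters.
#' @export
overrepresentation <- function(candidates, background, pathways,
                               q_max = 0.01, min_background = 5L,
                               min_candidates = 2L, min_abs_log2fe = 1) {
  background <- unique(background)
  candidates <- unique(candidates)
  if (!length(background)) stop("empty background")
  extra <- setdiff(candidates, background)
  if (length(extra))
    stop("candidates outside the background: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  N <- length(background)
  n <- length(candidates)
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(pathways[[nm]]$genes, background)
    K <- length(pw)
    k <- length(intersect(pw, candidates))
    # over: P(X >= k); under: P(X <= k); X ~ Hypergeom(N, K, n)
    p_over <- if (K == 0L) 1 else stats::phyper(k - 1L, K, N - K, n,
                                                lower.tail = FALSE)
    p_under <- stats::phyper(k, K, N - K, n)
    fe <- if (K == 0L) NA_real_ else log2((k / n) / (K / N))
    data.frame(pathway = nm, n_background_overlap = K,
               n_candidate_overlap = k, p_over = p_over, p_under = p_under,
               log2_fold_enrichment = fe, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_over <- as.numeric(storey_qvalues(res$p_over))
  res$q_under <- as.numeric(storey_qvalues(res$p_under))
  res$direction <- ifelse(res$p_over <= res$p_under, "over", "under")
  dir_q <- ifelse(res$direction == "over", res$q_over, res$q_under)
  fe_ok <- !is.na(res$log2_fold_enrichment) &
    (res$log2_fold_enrichment > min_abs_log2fe |
       res$log2_fold_enrichment < -min_abs_log2fe)
  res$passes_filters <- dir_q < q_max &
    res$n_background_overlap >= min_background &
    res$n_candidate_overlap >= min_candidates &
    fe_ok
  res[order(res$pathway), ]
}
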