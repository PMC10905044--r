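test_that("storey q-values honour closed-form limits and the BH relation", {
  expect_equal(as.numeric(storey_qvalues(rep(1, 20))), rep(1, 20))
  expect_error(storey_qvalues(numeric()), "empty")
  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")

  # q = pi0 * BH running-min, checked against p.adjust as independent oracle
  set.seed(1)
  p <- runif(500)^1.5
  q <- storey_qvalues(p)
  pi0 <- attr(q, "pi0")
  expect_equal(as.numeric(q), pmin(1, pi0 * p.adjust(p, "BH")),
               tolerance = 1e-12)
  expect_true(all(q >= pi0 * p.adjust(p, "BH") - 1e-12))

  # permutation invariance
  perm <- sample(length(p))
  expect_equal(as.numeric(storey_qvalues(p[perm])), as.numeric(q)[perm],
               tolerance = 1e-15)

  # monotone in p after sorting
  o <- order(p)
  expect_true(all(diff(as.numeric(q)[o]) >= -1e-15))
})

test_that("pi0 estimation is near 1 for uniform p-values", {
  set.seed(2)
  p <- runif(10000)
  q <- storey_qvalues(p)
  expect_gte(attr(q, "pi0"), 0.9)
  expect_lte(attr(q, "pi0"), 1)
  qs <- storey_qvalues(p, pi0_method = "smoother")
  expect_gte(attr(qs, "pi0"), 0.85)
})

test_that("paired testing recovers planted differences and handles degenerate proteins", {
  # identical paired values: log2fc 0, p = 1
  l2 <- matrix(rep(10:14, each = 3), nrow = 3, byrow = TRUE)
  m <- matrix_from_log2(l2, l2)
  t0 <- differential_test(m, c("case", "ctrl"))
  expect_equal(t0$log2fc, rep(0, 3))
  expect_equal(unname(attr(t0, "pvalues")), rep(1, 3))

  # paired log2 differences ~1 with tiny jitter -> log2fc ~ 1
  set.seed(3)
  ctrl <- matrix(runif(5 * 5, 10, 20), 5, 5)
  case <- ctrl + 1 + rnorm(25, 0, 1e-4)
  t1 <- differential_test(matrix_from_log2(case, ctrl), c("case", "ctrl"))
  expect_equal(t1$log2fc, rep(1, 5), tolerance = 1e-3)

  # unique-peptide filter removes single-peptide groups before testing
  m2 <- matrix_from_log2(case, ctrl, n_unique_peptides = c(1L, rep(3L, 4)))
  t2 <- differential_test(m2, c("case", "ctrl"))
  expect_false("PG001" %in% t2$feature_id)
  expect_equal(nrow(t2), 4L)

  # missing values: pairwise-complete; a protein below min_pairs is skipped
  v <- m2$values
  v[2, c("case_m01", "case_m02", "case_m03", "case_m04")] <- NA
  m3 <- abundance_matrix(v, m2$samples, m2$gene_symbols, rep(3L, 5))
  expect_message(t3 <- differential_test(m3, c("case", "ctrl")), "skipped")
  expect_equal(length(attr(t3, "skipped")), 1L)
})

test_that("replicate correlation flags planted outliers", {
  set.seed(4)
  base <- runif(300, 10, 20)
  good <- sapply(1:4, function(i) base + rnorm(300, 0, 0.3))
  bad <- runif(300, 10, 20)  # independent of the shared profile
  v <- 2^cbind(good, bad)
  colnames(v) <- sprintf("s%d", 1:5); rownames(v) <- sprintf("PG%03d", 1:300)
  m <- abundance_matrix(v, data.frame(sample_id = colnames(v), group = "g",
                                      pair = sprintf("m%d", 1:5)),
                        sprintf("G%03d", 1:300), rep(3L, 300))
  rc <- replicate_correlation(m, "g")
  expect_identical(rc$outliers, "s5")
  expect_true(all(rc$median_r[paste0("s", 1:4)] > 0.85))

  # duplicated sample correlates at exactly 1, negated log profile at -1
  v2 <- 2^cbind(a = base, b = base, c = -base)
  rownames(v2) <- sprintf("PG%03d", 1:300)
  m2 <- abundance_matrix(v2, data.frame(sample_id = c("a", "b", "c"),
                                        group = "g", pair = c("1", "2", "3")),
                         sprintf("G%03d", 1:300), rep(3L, 300))
  rc2 <- replicate_correlation(m2, "g")
  pr <- rc2$pairs
  expect_equal(pr$r[pr$sample_a == "a" & pr$sample_b == "b"], 1)
  expect_equal(pr$r[pr$sample_a == "a" & pr$sample_b == "c"], -1)
  expect_error(replicate_correlation(m2, "absent"), "group")
})

test_that("significance filtering uses strict thresholds and is idempotent", {
  t <- differential_table(c("f1", "f2", "f3"), c("G1", "G2", "G3"),
                          c(2, 0.5, -3), c(0.05, 0.01, 0.04), "A")
  f <- filter_significant(t, 0.05)
  expect_setequal(f$gene_symbol, c("G2", "G3"))   # q = 0.05 excluded
  fle <- filter_significant(t, 0.05, comparator = "le")
  expect_setequal(fle$gene_symbol, c("G1", "G2", "G3"))
  ffc <- filter_significant(t, 0.05, abs_log2fc_min = 1)
  expect_equal(ffc$gene_symbol, "G3")             # |0.5| < 1 excluded

  r <- random_table(500, seed = 6)
  once <- filter_significant(r, 0.3, abs_log2fc_min = 1)
  twice <- filter_significant(once, 0.3, abs_log2fc_min = 1)
  expect_identical(as.data.frame(once), as.data.frame(twice))
  # brute-force scan oracle
  keep <- r$significance < 0.3 & abs(r$log2fc) > 1
  expect_setequal(once$feature_id, r$feature_id[keep])
})

test_that("top-N selection is deterministic with the documented tie rules", {
  t <- differential_table(c("f1", "f2", "f3"), c("Ga", "Gb", "Gc"),
                          c(1, 2, 1), c(0.01, 0.01, 0.001), "A")
  top <- top_n_signature(t, 2)
  expect_equal(top$gene_symbol, c("Gc", "Gb"))  # lowest q first, then |fc|

  r <- random_table(1000, seed = 7)
  r$significance <- round(r$significance, 1)  # force heavy ties
  top200 <- top_n_signature(r, 200)
  o <- order(r$significance, -abs(r$log2fc), r$gene_symbol)
  expect_identical(top200$feature_id, r$feature_id[o][1:200])
  expect_warning(top_n_signature(t, 10), "exceeds")
})

test_that("venn partition obeys the direction rule and conserves the union", {
  tA <- differential_table(c("a", "b", "c", "d"), c("Ga", "Gb", "Gc", "Gd"),
                           c(1, 1, 1, 0), c(0.01, 0.01, 0.01, 0.01), "A")
  tB <- differential_table(c("a", "b", "c", "d"), c("Ga", "Gb", "Gc", "Gd"),
                           c(1, -1, 1, 1), c(0.5, 0.01, 0.01, 0.01), "B")
  vp <- venn_direction_partition(tA, tB)
  expect_equal(vp$only_A, "Ga")
  expect_equal(vp$shared_opposite_direction, c("Gb", "Gd"))  # 0 vs + discordant
  expect_equal(vp$shared_same_direction, "Gc")
  expect_length(vp$only_B, 0L)

  # fuzz: disjoint, exhaustive, and equal to a brute-force classifier
  for (seed in 1:25) {
    a <- random_table(60, seed = seed, comparison_id = "A")
    b <- random_table(60, seed = seed + 1000, comparison_id = "B")
    v <- venn_direction_partition(a, b, 0.3)
    sets <- list(v$only_A, v$only_B, v$shared_same_direction,
                 v$shared_opposite_direction)
    all_genes <- unlist(sets)
    expect_equal(anyDuplicated(all_genes), 0L)
    sa <- a$gene_symbol[a$significance < 0.3]
    sb <- b$gene_symbol[b$significance < 0.3]
    expect_setequal(all_genes, union(sa, sb))
    for (g in intersect(sa, sb)) {
      fa <- a$log2fc[a$gene_symbol == g]; fb <- b$log2fc[b$gene_symbol == g]
      expect_true(g %in% (if (sign(fa) == sign(fb))
        v$shared_same_direction else v$shared_opposite_direction))
    }
  }
})

test_that("category summaries separate planted category shifts", {
  ann <- annotation_db(data.frame(
    gene_symbol = c(sprintf("Pg%d", 1:6), sprintf("Cl%d", 1:6), "Other1"),
    matrisome_division = c(rep("core", 12), "none"),
    matrisome_category = c(rep("proteoglycans", 6), rep("collagens", 6), "none"),
    colon_matrisome = c(rep(TRUE, 12), FALSE),
    extracellular_go = TRUE))
  set.seed(8)
  t <- differential_table(
    sprintf("f%d", 1:13), ann$gene_symbol,
    c(rnorm(6, -3, 0.1), rnorm(6, 3, 0.1), 0), rep(0.01, 13), "A")
  cs <- category_fc_summary(t, ann)
  expect_lt(cs$summary$mean_log2fc[cs$summary$category == "proteoglycans"], 0)
  expect_lt(cs$tests$p[1], 0.05)

  # a single category yields a summary but no tests
  one <- category_fc_summary(t[t$gene_symbol %in% sprintf("Pg%d", 1:6), ], ann)
  expect_null(one$tests)
  expect_equal(nrow(one$summary), 1L)

  # identical distributions give p ~ 1 (checked against t.test directly)
  t2 <- differential_table(
    sprintf("f%d", 1:12), ann$gene_symbol[1:12],
    rep(c(1, 2, 3), 4), rep(0.01, 12), "A")
  cs2 <- category_fc_summary(t2, ann)
  expect_gt(cs2$tests$p[1], 0.95)
})

test_that("overrepresentation matches exhaustive enumeration and the printed filters", {
  # 10-gene universe: compare against an enumeration oracle to 1e-12
  universe <- sprintf("u%02d", 1:10)
  set.seed(9)
  for (i in 1:20) {
    cand <- sample(universe, sample(2:8, 1))
    pw_genes <- sample(universe, sample(1:9, 1))
    pw <- signature_set(list(pw = pw_genes), level = "pathway")
    res <- overrepresentation(cand, universe, pw)
    k <- length(intersect(pw_genes, cand))
    expect_equal(res$p_over,
                 enum_hyper_tail(k, length(pw_genes), 10, length(cand), TRUE),
                 tolerance = 1e-12)
    expect_equal(res$p_under,
                 enum_hyper_tail(k, length(pw_genes), 10, length(cand), FALSE),
                 tolerance = 1e-12)
  }

  # constructed example with a hand-derived expected pass set:
  # 200-gene background, 20 candidates
  bg <- sprintf("b%03d", 1:200)
  cand <- bg[1:20]
  pws <- signature_set(list(
    hit = c(bg[1:8], bg[100:106]),    # k=8, K=15: strongly enriched
    small_bg = c(bg[1:3], bg[21]),    # K=4 fails the background filter
    one_cand = c(bg[1], bg[50:69]),   # k=1 fails the candidate filter
    flat = bg[11:80]                  # enrichment too weak
  ), level = "pathway")
  res <- overrepresentation(cand, bg, pws)
  expect_identical(res$pathway[res$passes_filters], "hit")
  expect_equal(res$log2_fold_enrichment[res$pathway == "hit"],
               log2((8 / 20) / (15 / 200)), tolerance = 1e-12)

  # candidates = background: fold enrichment exactly 0
  res2 <- overrepresentation(bg, bg, pws)
  expect_true(all(abs(res2$log2_fold_enrichment) < 1e-12))

  # disjoint pathway: zero overlap, reported depleted
  pw0 <- signature_set(list(p0 = bg[150:160]), level = "pathway")
  res3 <- overrepresentation(bg[1:10], bg, pw0)
  expect_equal(res3$n_candidate_overlap, 0L)
  expect_identical(res3$direction, "under")
  expect_error(overrepresentation(c(bg[1], "zzz"), bg, pws), "outside")
})
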