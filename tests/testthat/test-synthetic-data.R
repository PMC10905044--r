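test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- tiny_cfg(seed = 21)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$abundances$matrix$values, b$abundances$matrix$values)
  expect_identical(as.data.frame(a$tables$prot_A),
                   as.data.frame(b$tables$prot_A))
  expect_identical(signature_genes(a$kb$combined),
                   signature_genes(b$kb$combined))
  expect_identical(a$kb$interactions$pairs, b$kb$interactions$pairs)
  # and the seed actually matters
  c <- simulate_study(tiny_cfg(seed = 22))
  expect_false(identical(a$abundances$matrix$values,
                         c$abundances$matrix$values))
})

test_that("a null configuration plants no differential features", {
  cfg <- tiny_cfg(seed = 3, frac_de = 0, n_planted_triples = 0,
                  celltype_shift = FALSE, slrp_flip = FALSE)
  tb <- simulate_differential_tables(cfg)
  expect_equal(sum(tb$truth$prot$de_A | tb$truth$prot$de_B), 0L)
  ab <- simulate_abundances(cfg)
  expect_equal(sum(ab$truth$de_A | ab$truth$de_B), 0L)
})

test_that("planted abundance shifts are recovered within sampling error", {
  # fixed magnitude 2, tiny noise, 10 pairs: observed paired-mean difference
  # must fall within 3 standard errors of the planted shift
  cfg <- tiny_cfg(seed = 8, n_proteins = 200, n_samples_per_group = 10L,
                  effect_size_mean = 2, effect_size_sd = 0,
                  noise_sd = 0.1, frac_de = 0.5)
  ab <- simulate_abundances(cfg)
  m <- ab$matrix
  de <- ab$truth[ab$truth$de_A, ]
  case <- m$samples$sample_id[m$samples$group == "hom_A"]
  ctrl <- m$samples$sample_id[m$samples$group == "het"]
  ctrl <- ctrl[match(sub("hom_A_", "", case), sub("het_", "", ctrl))]
  d <- log2(m$values[de$protein_id, case]) - log2(m$values[de$protein_id, ctrl])
  obs <- rowMeans(d)
  se <- apply(d, 1, sd) / sqrt(ncol(d))
  z <- abs(obs - de$lfc_A) / se
  # per-protein bound wide enough for ~100 simultaneous checks, plus the
  # usual 3-SE coverage for the bulk
  expect_true(all(z <= 5))
  expect_gte(mean(z <= 3), 0.95)
})

test_that("knowledge bases realize every planted triple", {
  cfg <- tiny_cfg(seed = 13)
  kb <- simulate_knowledge_bases(cfg)
  tr <- kb$truth
  pair_key <- paste(kb$interactions$pairs$ligand, kb$interactions$pairs$receptor)
  matri <- matrisomal_genes(kb$annotation)
  for (i in seq_len(nrow(tr))) {
    expect_true(paste(tr$ligand[i], tr$receptor[i]) %in% pair_key)
    expect_true(tr$ligand[i] %in% matri)
    expect_equal(unname(kb$interactions$protein_type[tr$ligand[i]]), "ligand")
    expect_true(tr$receptor[i] %in% kb$combined[[tr$cell_type[i]]]$genes)
  }
})

test_that("closure leaves no orphan receptors and frac_matrisomal=1 annotates everything", {
  cfg <- tiny_cfg(seed = 17, closure = TRUE)
  kb <- simulate_knowledge_bases(cfg)
  receptors <- names(kb$interactions$protein_type)[
    kb$interactions$protein_type == "receptor"]
  in_sig <- unique(unlist(signature_genes(kb$extended)))
  expect_length(setdiff(receptors, in_sig), 0L)

  kb1 <- simulate_knowledge_bases(tiny_cfg(seed = 17, n_proteins = 80,
                                           frac_matrisomal = 1,
                                           n_planted_triples = 0))
  expect_true(all(kb1$annotation$matrisome_division != "none"))
})

test_that("SLRP direction flip plants opposing signs in the two comparisons", {
  tb <- simulate_differential_tables(tiny_cfg(seed = 5, slrp_flip = TRUE))
  slrps <- c("Dcn", "Bgn", "Aspn", "Ogn", "Prelp", "Fmod")
  a <- tb$prot_A[tb$prot_A$gene_symbol %in% slrps, ]
  b <- tb$prot_B[tb$prot_B$gene_symbol %in% slrps, ]
  b <- b[match(a$gene_symbol, b$gene_symbol), ]
  expect_true(all(a$significance < 0.05 & b$significance < 0.05))
  expect_true(all(sign(a$log2fc) == -sign(b$log2fc)))
})

test_that("planted concordant fraction matches the truth within binomial bounds", {
  cfg <- tiny_cfg(seed = 29, n_proteins = 1000, frac_de = 0.5,
                  frac_shared = 0.6, frac_concordant = 0.6,
                  celltype_shift = FALSE)
  tb <- simulate_differential_tables(cfg)
  pt <- tb$truth$prot
  shared <- pt$de_A & pt$de_B
  n <- sum(shared)
  obs <- tb$truth$concordant_fraction
  ci <- qbinom(c(0.005, 0.995), n, 0.6) / n
  expect_gte(obs, ci[1])
  expect_lte(obs, ci[2])
})

test_that("random configurations always yield invariant-satisfying knowledge bases", {
  # constructors validate on build, so survival of the loop is the assertion
  set.seed(99)
  for (i in 1:100) {
    cfg <- sim_config(seed = i, n_proteins = sample(80:150, 1),
                      n_cell_types = sample(2:6, 1),
                      n_pathways = sample(2:8, 1),
                      n_planted_triples = sample(0:6, 1),
                      frac_matrisomal = runif(1, 0.05, 0.5),
                      frac_de = runif(1),
                      slrp_flip = sample(c(TRUE, FALSE), 1),
                      celltype_shift = sample(c(TRUE, FALSE), 1))
    kb <- simulate_knowledge_bases(cfg)
    expect_s3_class(kb$annotation, "annotation_db")
    expect_true(all(lengths(signature_genes(kb$combined)) >= 1))
  }
})
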