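test_that("symbol normalization follows the species convention and is idempotent", {
  expect_equal(normalize_symbols(c(" DCN ", "prelp", "Col6a5")),
               c("Dcn", "Prelp", "Col6a5"))
  expect_equal(normalize_symbols("dcn", species = "human"), "DCN")
  x <- c("DCN", " aspn", "Gm0001", "")
  expect_identical(normalize_symbols(normalize_symbols(x)),
                   normalize_symbols(x))
})

test_that("abundance matrices round-trip through TSV and reject bad input", {
  cfg <- tiny_cfg(seed = 11, n_proteins = 60)
  m <- simulate_abundances(cfg)$matrix
  d <- withr::local_tempdir()
  write_abundance_matrix(m, file.path(d, "m.tsv"), file.path(d, "s.tsv"))
  m2 <- read_abundance_matrix(file.path(d, "m.tsv"), file.path(d, "s.tsv"))
  expect_equal(m2$values, m$values, tolerance = 1e-12)
  expect_identical(m2$gene_symbols, m$gene_symbols)
  expect_identical(m2$n_unique_peptides, m$n_unique_peptides)
  expect_identical(m2$samples$group, m$samples$group)

  # duplicate protein id names the offender
  df <- utils::read.delim(file.path(d, "m.tsv"), check.names = FALSE)
  df$protein_id[2] <- df$protein_id[1]
  utils::write.table(df, file.path(d, "dup.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_abundance_matrix(file.path(d, "dup.tsv"),
                                     file.path(d, "s.tsv")),
               df$protein_id[1], fixed = TRUE)

  # negative abundance is a validation error with a line number
  df <- utils::read.delim(file.path(d, "m.tsv"), check.names = FALSE)
  df[3, 5] <- -1
  utils::write.table(df, file.path(d, "neg.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_abundance_matrix(file.path(d, "neg.tsv"),
                                     file.path(d, "s.tsv")), "negative")

  # missing schema column
  df$protein_id <- NULL
  utils::write.table(df, file.path(d, "noid.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_abundance_matrix(file.path(d, "noid.tsv"),
                                     file.path(d, "s.tsv")), "schema")
})

test_that("multi-symbol protein groups split into one record per symbol", {
  t <- differential_table("PG1", "Col6a5;Col6a6", -1.2, 0.01, "A")
  expect_equal(nrow(t), 2L)
  expect_setequal(t$gene_symbol, c("Col6a5", "Col6a6"))
  expect_equal(t$log2fc, c(-1.2, -1.2))
  expect_equal(t$significance, c(0.01, 0.01))

  t1 <- differential_table("PG2", "Dcn", -1.8, 0.003, "A")
  expect_equal(t1$gene_symbol, "Dcn")
  expect_equal(nrow(t1), 1L)
})

test_that("differential tables round-trip, validate, and warn when empty", {
  t <- random_table(40, seed = 5)
  d <- withr::local_tempdir()
  write_differential_table(t, file.path(d, "t.tsv"))
  t2 <- read_differential_table(file.path(d, "t.tsv"), "A")
  expect_equal(as.data.frame(t2), as.data.frame(t), tolerance = 1e-12)

  expect_error(differential_table("f", "G", 1, 1.2, "A"), "significance")
  expect_error(differential_table("f", "G", Inf, 0.5, "A"), "log2fc")
  expect_error(differential_table(c("f", "f"), c("G", "G"), c(1, 2),
                                  c(0.1, 0.2), "A"), "duplicated")

  writeLines("feature_id\tgene_symbol\tlog2fc\tsignificance",
             file.path(d, "empty.tsv"))
  expect_warning(te <- read_differential_table(file.path(d, "empty.tsv"), "A"),
                 "empty")
  expect_equal(nrow(te), 0L)
})

test_that("GMT gene sets round-trip and collapse duplicate genes", {
  d <- withr::local_tempdir()
  writeLines(c("setA\tsrc1\tDcn\tBgn\tDcn", "setB\tsrc2\tAspn"),
             file.path(d, "two.gmt"))
  sig <- read_gene_sets(file.path(d, "two.gmt"))
  expect_length(sig, 2L)
  expect_equal(sig[["setA"]]$genes, c("Dcn", "Bgn"))  # duplicate counted once
  expect_equal(sig[["setB"]]$source, "src2")

  writeLines("\tsrc\tDcn", file.path(d, "blank.gmt"))
  expect_error(read_gene_sets(file.path(d, "blank.gmt")), "malformed")

  # randomized round trip
  set.seed(42)
  sets <- setNames(lapply(1:6, function(i)
    sample(sprintf("g%03d", 1:50), sample(3:12, 1))), paste0("set", 1:6))
  sig <- signature_set(sets, sources = paste0("src", 1:6), level = "pathway")
  write_gene_sets(sig, file.path(d, "rt.gmt"))
  sig2 <- read_gene_sets(file.path(d, "rt.gmt"))
  expect_identical(signature_genes(sig2), signature_genes(sig))
  expect_identical(vapply(sig2, `[[`, "", "source"),
                   vapply(sig, `[[`, "", "source"))
})

test_that("annotation and interaction tables enforce their invariants", {
  ann_df <- data.frame(
    gene_symbol = c("Dcn", "Gm0001", "Gm0002"),
    matrisome_division = c("core", "none", "associated"),
    matrisome_category = c("proteoglycans", "none", "ECM regulators"),
    colon_matrisome = c(TRUE, FALSE, FALSE),
    extracellular_go = c(TRUE, FALSE, TRUE))
  ann <- annotation_db(ann_df)
  expect_setequal(matrisomal_genes(ann), c("Dcn", "Gm0002"))
  expect_equal(matrisomal_genes(ann, colon_only = TRUE), "Dcn")

  bad <- ann_df; bad$matrisome_category[2] <- "collagens"
  expect_error(annotation_db(bad), "iff")
  bad <- ann_df; bad$colon_matrisome[2] <- TRUE
  expect_error(annotation_db(bad), "colon")

  d <- withr::local_tempdir()
  write_annotation_db(ann, file.path(d, "ann.tsv"))
  expect_equal(as.data.frame(read_annotation_db(file.path(d, "ann.tsv"))),
               as.data.frame(ann))

  pairs <- data.frame(ligand = c("L1", "L1"), receptor = c("R1", "R2"))
  pt <- c(L1 = "ligand", R1 = "receptor", R2 = "receptor", X = "other")
  db <- interaction_db(pairs, pt)
  write_interaction_db(db, file.path(d, "p.tsv"), file.path(d, "ty.tsv"))
  db2 <- read_interaction_db(file.path(d, "p.tsv"), file.path(d, "ty.tsv"))
  expect_equal(db2$pairs, db$pairs)
  expect_equal(db2$protein_type, db$protein_type)

  expect_error(interaction_db(rbind(pairs, pairs[1, ]), pt), "duplicate")
  expect_error(interaction_db(data.frame(ligand = "R1", receptor = "L1"), pt),
               "not typed")
})
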