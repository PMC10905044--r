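edges_df <- function(lig, rec, rfc = NULL) {
  e <- data.frame(ligand = lig, receptor = rec,
                  ligand_log2fc = rep(1, length(lig)),
                  ligand_q = rep(0.01, length(lig)),
                  receptor_log2fc = rfc %||% rep(1, length(lig)),
                  receptor_padj = rep(0.01, length(lig)),
                  stringsAsFactors = FALSE)
  class(e) <- c("lr_edges", "data.frame")
  e
}

test_that("network assembly links receptors to every containing signature", {
  sig <- signature_set(list(ct1 = c("R1", "x"), ct2 = c("R1", "R2")),
                       level = "combined")
  net <- build_network(edges_df(c("L1", "L1"), c("R1", "R2")), sig)
  # receptor in two signatures yields two receptor->cell-type edges
  expect_equal(sum(net$rc_edges$receptor == "R1"), 2L)
  expect_equal(nrow(net$rc_edges), 3L)
  expect_length(net$orphans, 0L)

  # orphan receptors are retained and reported
  net2 <- build_network(edges_df("L1", "R9"), sig)
  expect_equal(net2$orphans, "R9")
  expect_equal(nrow(net2$lr_edges), 1L)

  # empty edge list: empty network and summaries
  net0 <- build_network(edges_df(character(), character()), sig)
  expect_equal(nrow(net0$lr_edges), 0L)
  expect_length(net0$cell_types, 0L)
  expect_equal(length(net0$ligands_per_celltype), 0L)
})

test_that("heat matrices count receptors and normalize rows to one", {
  sig <- signature_set(list(ct1 = c("R1", "R2"), ct2 = c("R3")),
                       level = "combined")
  # L1 acts on ct1 only; L2 splits evenly between ct1 and ct2
  e <- edges_df(c("L1", "L2", "L2"), c("R1", "R2", "R3"), rfc = c(2, 1, 3))
  net <- build_network(e, sig)
  h <- heat_matrices(net)
  expect_equal(h$row_normalized["L1", ], c(ct1 = 1, ct2 = 0))
  expect_equal(h$row_normalized["L2", ], c(ct1 = 0.5, ct2 = 0.5))
  expect_equal(h$raw["L2", "ct2"], 1L)
  expect_equal(h$mean_log2fc["L2", "ct1"], 1)
  expect_equal(attr(h, "celltype_mean_log2fc"),
               c(ct1 = mean(c(2, 1)), ct2 = 3))

  # randomized: raw equals brute-force counting; rows sum to 1;
  # cell types per ligand equals nonzero raw entries
  set.seed(81)
  for (i in 1:10) {
    lig <- sprintf("L%d", 1:6)
    rec <- sprintf("R%d", 1:10)
    e <- unique(data.frame(ligand = sample(lig, 25, TRUE),
                           receptor = sample(rec, 25, TRUE)))
    er <- edges_df(e$ligand, e$receptor)
    rsig <- signature_set(lapply(setNames(1:4, paste0("ct", 1:4)),
                                 function(j) sample(rec, 4)),
                          level = "combined")
    net <- build_network(er, rsig)
    h <- heat_matrices(net)
    for (l in rownames(h$raw)) for (ct in colnames(h$raw)) {
      cnt <- 0L
      for (r in unique(er$receptor[er$ligand == l]))
        if (r %in% rsig[[ct]]$genes) cnt <- cnt + 1L
      expect_equal(unname(h$raw[l, ct]), cnt)
    }
    if (nrow(h$row_normalized))
      expect_true(all(abs(rowSums(h$row_normalized) - 1) < 1e-9))
    cpl <- net$celltypes_per_ligand
    for (l in names(cpl))
      expect_equal(unname(cpl[l]), sum(h$raw[l, ] > 0))
  }
})

test_that("ligand clustering matches a hand-stepped average-linkage oracle", {
  # identical rows merge at distance zero
  m <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1))
  cl <- cluster_ligands(m)
  expect_equal(min(cl$heights), 0)
  # orthogonal one-hot rows merge last
  expect_equal(max(cl$heights),
               mean(c(dist(m)[1:2][c(2)], dist(m)[3])))  # avg of a-c, b-c

  # single row: trivial result
  cl1 <- cluster_ligands(m[1, , drop = FALSE])
  expect_null(cl1$hclust)
  expect_equal(cl1$order, "a")

  # naive agglomerative average-linkage oracle, stepped by hand
  naive_avg_linkage <- function(x) {
    groups <- lapply(seq_len(nrow(x)), identity)
    d <- as.matrix(dist(x))
    heights <- numeric()
    while (length(groups) > 1L) {
      best <- c(NA, NA); bd <- Inf
      for (i in seq_along(groups)) for (j in seq_along(groups)) if (i < j) {
        dd <- mean(d[groups[[i]], groups[[j]]])
        if (dd < bd) { bd <- dd; best <- c(i, j) }
      }
      heights <- c(heights, bd)
      groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
      groups[[best[2]]] <- NULL
    }
    heights
  }
  set.seed(91)
  for (i in 1:5) {
    x <- matrix(runif(5 * 4), 5, 4, dimnames = list(letters[1:5], NULL))
    cl <- cluster_ligands(x)
    expect_equal(sort(cl$hclust$height), sort(naive_avg_linkage(x)),
                 tolerance = 1e-12)
  }
})

test_that("exports are deterministic with stable headers", {
  sig <- signature_set(list(ct1 = "R1"), level = "combined")
  net <- build_network(edges_df("L1", "R1"), sig)
  d <- withr::local_tempdir()
  export_circos(net, file.path(d, "l1.tsv"), file.path(d, "t1.tsv"))
  export_circos(net, file.path(d, "l2.tsv"), file.path(d, "t2.tsv"))
  expect_identical(readLines(file.path(d, "l1.tsv")),
                   readLines(file.path(d, "l2.tsv")))
  l <- read.delim(file.path(d, "l1.tsv"))
  expect_equal(nrow(l), 2L)  # one LR link plus one receptor->cell-type link

  # empty network: header-only link file
  net0 <- build_network(edges_df(character(), character()), sig)
  export_circos(net0, file.path(d, "l0.tsv"), file.path(d, "t0.tsv"))
  expect_equal(readLines(file.path(d, "l0.tsv")), "source\ttarget\tweight")

  paths <- export_network(net, file.path(d, "n.tsv"), file.path(d, "e.tsv"),
                          file.path(d, "g.graphml"))
  nodes <- read.delim(file.path(d, "n.tsv"))
  expect_setequal(nodes$kind, c("ligand", "receptor", "cell_type"))
  gm <- readLines(file.path(d, "g.graphml"))
  expect_true(any(grepl("graphml", gm)))
  expect_equal(sum(grepl("<edge ", gm)), 2L)

  hp <- write_heat_matrices(heat_matrices(net), d)
  expect_true(all(file.exists(hp)))
})

test_that("end-to-end heat support equals the planted orchestration map", {
  st <- simulate_study(tiny_cfg(seed = 95))
  edges <- ligand_receptor_map(st$tables$prot_A, st$tables$rna_A,
                               st$kb$annotation, st$kb$interactions)
  net <- build_network(edges, st$kb$combined)
  h <- heat_matrices(net, st$tables$rna_A)
  got <- which(h$raw > 0, arr.ind = TRUE)
  got_pairs <- paste(rownames(h$raw)[got[, 1]], colnames(h$raw)[got[, 2]])
  planted <- unique(paste(st$kb$truth$ligand, st$kb$truth$cell_type))
  expect_setequal(got_pairs, planted)
})
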