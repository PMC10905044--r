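#!/usr/bin/env Rscript
# Stage 4: SLRP interactor profiling and the pathway enrichment score
# ES = ES_interactors * (N_de_interactors / N_interactors), where
# ES_interactors = mean(log2fc) * mean(q) over differential in-pathway
# interactors. Outputs under results/slrp/.

suppressMessages(library(matrinet))
stopifnot(file.exists("results/differential/prot_A.tsv"))
out <- "results/slrp"; dir.create(out, showWarnings = FALSE)

db <- read_interaction_db("results/fixture/pairs.tsv",
                          "results/fixture/types.tsv")
pathways <- read_gene_sets("results/fixture/pathways.gmt", level = "pathway")
slrps <- c("Dcn", "Bgn", "Aspn", "Ogn", "Prelp", "Fmod")

for (comp in c("A", "B")) {
  t <- read_differential_table(
    sprintf("results/differential/prot_%s.tsv", comp), comp)
  prof <- interactors_of(slrps, db, t, q_max = 0.05)
  counts <- interactor_counts(prof)
  cat(sprintf("Comparison %s SLRP interactors (total / differential):\n", comp))
  print(counts, row.names = FALSE)
  sc <- slrp_pathway_scores(slrps, prof, t, pathways)
  cat(sprintf("  %d pathways scored; strongest |ES| = %.4g (%s)\n",
              nrow(sc), max(abs(sc$es)), sc$pathway[which.max(abs(sc$es))]))
  links <- slrp_pathway_links(sc, prof, pathways, top_n = 5)
  write.table(counts, file.path(out, sprintf("interactor_counts_%s.tsv", comp)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_pathway_scores(sc, file.path(out, sprintf("pathway_scores_%s.tsv", comp)))
  write.table(links, file.path(out, sprintf("circos_links_%s.tsv", comp)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("written:", out, "\n")
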