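#!/usr/bin/env Rscript
# Stage 3: cell-type deconvolution. Maps significant proteins onto the
# combined cell-type signatures and reads enrichment from the sign of the
# median log2 fold change. Outputs under results/celltypes/.

suppressMessages(library(matrinet))
stopifnot(file.exists("results/differential/prot_A.tsv"))
out <- "results/celltypes"; dir.create(out, showWarnings = FALSE)

combined <- read_gene_sets("results/fixture/combined.gmt", level = "combined")
for (comp in c("A", "B")) {
  t <- read_differential_table(
    sprintf("results/differential/prot_%s.tsv", comp), comp)
  ce <- score_celltypes(filter_significant(t, 0.05), combined,
                        min_mapped = 3)
  cat(sprintf("Comparison %s: %d cell types scored (%d positive, %d negative)\n",
              comp, nrow(ce), sum(ce$direction == "positive"),
              sum(ce$direction == "negative")))
  write_celltype_enrichment(ce, file.path(out,
                                          sprintf("enrichment_%s.tsv", comp)))
}
cat("written:", out, "\n")
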