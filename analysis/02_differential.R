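#!/usr/bin/env Rscript
# Stage 2: replicate QC, paired differential testing with Storey q-values,
# significance filtering, the direction-aware Venn partition of the two
# comparisons, the top-200 significance signature, and the per-matrisome-
# category fold-change summary. Outputs under results/differential/.

suppressMessages(library(matrinet))
stopifnot(file.exists("results/fixture/config.yaml"))
out <- "results/differential"; dir.create(out, showWarnings = FALSE)

m <- read_abundance_matrix("results/fixture/abundance.tsv",
                           "results/fixture/samples.tsv")
ann <- read_annotation_db("results/fixture/annotation.tsv")

for (g in unique(m$samples$group)) {
  rc <- replicate_correlation(m, g)
  cat(sprintf("QC %-6s median within-group r: %.3f%s\n", g,
              median(rc$pairs$r),
              if (length(rc$outliers))
                paste0("  outliers: ", paste(rc$outliers, collapse = ", "))
              else ""))
}

prot_A <- differential_test(m, c("hom_A", "het")); prot_A$comparison_id <- "A"
prot_B <- differential_test(m, c("hom_B", "het")); prot_B$comparison_id <- "B"
sig_A <- filter_significant(prot_A, 0.05)
sig_B <- filter_significant(prot_B, 0.05)
cat(sprintf("Differential: %d/%d significant (q<0.05) in A, %d/%d in B\n",
            nrow(sig_A), nrow(prot_A), nrow(sig_B), nrow(prot_B)))

vp <- venn_direction_partition(prot_A, prot_B, 0.05)
print(vp)
top <- top_n_signature(prot_A, min(200L, nrow(prot_A)))
cs <- category_fc_summary(sig_A, ann)
cat("Matrisome category log2fc means:\n")
print(cs$summary, row.names = FALSE)

write_differential_table(prot_A, file.path(out, "prot_A.tsv"))
write_differential_table(prot_B, file.path(out, "prot_B.tsv"))
write_differential_table(top, file.path(out, "top200_signature_A.tsv"))
write_venn_partition(vp, file.path(out, "venn_partition.tsv"))
write.table(cs$summary, file.path(out, "category_summary_A.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("written:", out, "\n")
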