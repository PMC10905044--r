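#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study (all pipeline inputs with planted
# ground truth) under results/fixture/.
#
# The study emulates a two-contrast decellularized-colon proteomics design:
# comparison A ("proximal", overtly inflamed) and comparison B ("middle",
# prepathologic) against a shared paired control group, plus a matrisome
# annotation, a typed ligand-receptor set, cell-type signatures from three
# pseudo-source datasets, and hallmark-style pathway gene sets.

suppressMessages(library(matrinet))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args)) args[[1]] else 1L)

dir.create("results", showWarnings = FALSE)
cp <- make_fixtures("results/fixture", seed = seed, size = "medium")
st <- attr(cp, "study")

cat("Synthetic study written to results/fixture (seed", seed, ")\n")
cat(sprintf("  %d protein groups x %d samples (%d per group)\n",
            nrow(st$abundances$matrix$values),
            ncol(st$abundances$matrix$values),
            length(unique(st$abundances$matrix$samples$pair))))
cat(sprintf("  matrisomal genes: %d | SLRPs: %s\n",
            length(matrisomal_genes(st$kb$annotation)),
            paste(st$kb$slrps, collapse = ", ")))
cat(sprintf("  interaction set: %d pairs | planted network triples: %d (%d active in B)\n",
            nrow(st$kb$interactions$pairs), nrow(st$kb$truth),
            sum(st$kb$truth$in_B)))
cat(sprintf("  planted DE (protein truth): %d in A, %d in B; concordant fraction %.2f\n",
            sum(st$tables$truth$prot$de_A), sum(st$tables$truth$prot$de_B),
            st$tables$truth$concordant_fraction))
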