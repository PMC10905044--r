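---
title: "Methods: matrisome-centred downstream analysis of ECM proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matrisome-centred downstream analysis of ECM proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matrinet)
```

## The problem

Chronic colitis remodels the colonic extracellular matrix long before the
tissue looks abnormal under the microscope. Given (i) a summed-intensity
protein abundance matrix from decellularized colon in a paired
case/control design with two anatomical contrasts — an overtly inflamed
region (comparison A) and a histologically normal, prepathologic region
(comparison B) — and (ii) a transcriptomic differential table from the
same model, the package infers which matrisomal ligands change, which
receptors and cell types they plausibly act on, and how the two disease
states differ. Small leucine-rich proteoglycans (SLRPs: decorin,
biglycan, asporin, osteoglycin, Prelp, fibromodulin) get dedicated
treatment because their direction of change separates the two states.

## Statistical model

**Paired differential abundance.** Abundances are modelled log-normal:
testing happens on log2 values, where a paired design with a per-mouse
random effect makes the paired *t*-test the natural model. For protein
$i$ with paired log2 differences $d_{i1},\dots,d_{ik}$,
$\widehat{\mathrm{lfc}}_i = \bar d_i$ and $p_i$ comes from the two-sided
paired $t$-test. Proteins quantified by fewer than 2 unique peptides are
excluded before testing; pairs with a missing member are dropped per
protein (pairwise-complete), never imputed, and proteins left with fewer
than 2 complete pairs are skipped and logged.

**Storey q-values.** With $m$ p-values, the null proportion is estimated
as $\hat\pi_0 = \#\{p > \lambda\} / (m(1-\lambda))$ at a single fixed
$\lambda = 0.5$ (a natural-spline smoother over a $\lambda$ grid is
available via `pi0_method = "smoother"`); the method citation does not
pin the variant, and the fixed-$\lambda$ form has an exact closed-form
relation to Benjamini–Hochberg ($q = \hat\pi_0 \times$ BH running
minimum) that the tests exploit as an independent oracle. $\hat\pi_0$ is
truncated to $(1/m, 1]$ so q-values are always defined.

**Thresholds.** Significance thresholds are strict by default
(`significance < q_max`), matching the convention used for downstream
result filtering; the inclusive comparator used by some acquisition
pipelines for initial significance calls is available per stage via
`comparator = "le"`. Defaults: protein q < 0.05, transcript adjusted
p < 0.05, volcano-style fold-change filter |log2fc| > 1 when requested,
top-200 significance signature, ORA filters q < 0.01 / background ≥ 5 /
candidates ≥ 2 / |log2 FE| > 1.

**Degenerate inputs.** A zero-variance, zero-difference paired vector is
a valid observation carrying no evidence: p = 1. A constant nonzero
difference leaves the *t*-statistic undefined: p = NA, reported as
missing. In the top-N signature, ties on significance break by larger
|log2fc|, then lexicographic symbol, so output is deterministic. In the
direction partition, a log2fc of exactly zero is its own sign and is
therefore discordant with both positive and negative changes.

## Overrepresentation

Pathway enrichment of a candidate set against a background universe uses
the hypergeometric distribution in both directions
($P(X \ge k)$ and $P(X \le k)$), with Storey q-values computed over
pathways separately per direction and
$\mathrm{log2FE} = \log_2\frac{k/n_{\text{cand}}}{K/n_{\text{bg}}}$.
A pathway is called only when all four filters pass. The q-value enters
on the direction with the smaller p; the underlying reference
implementation does not state this detail, so it is a package decision.

## Cell-type deconvolution

Signatures from three source datasets are united per cell-type name
(extended level) and further merged into broader groups (combined level),
with per-source provenance counts retained. Scoring is deliberately
descriptive, mirroring violin-plot reading of protein shifts: a cell type
is enriched when the median log2 fold change of its mapped significant
features is positive, depleted when negative. A Wilcoxon signed-rank
p-value against zero is emitted for reference but takes no part in the
call. Genes mapping to several signatures contribute to each without
down-weighting (simplest rule; documented, switchable nowhere on
purpose), and signatures mapping fewer than `min_mapped = 3` features are
not scored — a single-gene "enrichment" is noise.

## SLRP pathway enrichment score

For each pathway $P$, with $I$ the union of SLRP interactors falling in
$P$ and $D \subseteq I$ those differential in the relevant comparison:

$$\mathrm{ES} = \underbrace{\overline{\mathrm{lfc}}_{D} \times \bar q_{D}}_{\mathrm{ES}_{\text{interactors}}} \times \frac{|D|}{|I|}$$

The defining formula says the averages run over "all interactors found in
the pathway", but q-values exist only for tested features of the given
comparison, so averaging over the non-differential subset is not
well-defined in general; the default averaging set is therefore $D$
(`mode = "de_only"`), with `mode = "all_with_values"` averaging over
every in-pathway interactor present in the table. Both modes ship because
the printed formula is genuinely ambiguous on this point. Interactor sets
are sets — a gene shared by two SLRPs' interactor lists counts once — and
multiplying by the *average q-value* shrinks strongly significant sets
toward zero; that is a property of the score as defined and is
implemented exactly, not "improved". Pathways with $I = \emptyset$ are
omitted; $D = \emptyset$ yields ES = 0 with an explicit flag.

## Network construction

Ligand–receptor edges require: ligand annotated matrisomal, typed as a
ligand, significant in the protein comparison; receptor typed as a
receptor and significant in the transcript comparison (the receptor
filter is transcriptomic only — a receptor differential solely at the
protein level does not qualify); and the pair present in the interaction
set. No fold-change threshold is applied to ligands beyond the q-value —
the source convention does not state one. Receptors then link to every
combined cell-type signature containing them; receptors in no signature
are kept and reported as orphans rather than silently dropped, for
auditability. Interactor *profiling* (`interactors_of`), by contrast, is
direction-agnostic: the SLRP interactor counts are not
direction-annotated, so a query on the receptor side still reports its
partners.

Heat matrices over (ligand, cell type): raw distinct-receptor counts;
row-normalized counts (each row divided by its sum, so a ligand acting
through a single cell type scores 1 there — unique interactions carry
more weight; all-zero rows are dropped); and mean transcript log2fc of
the linking receptors. The per-cell-type mean defaults to averaging over
unique receptors rather than (ligand, receptor) incidences — the
alternative is available via `celltype_average = "incidence"` — because
a promiscuous receptor should not dominate a cell type's average merely
by partnering many ligands. Ligands are clustered by average-linkage
agglomeration on Euclidean distances of the row-normalized rows; no
linkage is canonical for this display, so the most common default is
fixed for determinism and cross-checked in the tests against a naive
step-by-step implementation.

## The synthetic-data generator

`sim_config()` defines the study; all three generators
(`simulate_abundances`, `simulate_knowledge_bases`,
`simulate_differential_tables`) derive shared structure from one
deterministic role assignment under the seed, so they are mutually
consistent however combined. Defaults mirror the scale of a
decellularized-colon DIA study: ~2000 protein groups, 5 paired samples
per group, ~8% matrisomal genes, log2 effect magnitudes |N(2, 0.5)|,
within-group log2 dispersion 0.5 plus a per-(pair, protein) random
effect of SD 0.5 that the paired design removes.

Design choices worth stating:

- **One shared control group.** Both case groups pair against a single
  control group by mouse index. A fully location-matched design would use
  separate controls per region; sharing one control keeps the generator a
  three-group design whose two contrasts still exercise every downstream
  path, at the cost of correlated comparisons — acceptable for planted-
  truth validation, and stated here so nobody mistakes it for the real
  study design.
- **Decoy construction.** Every interaction pair outside the planted
  network has at least one non-differential endpoint (decoy ligands are
  forced null at the protein level, decoy receptors at the transcript
  level), which makes "recovered edges = planted edges" a well-defined,
  exact criterion. SLRP interactor partners are drawn from
  transcript-null receptors so SLRP edges never contaminate that truth,
  while remaining free to be protein-differential for the interactor
  counting display.
- **Planted structure.** Opposing SLRP directions between comparisons
  (down in inflamed A, up in prepathologic B) under `slrp_flip`; coherent
  per-cell-type marker shifts in comparison A for deconvolution
  validation; pathway gene sets seeded to overlap the SLRP interactor
  union by a configurable fraction so the enrichment score has a known
  support.

What the generator does **not** emulate: intensity-dependent missingness
(missing values are MCAR only), between-protein correlation, shared
peptides between protein groups, batch effects, compositional effects of
normalization, or any spatial structure. Passing tests therefore
demonstrate algorithmic correctness on the stated model, not robustness
to those real-data pathologies.

## Problem sizes and verification

The test suite validates the formula-level operations against independent
oracles (enumeration of the hypergeometric distribution on a 10-gene
universe, literal re-evaluation of the ES formula on 100 random
instances, a hand-stepped average-linkage implementation, brute-force
partition classifiers over 1000 fuzzed table pairs) and the statistical
guarantees by simulation: 20 complete-null replicates of 2000 proteins
for false-discovery behaviour, one 2000-protein study at 5 pairs and
noise SD 0.5 for power (planted |log2fc| ≥ 2 detected with ≥80% power),
and three 600-protein studies for deconvolution sign accuracy. These
sizes make the full suite run in well under a minute per concern while
keeping binomial uncertainty far from the asserted margins.
`scripts/acceptance.R` recomputes the same quantities from scratch at any
seed.

## Limitations

Enrichment calls are descriptive medians, not calibrated tests; the ES
score has no permutation null (none is defined for it); the ORA is a
plain hypergeometric, not a reimplementation of any specific database's
statistic; and identifier handling assumes mouse-style symbols with a
simple title-case normalization — no orthology or alias resolution.
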