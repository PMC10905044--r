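Package: matrinet
Title: Matrisome-Centred Downstream Analysis of ECM Proteomics in Colitis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis pipeline for extracellular-matrix (ECM)
    proteomics of chronic colitis models: paired differential abundance
    testing with Storey q-values, matrisome annotation and category
    summaries, hypergeometric pathway overrepresentation, cell-type
    signature scoring, ligand-receptor interactor mapping, a small
    leucine-rich proteoglycan (SLRP) pathway enrichment score, and
    assembly of tripartite matrisomal-ligand to receptor to cell-type
    networks with row-normalized interaction heat matrices. Includes a
    synthetic-data generator with planted ground truth for end-to-end
    validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
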