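# Pipeline orchestration: config, fixtures, and the staged run.

PIPELINE_STAGES <- c("differential", "deconvolution", "interactions",
                     "scoring", "network")

#' Build and validate a pipeline configuration
#'
#' All thresholds default to the printed conventions of the analysis:
#' protein q-value < 0.05, transcript adjusted p < 0.05, top-200 signature,
#' ORA filters q < 0.01 / background >= 5 / candidates >= 2 /
#' |log2 FE| > 1.
#'
#' @param inputs Named list of input paths: `abundance`, `samples` (or
#'   `prot_A`, `prot_B` differential TSVs), `rna_A`, `rna_B`, `annotation`,
#'   `pairs`, `types`, `pathways`, `combined`. Relative paths are resolved
#'   against `base_dir`.
#' @param out_dir Output directory (created if absent).
#' @param slrps SLRP gene symbols to profile.
#' @param q_max,padj_max,abs_log2fc_min,top_n,min_mapped Stage thresholds.
#' @param seed Integer seed recorded in the run report.
#' @param stages Stages to run, in dependency order; subset of
#'   `differential`, `deconvolution`, `interactions`, `scoring`, `network`.
#' @param base_dir Directory against which relative input paths resolve.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs, out_dir, slrps = CANONICAL_SLRPS,
                            q_max = 0.05, padj_max = 0.05,
                            abs_log2fc_min = NULL, top_n = 200L,
                            min_mapped = 3L, seed = 1L,
                            stages = PIPELINE_STAGES, base_dir = ".") {
  inputs <- lapply(inputs, function(p)
    if (is.character(p) && !grepl("^(/|[A-Za-z]:)", p))
      file.path(base_dir, p) else p)
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (q_max <= 0 || q_max > 1 || padj_max <= 0 || padj_max > 1)
    stop("thresholds must be in (0, 1]")
  if (top_n < 1L) stop("top_n must be >= 1")
  need <- c("rna_A", "rna_B", "annotation", "pairs", "types", "pathways",
            "combined")
  if (is.null(inputs$abundance)) {
    need <- c(need, "prot_A", "prot_B")
  } else {
    need <- c(need, "abundance", "samples")
  }
  active_need <- need
  if (!"network" %in% stages && !"interactions" %in% stages)
    active_need <- setdiff(active_need, c("pairs", "types"))
  miss <- setdiff(active_need, names(inputs))
  if (length(miss))
    stop("validation error: config missing input field(s): ",
         paste(miss, collapse = ", "))
  for (f in active_need)
    if (!file.exists(inputs[[f]]))
      stop("validation error: input '", f, "' not found at ", inputs[[f]])
  structure(list(inputs = inputs, out_dir = out_dir, slrps = slrps,
                 q_max = q_max, padj_max = padj_max,
                 abs_log2fc_min = abs_log2fc_min, top_n = as.integer(top_n),
                 min_mapped = as.integer(min_mapped),
                 seed = as.integer(seed), stages = stages),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Relative input paths are resolved against the YAML file's directory.
#'
#' @param path YAML config path.
#' @param out_dir Optional override for the output directory.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (is.null(y$out_dir)) y$out_dir <- "results"
  if (!grepl("^(/|[A-Za-z]:)", y$out_dir))
    y$out_dir <- file.path(dirname(path), y$out_dir)
  y$base_dir <- dirname(path)
  do.call(pipeline_config, y)
}

#' Generate a self-contained fixture directory
#'
#' Simulates a complete study (see [sim_config()]) and writes every
#' pipeline input in its on-disk format — abundance matrix and sample
#' metadata, protein and transcript differential tables for both
#' comparisons, matrisome annotation, interaction pair and protein-type
#' tables, pathway and combined cell-type GMTs — together with the planted
#' truth tables and a `config.yaml` runnable by [run_pipeline()].
#'
#' @param dir Fixture directory (created).
#' @param seed Integer seed.
#' @param size `"small"` (fast, for tests) or `"medium"`.
#' @param ... Overrides forwarded to [sim_config()].
#' @return Path to the written `config.yaml`, invisibly; the full study
#'   object is attached as attribute `"study"`.
#' @export
make_fixtures <- function(dir, seed = 1L, size = c("small", "medium"), ...) {
  size <- match.arg(size)
  base <- if (size == "small") {
    list(seed = seed, n_proteins = 300L, n_samples_per_group = 4L,
         n_cell_types = 5L, n_pathways = 6L, n_planted_triples = 8L)
  } else {
    list(seed = seed, n_proteins = 1000L, n_samples_per_group = 5L,
         n_cell_types = 8L, n_pathways = 10L, n_planted_triples = 12L)
  }
  cfg <- do.call(sim_config, utils::modifyList(base, list(...)))
  study <- simulate_study(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f
  }
  write_abundance_matrix(study$abundances$matrix,
                         file.path(dir, "abundance.tsv"),
                         file.path(dir, "samples.tsv"))
  write_differential_table(study$tables$prot_A, file.path(dir, "prot_A.tsv"))
  write_differential_table(study$tables$prot_B, file.path(dir, "prot_B.tsv"))
  write_differential_table(study$tables$rna_A, file.path(dir, "rna_A.tsv"))
  write_differential_table(study$tables$rna_B, file.path(dir, "rna_B.tsv"))
  write_annotation_db(study$kb$annotation, file.path(dir, "annotation.tsv"))
  write_interaction_db(study$kb$interactions, file.path(dir, "pairs.tsv"),
                       file.path(dir, "types.tsv"))
  write_gene_sets(study$kb$pathways, file.path(dir, "pathways.gmt"))
  write_gene_sets(study$kb$combined, file.path(dir, "combined.gmt"))
  write_gene_sets(study$kb$extended, file.path(dir, "extended.gmt"))
  w(study$abundances$truth, "truth_abundance.tsv")
  w(study$kb$truth, "truth_network.tsv")
  w(study$tables$truth$prot, "truth_prot.tsv")
  w(study$tables$truth$rna, "truth_rna.tsv")
  conf <- list(
    inputs = list(abundance = "abundance.tsv", samples = "samples.tsv",
                  prot_A = "prot_A.tsv", prot_B = "prot_B.tsv",
                  rna_A = "rna_A.tsv", rna_B = "rna_B.tsv",
                  annotation = "annotation.tsv", pairs = "pairs.tsv",
                  types = "types.tsv", pathways = "pathways.gmt",
                  combined = "combined.gmt"),
    out_dir = "results", slrps = study$kb$slrps, seed = as.integer(seed))
  yaml::write_yaml(conf, file.path(dir, "config.yaml"))
  invisible(structure(file.path(dir, "config.yaml"), study = study))
}

write_tsv_out <- function(x, out_dir, name) {
  p <- file.path(out_dir, name)
  tmp <- paste0(p, ".partial")
  utils::write.table(as.data.frame(x), tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  file.rename(tmp, p)
  p
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order — differential testing and
#' filtering, cell-type deconvolution, interactor mapping, SLRP pathway
#' scoring, network assembly — writing every stage output as TSV under the
#' configured output directory plus a `run_report.txt` recording versions,
#' seed, and per-stage feature counts. A stage failure aborts with the
#' stage name; files written by the failing stage keep a `.partial`
#' suffix. Reruns on identical inputs and seed are byte-identical.
#'
#' @param cfg A [pipeline_config()] or the path to a YAML config.
#' @return Invisible list: `report` (character lines), `outputs` (paths),
#'   and the in-memory stage results.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- c(sprintf("matrinet %s | R %s.%s",
                      as.character(utils::packageVersion("matrinet")),
                      R.version$major, R.version$minor),
              sprintf("seed: %d", cfg$seed),
              sprintf("stages: %s", paste(cfg$stages, collapse = ", ")))
  outputs <- character()
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # differential ---------------------------------------------------------
  if ("differential" %in% cfg$stages) stage("differential", {
    if (!is.null(cfg$inputs$abundance)) {
      m <- read_abundance_matrix(cfg$inputs$abundance, cfg$inputs$samples)
      prot_A <- differential_test(m, c("hom_A", "het"))
      prot_B <- differential_test(m, c("hom_B", "het"))
      prot_A$comparison_id <- "A"
      prot_B$comparison_id <- "B"
      qc <- do.call(rbind, lapply(unique(m$samples$group), function(g) {
        rc <- replicate_correlation(m, g)
        data.frame(group = g, sample_id = names(rc$median_r),
                   median_r = unname(rc$median_r),
                   outlier = names(rc$median_r) %in% rc$outliers,
                   stringsAsFactors = FALSE)
      }))
      outputs <- c(outputs, write_tsv_out(qc, cfg$out_dir, "replicate_qc.tsv"))
    } else {
      prot_A <- read_differential_table(cfg$inputs$prot_A, "A")
      prot_B <- read_differential_table(cfg$inputs$prot_B, "B")
    }
    rna_A <- read_differential_table(cfg$inputs$rna_A, "A")
    rna_B <- read_differential_table(cfg$inputs$rna_B, "B")
    ann <- read_annotation_db(cfg$inputs$annotation)
    sig_A <- filter_significant(prot_A, cfg$q_max, cfg$abs_log2fc_min)
    sig_B <- filter_significant(prot_B, cfg$q_max, cfg$abs_log2fc_min)
    vp <- venn_direction_partition(prot_A, prot_B, cfg$q_max)
    top <- top_n_signature(prot_A, min(cfg$top_n, nrow(prot_A)))
    catsum <- category_fc_summary(sig_A, ann)
    outputs <- c(outputs,
                 write_tsv_out(prot_A, cfg$out_dir, "differential_prot_A.tsv"),
                 write_tsv_out(prot_B, cfg$out_dir, "differential_prot_B.tsv"),
                 write_tsv_out(sig_A, cfg$out_dir, "significant_prot_A.tsv"),
                 write_tsv_out(sig_B, cfg$out_dir, "significant_prot_B.tsv"),
                 write_tsv_out(top, cfg$out_dir, "top_signature_A.tsv"),
                 write_tsv_out(catsum$summary, cfg$out_dir,
                               "category_summary_A.tsv"))
    p <- file.path(cfg$out_dir, "venn_partition.tsv")
    write_venn_partition(vp, p)
    outputs <- c(outputs, p)
    report <- c(report,
                sprintf("differential: %d/%d significant in A, %d/%d in B",
                        nrow(sig_A), nrow(prot_A), nrow(sig_B), nrow(prot_B)),
                sprintf("venn: only_A %d, only_B %d, same %d, opposite %d",
                        length(vp$only_A), length(vp$only_B),
                        length(vp$shared_same_direction),
                        length(vp$shared_opposite_direction)))
    res$prot_A <- prot_A; res$prot_B <- prot_B
    res$rna_A <- rna_A; res$rna_B <- rna_B
    res$sig_A <- sig_A; res$sig_B <- sig_B
    res$ann <- ann; res$venn <- vp
    outputs <- outputs; report <- report
  })

  # deconvolution ---------------------------------------------------------
  if ("deconvolution" %in% cfg$stages) stage("deconvolution", {
    combined <- read_gene_sets(cfg$inputs$combined, level = "combined")
    for (comp in c("A", "B")) {
      ce <- score_celltypes(res[[paste0("sig_", comp)]], combined,
                            cfg$min_mapped)
      outputs <- c(outputs, write_tsv_out(
        ce, cfg$out_dir, sprintf("celltype_enrichment_%s.tsv", comp)))
    }
    res$combined <- combined
    report <- c(report, sprintf("deconvolution: %d combined cell types",
                                 length(combined)))
  })

  # interactions ----------------------------------------------------------
  if ("interactions" %in% cfg$stages) stage("interactions", {
    db <- read_interaction_db(cfg$inputs$pairs, cfg$inputs$types)
    res$db <- db
    for (comp in c("A", "B")) {
      prof <- interactors_of(cfg$slrps, db, res[[paste0("prot_", comp)]],
                             cfg$q_max)
      edges <- ligand_receptor_map(res[[paste0("prot_", comp)]],
                                   res[[paste0("rna_", comp)]],
                                   res$ann, db, cfg$q_max, cfg$padj_max)
      res[[paste0("profiles_", comp)]] <- prof
      res[[paste0("edges_", comp)]] <- edges
      outputs <- c(outputs,
                    write_tsv_out(interactor_counts(prof), cfg$out_dir,
                                  sprintf("slrp_interactors_%s.tsv", comp)),
                    write_tsv_out(edges, cfg$out_dir,
                                  sprintf("lr_edges_%s.tsv", comp)))
      report <- c(report, sprintf(
        "interactions %s: %d edges (%d ligands x %d receptors)", comp,
        nrow(edges), length(unique(edges$ligand)),
        length(unique(edges$receptor))))
    }
  })

  # scoring ---------------------------------------------------------------
  if ("scoring" %in% cfg$stages) stage("scoring", {
    pathways <- read_gene_sets(cfg$inputs$pathways, level = "pathway")
    res$pathways <- pathways
    for (comp in c("A", "B")) {
      sc <- slrp_pathway_scores(cfg$slrps, res[[paste0("profiles_", comp)]],
                                res[[paste0("prot_", comp)]], pathways,
                                cfg$q_max)
      links <- slrp_pathway_links(sc, res[[paste0("profiles_", comp)]],
                                  pathways)
      res[[paste0("scores_", comp)]] <- sc
      outputs <- c(outputs,
                    write_tsv_out(sc, cfg$out_dir,
                                  sprintf("slrp_pathway_scores_%s.tsv", comp)),
                    write_tsv_out(links, cfg$out_dir,
                                  sprintf("slrp_pathway_links_%s.tsv", comp)))
      report <- c(report, sprintf("scoring %s: %d pathways scored", comp,
                                   nrow(sc)))
    }
  })

  # network ---------------------------------------------------------------
  if ("network" %in% cfg$stages) stage("network", {
    for (comp in c("A", "B")) {
      net <- build_network(res[[paste0("edges_", comp)]], res$combined)
      h <- heat_matrices(net)
      cl <- if (nrow(h$row_normalized) >= 1L) cluster_ligands(h)
            else list(order = character())
      res[[paste0("network_", comp)]] <- net
      res[[paste0("heat_", comp)]] <- h
      outputs <- c(outputs,
                    export_network(net,
                                   file.path(cfg$out_dir,
                                             sprintf("network_nodes_%s.tsv", comp)),
                                   file.path(cfg$out_dir,
                                             sprintf("network_edges_%s.tsv", comp)),
                                   file.path(cfg$out_dir,
                                             sprintf("network_%s.graphml", comp))),
                    write_heat_matrices(h, cfg$out_dir,
                                        sprintf("heat_%s", comp)))
      export_circos(net,
                    file.path(cfg$out_dir, sprintf("circos_links_%s.tsv", comp)),
                    file.path(cfg$out_dir, sprintf("circos_tracks_%s.tsv", comp)))
      writeLines(cl$order,
                 file.path(cfg$out_dir, sprintf("ligand_order_%s.txt", comp)))
      report <- c(report, sprintf(
        "network %s: %d ligands, %d receptors, %d cell types, %d orphans",
        comp, nrow(net$ligands), nrow(net$receptors),
        length(net$cell_types), length(net$orphans)))
    }
  })

  writeLines(report, file.path(cfg$out_dir, "run_report.txt"))
  invisible(c(list(report = report, outputs = outputs), res))
}
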