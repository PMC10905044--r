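# Synthetic-data generator: every pipeline input with planted ground truth.
#
# All three entry points (abundances, knowledge bases, differential tables)
# derive their shared structure from one deterministic role assignment
# (sim_roles), so they are mutually consistent however they are combined.

#' Simulation configuration
#'
#' Defines the synthetic study: a two-contrast paired proteomics design
#' (comparison A, "proximal" inflamed vs control; comparison B, "middle"
#' prepathologic vs control, sharing one control group), a matrisome
#' annotation, a ligand-receptor interaction set, cell-type signatures from
#' three pseudo-source datasets, pathway gene sets, and a planted
#' ligand-to-receptor-to-cell-type network.
#'
#' @param seed Integer; fixes all randomness end-to-end.
#' @param n_proteins Number of protein groups / genes in the universe.
#' @param n_samples_per_group Paired samples per group (two case groups and
#'   one shared control).
#' @param frac_matrisomal Fraction of the universe annotated matrisomal.
#' @param frac_de Fraction of unconstrained genes planted as differential.
#' @param frac_shared Probability a planted-DE gene is differential in both
#'   comparisons.
#' @param frac_concordant Probability a shared-DE gene changes in the same
#'   direction in both comparisons.
#' @param effect_size_mean,effect_size_sd Planted log2 shift magnitude is
#'   `|N(mean, sd)|`.
#' @param noise_sd Within-group log2 dispersion.
#' @param pair_sd Log2 scale mouse (pairing) random effect.
#' @param n_cell_types Number of combined cell types.
#' @param n_pathways Number of pathway gene sets.
#' @param slrp_flip Plant opposing SLRP directions (down in A, up in B)?
#' @param planted_network Optional explicit data frame of
#'   (`ligand`, `receptor`, `cell_type`) triples; when `NULL`,
#'   `n_planted_triples` random triples are planted.
#' @param n_planted_triples Number of auto-planted network triples.
#' @param frac_planted_in_B Fraction of planted triples also active in
#'   comparison B (the prepathologic map is sparser than the inflamed one).
#' @param celltype_shift Plant a coherent per-cell-type log2fc direction in
#'   comparison A (for deconvolution validation)?
#' @param n_celltype_markers Non-receptor marker genes per combined cell
#'   type carrying the planted shift.
#' @param pathway_interactor_overlap Fraction of each pathway drawn from
#'   the SLRP-interactor union.
#' @param frac_single_peptide Fraction of protein groups with a single
#'   unique peptide (excluded from testing by the peptide filter).
#' @param missing_rate Missing-completely-at-random abundance rate.
#' @param closure Guarantee every receptor belongs to at least one cell-type
#'   signature?
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 2000L,
                       n_samples_per_group = 5L,
                       frac_matrisomal = 0.08,
                       frac_de = 0.3,
                       frac_shared = 0.4,
                       frac_concordant = 0.85,
                       effect_size_mean = 2,
                       effect_size_sd = 0.5,
                       noise_sd = 0.5,
                       pair_sd = 0.5,
                       n_cell_types = 8L,
                       n_pathways = 10L,
                       slrp_flip = TRUE,
                       planted_network = NULL,
                       n_planted_triples = 12L,
                       frac_planted_in_B = 0.5,
                       celltype_shift = TRUE,
                       n_celltype_markers = 15L,
                       pathway_interactor_overlap = 0.5,
                       frac_single_peptide = 0.05,
                       missing_rate = 0,
                       closure = TRUE) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  for (f in c("n_proteins", "n_samples_per_group", "n_cell_types",
              "n_pathways", "n_celltype_markers")) {
    cfg[[f]] <- as.integer(cfg[[f]])
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) stop("config error: ", f, " must be >= 1")
  }
  cfg$n_planted_triples <- as.integer(cfg$n_planted_triples)
  if (is.na(cfg$n_planted_triples) || cfg$n_planted_triples < 0L)
    stop("config error: n_planted_triples must be >= 0")
  for (f in c("frac_matrisomal", "frac_de", "frac_shared", "frac_concordant",
              "frac_planted_in_B", "pathway_interactor_overlap",
              "frac_single_peptide", "missing_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("config error: ", f, " must be in [0, 1]")
  }
  if (cfg$noise_sd < 0 || cfg$pair_sd < 0 || cfg$effect_size_sd < 0)
    stop("config error: dispersions must be >= 0")
  if (cfg$n_proteins < 60L)
    stop("config error: need n_proteins >= 60 to host all gene roles")
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys are [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

# Run expr under a fixed seed without clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

CANONICAL_SLRPS <- c("Dcn", "Bgn", "Aspn", "Ogn", "Prelp", "Fmod")

# Deterministic role assignment shared by all simulate_* entry points.
# Decides the gene universe, matrisome membership, ligand/receptor pools,
# SLRPs and their interactors, cell types and signature membership, planted
# network triples, pathways, and the full differential truth (which genes
# change, in which comparison, with what planted log2fc) for both the
# protein and transcript layers.
sim_roles <- function(cfg) {
  with_seed(cfg$seed, {
    n <- cfg$n_proteins
    slrps <- CANONICAL_SLRPS
    genes <- c(slrps, sprintf("Gm%04d", seq_len(n - length(slrps))))

    n_matri <- max(length(slrps) + 10L, ceiling(cfg$frac_matrisomal * n))
    matrisomal <- c(slrps, sample(setdiff(genes, slrps), n_matri - length(slrps)))

    non_matri <- setdiff(genes, matrisomal)
    n_rec <- min(length(non_matri), max(24L, round(0.08 * n)))
    receptor_pool <- if (n_rec > 0L) sample(non_matri, n_rec) else character()

    # planted tripartite network ----------------------------------------
    cell_types <- sprintf("celltype%02d", seq_len(cfg$n_cell_types))
    lig_candidates <- setdiff(matrisomal, slrps)
    if (!is.null(cfg$planted_network)) {
      triples <- as.data.frame(cfg$planted_network, stringsAsFactors = FALSE)
      if (!all(c("ligand", "receptor", "cell_type") %in% names(triples)))
        stop("config error: planted_network needs ligand/receptor/cell_type")
      if (!all(triples$cell_type %in% cell_types))
        stop("config error: planted cell types exceed n_cell_types")
      if (!all(triples$ligand %in% lig_candidates))
        stop("config error: planted ligands must be non-SLRP matrisomal genes")
      if (!all(triples$receptor %in% receptor_pool))
        stop("config error: planted receptors must come from the receptor pool")
    } else if (cfg$n_planted_triples == 0L) {
      triples <- data.frame(ligand = character(), receptor = character(),
                            cell_type = character(), stringsAsFactors = FALSE)
    } else {
      k <- cfg$n_planted_triples
      n_pl_lig <- max(3L, ceiling(k * 0.6))
      n_pl_rec <- max(3L, ceiling(k * 0.7))
      if (n_pl_lig > length(lig_candidates) || n_pl_rec > length(receptor_pool))
        stop("config error: planted network larger than available gene pools")
      pl_lig <- sample(lig_candidates, n_pl_lig)
      pl_rec <- sample(receptor_pool, n_pl_rec)
      rec_ct <- stats::setNames(sample(cell_types, n_pl_rec, replace = TRUE), pl_rec)
      grid <- expand.grid(ligand = pl_lig, receptor = pl_rec,
                          stringsAsFactors = FALSE)
      # every planted ligand and receptor appears at least once
      first <- data.frame(ligand = pl_lig[((seq_len(max(n_pl_lig, n_pl_rec)) - 1L) %% n_pl_lig) + 1L],
                          receptor = pl_rec[((seq_len(max(n_pl_lig, n_pl_rec)) - 1L) %% n_pl_rec) + 1L],
                          stringsAsFactors = FALSE)
      extra_n <- max(0L, k - nrow(first))
      pool <- grid[!paste(grid$ligand, grid$receptor) %in%
                     paste(first$ligand, first$receptor), , drop = FALSE]
      extra <- pool[sample(nrow(pool), min(extra_n, nrow(pool))), , drop = FALSE]
      triples <- unique(rbind(first, extra))
      triples$cell_type <- rec_ct[triples$receptor]
      rownames(triples) <- NULL
    }
    planted_ligands <- unique(triples$ligand)
    planted_receptors <- unique(triples$receptor)
    decoy_receptors <- setdiff(receptor_pool, planted_receptors)
    n_decoy_lig <- min(length(setdiff(lig_candidates, planted_ligands)),
                       max(4L, length(planted_ligands)))
    decoy_ligands <- sample(setdiff(lig_candidates, planted_ligands), n_decoy_lig)
    ligand_pool <- c(planted_ligands, decoy_ligands, slrps)

    # comparison B keeps a subset of the planted map (sparser prepathology)
    in_B <- rep(FALSE, nrow(triples))
    nB <- round(cfg$frac_planted_in_B * nrow(triples))
    if (nB > 0L) in_B[sample(nrow(triples), nB)] <- TRUE
    triples$in_B <- if (nrow(triples)) in_B else logical()

    # SLRP interactors: decoy receptors only, so SLRP edges never enter the
    # planted ligand->receptor truth (decoys stay non-DE transcriptomically)
    slrp_partners <- lapply(stats::setNames(slrps, slrps), function(s) {
      sort(sample(decoy_receptors, min(length(decoy_receptors),
                                       sample(3:8, 1L))))
    })
    interactor_union <- sort(unique(unlist(slrp_partners)))

    # cell-type structure ------------------------------------------------
    n_sub <- sample(1:2, cfg$n_cell_types, replace = TRUE)
    extended_map <- stats::setNames(
      lapply(seq_len(cfg$n_cell_types), function(i)
        paste0(cell_types[i], "_sub", seq_len(n_sub[i]))),
      cell_types)
    subtypes <- unlist(extended_map, use.names = FALSE)
    # each planted receptor lives only in subtypes of its planted cell types
    rec_ct_map <- split(triples$cell_type, triples$receptor)
    marker_pool <- setdiff(genes, c(receptor_pool, ligand_pool))
    ct_direction <- stats::setNames(sample(c(-1, 1), cfg$n_cell_types,
                                           replace = TRUE), cell_types)
    ct_markers <- stats::setNames(vector("list", cfg$n_cell_types), cell_types)
    sig_members <- stats::setNames(vector("list", length(subtypes)), subtypes)
    for (ct in cell_types) {
      mk <- sample(marker_pool, min(cfg$n_celltype_markers, length(marker_pool)))
      marker_pool <- setdiff(marker_pool, mk)
      ct_markers[[ct]] <- mk
      subs <- extended_map[[ct]]
      split_idx <- sample(seq_along(subs), length(mk), replace = TRUE)
      for (i in seq_along(subs)) {
        sig_members[[subs[i]]] <- mk[split_idx == i]
      }
      rec_here <- names(rec_ct_map)[vapply(rec_ct_map, function(x) ct %in% x, TRUE)]
      if (length(rec_here)) {
        home <- sample(subs, length(rec_here), replace = TRUE)
        for (i in seq_along(rec_here))
          sig_members[[home[i]]] <- c(sig_members[[home[i]]], rec_here[i])
      }
    }
    if (cfg$closure && length(decoy_receptors)) {
      host <- sample(subtypes, length(decoy_receptors), replace = TRUE)
      for (i in seq_along(decoy_receptors))
        sig_members[[host[i]]] <- c(sig_members[[host[i]]], decoy_receptors[i])
    }
    sig_members <- lapply(sig_members, function(g) sort(unique(g)))
    empty <- !lengths(sig_members)
    if (any(empty)) {
      # keep gene sets nonempty (data_model invariant)
      filler <- sample(setdiff(genes, receptor_pool), sum(empty))
      sig_members[empty] <- as.list(filler)
    }

    # pathways overlap SLRP interactors by a configurable fraction --------
    pw_size <- 15L
    pathways <- stats::setNames(
      lapply(seq_len(cfg$n_pathways), function(i) {
        k_ov <- min(length(interactor_union),
                    round(cfg$pathway_interactor_overlap * pw_size))
        ov <- if (k_ov > 0L) sample(interactor_union, k_ov) else character()
        rest <- sample(setdiff(genes, interactor_union), pw_size - length(ov))
        sort(unique(c(ov, rest)))
      }),
      sprintf("pathway%02d", seq_len(cfg$n_pathways)))

    # differential truth --------------------------------------------------
    draw_mag <- function(k) abs(stats::rnorm(k, cfg$effect_size_mean,
                                             cfg$effect_size_sd))
    prot <- data.frame(gene_symbol = genes, de_A = FALSE, lfc_A = 0,
                       de_B = FALSE, lfc_B = 0, stringsAsFactors = FALSE)
    rownames(prot) <- genes
    set_de <- function(tr, g, comp, sign, mag = draw_mag(length(g))) {
      tr[g, paste0("de_", comp)] <- TRUE
      tr[g, paste0("lfc_", comp)] <- sign * mag
      tr
    }
    # planted ligands: DE (protein level) in A; B only if active there
    prot <- set_de(prot, planted_ligands, "A", sample(c(-1, 1), length(planted_ligands), TRUE))
    lig_B <- unique(triples$ligand[triples$in_B])
    if (length(lig_B))
      prot <- set_de(prot, lig_B, "B", sample(c(-1, 1), length(lig_B), TRUE))
    # SLRPs: down in inflamed A, up in prepathologic B; without the flip
    # they are unconstrained and follow the global scheme below
    if (cfg$slrp_flip) {
      prot <- set_de(prot, slrps, "A", -1)
      prot <- set_de(prot, slrps, "B", +1)
    }
    # coherent per-cell-type marker shifts in comparison A
    if (cfg$celltype_shift) {
      for (ct in cell_types)
        prot <- set_de(prot, ct_markers[[ct]], "A", ct_direction[[ct]])
    }
    # unconstrained genes: frac_de split into shared/unique with a planted
    # direction-concordance fraction (the Venn/scatter structure)
    constrained <- c(ligand_pool, if (cfg$slrp_flip) slrps,
                     if (cfg$celltype_shift) unlist(ct_markers))
    free <- setdiff(genes, constrained)
    de_any <- free[stats::runif(length(free)) < cfg$frac_de]
    shared <- de_any[stats::runif(length(de_any)) < cfg$frac_shared]
    solo <- setdiff(de_any, shared)
    half <- seq_along(solo) %% 2L == 0L
    sign_A <- sample(c(-1, 1), length(shared), TRUE)
    same_dir <- stats::runif(length(shared)) < cfg$frac_concordant
    if (length(shared)) {
      prot <- set_de(prot, shared, "A", sign_A)
      prot <- set_de(prot, shared, "B", ifelse(same_dir, sign_A, -sign_A))
    }
    if (any(half)) prot <- set_de(prot, solo[half], "A",
                                  sample(c(-1, 1), sum(half), TRUE))
    if (any(!half)) prot <- set_de(prot, solo[!half], "B",
                                   sample(c(-1, 1), sum(!half), TRUE))
    # decoy ligands stay non-DE at the protein level (forced; see vignette)
    prot[decoy_ligands, c("de_A", "de_B")] <- FALSE
    prot[decoy_ligands, c("lfc_A", "lfc_B")] <- 0

    # transcript layer: only planted receptors are DE; decoys never are
    rna_genes <- sort(unique(c(receptor_pool,
                               sample(setdiff(genes, receptor_pool),
                                      round(0.3 * n)))))
    rna <- data.frame(gene_symbol = rna_genes, de_A = FALSE, lfc_A = 0,
                      de_B = FALSE, lfc_B = 0, stringsAsFactors = FALSE)
    rownames(rna) <- rna_genes
    rna <- set_de(rna, planted_receptors, "A",
                  sample(c(-1, 1), length(planted_receptors), TRUE))
    rec_B <- unique(triples$receptor[triples$in_B])
    if (length(rec_B))
      rna <- set_de(rna, rec_B, "B", sample(c(-1, 1), length(rec_B), TRUE))
    free_rna <- setdiff(rna_genes, receptor_pool)
    de_rna <- free_rna[stats::runif(length(free_rna)) < cfg$frac_de]
    if (length(de_rna)) {
      rna <- set_de(rna, de_rna, "A", sample(c(-1, 1), length(de_rna), TRUE))
    }

    list(genes = genes, slrps = slrps, matrisomal = matrisomal,
         receptor_pool = receptor_pool, ligand_pool = ligand_pool,
         planted_ligands = planted_ligands, decoy_ligands = decoy_ligands,
         planted_receptors = planted_receptors,
         decoy_receptors = decoy_receptors,
         cell_types = cell_types, extended_map = extended_map,
         sig_members = sig_members, ct_markers = ct_markers,
         ct_direction = ct_direction, triples = triples,
         slrp_partners = slrp_partners, pathways = pathways,
         prot_truth = prot, rna_truth = rna)
  })
}

#' Simulate paired abundance matrices
#'
#' Log-normal protein abundances for a paired two-contrast design: case
#' groups `hom_A` ("proximal inflamed") and `hom_B` ("middle
#' prepathologic") against a shared paired control group `het`. Planted
#' differential proteins shift the case-group log2 mean by their truth
#' log2fc; a per-(pair, protein) random effect makes the pairing
#' informative.
#'
#' @param cfg A [sim_config()].
#' @return List with `matrix` (an [abundance_matrix()]) and `truth`
#'   (data frame: `gene_symbol`, `de_A`, `lfc_A`, `de_B`, `lfc_B`).
#' @export
simulate_abundances <- function(cfg) {
  roles <- sim_roles(cfg)
  with_seed(cfg$seed + 1L, {
    n <- cfg$n_proteins
    k <- cfg$n_samples_per_group
    truth <- roles$prot_truth
    base <- stats::runif(n, 16, 24)
    groups <- c("hom_A", "hom_B", "het")
    sample_ids <- as.vector(vapply(groups, function(g)
      sprintf("%s_m%02d", g, seq_len(k)), character(k)))
    samples <- data.frame(
      sample_id = sample_ids,
      group = rep(groups, each = k),
      pair = rep(sprintf("m%02d", seq_len(k)), times = length(groups)),
      stringsAsFactors = FALSE)
    pair_eff <- matrix(stats::rnorm(n * k, 0, cfg$pair_sd), n, k)
    shift <- cbind(hom_A = truth$lfc_A, hom_B = truth$lfc_B, het = 0)
    logv <- matrix(NA_real_, n, length(sample_ids),
                   dimnames = list(sprintf("PG%05d", seq_len(n)), sample_ids))
    for (j in seq_along(sample_ids)) {
      g <- samples$group[j]
      p <- match(samples$pair[j], sprintf("m%02d", seq_len(k)))
      logv[, j] <- base + pair_eff[, p] + shift[, g] +
        stats::rnorm(n, 0, cfg$noise_sd)
    }
    v <- 2^logv
    if (cfg$missing_rate > 0) {
      drop <- matrix(stats::runif(length(v)) < cfg$missing_rate,
                     nrow(v), ncol(v))
      v[drop] <- NA_real_
    }
    npep <- ifelse(stats::runif(n) < cfg$frac_single_peptide, 1L,
                   1L + stats::rpois(n, 8))
    npep[npep < 1L] <- 1L
    m <- abundance_matrix(v, samples, gene_symbols = roles$genes,
                          n_unique_peptides = npep)
    truth$protein_id <- rownames(v)
    truth$n_unique_peptides <- npep
    rownames(truth) <- NULL
    list(matrix = m, truth = truth)
  })
}

#' Simulate knowledge bases
#'
#' Generates the matrisome annotation, the typed ligand-receptor interaction
#' set, cell-type signatures from three pseudo-source datasets (plus their
#' extended and combined merges), and pathway gene sets seeded to overlap
#' the SLRP interactor union. Every planted network triple is realizable:
#' its ligand is annotated matrisomal and typed as a ligand, the pair is in
#' the interaction set, and the receptor sits in the planted cell type's
#' signature (and, under `closure`, nowhere else among receptors).
#'
#' @param cfg A [sim_config()].
#' @return List with `annotation` ([annotation_db()]), `interactions`
#'   ([interaction_db()]), `signature_sources` (list of three
#'   per-source [signature_set()]s), `extended`, `combined`, `merge_map`,
#'   `pathways` ([signature_set()]), `slrps`, and `truth` (the planted
#'   triples with per-comparison activity flags).
#' @export
simulate_knowledge_bases <- function(cfg) {
  roles <- sim_roles(cfg)
  with_seed(cfg$seed + 2L, {
    genes <- roles$genes
    is_matri <- genes %in% roles$matrisomal
    is_slrp <- genes %in% roles$slrps
    division <- ifelse(is_slrp, "core",
                       ifelse(is_matri, sample(c("core", "associated"),
                                               length(genes), TRUE), "none"))
    core_cat <- c("collagens", "glycoproteins", "proteoglycans")
    assoc_cat <- c("ECM regulators", "secreted factors", "ECM-affiliated")
    category <- rep("none", length(genes))
    category[division == "core"] <- sample(core_cat, sum(division == "core"), TRUE)
    category[division == "associated"] <- sample(assoc_cat,
                                                 sum(division == "associated"), TRUE)
    category[is_slrp] <- "proteoglycans"
    colon <- is_matri & (is_slrp | stats::runif(length(genes)) < 0.7)
    extra_go <- !is_matri & stats::runif(length(genes)) < 0.3
    ann <- annotation_db(data.frame(
      gene_symbol = genes, matrisome_division = division,
      matrisome_category = category, colon_matrisome = colon,
      extracellular_go = is_matri | extra_go, stringsAsFactors = FALSE))

    # interaction pairs: planted + SLRP interactors + decoy pairs whose
    # endpoints are never both differential
    planted_pairs <- unique(roles$triples[, c("ligand", "receptor")])
    slrp_pairs <- do.call(rbind, lapply(names(roles$slrp_partners), function(s)
      data.frame(ligand = rep(s, length(roles$slrp_partners[[s]])),
                 receptor = roles$slrp_partners[[s]],
                 stringsAsFactors = FALSE)))
    n_decoy <- max(10L, nrow(planted_pairs))
    decoy_pairs <- if (length(roles$decoy_ligands) && length(roles$receptor_pool))
      data.frame(
        ligand = sample(roles$decoy_ligands, n_decoy, replace = TRUE),
        receptor = sample(roles$receptor_pool, n_decoy, replace = TRUE),
        stringsAsFactors = FALSE)
    else data.frame(ligand = character(), receptor = character(),
                    stringsAsFactors = FALSE)
    if (length(roles$decoy_receptors) && length(roles$planted_ligands)) {
      decoy_pairs <- rbind(decoy_pairs, data.frame(
        ligand = sample(roles$planted_ligands, 5L, replace = TRUE),
        receptor = sample(roles$decoy_receptors, 5L, replace = TRUE),
        stringsAsFactors = FALSE))
    }
    pairs <- unique(rbind(planted_pairs, slrp_pairs, decoy_pairs))
    pairs <- pairs[order(pairs$ligand, pairs$receptor), ]
    rownames(pairs) <- NULL
    ptype <- stats::setNames(rep("other", length(genes)), genes)
    ptype[roles$ligand_pool] <- "ligand"
    ptype[roles$receptor_pool] <- "receptor"
    db <- interaction_db(pairs, ptype)

    # three pseudo-sources each observe a subset of every extended set
    subtypes <- names(roles$sig_members)
    src_names <- c("kinchen_like", "smillie_like", "mitsialis_like")
    sources <- lapply(seq_along(src_names), function(si) {
      sets <- lapply(roles$sig_members, function(g) {
        seen <- g[stats::runif(length(g)) < 0.7]
        if (!length(seen)) seen <- g[1L]
        seen
      })
      signature_set(sets, sources = src_names[si], level = "extended")
    })
    names(sources) <- src_names
    # guarantee every member survives in the union across sources
    for (st in subtypes) {
      have <- unique(unlist(lapply(sources, function(s) s[[st]]$genes)))
      lost <- setdiff(roles$sig_members[[st]], have)
      if (length(lost))
        sources[[1L]][[st]]$genes <- sort(unique(c(sources[[1L]][[st]]$genes, lost)))
    }
    merge_map <- roles$extended_map
    built <- build_signatures(sources, merge_map)
    pathways <- signature_set(roles$pathways, sources = "hallmark_like",
                              level = "pathway")
    list(annotation = ann, interactions = db,
         signature_sources = sources,
         extended = built$extended, combined = built$combined,
         merge_map = merge_map, pathways = pathways,
         slrps = roles$slrps, truth = roles$triples)
  })
}

#' Simulate differential tables directly
#'
#' Shortcut generator for stages that consume differential tables rather
#' than abundance matrices: protein tables for comparisons A and B
#' (significance = q-value) and transcript tables for both comparisons
#' (significance = adjusted p). Planted-DE features get significance drawn
#' below 0.05 and log2fc equal to the truth shift plus small noise; null
#' features get significance above 0.05. With `slrp_flip = TRUE` every SLRP
#' is significant in both protein comparisons with opposite signs.
#'
#' @param cfg A [sim_config()].
#' @return List with `prot_A`, `prot_B`, `rna_A`, `rna_B`
#'   ([differential_table()]s), and `truth` (list `prot`, `rna`,
#'   `concordant_fraction`).
#' @export
simulate_differential_tables <- function(cfg) {
  roles <- sim_roles(cfg)
  with_seed(cfg$seed + 3L, {
    draw_table <- function(tr, comp, comparison_id, prefix) {
      de <- tr[[paste0("de_", comp)]]
      lfc <- tr[[paste0("lfc_", comp)]] + stats::rnorm(nrow(tr), 0, 0.05)
      lfc[!de] <- stats::rnorm(sum(!de), 0, 0.15)
      sig <- ifelse(de, stats::runif(nrow(tr), 1e-6, 0.04),
                    stats::runif(nrow(tr), 0.051, 1))
      differential_table(paste0(prefix, tr$gene_symbol), tr$gene_symbol,
                         lfc, sig, comparison_id = comparison_id,
                         split = FALSE)
    }
    prot_A <- draw_table(roles$prot_truth, "A", "A", "p_")
    prot_B <- draw_table(roles$prot_truth, "B", "B", "p_")
    rna_A <- draw_table(roles$rna_truth, "A", "A", "g_")
    rna_B <- draw_table(roles$rna_truth, "B", "B", "g_")
    pt <- roles$prot_truth
    shared <- pt$de_A & pt$de_B
    conc <- if (any(shared))
      mean(sign(pt$lfc_A[shared]) == sign(pt$lfc_B[shared])) else NA_real_
    list(prot_A = prot_A, prot_B = prot_B, rna_A = rna_A, rna_B = rna_B,
         truth = list(prot = pt, rna = roles$rna_truth,
                      concordant_fraction = conc))
  })
}

#' Simulate the complete synthetic study
#'
#' Convenience wrapper running all three generators under one configuration.
#'
#' @param cfg A [sim_config()].
#' @return List with `abundances`, `kb` (knowledge bases), `tables`, and
#'   `cfg`.
#' @export
simulate_study <- function(cfg) {
  list(abundances = simulate_abundances(cfg),
       kb = simulate_knowledge_bases(cfg),
       tables = simulate_differential_tables(cfg),
       cfg = cfg)
}
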