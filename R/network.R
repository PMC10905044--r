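# Tripartite ligand -> receptor -> cell-type network assembly, heat
# matrices, ligand clustering, and plain-text exports.

#' Assemble the tripartite network
#'
#' Extends a ligand-receptor edge list with receptor-to-cell-type edges:
#' one edge for every combined cell-type signature containing the receptor
#' gene. Receptors found in no signature are kept as ligand-receptor edges
#' and reported as orphans rather than silently dropped.
#'
#' @param edges An `lr_edges` data frame from [ligand_receptor_map()].
#' @param sig Combined cell-type [signature_set()].
#' @return Object of class `tripartite_network`: `ligands`, `receptors`
#'   (data frames with their differential statistics), `cell_types`,
#'   `lr_edges`, `rc_edges` (receptor, cell_type), `orphans`, and summary
#'   counts `ligands_per_celltype`, `celltypes_per_ligand`.
#' @export
build_network <- function(edges, sig) {
  edges <- as.data.frame(edges)
  receptors <- unique(edges$receptor)
  rc <- do.call(rbind, c(list(data.frame(receptor = character(),
                                         cell_type = character(),
                                         stringsAsFactors = FALSE)),
    lapply(names(sig), function(ct) {
      r <- intersect(receptors, sig[[ct]]$genes)
      if (length(r)) data.frame(receptor = r, cell_type = ct,
                                stringsAsFactors = FALSE)
    })))
  rc <- rc[order(rc$receptor, rc$cell_type), , drop = FALSE]
  rownames(rc) <- NULL
  orphans <- sort(setdiff(receptors, rc$receptor))
  lig_df <- unique(edges[, c("ligand", "ligand_log2fc", "ligand_q")])
  rec_df <- unique(edges[, c("receptor", "receptor_log2fc", "receptor_padj")])
  # ligand -> cell type incidence via shared receptors
  lc <- unique(merge(edges[, c("ligand", "receptor")], rc, by = "receptor")[,
                     c("ligand", "cell_type")])
  net <- structure(list(
    ligands = lig_df[order(lig_df$ligand), , drop = FALSE],
    receptors = rec_df[order(rec_df$receptor), , drop = FALSE],
    cell_types = sort(unique(rc$cell_type)),
    lr_edges = edges,
    rc_edges = rc,
    orphans = orphans,
    ligands_per_celltype = if (nrow(lc))
      sort(table(lc$cell_type), decreasing = TRUE) else table(character()),
    celltypes_per_ligand = if (nrow(lc))
      sort(table(lc$ligand), decreasing = TRUE) else table(character())
  ), class = "tripartite_network")
  net
}

#' @export
print.tripartite_network <- function(x, ...) {
  cat(sprintf("tripartite_network: %d ligands -> %d receptors -> %d cell types (%d LR edges, %d orphan receptors)\n",
              nrow(x$ligands), nrow(x$receptors), length(x$cell_types),
              nrow(x$lr_edges), length(x$orphans)))
  invisible(x)
}

#' Ligand-by-cell-type heat matrices
#'
#' Three matrices over (ligand, cell type): `raw` counts the distinct
#' receptors linking the ligand to the cell type; `row_normalized` divides
#' each raw row by its sum, so a ligand acting through a single cell type
#' scores 1 there — the weighting that gives unique interactions more
#' power (rows with an all-zero raw count are dropped); `mean_log2fc`
#' averages the transcriptomic log2 fold change of those receptors. A
#' per-cell-type summary (mean transcript log2fc over receptors mapping to
#' the cell type) is attached as attribute `"celltype_mean_log2fc"`,
#' averaging over unique receptors by default or over (ligand, receptor)
#' incidences with `celltype_average = "incidence"`.
#'
#' @param net A [build_network()] result.
#' @param t_rna Transcript [differential_table()] giving receptor log2fc
#'   (defaults to the fold changes stored on the network's edges).
#' @param celltype_average `"unique"` (default) or `"incidence"`.
#' @return List of class `heat_matrices`: `raw`, `row_normalized`,
#'   `mean_log2fc`.
#' @export
heat_matrices <- function(net, t_rna = NULL,
                          celltype_average = c("unique", "incidence")) {
  celltype_average <- match.arg(celltype_average)
  ligands <- net$ligands$ligand
  cts <- net$cell_types
  rec_fc <- if (!is.null(t_rna))
    tapply(t_rna$log2fc, t_rna$gene_symbol, function(x) x[1L])
  else
    stats::setNames(net$receptors$receptor_log2fc, net$receptors$receptor)
  raw <- matrix(0L, length(ligands), length(cts),
                dimnames = list(ligands, cts))
  mfc <- matrix(NA_real_, length(ligands), length(cts),
                dimnames = list(ligands, cts))
  inc <- merge(net$lr_edges[, c("ligand", "receptor")], net$rc_edges,
               by = "receptor")
  for (i in seq_along(ligands)) {
    for (j in seq_along(cts)) {
      r <- unique(inc$receptor[inc$ligand == ligands[i] &
                                 inc$cell_type == cts[j]])
      raw[i, j] <- length(r)
      if (length(r)) mfc[i, j] <- mean(rec_fc[r], na.rm = TRUE)
    }
  }
  rs <- rowSums(raw)
  rn <- raw[rs > 0, , drop = FALSE] / rs[rs > 0]
  ct_fc <- vapply(cts, function(ct) {
    if (celltype_average == "unique") {
      r <- unique(inc$receptor[inc$cell_type == ct])
    } else {
      r <- inc$receptor[inc$cell_type == ct]
    }
    if (!length(r)) NA_real_ else mean(rec_fc[r], na.rm = TRUE)
  }, 0)
  structure(list(raw = raw, row_normalized = rn, mean_log2fc = mfc),
            celltype_mean_log2fc = ct_fc, class = "heat_matrices")
}

#' Hierarchically cluster ligands by their cell-type interaction profile
#'
#' Agglomerative clustering (average linkage, Euclidean distance) of the
#' row-normalized heat rows, grouping ligands that distribute their
#' receptor interactions across cell types in similar proportions. The
#' result is deterministic for a fixed input.
#'
#' @param h A `heat_matrices` object (its `row_normalized` component is
#'   used) or a numeric matrix of rows to cluster.
#' @return List: `hclust` (a [stats::hclust] object, or `NULL` for a
#'   single row), `order` (ordered ligand labels), `heights`.
#' @export
cluster_ligands <- function(h) {
  m <- if (inherits(h, "heat_matrices")) h$row_normalized else as.matrix(h)
  if (nrow(m) < 1L) stop("no rows to cluster")
  if (nrow(m) == 1L)
    return(list(hclust = NULL, order = rownames(m), heights = numeric()))
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "average")
  list(hclust = hc, order = rownames(m)[hc$order], heights = hc$height)
}

#' Export chord-diagram link and track files
#'
#' Plain-text files for chord/circos renderers: a link file
#' (source, target, weight) connecting ligands (bottom axis) to receptors,
#' and, when cell-type edges exist, receptors to cell types; and a track
#' file (label, category, value) carrying per-node statistics (ligand
#' log2fc, receptor log2fc). Ordering is deterministic (category, then
#' label), so re-export of an identical network is byte-identical.
#'
#' @param net A [build_network()] result.
#' @param links_path,tracks_path Output TSV paths.
#' @return Invisible list of the two paths.
#' @export
export_circos <- function(net, links_path, tracks_path) {
  lr <- net$lr_edges
  links <- data.frame(source = lr$ligand, target = lr$receptor,
                      weight = rep(1, nrow(lr)), stringsAsFactors = FALSE)
  if (nrow(net$rc_edges)) {
    links <- rbind(links, data.frame(source = net$rc_edges$receptor,
                                     target = net$rc_edges$cell_type,
                                     weight = rep(1, nrow(net$rc_edges)),
                                     stringsAsFactors = FALSE))
  }
  links <- links[order(links$source, links$target), , drop = FALSE]
  tracks <- rbind(
    data.frame(label = net$ligands$ligand,
               category = rep("ligand", nrow(net$ligands)),
               value = net$ligands$ligand_log2fc, stringsAsFactors = FALSE),
    data.frame(label = net$receptors$receptor,
               category = rep("receptor", nrow(net$receptors)),
               value = net$receptors$receptor_log2fc,
               stringsAsFactors = FALSE))
  tracks <- tracks[order(tracks$category, tracks$label), , drop = FALSE]
  utils::write.table(links, links_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(tracks, tracks_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(links = links_path, tracks = tracks_path))
}

#' Export the network as node/edge TSVs and GraphML
#'
#' @param net A [build_network()] result.
#' @param nodes_path,edges_path TSV paths.
#' @param graphml_path Optional GraphML XML path.
#' @return Invisible vector of written paths.
#' @export
export_network <- function(net, nodes_path, edges_path,
                           graphml_path = NULL) {
  nodes <- rbind(
    data.frame(id = net$ligands$ligand,
               kind = rep("ligand", nrow(net$ligands)),
               log2fc = net$ligands$ligand_log2fc,
               significance = net$ligands$ligand_q,
               stringsAsFactors = FALSE),
    data.frame(id = net$receptors$receptor,
               kind = rep("receptor", nrow(net$receptors)),
               log2fc = net$receptors$receptor_log2fc,
               significance = net$receptors$receptor_padj,
               stringsAsFactors = FALSE),
    data.frame(id = net$cell_types,
               kind = rep("cell_type", length(net$cell_types)),
               log2fc = rep(NA_real_, length(net$cell_types)),
               significance = rep(NA_real_, length(net$cell_types)),
               stringsAsFactors = FALSE))
  nodes <- nodes[order(nodes$kind, nodes$id), , drop = FALSE]
  edges <- rbind(
    data.frame(source = net$lr_edges$ligand,
               target = net$lr_edges$receptor,
               kind = rep("ligand_receptor", nrow(net$lr_edges)),
               stringsAsFactors = FALSE),
    data.frame(source = net$rc_edges$receptor,
               target = net$rc_edges$cell_type,
               kind = rep("receptor_celltype", nrow(net$rc_edges)),
               stringsAsFactors = FALSE))
  edges <- edges[order(edges$kind, edges$source, edges$target), ,
                 drop = FALSE]
  utils::write.table(nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  written <- c(nodes_path, edges_path)
  if (!is.null(graphml_path)) {
    esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x, fixed = TRUE),
                            fixed = TRUE)
    xml <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="kind" for="node" attr.name="kind" attr.type="string"/>',
      '  <graph id="tripartite" edgedefault="directed">',
      sprintf('    <node id="%s"><data key="kind">%s</data></node>',
              esc(nodes$id), nodes$kind),
      sprintf('    <edge source="%s" target="%s"/>',
              esc(edges$source), esc(edges$target)),
      '  </graph>', '</graphml>')
    writeLines(xml, graphml_path)
    written <- c(written, graphml_path)
  }
  invisible(written)
}

#' Write heat matrices to TSV
#'
#' One TSV per mode with row and column headers.
#' @param h A `heat_matrices` object.
#' @param dir Output directory.
#' @param prefix File-name prefix (default `"heat"`).
#' @return Invisible vector of written paths.
#' @export
write_heat_matrices <- function(h, dir, prefix = "heat") {
  paths <- character()
  for (mode in c("raw", "row_normalized", "mean_log2fc")) {
    p <- file.path(dir, sprintf("%s_%s.tsv", prefix, mode))
    m <- h[[mode]]
    df <- data.frame(ligand = rownames(m), as.data.frame(m),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
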