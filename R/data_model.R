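# Domain types and tabular/GMT I/O for the pipeline.

#' Normalize gene symbols
#'
#' Trims whitespace and applies the species casing convention: mouse symbols
#' are title-cased (`Dcn`, not `DCN`), human symbols upper-cased. The
#' operation is idempotent.
#'
#' @param x Character vector of gene symbols.
#' @param species `"mouse"` (default) or `"human"`.
#' @return Character vector of normalized symbols.
#' @export
normalize_symbols <- function(x, species = c("mouse", "human")) {
  species <- match.arg(species)
  x <- trimws(as.character(x))
  if (species == "mouse") {
    paste0(toupper(substring(x, 1L, 1L)), tolower(substring(x, 2L)))
  } else {
    toupper(x)
  }
}

#' Construct an abundance matrix
#'
#' Container for summed protein-group abundances: a proteins-by-samples
#' numeric matrix plus sample metadata (condition group and pairing key,
#' e.g. mouse identity) and per-protein-group gene symbols and unique
#' peptide counts.
#'
#' @param values Numeric matrix, rows = protein groups (rownames are protein
#'   ids), columns = samples (colnames are sample ids). Abundances must be
#'   finite and non-negative; `NA` marks a missing quantification.
#' @param samples Data frame with columns `sample_id`, `group`, `pair`.
#' @param gene_symbols Character vector, one per protein group; protein
#'   groups mapping to several genes separate symbols with `";"`.
#' @param n_unique_peptides Integer vector, one per protein group, >= 1.
#' @return Object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, samples, gene_symbols, n_unique_peptides) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  m <- structure(
    list(
      values = as.matrix(values),
      samples = samples,
      gene_symbols = as.character(gene_symbols),
      n_unique_peptides = as.integer(n_unique_peptides)
    ),
    class = "abundance_matrix"
  )
  validate_abundance_matrix(m)
  m
}

#' Validate an abundance matrix
#'
#' Checks the class invariants: unique protein and sample ids, complete
#' sample metadata, finite non-negative abundances (`NA` allowed), and
#' unique-peptide counts >= 1. Violations raise an error listing the
#' offending rows.
#'
#' @param m An `abundance_matrix`.
#' @return `m`, invisibly.
#' @export
validate_abundance_matrix <- function(m) {
  v <- m$values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    stop("abundance matrix needs protein ids as rownames and sample ids as colnames")
  dup <- rownames(v)[duplicated(rownames(v))]
  if (length(dup))
    stop("duplicate protein ids: ", paste(unique(dup), collapse = ", "))
  need <- c("sample_id", "group", "pair")
  miss <- setdiff(need, names(m$samples))
  if (length(miss))
    stop("sample table missing columns: ", paste(miss, collapse = ", "))
  if (!setequal(m$samples$sample_id, colnames(v)) ||
      anyDuplicated(m$samples$sample_id))
    stop("sample metadata does not match matrix columns")
  if (any(is.na(m$samples$group)))
    stop("every sample needs a group label")
  bad <- which(apply(v, 1L, function(r) any(!is.na(r) & (!is.finite(r) | r < 0))))
  if (length(bad))
    stop("non-finite or negative abundances in rows: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  if (length(m$gene_symbols) != nrow(v) ||
      length(m$n_unique_peptides) != nrow(v))
    stop("per-protein annotations must match the number of matrix rows")
  if (any(is.na(m$n_unique_peptides)) || any(m$n_unique_peptides < 1L))
    stop("n_unique_peptides must be >= 1 for every protein group")
  invisible(m)
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d protein groups x %d samples (%d groups)\n",
              nrow(x$values), ncol(x$values), length(unique(x$samples$group))))
  invisible(x)
}

#' Read an abundance matrix from TSV
#'
#' The matrix file carries one row per protein group with annotation columns
#' (protein id, gene symbol, unique peptide count, names configurable via
#' `schema`) followed by one numeric column per sample. Sample metadata
#' (`sample_id`, `group`, `pair`) comes from a second TSV or an in-memory
#' data frame.
#'
#' @param path Matrix TSV path.
#' @param samples Path to the sample-metadata TSV, or a data frame.
#' @param schema Named list mapping the annotation roles `protein_id`,
#'   `gene_symbol`, `n_unique_peptides` to column names in the file.
#' @return An `abundance_matrix`.
#' @export
read_abundance_matrix <- function(path, samples,
                                  schema = list(protein_id = "protein_id",
                                                gene_symbol = "gene_symbol",
                                                n_unique_peptides = "n_unique_peptides")) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- unlist(schema)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error: missing columns ", paste(miss, collapse = ", "))
  if (is.character(samples)) {
    samples <- utils::read.delim(samples, stringsAsFactors = FALSE)
  }
  samples$pair <- as.character(samples$pair)
  sample_cols <- as.character(samples$sample_id)
  miss <- setdiff(sample_cols, names(df))
  if (length(miss))
    stop("schema error: sample columns absent from matrix: ",
         paste(miss, collapse = ", "))
  ids <- as.character(df[[schema$protein_id]])
  dup <- which(duplicated(ids))
  if (length(dup))
    stop("duplicate protein id at line(s) ",
         paste(dup + 1L, collapse = ", "), ": ",
         paste(unique(ids[dup]), collapse = ", "))
  v <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(v) <- "double"
  neg <- which(apply(v, 1L, function(r) any(!is.na(r) & r < 0)))
  if (length(neg))
    stop("validation error: negative abundance at line(s) ",
         paste(neg + 1L, collapse = ", "))
  rownames(v) <- ids
  abundance_matrix(v, samples,
                   gene_symbols = df[[schema$gene_symbol]],
                   n_unique_peptides = df[[schema$n_unique_peptides]])
}

#' Write an abundance matrix to TSV
#'
#' Inverse of [read_abundance_matrix()]: writes the matrix TSV and, when
#' `samples_path` is given, the sample-metadata TSV.
#'
#' @param m An `abundance_matrix`.
#' @param path Output matrix TSV path.
#' @param samples_path Optional sample metadata TSV path.
#' @return `path`, invisibly.
#' @export
write_abundance_matrix <- function(m, path, samples_path = NULL) {
  df <- data.frame(protein_id = rownames(m$values),
                   gene_symbol = m$gene_symbols,
                   n_unique_peptides = m$n_unique_peptides,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(m$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(samples_path))
    utils::write.table(m$samples, samples_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Construct a differential table
#'
#' One row per (feature, comparison): log2 fold change plus a significance
#' measure in `[0, 1]` — a Storey q-value for protein comparisons, an
#' adjusted p-value for transcript comparisons. Protein groups listing
#' several gene symbols (separated by `";"`) are split into one record per
#' symbol, each inheriting the group's log2 fold change and significance,
#' so that downstream symbol-keyed mapping (matrisome, interactions,
#' signatures) sees every gene.
#'
#' @param feature_id Feature (protein group or gene) identifiers.
#' @param gene_symbol Gene symbols; `";"`-separated lists are split.
#' @param log2fc Log2 fold changes (finite).
#' @param significance q-values / adjusted p-values in `[0, 1]` (`NA`
#'   allowed for untestable features).
#' @param comparison_id Label of the two-group contrast.
#' @param species Passed to [normalize_symbols()].
#' @param split Split multi-symbol groups? Default `TRUE`.
#' @return A data frame of class `differential_table`.
#' @export
differential_table <- function(feature_id, gene_symbol, log2fc, significance,
                               comparison_id, species = "mouse", split = TRUE) {
  df <- data.frame(feature_id = as.character(feature_id),
                   gene_symbol = as.character(gene_symbol),
                   log2fc = as.numeric(log2fc),
                   significance = as.numeric(significance),
                   comparison_id = as.character(comparison_id),
                   stringsAsFactors = FALSE)
  if (split && nrow(df)) {
    parts <- strsplit(df$gene_symbol, ";", fixed = TRUE)
    n <- lengths(parts)
    n[n == 0L] <- 1L
    parts[lengths(parts) == 0L] <- list("")
    df <- df[rep(seq_len(nrow(df)), n), , drop = FALSE]
    df$gene_symbol <- unlist(parts)
    rownames(df) <- NULL
  }
  if (nrow(df)) df$gene_symbol <- normalize_symbols(df$gene_symbol, species)
  class(df) <- c("differential_table", "data.frame")
  validate_differential_table(df)
  df
}

#' Validate a differential table
#'
#' @param t A `differential_table`.
#' @return `t`, invisibly; errors on invariant violations (significance
#'   outside `[0, 1]`, non-finite log2fc, duplicate feature/comparison).
#' @export
validate_differential_table <- function(t) {
  if (!nrow(t)) return(invisible(t))
  s <- t$significance
  if (any(!is.na(s) & (s < 0 | s > 1)))
    stop("validation error: significance outside [0, 1]")
  if (any(!is.finite(t$log2fc)))
    stop("validation error: non-finite log2fc")
  key <- paste(t$feature_id, t$gene_symbol, t$comparison_id)
  if (anyDuplicated(key))
    stop("validation error: duplicated (feature, comparison) records")
  invisible(t)
}

#' Read a differential table from TSV/CSV
#'
#' Consumes Spectronaut/DESeq2-style exports via a configurable column
#' mapping. Multi-symbol protein groups are split per record (see
#' [differential_table()]); symbols are species-normalized.
#'
#' @param path File path (tab- or comma-separated, inferred from extension).
#' @param comparison_id Contrast label to stamp on every record.
#' @param schema Named list with entries `feature_id`, `gene_symbol`,
#'   `log2fc`, `significance` naming the file's columns.
#' @param species Symbol casing convention.
#' @return A `differential_table`. An empty file yields an empty table with
#'   a warning.
#' @export
read_differential_table <- function(path, comparison_id,
                                    schema = list(feature_id = "feature_id",
                                                  gene_symbol = "gene_symbol",
                                                  log2fc = "log2fc",
                                                  significance = "significance"),
                                    species = "mouse") {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(unlist(schema), names(df))
  if (length(miss))
    stop("schema error: missing columns ", paste(miss, collapse = ", "))
  if (!nrow(df)) {
    warning("empty differential table: ", path)
    return(differential_table(character(), character(), numeric(), numeric(),
                              comparison_id = character(), species = species))
  }
  differential_table(df[[schema$feature_id]], df[[schema$gene_symbol]],
                     df[[schema$log2fc]], df[[schema$significance]],
                     comparison_id = comparison_id, species = species)
}

#' Write a differential table to TSV
#'
#' @param t A `differential_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential_table <- function(t, path) {
  utils::write.table(as.data.frame(t), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a signature set
#'
#' Named gene sets (cell types or pathways) with source provenance, the
#' in-memory form of a GMT file.
#'
#' @param sets Named list of character vectors (gene symbols). Duplicate
#'   genes within a set are collapsed.
#' @param sources Character vector of source labels, one per set (recycled).
#' @param level One of `"extended"`, `"combined"`, `"pathway"`.
#' @return Object of class `signature_set`: a named list with elements
#'   `list(genes, source)` and a `level` attribute.
#' @export
signature_set <- function(sets, sources = "unspecified",
                          level = c("pathway", "extended", "combined")) {
  level <- match.arg(level)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set needs a nonempty name")
  if (anyDuplicated(names(sets)))
    stop("duplicate set names within one level")
  sources <- rep_len(as.character(sources), length(sets))
  out <- mapply(function(g, s) {
    g <- unique(as.character(g))
    if (!length(g)) stop("empty gene set")
    list(genes = g, source = s)
  }, sets, sources, SIMPLIFY = FALSE)
  structure(out, class = "signature_set", level = level)
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set (%s): %d sets, median size %d\n",
              attr(x, "level"), length(x),
              as.integer(stats::median(lengths(lapply(x, `[[`, "genes"))))))
  invisible(x)
}

#' Extract the gene vectors of a signature set
#'
#' @param sig A `signature_set`.
#' @return Named list of character vectors.
#' @export
signature_genes <- function(sig) lapply(sig, `[[`, "genes")

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, `name<TAB>description<TAB>gene...`.
#' The description field is used as the source label. Duplicate genes within
#' a set are collapsed.
#'
#' @param path GMT file path.
#' @param level Signature level to stamp on the set.
#' @return A `signature_set`.
#' @export
read_gene_sets <- function(path, level = "pathway") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, function(f) length(f) < 3L || !nzchar(f[1L]), TRUE))
  if (length(bad))
    stop("malformed GMT line(s): ", paste(bad, collapse = ", "))
  nm <- vapply(fields, `[[`, "", 1L)
  src <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  names(sets) <- nm
  signature_set(sets, sources = src, level = level)
}

#' Write gene sets to a GMT file
#'
#' @param sig A `signature_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sig, path) {
  lines <- vapply(names(sig), function(nm) {
    paste(c(nm, sig[[nm]]$source, sig[[nm]]$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

MATRISOME_CATEGORIES <- c("collagens", "glycoproteins", "proteoglycans",
                          "ECM regulators", "secreted factors", "ECM-affiliated")

#' Construct a matrisome annotation table
#'
#' Gene-level annotation emulating a matrisome reference: division
#' (`core` / `associated` / `none`), category (collagens, glycoproteins,
#' proteoglycans, ECM regulators, secreted factors, ECM-affiliated, or
#' `none`), a colon-matrisome membership flag, and a GO extracellular flag.
#'
#' @param df Data frame with columns `gene_symbol`, `matrisome_division`,
#'   `matrisome_category`, `colon_matrisome`, `extracellular_go`.
#' @return Data frame of class `annotation_db`.
#' @export
annotation_db <- function(df) {
  need <- c("gene_symbol", "matrisome_division", "matrisome_category",
            "colon_matrisome", "extracellular_go")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$colon_matrisome <- as.logical(df$colon_matrisome)
  df$extracellular_go <- as.logical(df$extracellular_go)
  if (anyDuplicated(df$gene_symbol)) stop("duplicate gene symbols in annotation")
  if (!all(df$matrisome_division %in% c("core", "associated", "none")))
    stop("unknown matrisome division")
  if (!all(df$matrisome_category %in% c(MATRISOME_CATEGORIES, "none")))
    stop("unknown matrisome category")
  # division and category are none together or not at all
  if (any((df$matrisome_division == "none") != (df$matrisome_category == "none")))
    stop("division == 'none' iff category == 'none' violated")
  if (any(df$colon_matrisome & df$matrisome_division == "none"))
    stop("colon-matrisome genes must have a matrisome division")
  class(df) <- c("annotation_db", "data.frame")
  df
}

#' Matrisomal genes of an annotation table
#'
#' @param ann An `annotation_db`.
#' @param colon_only Restrict to the colon-matrisome subset?
#' @return Character vector of gene symbols.
#' @export
matrisomal_genes <- function(ann, colon_only = FALSE) {
  keep <- ann$matrisome_division != "none"
  if (colon_only) keep <- keep & ann$colon_matrisome
  ann$gene_symbol[keep]
}

#' Read a matrisome annotation TSV
#'
#' Expected columns: `gene_symbol`, `matrisome_division`,
#' `matrisome_category`, `colon_matrisome`, `extracellular_go`.
#'
#' @param path TSV path.
#' @return An `annotation_db`.
#' @export
read_annotation_db <- function(path) {
  annotation_db(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a matrisome annotation TSV
#' @param ann An `annotation_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_db <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a ligand-receptor interaction set
#'
#' Directed ligand-to-receptor pairs plus a protein-type lookup, emulating a
#' curated cell-cell interaction resource.
#'
#' @param pairs Data frame with columns `ligand`, `receptor` (no duplicates).
#' @param protein_type Named character vector mapping symbols to `"ligand"`,
#'   `"receptor"` or `"other"`; must type every pair endpoint consistently.
#' @return Object of class `interaction_db`.
#' @export
interaction_db <- function(pairs, protein_type) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(pairs)))
    stop("pairs need 'ligand' and 'receptor' columns")
  pairs <- pairs[, c("ligand", "receptor")]
  if (anyDuplicated(paste(pairs$ligand, pairs$receptor)))
    stop("duplicate interaction pairs")
  pt <- protein_type
  if (is.null(names(pt))) stop("protein_type must be a named vector")
  if (!all(pt %in% c("ligand", "receptor", "other")))
    stop("protein types must be ligand/receptor/other")
  bad_l <- setdiff(pairs$ligand, names(pt)[pt == "ligand"])
  if (length(bad_l))
    stop("pair ligands not typed as ligand: ", paste(utils::head(bad_l, 5L), collapse = ", "))
  bad_r <- setdiff(pairs$receptor, names(pt)[pt == "receptor"])
  if (length(bad_r))
    stop("pair receptors not typed as receptor: ", paste(utils::head(bad_r, 5L), collapse = ", "))
  structure(list(pairs = pairs, protein_type = pt), class = "interaction_db")
}

#' @export
print.interaction_db <- function(x, ...) {
  cat(sprintf("interaction_db: %d pairs, %d ligands, %d receptors\n",
              nrow(x$pairs), length(unique(x$pairs$ligand)),
              length(unique(x$pairs$receptor))))
  invisible(x)
}

#' Read an interaction set from two TSVs
#'
#' @param pairs_path TSV with columns `ligand`, `receptor`.
#' @param types_path TSV with columns `gene_symbol`, `protein_type`.
#' @return An `interaction_db`.
#' @export
read_interaction_db <- function(pairs_path, types_path) {
  pairs <- utils::read.delim(pairs_path, stringsAsFactors = FALSE)
  types <- utils::read.delim(types_path, stringsAsFactors = FALSE)
  interaction_db(pairs, stats::setNames(types$protein_type, types$gene_symbol))
}

#' Write an interaction set to two TSVs
#'
#' @param db An `interaction_db`.
#' @param pairs_path Output pairs TSV.
#' @param types_path Output protein-type TSV.
#' @return `pairs_path`, invisibly.
#' @export
write_interaction_db <- function(db, pairs_path, types_path) {
  utils::write.table(db$pairs, pairs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(gene_symbol = names(db$protein_type),
               protein_type = unname(db$protein_type),
               stringsAsFactors = FALSE),
    types_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pairs_path)
}
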