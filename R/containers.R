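#' Exon-by-sample expression container
#'
#' Bundles a log2 exon expression matrix with its sample design and the
#' exon-to-gene map. All pipeline preprocessing steps consume and return this
#' container.
#'
#' @param values Numeric matrix, exons in rows (rownames = exon ids), samples
#'   in columns (colnames = sample ids), log2 scale.
#' @param design Tibble with one row per sample: `sample_id`, `stage`, `sex`,
#'   `replicate`, `tissue`.
#' @param exon_map Tibble with one row per exon: `exon_id`, `gene_id`,
#'   `constitutive` (logical), `splice_group` (integer id shared by
#'   facultative exons with the same isoform-presence pattern, `NA` for
#'   constitutive exons).
#' @return An object of class `exon_matrix`.
#' @export
exon_matrix <- function(values, design, exon_map) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  design <- as_tibble(design)
  exon_map <- as_tibble(exon_map)
  if (!setequal(colnames(values), design$sample_id)) {
    stopf("matrix columns and design sample_ids differ")
  }
  if (!all(rownames(values) %in% exon_map$exon_id)) {
    stopf("every matrix row must appear in exon_map")
  }
  values <- values[, design$sample_id, drop = FALSE]
  structure(list(values = values, design = design, exon_map = exon_map),
            class = "exon_matrix")
}

#' @export
print.exon_matrix <- function(x, ...) {
  cat(sprintf("<exon_matrix> %d exons x %d samples (%d genes)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$exon_map$gene_id[x$exon_map$exon_id %in% rownames(x$values)]))))
  invisible(x)
}

#' Node-by-sample feature container
#'
#' Holds the decomposed features of the pipeline: one *transcription node*
#' per gene (constitutive-exon log2 signal), one *splicing node* per
#' facultative exon group (splicing ratio in \[0, 1\]), and, after
#' [collapse_ccres()], *CCRE* nodes representing groups of near-identical
#' features.
#'
#' @param values Numeric matrix, nodes x samples.
#' @param design Sample design tibble (see [exon_matrix()]).
#' @param nodes Tibble with one row per node: `node_id`, `kind`
#'   (`"transcription"`, `"splicing"` or `"ccre"`), `gene_id` (representative
#'   gene), `genes` (list-column of all member genes) and `members`
#'   (list-column of collapsed node ids, for CCREs).
#' @return An object of class `node_matrix`.
#' @export
node_matrix <- function(values, design, nodes) {
  stopifnot(is.matrix(values))
  nodes <- as_tibble(nodes)
  stopifnot(all(c("node_id", "kind", "gene_id") %in% names(nodes)))
  if (!"genes" %in% names(nodes)) nodes$genes <- as.list(nodes$gene_id)
  if (!"members" %in% names(nodes)) nodes$members <- as.list(nodes$node_id)
  stopifnot(nrow(values) == nrow(nodes))
  rownames(values) <- nodes$node_id
  design <- as_tibble(design)
  values <- values[, design$sample_id, drop = FALSE]
  structure(list(values = values, design = design, nodes = nodes),
            class = "node_matrix")
}

#' @export
print.node_matrix <- function(x, ...) {
  kind <- table(factor(x$nodes$kind, c("transcription", "splicing", "ccre")))
  cat(sprintf("<node_matrix> %d nodes x %d samples (%d transcription, %d splicing, %d ccre)\n",
              nrow(x$values), ncol(x$values), kind[1], kind[2], kind[3]))
  invisible(x)
}

# restrict a node_matrix to a sample subset (keeps design in step)
subset_samples <- function(nm, sample_ids) {
  nm$design <- dplyr::filter(nm$design, .data$sample_id %in% sample_ids)
  nm$values <- nm$values[, nm$design$sample_id, drop = FALSE]
  nm
}

# whole-body samples only (tissue == "whole")
whole_body <- function(nm) {
  subset_samples(nm, nm$design$sample_id[nm$design$tissue == "whole"])
}

#' Feature composition of a node set
#'
#' Counts transcription, splicing and CCRE features and the percentage each
#' contributes to the final feature set (integer-rounded, as conventionally
#' reported).
#'
#' @param nodes A `node_matrix` or its `nodes` tibble.
#' @return A tibble with columns `kind`, `n`, `percent`.
#' @export
feature_composition <- function(nodes) {
  tbl <- if (inherits(nodes, "node_matrix")) nodes$nodes else as_tibble(nodes)
  out <- dplyr::count(tbl, kind = factor(.data$kind, c("transcription", "splicing", "ccre")),
                      .drop = FALSE)
  out$percent <- round(100 * out$n / sum(out$n))
  out
}

# ---- plain-text IO ----------------------------------------------------------

#' Read and write pipeline tables
#'
#' Tab-delimited readers/writers for the formats the pipeline exchanges:
#' an expression matrix (features x samples with a header row of sample ids),
#' the sample design, and gene-model/annotation tables.
#'
#' @param x Object to write.
#' @param path File path.
#' @name sexbiasnet-io
NULL

#' @rdname sexbiasnet-io
#' @export
write_matrix_tsv <- function(x, path) {
  df <- tibble::rownames_to_column(as.data.frame(x), "feature_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname sexbiasnet-io
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname sexbiasnet-io
#' @param dir Output directory (created if missing).
#' @export
write_dataset <- function(x, dir) {
  stopifnot(inherits(x, "exon_matrix") || inherits(x, "node_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(x$values, file.path(dir, "values.tsv"))
  readr::write_tsv(x$design, file.path(dir, "design.tsv"))
  ann <- if (inherits(x, "exon_matrix")) x$exon_map else
    dplyr::select(x$nodes, -dplyr::any_of(c("genes", "members")))
  readr::write_tsv(ann, file.path(dir, "features.tsv"))
  invisible(dir)
}

#' @rdname sexbiasnet-io
#' @param kind `"exon"` or `"node"`.
#' @export
read_dataset <- function(dir, kind = c("exon", "node")) {
  kind <- match.arg(kind)
  values <- read_matrix_tsv(file.path(dir, "values.tsv"))
  design <- readr::read_tsv(file.path(dir, "design.tsv"), show_col_types = FALSE)
  feats <- readr::read_tsv(file.path(dir, "features.tsv"), show_col_types = FALSE)
  if (kind == "exon") exon_matrix(values, design, feats) else
    node_matrix(values, design, feats)
}
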