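#' Collapse low expression values to zero
#'
#' Applies the experiment-wide expression floor: every value strictly below
#' the given percentile of *all* values in the matrix is set to 0, removing
#' spurious signal from noise-level variation among non-expressed exons.
#' The percentile uses the inverted-ECDF definition (`quantile type = 1`):
#' the threshold is always an observed value, so values equal to the
#' threshold are kept. The cut is quantile-definition-sensitive, hence fixed
#' here.
#'
#' @param x An [exon_matrix()].
#' @param percentile Floor percentile in (0, 100); default 66.
#' @return The floored `exon_matrix`.
#' @export
apply_expression_floor <- function(x, percentile = 66) {
  stopifnot(inherits(x, "exon_matrix"))
  if (length(x$values) == 0) stopf("empty expression matrix")
  if (percentile <= 0 || percentile >= 100) stopf("percentile must be in (0, 100)")
  thr <- quantile(x$values, percentile / 100, type = 1, names = FALSE)
  x$values[x$values < thr] <- 0
  x
}

#' Keep exons detected consistently in at least one condition
#'
#' Retains exons with above-floor (positive) signal in at least `min_reps`
#' replicates of at least one biological condition (a stage x sex x tissue
#' cell). Genes left without any surviving exon are dropped entirely.
#'
#' @param x An [exon_matrix()] (normally after [apply_expression_floor()]).
#' @param min_reps Minimum replicates with signal; default 2 ("two out of
#'   three").
#' @return The filtered `exon_matrix`.
#' @export
filter_detected <- function(x, min_reps = 2) {
  stopifnot(inherits(x, "exon_matrix"))
  cell <- interaction(x$design$stage, x$design$sex, x$design$tissue, drop = TRUE)
  if (min_reps > max(table(cell))) {
    stopf("min_reps (%d) exceeds the available replication", min_reps)
  }
  detected <- x$values > 0
  # per cell, count replicates with signal; keep exon if any cell >= min_reps
  hits <- vapply(levels(cell), function(cc) {
    rowSums(detected[, cell == cc, drop = FALSE]) >= min_reps
  }, logical(nrow(x$values)))
  keep <- rownames(x$values)[rowSums(hits) > 0]
  x$values <- x$values[keep, , drop = FALSE]
  x$exon_map <- dplyr::filter(x$exon_map, .data$exon_id %in% keep)
  x
}

#' Decompose exons into transcription and splicing nodes
#'
#' Builds the node-level feature set: per gene one *transcription node*
#' (mean log2 signal of its constitutive exons) and one *splicing node* per
#' facultative exon group. Splicing values are splicing ratios — the
#' facultative group's mean linear signal divided by the gene's mean
#' constitutive linear signal, clamped to \[0, 1\] — so they estimate the
#' fraction of the gene's transcripts carrying that exon group,
#' decorrelated from overall transcription level. Samples where the gene
#' total is zero get ratio 0.
#'
#' @param x A filtered [exon_matrix()].
#' @param models A `gene_models` object (or any tibble with `gene_id`,
#'   `exon_id`, `constitutive`, `splice_group`); annotation is the authority
#'   on which exons are constitutive.
#' @return A [node_matrix()] of transcription and splicing nodes.
#' @export
decompose_nodes <- function(x, models) {
  stopifnot(inherits(x, "exon_matrix"))
  ex <- if (inherits(models, "gene_models")) models$exons else as_tibble(models)
  ex <- ex[ex$exon_id %in% rownames(x$values), ]
  if (!all(rownames(x$values) %in% ex$exon_id)) {
    stopf("every retained exon must map to a gene model")
  }
  n_s <- ncol(x$values)
  out_vals <- list(); out_info <- list()
  for (g in unique(ex$gene_id)) {
    exg <- ex[ex$gene_id == g, ]
    con <- exg$exon_id[exg$constitutive]
    if (!length(con)) {
      warnf("gene %s has no constitutive exon after filtering; using all-exon mean", g)
      con <- exg$exon_id
    }
    gsig <- colMeans(x$values[con, , drop = FALSE])
    out_vals[[length(out_vals) + 1]] <- gsig
    out_info[[length(out_info) + 1]] <- tibble(
      node_id = paste0(g, "_t"), kind = "transcription", gene_id = g)
    glin <- colMeans(lin(x$values[con, , drop = FALSE]))
    fac <- exg[!exg$constitutive & !is.na(exg$splice_group), ]
    for (sg in unique(fac$splice_group)) {
      fids <- fac$exon_id[fac$splice_group == sg]
      flin <- colMeans(lin(x$values[fids, , drop = FALSE]))
      ratio <- ifelse(glin > 0, pmin(flin / glin, 1), 0)
      out_vals[[length(out_vals) + 1]] <- ratio
      out_info[[length(out_info) + 1]] <- tibble(
        node_id = sprintf("%s_s%d", g, sg), kind = "splicing", gene_id = g)
    }
  }
  vals <- do.call(rbind, out_vals)
  info <- bind_rows(out_info)
  rownames(vals) <- info$node_id
  node_matrix(vals, x$design, info)
}

#' Collapse near-identical nodes into CCREs
#'
#' Groups nodes whose pairwise Pearson correlation exceeds `threshold` into
#' Constitutively Correlated Regulatory Events (CCREs) and replaces each
#' group by a single representative feature. Grouping is, by default, the
#' connected components of the above-threshold correlation graph
#' (single-linkage, `collapseRows`-style); `grouping = "clique"` instead
#' requires every within-group pair to exceed the threshold. The
#' representative is the member with the most above-threshold links inside
#' its group; for two-member groups, the member with the higher mean value.
#' Non-grouped nodes pass through unchanged. CCREs may span genes; the
#' gene-level roll-ups downstream attribute a CCRE's bias to all member
#' genes.
#'
#' @param nodes A [node_matrix()] with at least 3 samples.
#' @param threshold Correlation threshold in (0, 1); default 0.95.
#' @param grouping `"component"` (default) or `"clique"`.
#' @return A list: `nodes` (collapsed [node_matrix()]) and `ccre_map`
#'   (tibble `ccre_id`, `member` node ids, `representative`, `rule`).
#' @export
collapse_ccres <- function(nodes, threshold = 0.95,
                           grouping = c("component", "clique")) {
  stopifnot(inherits(nodes, "node_matrix"))
  grouping <- match.arg(grouping)
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  if (ncol(nodes$values) < 3) stopf("collapsing needs at least 3 samples")
  v <- nodes$values
  keep_sd <- apply(v, 1, sd) > 0
  r <- matrix(-Inf, nrow(v), nrow(v))
  if (any(keep_sd)) {
    r[keep_sd, keep_sd] <- suppressWarnings(cor(t(v[keep_sd, , drop = FALSE])))
  }
  diag(r) <- -Inf
  adj <- r > threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
  comp <- igraph::components(g)$membership
  groups <- split(seq_len(nrow(v)), comp)
  groups <- groups[lengths(groups) >= 2]
  if (grouping == "clique") groups <- split_into_cliques(groups, adj)

  if (!length(groups)) {
    return(list(nodes = nodes,
                ccre_map = tibble(ccre_id = character(), member = character(),
                                  representative = character(), rule = character())))
  }
  drop <- integer(); new_vals <- list(); new_info <- list(); map <- list()
  node_ids <- nodes$nodes$node_id
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    if (length(idx) == 2) {
      rep_i <- idx[which.max(rowMeans(v[idx, , drop = FALSE]))]
      rule <- "highest_mean"
    } else {
      links <- rowSums(adj[idx, idx, drop = FALSE])
      cand <- idx[links == max(links)]
      rep_i <- cand[which.max(rowMeans(v[cand, , drop = FALSE]))]
      rule <- "most_links"
    }
    ccre_id <- sprintf("CCRE_%04d", k)
    drop <- c(drop, idx)
    new_vals[[k]] <- v[rep_i, ]
    member_genes <- unique(nodes$nodes$gene_id[idx])
    new_info[[k]] <- tibble(
      node_id = ccre_id, kind = "ccre",
      gene_id = nodes$nodes$gene_id[rep_i],
      genes = list(member_genes), members = list(node_ids[idx]),
      rep_kind = nodes$nodes$kind[rep_i])
    map[[k]] <- tibble(ccre_id = ccre_id, member = node_ids[idx],
                       representative = node_ids[rep_i], rule = rule)
  }
  keep <- setdiff(seq_len(nrow(v)), drop)
  info_keep <- nodes$nodes[keep, ]
  if (!"rep_kind" %in% names(info_keep)) info_keep$rep_kind <- info_keep$kind
  if (!"genes" %in% names(info_keep)) info_keep$genes <- as.list(info_keep$gene_id)
  if (!"members" %in% names(info_keep)) info_keep$members <- as.list(info_keep$node_id)
  info <- bind_rows(info_keep, bind_rows(new_info))
  vals <- rbind(v[keep, , drop = FALSE], do.call(rbind, new_vals))
  list(nodes = node_matrix(vals, nodes$design, info),
       ccre_map = bind_rows(map))
}

# greedy partition of each connected component into all-pairs cliques
split_into_cliques <- function(groups, adj) {
  out <- list()
  for (idx in groups) {
    left <- idx
    while (length(left) >= 2) {
      seed <- left[which.max(colSums(adj[left, left, drop = FALSE]))]
      clique <- seed
      for (j in setdiff(left, seed)) {
        if (all(adj[j, clique])) clique <- c(clique, j)
      }
      if (length(clique) >= 2) out[[length(out) + 1]] <- clique
      left <- setdiff(left, clique)
    }
  }
  out
}
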