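#' Weighted co-expression adjacency
#'
#' Builds the soft-thresholded unsigned adjacency `a_ij = |cor(x_i, x_j)|^beta`
#' from node values, using the robust correlation of [cor_nodes()]. Raising
#' the correlation to a power suppresses weak links relative to strong ones;
#' the diagonal is excluded from all downstream sums.
#'
#' @param nodes A [node_matrix()].
#' @param beta Soft power (positive integer).
#' @param sample_subset Optional vector of sample ids to restrict to (e.g.
#'   the whole-body samples, or a subnetwork's retained samples).
#' @param method Correlation flavour, see [cor_nodes()].
#' @return An `adjacency` object: list with the weight matrix `a`, `beta`
#'   and the correlation `method`.
#' @export
correlation_adjacency <- function(nodes, beta = 6, sample_subset = NULL,
                                  method = c("bicor", "pearson")) {
  stopifnot(inherits(nodes, "node_matrix"))
  method <- match.arg(method)
  if (beta < 1 || beta != round(beta)) stopf("beta must be a positive integer")
  v <- nodes$values
  if (!is.null(sample_subset)) v <- v[, sample_subset, drop = FALSE]
  if (ncol(v) < 3) stopf("adjacency needs at least 3 samples")
  r <- cor_nodes(v, method)
  a <- abs_pow(r, beta)
  diag(a) <- 0
  structure(list(a = a, beta = as.integer(beta), method = method),
            class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf("<adjacency> %d nodes, beta = %d (%s), mean weight %.4f\n",
              nrow(x$a), x$beta, x$method,
              mean(x$a[upper.tri(x$a)])))
  invisible(x)
}

#' Scale-free fit of a degree sequence
#'
#' Linear fit of `log10(frequency)` against `log10(k)` over equal-width
#' degree bins; a scale-free (power-law) degree distribution gives a good
#' straight-line fit with negative slope.
#'
#' @param k Vector of (weighted) node degrees.
#' @param n_breaks Number of degree bins.
#' @return List with `r_squared` and `slope`.
#' @export
scale_free_fit <- function(k, n_breaks = 10) {
  cut_k <- cut(k, n_breaks)
  dk <- tapply(k, cut_k, mean)
  pk <- tapply(k, cut_k, length) / length(k)
  keep <- !is.na(dk) & !is.na(pk) & dk > 0
  if (sum(keep) < 3) return(list(r_squared = 0, slope = 0))
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  list(r_squared = summary(fit)$r.squared, slope = unname(coef(fit)[2]))
}

#' Select the soft power by the scale-free topology criterion
#'
#' Scans candidate powers and returns the lowest one whose soft-thresholded
#' degree distribution fits a power law (`R^2 >=` `r2_target` with negative
#' slope). If no candidate reaches the target, the power with the best fit
#' is returned with a warning.
#'
#' @param nodes A [node_matrix()].
#' @param candidate_betas Candidate powers (default 1..30).
#' @param r2_target Required fit; default 0.8.
#' @param sample_subset,method Passed to the correlation step.
#' @return The selected power (integer), with the scan table in attribute
#'   `"scan"`.
#' @export
select_soft_power <- function(nodes, candidate_betas = 1:30, r2_target = 0.8,
                              sample_subset = NULL, method = c("bicor", "pearson")) {
  stopifnot(length(candidate_betas) >= 2)
  method <- match.arg(method)
  v <- nodes$values
  if (!is.null(sample_subset)) v <- v[, sample_subset, drop = FALSE]
  r <- abs(cor_nodes(v, method))
  diag(r) <- 0
  scan <- purrr::map_dfr(sort(as.integer(candidate_betas)), function(b) {
    k <- rowSums(abs_pow(r, b))
    ft <- scale_free_fit(k)
    tibble(beta = b, r_squared = ft$r_squared, slope = ft$slope, mean_k = mean(k))
  })
  hit <- scan$beta[scan$r_squared >= r2_target & scan$slope < 0]
  if (length(hit)) {
    sel <- hit[1]
  } else {
    warnf("no candidate power reached R^2 >= %.2f; returning the best fit", r2_target)
    sel <- scan$beta[which.max(scan$r_squared)]
  }
  attr(sel, "scan") <- scan
  sel
}

#' Assign nodes to co-expression clusters
#'
#' `method = "tom-hierarchical"` computes the topological-overlap
#' dissimilarity of the adjacency, clusters it by average-linkage
#' hierarchical clustering, and cuts the tree at a fixed height; clusters
#' below `min_size` fall into the unassigned (`"grey"`) label. Cluster
#' labels are colour-style names ordered by decreasing cluster size, the
#' field's convention. `method = "provided"` passes externally supplied
#' labels through unchanged (used when subnetworks must reuse the main
#' network's assignment).
#'
#' @param adj An `adjacency` from [correlation_adjacency()].
#' @param method `"tom-hierarchical"` or `"provided"`.
#' @param labels For `method = "provided"`: tibble (`node_id`, `cluster`)
#'   covering every node.
#' @param cut_height Tree cut height on the TOM dissimilarity (0..1).
#' @param min_size Minimum cluster size; smaller groups become `"grey"`.
#' @return A `cluster_model`: tibble (`node_id`, `cluster`) with attributes
#'   `method` and (for tom-hierarchical) the cut parameters.
#' @export
detect_clusters <- function(adj, method = c("tom-hierarchical", "provided"),
                            labels = NULL, cut_height = 0.98, min_size = 5) {
  method <- match.arg(method)
  ids <- rownames(adj$a) %||% as.character(seq_len(nrow(adj$a)))
  if (method == "provided") {
    labels <- as_tibble(labels)
    if (!all(ids %in% labels$node_id)) stopf("provided labels must cover every node")
    out <- tibble(node_id = ids,
                  cluster = labels$cluster[match(ids, labels$node_id)])
    attr(out, "method") <- "provided"
    return(out)
  }
  tom <- tom_dissimilarity(adj$a)
  tree <- hclust(as.dist(tom), method = "average")
  raw <- cutree(tree, h = cut_height)
  sizes <- sort(table(raw), decreasing = TRUE)
  keep <- names(sizes)[sizes >= min_size]
  pal <- cluster_palette(length(keep))
  lab <- rep("grey", length(raw))
  for (i in seq_along(keep)) lab[raw == keep[i]] <- pal[i]
  out <- tibble(node_id = ids, cluster = lab)
  attr(out, "method") <- "tom-hierarchical"
  attr(out, "cut_height") <- cut_height
  attr(out, "min_size") <- min_size
  out
}

# unsigned topological overlap dissimilarity
tom_dissimilarity <- function(a) {
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  1 - tom
}

cluster_palette <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue", "darkred", "darkgreen", "darkturquoise",
            "darkgrey", "orange", "darkorange", "white", "skyblue", "saddlebrown",
            "steelblue", "paleturquoise", "violet", "darkolivegreen", "darkmagenta")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("module%03d", seq_len(n - length(base))))
}

#' Within-cluster node topology: degree, density, clustering, hub score
#'
#' For each node, computed against the other members of its own cluster:
#' the weighted degree `k_i = sum_j a_ij`; the connection density
#' `Kd_i = k_i / (N - 1)` (degree normalised by its maximum, so `Kd` lies in
#' \[0, 1\]); the weighted clustering coefficient
#' `CC_i = sum_{j != k} a_ij a_jk a_ki / ((sum_j a_ij)^2 - sum_j a_ij^2)`
#' (the interconnectedness of `i`'s neighbourhood); and the hub score
#' `Hub_i = Kd_i * (1 - CC_i)`, which rewards nodes whose many neighbours
#' are otherwise unconnected (regulator archetype) and penalises members of
#' tight cliques (interactor archetype). `Hub_i <= Kd_i` always.
#'
#' @param adj An `adjacency` over all nodes.
#' @param clusters A cluster label tibble (`node_id`, `cluster`).
#' @return Tibble: `node_id`, `cluster`, `degree`, `density`,
#'   `clustering_coef`, `hub_score`, `flag` (`"ok"`, `"small_cluster"`).
#' @export
node_topology <- function(adj, clusters) {
  clusters <- as_tibble(clusters)
  ids <- rownames(adj$a)
  stopifnot(all(ids %in% clusters$node_id))
  lab <- clusters$cluster[match(ids, clusters$node_id)]
  out <- vector("list", length(unique(lab)))
  for (ci in seq_along(unique(lab))) {
    cl <- unique(lab)[ci]
    idx <- which(lab == cl)
    n <- length(idx)
    if (n < 2) {
      out[[ci]] <- tibble(node_id = ids[idx], cluster = cl, degree = NA_real_,
                          density = NA_real_, clustering_coef = NA_real_,
                          hub_score = NA_real_, flag = "small_cluster")
      next
    }
    a <- adj$a[idx, idx, drop = FALSE]
    k <- rowSums(a)
    kd <- k / (n - 1)
    if (n < 3) {
      cc <- rep(0, n)
    } else {
      num <- diag(a %*% a %*% a)
      den <- k^2 - rowSums(a^2)
      cc <- ifelse(den > 1e-300, num / den, 0)
      cc <- pmin(pmax(cc, 0), 1)
    }
    out[[ci]] <- tibble(node_id = ids[idx], cluster = cl, degree = unname(k),
                        density = unname(kd), clustering_coef = unname(cc),
                        hub_score = unname(kd * (1 - cc)), flag = "ok")
  }
  res <- bind_rows(out)
  res[match(ids, res$node_id), ]
}

#' Per-cluster topology statistics
#'
#' Summarises each cluster of the network: size; density (mean off-diagonal
#' within-cluster weight); centralization `(N/(N-2)) * (max Kd - density)`;
#' heterogeneity (coefficient of variation of the degrees); median
#' clustering coefficient; diameter (longest shortest path under the
#' distance `d = 1 - a`, within the cluster); and the cluster's proportion
#' of splicing nodes and of nodes from duplicated genes, each normalised by
#' the corresponding network-wide proportion (1 = at the network average).
#'
#' @param adj An `adjacency` over all nodes.
#' @param clusters Cluster labels (`node_id`, `cluster`).
#' @param nodes The [node_matrix()] (provides node kinds and gene ids).
#' @param models Optional `gene_models` (or genes tibble with `gene_id`,
#'   `paralog_family`); needed for the duplicated-gene proportion.
#' @return Tibble: one row per cluster with the statistics above and a
#'   `flag` column (`"small_cluster"` when size < 3: diameter and
#'   centralization are `NA`).
#' @export
cluster_topology <- function(adj, clusters, nodes, models = NULL) {
  clusters <- as_tibble(clusters)
  ids <- rownames(adj$a)
  lab <- clusters$cluster[match(ids, clusters$node_id)]
  info <- nodes$nodes[match(ids, nodes$nodes$node_id), ]
  kind <- if ("rep_kind" %in% names(info)) {
    ifelse(info$kind == "ccre", info$rep_kind, info$kind)
  } else info$kind
  is_splice <- kind == "splicing"
  dup <- rep(FALSE, length(ids))
  if (!is.null(models)) {
    genes <- if (inherits(models, "gene_models")) models$genes else as_tibble(models)
    fam_sizes <- table(genes$paralog_family)
    dup_genes <- genes$gene_id[fam_sizes[genes$paralog_family] >= 2]
    dup <- purrr::map_lgl(info$genes, ~ any(.x %in% dup_genes))
  }
  net_splice <- mean(is_splice)
  net_dup <- mean(dup)

  purrr::map_dfr(unique(lab), function(cl) {
    idx <- which(lab == cl)
    n <- length(idx)
    a <- adj$a[idx, idx, drop = FALSE]
    k <- rowSums(a)
    dens <- if (n >= 2) mean(a[upper.tri(a)]) else NA_real_
    het <- if (n >= 2 && mean(k) > 0) sqrt(mean(k^2) / mean(k)^2 - 1) else NA_real_
    if (n >= 3) {
      centr <- (n / (n - 2)) * (max(k / (n - 1)) - dens)
      d <- 1 - a
      d[d <= 0] <- 1e-12  # keep perfect-correlation edges in the graph
      diag(d) <- 0
      g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                               weighted = TRUE, diag = FALSE)
      dmat <- igraph::distances(g)
      diam <- max(dmat[is.finite(dmat)])
      num <- diag(a %*% a %*% a)
      den <- k^2 - rowSums(a^2)
      med_cc <- median(pmin(pmax(ifelse(den > 1e-300, num / den, 0), 0), 1))
      flag <- "ok"
    } else {
      centr <- NA_real_; diam <- NA_real_; med_cc <- NA_real_
      flag <- "small_cluster"
    }
    tibble(cluster = cl, size = n, density = dens, centralization = centr,
           heterogeneity = het, median_cc = med_cc, diameter = diam,
           prop_splicing = if (net_splice > 0) mean(is_splice[idx]) / net_splice else NA_real_,
           prop_duplicated = if (net_dup > 0) mean(dup[idx]) / net_dup else NA_real_,
           flag = flag)
  })
}
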