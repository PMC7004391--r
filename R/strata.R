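#' PCA of cluster topology
#'
#' Centered-and-scaled principal component analysis of the eight cluster
#' topology variables (size, density, centralization, heterogeneity,
#' median clustering coefficient, diameter, and the normalised splicing and
#' duplicated-gene proportions), used to extract the latent independent
#' axes of cluster architecture. Zero-variance variables are dropped with a
#' warning; rows with missing statistics (flagged small clusters) are
#' removed. Sign convention: within each component the largest-magnitude
#' loading is positive.
#'
#' @param topology Result of [cluster_topology()].
#' @return A `topology_pca` object: list with `scores` (tibble, cluster x
#'   PC), `loadings` (tibble, variable x PC), `var_explained` (numeric).
#' @export
pca_cluster_topology <- function(topology) {
  vars <- c("size", "density", "centralization", "heterogeneity",
            "median_cc", "diameter", "prop_splicing", "prop_duplicated")
  vars <- intersect(vars, names(topology))
  m <- as.data.frame(topology[, vars])
  rownames(m) <- topology$cluster
  keep <- complete.cases(m)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2) stopf("PCA needs at least 2 clusters with complete topology")
  sds <- vapply(m, sd, numeric(1))
  if (any(sds == 0)) {
    warnf("dropping zero-variance variable(s): %s",
          paste(names(sds)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(pc$rotation))) {
    if (pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(list(
    scores = bind_cols(tibble(cluster = rownames(m)), as_tibble(pc$x)),
    loadings = bind_cols(tibble(variable = rownames(pc$rotation)),
                         as_tibble(pc$rotation)),
    var_explained = pc$sdev^2 / sum(pc$sdev^2)
  ), class = "topology_pca")
}

#' @export
print.topology_pca <- function(x, ...) {
  cat(sprintf("<topology_pca> %d clusters, %d components (PC1 %.0f%%, PC2 %.0f%%)\n",
              nrow(x$scores), length(x$var_explained),
              100 * x$var_explained[1], 100 * x$var_explained[2]))
  invisible(x)
}

# all subsets of `terms` containing `forced` and respecting marginality
# (an interaction "a:b" may only appear with both its main effects)
enumerate_models <- function(terms, forced = character()) {
  free <- setdiff(terms, forced)
  subsets <- purrr::map(seq_len(2^length(free)) - 1, function(bits) {
    sel <- free[bitwAnd(bits, 2^(seq_along(free) - 1)) > 0]
    c(forced, sel)
  })
  ok <- purrr::map_lgl(subsets, function(s) {
    ints <- s[grepl(":", s)]
    all(purrr::map_lgl(ints, function(i) {
      all(strsplit(i, ":")[[1]] %in% s)
    }))
  })
  subsets[ok]
}

aicc_from_fit <- function(fit, n) {
  ll <- logLik(fit)
  kk <- attr(ll, "df")
  -2 * as.numeric(ll) + 2 * kk + 2 * kk * (kk + 1) / max(n - kk - 1, 1e-9)
}

# shared all-subsets model averaging core; `fitter(formula)` returns a glm
average_models <- function(data, response, terms, forced, fitter) {
  models <- enumerate_models(terms, forced)
  n <- nrow(data)
  fits <- purrr::map(models, function(tm) {
    rhs <- if (length(tm)) paste(tm, collapse = " + ") else "1"
    fitter(stats::as.formula(paste(response, "~", rhs)))
  })
  aicc <- purrr::map_dbl(fits, aicc_from_fit, n = n)
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  coef_names <- unique(unlist(purrr::map(fits, ~ names(coef(.x)))))
  coef_avg <- setNames(numeric(length(coef_names)), coef_names)
  sep_warned <- FALSE
  for (i in seq_along(fits)) {
    cf <- coef(fits[[i]])
    cf <- cf[!is.na(cf)]  # aliased coefficients count as absent (zero)
    coef_avg[names(cf)] <- coef_avg[names(cf)] + w[i] * cf
    if (!sep_warned && any(abs(cf) > 15)) {
      warnf("large coefficients in one candidate model (possible separation)")
      sep_warned <- TRUE
    }
  }
  ri <- purrr::map_dbl(terms, function(tm) {
    sum(w[purrr::map_lgl(models, ~ tm %in% .x)])
  })
  list(
    terms = tibble(term = terms, ri = ri,
                   forced = terms %in% forced),
    coef = tibble(coefficient = coef_names, estimate = unname(coef_avg)),
    models = tibble(model = purrr::map_chr(models, ~ paste(.x, collapse = "+")),
                    aicc = aicc, weight = w)
  )
}

#' Binomial all-subsets model averaging with AICc weights
#'
#' Fits binomial GLMs for every subset of the predictors, ranks them by the
#' small-sample-corrected Akaike criterion (AICc), and reports each
#' predictor's relative importance (RI: the summed Akaike weights of the
#' models containing it) together with weight-averaged coefficients
#' (zero-filled over models omitting the term). Used to ask which principal
#' components of cluster architecture discriminate sex-biased from unbiased
#' clusters; RI above 0.70 is the conventional reporting threshold.
#'
#' @param data Data frame holding the response and predictors.
#' @param response Name of a binary (0/1 or logical) column; both classes
#'   must be present.
#' @param predictors Character vector of predictor columns (at most 10).
#' @param forced Predictors forced into every model (their RI is exactly 1).
#' @return A `model_avg` object: list of tibbles `terms` (term, ri,
#'   forced), `coef`, `models`.
#' @export
model_average_binomial <- function(data, response, predictors,
                                   forced = character()) {
  stopifnot(length(predictors) >= 1, length(predictors) <= 10)
  y <- data[[response]]
  if (length(unique(y[!is.na(y)])) < 2) stopf("response must contain both classes")
  out <- average_models(data, response, predictors, forced, function(fml) {
    suppressWarnings(glm(fml, data = data, family = binomial()))
  })
  structure(out, class = "model_avg")
}

#' @export
print.model_avg <- function(x, ...) {
  cat("<model_avg>", nrow(x$models), "models\n")
  print(dplyr::arrange(x$terms, dplyr::desc(.data$ri)), n = Inf)
  invisible(x)
}

#' Phylostratum fold enrichment by sex-bias class
#'
#' For each bias class and stratum: the proportion of the class's genes in
#' that stratum divided by the genome-wide proportion. A fold of 1.5 means
#' the class holds 50% more genes of that age than expected from the
#' genome-wide average; strata absent genome-wide give `NA`.
#'
#' @param genes Tibble with `gene_id` and `stratum`.
#' @param classes Tibble with `gene_id` and `class` (e.g. `"none"`,
#'   `"DE"`, `"DE+DC"`).
#' @return Tibble: `class`, `stratum`, `n`, `prop`, `genome_prop`, `fold`.
#' @export
stratum_fold_enrichment <- function(genes, classes) {
  genes <- as_tibble(genes)
  genes$stratum <- factor(as.character(genes$stratum), stratum_levels())
  genome <- dplyr::count(genes, .data$stratum, .drop = FALSE)
  genome$genome_prop <- genome$n / sum(genome$n)
  dat <- dplyr::inner_join(genes, as_tibble(classes), by = "gene_id")
  out <- dplyr::count(dplyr::group_by(dat, .data$class), .data$stratum, .drop = FALSE)
  out <- dplyr::mutate(out, prop = .data$n / sum(.data$n))
  out <- dplyr::ungroup(out)
  out <- dplyr::left_join(out, genome[, c("stratum", "genome_prop")], by = "stratum")
  out$fold <- ifelse(out$genome_prop > 0, out$prop / out$genome_prop, NA_real_)
  out
}

#' Gene-age models of node topology
#'
#' Tests whether a gene's phylogenetic stratum predicts its within-cluster
#' connection density and hub score, on their own and in interaction with
#' cluster-level sex bias, via the two gamma/logit GLM formulas
#' `Density ~ ClusterSize + Stratum + DE + DC + Stratum:DE + Stratum:DC`
#' and the same for `HubScore`, each expanded into all marginality-
#' respecting nested models and averaged with AICc weights (ClusterSize is
#' forced into every model, so its RI is exactly 1). DE and DC are
#' cluster-level flags propagated to member nodes; a cluster is annotated
#' DC regardless of its DE status and vice versa. Stratum is an unordered
#' factor with the oldest level (Metazoa) as reference; strata holding
#' fewer than `min_stratum` nodes are merged into the closest older
#' stratum with a warning. Responses are guarded into (0, 1) for the logit
#' link.
#'
#' @param topology Node topology from [node_topology()].
#' @param node_strata Tibble with `node_id` and `stratum`.
#' @param de_clusters,dc_clusters Character vectors of cluster labels with
#'   sex-biased differential expression / correlation.
#' @param restrict Optional character vector of strata to restrict the
#'   analysis to (e.g. the young strata for the finer-scale run).
#' @param min_stratum Minimum nodes per stratum level before merging.
#' @return A `stratum_models` object: list with elements `density` and
#'   `hub_score`, each a `model_avg`-style list, plus the model `data`.
#' @export
fit_strata_models <- function(topology, node_strata, de_clusters, dc_clusters,
                              restrict = NULL, min_stratum = 5) {
  dat <- dplyr::inner_join(
    dplyr::filter(topology, .data$flag == "ok"),
    as_tibble(node_strata), by = "node_id")
  if (!is.null(restrict)) dat <- dat[as.character(dat$stratum) %in% restrict, ]
  sizes <- dplyr::count(dat, .data$cluster)
  dat <- dplyr::left_join(dat, dplyr::rename(sizes, cluster_size = "n"), by = "cluster")
  dat$de <- as.integer(dat$cluster %in% de_clusters)
  dat$dc <- as.integer(dat$cluster %in% dc_clusters)
  dat$stratum <- merge_small_strata(factor(as.character(dat$stratum),
                                           intersect(stratum_levels(),
                                                     unique(as.character(dat$stratum)))),
                                    min_stratum)
  dat$density_y <- guard_unit(dat$density)
  dat$hub_y <- guard_unit(dat$hub_score)
  terms <- c("cluster_size", "stratum", "de", "dc", "stratum:de", "stratum:dc")
  fit_one <- function(resp) {
    average_models(dat, resp, terms, forced = "cluster_size", function(fml) {
      suppressWarnings(glm(fml, data = dat, family = Gamma(link = make.link("logit"))))
    })
  }
  structure(list(density = fit_one("density_y"),
                 hub_score = fit_one("hub_y"),
                 data = dat),
            class = "stratum_models")
}

# merge stratum levels with < min_n nodes into the closest older level
merge_small_strata <- function(stratum, min_n) {
  lev <- levels(stratum)
  repeat {
    counts <- table(stratum)
    small <- names(counts)[counts < min_n]
    if (!length(small) || length(levels(stratum)) == 1) break
    s <- small[1]
    i <- match(s, levels(stratum))
    target <- if (i > 1) levels(stratum)[i - 1] else levels(stratum)[2]
    warnf("merging stratum '%s' (%d nodes) into '%s'", s, counts[s], target)
    levels(stratum)[levels(stratum) == s] <- target
  }
  stratum
}

#' @export
print.stratum_models <- function(x, ...) {
  cat("<stratum_models>\n-- density --\n")
  print(x$density$terms, n = Inf)
  cat("-- hub score --\n")
  print(x$hub_score$terms, n = Inf)
  invisible(x)
}

#' Averaged young-stratum interaction coefficients
#'
#' Convenience accessor summarising, for a fitted [fit_strata_models()]
#' object, the model-averaged interaction coefficients of the young strata
#' (Chalcid, Nasonia) with the DE and DC flags, for each response. Positive
#' density interactions mean young genes are denser in biased clusters than
#' expected from unbiased ones; positive hub interactions mean young genes
#' gain regulatory (bridging) positions.
#'
#' @param x A `stratum_models` object.
#' @return Tibble: `response`, `bias`, `estimate` (mean over young-stratum
#'   interaction coefficients).
#' @export
young_interactions <- function(x) {
  stopifnot(inherits(x, "stratum_models"))
  young <- c("Chalcid", "Nasonia")
  purrr::map_dfr(c(density = "density", hub_score = "hub_score"), function(resp) {
    cf <- x[[resp]]$coef
    purrr::map_dfr(c(de = "de", dc = "dc"), function(b) {
      pat <- paste0("^stratum(", paste(young, collapse = "|"), "):", b, "$")
      hits <- grepl(pat, cf$coefficient)
      tibble(bias = b, estimate = if (any(hits)) mean(cf$estimate[hits]) else NA_real_)
    })
  }, .id = "response")
}
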