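#' Generate the developmental sampling design
#'
#' Builds the whole-body factorial design of the study system: five ordered
#' developmental stages (early embryo, late embryo, larva, pupa, adult), two
#' sexes, `n_reps` biological replicates per (stage, sex) cell. With
#' `with_gonads = TRUE` the design additionally carries the gonad contrast
#' samples: testes matched to male pupae and ovaries matched to adult
#' females, the two cells where gametogenesis peaks.
#'
#' @param n_reps Replicates per (stage, sex) cell; at least 2 (differential
#'   expression and correlation fits need replication).
#' @param with_gonads Include testis and ovary samples.
#' @return A tibble with columns `sample_id`, `stage` (ordered factor),
#'   `sex`, `replicate`, `tissue`.
#' @examples
#' generate_design()          # 30 whole-body samples + 6 gonad samples
#' generate_design(2, FALSE)  # 20 samples
#' @export
generate_design <- function(n_reps = 3, with_gonads = TRUE) {
  if (!is.numeric(n_reps) || n_reps < 2) {
    stopf("n_reps must be >= 2: replicated cells are required downstream")
  }
  n_reps <- as.integer(n_reps)
  grid <- tidyr::expand_grid(
    stage = factor(stage_levels(), stage_levels(), ordered = TRUE),
    sex = factor(sex_levels(), sex_levels()),
    replicate = seq_len(n_reps)
  )
  whole <- dplyr::mutate(grid,
    tissue = "whole",
    sample_id = sprintf("%s_%s_r%d", .data$stage, .data$sex, .data$replicate)
  )
  if (!with_gonads) return(dplyr::select(whole, "sample_id", "stage", "sex", "replicate", "tissue"))
  gonads <- tibble(
    stage = factor(rep(c("pupa", "adult"), each = n_reps), stage_levels(), ordered = TRUE),
    sex = factor(rep(c("M", "F"), each = n_reps), sex_levels()),
    replicate = rep(seq_len(n_reps), 2),
    tissue = rep(c("testis", "ovary"), each = n_reps)
  )
  gonads$sample_id <- sprintf("%s_%s_r%d", gonads$tissue, gonads$sex, gonads$replicate)
  dplyr::select(bind_rows(whole, gonads), "sample_id", "stage", "sex", "replicate", "tissue")
}

#' Generate synthetic gene models and annotations
#'
#' Draws a set of gene models with the annotation layers the pipeline
#' consumes: exon structure with constitutive and facultative exons (multiple
#' isoforms), latent co-expression cluster membership, paralog families,
#' linkage groups and phylogenetic strata. Categorical distributions default
#' to proportions of the scale seen in parasitoid-wasp annotation sets and
#' are fully configurable.
#'
#' @param n_genes Number of genes (>= 1).
#' @param isoform_rate Expected fraction of multi-isoform genes in \[0, 1\].
#' @param n_clusters Number of latent co-expression clusters.
#' @param dup_rate Expected fraction of genes belonging to a multi-member
#'   paralog family.
#' @param n_linkage_groups Number of linkage groups.
#' @param strata_props Named numeric vector of stratum proportions over
#'   [stratum_levels()]; normalised internally.
#' @param seed Integer seed; the same seed yields identical models.
#' @return A `gene_models` object: list with tibbles `genes` (`gene_id`,
#'   `cluster`, `paralog_family`, `linkage_group`, `stratum`,
#'   `multi_isoform`) and `exons` (`gene_id`, `exon_id`, `constitutive`,
#'   `splice_group`).
#' @export
generate_gene_models <- function(n_genes,
                                 isoform_rate = 0.58,
                                 n_clusters = 12,
                                 dup_rate = 0.3,
                                 n_linkage_groups = 12,
                                 strata_props = NULL,
                                 seed = 1) {
  if (n_genes < 1) stopf("n_genes must be >= 1")
  if (isoform_rate < 0 || isoform_rate > 1) stopf("isoform_rate must be in [0, 1]")
  strata_props <- strata_props %||%
    c(Metazoa = 0.25, Arthropoda = 0.07, Insecta = 0.18,
      Hymenoptera = 0.15, Chalcid = 0.25, Nasonia = 0.10)
  stopifnot(setequal(names(strata_props), stratum_levels()))
  strata_props <- strata_props[stratum_levels()] / sum(strata_props)

  with_seed(seed, {
    gene_id <- sprintf("g%05d", seq_len(n_genes))
    multi <- runif(n_genes) < isoform_rate
    # paralog families: duplicated genes grouped in families of 2-3
    fam <- paste0("fam_", gene_id)
    dup <- which(runif(n_genes) < dup_rate)
    if (length(dup) >= 2) {
      sizes <- sample(2:3, ceiling(length(dup) / 2), replace = TRUE)
      grp <- rep(seq_along(sizes), sizes)[seq_along(dup)]
      fam[dup] <- sprintf("fam_dup%04d", grp)
    }
    genes <- tibble(
      gene_id = gene_id,
      cluster = sprintf("cluster%02d", sample.int(n_clusters, n_genes, replace = TRUE)),
      paralog_family = fam,
      linkage_group = sprintf("LG%02d", sample.int(n_linkage_groups, n_genes, replace = TRUE)),
      stratum = factor(sample(stratum_levels(), n_genes, replace = TRUE, prob = strata_props),
                       stratum_levels()),
      multi_isoform = multi
    )
    n_fac_grp <- ifelse(multi, sample(1:2, n_genes, replace = TRUE), 0L)
    n_fac <- vapply(n_fac_grp, function(g) {
      if (g > 0) sum(sample(2:3, g, replace = TRUE)) else 0L
    }, integer(1))
    n_con <- sample(2:4, n_genes, replace = TRUE)  # >= 2 constitutive exons per gene
    k <- n_con + n_fac
    gi <- rep.int(seq_len(n_genes), k)
    within <- sequence(k)
    exon_gene <- gene_id[gi]
    exons <- tibble(
      gene_id = exon_gene,
      exon_id = sprintf("%s_e%02d", exon_gene, within),
      constitutive = within <= n_con[gi],
      splice_group = ifelse(within <= n_con[gi], NA_integer_,
                            1L + (within - n_con[gi] - 1L) %% pmax(n_fac_grp[gi], 1L))
    )
    structure(list(genes = genes, exons = exons), class = "gene_models")
  })
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes, %d exons (%.0f%% multi-isoform)\n",
              nrow(x$genes), nrow(x$exons), 100 * mean(x$genes$multi_isoform)))
  invisible(x)
}

#' Specify planted effects for the synthetic generator
#'
#' Collects every effect the generator can plant, each as a small tibble:
#'
#' * `de`: columns `cluster`, `stage`, `sex`, `lfc` — a log2 shift added to
#'   that (stage, sex) cell for all genes of the cluster.
#' * `dc`: columns `cluster`, `stage`, `r_m`, `r_f` — sex-specific
#'   within-cluster correlation at one stage (differential correlation).
#' * `gonad`: columns `gene_id`, `tissue` (`"testis"`/`"ovary"`), `lfc` —
#'   gonad-enrichment shifts.
#' * `linkage`: columns `linkage_group`, `sex`, `fraction`, and optionally
#'   `lfc` (default 2) and `stage` (default `"adult"`) — plants sex bias in
#'   a fraction of the group's genes.
#' * `stratum_topology`: columns `cluster`, `pattern` — plants an
#'   association between gene age and within-cluster network position:
#'   `"young_hub"` places young-stratum genes as bridges across otherwise
#'   weakly-linked halves of the cluster (lower density, higher hub score);
#'   `"young_interactor"` gives young genes a stronger loading on the
#'   cluster factor (higher density).
#'
#' @param de,dc,gonad,linkage,stratum_topology Effect tables as above, or
#'   `NULL` for none.
#' @param noise_sd Gaussian measurement noise SD on the log2 scale. The data
#'   emulate two-colour array log-ratios, so noise is additive in log space.
#' @param bio_sd SD of the replicate-level biological residual (log2).
#'   Replicates are pools of many individuals, so between-replicate
#'   biological variation is well below the stage-to-stage signal; the
#'   residual carries the planted within-cell correlation structure, which
#'   is scale-free and unaffected by this value.
#' @param baseline_cor Baseline within-cluster, within-cell correlation of
#'   gene signals.
#' @param stage_sd SD of the per-cluster stage profile (log2), the shared
#'   developmental trajectory that makes clusters detectable.
#' @param frac_silent Fraction of genes simulated as unexpressed noise (low
#'   baseline), emulating the large silent fraction of a genome-wide assay.
#' @param female_contamination Optional fraction of male signal mixed into
#'   pre-pupal female samples (brood contamination); default off.
#' @param seed Integer seed; fully determines the generated matrix.
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(de = NULL, dc = NULL, gonad = NULL, linkage = NULL,
                        stratum_topology = NULL,
                        noise_sd = 0.2, bio_sd = 0.3, baseline_cor = 0.3,
                        stage_sd = 1, frac_silent = 0,
                        female_contamination = 0, seed = 1) {
  if (!is.null(dc)) {
    dc <- as_tibble(dc)
    if (any(abs(c(dc$r_m, dc$r_f)) > 1)) stopf("dc correlations must lie in [-1, 1]")
  }
  for (tb in list(de, gonad, linkage)) {
    if (!is.null(tb) && !all(is.finite(unlist(Filter(is.numeric, as.list(tb)))))) {
      stopf("effect sizes must be finite")
    }
  }
  stopifnot(noise_sd >= 0, bio_sd > 0, baseline_cor >= 0, baseline_cor <= 1)
  structure(list(de = de, dc = dc, gonad = gonad, linkage = linkage,
                 stratum_topology = stratum_topology,
                 noise_sd = noise_sd, bio_sd = bio_sd,
                 baseline_cor = baseline_cor,
                 stage_sd = stage_sd, frac_silent = frac_silent,
                 female_contamination = female_contamination,
                 seed = as.integer(seed)),
            class = "effect_spec")
}

# ---- core latent simulator --------------------------------------------------

# gene-level log2 signal matrix (genes x samples), whole-body + gonad samples.
# Model per gene g in cluster c and sample s:
#   x_g[s] = mu_g + stage_c(stage_s) + sqrt(r_s) z_c[s] + sqrt(1 - r_s) e_g[s]
# where z_c is the cluster's shared per-sample factor and r_s the planted
# within-cell correlation (baseline_cor, or the dc-spec value for the focal
# stage/sex). Clusters under a stratum_topology pattern instead use explicit
# per-gene factor loadings (see effect_spec).
sim_gene_signals <- function(design, genes, effects) {
  n_g <- nrow(genes)
  n_s <- nrow(design)
  clusters <- unique(genes$cluster)
  silent <- runif(n_g) < effects$frac_silent
  mu <- ifelse(silent, rnorm(n_g, -2, 0.5), rnorm(n_g, 5, 1.5))

  vals <- matrix(0, n_g, n_s, dimnames = list(genes$gene_id, design$sample_id))
  topo <- effects$stratum_topology
  dc <- effects$dc

  for (cl in clusters) {
    gi <- which(genes$cluster == cl & !silent)
    if (!length(gi)) next
    stage_prof <- rnorm(length(stage_levels()), 0, effects$stage_sd)
    names(stage_prof) <- stage_levels()
    st <- as.character(design$stage)
    pattern <- if (!is.null(topo) && cl %in% topo$cluster) {
      topo$pattern[match(cl, topo$cluster)]
    } else NA_character_

    if (!is.na(pattern)) {
      # explicit loading structure; factors carry their own stage profile so
      # the cluster stays developmentally coherent
      young <- genes$stratum[gi] %in% c("Chalcid", "Nasonia")
      m <- length(gi)
      if (identical(pattern, "young_interactor")) {
        l <- ifelse(young, 0.95, 0.5)
        f1 <- (stage_prof[st] + rnorm(n_s)) / sqrt(effects$stage_sd^2 + 1)
        shared <- outer(l, f1)
        priv <- sqrt(1 - l^2) * matrix(rnorm(m * n_s), m, n_s)
      } else if (identical(pattern, "young_hub")) {
        half <- rep(1:2, length.out = sum(!young))
        # the two sub-factors carry no stage profile: with only five stage
        # levels, independent profiles still correlate appreciably across
        # samples and would couple the halves the young genes must bridge
        f1 <- rnorm(n_s)
        f2 <- rnorm(n_s)
        L <- matrix(0, m, 2)
        L[!young, 1] <- ifelse(half == 1, 0.999, 0)
        L[!young, 2] <- ifelse(half == 2, 0.999, 0)
        # young genes bridge both halves; alternating signs keep them
        # mutually uncorrelated (their neighbourhoods stay unclustered)
        L[young, 1] <- 0.65
        L[young, 2] <- 0.65 * rep_len(c(1, -1), sum(young))
        shared <- L %*% rbind(f1, f2)
        priv <- sqrt(pmax(0, 1 - rowSums(L^2))) * matrix(rnorm(m * n_s), m, n_s)
      } else {
        stopf("unknown stratum_topology pattern '%s'", pattern)
      }
      vals[gi, ] <- mu[gi] + effects$bio_sd * (shared + priv)
    } else {
      # per-sample correlation level (dc planting is stage x sex specific)
      r_s <- rep(effects$baseline_cor, n_s)
      if (!is.null(dc) && cl %in% dc$cluster) {
        for (k in which(dc$cluster == cl)) {
          focal <- design$tissue == "whole" & st == as.character(dc$stage[k])
          r_s[focal & design$sex == "M"] <- dc$r_m[k]
          r_s[focal & design$sex == "F"] <- dc$r_f[k]
        }
      }
      z <- rnorm(n_s)
      e <- matrix(rnorm(length(gi) * n_s), length(gi), n_s)
      vals[gi, ] <- mu[gi] + rep(stage_prof[st], each = length(gi)) +
        effects$bio_sd * (rep(sqrt(r_s) * z, each = length(gi)) +
                            sqrt(1 - rep(r_s, each = length(gi))) * e)
    }
  }
  vals[silent, ] <- mu[silent] +
    effects$bio_sd * matrix(rnorm(sum(silent) * n_s), sum(silent), n_s)
  vals
}

# apply planted mean-shift effects; returns list(vals, truth)
apply_shift_effects <- function(vals, design, genes, effects) {
  truth <- list()
  add_cell <- function(vals, gene_ids, stage, sex, lfc) {
    cols <- design$tissue == "whole" &
      as.character(design$stage) == stage & design$sex == sex
    vals[gene_ids, cols] <- vals[gene_ids, cols] + lfc
    vals
  }
  if (!is.null(effects$de)) {
    for (k in seq_len(nrow(effects$de))) {
      e <- effects$de[k, ]
      gid <- genes$gene_id[genes$cluster == e$cluster]
      if (!length(gid)) stopf("de effect references unknown cluster '%s'", e$cluster)
      vals <- add_cell(vals, gid, as.character(e$stage), as.character(e$sex), e$lfc)
      truth[[length(truth) + 1]] <- tibble(
        effect_type = "de", cluster = e$cluster, gene_id = gid,
        stage = as.character(e$stage), direction = as.character(e$sex), value = e$lfc)
    }
  }
  if (!is.null(effects$linkage)) {
    lk <- as_tibble(effects$linkage)
    if (is.null(lk$lfc)) lk$lfc <- 2
    if (is.null(lk$stage)) lk$stage <- "adult"
    for (k in seq_len(nrow(lk))) {
      pool <- genes$gene_id[genes$linkage_group == lk$linkage_group[k]]
      if (!length(pool)) stopf("linkage effect references unknown group '%s'", lk$linkage_group[k])
      gid <- pool[seq_len(max(1, round(lk$fraction[k] * length(pool))))]
      vals <- add_cell(vals, gid, lk$stage[k], as.character(lk$sex[k]), lk$lfc[k])
      truth[[length(truth) + 1]] <- tibble(
        effect_type = "linkage", cluster = lk$linkage_group[k], gene_id = gid,
        stage = lk$stage[k], direction = as.character(lk$sex[k]), value = lk$lfc[k])
    }
  }
  if (!is.null(effects$gonad)) {
    gn <- as_tibble(effects$gonad)
    for (k in seq_len(nrow(gn))) {
      if (!gn$gene_id[k] %in% genes$gene_id) {
        stopf("gonad effect references unknown gene '%s'", gn$gene_id[k])
      }
      cols <- design$tissue == gn$tissue[k]
      vals[gn$gene_id[k], cols] <- vals[gn$gene_id[k], cols] + gn$lfc[k]
      truth[[length(truth) + 1]] <- tibble(
        effect_type = "gonad", cluster = NA_character_, gene_id = gn$gene_id[k],
        stage = NA_character_, direction = gn$tissue[k], value = gn$lfc[k])
    }
  }
  if (!is.null(effects$dc)) {
    for (k in seq_len(nrow(effects$dc))) {
      e <- effects$dc[k, ]
      if (!e$cluster %in% genes$cluster) stopf("dc effect references unknown cluster '%s'", e$cluster)
      truth[[length(truth) + 1]] <- tibble(
        effect_type = "dc", cluster = e$cluster, gene_id = NA_character_,
        stage = as.character(e$stage),
        direction = if (e$r_m >= e$r_f) "M" else "F", value = e$r_m - e$r_f)
    }
  }
  if (!is.null(effects$stratum_topology)) {
    tp <- as_tibble(effects$stratum_topology)
    truth[[length(truth) + 1]] <- tibble(
      effect_type = "stratum_topology", cluster = tp$cluster, gene_id = NA_character_,
      stage = NA_character_, direction = tp$pattern, value = NA_real_)
  }
  list(vals = vals, truth = if (length(truth)) bind_rows(truth) else
    tibble(effect_type = character(), cluster = character(), gene_id = character(),
           stage = character(), direction = character(), value = double()))
}

#' Generate a synthetic exon expression matrix with ground truth
#'
#' Simulates exon-level log2 expression for the given design and gene models
#' under the planted effects of an [effect_spec()]. Baseline gene signals are
#' cluster-correlated Gaussians; constitutive exons track the gene signal,
#' facultative exons carry the gene signal scaled (on the linear scale) by a
#' latent splicing fraction; gonad samples are the matched whole-body cell
#' plus gene-specific enrichment shifts. Measurement noise is additive
#' Gaussian on the log2 scale.
#'
#' @param design From [generate_design()].
#' @param models From [generate_gene_models()].
#' @param effects An [effect_spec()]; its seed fully determines the output.
#' @return A list: `exons` (an [exon_matrix()]), `truth` (tibble of planted
#'   effects, one row per planted gene/cluster effect) and `splicing`
#'   (tibble of latent splicing fractions: `gene_id`, `splice_group`,
#'   `sample_id`, `fraction`).
#' @export
generate_expression <- function(design, models, effects = effect_spec()) {
  stopifnot(inherits(models, "gene_models"), inherits(effects, "effect_spec"))
  with_seed(effects$seed, {
    genes <- models$genes
    vals <- sim_gene_signals(design, genes, effects)
    shifted <- apply_shift_effects(vals, design, genes, effects)
    vals <- shifted$vals

    if (effects$female_contamination > 0) {
      # brood contamination: pre-pupal "female" pools contain some males
      a <- effects$female_contamination
      pre <- design$tissue == "whole" &
        as.character(design$stage) %in% c("early_embryo", "late_embryo", "larva")
      fcol <- which(pre & design$sex == "F")
      for (j in fcol) {
        m_match <- which(pre & design$sex == "M" &
                           design$stage == design$stage[j] &
                           design$replicate == design$replicate[j])
        if (length(m_match) == 1) {
          vals[, j] <- log2(pmax((1 - a) * 2^vals[, j] + a * 2^vals[, m_match], 1e-6))
        }
      }
    }

    # exon layer: constitutive exons track the gene; facultative exons are the
    # gene's linear signal times a latent per-group splicing fraction
    ex <- models$exons
    n_s <- nrow(design)
    fac <- dplyr::distinct(ex[!ex$constitutive, ], .data$gene_id, .data$splice_group)
    frac <- NULL
    if (nrow(fac)) {
      a0 <- rnorm(nrow(fac), 0, 1)
      fr <- plogis(a0 + 0.8 * matrix(rnorm(nrow(fac) * n_s), nrow(fac), n_s))
      frac <- tibble(
        gene_id = rep(fac$gene_id, n_s),
        splice_group = rep(fac$splice_group, n_s),
        sample_id = rep(design$sample_id, each = nrow(fac)),
        fraction = as.vector(fr)
      )
      rownames(fr) <- paste(fac$gene_id, fac$splice_group)
    }
    offs <- rnorm(nrow(ex), 0, 0.1)  # probe-affinity-like per-exon offsets
    emat <- matrix(0, nrow(ex), n_s, dimnames = list(ex$exon_id, design$sample_id))
    g_of <- match(ex$gene_id, rownames(vals))
    con <- ex$constitutive
    emat[con, ] <- vals[g_of[con], , drop = FALSE] + offs[con]
    if (any(!con)) {
      key <- paste(ex$gene_id[!con], ex$splice_group[!con])
      emat[!con, ] <- log2(pmax(2^(vals[g_of[!con], , drop = FALSE] + offs[!con]) *
                                  fr[key, , drop = FALSE], 2^-6))
    }
    emat <- emat + matrix(rnorm(length(emat), 0, effects$noise_sd), nrow(emat))

    exon_map <- dplyr::select(ex, "exon_id", "gene_id", "constitutive", "splice_group")
    list(exons = exon_matrix(emat, design, exon_map),
         truth = shifted$truth,
         splicing = frac)
  })
}

#' Generate node-level synthetic data directly
#'
#' Convenience wrapper for validating the network, differential-expression
#' and differential-correlation machinery at node scale: builds one
#' single-exon gene per node (so each node is a transcription node), runs the
#' same latent simulator, and returns the `node_matrix` together with truth
#' and the latent cluster labels.
#'
#' @param design From [generate_design()].
#' @param n_clusters Number of clusters.
#' @param nodes_per_cluster Nodes in each cluster.
#' @param effects An [effect_spec()].
#' @param strata_props Optional stratum proportions (see
#'   [generate_gene_models()]).
#' @return List: `nodes` (a [node_matrix()]), `clusters` (tibble `node_id`,
#'   `cluster`), `genes` (annotation tibble), `truth`.
#' @export
generate_node_data <- function(design, n_clusters = 10, nodes_per_cluster = 20,
                               effects = effect_spec(), strata_props = NULL) {
  models <- generate_gene_models(
    n_genes = n_clusters * nodes_per_cluster, isoform_rate = 0,
    n_clusters = n_clusters, strata_props = strata_props,
    seed = effects$seed
  )
  # deterministic balanced cluster assignment (exact sizes)
  models$genes$cluster <- rep(sprintf("cluster%02d", seq_len(n_clusters)),
                              each = nodes_per_cluster)
  with_seed(effects$seed, {
    vals <- sim_gene_signals(design, models$genes, effects)
    shifted <- apply_shift_effects(vals, design, models$genes, effects)
    vals <- shifted$vals + matrix(rnorm(length(vals), 0, effects$noise_sd), nrow(vals))
    nodes <- tibble(node_id = models$genes$gene_id, kind = "transcription",
                    gene_id = models$genes$gene_id)
    list(nodes = node_matrix(vals, design, nodes),
         clusters = tibble(node_id = models$genes$gene_id,
                           cluster = models$genes$cluster),
         genes = models$genes,
         truth = shifted$truth)
  })
}
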