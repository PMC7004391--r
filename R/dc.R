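#' Enumerate the leave-three-out subsampling scheme
#'
#' The targeted differential-correlation design: for each developmental
#' stage in turn, every combination of three of its six whole-body samples
#' is removed (one stage perturbed per subnetwork; all other stages keep
#' their six samples), giving 5 x C(6,3) = 100 subnetworks of constant
#' size. Removing three samples from a 3M + 3F cell systematically tilts
#' the sex composition of the focal stage: the retained-sample balance
#' `b = (#M - #F) / 3` takes the values {-1, -1/3, +1/3, +1} with
#' multiplicities {1, 9, 9, 1}, and is the sex covariate of the
#' downstream GLM.
#'
#' @param design A design tibble from [generate_design()] (or compatible);
#'   only whole-body samples are used, and every stage must hold exactly 3
#'   replicates per sex.
#' @return A `subsample_scheme` tibble: `subnetwork`, `stage`, `removed`
#'   and `retained` (list-columns of sample ids), `balance`.
#' @export
enumerate_subsamples <- function(design) {
  d <- as_tibble(design)
  d <- d[d$tissue == "whole", ]
  for (st in stage_levels()) {
    cell <- d[as.character(d$stage) == st, ]
    if (nrow(cell) != 6 || sum(cell$sex == "M") != 3) {
      stopf("stage '%s' must have exactly 3 male and 3 female whole-body samples", st)
    }
  }
  all_ids <- d$sample_id
  out <- purrr::map_dfr(stage_levels(), function(st) {
    cell <- d[as.character(d$stage) == st, ]
    combos <- combn(cell$sample_id, 3, simplify = FALSE)
    purrr::imap_dfr(combos, function(rm, j) {
      kept_focal <- setdiff(cell$sample_id, rm)
      sex_kept <- cell$sex[match(kept_focal, cell$sample_id)]
      tibble(
        subnetwork = sprintf("%s_%02d", st, j),
        stage = st,
        removed = list(rm),
        retained = list(setdiff(all_ids, rm)),
        balance = (sum(sex_kept == "M") - sum(sex_kept == "F")) / 3
      )
    })
  })
  class(out) <- c("subsample_scheme", class(out))
  out
}

#' Within-cluster densities across all subnetworks
#'
#' Rebuilds the adjacency of every subnetwork on its retained samples —
#' with the same soft power and the same node-to-cluster assignment as the
#' main network, never re-estimated — and measures each cluster's
#' within-cluster density (mean off-diagonal weight) plus the
#' whole-subnetwork density. Densities are guarded into `(eps, 1 - eps)`
#' because the downstream logit link is undefined at 0 and 1. Clusters
#' with fewer than 3 nodes are excluded with a warning.
#'
#' @param nodes A [node_matrix()].
#' @param clusters Cluster labels (`node_id`, `cluster`).
#' @param scheme From [enumerate_subsamples()].
#' @param beta Soft power of the main network.
#' @param method Correlation flavour (see [cor_nodes()]).
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation).
#' @return A `density_table` tibble: `cluster`, `subnetwork`, `stage`,
#'   `balance`, `density`, `net_density`.
#' @export
subnetwork_densities <- function(nodes, clusters, scheme, beta = 6,
                                 method = c("bicor", "pearson"),
                                 engine = c("cpp", "r")) {
  stopifnot(inherits(nodes, "node_matrix"), inherits(scheme, "subsample_scheme"))
  method <- match.arg(method)
  engine <- match.arg(engine)
  clusters <- as_tibble(clusters)
  wb <- whole_body(nodes)
  v <- wb$values
  lab <- clusters$cluster[match(rownames(v), clusters$node_id)]
  sizes <- table(lab)
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warnf("excluding %d cluster(s) with < 3 nodes: %s",
          length(small), paste(head(small, 5), collapse = ", "))
  }
  cl_names <- setdiff(names(sizes)[sizes >= 3], NA)
  cl_of <- match(lab, cl_names)  # NA for excluded
  sample_idx <- purrr::map(scheme$retained, ~ match(.x, colnames(v)))

  if (engine == "cpp") {
    res <- subnet_density_engine(v, ifelse(is.na(cl_of), -1L, cl_of - 1L),
                                 length(cl_names),
                                 lapply(sample_idx, function(i) as.integer(i - 1L)),
                                 as.integer(beta), method == "bicor")
    dens <- res$cluster_density   # n_subnet x n_clusters
    netd <- res$net_density
  } else {
    dens <- matrix(NA_real_, nrow(scheme), length(cl_names))
    netd <- numeric(nrow(scheme))
    for (s in seq_len(nrow(scheme))) {
      a <- abs_pow(suppressWarnings(cor_nodes(v[, sample_idx[[s]], drop = FALSE], method)),
                   beta)
      diag(a) <- 0
      ut <- upper.tri(a)
      netd[s] <- mean(a[ut])
      for (ci in seq_along(cl_names)) {
        idx <- which(!is.na(cl_of) & cl_of == ci)
        dens[s, ci] <- mean(a[idx, idx][upper.tri(diag(length(idx)))])
      }
    }
  }
  out <- tidyr::expand_grid(s = seq_len(nrow(scheme)), ci = seq_along(cl_names))
  out <- tibble(
    cluster = cl_names[out$ci],
    subnetwork = scheme$subnetwork[out$s],
    stage = scheme$stage[out$s],
    balance = scheme$balance[out$s],
    density = guard_unit(dens[cbind(out$s, out$ci)]),
    net_density = netd[out$s]
  )
  class(out) <- c("density_table", class(out))
  out
}

# design matrix of the per-cluster DC model:
# Density ~ Stage + Stage:Balance + NetDensity  (no balance main effect:
# the balance of every non-perturbed stage is structurally zero)
dc_model_matrix <- function(stage, balance, net_density) {
  st <- factor(stage, stage_levels())
  X <- model.matrix(~ st)
  for (s in stage_levels()) {
    X <- cbind(X, ifelse(as.character(st) == s, balance, 0))
    colnames(X)[ncol(X)] <- paste0("bal_", s)
  }
  cbind(X, net_density = net_density)
}

#' Per-cluster differential-correlation GLM
#'
#' Fits, for each cluster, a gamma-family GLM with a logit link to the
#' within-cluster densities of all subnetworks:
#' `Density ~ Stage + Stage:Balance + NetworkDensity`, where `Stage` is the
#' perturbed stage of the subnetwork and `Balance` the signed sex
#' composition of the retained focal-stage samples. The stage-by-balance
#' interaction coefficients measure how strongly removing one sex changes
#' the cluster's internal correlation at that stage; Wald p-values are
#' returned per stage. The network-density covariate absorbs global
#' connectivity shifts.
#'
#' @param table A `density_table` from [subnetwork_densities()].
#' @param engine `"glm"` (stats::glm, default) or `"irls"` (the compiled
#'   scorer used for permutations).
#' @return Tibble: `cluster`, `stage`, `coef`, `se`, `t`, `p`,
#'   `converged`.
#' @export
fit_dc_glm <- function(table, engine = c("glm", "irls")) {
  engine <- match.arg(engine)
  cl <- unique(table$cluster)
  one <- table[table$cluster == cl[1], ]
  if (nrow(one) < 100) {
    stopf("each cluster needs the full subsampling scheme (>= 100 rows), got %d", nrow(one))
  }
  X <- dc_model_matrix(one$stage, one$balance, one$net_density)
  # columns of Y follow `cl`; rows follow the subnetwork order of `one`
  Y <- vapply(cl, function(cc) table$density[table$cluster == cc], numeric(nrow(one)))
  int_idx <- match(paste0("bal_", stage_levels()), colnames(X))
  if (engine == "irls") {
    fit <- gamma_logit_batch(X, Y, as.integer(int_idx - 1L))
    res <- tidyr::expand_grid(cluster = cl, stage = stage_levels())
    res$coef <- as.vector(t(fit$coef))
    res$se <- as.vector(t(fit$se))
    res$converged <- rep(as.logical(fit$converged), each = length(stage_levels()))
  } else {
    res <- purrr::map_dfr(seq_along(cl), function(ci) {
      df <- as.data.frame(X[, -1])
      df$y <- Y[, ci]
      f <- suppressWarnings(glm(y ~ ., data = df,
                                family = Gamma(link = make.link("logit"))))
      sm <- coef(summary(f))
      rows <- match(paste0("bal_", stage_levels()), rownames(sm))
      tibble(cluster = cl[ci], stage = stage_levels(),
             coef = unname(sm[rows, 1]), se = unname(sm[rows, 2]),
             converged = f$converged)
    })
  }
  res$t <- res$coef / res$se
  df_resid <- nrow(one) - ncol(X)
  res$p <- ifelse(res$converged, 2 * pt(-abs(res$t), df_resid), NA_real_)
  res$stage <- factor(res$stage, stage_levels())
  as_tibble(res[, c("cluster", "stage", "coef", "se", "t", "p", "converged")])
}

#' Permutation null for the differential-correlation test
#'
#' Refits the per-cluster DC model to `n_perm` datasets in which the sex
#' labels are randomly permuted within each stage. Permuting sex labels
#' does not change any subnetwork's density — only the balance covariate —
#' so each permutation re-derives the balances from the shuffled labels and
#' re-fits the GLMs against the unchanged densities. Fully reproducible
#' given `seed`.
#'
#' @param table A `density_table`.
#' @param scheme The matching [enumerate_subsamples()] scheme.
#' @param design The sample design.
#' @param n_perm Number of permutations (>= 1; 1000 in the full protocol).
#' @param seed Integer seed.
#' @return A `dc_permutation` object: list with the p-value array `p`
#'   (`n_perm` x clusters x stages), `n_perm` and `seed`.
#' @export
permutation_null <- function(table, scheme, design, n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 1)
  d <- as_tibble(design)
  d <- d[d$tissue == "whole", ]
  cl <- unique(table$cluster)
  one <- table[table$cluster == cl[1], ]
  Y <- vapply(cl, function(cc) table$density[table$cluster == cc], numeric(nrow(one)))
  base_sex <- setNames(as.character(d$sex), d$sample_id)
  stage_of <- setNames(as.character(d$stage), d$sample_id)
  kept_focal <- purrr::map2(scheme$retained, scheme$stage,
                            ~ .x[stage_of[.x] == .y])
  df_resid <- nrow(one) -
    ncol(dc_model_matrix(one$stage, one$balance, one$net_density))
  p_arr <- array(NA_real_, c(n_perm, length(cl), length(stage_levels())),
                 dimnames = list(NULL, cl, stage_levels()))
  degen <- matrix(FALSE, n_perm, length(stage_levels()),
                  dimnames = list(NULL, stage_levels()))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm_sex <- base_sex
      for (st in stage_levels()) {
        ids <- d$sample_id[as.character(d$stage) == st]
        perm_sex[ids] <- base_sex[sample(ids)]
        # a permutation that reproduces the stage's observed labelling (or
        # its mirror image) regenerates the observed interaction statistic
        # rather than a null draw; flag it so calibration can drop it
        same <- all(perm_sex[ids] == base_sex[ids])
        flip <- all(perm_sex[ids] != base_sex[ids])
        degen[b, st] <- same || flip
      }
      bal <- purrr::map_dbl(kept_focal, function(ids) {
        (sum(perm_sex[ids] == "M") - sum(perm_sex[ids] == "F")) / 3
      })
      X <- dc_model_matrix(one$stage, bal[match(one$subnetwork, scheme$subnetwork)],
                           one$net_density)
      int_idx <- match(paste0("bal_", stage_levels()), colnames(X))
      fit <- gamma_logit_batch(X, Y, as.integer(int_idx - 1L))
      tmat <- fit$coef / fit$se
      pm <- 2 * pt(-abs(tmat), df_resid)
      pm[!as.logical(fit$converged), ] <- NA_real_
      p_arr[b, , ] <- pm
    }
  })
  structure(list(p = p_arr, degenerate = degen, n_perm = n_perm, seed = seed),
            class = "dc_permutation")
}

#' Two-stage permutation-calibrated local FDR for DC
#'
#' Stage 1 evaluates each observed stage-by-balance p-value against the
#' cluster's own permutation p-value distribution pooled across stages (its
#' empirical null): observed p-values are mapped through the permutation
#' ECDF with a continuity correction, and the local FDR of the transformed
#' values is estimated with a Grenander (least-concave-majorant) density
#' fit, which can resolve single extreme clusters. Pooling within cluster
#' (rather than across all clusters) keeps each test calibrated against its
#' own dependence-driven statistic inflation; permutations whose
#' focal-stage labelling reproduces the observed one or its mirror image
#' are excluded, since they regenerate the observed statistic instead of a
#' null draw. Stage 2 recalibrates each score against the distribution of
#' all clusters' stage-1 scores with the same machinery. Calls are stage-2
#' lFDR below `threshold` (default 10%); the direction is the sign of the
#' interaction coefficient (positive balance coefficients mean density
#' rises with male composition).
#'
#' @param observed Result of [fit_dc_glm()].
#' @param perm Result of [permutation_null()].
#' @param threshold Call threshold on the stage-2 lFDR scale.
#' @return A `dc_result` tibble: `cluster`, `stage`, `coef`, `p`,
#'   `stage1_lfdr`, `lfdr` (stage 2), `significant`, `direction`.
#' @export
calibrate_dc_lfdr <- function(observed, perm, threshold = 0.10) {
  stopifnot(inherits(perm, "dc_permutation"))
  keep_cell <- !perm$degenerate  # n_perm x n_stage
  out <- observed
  ok <- !is.na(out$p)
  if (length(unique(out$p[ok])) <= 1) {
    warnf("degenerate p-value distribution; conservative lFDR = 1")
    out$stage1_lfdr <- ifelse(ok, 1, NA_real_)
    out$lfdr <- out$stage1_lfdr
  } else {
    s1 <- rep(NA_real_, nrow(out))
    for (cc in unique(out$cluster)) {
      rows <- which(out$cluster == cc & ok)
      if (!length(rows)) next
      pool <- perm$p[, cc, ]
      pool <- pool[as.vector(keep_cell) & !is.na(pool)]
      # permutation ECDF with the usual finite-sample floor: evidence is
      # capped at the resolution of the permutation sample
      s1[rows] <- (vapply(out$p[rows], function(p) sum(pool <= p), numeric(1)) +
                     0.5) / (length(pool) + 1)
    }
    # s1 currently holds the null-ECDF-transformed values; convert to lfdr
    # jointly across all tests
    s1[!is.na(s1)] <- lfdr_grenander(s1[!is.na(s1)])
    out$stage1_lfdr <- s1
    s2 <- rep(NA_real_, nrow(out))
    s2[ok] <- lfdr_grenander(s1[ok])
    out$lfdr <- s2
  }
  out$significant <- !is.na(out$lfdr) & out$lfdr < threshold
  out$direction <- dplyr::case_when(
    out$significant & out$coef > 0 ~ "M",
    out$significant & out$coef < 0 ~ "F",
    TRUE ~ "none"
  )
  out <- dplyr::select(out, "cluster", "stage", "coef", "p", "stage1_lfdr",
                       "lfdr", "significant", "direction")
  class(out) <- c("dc_result", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Targeted differential-correlation test, end to end
#'
#' Convenience wrapper chaining [enumerate_subsamples()],
#' [subnetwork_densities()], [fit_dc_glm()], [permutation_null()] and
#' [calibrate_dc_lfdr()].
#'
#' @inheritParams subnetwork_densities
#' @inheritParams permutation_null
#' @inheritParams calibrate_dc_lfdr
#' @param design Optional design (defaults to the node matrix's).
#' @return A `dc_result` tibble (see [calibrate_dc_lfdr()]), with the
#'   density table in attribute `"densities"`.
#' @export
dc_test <- function(nodes, clusters, beta = 6, n_perm = 1000, seed = 1,
                    threshold = 0.10, method = c("bicor", "pearson"),
                    design = NULL) {
  design <- design %||% nodes$design
  scheme <- enumerate_subsamples(design)
  dens <- subnetwork_densities(nodes, clusters, scheme, beta, method)
  obs <- fit_dc_glm(dens)
  perm <- permutation_null(dens, scheme, design, n_perm, seed)
  res <- calibrate_dc_lfdr(obs, perm, threshold)
  attr(res, "densities") <- dens
  res
}
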