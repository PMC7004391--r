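test_that("identical male and female profiles give exactly zero interactions", {
  d <- wb_design()
  stage_means <- setNames(1:5, stage_levels())
  v <- matrix(rep(stage_means[as.character(d$stage)], each = 2), 2, byrow = FALSE)
  nm <- toy_node_matrix(v, d)
  de <- suppressWarnings(fit_node_de(nm))
  expect_equal(de$coef, rep(0, 10), tolerance = 1e-12)
})

test_that("unmoderated fits reproduce the textbook least-squares t", {
  d <- wb_design()
  set.seed(31)
  v <- matrix(rnorm(3 * 30, 5), 3, 30)
  nm <- toy_node_matrix(v, d)
  de <- suppressWarnings(fit_node_de(nm, moderation = FALSE))
  # oracle: plain lm per node
  dd <- data.frame(y = v[2, ], stage = factor(as.character(d$stage), stage_levels()),
                   sex = factor(as.character(d$sex), c("F", "M")))
  fit <- lm(y ~ stage + stage:sex, dd)
  sm <- coef(summary(fit))
  for (st in stage_levels()) {
    row <- de[de$node_id == rownames(v)[2] %||% "n2" & de$stage == st, ]
    orc <- sm[paste0("stage", st, ":sexM"), ]
    expect_equal(row$coef, unname(orc["Estimate"]), tolerance = 1e-10)
    expect_equal(row$t, unname(orc["t value"]), tolerance = 1e-10)
    expect_equal(row$p, unname(orc["Pr(>|t|)"]), tolerance = 1e-10)
  }
})

test_that("interaction coefficients ignore stage-wide shifts", {
  d <- wb_design()
  set.seed(32)
  v <- matrix(rnorm(4 * 30), 4, 30)
  nm <- toy_node_matrix(v, d)
  de1 <- suppressWarnings(fit_node_de(nm, moderation = FALSE))
  v2 <- v
  v2[, as.character(d$stage) == "larva"] <- v2[, as.character(d$stage) == "larva"] + 7
  de2 <- suppressWarnings(fit_node_de(toy_node_matrix(v2, d), moderation = FALSE))
  expect_equal(de1$coef, de2$coef, tolerance = 1e-10)
})

test_that("a rank-deficient design names the missing cell", {
  d <- wb_design()
  d <- d[!(d$stage == "pupa" & d$sex == "M" & d$replicate > 1), ]
  v <- matrix(rnorm(2 * nrow(d)), 2)
  nm <- toy_node_matrix(v, d)
  expect_error(fit_node_de(nm), "pupa.*M|M.*pupa")
})

test_that("module eigengenes summarise their cluster and orient consistently", {
  d <- wb_design()
  set.seed(33)
  prof <- rnorm(30)
  v <- rbind(a = prof, b = prof, c = prof)
  eg <- cluster_eigengene(toy_node_matrix(v, d),
                          tibble::tibble(node_id = c("a", "b", "c"), cluster = "m"))
  expect_equal(attr(eg, "var_explained")[["m"]], 1, tolerance = 1e-12)
  expect_gt(cor(eg["m", ], prof), 0.999)

  # 2-node closed form: eigengene equals the leading right singular vector
  v2 <- rbind(a = rnorm(30), b = rnorm(30))
  eg2 <- cluster_eigengene(toy_node_matrix(v2, d),
                           tibble::tibble(node_id = c("a", "b"), cluster = "m"))
  sv <- svd(t(scale(t(v2))))
  expect_equal(abs(unname(eg2["m", ])), abs(sv$v[, 1]), tolerance = 1e-10)

  # global sign flips do not change the oriented eigengene
  eg3 <- cluster_eigengene(toy_node_matrix(-v, d),
                           tibble::tibble(node_id = c("a", "b", "c"), cluster = "m"))
  expect_equal(unname(eg3["m", ]), unname(-eg["m", ]), tolerance = 1e-10)

  # constant cluster: zero eigengene, flagged
  v4 <- rbind(a = rep(1, 30), b = rep(2, 30))
  eg4 <- cluster_eigengene(toy_node_matrix(v4, d),
                           tibble::tibble(node_id = c("a", "b"), cluster = "m"))
  expect_equal(unname(eg4["m", ]), rep(0, 30))
  expect_equal(attr(eg4, "flagged"), "m")
})

test_that("cluster-level tests recover planted cluster effects and stay null otherwise", {
  d <- wb_design()
  n_seeds <- 5
  hits <- off_hits <- null_calls <- 0
  de_spec <- rbind(
    data.frame(cluster = sprintf("cluster%02d", 1:13), stage = "adult", sex = "F", lfc = 2),
    data.frame(cluster = sprintf("cluster%02d", 1:13), stage = "pupa", sex = "M", lfc = 2))
  for (s in 1:n_seeds) {
    nd <- generate_node_data(d, 45, 8, effect_spec(de = de_spec, seed = 40 + s))
    eg <- cluster_eigengene(nd$nodes, nd$clusters)
    res <- fit_cluster_de(eg, d)
    key <- paste(res$cluster, res$stage)
    planted <- key %in% paste(de_spec$cluster, de_spec$stage)
    hits <- hits + sum(res$direction != "none" & planted)
    off_hits <- off_hits + sum(res$direction != "none" & !planted)
    nd0 <- generate_node_data(d, 45, 8, effect_spec(seed = 140 + s))
    res0 <- fit_cluster_de(cluster_eigengene(nd0$nodes, nd0$clusters), d)
    null_calls <- null_calls + sum(res0$direction != "none")
  }
  expect_gte(hits / (nrow(de_spec) * n_seeds), 0.9)  # planted contrasts called
  expect_lte(off_hits / n_seeds, 2)                  # few spurious stage calls
  expect_lte(null_calls / n_seeds, 0.5)              # null runs call nothing
})

test_that("a cluster of one duplicated node matches the node-level test", {
  d <- wb_design()
  set.seed(34)
  prof <- rnorm(30, 5)
  nm <- toy_node_matrix(rbind(a = prof, b = prof), d)
  eg <- cluster_eigengene(nm, tibble::tibble(node_id = c("a", "b"), cluster = "m"))
  cres <- suppressWarnings(fit_cluster_de(eg, d, moderation = FALSE))
  nres <- suppressWarnings(fit_node_de(nm, moderation = FALSE))
  expect_equal(cres$t, nres$t[nres$node_id == "a"], tolerance = 1e-8)
  expect_equal(cres$p, nres$p[nres$node_id == "a"], tolerance = 1e-8)
})

test_that("gene bias classification follows the any-node rule", {
  d <- wb_design()
  v <- matrix(rnorm(3 * 30), 3, 30)
  rownames(v) <- c("n1", "n2", "n3")
  colnames(v) <- d$sample_id
  nodes <- node_matrix(v, d, tibble::tibble(
    node_id = c("n1", "n2", "n3"),
    kind = c("splicing", "transcription", "ccre"),
    gene_id = c("gA", "gB", "gB"),
    genes = list("gA", "gB", c("gB", "gC"))))
  de <- tidyr::expand_grid(node_id = c("n1", "n2", "n3"),
                           stage = factor(stage_levels(), stage_levels()))
  de$direction <- "none"
  de$direction[de$node_id == "n1" & de$stage == "larva"] <- "F"
  de$direction[de$node_id == "n2" & de$stage == "pupa"] <- "M"
  de$direction[de$node_id == "n2" & de$stage == "adult"] <- "F"
  de$direction[de$node_id == "n3" & de$stage == "adult"] <- "M"
  gb <- classify_gene_bias(de, nodes)
  gb <- gb[order(gb$gene_id), ]
  # gA: one F-biased splicing node at larva only
  expect_equal(gb$bias_larva[gb$gene_id == "gA"], "F")
  expect_false(gb$switch[gb$gene_id == "gA"])
  expect_false(gb$ever_m[gb$gene_id == "gA"])
  # gB: M at pupa (n2), F and M at adult (n2 + CCRE n3) -> both, switch
  expect_equal(gb$bias_pupa[gb$gene_id == "gB"], "M")
  expect_equal(gb$bias_adult[gb$gene_id == "gB"], "both")
  expect_true(gb$switch[gb$gene_id == "gB"])
  # gC: inherits the CCRE's adult M call
  expect_equal(gb$bias_adult[gb$gene_id == "gC"], "M")
  expect_false(gb$switch[gb$gene_id == "gC"])
})

test_that("adding a biased node never removes a gene's bias flag", {
  d <- wb_design()
  v <- matrix(rnorm(2 * 30), 2, 30)
  rownames(v) <- c("n1", "n2"); colnames(v) <- d$sample_id
  nodes <- node_matrix(v, d, tibble::tibble(node_id = c("n1", "n2"),
                                            kind = "transcription",
                                            gene_id = c("gA", "gA")))
  de <- tidyr::expand_grid(node_id = c("n1", "n2"),
                           stage = factor(stage_levels(), stage_levels()))
  de$direction <- "none"
  de$direction[de$node_id == "n1" & de$stage == "adult"] <- "M"
  before <- classify_gene_bias(de, nodes)
  de$direction[de$node_id == "n2" & de$stage == "pupa"] <- "F"
  after <- classify_gene_bias(de, nodes)
  expect_true(after$ever_m[after$gene_id == "gA"])
  expect_equal(before$bias_adult, after$bias_adult)
})

test_that("switch depletion testing matches the hypergeometric oracle", {
  gb <- tibble::tibble(ever_m = rep(c(TRUE, TRUE, FALSE, FALSE), c(10, 90, 90, 810)),
                       ever_f = rep(c(TRUE, FALSE, TRUE, FALSE), c(10, 90, 90, 810)))
  res <- test_switch_depletion(gb)
  # P(X <= 10) for the 2x2 margins, by explicit hypergeometric sum
  oracle <- sum(vapply(0:10, function(k) {
    exp(lchoose(100, k) + lchoose(900, 100 - k) - lchoose(1000, 100))
  }, numeric(1)))
  expect_equal(res$p, oracle, tolerance = 1e-12)

  # zero overlap with large margins is extreme depletion
  gb2 <- tibble::tibble(ever_m = rep(c(TRUE, FALSE, FALSE), c(200, 200, 600)),
                        ever_f = rep(c(FALSE, TRUE, FALSE), c(200, 200, 600)))
  expect_lt(test_switch_depletion(gb2)$p, 1e-10)

  # degenerate margin warns and returns 1
  gb3 <- tibble::tibble(ever_m = rep(TRUE, 5), ever_f = rep(c(TRUE, FALSE), c(2, 3)))
  expect_warning(res3 <- test_switch_depletion(gb3), "degenerate")
  expect_equal(res3$p, 1)
})

test_that("switch depletion p-values are uniform under independence", {
  set.seed(35)
  ps <- replicate(100, {
    gb <- tibble::tibble(ever_m = runif(400) < 0.3, ever_f = runif(400) < 0.3)
    test_switch_depletion(gb)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("gonad contrasts flag planted tissue-enriched genes", {
  d <- generate_design()
  rec <- matrix(0, 3, 2); false_pos <- 0
  for (s in 1:3) {
    m <- generate_gene_models(250, isoform_rate = 0, seed = s)
    gon <- rbind(data.frame(gene_id = m$genes$gene_id[1:50], tissue = "testis", lfc = 3),
                 data.frame(gene_id = m$genes$gene_id[51:100], tissue = "ovary", lfc = 3))
    sim <- generate_expression(d, m, effect_spec(gonad = gon, seed = 100 + s))
    nd <- decompose_nodes(sim$exons, m)
    gb <- suppressWarnings(fit_gonad_bias(nd))
    tf <- gb$genes$gene_id[gb$genes$gonad_status == "testis"]
    of <- gb$genes$gene_id[gb$genes$gonad_status == "ovary"]
    rec[s, ] <- c(sum(m$genes$gene_id[1:50] %in% tf), sum(m$genes$gene_id[51:100] %in% of))
    false_pos <- false_pos + sum(!tf %in% m$genes$gene_id[1:50]) +
      sum(!of %in% m$genes$gene_id[51:100])
  }
  expect_gte(mean(rec), 45)
  expect_lte(false_pos / 3, 2)
})

test_that("a gonad profile identical to the whole body yields zero flags", {
  d <- generate_design()
  set.seed(36)
  v <- matrix(rnorm(30 * nrow(d), 5), 30)
  rownames(v) <- paste0("n", 1:30); colnames(v) <- d$sample_id
  # copy each gonad sample from its matched whole-body replicate
  for (i in which(d$tissue != "whole")) {
    j <- which(d$tissue == "whole" & d$stage == d$stage[i] &
                 d$sex == d$sex[i] & d$replicate == d$replicate[i])
    v[, i] <- v[, j]
  }
  nodes <- node_matrix(v, d, tibble::tibble(node_id = rownames(v),
                                            kind = "transcription",
                                            gene_id = rownames(v)))
  gb <- suppressWarnings(fit_gonad_bias(nodes))
  expect_equal(sum(gb$nodes$testis), 0)
  expect_equal(sum(gb$nodes$ovary), 0)
})

test_that("gonad analysis requires gonad samples", {
  d <- wb_design()
  nm <- toy_node_matrix(matrix(rnorm(60), 2), d)
  expect_error(fit_gonad_bias(nm), "testis")
})

test_that("cluster gonad enrichment applies the count filter and the exact test", {
  flags <- tibble::tibble(
    node_id = paste0("n", 1:200),
    testis = rep(c(TRUE, FALSE), c(30, 170)),
    ovary = FALSE)
  clusters <- tibble::tibble(node_id = paste0("n", 1:200),
                             cluster = rep(c("hot", "cold"), c(40, 160)))
  # "hot" holds 30 testis nodes of 40; "cold" none
  en <- enrich_clusters_gonad(clusters, flags, min_count = 5)
  expect_equal(nrow(en), 1)
  expect_equal(en$cluster, "hot")
  expect_true(en$enriched)
  expect_equal(en$p, hypergeom_greater(30, 10, 0, 160), tolerance = 1e-10)

  # a cluster below min_count is skipped
  flags2 <- flags; flags2$testis <- rep(c(TRUE, FALSE), c(4, 196))
  expect_equal(nrow(enrich_clusters_gonad(clusters, flags2, min_count = 5)), 0)
})

test_that("linkage-group enrichment is one-tailed against the other groups pooled", {
  set.seed(37)
  n <- 600
  gb <- tibble::tibble(
    gene_id = paste0("g", 1:n),
    ever_m = c(rep(c(TRUE, FALSE), c(49, 60)), runif(n - 109) < 0.17),
    ever_f = FALSE, switch = FALSE)
  ann <- tibble::tibble(gene_id = paste0("g", 1:n),
                        linkage_group = c(rep("LG4.1", 109),
                                          rep(sprintf("LG%02d", 1:10), length.out = n - 109)))
  en <- suppressWarnings(enrich_linkage_groups(gb, ann))
  hit <- en[en$linkage_group == "LG4.1" & en$sex == "M", ]
  expect_true(hit$enriched)
  expect_equal(hit$n_biased, 49)
  # p equals the explicit hypergeometric sum for its 2x2 table
  a <- hit$n_biased; b <- hit$n_genes - a
  flag_rest <- sum(gb$ever_m) - a; rest <- n - hit$n_genes - flag_rest
  expect_equal(hit$p, hypergeom_greater(a, b, flag_rest, rest), tolerance = 1e-10)
  # background-rate groups are not called
  expect_false(any(en$enriched[en$linkage_group != "LG4.1"]))
})

test_that("switch genes are excluded before linkage enrichment", {
  gb <- tibble::tibble(gene_id = paste0("g", 1:100),
                       ever_m = c(rep(TRUE, 50), rep(FALSE, 50)),
                       ever_f = c(rep(TRUE, 50), rep(FALSE, 50)),
                       switch = c(rep(TRUE, 50), rep(FALSE, 50)))
  ann <- tibble::tibble(gene_id = paste0("g", 1:100),
                        linkage_group = rep(c("A", "B"), 50))
  en <- suppressWarnings(enrich_linkage_groups(gb, ann))
  expect_equal(unique(en$n_genes), 25)  # only the 50 non-switch genes remain
  expect_equal(sum(en$n_biased), 0)
})
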