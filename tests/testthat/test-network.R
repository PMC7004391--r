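test_that("soft-thresholded adjacency follows the |r|^beta convention", {
  d <- wb_design()
  # construct two profiles with exact correlation 0.9
  set.seed(11)
  x <- rnorm(30)
  z <- residuals(lm(rnorm(30) ~ x))
  y <- 0.9 * scale(x)[, 1] + sqrt(1 - 0.81) * scale(z)[, 1]
  nm <- toy_node_matrix(rbind(a = scale(x)[, 1], b = y), d)
  adj <- correlation_adjacency(nm, beta = 30, method = "pearson")
  expect_equal(adj$a["a", "b"], 0.9^30, tolerance = 1e-10)
  expect_equal(unname(diag(adj$a)), rep(0, 2))

  # identical nodes at beta 1; perfectly anti-correlated nodes are a = 1
  nm2 <- toy_node_matrix(rbind(a = x, b = x, c = -x), d)
  adj2 <- correlation_adjacency(nm2, beta = 1, method = "pearson")
  expect_equal(adj2$a["a", "b"], 1)
  expect_equal(adj2$a["a", "c"], 1)

  expect_error(correlation_adjacency(nm, beta = 0), "beta")
})

test_that("zero-variance nodes get zero correlations with a warning", {
  d <- wb_design()
  v <- rbind(a = rnorm(30), b = rep(1, 30))
  expect_warning(adj <- correlation_adjacency(toy_node_matrix(v, d), beta = 2),
                 "zero-variance")
  expect_equal(adj$a["a", "b"], 0)
})

test_that("raising beta weakly shrinks every off-diagonal weight", {
  d <- wb_design()
  set.seed(12)
  nm <- toy_node_matrix(matrix(rnorm(10 * 30), 10), d)
  a1 <- correlation_adjacency(nm, beta = 2)$a
  a2 <- correlation_adjacency(nm, beta = 6)$a
  off <- upper.tri(a1)
  expect_true(all(a2[off] <= a1[off] + 1e-12))
})

test_that("bicor agrees with Pearson on clean data and resists one outlier", {
  set.seed(13)
  x <- rnorm(40)
  y <- x + rnorm(40, 0, 0.2)
  m <- rbind(x, y)
  expect_equal(cor_nodes(m, "bicor")[1, 2], cor_nodes(m, "pearson")[1, 2],
               tolerance = 0.05)
  y2 <- y
  y2[1] <- 50  # single gross outlier
  m2 <- rbind(x, y2)
  expect_lt(abs(cor_nodes(m2, "pearson")[1, 2]), 0.6)
  expect_gt(cor_nodes(m2, "bicor")[1, 2], 0.9)
})

test_that("the scale-free criterion selects the lowest adequate power", {
  # exact power-law degree sequence fits with R^2 ~ 1
  k <- rep(1:20, times = round(1000 * (1:20)^-2))
  ft <- scale_free_fit(k)
  expect_gt(ft$r_squared, 0.9)
  expect_lt(ft$slope, 0)

  d <- wb_design()
  nd <- generate_node_data(d, 8, 12, effect_spec(baseline_cor = 0.7, seed = 21))
  sel <- suppressWarnings(select_soft_power(nd$nodes, 1:8))
  scan <- attr(sel, "scan")
  hit <- scan$beta[scan$r_squared >= 0.8 & scan$slope < 0]
  oracle <- if (length(hit)) hit[1] else scan$beta[which.max(scan$r_squared)]
  expect_equal(as.integer(sel), oracle)

  # i.i.d. noise cannot reach the target: warning path, argmax returned
  nd2 <- toy_node_matrix(matrix(rnorm(20 * 30), 20), d)
  expect_warning(sel2 <- select_soft_power(nd2, c(1, 2, 3)), "best fit")
  expect_true(as.integer(sel2) %in% 1:3)
})

test_that("planted blocks are recovered by TOM clustering", {
  d <- wb_design()
  ari <- replicate(5, {
    s <- sample.int(1e6, 1)
    nd <- generate_node_data(d, 2, 25,
                             effect_spec(baseline_cor = 0.9, stage_sd = 0,
                                         noise_sd = 0.05, seed = s))
    adj <- correlation_adjacency(nd$nodes, beta = 6)
    cl <- detect_clusters(adj)
    adjusted_rand(cl$cluster, nd$clusters$cluster)
  })
  expect_gte(min(ari), 0.95)
})

test_that("provided labels pass through and must be complete", {
  a <- toy_adjacency(matrix(0.5, 4, 4))
  lab <- tibble::tibble(node_id = paste0("n", 1:4), cluster = c("x", "x", "y", "y"))
  out <- detect_clusters(a, "provided", labels = lab)
  expect_equal(out$cluster, lab$cluster)
  expect_error(detect_clusters(a, "provided", labels = lab[1:3, ]), "cover")
})

test_that("small groups fall into the unassigned label", {
  d <- wb_design()
  set.seed(14)
  base1 <- rnorm(30); base2 <- rnorm(30)
  v <- rbind(matrix(rep(base1, 6), 6, byrow = TRUE) + rnorm(180, 0, 0.1),
             matrix(rep(base2, 6), 6, byrow = TRUE) + rnorm(180, 0, 0.1),
             lone = rnorm(30))
  rownames(v) <- c(paste0("a", 1:6), paste0("b", 1:6), "lone")
  adj <- correlation_adjacency(toy_node_matrix(v, d), beta = 6)
  cl <- detect_clusters(adj, min_size = 5)
  expect_equal(cl$cluster[cl$node_id == "lone"], "grey")
  expect_equal(length(setdiff(unique(cl$cluster), "grey")), 2)
})

test_that("node topology reproduces the regulator and interactor archetypes", {
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  tp <- node_topology(toy_adjacency(star), tibble::tibble(node_id = paste0("n", 1:5),
                                                          cluster = "c"))
  expect_equal(tp$density[1], 1)
  expect_equal(tp$clustering_coef[1], 0)
  expect_equal(tp$hub_score[1], 1)

  clique <- matrix(1, 4, 4)
  tp2 <- node_topology(toy_adjacency(clique), tibble::tibble(node_id = paste0("n", 1:4),
                                                             cluster = "c"))
  expect_equal(tp2$clustering_coef, rep(1, 4))
  expect_equal(tp2$hub_score, rep(0, 4))
})

test_that("node topology matches the brute-force oracle on random small graphs", {
  set.seed(15)
  for (rep in 1:50) {
    n <- sample(3:5, 1)
    a <- matrix(runif(n * n), n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    tp <- node_topology(toy_adjacency(a),
                        tibble::tibble(node_id = paste0("n", seq_len(n)), cluster = "c"))
    or <- brute_topology(a)
    expect_equal(tp$density, or$kd, tolerance = 1e-12)
    expect_equal(tp$clustering_coef, or$cc, tolerance = 1e-12)
    expect_equal(tp$hub_score, or$hub, tolerance = 1e-12)
    expect_true(all(tp$hub_score <= tp$density + 1e-12))
  }
})

test_that("cluster topology statistics match hand computation", {
  clique <- matrix(1, 4, 4)
  nm <- toy_node_matrix(matrix(rnorm(120), 4, 30))
  ct <- cluster_topology(toy_adjacency(clique),
                         tibble::tibble(node_id = paste0("n", 1:4), cluster = "c"),
                         nm)
  expect_equal(ct$density, 1)
  expect_equal(ct$heterogeneity, 0)
  expect_equal(ct$diameter, 0, tolerance = 1e-9)

  # 4-node weighted fixture: diameter equals exhaustive shortest-path search
  a <- matrix(0.1, 4, 4)
  a[1, 2] <- a[2, 1] <- 0.9
  a[2, 3] <- a[3, 2] <- 0.8
  a[3, 4] <- a[4, 3] <- 0.7
  diag(a) <- 0
  ct2 <- cluster_topology(toy_adjacency(a),
                          tibble::tibble(node_id = paste0("n", 1:4), cluster = "c"),
                          nm)
  d <- 1 - a; diag(d) <- 0
  all_pairs <- combn(4, 2)
  dist_or <- function(i, j) {
    nodes <- setdiff(1:4, c(i, j))
    cand <- c(d[i, j],
              d[i, nodes[1]] + d[nodes[1], j],
              d[i, nodes[2]] + d[nodes[2], j],
              d[i, nodes[1]] + d[nodes[1], nodes[2]] + d[nodes[2], j],
              d[i, nodes[2]] + d[nodes[2], nodes[1]] + d[nodes[1], j])
    min(cand)
  }
  diam_or <- max(apply(all_pairs, 2, function(p) dist_or(p[1], p[2])))
  expect_equal(ct2$diameter, diam_or, tolerance = 1e-9)
})

test_that("splicing and duplicate proportions are normalised to network shares", {
  d <- wb_design()
  v <- matrix(rnorm(6 * 30), 6, 30)
  rownames(v) <- paste0("n", 1:6)
  colnames(v) <- d$sample_id
  nodes <- node_matrix(v, d, tibble::tibble(
    node_id = paste0("n", 1:6),
    kind = rep(c("transcription", "splicing"), 3),
    gene_id = paste0("g", 1:6)))
  a <- matrix(0.5, 6, 6)
  cl <- tibble::tibble(node_id = paste0("n", 1:6), cluster = rep(c("x", "y"), each = 3))
  genes <- tibble::tibble(gene_id = paste0("g", 1:6),
                          paralog_family = c("f1", "f1", "f2", "f3", "f4", "f5"))
  ct <- cluster_topology(toy_adjacency(a), cl, nodes, genes)
  # cluster x holds 1 splicing node of 3 vs network share 1/2
  expect_equal(ct$prop_splicing[ct$cluster == "x"], (1 / 3) / (1 / 2))
  # duplicated genes: g1, g2 (family f1), both in cluster x
  expect_equal(ct$prop_duplicated[ct$cluster == "x"], (2 / 3) / (2 / 6))
  expect_equal(ct$prop_duplicated[ct$cluster == "y"], 0)
})
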