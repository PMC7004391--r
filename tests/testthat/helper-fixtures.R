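# shared fixture builders (everything generated in code; no stored data)

wb_design <- function(n_reps = 3) generate_design(n_reps, with_gonads = FALSE)

# an exon_matrix with arbitrary values and a minimal one-gene map
toy_exon_matrix <- function(values, n_con = nrow(values)) {
  n_s <- ncol(values)
  design <- tibble::tibble(
    sample_id = paste0("s", seq_len(n_s)),
    stage = rep(stage_levels(), length.out = n_s),
    sex = rep(c("F", "M"), length.out = n_s),
    replicate = seq_len(n_s),
    tissue = "whole"
  )
  rownames(values) <- paste0("e", seq_len(nrow(values)))
  colnames(values) <- design$sample_id
  exon_map <- tibble::tibble(
    exon_id = rownames(values),
    gene_id = "g1",
    constitutive = seq_len(nrow(values)) <= n_con,
    splice_group = ifelse(seq_len(nrow(values)) <= n_con, NA_integer_, 1L)
  )
  exon_matrix(values, design, exon_map)
}

# node_matrix directly from a values matrix (transcription nodes)
toy_node_matrix <- function(values, design = NULL) {
  if (is.null(design)) {
    design <- wb_design()[seq_len(ncol(values)), ]
  }
  colnames(values) <- design$sample_id
  ids <- rownames(values) %||% paste0("n", seq_len(nrow(values)))
  rownames(values) <- ids
  node_matrix(values, design,
              tibble::tibble(node_id = ids, kind = "transcription", gene_id = ids))
}

# wrap a raw symmetric weight matrix as an adjacency object
toy_adjacency <- function(a, beta = 1L) {
  if (is.null(rownames(a))) rownames(a) <- colnames(a) <- paste0("n", seq_len(nrow(a)))
  diag(a) <- 0
  structure(list(a = a, beta = as.integer(beta), method = "pearson"),
            class = "adjacency")
}

# independent one-tailed ("greater") Fisher p via explicit hypergeometric sum
hypergeom_greater <- function(a, b, c, d) {
  # P(X >= a) with X ~ Hypergeom(m = a + b draws from (a + c) successes,
  # (b + d) failures)
  m <- a + b
  k_max <- min(m, a + c)
  sum(vapply(a:k_max, function(k) {
    exp(lchoose(a + c, k) + lchoose(b + d, m - k) - lchoose(a + b + c + d, m))
  }, numeric(1)))
}

# adjusted Rand index between two label vectors
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# brute-force triple-loop node topology for small graphs
brute_topology <- function(a) {
  n <- nrow(a)
  kd <- cc <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(a[i, -i])
    kd[i] <- k / (n - 1)
    num <- 0
    for (j in seq_len(n)) {
      for (l in seq_len(n)) {
        if (j != i && l != i && j != l) num <- num + a[i, j] * a[j, l] * a[l, i]
      }
    }
    den <- k^2 - sum(a[i, -i]^2)
    cc[i] <- if (den > 1e-300) num / den else 0
  }
  list(kd = kd, cc = cc, hub = kd * (1 - cc))
}
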