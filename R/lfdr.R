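#' Local false discovery rates from p-values
#'
#' Two-component empirical-null estimator: the p-value density is modelled
#' as `f(p) = pi0 + (1 - pi0) f1(p)` with a uniform null component, and the
#' local FDR of each test is `lfdr(p) = pi0 / f(p)` (capped at 1). The
#' mixture density `f` is a Grenander-type monotone fit: an equal-count
#' histogram of the p-values, lightly shrunk towards the uniform density and
#' made non-increasing by weighted pool-adjacent-violators. Evaluating the
#' decreasing-density estimate on bins rather than on individual order
#' statistics keeps the left edge stable under a true null (the raw
#' Grenander estimator overshoots near zero), at the price of requiring the
#' alternative to contribute appreciable mass — appropriate for the
#' node/cluster differential-expression sweeps this function serves, where
#' many tests are truly non-null. `pi0` is estimated from the upper tail
#' (fraction of p-values above 0.75, rescaled; the conventional tail
#' cutoff).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param threshold Significance threshold on the lFDR scale; calls are
#'   `lfdr < threshold`. Default 0.05.
#' @return A tibble with columns `p`, `lfdr`, `significant`.
#' @examples
#' compute_lfdr(c(runif(200), runif(50, 0, 1e-6)))
#' @export
compute_lfdr <- function(p, threshold = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  ok <- !is.na(p)
  if (sum(ok) < 50) {
    warnf("fewer than 50 p-values (%d): lFDR density estimate may be unstable", sum(ok))
  }
  lf <- rep(NA_real_, length(p))
  lf[ok] <- lfdr_binned(p[ok])
  tibble(p = p, lfdr = lf, significant = !is.na(lf) & lf < threshold)
}

estimate_pi0 <- function(p, lambda = 0.75) {
  min(1, mean(p > lambda) / (1 - lambda))
}

# binned monotone-density lfdr (see compute_lfdr)
lfdr_binned <- function(p, shrink = 0.2) {
  n <- length(p)
  if (n == 0) return(numeric())
  if (all(p == p[1])) return(rep(1, n))  # degenerate: stay conservative
  pi0 <- estimate_pi0(p)
  k <- max(3L, min(40L, floor(n / 25)))
  br <- unique(quantile(p, seq(0, 1, length.out = k + 1), type = 1, names = FALSE))
  br[1] <- 0
  br[length(br)] <- 1
  br <- unique(br)
  if (length(br) < 3) br <- sort(unique(c(0, median(p), 1)))
  cnt <- tabulate(findInterval(p, br, rightmost.closed = TRUE, all.inside = TRUE),
                  length(br) - 1)
  w <- diff(br)
  dens <- ((cnt / n) / w + shrink) / (1 + shrink)
  dens <- pava_decreasing(dens, w)
  f <- dens[findInterval(p, br, rightmost.closed = TRUE, all.inside = TRUE)]
  lf <- pmin(1, pi0 / pmax(f, 1e-12))
  o <- order(p)
  lf[o] <- cummax(lf[o])
  lf
}

# Raw Grenander lfdr on order statistics: the decreasing density is the
# slope of the least concave majorant of the ECDF on [0, 1]. Sensitive to
# single extreme points (an observation far below the rest of the sample
# yields a large density spike and hence a small lfdr), which is what the
# permutation-calibrated differential-correlation stages need: there a
# single truly differential cluster must be resolvable against an explicit
# empirical null.
lfdr_grenander <- function(p) {
  n <- length(p)
  if (n == 0) return(numeric())
  if (all(p == p[1])) return(rep(1, n))
  pi0 <- estimate_pi0(p)
  ps <- sort(unique(pmax(p, 1e-300)))
  cnt <- tabulate(match(pmax(p, 1e-300), ps), length(ps))
  x <- c(0, ps, if (ps[length(ps)] < 1) 1)
  mass <- c(cnt / n, if (ps[length(ps)] < 1) 0)
  gaps <- diff(x)
  slopes <- mass / gaps
  dens <- pava_decreasing(slopes, gaps)
  f_at <- dens[match(pmax(p, 1e-300), ps)]
  lf <- pmin(1, pi0 / pmax(f_at, 1e-12))
  o <- order(p)
  lf[o] <- cummax(lf[o])
  lf
}

# weighted pool-adjacent-violators for a non-increasing fit
pava_decreasing <- function(y, w) {
  n <- length(y)
  vals <- y; wts <- w; sizes <- rep(1L, n); m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    vals[m] <- y[i]; wts[m] <- w[i]; sizes[m] <- 1L
    while (m > 1L && vals[m - 1L] < vals[m]) {
      tw <- wts[m - 1L] + wts[m]
      vals[m - 1L] <- (vals[m - 1L] * wts[m - 1L] + vals[m] * wts[m]) / tw
      wts[m - 1L] <- tw
      sizes[m - 1L] <- sizes[m - 1L] + sizes[m]
      m <- m - 1L
    }
  }
  rep(vals[seq_len(m)], sizes[seq_len(m)])
}

# Map observed p-values through a permutation null and compute their lfdr.
# q_i = (#{null <= p_i} + p_i) / (n_null + 1) is the null ECDF with a
# continuity correction that falls back on the p-value itself below the
# resolution of the permutation sample (permutation p-values are themselves
# p-values, so sub-resolution tail behaviour is taken as uniform). Under the
# null q is uniform; the Grenander lfdr of q is returned.
lfdr_against_null <- function(p_obs, p_null) {
  if (!length(p_null)) stopf("empty permutation null")
  counts <- vapply(p_obs, function(p) sum(p_null <= p), numeric(1))
  q <- (counts + pmin(pmax(p_obs, 0), 1)) / (length(p_null) + 1)
  lfdr_grenander(q)
}
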