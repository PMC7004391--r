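#' Robust correlation between node profiles
#'
#' Correlation matrix across the rows of a node-by-sample matrix. The
#' default is the biweight midcorrelation (median/MAD-based weights,
#' tuning constant 9), the standard robust choice for weighted
#' co-expression networks; `method = "pearson"` is available behind a flag.
#' Rows whose MAD is zero fall back to mean/SD standardisation for that row;
#' zero-variance rows get correlation 0 with a warning.
#'
#' @param x Numeric matrix (features x samples).
#' @param method `"bicor"` (default) or `"pearson"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
cor_nodes <- function(x, method = c("bicor", "pearson")) {
  method <- match.arg(method)
  zv <- apply(x, 1, function(r) var(r) == 0 || !all(is.finite(r)))
  if (any(zv)) warnf("%d zero-variance nodes: correlations set to 0", sum(zv))
  out <- matrix(0, nrow(x), nrow(x), dimnames = list(rownames(x), rownames(x)))
  ok <- !zv
  if (any(ok)) {
    z <- if (method == "bicor") bicor_standardise(x[ok, , drop = FALSE]) else {
      xs <- x[ok, , drop = FALSE] - rowMeans(x[ok, , drop = FALSE])
      xs / sqrt(rowSums(xs^2))
    }
    out[ok, ok] <- tcrossprod(z)
  }
  diag(out) <- 1
  pmin(pmax(out, -1), 1)
}

# rows standardised so that tcrossprod() gives the biweight midcorrelation:
# u = (x - med) / (9 * mad_raw); w = (1 - u^2)^2 on |u| < 1; row is
# w * (x - med), scaled to unit norm. Zero-MAD rows use mean/SD (Pearson
# fallback), matching the usual robust-correlation implementation.
bicor_standardise <- function(x) {
  med <- apply(x, 1, median)
  madv <- apply(x, 1, function(r) median(abs(r - median(r))))
  z <- x - med
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    if (madv[i] > 0) {
      u <- z[i, ] / (9 * madv[i])
      w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
      v <- z[i, ] * w
    } else {
      v <- x[i, ] - mean(x[i, ])
    }
    out[i, ] <- v / sqrt(sum(v^2))
  }
  out
}
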