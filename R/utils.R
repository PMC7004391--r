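# internal helpers

# run code with a temporary RNG state seeded by `seed`, restoring the caller's
# stream afterwards (so generators are reproducible without clobbering the
# session RNG)
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# log2 signal -> linear abundance; values at or below 0 mean "not detected"
# (the expression scale is log2 ratio over the array noise floor)
lin <- function(x) ifelse(x > 0, 2^x, 0)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

# squeeze values into (eps, 1 - eps); the logit link is undefined at {0, 1}
guard_unit <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

# elementwise |r|^beta without pow() for integer beta (hot path)
abs_pow <- function(r, beta) {
  beta <- as.integer(beta)
  if (beta == 1L) return(abs(r))
  out <- r * r
  b <- 2L
  acc <- out
  while (b + 2L <= beta) {
    acc <- acc * out
    b <- b + 2L
  }
  if (b < beta) acc <- acc * abs(r)
  acc
}
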