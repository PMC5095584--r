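# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  With seed = NULL the expression runs
# under the ambient RNG stream.  Keeps every stochastic operation explicitly
# seedable without mutating hidden global state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Trapezoidal quadrature on an equispaced or general grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Trapezoidal quadrature weights: integral(f) = sum(w * f(x)).
trapz_weights <- function(x) {
  n <- length(x)
  dx <- diff(x)
  w <- numeric(n)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}

# FWHM of a Gaussian <-> standard deviation.
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Tiny deterministic rolling text hash for tagging reports with their
# configuration; not cryptographic.
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(txt)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}
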