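# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# Truncated normal draws by inverse-CDF; deterministic under the current
# RNG stream and exact for any truncation window.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

# Gaussian maximum log-likelihood implied by a residual sum of squares.
gaussian_loglik <- function(sse, n) {
  -n / 2 * (log(2 * pi) + log(sse / n) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
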