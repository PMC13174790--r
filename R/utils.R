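#' @keywords internal
"_PACKAGE"

# Numerical guards used throughout: posteriors are clamped away from {0, 1}
# before odds conversion so that log-LRs stay finite.
.EPS <- 1e-9

clamp01 <- function(p, eps = .EPS) pmin(pmax(p, eps), 1 - eps)

logit <- function(p) log(p) - log1p(-p)

odds <- function(p) p / (1 - p)

#' Evaluate code with a temporary RNG seed
#'
#' Sets the random seed for the duration of `code` and restores the previous
#' RNG state afterwards, so stochastic operations are reproducible without
#' clobbering the caller's stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Deterministic child seed
#'
#' Derives a reproducible sub-seed for replicate `b` of a stochastic
#' operation seeded with `seed`. Kept below 2^31 so it is a valid R integer.
#'
#' @param seed Parent integer seed.
#' @param b Replicate index (non-negative integer).
#' @return An integer seed.
#' @export
child_seed <- function(seed, b) {
  as.integer((as.double(seed) * 48271 + as.double(b) * 16807 + 1) %% 2147483629)
}

# Simpson-rule quadrature of f on [lo, hi] over an odd-length equispaced grid.
simpson <- function(fx, lo, hi) {
  n <- length(fx)
  stopifnot(n >= 3, n %% 2 == 1)
  h <- (hi - lo) / (n - 1)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  sum(w * fx) * h / 3
}

is_prob <- function(p) is.numeric(p) && all(is.finite(p)) && all(p > 0) && all(p < 1)
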