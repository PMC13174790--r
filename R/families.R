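# Parametric score-distribution families on [0, 1].
#
# Four families cover the shapes seen in real predictor score sets: Beta
# (bounded, flexible), truncated Normal (symmetric core), truncated Skew-t
# (skewness + heavy tails) and truncated Skew-Cauchy (extreme tails).
# Truncated families are renormalized to [0, 1] by dividing by the density
# mass on the interval (Simpson quadrature on a fixed fine grid).

#' Names of the four score-distribution families
#' @format Character vector.
#' @export
FAMILIES <- c("beta", "trunc_normal", "trunc_skew_t", "trunc_skew_cauchy")

.QGRID_N <- 2001L
.qgrid <- seq(0, 1, length.out = .QGRID_N)
# coarser grid for quadrature inside optimization loops
.qgrid_fit <- seq(0, 1, length.out = 401L)

# Azzalini skew-t density (location xi, scale omega, slant alpha, df nu);
# skew-Cauchy is the nu = 1 special case.
dskewt <- function(x, xi, omega, alpha, nu) {
  z <- (x - xi) / omega
  2 / omega * stats::dt(z, df = nu) *
    stats::pt(alpha * z * sqrt((nu + 1) / (nu + z^2)), df = nu + 1)
}

# Unnormalized density of a family on the open interval.
family_density_raw <- function(x, family, params) {
  switch(family,
    beta = stats::dbeta(x, params[["shape1"]], params[["shape2"]]),
    trunc_normal = stats::dnorm(x, params[["mean"]], params[["sd"]]),
    trunc_skew_t = dskewt(x, params[["xi"]], params[["omega"]], params[["alpha"]], params[["nu"]]),
    trunc_skew_cauchy = dskewt(x, params[["xi"]], params[["omega"]], params[["alpha"]], 1),
    stop("unknown family: ", family))
}

family_mass <- function(family, params, grid = .qgrid) {
  if (family == "beta") return(1)
  fx <- family_density_raw(grid, family, params)
  fx[!is.finite(fx)] <- 0
  simpson(fx, 0, 1)
}

#' Construct a fitted score distribution on [0, 1]
#'
#' @param family One of `"beta"`, `"trunc_normal"`, `"trunc_skew_t"`,
#'   `"trunc_skew_cauchy"`.
#' @param params Named parameter vector (`shape1`/`shape2`; `mean`/`sd`;
#'   `xi`/`omega`/`alpha`/`nu`; `xi`/`omega`/`alpha`).
#' @return Object of class `score_dist` with a cached normalization mass.
#' @export
score_dist <- function(family, params) {
  family <- match.arg(family, FAMILIES)
  mass <- family_mass(family, params)
  if (!is.finite(mass) || mass <= 0) stop("degenerate density: zero mass on [0, 1]")
  structure(list(family = family, params = as.list(params), mass = mass),
            class = "score_dist")
}

#' Density of a fitted score distribution (normalized to [0, 1])
#'
#' @param dist A `score_dist`.
#' @param x Scores.
#' @return Density values.
#' @export
ddist <- function(dist, x) {
  fx <- family_density_raw(x, dist$family, dist$params) / dist$mass
  fx[x < 0 | x > 1] <- 0
  fx
}

#' Draw samples from a fitted score distribution
#'
#' Beta draws use `rbeta`; truncated families use grid-based inverse-CDF
#' sampling on a 2001-point grid (deterministic given the RNG state).
#'
#' @param dist A `score_dist`.
#' @param n Number of draws.
#' @return Numeric vector of scores in [0, 1].
#' @export
rdist <- function(dist, n) {
  if (n == 0) return(numeric(0))
  if (dist$family == "beta")
    return(stats::rbeta(n, dist$params$shape1, dist$params$shape2))
  fx <- family_density_raw(.qgrid, dist$family, dist$params)
  fx[!is.finite(fx)] <- 0
  cdf <- cumsum((fx[-1] + fx[-.QGRID_N]) / 2) * (1 / (.QGRID_N - 1))
  cdf <- c(0, cdf / cdf[.QGRID_N - 1])
  stats::approx(cdf, .qgrid, xout = stats::runif(n), ties = "ordered")$y
}

# Analytic / quadrature mean, used by moment-recovery tests.
dist_mean <- function(dist) {
  fx <- ddist(dist, .qgrid) * .qgrid
  simpson(fx, 0, 1)
}

#' Maximum-likelihood fit of one family to scores
#'
#' @param scores Scores in (0, 1); at least 5 required.
#' @param family Family name.
#' @return List with `family`, `params`, `loglik`, `converged`, and `dist`
#'   (a `score_dist`) on success; `converged = FALSE` and `dist = NULL` on
#'   optimizer failure.
#' @export
fit_family <- function(scores, family) {
  family <- match.arg(family, FAMILIES)
  s <- clamp01(scores, 1e-6)
  if (length(s) < 5) stop("need at least 5 scores to fit a family")
  m <- mean(s); v <- max(stats::var(s), 1e-6)
  nll_fun <- function(build) {
    function(theta) {
      p <- build(theta)
      mass <- family_mass(family, p, grid = .qgrid_fit)
      if (!is.finite(mass) || mass <= 0) return(1e10)
      ll <- sum(log(pmax(family_density_raw(s, family, p), 1e-300))) - length(s) * log(mass)
      if (!is.finite(ll)) return(1e10)
      -ll
    }
  }
  spec <- switch(family,
    beta = {
      k <- m * (1 - m) / v - 1
      list(init = log(pmax(c(m * k, (1 - m) * k), 0.05)),
           build = function(t) list(shape1 = exp(t[1]), shape2 = exp(t[2])))
    },
    trunc_normal = list(
      init = c(m, log(sqrt(v))),
      build = function(t) list(mean = t[1], sd = exp(t[2]))),
    trunc_skew_t = list(
      init = c(m, log(sqrt(v)), 0, log(5)),
      build = function(t) list(xi = t[1], omega = exp(t[2]), alpha = t[3],
                               nu = 1 + exp(pmin(t[4], 6)))),
    trunc_skew_cauchy = list(
      init = c(m, log(sqrt(v)), 0),
      build = function(t) list(xi = t[1], omega = exp(t[2]), alpha = t[3])))
  fit <- tryCatch(
    stats::optim(spec$init, nll_fun(spec$build), method = "Nelder-Mead",
                 control = list(maxit = if (length(spec$init) > 3) 1500 else 600,
                                reltol = 1e-9)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10)
    return(list(family = family, params = NULL, loglik = -Inf,
                converged = FALSE, dist = NULL))
  params <- spec$build(fit$par)
  list(family = family, params = params, loglik = -fit$value,
       converged = fit$convergence == 0, dist = score_dist(family, params))
}

#' Best-fitting family by maximum log-likelihood
#'
#' Fits all four candidate families and returns the maximum-log-likelihood
#' fit; ties break by family order (`beta`, `trunc_normal`, `trunc_skew_t`,
#' `trunc_skew_cauchy`).
#'
#' @param scores Scores in (0, 1).
#' @return The winning [fit_family()] result.
#' @export
select_best_family <- function(scores) {
  fits <- lapply(FAMILIES, function(f) fit_family(scores, f))
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  if (all(!is.finite(lls))) stop("all four family fits failed")
  fits[[which.max(lls)]]
}

#' A pathogenic/benign distribution pair
#'
#' @param dist_P,dist_B `score_dist` objects for the pathogenic and benign
#'   class-conditional score densities.
#' @return Object of class `dist_pair`.
#' @export
dist_pair <- function(dist_P, dist_B) {
  stopifnot(inherits(dist_P, "score_dist"), inherits(dist_B, "score_dist"))
  structure(list(P = dist_P, B = dist_B), class = "dist_pair")
}

#' Closed-form true posterior under a distribution pair
#'
#' `alpha * f_P(s) / (alpha * f_P(s) + (1 - alpha) * f_B(s))`. Where both
#' densities vanish the prior is returned with a warning.
#'
#' @param s Scores in [0, 1].
#' @param pair A `dist_pair`.
#' @param alpha_true True prior in (0, 1).
#' @return Posterior probabilities.
#' @export
true_posterior <- function(s, pair, alpha_true) {
  stopifnot(inherits(pair, "dist_pair"))
  if (!is_prob(alpha_true)) stop("`alpha_true` must be in (0, 1)")
  fp <- ddist(pair$P, s); fb <- ddist(pair$B, s)
  num <- alpha_true * fp
  den <- num + (1 - alpha_true) * fb
  out <- ifelse(den > 0, num / den, alpha_true)
  if (any(den == 0)) warning("both densities zero at some scores; returning the prior there")
  out
}
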