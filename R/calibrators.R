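# Posterior-calibration methods.
#
# Every method maps a predictor score in [0, 1] to a posterior probability
# of pathogenicity reflecting the pathogenic fraction alpha' of its training
# set. Discriminative methods (Platt, weighted Platt, beta calibration,
# isotonic, smoothed isotonic, spline, monotone NN) regress labels on
# scores; mixture methods fit one density per class and combine them by
# Bayes' rule with alpha'; the local posterior method uses expanding
# symmetric windows. A post-hoc prior-shift correction transports posteriors
# from the training prior alpha' to a target prior alpha.

#' Names of the eleven posterior-calibration methods
#' @format Character vector.
#' @export
CALIBRATION_METHODS <- c("platt", "weighted_platt", "beta_calibration",
                         "skewnormal_mixture", "beta_mixture",
                         "truncnormal_mixture", "isotonic",
                         "smoothed_isotonic", "spline", "mono_post_nn",
                         "local_posterior")

#' Methods whose score-to-posterior map is monotone by construction
#' @format Character vector.
#' @export
MONOTONE_METHODS <- c("platt", "weighted_platt", "beta_calibration",
                      "isotonic", "smoothed_isotonic", "mono_post_nn")

#' Labeled (and optionally unlabeled) scores for one calibration unit
#'
#' @param pathogenic,benign Numeric scores in [0, 1].
#' @param unlabeled Optional unlabeled (population) scores in [0, 1].
#' @param unit_id Identifier (gene symbol or cluster id).
#' @return Object of class `score_set`.
#' @export
score_set <- function(pathogenic, benign, unlabeled = NULL, unit_id = "unit") {
  chk <- function(x, nm) {
    if (length(x) && (any(!is.finite(x)) || any(x < 0 | x > 1)))
      stop(nm, " scores must be finite and within [0, 1]")
    as.numeric(x)
  }
  structure(list(pathogenic = chk(pathogenic, "pathogenic"),
                 benign = chk(benign, "benign"),
                 unlabeled = if (is.null(unlabeled)) NULL else chk(unlabeled, "unlabeled"),
                 unit_id = unit_id),
            class = "score_set")
}

#' Observed pathogenic fraction of a score set
#' @param data A `score_set`.
#' @return `n_P / (n_P + n_B)`.
#' @export
alpha_obs <- function(data) {
  np <- length(data$pathogenic); nb <- length(data$benign)
  if (np + nb == 0) stop("no labeled scores")
  np / (np + nb)
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("score_set '%s': %d pathogenic, %d benign, %d unlabeled\n",
              x$unit_id, length(x$pathogenic), length(x$benign),
              length(x$unlabeled %||% numeric(0))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_calibrator <- function(method, train_alpha, posterior_fn, ok = TRUE,
                           diagnostics = list()) {
  structure(list(method = method, train_alpha = train_alpha,
                 posterior_fn = posterior_fn, ok = ok,
                 fit_diagnostics = diagnostics),
            class = "vep_calibrator")
}

#' @export
print.vep_calibrator <- function(x, ...) {
  cat(sprintf("calibrator '%s' (train alpha' = %.3f, %s)\n", x$method,
              x$train_alpha, if (x$ok) "converged" else "FIT FAILED"))
  invisible(x)
}

#' Predict posteriors from a fitted calibrator
#' @param object A `vep_calibrator`.
#' @param scores Scores in [0, 1].
#' @param ... Unused.
#' @return Posterior probabilities in [0, 1].
#' @export
predict.vep_calibrator <- function(object, scores, ...) {
  if (!object$ok) stop("calibrator '", object$method, "' failed to fit")
  pmin(pmax(object$posterior_fn(scores), 0), 1)
}

labeled_xy <- function(data) {
  x <- c(data$pathogenic, data$benign)
  y <- c(rep(1, length(data$pathogenic)), rep(0, length(data$benign)))
  list(x = x, y = y)
}

fit_platt <- function(data, weighted = FALSE) {
  d <- labeled_xy(data)
  w <- if (weighted) {
    n <- length(d$y)
    ifelse(d$y == 1, n / (2 * sum(d$y == 1)), n / (2 * sum(d$y == 0)))
  } else rep(1, length(d$y))
  fit <- suppressWarnings(stats::glm(d$y ~ d$x, family = stats::binomial(), weights = w))
  cf <- stats::coef(fit)
  function(s) stats::plogis(cf[1] + cf[2] * s)
}

# Three-parameter beta calibration: logistic regression on log(s) and
# -log(1 - s); monotonicity requires both slope coefficients >= 0, and a
# negative slope triggers a refit with the offending term dropped.
fit_beta_calibration <- function(data) {
  d <- labeled_xy(data)
  s <- clamp01(d$x, 1e-6)
  f1 <- log(s); f2 <- -log1p(-s)
  fit <- suppressWarnings(stats::glm(d$y ~ f1 + f2, family = stats::binomial()))
  cf <- stats::coef(fit)
  if (is.na(cf[2]) || cf[2] < 0) {
    fit <- suppressWarnings(stats::glm(d$y ~ f2, family = stats::binomial()))
    cf <- c(stats::coef(fit)[1], 0, stats::coef(fit)[2])
  } else if (is.na(cf[3]) || cf[3] < 0) {
    fit <- suppressWarnings(stats::glm(d$y ~ f1, family = stats::binomial()))
    cf <- c(stats::coef(fit)[1], stats::coef(fit)[2], 0)
  }
  cf[is.na(cf)] <- 0
  function(s) {
    s <- clamp01(s, 1e-6)
    stats::plogis(cf[1] + cf[2] * log(s) + cf[3] * (-log1p(-s)))
  }
}

mixture_family_for <- function(method) {
  switch(method,
    skewnormal_mixture = "trunc_skew_normal",
    beta_mixture = "beta",
    truncnormal_mixture = "trunc_normal")
}

# Truncated skew-normal density fit (not one of the four simulation
# families, so fitted locally here with the same quadrature machinery).
fit_skewnormal_class <- function(s) {
  s <- clamp01(s, 1e-6)
  m <- mean(s); v <- max(stats::var(s), 1e-6)
  dens <- function(x, p) 2 / p$omega * stats::dnorm((x - p$xi) / p$omega) *
    stats::pnorm(p$alpha * (x - p$xi) / p$omega)
  nll <- function(t) {
    p <- list(xi = t[1], omega = exp(t[2]), alpha = t[3])
    fx <- dens(.qgrid_fit, p)
    mass <- simpson(fx, 0, 1)
    if (!is.finite(mass) || mass <= 0) return(1e10)
    ll <- sum(log(pmax(dens(s, p), 1e-300))) - length(s) * log(mass)
    if (!is.finite(ll)) 1e10 else -ll
  }
  fit <- tryCatch(stats::optim(c(m, log(sqrt(v)), 0), nll, method = "Nelder-Mead",
                               control = list(maxit = 400)),
                  error = function(e) NULL)
  if (is.null(fit) || fit$value >= 1e10) return(NULL)
  p <- list(xi = fit$par[1], omega = exp(fit$par[2]), alpha = fit$par[3])
  mass <- simpson(dens(.qgrid, p), 0, 1)
  list(density = function(x) {
    fx <- dens(x, p) / mass
    fx[x < 0 | x > 1] <- 0
    fx
  }, loglik = -fit$value, params = p)
}

fit_mixture_calibrator <- function(data, method) {
  a_tr <- alpha_obs(data)
  fit_one <- function(s) {
    if (method == "skewnormal_mixture") return(fit_skewnormal_class(s))
    fam <- mixture_family_for(method)
    f <- fit_family(s, fam)
    if (is.null(f$dist)) return(NULL)
    list(density = function(x) ddist(f$dist, x), loglik = f$loglik)
  }
  fp <- fit_one(data$pathogenic); fb <- fit_one(data$benign)
  if (is.null(fp) || is.null(fb)) return(NULL)
  function(s) {
    num <- a_tr * fp$density(s)
    den <- num + (1 - a_tr) * fb$density(s)
    ifelse(den > 0, num / den, a_tr)
  }
}

fit_isotonic <- function(data) {
  d <- labeled_xy(data)
  o <- order(d$x, d$y)
  ir <- stats::isoreg(d$x[o], d$y[o])
  xs <- ir$x; ys <- ir$yf
  grp <- cumsum(!duplicated(xs))
  ux <- xs[!duplicated(xs)]
  uy <- as.numeric(tapply(ys, grp, mean))
  function(s) stats::approx(ux, uy, xout = s, method = "constant",
                            rule = 2, f = 0, ties = "ordered")$y
}

# Midpoints of the isotonic step function, joined by a monotone piecewise
# cubic Hermite interpolant (Fritsch-Carlson).
fit_smoothed_isotonic <- function(data) {
  d <- labeled_xy(data)
  o <- order(d$x, d$y)
  ir <- stats::isoreg(d$x[o], d$y[o])
  xs <- ir$x; ys <- ir$yf
  steps <- split(seq_along(ys), cumsum(c(1, diff(ys) != 0)))
  mx <- vapply(steps, function(i) mean(range(xs[i])), numeric(1))
  my <- vapply(steps, function(i) ys[i[1]], numeric(1))
  if (length(mx) < 2) { cv <- my[1]; return(function(s) rep(cv, length(s))) }
  keep <- !duplicated(mx)
  f <- stats::splinefun(mx[keep], my[keep], method = "monoH.FC")
  rng <- range(mx)
  function(s) f(pmin(pmax(s, rng[1]), rng[2]))
}

# SplineCalib-style: cubic smoothing spline on the logit of an isotonic
# pre-fit, smoothing parameter chosen by 5-fold cross-validated log-loss
# (or fixed via `spar`, e.g. when bootstrap refits reuse the full-data CV
# choice).
fit_spline <- function(data, spar_grid = c(0.4, 0.6, 0.8, 1.0), n_folds = 5,
                       seed = 1L, spar = NULL) {
  d <- labeled_xy(data)
  n <- length(d$x)
  eta_of <- function(x, y) {
    ds <- score_set(x[y == 1], x[y == 0])
    iso <- fit_isotonic(ds)
    function(s) logit(clamp01(iso(s), 1e-3))
  }
  if (is.null(spar)) {
    folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
    cv_loss <- vapply(spar_grid, function(sp) {
      loss <- 0
      for (k in seq_len(n_folds)) {
        tr <- folds != k
        if (sum(d$y[tr] == 1) < 2 || sum(d$y[tr] == 0) < 2) return(Inf)
        eta <- eta_of(d$x[tr], d$y[tr])
        fit <- tryCatch(stats::smooth.spline(d$x[tr], eta(d$x[tr]), spar = sp),
                        error = function(e) NULL)
        if (is.null(fit)) return(Inf)
        p <- clamp01(stats::plogis(stats::predict(fit, d$x[!tr])$y), 1e-6)
        loss <- loss - sum(d$y[!tr] * log(p) + (1 - d$y[!tr]) * log(1 - p))
      }
      loss
    }, numeric(1))
    if (all(!is.finite(cv_loss))) return(NULL)
    spar <- spar_grid[which.min(cv_loss)]
  }
  eta <- eta_of(d$x, d$y)
  fit <- tryCatch(stats::smooth.spline(d$x, eta(d$x), spar = spar),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  fn <- function(s) stats::plogis(stats::predict(fit, s)$y)
  attr(fn, "spar") <- spar
  fn
}

#' Fit a posterior-calibration method to a score set
#'
#' @param method One of [CALIBRATION_METHODS]. `"local_posterior"` delegates
#'   to [local_posterior()] with the options `window_frac`, `gnomad_frac`,
#'   `target_prior` (default: the training fraction).
#' @param data A [score_set()]; discriminative methods require at least two
#'   scores per class.
#' @param options Named list of method options (`seed`, `spar_grid`,
#'   `nn_epochs`, `window_frac`, `gnomad_frac`, `target_prior`).
#' @return A `vep_calibrator`. Optimizer failures return an object with
#'   `ok = FALSE` rather than erroring, so a failing method can be excluded
#'   downstream without crashing a pipeline.
#' @export
fit_calibrator <- function(method, data, options = list()) {
  method <- match.arg(method, CALIBRATION_METHODS)
  stopifnot(inherits(data, "score_set"))
  if (length(data$pathogenic) < 2 || length(data$benign) < 2)
    stop("need at least 2 pathogenic and 2 benign scores")
  if (length(unique(c(data$pathogenic, data$benign))) == 1)
    stop("degenerate single-valued scores")
  a_tr <- alpha_obs(data)
  seed <- options$seed %||% 1L
  fn <- tryCatch(switch(method,
    platt = fit_platt(data, weighted = FALSE),
    weighted_platt = fit_platt(data, weighted = TRUE),
    beta_calibration = fit_beta_calibration(data),
    skewnormal_mixture = ,
    beta_mixture = ,
    truncnormal_mixture = fit_mixture_calibrator(data, method),
    isotonic = fit_isotonic(data),
    smoothed_isotonic = fit_smoothed_isotonic(data),
    spline = fit_spline(data, spar_grid = options$spar_grid %||% c(0.4, 0.6, 0.8, 1.0),
                        seed = seed, spar = options$spar),
    mono_post_nn = fit_mono_post_nn(data, epochs = options$nn_epochs %||% 300L,
                                    seed = seed),
    local_posterior = {
      cal <- local_posterior(data,
                             window_frac = options$window_frac %||% 0.10,
                             gnomad_frac = options$gnomad_frac %||% 0,
                             target_prior = options$target_prior %||% a_tr)
      cal$posterior_fn
    }), error = function(e) NULL)
  if (is.null(fn))
    return(new_calibrator(method, a_tr, function(s) rep(NA_real_, length(s)),
                          ok = FALSE, diagnostics = list(error = "fit failure")))
  new_calibrator(method, a_tr, fn,
                 diagnostics = list(spar = attr(fn, "spar")))
}

#' Local posterior calibration (sliding-window method)
#'
#' For each evaluation score a symmetric window expands until it contains at
#' least `window_frac` of the labeled variants and at least `gnomad_frac` of
#' the unlabeled variants; the local posterior combines the window's class
#' counts with the target prior:
#' `alpha * (nP_w / N_P) / (alpha * nP_w / N_P + (1 - alpha) * nB_w / N_B)`.
#'
#' @param data A [score_set()] (unlabeled scores required when
#'   `gnomad_frac > 0`).
#' @param window_frac Fraction of labeled variants per window (0.10, 0.20,
#'   0.30 in the sensitivity grid).
#' @param gnomad_frac Minimum fraction of unlabeled variants per window
#'   (0, 0.03, 0.06 in the grid).
#' @param target_prior Prior used in the local Bayes combination.
#' @return A `vep_calibrator` with method `"local_posterior"`.
#' @export
local_posterior <- function(data, window_frac = 0.10, gnomad_frac = 0,
                            target_prior = alpha_obs(data)) {
  stopifnot(inherits(data, "score_set"))
  if (gnomad_frac > 0 && is.null(data$unlabeled))
    stop("unlabeled scores required when gnomad_frac > 0")
  lab <- sort(c(data$pathogenic, data$benign))
  pat <- sort(data$pathogenic); ben <- sort(data$benign)
  unl <- sort(data$unlabeled %||% numeric(0))
  N_P <- length(pat); N_B <- length(ben); N_L <- length(lab); N_U <- length(unl)
  k_lab <- max(1L, ceiling(window_frac * N_L))
  k_unl <- if (gnomad_frac > 0) max(1L, ceiling(gnomad_frac * N_U)) else 0L
  a <- target_prior
  # minimal half-width so a symmetric window at s holds >= k of sorted x;
  # vectorized over s by sweeping the k + 1 candidate window offsets
  min_halfwidth <- function(s, x, k) {
    n <- length(x)
    if (k > n) return(rep(Inf, length(s)))
    pos <- findInterval(s, x)
    h <- rep(Inf, length(s))
    for (d in 0:k) {
      j <- pos - d + 1L
      ok <- j >= 1L & (j + k - 1L) <= n
      if (!any(ok)) next
      jj <- j[ok]
      h[ok] <- pmin(h[ok], pmax(s[ok] - x[jj], x[jj + k - 1L] - s[ok]))
    }
    h
  }
  fn <- function(s) {
    h <- min_halfwidth(s, lab, k_lab)
    if (k_unl > 0) h <- pmax(h, min_halfwidth(s, unl, k_unl))
    bad <- !is.finite(h)
    if (any(bad)) {
      warning("window cannot satisfy constraints; using full-data counts")
      h[bad] <- 1
    }
    np <- findInterval(s + h, pat) - findInterval(s - h - 1e-12, pat)
    nb <- findInterval(s + h, ben) - findInterval(s - h - 1e-12, ben)
    num <- a * np / N_P
    den <- num + (1 - a) * nb / N_B
    ifelse(den > 0, num / den, a)
  }
  new_calibrator("local_posterior", alpha_obs(data), fn,
                 diagnostics = list(window_frac = window_frac,
                                    gnomad_frac = gnomad_frac,
                                    target_prior = target_prior))
}

#' Prior-shift correction of a calibrated posterior
#'
#' Converts a posterior fitted at training prior `alpha_train` to the
#' target prior `alpha_target`: the implied LR
#' `rho / (1 - rho) * (1 - alpha') / alpha'` is recombined with the target
#' prior odds. Identity when `alpha_train == alpha_target`.
#'
#' @param rho Uncorrected posterior(s) in (0, 1); saturated values are
#'   clamped by epsilon with a warning.
#' @param alpha_train Training pathogenic fraction in (0, 1).
#' @param alpha_target Target prior in (0, 1).
#' @return Corrected posterior probabilities.
#' @export
prior_shift_correct <- function(rho, alpha_train, alpha_target) {
  if (!is_prob(alpha_train) || !is_prob(alpha_target))
    stop("priors must be in (0, 1)")
  if (any(rho <= 0 | rho >= 1)) {
    warning("saturated posteriors clamped by epsilon")
    rho <- clamp01(rho)
  }
  lr <- odds(rho) / odds(alpha_train)
  posterior_from_lr(lr, alpha_target)
}
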