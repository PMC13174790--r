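# Synthetic score-set engine: the printed scenario grid, calibration-set and
# test-set generation, and scenario containers. A scenario fixes the
# class-conditional pair (f_P, f_B), the calibration-set size n, the observed
# pathogenic fraction alpha' in the calibration set, and the true prior alpha
# used for test-set mixing and posterior truth.

GRID_SIZES <- c(25L, 50L, 100L, 300L, 500L, 1000L)
GRID_ALPHA_OBS <- c(0.05, seq(0.1, 0.9, by = 0.1), 0.95)
GRID_ALPHA_TRUE <- c(seq(0.01, 0.10, by = 0.01), 0.2, 0.3, 0.4, 0.5)

#' A simulation scenario
#'
#' @param pair A [dist_pair()].
#' @param n Calibration-set size.
#' @param alpha_obs Observed pathogenic fraction in the calibration set.
#' @param alpha_true True prior probability of pathogenicity.
#' @param n_test Test-set size (default 1000).
#' @param seed Integer seed.
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(pair, n, alpha_obs, alpha_true, n_test = 1000L, seed = 1L) {
  stopifnot(inherits(pair, "dist_pair"), n >= 2,
            alpha_obs > 0, alpha_obs < 1, alpha_true > 0, alpha_true < 1)
  structure(list(pair = pair, n = as.integer(n), alpha_obs = alpha_obs,
                 alpha_true = alpha_true, n_test = as.integer(n_test),
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Full scenario grid for one distribution pair
#'
#' Cartesian product of the calibration sizes \{25, 50, 100, 300, 500,
#' 1000\}, observed fractions \{0.05, 0.1, ..., 0.9, 0.95\} and true priors
#' \{0.01, ..., 0.1, 0.2, 0.3, 0.4, 0.5\}: 6 x 11 x 14 = 924 scenarios.
#'
#' @param pair A [dist_pair()].
#' @param n_test Test-set size per scenario.
#' @param seed Base seed; scenario i receives `child_seed(seed, i)`.
#' @return List of `sim_scenario` objects (length 924).
#' @export
build_grid <- function(pair, n_test = 1000L, seed = 1L) {
  g <- expand.grid(n = GRID_SIZES, alpha_obs = GRID_ALPHA_OBS,
                   alpha_true = GRID_ALPHA_TRUE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i)
    sim_scenario(pair, g$n[i], g$alpha_obs[i], g$alpha_true[i],
                 n_test = n_test, seed = child_seed(seed, i)))
}

#' Sample a calibration score set from a scenario
#'
#' Draws `round(n * alpha_obs)` pathogenic and the remaining benign scores
#' from the scenario's class-conditional densities. At least one score per
#' class is enforced (with a warning) so degenerate sets cannot arise.
#'
#' @param scn A `sim_scenario`.
#' @return A [score_set()].
#' @export
sample_calibration_set <- function(scn) {
  stopifnot(inherits(scn, "sim_scenario"))
  n_p <- round(scn$n * scn$alpha_obs)
  if (n_p < 1 || n_p > scn$n - 1) {
    warning("enforcing at least one score per class")
    n_p <- min(max(n_p, 1), scn$n - 1)
  }
  with_seed(scn$seed, {
    p <- rdist(scn$pair$P, n_p)
    b <- rdist(scn$pair$B, scn$n - n_p)
    score_set(pathogenic = p, benign = b, unit_id = "sim")
  })
}

#' Sample a test set with true posteriors and true evidence points
#'
#' Draws `n_test` scores from the alpha-weighted mixture
#' `alpha * f_P + (1 - alpha) * f_B`, and attaches the closed-form true
#' posterior and the continuous true evidence points under `scale` (built
#' from `alpha_true` when not supplied).
#'
#' @param scn A `sim_scenario`.
#' @param scale Optional `evidence_scale`; default built from the scenario's
#'   true prior.
#' @return data.frame with columns `score`, `label` ("P"/"B"), `posterior_true`,
#'   `ep_true`.
#' @export
sample_test_set <- function(scn, scale = NULL) {
  stopifnot(inherits(scn, "sim_scenario"))
  if (is.null(scale)) scale <- build_evidence_scale(scn$alpha_true)
  with_seed(child_seed(scn$seed, 1e6), {
    from_p <- stats::runif(scn$n_test) < scn$alpha_true
    s <- numeric(scn$n_test)
    s[from_p] <- rdist(scn$pair$P, sum(from_p))
    s[!from_p] <- rdist(scn$pair$B, sum(!from_p))
    post <- true_posterior(s, scn$pair, scn$alpha_true)
    data.frame(score = s, label = ifelse(from_p, "P", "B"),
               posterior_true = post,
               ep_true = ep_from_posterior(post, scale))
  })
}

#' Serialize a scenario grid to JSON
#'
#' @param grid List of `sim_scenario`s from [build_grid()].
#' @param path Optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
scenario_grid_json <- function(grid, path = NULL) {
  rows <- lapply(grid, function(s)
    list(n = s$n, alpha_obs = s$alpha_obs, alpha_true = s$alpha_true,
         n_test = s$n_test, seed = s$seed,
         family_P = s$pair$P$family, family_B = s$pair$B$family))
  js <- jsonlite::toJSON(rows, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
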