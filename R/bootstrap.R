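# Out-of-bag bootstrap posterior envelopes.
#
# Each bootstrap round resamples the labeled scores with replacement, fits
# the calibration method on the resample, and predicts posteriors for the
# out-of-bag scores. Across rounds every score accumulates many estimates;
# the 5th and 95th percentiles form a conservative envelope: in the
# pathogenic-supporting region (full-data fit implies >= +1 point) the 5th
# percentile is used, in the benign-supporting region (<= -1 point) the
# 95th, and in the indeterminate region the full-data fit itself.

#' Conservative out-of-bag bootstrap posterior envelope
#'
#' @param data A [score_set()].
#' @param method Calibration method name (see [CALIBRATION_METHODS]).
#' @param scale An [build_evidence_scale()] object; its prior and thresholds
#'   define the pathogenic / benign / indeterminate regions of the full-data
#'   fit (posteriors are prior-shift corrected from the training fraction to
#'   the scale prior before region assignment).
#' @param n_boot Number of bootstrap rounds (paper-scale default 1000).
#' @param seed Integer seed; round `b` uses `child_seed(seed, b)`.
#' @param options Method options passed to [fit_calibrator()].
#' @return Object of class `posterior_envelope`: list with `grid` (the
#'   sorted labeled scores), `point_estimate`, `lower_05`, `upper_95`,
#'   `conservative` (all prior-corrected to the scale prior), `n_estimates`
#'   per score, `method`, `train_alpha`.
#' @export
oob_bootstrap_envelope <- function(data, method, scale, n_boot = 1000L,
                                   seed = 1L, options = list()) {
  stopifnot(inherits(data, "score_set"), inherits(scale, "evidence_scale"))
  full <- fit_calibrator(method, data, options = c(options, list(seed = seed)))
  if (!full$ok) stop("method '", method, "' failed on the full data")
  # hyperparameters tuned on the full data are reused by bootstrap refits
  if (method == "spline" && !is.null(full$fit_diagnostics$spar))
    options$spar <- full$fit_diagnostics$spar
  a_tr <- alpha_obs(data)
  correct <- function(p) prior_shift_correct(clamp_posterior(p), a_tr, scale$prior)

  x <- c(data$pathogenic, data$benign)
  lab <- c(rep("P", length(data$pathogenic)), rep("B", length(data$benign)))
  o <- order(x)
  x <- x[o]; lab <- lab[o]
  n <- length(x)
  est_mat <- matrix(NA_real_, n_boot, n)
  for (b in seq_len(n_boot)) {
    sd_b <- child_seed(seed, b)
    idx <- with_seed(sd_b, sample.int(n, n, replace = TRUE))
    oob <- which(tabulate(idx, n) == 0L)
    if (length(oob) == 0) next
    bp <- x[idx][lab[idx] == "P"]; bb <- x[idx][lab[idx] == "B"]
    if (length(bp) < 2 || length(bb) < 2 || length(unique(c(bp, bb))) < 2) next
    ds <- score_set(bp, bb, unlabeled = data$unlabeled, unit_id = data$unit_id)
    cal <- fit_calibrator(method, ds, options = c(options, list(seed = sd_b)))
    if (!cal$ok) next
    est_mat[b, oob] <- suppressWarnings(predict(cal, x[oob]))
  }
  n_est <- colSums(!is.na(est_mat))
  if (any(n_est == 0)) {
    warning(sum(n_est == 0), " scores never out-of-bag; falling back to point estimate")
  }
  point <- correct(suppressWarnings(predict(full, x)))
  lo <- hi <- point
  has <- n_est > 0
  lo[has] <- vapply(which(has), function(j)
    stats::quantile(correct(est_mat[!is.na(est_mat[, j]), j]), 0.05, names = FALSE), numeric(1))
  hi[has] <- vapply(which(has), function(j)
    stats::quantile(correct(est_mat[!is.na(est_mat[, j]), j]), 0.95, names = FALSE), numeric(1))
  ep_point <- ep_from_posterior(point, scale)
  conservative <- point
  conservative[ep_point >= 1] <- lo[ep_point >= 1]
  conservative[ep_point <= -1] <- hi[ep_point <= -1]
  structure(list(grid = x, point_estimate = point, lower_05 = lo,
                 upper_95 = hi, conservative = conservative,
                 n_estimates = n_est, method = method, train_alpha = a_tr,
                 prior = scale$prior),
            class = "posterior_envelope")
}

#' Interpolate an envelope posterior onto a regular score grid
#'
#' @param env A `posterior_envelope`.
#' @param grid Target grid (default 1001 equispaced points on [0, 1]).
#' @param which Which posterior to interpolate (`"conservative"`,
#'   `"point_estimate"`, `"lower_05"`, `"upper_95"`).
#' @return List with `grid` and `posterior`.
#' @export
envelope_on_grid <- function(env, grid = seq(0, 1, length.out = 1001),
                             which = "conservative") {
  stopifnot(inherits(env, "posterior_envelope"))
  y <- env[[match.arg(which, c("conservative", "point_estimate",
                               "lower_05", "upper_95"))]]
  ux <- !duplicated(env$grid)
  post <- stats::approx(env$grid[ux], y[ux], xout = grid, rule = 2,
                        ties = "ordered")$y
  list(grid = grid, posterior = post)
}

#' Serialize a posterior envelope to TSV
#' @param env A `posterior_envelope`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_envelope <- function(env, path) {
  df <- data.frame(grid = env$grid, point = env$point_estimate,
                   lo = env$lower_05, hi = env$upper_95,
                   conservative = env$conservative)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
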