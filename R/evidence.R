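# The ACMG/AMP Bayesian evidence engine.
#
# Evidence strengths are expressed as integer points: +1 supporting, +2
# moderate, +3, +4 strong toward pathogenicity, with negative mirror images
# toward benignity. Points combine additively, and a likelihood ratio (LR)
# maps onto the point scale exponentially: LR_x = LR1^x, where LR1 is the LR
# threshold earning +1 point. LR1 itself depends on the prior probability of
# pathogenicity through the constraint that a variant reaching the minimal
# Pathogenic point total attains a fixed posterior probability.

#' Posterior probability from a likelihood ratio
#'
#' Bayes' rule on the odds scale: posterior odds = prior odds x LR.
#'
#' @param lr Positive likelihood ratio(s).
#' @param prior Prior probability of pathogenicity in (0, 1).
#' @return Posterior probability, same length as `lr`.
#' @examples
#' posterior_from_lr(16, 0.1)  # 0.64
#' @export
posterior_from_lr <- function(lr, prior) {
  if (!is.numeric(lr) || any(!is.finite(lr) & !is.infinite(lr)) || any(lr <= 0))
    stop("`lr` must be positive (Inf allowed)")
  if (!is_prob(prior)) stop("`prior` must be in (0, 1)")
  out <- prior * lr / (prior * lr + (1 - prior))
  out[is.infinite(lr)] <- 1
  out
}

#' Likelihood ratio from a posterior probability
#'
#' Exact inverse of [posterior_from_lr()]: the ratio of posterior odds to
#' prior odds. Saturated posteriors (0 or 1) are rejected; callers clamp by
#' a small epsilon first (see [clamp_posterior()]).
#'
#' @param post Posterior probability in (0, 1).
#' @param prior Prior probability in (0, 1).
#' @return Positive likelihood ratio.
#' @export
lr_from_posterior <- function(post, prior) {
  if (!is_prob(post)) stop("`post` must be strictly inside (0, 1); clamp saturated posteriors first")
  if (!is_prob(prior)) stop("`prior` must be in (0, 1)")
  odds(post) / odds(prior)
}

#' Clamp posteriors away from saturation
#'
#' @param post Posterior probabilities.
#' @param eps Clamp margin (default 1e-9).
#' @return Posteriors in `[eps, 1 - eps]`.
#' @export
clamp_posterior <- function(post, eps = .EPS) clamp01(post, eps)

#' Build an evidence scale from a prior
#'
#' Solves for the very-strong odds constant `C` such that the posterior at
#' the minimal Pathogenic point total (`path_points`, default 10) equals
#' `path_posterior` (default 0.99) at the given prior, using the exponential
#' point scaling `LR_x = C^(x/8)`. `LR1 = C^(1/8)` is the +1-point LR
#' threshold; thresholds for x in {-4..-1, +1..+4} and the matching posterior
#' thresholds follow.
#'
#' @param prior Prior probability of pathogenicity in (0, 1).
#' @param clip Integer pair: continuous evidence-point clip (default c(-8, 8)).
#' @param path_points Point total anchoring the constraint (default 10).
#' @param path_posterior Posterior required at the anchor (default 0.99).
#' @return An object of class `evidence_scale`: list with `prior`, `lr1`,
#'   `lr_thresholds` (named -4..4 excluding 0), `posterior_thresholds`,
#'   `clip_min`, `clip_max`, `C`.
#' @export
build_evidence_scale <- function(prior, clip = c(-8L, 8L),
                                 path_points = 10, path_posterior = 0.99) {
  if (!is_prob(prior)) stop("`prior` must be in (0, 1)")
  stopifnot(length(clip) == 2, clip[1] < 0, clip[2] > 0)
  target_odds <- odds(path_posterior)
  po <- odds(prior)
  # posterior odds at the anchor total: prior odds * C^(path_points/8)
  f <- function(logC) log(po) + (path_points / 8) * logC - log(target_odds)
  root <- tryCatch(
    stats::uniroot(f, lower = log(1), upper = log(1e12), tol = 1e-12),
    error = function(e) stop("no root for C in bracket [1, 1e12]: ", conditionMessage(e))
  )
  C <- exp(root$root)
  lr1 <- C^(1 / 8)
  levels <- c(-4:-1, 1:4)
  lr_thr <- stats::setNames(lr1^levels, levels)
  post_thr <- stats::setNames(posterior_from_lr(lr_thr, prior), levels)
  structure(
    list(prior = prior, lr1 = lr1, C = C,
         lr_thresholds = lr_thr, posterior_thresholds = post_thr,
         clip_min = as.integer(clip[1]), clip_max = as.integer(clip[2])),
    class = "evidence_scale")
}

#' @export
print.evidence_scale <- function(x, ...) {
  cat(sprintf("ACMG/AMP evidence scale: prior = %.4g, LR1 = %.4g, C = %.4g\n",
              x$prior, x$lr1, x$C))
  cat("LR thresholds:\n")
  print(signif(x$lr_thresholds, 4))
  invisible(x)
}

#' Continuous and integer evidence points from a likelihood ratio
#'
#' The continuous point value is `log(lr) / log(LR1)`, clipped to the scale's
#' `[clip_min, clip_max]`. The integer value truncates toward zero, so a
#' variant must meet or exceed `LR_x` to earn `x` points (conservative).
#'
#' @param lr Positive likelihood ratio(s).
#' @param scale An `evidence_scale`.
#' @return List with `ep_continuous` and `ep_integer` (vectors).
#' @export
evidence_points <- function(lr, scale) {
  stopifnot(inherits(scale, "evidence_scale"))
  if (scale$lr1 <= 1) stop("invalid scale: lr1 must exceed 1")
  if (any(lr <= 0 | is.na(lr))) stop("`lr` must be positive")
  ep <- log(lr) / log(scale$lr1)
  ep <- pmin(pmax(ep, scale$clip_min), scale$clip_max)
  list(ep_continuous = ep, ep_integer = as.integer(trunc(ep)))
}

#' Continuous evidence points from posteriors
#'
#' Convenience wrapper: clamps posteriors, converts to LR against the
#' scale's prior, and returns continuous evidence points.
#'
#' @param post Posterior probabilities.
#' @param scale An `evidence_scale`.
#' @return Numeric vector of continuous (clipped) evidence points.
#' @export
ep_from_posterior <- function(post, scale) {
  lr <- lr_from_posterior(clamp_posterior(post), scale$prior)
  evidence_points(lr, scale)$ep_continuous
}

#' Extract evidence score intervals from a posterior curve
#'
#' Given posteriors on a score grid, returns for each point level the score
#' regions where the posterior reaches that level's posterior threshold but
#' not the next level's (the exclusive band); the complement is the
#' indeterminate region (0 points).
#'
#' @param grid Ordered score grid.
#' @param posterior Posterior probabilities on the grid.
#' @param scale An `evidence_scale`.
#' @return Object of class `score_intervals`: list with `levels` (named list
#'   mapping "-4".."4" to matrices with columns lo, hi of contiguous score
#'   intervals) and `assignment` (integer level per grid point).
#' @export
score_intervals <- function(grid, posterior, scale) {
  if (length(grid) == 0) stop("empty grid")
  stopifnot(length(grid) == length(posterior), !is.unsorted(grid))
  pt <- scale$posterior_thresholds
  lev <- integer(length(grid))
  for (x in 1:4) lev[posterior >= pt[as.character(x)]] <- x
  for (x in -1:-4) lev[posterior <= pt[as.character(x)] & lev == 0] <- x
  # benign thresholds decrease with |x|; deepest applicable level wins
  for (x in c(-2L, -3L, -4L)) lev[posterior <= pt[as.character(x)]] <- x
  out <- list()
  for (x in c(-4:-1, 1:4)) {
    idx <- which(lev == x)
    if (length(idx) == 0) { out[[as.character(x)]] <- matrix(numeric(0), 0, 2,
      dimnames = list(NULL, c("lo", "hi"))); next }
    runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
    m <- t(vapply(runs, function(r) c(grid[min(r)], grid[max(r)]), numeric(2)))
    colnames(m) <- c("lo", "hi")
    out[[as.character(x)]] <- m
  }
  structure(list(levels = out, assignment = lev, grid = grid), class = "score_intervals")
}

#' Assign evidence points to scores via intervals
#'
#' @param scores Numeric scores.
#' @param intervals A `score_intervals` object.
#' @return Integer points per score (0 where indeterminate / outside grid).
#' @export
points_from_intervals <- function(scores, intervals) {
  g <- intervals$grid
  idx <- findInterval(scores, g, all.inside = TRUE)
  intervals$assignment[idx]
}

#' Five-tier classification from an evidence point total
#'
#' Point-based tiers: Pathogenic >= 10, Likely pathogenic 6..9, VUS 0..5,
#' Likely benign -6..-1, Benign <= -7.
#'
#' @param point_total Integer point total(s).
#' @return Character vector of tiers.
#' @export
classify_from_points <- function(point_total) {
  stopifnot(is.numeric(point_total), all(point_total == round(point_total)))
  cut_tier <- function(p) {
    if (p >= 10) "Pathogenic"
    else if (p >= 6) "Likely pathogenic"
    else if (p >= 0) "VUS"
    else if (p >= -6) "Likely benign"
    else "Benign"
  }
  vapply(point_total, cut_tier, character(1))
}

#' Serialize an evidence scale to JSON
#'
#' @param scale An `evidence_scale`.
#' @param path Optional file path; if `NULL`, returns the JSON string.
#' @return JSON string (invisibly if written to file).
#' @export
evidence_scale_json <- function(scale, path = NULL) {
  obj <- list(prior = scale$prior, lr1 = scale$lr1,
              lr_thresholds = as.list(scale$lr_thresholds),
              posterior_thresholds = as.list(scale$posterior_thresholds),
              clip = c(scale$clip_min, scale$clip_max))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
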