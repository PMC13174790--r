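# Evidence-point miscalibration metrics, interval likelihood ratios with
# conservative win rules, and classification-consistency metrics.

#' Evidence-point miscalibration summary
#'
#' Converts estimated and true posteriors to continuous evidence points
#' under the scale (clip +-8) and summarizes the per-score error
#' `dEP = EP_est - EP_true`:
#' * `mape`: mean absolute error in evidence points;
#' * `pfraction`: proportion of scores with `dEP > 1` among scores in the
#'   pathogenic region (`EP_true > 1`, or `>= 1` with `region_rule = "ge1"`);
#' * `bfraction`: proportion with `dEP < -1` among scores with
#'   `EP_true < -1` (benign region);
#' * region-wise 75th-percentile and maximum overconfidence errors, using
#'   `+dEP` in the pathogenic region and `-dEP` in the benign region.
#'
#' @param est_posteriors,true_posteriors Equal-length posterior vectors.
#' @param scale An `evidence_scale`.
#' @param region_rule `"strict"` (default; pathogenic region `EP_true > 1`)
#'   or `"ge1"` (`EP_true >= 1`, mirrored for benign).
#' @return Object of class `miscalibration_summary`.
#' @export
miscalibration <- function(est_posteriors, true_posteriors, scale,
                           region_rule = c("strict", "ge1")) {
  region_rule <- match.arg(region_rule)
  stopifnot(length(est_posteriors) == length(true_posteriors))
  ep_est <- ep_from_posterior(clamp_posterior(est_posteriors), scale)
  ep_true <- ep_from_posterior(clamp_posterior(true_posteriors), scale)
  delta <- ep_est - ep_true
  # boundary comparisons carry a 1e-9 guard so a score whose true evidence
  # is exactly one point is excluded under "strict" and included under
  # "ge1" regardless of floating-point noise in the log-LR conversion
  tol <- 1e-9
  if (region_rule == "strict") {
    in_p <- ep_true > 1 + tol; in_b <- ep_true < -1 - tol
  } else {
    in_p <- ep_true >= 1 - tol; in_b <- ep_true <= -1 + tol
  }
  frac <- function(viol, region) if (any(region)) mean(viol[region]) else NA_real_
  reg_summ <- function(err, region) {
    if (!any(region)) return(c(pct75 = 0, max = 0))
    e <- err[region]
    c(pct75 = stats::quantile(e, 0.75, names = FALSE), max = max(e))
  }
  sp <- reg_summ(delta, in_p)
  sb <- reg_summ(-delta, in_b)
  structure(list(
    mape = mean(abs(delta)),
    pfraction = frac(delta > 1, in_p),
    bfraction = frac(delta < -1, in_b),
    per_score_delta = delta,
    pct75_err_P = sp[["pct75"]], max_err_P = sp[["max"]],
    pct75_err_B = sb[["pct75"]], max_err_B = sb[["max"]],
    n_pathogenic_region = sum(in_p), n_benign_region = sum(in_b)),
    class = "miscalibration_summary")
}

#' @export
print.miscalibration_summary <- function(x, ...) {
  cat(sprintf("MAPE = %.3f EP | PFraction = %s | BFraction = %s\n", x$mape,
              format(x$pfraction, digits = 3), format(x$bfraction, digits = 3)))
  invisible(x)
}

#' Interval likelihood ratios for evidence-level score intervals
#'
#' For each point level, the empirical LR of its score interval(s):
#' the fraction of pathogenic controls inside divided by the fraction of
#' benign controls inside. A level whose interval holds pathogenic but no
#' benign controls reports `Inf` (flagged); a level with no controls of
#' either class is `NA` (undefined, flagged).
#'
#' @param intervals A [score_intervals()] object.
#' @param pathogenic_scores,benign_scores Control scores.
#' @param scale An `evidence_scale` providing the per-level LR thresholds.
#' @return Object of class `interval_lr_report`: data.frame with columns
#'   `level`, `lr`, `threshold`, `n_p`, `n_b`, `defined`.
#' @export
interval_lr <- function(intervals, pathogenic_scores, benign_scores, scale) {
  stopifnot(inherits(intervals, "score_intervals"))
  N_P <- length(pathogenic_scores); N_B <- length(benign_scores)
  if (N_P == 0 || N_B == 0) stop("need at least one control of each class")
  in_intervals <- function(s, m) {
    if (nrow(m) == 0 || length(s) == 0) return(rep(FALSE, length(s)))
    Reduce(`|`, lapply(seq_len(nrow(m)),
                       function(i) s >= m[i, "lo"] & s <= m[i, "hi"]))
  }
  levels <- c(-4:-1, 1:4)
  rows <- lapply(levels, function(x) {
    m <- intervals$levels[[as.character(x)]]
    np <- sum(in_intervals(pathogenic_scores, m))
    nb <- sum(in_intervals(benign_scores, m))
    lr <- if (np == 0 && nb == 0) NA_real_
          else if (nb == 0) Inf
          else (np / N_P) / (nb / N_B)
    data.frame(level = x, lr = lr, threshold = scale$lr_thresholds[[as.character(x)]],
               n_p = np, n_b = nb, defined = !(np == 0 && nb == 0))
  })
  structure(do.call(rbind, rows), class = c("interval_lr_report", "data.frame"))
}

#' Compare two interval-LR reports with conservative win rules
#'
#' Per level: if both LRs sit on the preferred side of the threshold (at or
#' above for pathogenic levels, at or below for benign), the one closest to
#' the threshold wins; if they sit on opposite sides, the conservative one
#' wins (higher LR for pathogenic levels, lower for benign); equal LRs tie.
#' Levels undefined in either report are skipped and recorded.
#'
#' @param report_A,report_B `interval_lr_report`s on the same scale.
#' @return List with `per_level` (data.frame: level, winner in
#'   \{"A","B","tie","skipped"\}), `wins_A`, `wins_B`, `ties`, `skipped`.
#' @export
win_compare <- function(report_A, report_B) {
  stopifnot(all(report_A$level == report_B$level),
            all(report_A$threshold == report_B$threshold))
  decide <- function(a, b, thr, pathogenic) {
    if (is.na(a) || is.na(b)) return("skipped")
    if (a == b) return("tie")
    ok_a <- if (pathogenic) a >= thr else a <= thr
    ok_b <- if (pathogenic) b >= thr else b <= thr
    if (ok_a && ok_b) {
      da <- abs(log(a) - log(thr)); db <- abs(log(b) - log(thr))
      if (da == db) "tie" else if (da < db) "A" else "B"
    } else if (ok_a != ok_b) {
      # opposite sides: conservative side preferred
      if (pathogenic) { if (a > b) "A" else "B" } else { if (a < b) "A" else "B" }
    } else {
      # both on the non-preferred side: closest (least anti-conservative) wins
      if (pathogenic) { if (a > b) "A" else "B" } else { if (a < b) "A" else "B" }
    }
  }
  winner <- vapply(seq_len(nrow(report_A)), function(i)
    decide(report_A$lr[i], report_B$lr[i], report_A$threshold[i],
           report_A$level[i] > 0), character(1))
  list(per_level = data.frame(level = report_A$level, winner = winner),
       wins_A = sum(winner == "A"), wins_B = sum(winner == "B"),
       ties = sum(winner == "tie"), skipped = sum(winner == "skipped"))
}

#' One-sided binomial win test
#'
#' Exact tail probability `P(X >= wins)` for `X ~ Binomial(n_total - ties,
#' 0.5)`: the null that two calibration approaches are equally likely to win
#' a unit, ties excluded.
#'
#' @param wins Number of units won.
#' @param ties Number of tied units (excluded from trials).
#' @param n_total Total units compared.
#' @return One-sided p-value.
#' @export
binomial_win_test <- function(wins, ties, n_total) {
  stopifnot(wins >= 0, ties >= 0, wins + ties <= n_total)
  n <- n_total - ties
  if (n == 0) stop("no non-tied comparisons: test undefined")
  sum(stats::dbinom(wins:n, n, 0.5))
}

#' Classification metrics against labeled controls
#'
#' The pathogenic side calls `points >= +1` positive with P/LP as the
#' positive class; the benign side calls `points <= -1` positive with B/LB
#' as the positive class. Reports per-side TPR/FPR, their means, per-side
#' Matthews correlation coefficients and their mean, and the determinate
#' rate (fraction of all supplied variants with nonzero points).
#'
#' @param points Integer evidence points per variant.
#' @param labels Character labels; `"P"` and `"B"` rows enter the control
#'   metrics, all rows enter `determinate_rate`.
#' @return Named list of metrics (undefined sides propagate as `NA`).
#' @export
classification_metrics <- function(points, labels) {
  stopifnot(length(points) == length(labels))
  is_p <- labels == "P"; is_b <- labels == "B"
  side <- function(call_pos, pos_class, neg_class) {
    tp <- sum(call_pos & pos_class); fn <- sum(!call_pos & pos_class)
    fp <- sum(call_pos & neg_class); tn <- sum(!call_pos & neg_class)
    tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
    den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    mcc <- if (den > 0) (tp * tn - fp * fn) / den else NA_real_
    list(tpr = tpr, fpr = fpr, mcc = mcc)
  }
  p_side <- side(points >= 1, is_p, is_b)
  b_side <- side(points <= -1, is_b, is_p)
  list(TPR_P = p_side$tpr, FPR_P = p_side$fpr,
       TPR_B = b_side$tpr, FPR_B = b_side$fpr,
       AvgTPR = mean(c(p_side$tpr, b_side$tpr)),
       AvgFPR = mean(c(p_side$fpr, b_side$fpr)),
       MCC_P = p_side$mcc, MCC_B = b_side$mcc,
       MCC = mean(c(p_side$mcc, b_side$mcc)),
       determinate_rate = mean(points != 0))
}

#' Evidence-point assignment heatmap
#'
#' Per-stratum percentage of variants at each point level -4..+4 (points
#' beyond the clinical +-4 cap are capped). Rows sum to 100, including the
#' 0 column; empty strata yield rows of `NA`.
#'
#' @param points Integer evidence points per variant.
#' @param strata Character stratum per variant (e.g. "P/LP", "B/LB", "VUS",
#'   "population", "all-SNV").
#' @return Matrix (strata x levels) of percentages.
#' @export
evidence_heatmap <- function(points, strata) {
  stopifnot(length(points) == length(strata))
  capped <- pmin(pmax(points, -4L), 4L)
  levs <- -4:4
  groups <- unique(strata)
  out <- matrix(NA_real_, length(groups), length(levs),
                dimnames = list(groups, as.character(levs)))
  for (g in groups) {
    p <- capped[strata == g]
    if (length(p) == 0) next
    out[g, ] <- 100 * vapply(levs, function(l) mean(p == l), numeric(1))
  }
  out
}
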