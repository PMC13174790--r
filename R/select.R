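# Data-adaptive calibration: gene eligibility, the three-stage selection
# procedure over replicate synthetic score sets, and the end-to-end
# per-unit workflow (fit class distributions, simulate replicates, select
# a method, apply it with a conservative bootstrap envelope, extract
# evidence score intervals).

#' Gene eligibility for gene-specific calibration
#'
#' Tiered rules on `sum = n_p + n_b` and `pfrac = n_p / sum`:
#' * condition 1: 50 <= sum <= 99 and 0.4 <= pfrac <= 0.7;
#' * condition 2: 100 <= sum <= 299 and 0.1 <= pfrac <= 0.9;
#' * condition 3: sum >= 300, 0.05 <= pfrac <= 0.99 and n_b >= 10.
#'
#' The sum ranges are disjoint, so at most one condition applies.
#'
#' @param n_p,n_b Counts of P/LP and B/LB control variants.
#' @return List with `eligible`, `condition` ("cond1"/"cond2"/"cond3"/
#'   "none"), `n_p`, `n_b`, `sum`, `pfrac`.
#' @export
gene_eligibility <- function(n_p, n_b) {
  stopifnot(n_p >= 0, n_b >= 0)
  s <- n_p + n_b
  pf <- if (s > 0) n_p / s else NA_real_
  cond <- if (s >= 50 && s <= 99 && !is.na(pf) && pf >= 0.4 && pf <= 0.7) "cond1"
    else if (s >= 100 && s <= 299 && pf >= 0.1 && pf <= 0.9) "cond2"
    else if (s >= 300 && pf >= 0.05 && pf <= 0.99 && n_b >= 10) "cond3"
    else "none"
  list(eligible = cond != "none", condition = cond,
       n_p = n_p, n_b = n_b, sum = s, pfrac = pf)
}

#' Stage 1: over-confident estimation risk filter
#'
#' A replicate violates for a method when its 75th-percentile regional
#' overconfidence error exceeds 2 points or its maximum exceeds 3 points in
#' either the pathogenic region (`+dEP`) or the benign region (`-dEP`).
#' Methods violating in strictly more than 25% of replicates are removed.
#'
#' @param summaries Named list (per method) of lists of
#'   `miscalibration_summary` objects (one per replicate).
#' @param max_violation_rate Removal threshold (default 0.25, strict `>`).
#' @return Character vector of surviving methods (may be empty).
#' @export
stage1_safety_filter <- function(summaries, max_violation_rate = 0.25) {
  viol_rate <- vapply(summaries, function(reps) {
    v <- vapply(reps, function(m)
      m$pct75_err_P > 2 || m$max_err_P > 3 ||
      m$pct75_err_B > 2 || m$max_err_B > 3, logical(1))
    mean(v)
  }, numeric(1))
  names(viol_rate)[viol_rate <= max_violation_rate]
}

#' Stage 2: retain the three methods with lowest mean MAPE rank
#'
#' Ranks methods per replicate by MAPE (rank 1 = lowest), averages ranks
#' across replicates, and keeps the best three (all, if fewer survive).
#' Ties in mean rank break by method name order.
#'
#' @param survivors Method names surviving stage 1.
#' @param summaries As in [stage1_safety_filter()].
#' @return Up to three method names, best first.
#' @export
stage2_rank_mape <- function(survivors, summaries) {
  stopifnot(length(survivors) >= 1)
  mape <- vapply(summaries[survivors], function(reps)
    vapply(reps, `[[`, numeric(1), "mape"), numeric(length(summaries[[survivors[1]]])))
  mape <- matrix(mape, ncol = length(survivors),
                 dimnames = list(NULL, survivors))
  ranks <- t(apply(mape, 1, rank, ties.method = "average"))
  if (length(survivors) == 1) ranks <- matrix(1, nrow(mape), 1, dimnames = list(NULL, survivors))
  mean_rank <- colMeans(ranks)
  ord <- order(mean_rank, names(mean_rank))
  names(mean_rank)[ord][seq_len(min(3, length(survivors)))]
}

#' Stage 3: pick the least over-confident of the finalists
#'
#' Mean rank of `PFraction + BFraction` across replicates (undefined
#' fractions count as zero violations); lowest mean rank wins, ties by
#' method name order.
#'
#' @param top3 Candidate method names from stage 2.
#' @param summaries As in [stage1_safety_filter()].
#' @return The chosen method name.
#' @export
stage3_pick <- function(top3, summaries) {
  stopifnot(length(top3) >= 1)
  if (length(top3) == 1) return(top3)
  comb <- vapply(summaries[top3], function(reps)
    vapply(reps, function(m) {
      pf <- m$pfraction; bf <- m$bfraction
      (if (is.na(pf)) 0 else pf) + (if (is.na(bf)) 0 else bf)
    }, numeric(1)), numeric(length(summaries[[top3[1]]])))
  comb <- matrix(comb, ncol = length(top3), dimnames = list(NULL, top3))
  ranks <- t(apply(comb, 1, rank, ties.method = "average"))
  mean_rank <- colMeans(ranks)
  names(mean_rank)[order(mean_rank, names(mean_rank))][1]
}

#' Candidate method list for selection
#'
#' The ten post-hoc methods plus the nine local-posterior configurations
#' (window fraction x gnomAD fraction), each entering as a distinct
#' candidate. Configurations needing unlabeled scores are included only
#' when `has_unlabeled`.
#'
#' @param methods Post-hoc method names (default: the ten non-local ones).
#' @param has_unlabeled Whether the unit carries unlabeled scores.
#' @return Named list: candidate id -> list(method, options).
#' @export
candidate_methods <- function(methods = setdiff(CALIBRATION_METHODS, "local_posterior"),
                              has_unlabeled = FALSE) {
  out <- stats::setNames(
    lapply(methods, function(m) list(method = m, options = list())), methods)
  for (w in c(0.10, 0.20, 0.30)) for (g in c(0, 0.03, 0.06)) {
    if (g > 0 && !has_unlabeled) next
    id <- sprintf("local_w%02.0f_g%02.0f", 100 * w, 100 * g)
    out[[id]] <- list(method = "local_posterior",
                      options = list(window_frac = w, gnomad_frac = g))
  }
  out
}

#' Default framework configuration
#'
#' `profile = "paper"` uses the study-scale settings (30 replicates, 1000
#' bootstrap rounds); `profile = "fast"` is the desk-scale profile used by
#' the test suite (10 replicates, 25 bootstrap rounds, reduced NN epochs).
#'
#' @param profile `"paper"` or `"fast"`.
#' @param ... Overrides of individual fields.
#' @return Named list of settings.
#' @export
framework_config <- function(profile = c("paper", "fast"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "paper")
    list(n_replicates = 30L, n_boot_select = 1000L, n_boot_final = 1000L,
         nn_epochs = 300L, use_conservative = TRUE, region_rule = "strict",
         methods = setdiff(CALIBRATION_METHODS, "local_posterior"))
  else
    list(n_replicates = 10L, n_boot_select = 25L, n_boot_final = 100L,
         nn_epochs = 120L, use_conservative = TRUE, region_rule = "strict",
         methods = setdiff(CALIBRATION_METHODS, "local_posterior"))
  mods <- list(...)
  cfg[names(mods)] <- mods
  cfg
}

#' Data-adaptive calibration of one unit (gene or domain cluster)
#'
#' The five-step workflow: (1) fit the best-scoring family to each class of
#' the unit's labeled scores; (2) generate replicate synthetic score sets
#' matching the unit's size and pathogenic fraction; (3) run every candidate
#' method on each replicate with a conservative out-of-bag bootstrap
#' envelope, prior-corrected to the unit prior, and score the evidence-point
#' miscalibration against the closed-form true posterior; (4) select a
#' method through the three-stage filter; (5) apply the chosen method to the
#' real unit with the full bootstrap and extract evidence score intervals
#' from the conservative envelope.
#'
#' @param unit A [score_set()].
#' @param prior Unit prior probability of pathogenicity in (0, 1).
#' @param config A [framework_config()] list.
#' @param seed Integer seed.
#' @return Object of class `unit_calibration`: list with `chosen`,
#'   `selection` (stage outcomes and per-method scores), `envelope`,
#'   `intervals`, `scale`, `pair` (fitted class distributions), or
#'   `chosen = NA` when every method fails or is filtered out
#'   (uncalibratable unit).
#' @export
select_and_calibrate <- function(unit, prior, config = framework_config("fast"),
                                 seed = 1L) {
  stopifnot(inherits(unit, "score_set"))
  scale <- build_evidence_scale(prior)
  fit_P <- select_best_family(unit$pathogenic)
  fit_B <- select_best_family(unit$benign)
  pair <- dist_pair(fit_P$dist, fit_B$dist)
  n_p <- length(unit$pathogenic); n_b <- length(unit$benign)
  n_u <- length(unit$unlabeled %||% numeric(0))
  cands <- candidate_methods(config$methods, has_unlabeled = n_u > 0)
  summaries <- stats::setNames(
    lapply(cands, function(.) vector("list", config$n_replicates)), names(cands))
  failed <- stats::setNames(rep(FALSE, length(cands)), names(cands))
  for (r in seq_len(config$n_replicates)) {
    sd_r <- child_seed(seed, r)
    rep_set <- with_seed(sd_r, {
      u <- if (n_u > 0) {
        from_p <- stats::runif(n_u) < prior
        c(rdist(pair$P, sum(from_p)), rdist(pair$B, sum(!from_p)))
      } else NULL
      score_set(rdist(pair$P, n_p), rdist(pair$B, n_b), unlabeled = u,
                unit_id = unit$unit_id)
    })
    truth_cache <- NULL
    for (id in names(cands)) {
      if (failed[id]) next
      cand <- cands[[id]]
      opts <- c(cand$options, list(nn_epochs = config$nn_epochs))
      env <- tryCatch(suppressWarnings(
        oob_bootstrap_envelope(rep_set, cand$method, scale,
                               n_boot = config$n_boot_select,
                               seed = child_seed(sd_r, match(id, names(cands))),
                               options = opts)),
        error = function(e) NULL)
      if (is.null(env)) { failed[id] <- TRUE; next }
      est <- if (config$use_conservative) env$conservative else env$point_estimate
      if (is.null(truth_cache))
        truth_cache <- suppressWarnings(true_posterior(env$grid, pair, prior))
      summaries[[id]][[r]] <- miscalibration(est, truth_cache, scale,
                                             region_rule = config$region_rule)
    }
  }
  ok <- names(cands)[!failed &
    vapply(summaries, function(x) !any(vapply(x, is.null, logical(1))), logical(1))]
  if (length(ok) == 0)
    return(structure(list(chosen = NA_character_, selection = NULL,
                          envelope = NULL, intervals = NULL, scale = scale,
                          pair = pair), class = "unit_calibration"))
  summaries <- summaries[ok]
  survivors <- stage1_safety_filter(summaries)
  selection <- list(survivors_stage1 = survivors, top3_stage2 = character(0),
                    chosen = NA_character_,
                    per_method_scores = lapply(summaries, function(reps) list(
                      mean_mape = mean(vapply(reps, `[[`, numeric(1), "mape")),
                      violation_rate = mean(vapply(reps, function(m)
                        m$pct75_err_P > 2 || m$max_err_P > 3 ||
                        m$pct75_err_B > 2 || m$max_err_B > 3, logical(1))))))
  if (length(survivors) == 0)
    return(structure(list(chosen = NA_character_, selection = selection,
                          envelope = NULL, intervals = NULL, scale = scale,
                          pair = pair), class = "unit_calibration"))
  top3 <- stage2_rank_mape(survivors, summaries)
  chosen <- stage3_pick(top3, summaries)
  selection$top3_stage2 <- top3
  selection$chosen <- chosen
  cand <- cands[[chosen]]
  env <- suppressWarnings(
    oob_bootstrap_envelope(unit, cand$method, scale,
                           n_boot = config$n_boot_final,
                           seed = child_seed(seed, 999983L),
                           options = c(cand$options,
                                       list(nn_epochs = config$nn_epochs))))
  on_grid <- envelope_on_grid(env)
  intervals <- score_intervals(on_grid$grid, on_grid$posterior, scale)
  structure(list(chosen = chosen, selection = selection, envelope = env,
                 intervals = intervals, scale = scale, pair = pair),
            class = "unit_calibration")
}

#' @export
print.unit_calibration <- function(x, ...) {
  if (is.na(x$chosen)) cat("unit could not be calibrated\n")
  else cat(sprintf("chosen method: %s (of %d candidates; %d survived stage 1)\n",
                   x$chosen, length(x$selection$per_method_scores),
                   length(x$selection$survivors_stage1)))
  invisible(x)
}

#' Route a gene to a calibration strategy
#'
#' Gene-specific calibration when the gene is eligible and calibration
#' succeeded; otherwise the variant's domain-cluster thresholds; otherwise
#' the non-domain cluster; otherwise uncalibrated.
#'
#' @param gene Gene symbol.
#' @param eligibility A [gene_eligibility()] result.
#' @param gene_calibrated Did gene-specific calibration succeed?
#' @param cluster Cluster id for the variant's domain, or `NA`.
#' @param cluster_calibrated Named logical: which clusters have thresholds
#'   (may include `"non_domain"`).
#' @return List with `strategy` in \{"gene_specific", "domain_aggregate",
#'   "uncalibrated"\} and `cluster` (id used, or `NA`).
#' @export
hybrid_route <- function(gene, eligibility, gene_calibrated = FALSE,
                         cluster = NA_character_,
                         cluster_calibrated = logical(0)) {
  if (isTRUE(eligibility$eligible) && isTRUE(gene_calibrated))
    return(list(strategy = "gene_specific", cluster = NA_character_))
  if (!is.na(cluster) && isTRUE(cluster_calibrated[cluster]))
    return(list(strategy = "domain_aggregate", cluster = cluster))
  if (isTRUE(cluster_calibrated["non_domain"]))
    return(list(strategy = "domain_aggregate", cluster = "non_domain"))
  list(strategy = "uncalibrated", cluster = NA_character_)
}

#' Serialize a selection log to JSON
#'
#' Audit record of a [select_and_calibrate()] run: stage outcomes and
#' per-method violation rates and mean MAPE.
#'
#' @param result A `unit_calibration`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
selection_log_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "unit_calibration"))
  obj <- list(chosen = result$chosen,
              survivors_stage1 = result$selection$survivors_stage1,
              top3_stage2 = result$selection$top3_stage2,
              per_method = result$selection$per_method_scores)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
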