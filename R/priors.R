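# Positive-unlabeled class-prior estimation.
#
# A labeled-positive set P (P/LP variants) and an unlabeled set U
# (population variants) share a feature space. An out-of-bag ensemble of
# L2-regularized logistic classifiers, trained P-vs-U on unique-bootstrap
# samples with class balancing and per-sample PCA, produces a leakage-free
# score per variant. A distance-removal curve over those scores (repeatedly
# draw a positive, remove the closest unlabeled variant, record the
# distance) stays low while unlabeled positives remain and rises once they
# are exhausted; the elbow index estimates the number of unlabeled
# positives, hence the prior. Bootstrapping the scores yields a median
# prior with an interquartile range, gated by the PU-AUC separability check.

#' Positive/unlabeled feature data
#'
#' @param features_P Numeric matrix (variants x features) for labeled
#'   positives, rownames = variant ids.
#' @param features_U Numeric matrix for unlabeled variants, rownames =
#'   variant ids. Ids shared with `features_P` mark duplicate variants.
#' @return Object of class `pu_data`.
#' @export
pu_data <- function(features_P, features_U) {
  stopifnot(is.matrix(features_P), is.matrix(features_U),
            ncol(features_P) == ncol(features_U))
  if (is.null(rownames(features_P)))
    rownames(features_P) <- paste0("P", seq_len(nrow(features_P)))
  if (is.null(rownames(features_U)))
    rownames(features_U) <- paste0("U", seq_len(nrow(features_U)))
  structure(list(P = features_P, U = features_U,
                 dup_ids = intersect(rownames(features_P), rownames(features_U))),
            class = "pu_data")
}

#' Unique bootstrap split of positive and unlabeled sets
#'
#' Resamples P and U with replacement, then repairs duplicate variants
#' (same id in both sets) so both copies land on the same side: if either
#' copy was drawn, the partner copy joins the training sample; a duplicate
#' is out-of-bag only when neither copy was drawn. Without duplicates this
#' reduces to an ordinary per-set bootstrap.
#'
#' @param data A [pu_data()].
#' @param seed Integer seed.
#' @return List with `train_P`, `train_U` (row indices with multiplicity)
#'   and `oob_P`, `oob_U` (indices never in training).
#' @export
unique_bootstrap_split <- function(data, seed = 1L) {
  stopifnot(inherits(data, "pu_data"))
  nP <- nrow(data$P); nU <- nrow(data$U)
  idsP <- rownames(data$P); idsU <- rownames(data$U)
  with_seed(seed, {
    bP <- sample.int(nP, nP, replace = TRUE)
    bU <- sample.int(nU, nU, replace = TRUE)
    for (id in data$dup_ids) {
      iP <- which(idsP == id); iU <- which(idsU == id)
      inP <- any(bP %in% iP); inU <- any(bU %in% iU)
      if (inP && !inU) bU <- c(bU, iU)
      if (inU && !inP) bP <- c(bP, iP)
    }
    list(train_P = bP, train_U = bU,
         oob_P = setdiff(seq_len(nP), bP), oob_U = setdiff(seq_len(nU), bU))
  })
}

# z-score + PCA to the fewest components reaching 95% cumulative explained
# variance, parameters learned on the training rows only.
pca_project <- function(train, test, var_target = 0.95) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  zt <- scale(train, center = mu, scale = sdv)
  pc <- stats::prcomp(zt, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev[ev > 1e-12]
  k <- max(1L, which(cumsum(ev) / sum(ev) >= var_target)[1])
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  list(train = zt %*% rot,
       test = scale(test, center = mu, scale = sdv) %*% rot, k = k)
}

#' Out-of-bag ensemble scores for PU data
#'
#' Each ensemble member takes a unique-bootstrap training sample, balances
#' classes by random under-sampling of the larger side, z-scores and
#' PCA-projects features (95% variance) on its own training sample, and
#' fits an L2-regularized logistic regression P-vs-U. A variant's final
#' score is the mean over members for which it was out-of-bag.
#'
#' @param data A [pu_data()] with at least 10 positives.
#' @param n_members Ensemble size (default 100).
#' @param seed Integer seed.
#' @return List with `scores_P`, `scores_U` (NA where never out-of-bag,
#'   with a warning), `pu_auc`.
#' @export
oob_ensemble_scores <- function(data, n_members = 100L, seed = 1L) {
  stopifnot(inherits(data, "pu_data"))
  nP <- nrow(data$P); nU <- nrow(data$U)
  if (nP < 10) stop("need at least 10 labeled positives")
  accP <- cntP <- numeric(nP); accU <- cntU <- numeric(nU)
  for (m in seq_len(n_members)) {
    sd_m <- child_seed(seed, m)
    sp <- unique_bootstrap_split(data, seed = sd_m)
    trP <- sp$train_P; trU <- sp$train_U
    with_seed(child_seed(sd_m, 1L), {
      if (length(trU) > length(trP)) trU <- sample(trU, length(trP))
      else if (length(trP) > length(trU)) trP <- sample(trP, length(trU))
    })
    Xtr <- rbind(data$P[trP, , drop = FALSE], data$U[trU, , drop = FALSE])
    ytr <- c(rep(1, length(trP)), rep(0, length(trU)))
    Xte <- rbind(data$P[sp$oob_P, , drop = FALSE], data$U[sp$oob_U, , drop = FALSE])
    if (nrow(Xte) == 0 || length(unique(ytr)) < 2) next
    pr <- pca_project(Xtr, Xte)
    fit <- tryCatch(
      glmnet::glmnet(cbind(pr$train, 0), ytr, family = "binomial",
                     alpha = 0, lambda = 1 / length(ytr), standardize = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) next
    sc <- as.numeric(stats::predict(fit, cbind(pr$test, 0), type = "response"))
    kP <- length(sp$oob_P)
    if (kP > 0) { accP[sp$oob_P] <- accP[sp$oob_P] + sc[seq_len(kP)]
                  cntP[sp$oob_P] <- cntP[sp$oob_P] + 1 }
    if (length(sp$oob_U) > 0) {
      scu <- sc[(kP + 1):length(sc)]
      accU[sp$oob_U] <- accU[sp$oob_U] + scu
      cntU[sp$oob_U] <- cntU[sp$oob_U] + 1
    }
  }
  if (any(cntP == 0) || any(cntU == 0))
    warning(sum(cntP == 0) + sum(cntU == 0), " variants never out-of-bag; excluded")
  sP <- ifelse(cntP > 0, accP / cntP, NA_real_)
  sU <- ifelse(cntU > 0, accU / cntU, NA_real_)
  list(scores_P = sP, scores_U = sU, pu_auc = pu_auc(sP[!is.na(sP)], sU[!is.na(sU)]))
}

#' PU-AUC: separability of positives from unlabeled variants
#'
#' Area under the ROC curve with labeled positives as positives and
#' unlabeled variants as negatives (rank statistic, ties at half weight).
#'
#' @param scores_P,scores_U Numeric score vectors.
#' @return AUC in [0, 1].
#' @export
pu_auc <- function(scores_P, scores_U) {
  nP <- length(scores_P); nU <- length(scores_U)
  if (nP == 0 || nU == 0) stop("both score sets must be nonempty")
  r <- rank(c(scores_P, scores_U))
  (sum(r[seq_len(nP)]) - nP * (nP + 1) / 2) / (nP * nU)
}

#' Distance-removal curve
#'
#' Iteratively draws a labeled positive score at random (with replacement);
#' the closest unlabeled score is removed and the absolute distance
#' recorded, until U is exhausted (|U| iterations).
#'
#' @param scores_P,scores_U Numeric score vectors (both nonempty).
#' @param seed Integer seed.
#' @return Numeric vector of recorded distances in removal order,
#'   length `length(scores_U)`.
#' @export
distance_curve <- function(scores_P, scores_U, seed = 1L) {
  stopifnot(length(scores_P) > 0, length(scores_U) > 0)
  with_seed(seed, {
    o <- order(scores_U)
    u <- scores_U[o]
    alive <- rep(TRUE, length(u))
    n_alive <- length(u)
    draws <- sample(scores_P, length(u), replace = TRUE)
    dists <- numeric(length(u))
    for (i in seq_along(u)) {
      p <- draws[i]
      cand <- which(alive)
      j <- cand[which.min(abs(u[cand] - p))]
      dists[i] <- abs(u[j] - p)
      alive[j] <- FALSE
    }
    dists
  })
}

#' Prior estimate from a distance curve
#'
#' Fits a two-segment model to the cumulative distance curve — piecewise
#' linear with each segment's slope equal to its mean recorded distance —
#' and places the breakpoint where the total squared error of the distance
#' increments is minimal (a changepoint in mean). Unlabeled positives are
#' removed first, so recorded distances stay small until they are exhausted
#' and the slope jumps at the elbow; the breakpoint index over `n_U`
#' estimates the prior. When the two segment slopes are too similar (no
#' elbow) the curve is degenerate: uniformly tiny distances mean U is
#' saturated with positives (prior 1), uniformly large distances mean it
#' holds none (prior 0); both are flagged low-confidence.
#'
#' @param curve Distance vector from [distance_curve()] (length >= 20).
#' @param n_U Size of the unlabeled set (defaults to `length(curve)`).
#' @param slope_ratio_min Minimal slope2/slope1 ratio accepted as an elbow
#'   (default 1.5).
#' @return List with `prior`, `elbow_index`, `confident` (logical).
#' @export
estimate_prior_from_curve <- function(curve, n_U = length(curve),
                                      slope_ratio_min = 1.5) {
  n <- length(curve)
  if (n < 20) stop("curve too short (need >= 20 points)")
  # O(n) changepoint in mean via prefix sums of the increments
  S <- c(0, cumsum(curve)); S2 <- c(0, cumsum(curve^2))
  ks <- 1:(n - 1)
  sse <- vapply(ks, function(k) {
    s1 <- S[k + 1]; q1 <- S2[k + 1]
    s2 <- S[n + 1] - s1; q2 <- S2[n + 1] - q1
    (q1 - s1^2 / k) + (q2 - s2^2 / (n - k))
  }, numeric(1))
  k_star <- ks[which.min(sse)]
  slope1 <- mean(curve[1:k_star])
  slope2 <- mean(curve[(k_star + 1):n])
  if (slope1 <= 0) slope1 <- 1e-12
  if (slope2 / slope1 < slope_ratio_min) {
    # no elbow: uniformly tiny distances mean U is saturated with
    # positives; uniformly large distances mean it holds none
    tiny <- mean(curve) < 0.02
    return(list(prior = if (tiny) 1 else 0, elbow_index = if (tiny) n else 0L,
                confident = FALSE))
  }
  list(prior = k_star / n_U, elbow_index = k_star, confident = TRUE)
}

#' Bootstrap prior estimate with uncertainty and PU-AUC gate
#'
#' Resamples the out-of-bag scores of each set with replacement
#' `n_bootstrap` times; each resample yields a distance-curve prior. The
#' final prior is the bootstrap median with the interquartile range as
#' uncertainty; the estimate is retained only when the PU-AUC of the
#' underlying scores exceeds 0.75.
#'
#' @param scores_P,scores_U Out-of-bag scores (see [oob_ensemble_scores()]).
#' @param n_bootstrap Number of bootstrap rounds (paper-scale default 5000;
#'   values below 100 warn as test mode).
#' @param seed Integer seed.
#' @return Object of class `prior_estimate`: list with `prior_median`,
#'   `q25`, `q75`, `n_bootstrap`, `pu_auc`, `retained`.
#' @export
bootstrap_prior <- function(scores_P, scores_U, n_bootstrap = 5000L, seed = 1L) {
  scores_P <- scores_P[!is.na(scores_P)]
  scores_U <- scores_U[!is.na(scores_U)]
  stopifnot(length(scores_P) > 0, length(scores_U) >= 20)
  if (n_bootstrap < 100) warning("n_bootstrap < 100: test mode")
  auc <- pu_auc(scores_P, scores_U)
  ests <- vapply(seq_len(n_bootstrap), function(b) {
    sd_b <- child_seed(seed, b)
    rs <- with_seed(sd_b, list(
      p = sample(scores_P, replace = TRUE),
      u = sample(scores_U, replace = TRUE)))
    cv <- distance_curve(rs$p, rs$u, seed = child_seed(sd_b, 1L))
    estimate_prior_from_curve(cv)$prior
  }, numeric(1))
  q <- stats::quantile(ests, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(prior_median = q[2], q25 = q[1], q75 = q[3],
                 n_bootstrap = n_bootstrap, pu_auc = auc,
                 retained = auc > 0.75),
            class = "prior_estimate")
}

#' @export
print.prior_estimate <- function(x, ...) {
  cat(sprintf("prior = %.4f [IQR %.4f-%.4f], PU-AUC = %.3f (%s)\n",
              x$prior_median, x$q25, x$q75, x$pu_auc,
              if (x$retained) "retained" else "not retained"))
  invisible(x)
}

#' Serialize a prior estimate to JSON
#' @param est A `prior_estimate`.
#' @param path Optional output file.
#' @return JSON string.
#' @export
prior_estimate_json <- function(est, path = NULL) {
  js <- jsonlite::toJSON(list(median = est$prior_median, q25 = est$q25,
                              q75 = est$q75, pu_auc = est$pu_auc,
                              retained = est$retained),
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
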