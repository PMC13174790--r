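test_that("unique bootstrap keeps duplicate variants on one side", {
  # every positive also present in the unlabeled set
  feats <- matrix(rnorm(40), 20, 2,
                  dimnames = list(paste0("v", 1:20), NULL))
  extra <- matrix(rnorm(60), 30, 2,
                  dimnames = list(paste0("u", 1:30), NULL))
  d <- pu_data(feats, rbind(feats, extra))
  for (b in 1:200) {
    sp <- unique_bootstrap_split(d, seed = b)
    train_ids <- union(rownames(d$P)[sp$train_P], rownames(d$U)[sp$train_U])
    for (id in d$dup_ids) {
      inP_train <- id %in% rownames(d$P)[sp$train_P]
      inU_train <- id %in% rownames(d$U)[sp$train_U]
      # both copies together: in training on both sides, or OOB on both
      expect_equal(inP_train, inU_train)
      if (!inP_train) {
        expect_true(which(rownames(d$P) == id) %in% sp$oob_P)
        expect_true(which(rownames(d$U) == id) %in% sp$oob_U)
      }
    }
  }
  # same seed reproduces the split exactly
  expect_identical(unique_bootstrap_split(d, seed = 9),
                   unique_bootstrap_split(d, seed = 9))
  # without duplicates the split is an ordinary per-set bootstrap
  d2 <- pu_data(feats, extra)
  sp <- unique_bootstrap_split(d2, seed = 3)
  expect_length(sp$train_P, 20)
  expect_length(sp$train_U, 30)
  expect_setequal(sp$oob_P, setdiff(1:20, sp$train_P))
})

test_that("PCA keeps the fewest components reaching 95% variance", {
  set.seed(6)
  # fixed covariance: three strong directions, five weak
  X <- cbind(matrix(rnorm(600), 200, 3) %*% diag(c(10, 5, 3)),
             matrix(rnorm(1000, sd = 0.01), 200, 5))
  pr <- vepcal:::pca_project(X, X[1:5, , drop = FALSE])
  ev <- prcomp(scale(X))$sdev^2
  want_k <- which(cumsum(ev) / sum(ev) >= 0.95)[1]
  expect_equal(pr$k, want_k)
})

test_that("OOB ensemble separates classes and stays null on noise", {
  fx <- generate_fixture(gene_config("G1", prior = 0.1, n_p = 30, n_b = 30,
                                     n_unlabeled = 200, feature_sep = 3),
                         seed = 2)
  d <- pu_data(fx$features_P, fx$features_U)
  oo <- oob_ensemble_scores(d, n_members = 40, seed = 3)
  expect_gt(mean(oo$scores_P, na.rm = TRUE), mean(oo$scores_U, na.rm = TRUE))
  expect_gt(oo$pu_auc, 0.75)
  # pure-noise features: PU-AUC hovers at chance
  fx0 <- generate_fixture(gene_config("G0", prior = 0.1, n_p = 40, n_b = 40,
                                      n_unlabeled = 300, feature_sep = 0),
                          seed = 4)
  oo0 <- oob_ensemble_scores(pu_data(fx0$features_P, fx0$features_U),
                             n_members = 40, seed = 5)
  expect_lt(abs(oo0$pu_auc - 0.5), 0.07)
  expect_error(oob_ensemble_scores(pu_data(fx$features_P[1:5, ], fx$features_U)),
               "at least 10")
})

test_that("distance curves record nearest-removal distances in order", {
  # U a subset of P's scores: the matching distances are zero
  cv <- distance_curve(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9), seed = 1)
  expect_length(cv, 3)
  expect_equal(sort(cv)[1:2], c(0, 0), tolerance = 0.05)
  # hand trace with a single positive: removal order is by distance from it,
  # so recorded distances equal the sorted absolute differences
  u <- c(0.2, 0.9, 0.45, 0.35, 0.6)
  cv2 <- distance_curve(0.4, u, seed = 2)
  expect_equal(cv2, sort(abs(u - 0.4)))
  expect_length(distance_curve(runif(10), runif(25), seed = 3), 25)
})

test_that("the elbow estimator recovers mixing proportions and degenerate curves", {
  for (pi_u in c(0.05, 0.2, 0.5)) {
    ests <- vapply(1:10, function(s) {
      d <- pu_sim_scores(pi_u, seed = s)
      estimate_prior_from_curve(distance_curve(d$p, d$u, seed = s + 100))$prior
    }, numeric(1))
    expect_lt(abs(median(ests) - pi_u), 0.07)
  }
  # U entirely positive: prior near one
  d1 <- pu_sim_scores(1, seed = 3)
  e1 <- estimate_prior_from_curve(distance_curve(d1$p, d1$u, seed = 7))
  expect_gt(e1$prior, 0.85)
  # U entirely negative: prior near zero
  d0 <- pu_sim_scores(0, seed = 4)
  e0 <- estimate_prior_from_curve(distance_curve(d0$p, d0$u, seed = 8))
  expect_lt(e0$prior, 0.1)
  expect_error(estimate_prior_from_curve(runif(10)), "short")
})

test_that("median prior recovery is monotone in the true mixing proportion", {
  meds <- vapply(c(0.05, 0.2, 0.5), function(pi_u) {
    median(vapply(1:8, function(s) {
      d <- pu_sim_scores(pi_u, n_u = 600, seed = 20 * s)
      estimate_prior_from_curve(distance_curve(d$p, d$u, seed = s))$prior
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
  expect_true(all(meds >= 0 & meds <= 1))
})

test_that("bootstrap priors gate on PU-AUC and summarize uncertainty", {
  d <- pu_sim_scores(0.2, n_u = 300, n_p = 100, seed = 12)
  est <- suppressWarnings(bootstrap_prior(d$p, d$u, n_bootstrap = 60, seed = 13))
  expect_true(est$q25 <= est$prior_median && est$prior_median <= est$q75)
  expect_lt(abs(est$prior_median - 0.2), 0.1)
  expect_true(est$retained)  # well separated: PU-AUC far above 0.75
  # fully separated degenerate sets: every bootstrap estimate identical,
  # so the IQR has zero width
  cst <- suppressWarnings(
    bootstrap_prior(rep(0.9, 30), rep(0.1, 50), n_bootstrap = 30, seed = 14))
  expect_equal(cst$q75 - cst$q25, 0)
  # strict retention threshold at 0.75
  expect_false(structure(list(pu_auc = 0.74), class = "x")$pu_auc > 0.75)
  expect_warning(bootstrap_prior(d$p, d$u, n_bootstrap = 20, seed = 1),
                 "test mode")
})

test_that("oracle posteriors bound the learned PU-AUC", {
  # the true class posterior is the AUC-optimal score; a learned OOB score
  # cannot beat it beyond Monte-Carlo noise
  fx <- generate_fixture(gene_config("G1", prior = 0.15, n_p = 40, n_b = 40,
                                     n_unlabeled = 300, feature_sep = 3),
                         seed = 21)
  d <- pu_data(fx$features_P, fx$features_U)
  oo <- oob_ensemble_scores(d, n_members = 40, seed = 22)
  # oracle: projection onto the class-mean difference direction is the
  # optimal discriminant for isotropic Gaussian classes
  dir_hat <- colMeans(fx$features_P) - colMeans(fx$features_U)
  auc_oracle <- pu_auc(drop(fx$features_P %*% dir_hat),
                       drop(fx$features_U %*% dir_hat))
  expect_lt(oo$pu_auc, auc_oracle + 0.05)
})
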