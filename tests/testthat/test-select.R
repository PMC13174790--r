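# Helper to fabricate miscalibration summaries with prescribed fields.
mk_summary <- function(mape = 0, pfrac = 0, bfrac = 0,
                       p75P = 0, maxP = 0, p75B = 0, maxB = 0) {
  structure(list(mape = mape, pfraction = pfrac, bfraction = bfrac,
                 per_score_delta = numeric(0),
                 pct75_err_P = p75P, max_err_P = maxP,
                 pct75_err_B = p75B, max_err_B = maxB,
                 n_pathogenic_region = 1L, n_benign_region = 1L),
            class = "miscalibration_summary")
}

test_that("gene eligibility applies the tiered count and balance rules", {
  e <- gene_eligibility(30, 30)
  expect_true(e$eligible); expect_equal(e$condition, "cond1")
  e <- gene_eligibility(90, 10)  # sum 100, pfrac 0.9 inclusive boundary
  expect_true(e$eligible); expect_equal(e$condition, "cond2")
  e <- gene_eligibility(295, 8)  # pfrac in range but fewer than 10 B/LB
  expect_false(e$eligible)
  e <- gene_eligibility(45, 4)   # sum 49, below every range
  expect_false(e$eligible)
  expect_equal(gene_eligibility(400, 50)$condition, "cond3")
  # balance violations inside each range
  expect_false(gene_eligibility(10, 60)$eligible)   # sum 70, pfrac 0.14
  expect_false(gene_eligibility(95, 10)$eligible)   # sum 105, pfrac ~0.905
})

test_that("eligibility conditions partition: no pair satisfies two conditions", {
  for (n_p in seq(0, 500, by = 25)) for (n_b in seq(0, 500, by = 25)) {
    s <- n_p + n_b
    if (s == 0) next
    pf <- n_p / s
    hits <- c(
      cond1 = s >= 50 && s <= 99 && pf >= 0.4 && pf <= 0.7,
      cond2 = s >= 100 && s <= 299 && pf >= 0.1 && pf <= 0.9,
      cond3 = s >= 300 && pf >= 0.05 && pf <= 0.99 && n_b >= 10)
    expect_lte(sum(hits), 1)
    got <- gene_eligibility(n_p, n_b)
    expect_equal(got$eligible, any(hits))
    if (any(hits)) expect_equal(got$condition, names(hits)[hits])
  }
})

test_that("stage 1 removes methods at a strict 25% violation rate", {
  clean <- replicate(30, mk_summary(), simplify = FALSE)
  viol <- function(k) c(replicate(k, mk_summary(p75P = 2.5), simplify = FALSE),
                        replicate(30 - k, mk_summary(), simplify = FALSE))
  summaries <- list(good = clean, borderline = viol(7), bad = viol(8))
  surv <- stage1_safety_filter(summaries)
  expect_setequal(surv, c("good", "borderline"))  # 7/30 <= 0.25 < 8/30
  # max-error rule triggers independently of the percentile rule
  summaries2 <- list(maxbad = viol(0))
  summaries2$maxbad[[1]] <- mk_summary(maxB = 3.5)
  expect_length(stage1_safety_filter(summaries2, max_violation_rate = 0), 0)
  # violation counting matches a direct enumeration on random error tensors
  set.seed(33)
  for (rep in 1:20) {
    reps <- lapply(1:10, function(i)
      mk_summary(p75P = runif(1, 0, 4), maxP = runif(1, 0, 5),
                 p75B = runif(1, 0, 4), maxB = runif(1, 0, 5)))
    got <- length(stage1_safety_filter(list(m = reps))) == 1
    rate <- mean(vapply(reps, function(m)
      m$pct75_err_P > 2 || m$max_err_P > 3 ||
      m$pct75_err_B > 2 || m$max_err_B > 3, logical(1)))
    expect_equal(got, rate <= 0.25)
  }
})

test_that("stage 2 keeps the three best mean MAPE ranks", {
  set.seed(44)
  methods <- paste0("m", 1:6)
  summaries <- setNames(lapply(1:6, function(j)
    lapply(1:10, function(i) mk_summary(mape = runif(1) + j / 10))), methods)
  top3 <- stage2_rank_mape(methods, summaries)
  expect_length(top3, 3)
  # sorting oracle
  mape_mat <- sapply(methods, function(m)
    vapply(summaries[[m]], `[[`, numeric(1), "mape"))
  mean_rank <- colMeans(t(apply(mape_mat, 1, rank)))
  expect_setequal(top3, names(sort(mean_rank))[1:3])
  # single survivor returned alone
  expect_equal(stage2_rank_mape("m1", summaries), "m1")
  # identical MAPEs: deterministic alphabetical tie-break
  tied <- setNames(lapply(1:4, function(j)
    lapply(1:5, function(i) mk_summary(mape = 1))), c("d", "b", "a", "c"))
  expect_equal(stage2_rank_mape(names(tied), tied), c("a", "b", "c"))
})

test_that("stage 3 picks the least over-confident finalist", {
  summaries <- list(
    hot = lapply(1:5, function(i) mk_summary(pfrac = 0.4, bfrac = 0.1)),
    cool = lapply(1:5, function(i) mk_summary(pfrac = 0, bfrac = 0)),
    warm = lapply(1:5, function(i) mk_summary(pfrac = 0.1, bfrac = 0.05)))
  expect_equal(stage3_pick(names(summaries), summaries), "cool")
  expect_equal(stage3_pick("hot", summaries), "hot")
  # NA fractions count as zero violations
  nas <- list(
    a = lapply(1:5, function(i) mk_summary(pfrac = NA, bfrac = NA)),
    b = lapply(1:5, function(i) mk_summary(pfrac = 0.2, bfrac = 0.2)))
  expect_equal(stage3_pick(names(nas), nas), "a")
  # rank oracle on random tensors
  set.seed(55)
  for (rep in 1:10) {
    s <- setNames(lapply(1:3, function(j)
      lapply(1:8, function(i) mk_summary(pfrac = runif(1), bfrac = runif(1)))),
      c("x", "y", "z"))
    comb <- sapply(s, function(reps) vapply(reps, function(m)
      m$pfraction + m$bfraction, numeric(1)))
    want <- names(which.min(colMeans(t(apply(comb, 1, rank)))))
    expect_equal(stage3_pick(names(s), s), want)
  }
})

test_that("candidate list holds ten post-hoc methods plus local configurations", {
  c0 <- candidate_methods(has_unlabeled = FALSE)
  expect_length(c0, 13)  # 10 + 3 local configs without a gnomAD constraint
  c1 <- candidate_methods(has_unlabeled = TRUE)
  expect_length(c1, 19)  # 10 + full 3 x 3 local grid
  expect_true(all(grepl("^local", setdiff(names(c1), names(c0)))))
})

test_that("hybrid routing falls through gene, cluster, non-domain, uncalibrated", {
  elig <- gene_eligibility(100, 100)
  r <- hybrid_route("G", elig, gene_calibrated = TRUE)
  expect_equal(r$strategy, "gene_specific")
  inelig <- gene_eligibility(5, 5)
  r <- hybrid_route("G", inelig, cluster = "c7",
                    cluster_calibrated = c(c7 = TRUE, non_domain = TRUE))
  expect_equal(r$strategy, "domain_aggregate")
  expect_equal(r$cluster, "c7")
  r <- hybrid_route("G", inelig, cluster = NA_character_,
                    cluster_calibrated = c(non_domain = TRUE))
  expect_equal(r$cluster, "non_domain")
  r <- hybrid_route("G", inelig)
  expect_equal(r$strategy, "uncalibrated")
})
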