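test_that("miscalibration summarizes evidence-point errors by definition", {
  sc <- build_evidence_scale(0.1)
  post <- posterior_from_lr(sc$lr1^c(-3, -1.5, 0.5, 2, 3.5), 0.1)
  m0 <- miscalibration(post, post, sc)
  expect_equal(m0$mape, 0)
  expect_equal(m0$pfraction, 0)
  expect_equal(m0$bfraction, 0)
  # the worked one-score example: true +5 estimated +7
  m1 <- miscalibration(posterior_from_lr(sc$lr1^7, 0.1),
                       posterior_from_lr(sc$lr1^5, 0.1), sc)
  expect_equal(m1$per_score_delta, 2, tolerance = 1e-9)
  expect_equal(m1$mape, 2, tolerance = 1e-9)
  # hand enumeration: four scores at EP_true = 2 with dEP (0, 1.5, 0.5, 2)
  ep_true <- rep(2, 4)
  delta <- c(0, 1.5, 0.5, 2.0)
  est <- posterior_from_lr(sc$lr1^(ep_true + delta), 0.1)
  tru <- posterior_from_lr(sc$lr1^ep_true, 0.1)
  m2 <- miscalibration(est, tru, sc)
  expect_equal(m2$pfraction, 0.5)
  expect_equal(m2$mape, 1, tolerance = 1e-9)
  expect_equal(m2$pct75_err_P, quantile(delta, 0.75, names = FALSE),
               tolerance = 1e-9)
  expect_equal(m2$max_err_P, 2, tolerance = 1e-9)
})

test_that("miscalibration region rules and empty regions behave as documented", {
  sc <- build_evidence_scale(0.1)
  # scores exactly at EP_true = 1: in the region only under the ge1 rule
  est <- posterior_from_lr(sc$lr1^2.5, 0.1)
  tru <- posterior_from_lr(sc$lr1^1, 0.1)
  strict <- miscalibration(est, tru, sc, region_rule = "strict")
  ge1 <- miscalibration(est, tru, sc, region_rule = "ge1")
  expect_true(is.na(strict$pfraction))
  expect_equal(ge1$pfraction, 1)
  # no benign region: bfraction undefined
  expect_true(is.na(strict$bfraction))
})

test_that("miscalibration is permutation-invariant and antisymmetric", {
  sc <- build_evidence_scale(0.2)
  set.seed(5)
  est <- runif(50, 0.01, 0.99); tru <- runif(50, 0.01, 0.99)
  m <- miscalibration(est, tru, sc)
  p <- sample(50)
  expect_equal(miscalibration(est[p], tru[p], sc)$mape, m$mape)
  expect_equal(miscalibration(tru, est, sc)$per_score_delta,
               -m$per_score_delta)
})

test_that("interval LRs equal exhaustive counting on random instances", {
  sc <- build_evidence_scale(0.1)
  grid <- seq(0, 1, length.out = 1001)
  # toy arithmetic case: interval holding 4 of 10 P and 2 of 20 B has LR 4
  iv <- score_intervals(grid, ifelse(grid >= 0.6,
                                     sc$posterior_thresholds[["1"]] + 0.001,
                                     0.1), sc)
  pth <- c(runif(4, 0.65, 0.9), runif(6, 0.1, 0.5))
  ben <- c(runif(2, 0.65, 0.9), runif(18, 0.1, 0.5))
  rep1 <- interval_lr(iv, pth, ben, sc)
  expect_equal(rep1$lr[rep1$level == 1], 4)
  # 100 random instances vs a direct counting oracle
  set.seed(17)
  for (i in 1:100) {
    post <- cumsum(runif(1001)); post <- 0.001 + 0.998 * post / max(post)
    ivr <- score_intervals(grid, post, sc)
    p_s <- runif(15); b_s <- runif(15)
    rep2 <- interval_lr(ivr, p_s, b_s, sc)
    for (r in seq_len(nrow(rep2))) {
      m <- ivr$levels[[as.character(rep2$level[r])]]
      inm <- function(s) if (nrow(m) == 0) rep(FALSE, length(s)) else
        Reduce(`|`, lapply(seq_len(nrow(m)), function(k)
          s >= m[k, 1] & s <= m[k, 2]))
      np <- sum(inm(p_s)); nb <- sum(inm(b_s))
      want <- if (np == 0 && nb == 0) NA_real_ else if (nb == 0) Inf else
        (np / 15) / (nb / 15)
      expect_equal(rep2$lr[r], want)
    }
  }
  expect_error(interval_lr(iv, numeric(0), ben, sc), "control")
})

test_that("win rules prefer conservative interval LRs", {
  sc <- build_evidence_scale(0.1)
  mk_report <- function(lrs) {
    data.frame(level = c(-4:-1, 1:4), lr = lrs,
               threshold = sc$lr_thresholds[as.character(c(-4:-1, 1:4))],
               n_p = 1, n_b = 1, defined = !is.na(lrs))
  }
  thr1 <- sc$lr_thresholds[["1"]]
  a <- mk_report(rep(1, 8)); b <- mk_report(rep(1, 8))
  expect_equal(win_compare(a, b)$ties, 8)
  # both above the +1 threshold: closest wins
  a$lr[a$level == 1] <- thr1 + 0.5; b$lr[b$level == 1] <- thr1 + 3
  expect_equal(win_compare(a, b)$per_level$winner[a$level == 1], "A")
  # opposite sides: the conservative (higher for pathogenic) wins
  a$lr[a$level == 1] <- thr1 - 0.5; b$lr[b$level == 1] <- thr1 + 0.5
  expect_equal(win_compare(a, b)$per_level$winner[a$level == 1], "B")
  # benign side mirror: lower is conservative
  thrm1 <- sc$lr_thresholds[["-1"]]
  a$lr[a$level == -1] <- thrm1 + 0.1; b$lr[b$level == -1] <- thrm1 - 0.1
  expect_equal(win_compare(a, b)$per_level$winner[a$level == -1], "B")
  # undefined level skipped
  a$lr[a$level == 4] <- NA
  expect_equal(win_compare(a, b)$skipped, 1)
})

test_that("the binomial win test reproduces printed p-values", {
  expect_equal(binomial_win_test(5, 0, 5), 0.5^5)
  expect_equal(signif(binomial_win_test(65, 10, 101), 1), 3e-5)
  expect_equal(round(binomial_win_test(51, 20, 105), 3), 0.041)
  expect_equal(round(binomial_win_test(47, 17, 98), 3), 0.091)
  # matches the analytic PMF sum
  expect_equal(binomial_win_test(7, 2, 12),
               sum(choose(10, 7:10)) / 2^10, tolerance = 1e-12)
  expect_error(binomial_win_test(0, 5, 5), "undefined")
})

test_that("classification metrics match the hand-built 2x2 tables", {
  # 10 P: 7 at +1, 1 at -1, 2 at 0; 10 B: 6 at -1, 1 at +2, 3 at 0
  points <- c(rep(1, 7), -1, 0, 0, rep(-1, 6), 2, 0, 0, 0)
  labels <- rep(c("P", "B"), each = 10)
  m <- classification_metrics(points, labels)
  expect_equal(m$TPR_P, 0.7)
  expect_equal(m$FPR_P, 0.1)
  expect_equal(m$TPR_B, 0.6)
  expect_equal(m$FPR_B, 0.1)
  expect_equal(m$AvgTPR, 0.65)
  expect_equal(m$AvgFPR, 0.1)
  expect_equal(m$determinate_rate, 15 / 20)
  # perfect assignment
  perf <- classification_metrics(c(rep(2, 5), rep(-2, 5)),
                                 rep(c("P", "B"), each = 5))
  expect_equal(perf$AvgTPR, 1)
  expect_equal(perf$AvgFPR, 0)
  expect_equal(perf$MCC, 1)
  # all indeterminate
  zero <- classification_metrics(rep(0, 10), rep(c("P", "B"), 5))
  expect_equal(zero$determinate_rate, 0)
  expect_equal(zero$AvgTPR, 0)
})

test_that("evidence heatmaps report per-stratum percentages", {
  hm <- evidence_heatmap(c(3, 3, 0, -2), c("P/LP", "P/LP", "VUS", "B/LB"))
  expect_equal(rowSums(hm), c("P/LP" = 100, "VUS" = 100, "B/LB" = 100))
  expect_equal(hm["P/LP", "3"], 100)
  expect_equal(hm["B/LB", "-2"], 100)
  # points beyond the clinical cap land in the +-4 columns
  hm2 <- evidence_heatmap(c(7, -8), c("a", "a"))
  expect_equal(hm2["a", "4"], 50)
  expect_equal(hm2["a", "-4"], 50)
  # heatmap differences are antisymmetric to swapping operands
  h1 <- evidence_heatmap(c(1, 0), c("x", "x"))
  h2 <- evidence_heatmap(c(-1, 0), c("x", "x"))
  expect_equal(h1 - h2, -(h2 - h1))
})
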