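test_that("overlapping domains merge or split per the 50% reciprocal rule", {
  iv <- data.frame(gene = "G", start = c(1, 40), end = c(100, 140),
                   domain_id = c("d1", "d2"))
  out <- resolve_overlaps(iv)  # overlap 61 covers >= 50% of both
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start, out$end), c(1, 140))
  iv2 <- data.frame(gene = "G", start = c(1, 90), end = c(100, 300),
                    domain_id = c("d1", "d2"))
  out2 <- resolve_overlaps(iv2)  # overlap 11 < 50%: split at midpoint 95
  expect_equal(out2$end[1], 95)
  expect_equal(out2$start[2], 96)
  iv3 <- data.frame(gene = "G", start = c(1, 200), end = c(100, 300),
                    domain_id = c("d1", "d2"))
  expect_equal(resolve_overlaps(iv3)[, c("start", "end")],
               iv3[, c("start", "end")])
  # residues belong to at most one domain after resolution
  set.seed(8)
  iv4 <- data.frame(gene = "G",
                    start = sample(1:400, 12), domain_id = paste0("d", 1:12))
  iv4$end <- iv4$start + sample(20:120, 12)
  out4 <- resolve_overlaps(iv4)
  cover <- unlist(mapply(seq, out4$start, out4$end, SIMPLIFY = FALSE))
  expect_equal(anyDuplicated(cover), 0)
})

test_that("score histograms are normalized probability vectors", {
  set.seed(3)
  h <- score_histogram(runif(10000))
  expect_equal(sum(h), 1)
  # near-flat for uniform scores (chi-square sanity)
  expect_lt(max(abs(h - 1 / 100)), 4 * sqrt(0.01 * 0.99 / 10000))
  h1 <- score_histogram(0.505)
  expect_equal(which.max(h1), 51)
  expect_gt(max(h1), 0.99)
  expect_error(score_histogram(numeric(0)), "empty")
})

test_that("JSD matrices are metric and match direct summation", {
  set.seed(4)
  hs <- t(replicate(6, { v <- runif(5); v / sum(v) }))
  J <- jsd_matrix(hs)
  expect_equal(J, t(J))
  expect_equal(diag(J), rep(0, 6))
  expect_true(all(J >= 0 & J <= 1))
  # direct-summation oracle
  for (i in 1:5) for (j in (i + 1):6) {
    p <- hs[i, ]; q <- hs[j, ]; m <- (p + q) / 2
    want <- sqrt(0.5 * sum(p * log2(p / m)) + 0.5 * sum(q * log2(q / m)))
    expect_equal(J[i, j], want, tolerance = 1e-12)
  }
  # triangle inequality on random instances
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(J[i, j], J[i, k] + J[k, j] + 1e-12)
  # identical histograms at zero, disjoint supports at one
  expect_equal(js_distance <- vepcal:::js_distance(hs[1, ], hs[1, ]), 0)
  expect_equal(vepcal:::js_distance(c(1, 0), c(0, 1)), 1)
})

test_that("dynamic tree splitting respects the labeled-count cap", {
  set.seed(2)
  hs <- rbind(score_histogram(rbeta(500, 2, 8)),
              score_histogram(rbeta(500, 2, 8) * 0.99),
              score_histogram(rbeta(500, 8, 2)),
              score_histogram(rbeta(500, 8, 2) * 0.99 + 0.01))
  rownames(hs) <- paste0("d", 1:4)
  J <- jsd_matrix(hs)
  counts <- c(d1 = 300, d2 = 300, d3 = 300, d4 = 300)
  # cap 650: the root (1200) splits once into the two shape pairs (600 each)
  cl <- cluster_and_split(J, counts, 650)
  expect_equal(length(unique(cl$clusters)), 2)
  expect_equal(unname(cl$clusters["d1"]), unname(cl$clusters["d2"]))
  expect_equal(unname(cl$clusters["d3"]), unname(cl$clusters["d4"]))
  per <- tapply(counts, cl$clusters, sum)
  expect_true(all(per <= 650))
  # cap above the total: a single root cluster
  cl1 <- cluster_and_split(J, counts, 5000)
  expect_equal(length(unique(cl1$clusters)), 1)
  # zero counts never split
  cl0 <- cluster_and_split(J, setNames(rep(0, 4), names(counts)), 1)
  expect_equal(length(unique(cl0$clusters)), 1)
  # an unsplittable singleton above the cap is flagged
  cl2 <- cluster_and_split(J, c(d1 = 900, d2 = 10, d3 = 10, d4 = 10), 100)
  expect_true("d1" %in% cl2$flagged)
})

test_that("the cap grid search hits an achievable target median", {
  set.seed(5)
  hs <- do.call(rbind, lapply(1:8, function(i)
    score_histogram(rbeta(400, i, 9 - i))))
  rownames(hs) <- paste0("d", 1:8)
  J <- jsd_matrix(hs)
  counts <- setNames(rep(250, 8), rownames(hs))
  gs <- grid_search_max_count(J, counts, target_median = 500)
  expect_equal(gs$median_count, 500)  # pairs of 250 reach the target exactly
  per <- tapply(counts, gs$clustering$clusters, sum)
  expect_equal(median(per), 500)
  # target above the total: coarsest clustering wins
  gs2 <- grid_search_max_count(J, counts, target_median = 5000)
  expect_equal(length(unique(gs2$clustering$clusters)), 1)
  # deterministic
  expect_identical(gs$max_count,
                   grid_search_max_count(J, counts, 500)$max_count)
})

test_that("cluster validation prefers matching control distributions", {
  set.seed(9)
  allv <- c(rbeta(500, 8, 2), rbeta(700, 2, 8))
  cluster_ctl <- list(benign = rbeta(300, 2, 8), pathogenic = rbeta(300, 8, 2))
  global_ctl <- list(benign = runif(300), pathogenic = runif(300))
  cv <- cluster_validation(allv, cluster_ctl, global_ctl, seed = 10)
  expect_true(cv$converged)
  # component labels ordered by mean: "normal" below "abnormal"
  expect_lt(cv$mixture$means[1], cv$mixture$means[2])
  # cluster controls drawn from the generating components match better
  expect_gt(cv$difference, 0)
  expect_true(all(cv$jsd_cluster < cv$jsd_global))
  # identical cluster and global controls: difference vanishes
  cv0 <- cluster_validation(allv, cluster_ctl, cluster_ctl, seed = 11)
  expect_equal(cv0$difference, 0, tolerance = 1e-12)
  expect_error(cluster_validation(runif(10), cluster_ctl, global_ctl), "50")
})

test_that("variants map to exactly one cluster or the non-domain set", {
  dom <- resolve_overlaps(data.frame(
    gene = c("G1", "G1", "G2"), start = c(10, 200, 1),
    end = c(100, 300, 50), domain_id = c("dA", "dB", "dC")))
  clusters <- c("G1:dA" = 1L, "G1:dB" = 2L, "G2:dC" = 1L)
  expect_equal(assign_variant_to_cluster("G1", 50, dom, clusters), "1")
  expect_equal(assign_variant_to_cluster("G1", 10, dom, clusters), "1")  # start inclusive
  expect_equal(assign_variant_to_cluster("G1", 300, dom, clusters), "2") # end inclusive
  expect_equal(assign_variant_to_cluster("G1", 150, dom, clusters), "non_domain")
  expect_warning(r <- assign_variant_to_cluster("G1", NA, dom, clusters),
                 "missing")
  expect_equal(r, "non_domain")
  # partition property over a position sweep
  hits <- vapply(1:350, function(p)
    assign_variant_to_cluster("G1", p, dom, clusters), character(1))
  expect_true(all(hits %in% c("1", "2", "non_domain")))
  expect_equal(sum(hits != "non_domain"), (100 - 10 + 1) + (300 - 200 + 1))
})
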