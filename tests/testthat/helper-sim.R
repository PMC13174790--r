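# Shared builders for simulation-backed tests. All fixtures are generated
# in code under fixed seeds; nothing is read from disk.

beta_pair <- function(a = 8, b = 2) {
  dist_pair(score_dist("beta", c(shape1 = a, shape2 = b)),
            score_dist("beta", c(shape1 = b, shape2 = a)))
}

# PU score sets with known mixing proportion and near-complete class
# separation (the high-separability design the prior estimator targets)
pu_sim_scores <- function(pi_u, n_u = 1000, n_p = 200,
                          centers = c(0.85, 0.15), noise = 0.08, seed = 1) {
  with_seed(seed, {
    p <- clamp01(stats::rnorm(n_p, centers[1], noise), 1e-4)
    n_pos <- stats::rbinom(1, n_u, pi_u)
    u <- clamp01(c(stats::rnorm(n_pos, centers[1], noise),
                   stats::rnorm(n_u - n_pos, centers[2], noise)), 1e-4)
    list(p = p, u = u, n_pos = n_pos)
  })
}

clamp01 <- vepcal:::clamp01
with_seed <- vepcal::with_seed
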