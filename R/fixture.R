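# Synthetic study generator.
#
# Emulates the full input bundle — control variant tables, unlabeled
# population variants, per-variant feature matrices and domain interval
# tables — with a ground-truth manifest (per-gene priors, class-conditional
# distributions, true posteriors), so every module's recovery behavior can
# be tested without any external download.

#' Configuration for one synthetic gene
#'
#' @param gene Gene symbol.
#' @param prior True prior probability of pathogenicity among the gene's
#'   rare missense variants.
#' @param n_p,n_b Labeled P/LP and B/LB control counts.
#' @param n_unlabeled Unlabeled population variant count.
#' @param dist_P,dist_B [score_dist()] class-conditional score densities
#'   (defaults Beta(8,2) vs Beta(2,8)).
#' @param feature_dim Feature dimension for the prior-estimation matrix.
#' @param feature_sep Class separation of the Gaussian feature clouds (in
#'   SD units; controls achievable PU-AUC).
#' @param protein_length Protein length for domain layout.
#' @param domains data.frame(start, end, domain_id) or NULL for none.
#' @return List of class `gene_config`.
#' @export
gene_config <- function(gene, prior = 0.1, n_p = 50L, n_b = 50L,
                        n_unlabeled = 500L,
                        dist_P = score_dist("beta", c(shape1 = 8, shape2 = 2)),
                        dist_B = score_dist("beta", c(shape1 = 2, shape2 = 8)),
                        feature_dim = 8L, feature_sep = 2.5,
                        protein_length = 500L, domains = NULL) {
  if (!is_prob(prior)) stop("invalid config: prior must be in (0, 1)")
  if (n_p < 1 || n_b < 1 || n_unlabeled < 1)
    stop("invalid config: counts must be positive")
  structure(list(gene = gene, prior = prior, n_p = n_p, n_b = n_b,
                 n_unlabeled = n_unlabeled, dist_P = dist_P, dist_B = dist_B,
                 feature_dim = feature_dim, feature_sep = feature_sep,
                 protein_length = protein_length, domains = domains),
            class = "gene_config")
}

#' Generate a full synthetic study
#'
#' @param configs List of [gene_config()]s.
#' @param seed Integer seed (regeneration with the same seed is
#'   bit-identical).
#' @return List with `controls` (variant table: gene, chrom, pos, ref, alt,
#'   protein_pos, label, review_stars, allele_freq, splice_score, score),
#'   `unlabeled` (population table with scores and features), `features_P`,
#'   `features_U` (matrices, rownames = variant keys), `domains` (interval
#'   table), `manifest` (per-gene truth: prior, distributions, fraction of
#'   unlabeled variants that are pathogenic).
#' @export
generate_fixture <- function(configs, seed = 1L) {
  if (inherits(configs, "gene_config")) configs <- list(configs)
  bases <- c("A", "C", "G", "T")
  all_controls <- list(); all_unl <- list(); all_dom <- list()
  fP <- list(); fU <- list(); manifest <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    sd_g <- child_seed(seed, ci)
    out <- with_seed(sd_g, {
      n_lab <- cfg$n_p + cfg$n_b
      scores_p <- rdist(cfg$dist_P, cfg$n_p)
      scores_b <- rdist(cfg$dist_B, cfg$n_b)
      # unlabeled pool mixes classes at the true prior
      u_path <- stats::runif(cfg$n_unlabeled) < cfg$prior
      scores_u <- numeric(cfg$n_unlabeled)
      scores_u[u_path] <- rdist(cfg$dist_P, sum(u_path))
      scores_u[!u_path] <- rdist(cfg$dist_B, sum(!u_path))
      mk_var <- function(n, label, scores) {
        pos <- sample.int(3L * cfg$protein_length, n)
        ref <- sample(bases, n, replace = TRUE)
        alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
        data.frame(gene = cfg$gene, chrom = "1", pos = 1e6 * ci + pos,
                   ref = ref, alt = alt,
                   protein_pos = ceiling(pos / 3), label = label,
                   review_stars = sample(1:3, n, replace = TRUE),
                   allele_freq = stats::rbeta(n, 0.5, 200),
                   splice_score = round(stats::runif(n, 0, 0.19), 3),
                   score = scores)
      }
      controls <- rbind(mk_var(cfg$n_p, "P", scores_p),
                        mk_var(cfg$n_b, "B", scores_b))
      unl <- mk_var(cfg$n_unlabeled, "U", scores_u)
      # Gaussian feature clouds: positives shifted by feature_sep along a
      # random unit direction; unlabeled mixes the clouds at the prior
      dir <- stats::rnorm(cfg$feature_dim)
      dir <- dir / sqrt(sum(dir^2))
      feat <- function(n, pathogenic) {
        base <- matrix(stats::rnorm(n * cfg$feature_dim), n)
        if (any(pathogenic))
          base[pathogenic, ] <- base[pathogenic, , drop = FALSE] +
            matrix(cfg$feature_sep * dir, sum(pathogenic), cfg$feature_dim,
                   byrow = TRUE)
        base
      }
      featP <- feat(cfg$n_p, rep(TRUE, cfg$n_p))
      featU <- feat(cfg$n_unlabeled, u_path)
      rownames(featP) <- paste(controls$chrom[1:cfg$n_p], controls$pos[1:cfg$n_p],
                               controls$ref[1:cfg$n_p], controls$alt[1:cfg$n_p],
                               sep = ":")
      rownames(featU) <- paste(unl$chrom, unl$pos, unl$ref, unl$alt, sep = ":")
      dom <- cfg$domains
      if (!is.null(dom)) dom <- data.frame(gene = cfg$gene, dom)
      list(controls = controls, unl = unl, featP = featP, featU = featU,
           dom = dom,
           manifest = list(gene = cfg$gene, prior = cfg$prior,
                           dist_P = cfg$dist_P, dist_B = cfg$dist_B,
                           unlabeled_path_frac = mean(u_path)))
    })
    all_controls[[ci]] <- out$controls
    all_unl[[ci]] <- out$unl
    if (!is.null(out$dom)) all_dom[[ci]] <- out$dom
    fP[[ci]] <- out$featP; fU[[ci]] <- out$featU
    manifest[[cfg$gene]] <- out$manifest
  }
  list(controls = do.call(rbind, all_controls),
       unlabeled = do.call(rbind, all_unl),
       features_P = do.call(rbind, fP),
       features_U = do.call(rbind, fU),
       domains = if (length(all_dom)) do.call(rbind, all_dom) else NULL,
       manifest = manifest)
}

#' Score set of one gene from a fixture
#'
#' @param fixture Output of [generate_fixture()].
#' @param gene Gene symbol.
#' @return A [score_set()].
#' @export
fixture_score_set <- function(fixture, gene) {
  ct <- fixture$controls[fixture$controls$gene == gene, ]
  un <- fixture$unlabeled[fixture$unlabeled$gene == gene, ]
  score_set(pathogenic = ct$score[ct$label == "P"],
            benign = ct$score[ct$label == "B"],
            unlabeled = un$score, unit_id = gene)
}
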