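# Protein-domain aggregation: interval resolution, per-domain score
# histograms, Jensen-Shannon distance clustering with dynamic splitting of
# the dendrogram by labeled-variant count, and cluster validation via an
# unsupervised two-component skew-normal mixture.

#' Resolve overlapping domain intervals within a gene
#'
#' Pairwise, left to right: two overlapping intervals merge when the
#' overlap covers at least 50% of each; otherwise the overlap is split at
#' its midpoint, the left interval keeping positions up to the midpoint.
#' Iterates until no overlaps remain, so every residue belongs to at most
#' one domain.
#'
#' @param intervals data.frame with columns `gene`, `start`, `end`,
#'   `domain_id` (1-based inclusive amino-acid positions).
#' @return data.frame of the same shape with non-overlapping intervals.
#' @export
resolve_overlaps <- function(intervals) {
  stopifnot(all(c("gene", "start", "end", "domain_id") %in% names(intervals)),
            all(intervals$start <= intervals$end))
  resolve_gene <- function(df) {
    repeat {
      df <- df[order(df$start, df$end), , drop = FALSE]
      changed <- FALSE
      i <- 1
      while (i < nrow(df)) {
        s1 <- df$start[i]; e1 <- df$end[i]
        s2 <- df$start[i + 1]; e2 <- df$end[i + 1]
        os <- max(s1, s2); oe <- min(e1, e2)
        if (os <= oe) {
          ov <- oe - os + 1
          len1 <- e1 - s1 + 1; len2 <- e2 - s2 + 1
          if (ov >= 0.5 * len1 && ov >= 0.5 * len2) {
            df$start[i] <- min(s1, s2); df$end[i] <- max(e1, e2)
            df$domain_id[i] <- paste(unique(c(df$domain_id[i], df$domain_id[i + 1])),
                                     collapse = "+")
            df <- df[-(i + 1), , drop = FALSE]
          } else {
            mid <- floor((os + oe) / 2)
            df$end[i] <- mid
            df$start[i + 1] <- mid + 1
          }
          changed <- TRUE
        } else i <- i + 1
      }
      if (!changed) break
    }
    df
  }
  out <- do.call(rbind, lapply(split(intervals, intervals$gene), resolve_gene))
  rownames(out) <- NULL
  out
}

#' Normalized score histogram on [0, 1]
#'
#' Equal-width bins with a pseudocount so Jensen-Shannon distances stay
#' finite, normalized to sum 1.
#'
#' @param scores Scores in [0, 1] (at least one).
#' @param n_bins Number of bins (default 100).
#' @param pseudocount Added to each bin before normalization (default 1e-6).
#' @return Numeric probability vector of length `n_bins`.
#' @export
score_histogram <- function(scores, n_bins = 100L, pseudocount = 1e-6) {
  if (length(scores) == 0) stop("empty score list")
  stopifnot(all(scores >= 0 & scores <= 1))
  bin <- pmin(pmax(ceiling(scores * n_bins), 1L), n_bins)
  h <- tabulate(bin, n_bins) + pseudocount
  h / sum(h)
}

js_distance <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    ok <- a > 0
    sum(a[ok] * (log2(a[ok]) - log2(b[ok])))
  }
  sqrt(pmax(0, 0.5 * kl(p, m) + 0.5 * kl(q, m)))
}

#' All-by-all Jensen-Shannon distance matrix of histograms
#'
#' JSD = square root of the Jensen-Shannon divergence (base 2), a bounded
#' metric in [0, 1].
#'
#' @param histograms Matrix (domains x bins) of probability vectors, or a
#'   list of equal-length vectors.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
jsd_matrix <- function(histograms) {
  if (is.list(histograms)) histograms <- do.call(rbind, histograms)
  n <- nrow(histograms)
  d <- matrix(0, n, n, dimnames = list(rownames(histograms), rownames(histograms)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
    d[i, j] <- d[j, i] <- js_distance(histograms[i, ], histograms[j, ])
  }
  d
}

#' Dynamic splitting of a dendrogram by labeled-variant count
#'
#' Hierarchical clustering (average linkage by default) of the JSD matrix,
#' then a recursive descent from the root: any branch whose member domains
#' carry more labeled controls than `max_count` is replaced by its two
#' children; compliant branches and leaves become clusters. A singleton
#' domain exceeding `max_count` cannot be split and is flagged.
#'
#' @param jsd Symmetric JSD matrix (rownames = domain ids).
#' @param clinvar_counts Named labeled-control count per domain.
#' @param max_count Maximum labeled controls per cluster.
#' @param linkage `hclust` linkage method (default "average").
#' @return List with `clusters` (named integer cluster id per domain),
#'   `flagged` (singleton domains over the cap), `hclust`.
#' @export
cluster_and_split <- function(jsd, clinvar_counts, max_count,
                              linkage = "average") {
  ids <- rownames(jsd) %||% paste0("d", seq_len(nrow(jsd)))
  rownames(jsd) <- colnames(jsd) <- ids
  stopifnot(all(ids %in% names(clinvar_counts)))
  counts <- clinvar_counts[ids]
  if (nrow(jsd) == 1) {
    return(list(clusters = stats::setNames(1L, ids),
                flagged = ids[counts > max_count],
                hclust = NULL))
  }
  hc <- stats::hclust(stats::as.dist(jsd), method = linkage)
  leaves_of <- function(node) {
    # node < 0: leaf -node; node > 0: row of merge matrix
    if (node < 0) return(-node)
    c(leaves_of(hc$merge[node, 1]), leaves_of(hc$merge[node, 2]))
  }
  clusters <- integer(length(ids)); names(clusters) <- ids
  flagged <- character(0)
  next_id <- 0L
  assign_cluster <- function(node) {
    lv <- leaves_of(node)
    total <- sum(counts[lv])
    if (total > max_count && node > 0) {
      assign_cluster(hc$merge[node, 1])
      assign_cluster(hc$merge[node, 2])
    } else {
      next_id <<- next_id + 1L
      clusters[lv] <<- next_id
      if (total > max_count) flagged <<- c(flagged, ids[lv])
    }
  }
  assign_cluster(nrow(hc$merge))
  list(clusters = clusters, flagged = flagged, hclust = hc)
}

#' Grid search for the count cap yielding a target median cluster size
#'
#' Over 50 log-spaced candidate caps between 50 and the total labeled
#' count, picks the cap whose resulting clustering has median labeled
#' count per cluster closest to `target_median` (ties break toward the
#' larger cap).
#'
#' @param jsd JSD matrix.
#' @param clinvar_counts Named labeled count per domain.
#' @param target_median Target median labeled count per cluster (500).
#' @param n_candidates Grid size (default 50).
#' @param linkage `hclust` linkage method.
#' @return List with `max_count`, `clustering` (the winning
#'   [cluster_and_split()] result), `median_count`, `grid` (data.frame of
#'   candidate vs achieved median).
#' @export
grid_search_max_count <- function(jsd, clinvar_counts, target_median = 500,
                                  n_candidates = 50L, linkage = "average") {
  total <- sum(clinvar_counts)
  lo <- min(50, total)
  cand <- unique(round(exp(seq(log(lo), log(max(total, lo + 1)),
                               length.out = n_candidates))))
  meds <- numeric(length(cand))
  clns <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    cl <- cluster_and_split(jsd, clinvar_counts, cand[i], linkage = linkage)
    per <- tapply(clinvar_counts[names(cl$clusters)], cl$clusters, sum)
    meds[i] <- stats::median(per)
    clns[[i]] <- cl
  }
  dev <- abs(meds - target_median)
  best <- which(dev == min(dev))
  best <- best[which.max(cand[best])]
  list(max_count = cand[best], clustering = clns[[best]],
       median_count = meds[best],
       grid = data.frame(max_count = cand, median_count = meds))
}

# two-component skew-normal mixture on [0, 1] by direct numerical ML with
# seeded random restarts; components ordered by mean.
fit_skewnormal_mixture2 <- function(scores, n_restarts = 20L, seed = 1L) {
  s <- clamp01(scores, 1e-6)
  dcomp <- function(x, xi, omega, alpha) {
    fx <- 2 / omega * stats::dnorm((x - xi) / omega) *
      stats::pnorm(alpha * (x - xi) / omega)
    mass <- simpson(2 / omega * stats::dnorm((.qgrid - xi) / omega) *
                    stats::pnorm(alpha * (.qgrid - xi) / omega), 0, 1)
    if (!is.finite(mass) || mass <= 0) return(rep(NA_real_, length(x)))
    fx / mass
  }
  nll <- function(t) {
    w <- stats::plogis(t[1])
    f1 <- dcomp(s, t[2], exp(t[3]), t[4])
    f2 <- dcomp(s, t[5], exp(t[6]), t[7])
    if (any(!is.finite(f1)) || any(!is.finite(f2))) return(1e10)
    ll <- sum(log(pmax(w * f1 + (1 - w) * f2, 1e-300)))
    if (!is.finite(ll)) 1e10 else -ll
  }
  best <- NULL
  qs <- stats::quantile(s, c(0.25, 0.75), names = FALSE)
  for (r in seq_len(n_restarts)) {
    init <- with_seed(child_seed(seed, r), c(
      stats::rnorm(1, 0, 0.5),
      qs[1] + stats::rnorm(1, 0, 0.1), log(0.15) + stats::rnorm(1, 0, 0.3),
      stats::rnorm(1, 0, 1),
      qs[2] + stats::rnorm(1, 0, 0.1), log(0.15) + stats::rnorm(1, 0, 0.3),
      stats::rnorm(1, 0, 1)))
    fit <- tryCatch(stats::optim(init, nll, method = "Nelder-Mead",
                                 control = list(maxit = 600)),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$value < 1e10 &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(NULL)
  t <- best$par
  comp <- list(
    list(w = stats::plogis(t[1]), density = function(x) dcomp(x, t[2], exp(t[3]), t[4])),
    list(w = 1 - stats::plogis(t[1]), density = function(x) dcomp(x, t[5], exp(t[6]), t[7])))
  means <- vapply(comp, function(cm) simpson(cm$density(.qgrid) * .qgrid, 0, 1),
                  numeric(1))
  comp <- comp[order(means)]  # component 1 = "normal" (lower mean)
  list(components = comp, means = sort(means), loglik = -best$value,
       converged = TRUE)
}

#' Cluster validation by mixture-vs-control distribution comparison
#'
#' Fits an unsupervised two-component skew-normal mixture to a cluster's
#' all-variant scores (component 1 = "normal", lower mean; component 2 =
#' "abnormal"); compares each component density (discretized to the
#' histogram bins) against the cluster-specific control class histograms
#' and against the global control class histograms via Jensen-Shannon
#' distance. `difference = mean(global JSD) - mean(cluster JSD)`; positive
#' values mean the cluster's own controls match the mixture better.
#'
#' @param all_scores All-variant scores for the cluster (>= 50).
#' @param cluster_controls List with `benign` and `pathogenic` control
#'   scores of the cluster.
#' @param global_controls List with `benign` and `pathogenic` genome-wide
#'   control scores.
#' @param n_bins Histogram bins (default 100).
#' @param seed Seed for the mixture restarts.
#' @return List with `jsd_cluster`, `jsd_global` (each c(normal, abnormal)),
#'   `difference`, `mixture` (fit), `converged`.
#' @export
cluster_validation <- function(all_scores, cluster_controls, global_controls,
                               n_bins = 100L, seed = 1L) {
  if (length(all_scores) < 50) stop("need >= 50 all-variant scores")
  mix <- fit_skewnormal_mixture2(all_scores, seed = seed)
  if (is.null(mix))
    return(list(jsd_cluster = c(NA, NA), jsd_global = c(NA, NA),
                difference = NA_real_, mixture = NULL, converged = FALSE))
  mids <- seq(0, 1, length.out = n_bins + 1)
  mids <- (mids[-1] + mids[-length(mids)]) / 2
  comp_hist <- function(cm) {
    h <- cm$density(mids) + 1e-6
    h / sum(h)
  }
  h1 <- comp_hist(mix$components[[1]]); h2 <- comp_hist(mix$components[[2]])
  hcb <- score_histogram(cluster_controls$benign, n_bins)
  hcp <- score_histogram(cluster_controls$pathogenic, n_bins)
  hgb <- score_histogram(global_controls$benign, n_bins)
  hgp <- score_histogram(global_controls$pathogenic, n_bins)
  jsd_cluster <- c(normal = js_distance(h1, hcb), abnormal = js_distance(h2, hcp))
  jsd_global <- c(normal = js_distance(h1, hgb), abnormal = js_distance(h2, hgp))
  list(jsd_cluster = jsd_cluster, jsd_global = jsd_global,
       difference = mean(jsd_global) - mean(jsd_cluster),
       mixture = mix, converged = mix$converged)
}

#' Assign a variant to a domain cluster
#'
#' @param gene Gene symbol.
#' @param protein_pos Amino-acid position (NA yields "non_domain" with a
#'   warning).
#' @param resolved_domains Output of [resolve_overlaps()].
#' @param clusters Named cluster id per domain (names formatted
#'   `gene:domain_id`, or plain `domain_id`).
#' @return Cluster id (character) or `"non_domain"`.
#' @export
assign_variant_to_cluster <- function(gene, protein_pos, resolved_domains,
                                      clusters) {
  if (is.na(protein_pos)) {
    warning("missing protein position; assigning non_domain")
    return("non_domain")
  }
  d <- resolved_domains[resolved_domains$gene == gene &
                        resolved_domains$start <= protein_pos &
                        resolved_domains$end >= protein_pos, , drop = FALSE]
  if (nrow(d) == 0) return("non_domain")
  key1 <- paste0(d$gene[1], ":", d$domain_id[1])
  if (key1 %in% names(clusters)) return(as.character(clusters[[key1]]))
  if (d$domain_id[1] %in% names(clusters))
    return(as.character(clusters[[d$domain_id[1]]]))
  "non_domain"
}
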