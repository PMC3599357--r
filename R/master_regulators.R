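# Master-regulator discovery: rank-based binding-score enrichment for TFs and
# hypergeometric target enrichment for miRNAs.

#' Rank-based R-scores from binding scores
#'
#' R(g) = ascending rank of g's binding score / N, with average ranks on ties;
#' a higher binding score always maps to a higher R, and max(R) = 1 when the
#' top score is untied.
#'
#' @param scores named numeric vector of binding scores for one regulator
#'   (>= 2 targets).
#' @return named numeric vector of R-scores in (0, 1].
#' @export
r_scores <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 scored targets")
  rank(scores, ties.method = "average") / length(scores)
}

#' Master TF regulators by R-score enrichment
#'
#' For each regulator, the statistic is the mean R-score over cluster members;
#' the null is `n_random` uniform same-size draws from the universe and
#' p = (1 + #\{null mean >= observed\}) / (n_random + 1). P-values are
#' Bonferroni-corrected over the number of regulators tested (configurable).
#'
#' @param cluster character vector of member ids (subset of `universe`).
#' @param rtable named list (regulator -> named R-score vector over the
#'   universe) or a regulators x universe matrix.
#' @param universe character vector of ids forming the sampling universe.
#' @param n_random number of random clusters (>= 99; default 9999).
#' @param seed integer seed.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param correction "bonferroni" (default) or "none".
#' @return data.frame (regulator, statistic, p, adjusted_p, significant).
#' @export
master_tfs <- function(cluster, rtable, universe, n_random = 9999, seed = 1,
                       alpha = 0.05, correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  if (n_random < 99) stop("n_random must be at least 99")
  if (!all(cluster %in% universe)) stop("cluster must be a subset of universe")
  if (length(cluster) > length(universe)) stop("cluster larger than universe")
  if (is.matrix(rtable))
    rtable <- lapply(setNames(rownames(rtable), rownames(rtable)),
                     function(r) rtable[r, ])
  set.seed(seed)
  # random clusters of the same size: distinct members, as in real clusters
  idx <- t(vapply(seq_len(n_random), function(i)
    sample.int(length(universe), length(cluster)),
    integer(length(cluster))))
  out <- lapply(names(rtable), function(reg) {
    R <- rtable[[reg]][universe]
    obs <- mean(rtable[[reg]][cluster])
    null_means <- rowMeans(matrix(R[idx], nrow = n_random))
    p <- (1 + sum(null_means >= obs)) / (n_random + 1)
    data.frame(regulator = reg, statistic = obs, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$adjusted_p <- if (correction == "bonferroni")
    pmin(1, out$p * nrow(out)) else out$p
  out$significant <- out$adjusted_p <= alpha
  out
}

#' Hypergeometric p-value for target enrichment
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing n from a population of N
#' containing K successes.
#'
#' @param k observed successes in the sample.
#' @param N population size.
#' @param K successes in the population.
#' @param n sample size.
#' @return upper-tail p-value (k = 0 gives 1).
#' @export
hyper_p <- function(k, N, K, n) {
  if (N <= 0) stop("population size must be positive")
  stopifnot(k <= min(K, n))
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Master miRNA regulators by hypergeometric target enrichment
#'
#' For each miRNA: N = universe size (nerve-expressed genes that are a
#' predicted target of at least one miRNA), K = the miRNA's targets in the
#' universe, n = cluster size, k = the miRNA's targets in the cluster;
#' p = P(X >= k). Following the original procedure no multiplicity correction
#' is applied by default.
#'
#' @param cluster character vector of cluster gene ids (subset of universe).
#' @param consensus_targets data.frame with columns `mirna`, `gene`.
#' @param universe character vector of universe gene ids.
#' @param alpha significance cutoff (default 0.05).
#' @param correction "none" (default) or "bonferroni".
#' @return data.frame (regulator, N, K, n, k, p, adjusted_p, significant).
#' @export
master_mirnas <- function(cluster, consensus_targets, universe, alpha = 0.05,
                          correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  if (!length(universe)) stop("empty universe")
  if (!all(cluster %in% universe)) stop("cluster must be a subset of universe")
  N <- length(universe)
  n <- length(cluster)
  mirnas <- unique(consensus_targets$mirna)
  out <- lapply(mirnas, function(m) {
    tg <- unique(consensus_targets$gene[consensus_targets$mirna == m])
    K <- length(intersect(tg, universe))
    k <- length(intersect(tg, cluster))
    data.frame(regulator = m, N = N, K = K, n = n, k = k,
               p = if (K == 0) 1 else hyper_p(k, N, K, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$adjusted_p <- if (correction == "bonferroni")
    pmin(1, out$p * nrow(out)) else out$p
  out$significant <- out$adjusted_p <= alpha
  out
}
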