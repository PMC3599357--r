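# PWM promoter scanning with phylogenetically weighted binding scores.
#
# A site x found at log-odds score s_x and conserved in species set S(x)
# (always including the reference) contributes w_x * exp(s_x) to the target's
# binding score, where w_x is the total branch length of the minimal subtree
# of the species tree spanning S(x). Shared branches are counted once, so a
# site conserved in a distant species outweighs one conserved in a close
# relative. The per-target score is compared against a permutation null that
# relocates every detected site of the PWM uniformly over the concatenated
# search space of all targets.

BASES <- c("A", "C", "G", "T")

#' Default PWM score cutoff by exact tail probability
#'
#' Computes the exact distribution of the PWM log-odds score under the
#' background base model by dynamic programming over positions (scores
#' discretized at `step`), and returns the smallest score whose exceedance
#' probability is at most `p_tail` per scanned position and strand.
#'
#' @param pwm `pwm` object (natural-log-odds matrix).
#' @param p_tail tail probability bound (default 1e-3).
#' @param step discretization step for the score distribution.
#' @return score cutoff in the PWM's log-odds units.
#' @export
pwm_default_cutoff <- function(pwm, p_tail = 1e-3, step = 0.01) {
  scaled <- round(pwm$mat / step)
  probs <- pwm$background
  # distribution as named vector: names = integer score, values = probability
  dist <- c(`0` = 1)
  for (j in seq_len(ncol(scaled))) {
    vals <- as.integer(names(dist))
    new <- tapply(rep(dist, each = 4) * rep(probs, length(dist)),
                  rep(vals, each = 4) + rep(scaled[, j], length(dist)),
                  sum)
    dist <- new
  }
  vals <- as.integer(names(dist))
  ord <- order(vals)
  vals <- vals[ord]; p <- as.numeric(dist[ord])
  tail_p <- rev(cumsum(rev(p)))   # P(S >= vals[i])
  ok <- which(tail_p <= p_tail)
  if (!length(ok)) return(max(vals) * step + step)  # nothing passes
  vals[min(ok)] * step
}

seq_to_index <- function(seq_chars) {
  idx <- match(seq_chars, BASES)
  idx  # NA for non-ACGT
}

revcomp_pwm <- function(mat) {
  mat[rev(seq_len(4)), rev(seq_len(ncol(mat))), drop = FALSE]
}

# score every start position of `idx` (integer base indices, NA for non-ACGT)
# with log-odds matrix `mat`; non-ACGT positions score -Inf per column
score_positions <- function(idx, mat) {
  L <- ncol(mat)
  n <- length(idx) - L + 1
  if (n < 1) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L)) {
    col <- mat[, j][idx[j:(n + j - 1)]]
    col[is.na(col)] <- -Inf
    s <- s + col
  }
  s
}

#' Scan a promoter sequence with a PWM
#'
#' Scans both strands of the sequence covering a target's search space and
#' reports every position whose log-odds score reaches the cutoff. The
#' default cutoff is the exact dynamic-programming tail cutoff of
#' [pwm_default_cutoff()] (exceedance probability <= 1e-3 per position per
#' strand under the background model). Non-ACGT characters score -Inf per
#' column; when they exceed 10% of the sequence a warning is issued.
#'
#' @param seq character string (promoter/search-space sequence).
#' @param pwm `pwm` object.
#' @param cutoff numeric score cutoff or "default".
#' @param target id recorded on each site.
#' @param offset genomic coordinate of the first sequence character (0-based),
#'   used to report site locations.
#' @param chrom chromosome recorded on each site.
#' @return data.frame of sites: pwm, target, chrom, start, end, strand, s.
#' @export
scan_pwm <- function(seq, pwm, cutoff = "default", target = NA_character_,
                     offset = 0, chrom = NA_character_) {
  L <- ncol(pwm$mat)
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) < L)
    stop("sequence shorter than the PWM (", L, " bp)")
  idx <- seq_to_index(chars)
  if (mean(is.na(idx)) > 0.10)
    warning("more than 10% non-ACGT characters in the scanned sequence")
  if (identical(cutoff, "default")) cutoff <- pwm_default_cutoff(pwm)
  fwd <- score_positions(idx, pwm$mat)
  rev <- score_positions(idx, revcomp_pwm(pwm$mat))
  hits_f <- which(fwd >= cutoff)
  hits_r <- which(rev >= cutoff)
  n_hit <- length(hits_f) + length(hits_r)
  data.frame(
    pwm = rep(pwm$id, n_hit), target = rep(target, n_hit),
    chrom = rep(chrom, n_hit),
    start = offset + c(hits_f, hits_r) - 1,
    end = offset + c(hits_f, hits_r) - 1 + L,
    strand = rep(c("+", "-"), c(length(hits_f), length(hits_r))),
    s = c(fwd[hits_f], rev[hits_r]), stringsAsFactors = FALSE)
}

#' Branch length of the minimal spanning subtree of a species set
#'
#' Sum of the branch lengths of the edges in the smallest subtree of the
#' species tree connecting all given species; a single species spans no
#' branches and returns 0.
#'
#' @param tree `phylo` species tree (with branch lengths).
#' @param species character vector of leaf labels.
#' @return total branch length.
#' @export
subtree_weight <- function(tree, species) {
  species <- unique(species)
  unknown <- setdiff(species, tree$tip.label)
  if (length(unknown)) stop("unknown species: ", paste(unknown, collapse = ", "))
  if (length(species) <= 1) return(0)
  pruned <- ape::keep.tip(tree, species)
  sum(pruned$edge.length)
}

#' Annotate sites with conservation and phylogenetic weights
#'
#' A site is conserved in a species when that species' alignment blocks fully
#' cover the site interval; the reference species is always included. The
#' weight w_x is the spanning-subtree branch length of the conserved species;
#' a reference-only site receives `w_floor` (default 0, i.e. non-conserved
#' sites contribute nothing).
#'
#' @param sites site data.frame from [scan_pwm()] (with genomic coordinates).
#' @param alignment named list (species -> alignment-block intervals).
#' @param tree `phylo` species tree including the reference.
#' @param reference reference species name.
#' @param w_floor baseline weight of reference-only sites.
#' @return `sites` with added columns `n_species` and `w`.
#' @export
weight_sites <- function(sites, alignment, tree, reference,
                         w_floor = 0) {
  if (!nrow(sites)) {
    sites$n_species <- integer(0); sites$w <- numeric(0)
    return(sites)
  }
  ivs <- genomic_intervals(sites$chrom, sites$start, sites$end)
  # full containment of the site within one alignment block of the species
  covered <- vapply(names(alignment), function(sp) {
    blocks <- alignment[[sp]]
    hit <- logical(nrow(ivs))
    if (is.null(blocks) || !nrow(blocks)) return(hit)
    for (ch in unique(ivs$chrom)) {
      qi <- which(ivs$chrom == ch)
      si <- which(blocks$chrom == ch)
      if (!length(si)) next
      hit[qi] <- IRanges::overlapsAny(
        as_iranges(ivs[qi, , drop = FALSE]),
        as_iranges(blocks[si, , drop = FALSE]), type = "within")
    }
    hit
  }, logical(nrow(sites)))
  covered <- matrix(covered, nrow = nrow(sites),
                    dimnames = list(NULL, names(alignment)))
  sp_sets <- lapply(seq_len(nrow(sites)), function(i)
    union(reference, names(alignment)[covered[i, ]]))
  sites$n_species <- lengths(sp_sets)
  sig <- vapply(sp_sets, function(s) paste(sort(s), collapse = ","), "")
  w_of <- vapply(unique(sig), function(g) {
    s <- strsplit(g, ",", fixed = TRUE)[[1]]
    if (length(s) <= 1) w_floor else subtree_weight(tree, s)
  }, numeric(1))
  sites$w <- unname(w_of[sig])
  sites
}

#' Phylogenetically weighted binding score
#'
#' Score of a (PWM, target) pair over its detected sites:
#' sum over sites of w_x * exp(s_x). An empty site collection scores 0.
#'
#' @param sites data.frame with columns `w` and `s` (one PWM-target pair).
#' @return nonnegative score.
#' @export
binding_score <- function(sites) {
  if (!nrow(sites)) return(0)
  sum(sites$w * exp(sites$s))
}

#' Permutation p-values for per-target binding scores
#'
#' Null model: each permutation relocates every detected site of a PWM
#' uniformly at random over the concatenated search space of all targets
#' (keeping its (s, w) pair) and reassigns sites to targets by landing
#' position; the per-target score is then recomputed. Since the score only
#' depends on which target a site lands in, relocation reduces to sampling a
#' target per site with probability proportional to its search-space length.
#' raw_p = (1 + #\{permuted score >= observed\}) / (n_perm + 1).
#'
#' @param sites weighted site data.frame (columns target, w, s) for one PWM.
#' @param space_lengths named numeric vector: search-space length per target
#'   (all targets scanned, including those without sites).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return data.frame (target, n_sites, score, raw_p) covering every target in
#'   `space_lengths`. With an empty site pool all p-values are 1.
#' @export
binding_pvalues <- function(sites, space_lengths, n_perm = 999, seed = 1) {
  if (n_perm < 99) stop("n_perm must be at least 99")
  targets <- names(space_lengths)
  obs <- setNames(numeric(length(targets)), targets)
  nst <- setNames(integer(length(targets)), targets)
  if (nrow(sites)) {
    contrib <- sites$w * exp(sites$s)
    agg <- tapply(contrib, sites$target, sum)
    obs[names(agg)] <- agg
    cnt <- table(sites$target)
    nst[names(cnt)] <- as.integer(cnt)
  }
  if (!nrow(sites)) {
    return(data.frame(target = targets, n_sites = 0L, score = 0,
                      raw_p = 1, stringsAsFactors = FALSE))
  }
  set.seed(seed)
  contrib <- sites$w * exp(sites$s)
  # zero-contribution sites cannot change any score under relocation
  contrib <- contrib[contrib > 0]
  prob <- space_lengths / sum(space_lengths)
  exceed <- setNames(numeric(length(targets)), targets)
  nt <- length(targets)
  if (length(contrib)) {
    for (b in seq_len(n_perm)) {
      landed <- sample.int(nt, length(contrib), replace = TRUE, prob = prob)
      perm_scores <- numeric(nt)
      for (i in seq_along(landed))
        perm_scores[landed[i]] <- perm_scores[landed[i]] + contrib[i]
      exceed <- exceed + (perm_scores >= obs)
    }
  } else {
    exceed <- exceed + n_perm * (0 >= obs)
  }
  raw_p <- (1 + exceed) / (n_perm + 1)
  raw_p[obs == 0] <- 1  # every null score is >= 0
  data.frame(target = targets, n_sites = unname(nst), score = unname(obs),
             raw_p = unname(raw_p), stringsAsFactors = FALSE)
}

#' Call TF regulatory targets from binding results
#'
#' Bonferroni-adjusts each raw p-value by the number of PWMs modeling the TF
#' (adjusted_p = min(1, raw_p * m)), and emits a TF -> target edge when any of
#' the TF's PWMs reaches `alpha`, recording the best adjusted p and winning
#' PWM.
#'
#' @param results data.frame with columns tf, pwm, target, n_sites, score,
#'   raw_p.
#' @param alpha adjusted p-value cutoff (0.005 in the method).
#' @return list with `results` (adds adjusted_p, is_target) and `edges`
#'   (tf, target, best_adjusted_p, pwm).
#' @export
tf_targets <- function(results, alpha = 0.005) {
  m_tf <- tapply(results$pwm, results$tf, function(p) length(unique(p)))
  results$adjusted_p <- pmin(1, results$raw_p * as.numeric(m_tf[results$tf]))
  results$is_target <- results$adjusted_p <= alpha
  hits <- results[results$is_target, , drop = FALSE]
  if (nrow(hits)) {
    ord <- order(hits$tf, hits$target, hits$adjusted_p)
    hits <- hits[ord, ]
    key <- paste(hits$tf, hits$target)
    best <- hits[!duplicated(key), ]
    edges <- data.frame(tf = best$tf, target = best$target,
                        best_adjusted_p = best$adjusted_p, pwm = best$pwm,
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(tf = character(0), target = character(0),
                        best_adjusted_p = numeric(0), pwm = character(0))
  }
  list(results = results, edges = edges)
}

#' Predict TF targets by phylogenetically weighted promoter scanning
#'
#' End-to-end wrapper: scans each target's promoter sequence with each PWM,
#' weights sites by conservation, computes per-target binding scores,
#' permutation p-values and Bonferroni-adjusted target calls.
#'
#' @param promoters named list per target: list(seq, chrom, start, strand)
#'   giving the search-space sequence and its genomic offset.
#' @param pwms named list of `pwm` objects.
#' @param tf_of named character vector mapping PWM id -> TF id.
#' @param alignment named list of per-species alignment-block intervals.
#' @param tree `phylo` species tree.
#' @param reference reference species name.
#' @param cutoff score cutoff or "default".
#' @param n_perm permutations for the p-value.
#' @param seed integer seed.
#' @param alpha adjusted-p cutoff for target calls.
#' @param w_floor baseline weight for non-conserved sites.
#' @return list with `results` (per PWM-target statistics), `edges`
#'   (TF -> target calls) and `sites` (all weighted sites).
#' @export
predict_tf_targets <- function(promoters, pwms, tf_of, alignment, tree,
                               reference, cutoff = "default", n_perm = 999,
                               seed = 1, alpha = 0.005, w_floor = 0) {
  space_lengths <- vapply(promoters, function(p) nchar(p$seq), numeric(1))
  all_sites <- list(); all_results <- list()
  for (k in seq_along(pwms)) {
    pwm <- pwms[[k]]
    cut_k <- if (identical(cutoff, "default")) pwm_default_cutoff(pwm) else cutoff
    sites <- lapply(names(promoters), function(tg) {
      p <- promoters[[tg]]
      scan_pwm(p$seq, pwm, cutoff = cut_k, target = tg,
               offset = p$start, chrom = p$chrom)
    })
    sites <- do.call(rbind, sites)
    sites <- weight_sites(sites, alignment, tree, reference, w_floor)
    pv <- binding_pvalues(sites, space_lengths, n_perm = n_perm,
                          seed = seed + k)
    pv$tf <- unname(tf_of[pwm$id])
    pv$pwm <- pwm$id
    all_results[[k]] <- pv[, c("tf", "pwm", "target", "n_sites", "score",
                               "raw_p")]
    all_sites[[k]] <- sites
  }
  results <- do.call(rbind, all_results)
  called <- tf_targets(results, alpha = alpha)
  list(results = called$results, edges = called$edges,
       sites = do.call(rbind, all_sites))
}
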