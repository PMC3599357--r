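# Injury-response gene cluster (IRGC) discovery and regulator correlation.
#
# Profiles are row-standardized (z-scored) before clustering so that k-means
# groups by shape rather than absolute intensity; rows with zero variance are
# mapped to the all-zero profile.

zscore_rows <- function(mat) {
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, sd)
  z <- (mat - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

# Pearson r of rows of `mat` against vector `v`; zero-variance rows -> NA
cor_to_vec <- function(mat, v) {
  if (sd(v) == 0) return(rep(NA_real_, nrow(mat)))
  sdv <- apply(mat, 1, sd)
  r <- rep(NA_real_, nrow(mat))
  ok <- sdv > 0
  if (any(ok)) r[ok] <- as.vector(cor(t(mat[ok, , drop = FALSE]), v))
  r
}

#' Genes called expressed
#'
#' A feature is expressed when it carries at least one positive presence call
#' across all profiled timepoints.
#'
#' @param expr `expr_set` object.
#' @return character vector of expressed feature ids.
#' @export
call_expressed <- function(expr) {
  rownames(expr$values)[rowSums(expr$presence) >= 1]
}

#' Identify injury-response gene clusters
#'
#' Pipeline: (a) k-means on row-standardized expression profiles under a fixed
#' seed; (b) keep clusters that contain at least one known myelin gene and
#' whose member-mean profile differs between pre- and post-crush timepoints by
#' a two-sample t-test at `alpha`; (c) iteratively merge surviving clusters
#' whose centroids correlate at Pearson r >= `merge_r`, recomputing centroids
#' as member means; (d) re-assign every expressed gene to the centroid it best
#' correlates with, keeping genes with r >= `assign_r` (memberships are
#' disjoint); (e) label each cluster MGC when the centroid drops immediately
#' after crush relative to the pre-crush level, PGC otherwise.
#'
#' @param expr `expr_set` restricted to expressed genes (rows are genes,
#'   columns named timepoints).
#' @param k number of k-means clusters (reduced with a message when the data
#'   hold fewer distinct standardized profiles).
#' @param myelin_genes character vector of known myelin gene ids.
#' @param pre_timepoints,post_timepoints column names of pre-crush and
#'   post-crush timepoints used by the t-test and the MGC/PGC label.
#' @param alpha t-test level for differential pre/post expression.
#' @param merge_r centroid-correlation threshold for merging clusters.
#' @param assign_r final membership correlation cutoff (0.8 in the study).
#' @param seed integer seed fixing the k-means start.
#' @return list of class `gene_clusters`; each element has `members`
#'   (character), `centroid` (named numeric over timepoints) and
#'   `cluster_class` ("MGC"/"PGC"). Empty list (with a warning) when no
#'   cluster survives filtering.
#' @export
find_irgcs <- function(expr, k = 12, myelin_genes, pre_timepoints,
                       post_timepoints, alpha = 0.05, merge_r = 0.85,
                       assign_r = 0.8, seed = 1) {
  values <- expr$values
  if (k > nrow(values)) stop("k exceeds the number of genes")
  stopifnot(all(c(pre_timepoints, post_timepoints) %in% colnames(values)))
  z <- zscore_rows(values)
  n_distinct <- nrow(unique(round(z, 10)))
  if (k > n_distinct) {
    message("reducing k from ", k, " to ", n_distinct,
            " distinct standardized profiles")
    k <- n_distinct
  }
  set.seed(seed)
  km <- kmeans(z, centers = k, nstart = 5, iter.max = 100)
  # (b) filter: myelin gene content + pre/post differential centroid
  kept <- list()
  for (cl in seq_len(k)) {
    members <- rownames(z)[km$cluster == cl]
    if (!any(members %in% myelin_genes)) next
    centroid <- colMeans(z[members, , drop = FALSE])
    pre <- centroid[pre_timepoints]
    post <- centroid[post_timepoints]
    p <- tryCatch(t.test(pre, post)$p.value, error = function(e) 1)
    if (is.na(p) || p >= alpha) next
    kept[[length(kept) + 1]] <- list(members = members, centroid = centroid)
  }
  if (!length(kept)) {
    warning("no cluster passed the myelin-gene / differential-expression filter")
    return(structure(list(), class = "gene_clusters"))
  }
  # (c) merge similar centroids until stable
  repeat {
    if (length(kept) < 2) break
    cen <- do.call(rbind, lapply(kept, `[[`, "centroid"))
    cc <- suppressWarnings(cor(t(cen)))
    diag(cc) <- -Inf
    cc[is.na(cc)] <- -Inf
    if (max(cc) < merge_r) break
    ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    members <- union(kept[[i]]$members, kept[[j]]$members)
    kept[[i]] <- list(members = members,
                      centroid = colMeans(z[members, , drop = FALSE]))
    kept[[j]] <- NULL
  }
  # (d) final membership: best-r centroid with r >= assign_r
  cen <- do.call(rbind, lapply(kept, `[[`, "centroid"))
  rmat <- vapply(seq_len(nrow(cen)), function(i) cor_to_vec(z, cen[i, ]),
                 numeric(nrow(z)))
  rmat <- matrix(rmat, nrow = nrow(z))
  best <- apply(rmat, 1, function(r)
    if (all(is.na(r))) NA_integer_ else which.max(r))
  best_r <- rmat[cbind(seq_len(nrow(z)), best)]
  assigned <- !is.na(best_r) & best_r >= assign_r
  clusters <- list()
  for (i in seq_len(nrow(cen))) {
    members <- rownames(z)[assigned & best == i]
    if (!length(members)) next
    centroid <- colMeans(z[members, , drop = FALSE])
    clusters[[length(clusters) + 1]] <-
      list(members = members, centroid = centroid,
           cluster_class = classify_cluster(centroid, pre_timepoints,
                                            post_timepoints))
  }
  names(clusters) <- paste0("IRGC", seq_along(clusters))
  structure(clusters, class = "gene_clusters")
}

# MGC: centroid down immediately post-crush relative to the pre-crush level
classify_cluster <- function(centroid, pre_timepoints, post_timepoints) {
  pre_level <- mean(centroid[pre_timepoints])
  first_post <- centroid[post_timepoints[1]]
  if (first_post < pre_level) "MGC" else "PGC"
}

#' @export
print.gene_clusters <- function(x, ...) {
  cat("gene_clusters:", length(x), "clusters\n")
  for (nm in names(x))
    cat("  ", nm, ": ", length(x[[nm]]$members), " genes, class ",
        x[[nm]]$cluster_class, "\n", sep = "")
  invisible(x)
}

#' Write cluster assignments to TSV
#'
#' @param clusters `gene_clusters` object.
#' @param path output TSV (gene, cluster, r, class).
#' @export
write_clusters <- function(clusters, path) {
  rows <- lapply(names(clusters), function(nm) {
    cl <- clusters[[nm]]
    data.frame(gene = cl$members, cluster = nm,
               r = NA_real_, class = cl$cluster_class)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), cluster = character(0),
               r = numeric(0), class = character(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter duplicate-probeset miRNA expression
#'
#' Each miRNA is measured by exactly two probesets. A miRNA is dropped when
#' (i) its maximum expression over both probesets and all timepoints falls
#' below the mean of the control probeset values, or (ii) one duplicate
#' exceeds the other at every timepoint and a one-sided Mann-Whitney U test
#' across timepoints gives p < `alpha` (a directional duplicate disagreement).
#' Surviving miRNAs are summarized as the per-timepoint mean of their two
#' duplicates.
#'
#' @param mirna_expr `expr_set` whose rows are probesets.
#' @param probe_map data.frame with columns `probeset`, `mirna`.
#' @param control_probesets probeset ids of the control probes.
#' @param alpha level of the duplicate-disagreement test.
#' @return `expr_set` with one row per surviving miRNA.
#' @export
filter_mirna_expression <- function(mirna_expr, probe_map, control_probesets,
                                    alpha = 0.05) {
  values <- mirna_expr$values
  if (!length(control_probesets) || !all(control_probesets %in% rownames(values)))
    stop("control probesets missing from the expression matrix")
  control_mean <- mean(values[control_probesets, , drop = FALSE])
  mirnas <- unique(probe_map$mirna)
  keep <- list()
  for (m in mirnas) {
    probes <- probe_map$probeset[probe_map$mirna == m]
    if (length(probes) != 2)
      stop("miRNA ", m, " has ", length(probes), " probesets (expected 2)")
    a <- values[probes[1], ]
    b <- values[probes[2], ]
    if (max(c(a, b)) < control_mean) next
    hi <- if (mean(a) >= mean(b)) a else b
    lo <- if (mean(a) >= mean(b)) b else a
    if (all(hi > lo)) {
      p <- suppressWarnings(
        wilcox.test(hi, lo, alternative = "greater")$p.value)
      if (!is.na(p) && p < alpha) next
    }
    keep[[m]] <- (a + b) / 2
  }
  if (!length(keep))
    return(expr_set(matrix(numeric(0), 0, ncol(values),
                           dimnames = list(NULL, colnames(values)))))
  out <- do.call(rbind, keep)
  rownames(out) <- names(keep)
  expr_set(out)
}

#' Correlate candidate regulators with cluster centroids
#'
#' Computes Pearson r between each candidate regulator's profile and each
#' cluster centroid over a set of matched timepoints; r >= `r_cut` yields a
#' `correlated` call, r <= -`r_cut` an `anti-correlated` call, anything else
#' no call. Constant (zero-variance) profiles give no call and a message.
#'
#' @param candidates `expr_set` of candidate regulator profiles.
#' @param clusters `gene_clusters` object.
#' @param timepoint_map named character vector mapping candidate timepoint
#'   names to centroid timepoint names (e.g. the study matched miRNA days
#'   0/4/14 to mRNA days 0/4/10); at least 3 pairs required.
#' @param r_cut correlation cutoff (default 0.8).
#' @param regulator_type "TF" or "miRNA", recorded on each call.
#' @return data.frame (regulator, regulator_type, cluster, relation, r), one
#'   row per called (regulator, cluster) pair.
#' @export
correlate_regulators <- function(candidates, clusters, timepoint_map,
                                 r_cut = 0.8,
                                 regulator_type = c("TF", "miRNA")) {
  regulator_type <- match.arg(regulator_type)
  if (length(timepoint_map) < 3)
    stop("fewer than 3 mapped timepoints: correlation is degenerate")
  values <- candidates$values
  stopifnot(all(names(timepoint_map) %in% colnames(values)))
  calls <- list()
  for (cl_name in names(clusters)) {
    centroid <- clusters[[cl_name]]$centroid
    stopifnot(all(timepoint_map %in% names(centroid)))
    v <- centroid[unname(timepoint_map)]
    sub <- values[, names(timepoint_map), drop = FALSE]
    r <- cor_to_vec(sub, v)
    if (any(is.na(r)))
      message(sum(is.na(r)), " constant candidate profile(s): no call")
    called <- !is.na(r) & abs(r) >= r_cut
    if (!any(called)) next
    calls[[cl_name]] <- data.frame(
      regulator = rownames(values)[called],
      regulator_type = regulator_type,
      cluster = cl_name,
      relation = ifelse(r[called] > 0, "correlated", "anti-correlated"),
      r = r[called], stringsAsFactors = FALSE)
  }
  if (!length(calls))
    return(data.frame(regulator = character(0),
                      regulator_type = character(0), cluster = character(0),
                      relation = character(0), r = numeric(0)))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
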