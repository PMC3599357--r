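# Stepwise assembly of the TF/miRNA regulatory network and motif analysis.
#
# Step provenance follows the inference workflow: 0 cluster genes as seed
# nodes; 1 correlated/anti-correlated regulators; 2 ChIP-Seq edges; 3
# predicted TF edges for TFs without ChIP data; 4 consensus miRNA-mRNA edges;
# 5/6 master TFs and miRNAs added as nodes; 7 edges connecting the new master
# regulators to the existing network (ChIP first, prediction second).

#' Sign of a regulatory edge
#'
#' miRNA regulators always repress ("-"). TF edge signs come from the Pearson
#' correlation of regulator and target expression over shared timepoints: "+"
#' for r >= 0, "-" otherwise, flagged low-confidence when |r| < `r_threshold`
#' or either profile is missing (then "+" by convention).
#'
#' @param regulator,target node ids.
#' @param profiles named list of numeric expression vectors with timepoint
#'   names (profiles on different grids are correlated over shared names).
#' @param mirna_ids ids to treat as miRNA regulators.
#' @param r_threshold |r| below which the sign is flagged (default 0.3).
#' @return list(sign, low_confidence, r).
#' @export
edge_sign <- function(regulator, target, profiles, mirna_ids = character(0),
                      r_threshold = 0.3) {
  if (regulator %in% mirna_ids)
    return(list(sign = "-", low_confidence = FALSE, r = NA_real_))
  rp <- profiles[[regulator]]
  tp <- profiles[[target]]
  if (is.null(rp) || is.null(tp))
    return(list(sign = "+", low_confidence = TRUE, r = NA_real_))
  shared <- intersect(names(rp), names(tp))
  if (length(shared) < 3 || sd(rp[shared]) == 0 || sd(tp[shared]) == 0)
    return(list(sign = "+", low_confidence = TRUE, r = NA_real_))
  r <- cor(rp[shared], tp[shared])
  list(sign = if (r >= 0) "+" else "-",
       low_confidence = abs(r) < r_threshold, r = r)
}

#' Assemble the regulatory network
#'
#' Realizes the stepwise workflow (see file header) with evidence precedence
#' chipseq > predicted when a (regulator, target) pair is supported by both.
#' Predicted TF edges are only used for TFs without ChIP data (`chip_tfs`).
#' Nodes left without any edge are pruned unless `keep_isolated`.
#'
#' @param irgcs `gene_clusters` object (seed genes and their MGC/PGC class).
#' @param regulator_calls data.frame from [correlate_regulators()] (columns
#'   regulator, regulator_type, cluster, relation, r); may be empty.
#' @param chip_edges data.frame (tf, target) of ChIP-derived edges.
#' @param chip_tfs TFs that have ChIP-Seq data (controls Step 3 eligibility).
#' @param predicted_tf_edges data.frame (tf, target) of predicted TF edges.
#' @param mirna_edges data.frame (mirna, gene) of consensus miRNA targets.
#' @param master_tf_calls,master_mirna_calls data.frames with columns
#'   regulator, significant (from [master_tfs()]/[master_mirnas()]); may be
#'   NULL.
#' @param profiles named list of expression vectors for edge signing.
#' @param tf_ids,mirna_ids id sets fixing node types; an id in both is an
#'   error.
#' @param keep_isolated keep edge-less nodes (default FALSE).
#' @param r_threshold sign-confidence threshold for [edge_sign()].
#' @return `regnet` object; every edge is stamped with its provenance step.
#' @export
build_network <- function(irgcs, regulator_calls = NULL, chip_edges = NULL,
                          chip_tfs = character(0),
                          predicted_tf_edges = NULL, mirna_edges = NULL,
                          master_tf_calls = NULL, master_mirna_calls = NULL,
                          profiles = list(), tf_ids = character(0),
                          mirna_ids = character(0), keep_isolated = FALSE,
                          r_threshold = 0.3) {
  clash <- intersect(tf_ids, mirna_ids)
  if (length(clash))
    stop("id(s) declared both TF and miRNA: ", paste(clash, collapse = ", "))
  node_type <- function(id)
    ifelse(id %in% mirna_ids, "miRNA", ifelse(id %in% tf_ids, "TF", "mRNA"))

  # Step 0: IRGC genes
  nodes <- data.frame(id = character(0), type = character(0),
                      role = character(0), cluster_class = character(0),
                      stringsAsFactors = FALSE)
  for (nm in names(irgcs)) {
    cl <- irgcs[[nm]]
    nodes <- rbind(nodes, data.frame(
      id = cl$members, type = node_type(cl$members), role = "target-only",
      cluster_class = cl$cluster_class, stringsAsFactors = FALSE))
  }
  nodes <- nodes[!duplicated(nodes$id), ]

  add_nodes <- function(nodes, ids, role) {
    ids <- setdiff(unique(ids), nodes$id)
    if (!length(ids)) return(nodes)
    rbind(nodes, data.frame(id = ids, type = node_type(ids), role = role,
                            cluster_class = "none", stringsAsFactors = FALSE))
  }

  # Step 1: correlated / anti-correlated regulators
  if (!is.null(regulator_calls) && nrow(regulator_calls)) {
    for (rel in c("correlated", "anti-correlated")) {
      ids <- regulator_calls$regulator[regulator_calls$relation == rel]
      new <- setdiff(ids, character(0))
      # update role of existing nodes (e.g. a TF inside a cluster)
      upd <- nodes$id %in% ids
      nodes$role[upd] <- rel
      nodes <- add_nodes(nodes, ids, rel)
    }
  }
  regulator_ids <- if (!is.null(regulator_calls))
    unique(regulator_calls$regulator) else character(0)

  edges <- list()
  in_nodes <- function(ids) ids %in% nodes$id
  take_edges <- function(df, step, evidence) {
    if (is.null(df) || !nrow(df)) return(NULL)
    reg <- df[[1]]; tgt <- df[[2]]
    sel <- in_nodes(reg) & in_nodes(tgt)
    if (!any(sel)) return(NULL)
    data.frame(regulator = reg[sel], target = tgt[sel], evidence = evidence,
               step = step, stringsAsFactors = FALSE)
  }

  # Step 2: ChIP edges among current nodes
  edges$s2 <- take_edges(chip_edges, 2L, "chipseq")
  # Step 3: predicted edges for TFs lacking ChIP data
  if (!is.null(predicted_tf_edges) && nrow(predicted_tf_edges)) {
    nochip <- predicted_tf_edges[!predicted_tf_edges[[1]] %in% chip_tfs, ,
                                 drop = FALSE]
    edges$s3 <- take_edges(nochip, 3L, "predicted")
  }
  # Step 4: consensus miRNA -> mRNA edges
  edges$s4 <- take_edges(mirna_edges, 4L, "predicted")

  # Steps 5-6: master regulators as new nodes
  master_ids <- character(0)
  for (calls in list(master_tf_calls, master_mirna_calls)) {
    if (is.null(calls) || !nrow(calls)) next
    sig <- unique(calls$regulator[calls$significant])
    master_ids <- union(master_ids, setdiff(sig, nodes$id))
    nodes <- add_nodes(nodes, sig, "master")
  }

  # Step 7: edges touching the newly added masters (ChIP, then prediction)
  if (length(master_ids)) {
    touches <- function(df) {
      if (is.null(df) || !nrow(df)) return(NULL)
      df[df[[1]] %in% master_ids | df[[2]] %in% master_ids, , drop = FALSE]
    }
    edges$s7a <- take_edges(touches(chip_edges), 7L, "chipseq")
    if (!is.null(predicted_tf_edges)) {
      nochip <- predicted_tf_edges[!predicted_tf_edges[[1]] %in% chip_tfs, ,
                                   drop = FALSE]
      edges$s7b <- take_edges(touches(nochip), 7L, "predicted")
    }
    edges$s7c <- take_edges(touches(mirna_edges), 7L, "predicted")
  }

  e <- do.call(rbind, edges)
  if (is.null(e) || !nrow(e)) {
    net_nodes <- if (keep_isolated) nodes else nodes[0, ]
    return(regnet(net_nodes, NULL))
  }
  # evidence precedence (chipseq first), then earliest step
  prec <- match(e$evidence, EDGE_EVIDENCE)
  key <- paste(e$regulator, e$target)
  ord <- order(key, prec, e$step)
  e <- e[ord, ][!duplicated(key[ord]), ]
  nself <- sum(e$regulator == e$target)
  if (nself) message(nself, " self-loop(s) present in the input edge sets")

  signed <- lapply(seq_len(nrow(e)), function(i)
    edge_sign(e$regulator[i], e$target[i], profiles, mirna_ids, r_threshold))
  e$sign <- vapply(signed, `[[`, "", "sign")
  e$low_confidence <- vapply(signed, `[[`, logical(1), "low_confidence")
  e <- e[order(e$step, e$regulator, e$target), ]

  if (!keep_isolated) {
    used <- union(e$regulator, e$target)
    nodes <- nodes[nodes$id %in% used, ]
  }
  regnet(nodes, e)
}

#' Ego subnetwork of a node
#'
#' Nodes: the focal node, its direct regulators and direct targets; edges: all
#' network edges with both endpoints in that node set (including edges among
#' the neighbors).
#'
#' @param network `regnet` object.
#' @param node focal node id.
#' @return `regnet` object.
#' @export
ego_subnetwork <- function(network, node) {
  if (!node %in% network$nodes$id) stop("unknown node: ", node)
  e <- network$edges
  keep <- unique(c(node, e$regulator[e$target == node],
                   e$target[e$regulator == node]))
  sub_e <- e[e$regulator %in% keep & e$target %in% keep, , drop = FALSE]
  regnet(network$nodes[network$nodes$id %in% keep, , drop = FALSE],
         if (nrow(sub_e)) sub_e else NULL)
}

#' Enumerate TF-miRNA-gene feedforward loops
#'
#' Emits every triple (T, M, G) with T a TF, M a miRNA and G a non-miRNA
#' target gene such that edges T->G, T->M and M->G all exist. The loop is
#' coherent when sign(T->G) = sign(T->M) x sign(M->G). The target class comes
#' from G's cluster class (MGC -> myelination, PGC -> proliferation);
#' unclassified targets are excluded from categorization and counted in the
#' `n_unclassified` attribute. Categories: I1 incoherent/myelination, I2
#' incoherent/proliferation, C1 coherent/myelination, C2
#' coherent/proliferation.
#'
#' @param network `regnet` with signed edges.
#' @return data.frame (tf, mirna, target, sign_direct, sign_tm, sign_mg,
#'   coherence, target_class, category) with attribute `n_unclassified`.
#' @export
find_ffls <- function(network) {
  e <- network$edges
  nodes <- network$nodes
  type_of <- setNames(nodes$type, nodes$id)
  class_of <- setNames(nodes$cluster_class, nodes$id)
  tm <- e[type_of[e$regulator] == "TF" & type_of[e$target] == "miRNA", ]
  mg <- e[type_of[e$regulator] == "miRNA" & type_of[e$target] != "miRNA", ]
  tg <- e[type_of[e$regulator] == "TF" & type_of[e$target] != "miRNA", ]
  out <- list(); n_skip <- 0L
  if (nrow(tm) && nrow(mg) && nrow(tg)) {
    sign_tg <- setNames(tg$sign, paste(tg$regulator, tg$target))
    for (i in seq_len(nrow(tm))) {
      Tn <- tm$regulator[i]; Mn <- tm$target[i]
      gs <- mg[mg$regulator == Mn, ]
      for (j in seq_len(nrow(gs))) {
        Gn <- gs$target[j]
        if (Gn == Tn) next
        sd_ <- sign_tg[paste(Tn, Gn)]
        if (is.na(sd_)) next
        indirect <- if (tm$sign[i] == gs$sign[j]) "+" else "-"
        coherence <- if (sd_ == indirect) "coherent" else "incoherent"
        cls <- switch(class_of[Gn], MGC = "myelination",
                      PGC = "proliferation", NA_character_)
        if (is.na(cls)) { n_skip <- n_skip + 1L; next }
        cat_ <- paste0(if (coherence == "incoherent") "I" else "C",
                       if (cls == "myelination") "1" else "2")
        out[[length(out) + 1]] <- data.frame(
          tf = Tn, mirna = Mn, target = Gn, sign_direct = unname(sd_),
          sign_tm = tm$sign[i], sign_mg = gs$sign[j],
          coherence = coherence, target_class = cls, category = cat_,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(tf = character(0), mirna = character(0), target = character(0),
               sign_direct = character(0), sign_tm = character(0),
               sign_mg = character(0), coherence = character(0),
               target_class = character(0), category = character(0))
  attr(res, "n_unclassified") <- n_skip
  res
}

#' Enumerate short feedback loops
#'
#' All simple directed cycles of length <= `max_len`, each reported once in
#' canonical rotation (lexicographically smallest start node), with the loop
#' sign as the product of edge signs ("+" positive, "-" negative loop).
#'
#' @param network `regnet` with signed edges.
#' @param max_len maximum cycle length (>= 2; default 3).
#' @return data.frame (nodes = "a->b->c", length, sign).
#' @export
find_feedback_loops <- function(network, max_len = 3) {
  if (max_len < 2) stop("max_len must be >= 2")
  e <- network$edges
  if (!nrow(e))
    return(data.frame(nodes = character(0), length = integer(0),
                      sign = character(0)))
  sign_of <- setNames(e$sign, paste(e$regulator, e$target))
  adj <- split(e$target, e$regulator)
  ids <- sort(unique(c(e$regulator, e$target)))
  cycles <- list()
  # DFS from each start; only visit nodes lexicographically after the start so
  # every cycle is found exactly once, rooted at its smallest node
  for (s in ids) {
    stack <- list(list(path = s))
    while (length(stack)) {
      fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      last <- fr$path[length(fr$path)]
      for (nb in adj[[last]]) {
        if (is.null(nb)) next
        if (nb == s && length(fr$path) >= 2) {
          cyc <- fr$path
          sgn <- sign_of[paste(c(cyc), c(cyc[-1], s))]
          cycles[[length(cycles) + 1]] <- data.frame(
            nodes = paste(cyc, collapse = "->"),
            length = length(cyc),
            sign = if (sum(sgn == "-") %% 2 == 0) "+" else "-",
            stringsAsFactors = FALSE)
        } else if (nb > s && !(nb %in% fr$path) &&
                   length(fr$path) < max_len) {
          stack[[length(stack) + 1]] <- list(path = c(fr$path, nb))
        }
      }
    }
  }
  if (!length(cycles))
    return(data.frame(nodes = character(0), length = integer(0),
                      sign = character(0)))
  out <- do.call(rbind, cycles)
  out <- out[order(out$length, out$nodes), ]
  rownames(out) <- NULL
  out
}

#' Coherence-by-class bias of feedforward loops
#'
#' Builds the 2x2 table rows = (incoherent, coherent) x columns =
#' (myelination, proliferation), counting DISTINCT target genes per cell
#' (motif-level counts are also reported), and returns the two-sided Fisher
#' exact p-value. A table with an empty row or column gives p = 1 with a
#' warning.
#'
#' @param motifs data.frame from [find_ffls()].
#' @return list(table, motif_table, p).
#' @export
motif_bias_test <- function(motifs) {
  if (!nrow(motifs)) stop("no motifs supplied")
  lv_co <- c("incoherent", "coherent")
  lv_cl <- c("myelination", "proliferation")
  tab <- matrix(0L, 2, 2, dimnames = list(lv_co, lv_cl))
  mtab <- tab
  for (co in lv_co) for (cl in lv_cl) {
    sel <- motifs$coherence == co & motifs$target_class == cl
    tab[co, cl] <- length(unique(motifs$target[sel]))
    mtab[co, cl] <- sum(sel)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate motif table (empty row or column); p = 1")
    p <- 1
  } else {
    p <- fisher.test(tab)$p.value
  }
  list(table = tab, motif_table = mtab, p = p)
}
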