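# One-command orchestration of the network inference workflow (Steps 0-7),
# with config validation, per-step logging and a manifest of intermediates.

CONFIG_SECTIONS <- c("seed", "paths", "cluster", "tss", "tfbs", "targets",
                     "master", "network")

#' Read and validate a pipeline configuration
#'
#' Configurations are YAML files (or equivalent R lists) with the sections
#' `seed`, `paths`, `cluster`, `tss`, `tfbs`, `targets`, `master`,
#' `network`. Unknown sections or keys are rejected; referenced input files
#' must exist. Relative paths are resolved against the config file's
#' directory.
#'
#' @param config path to a YAML config or a config list.
#' @return validated config list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) {
    base <- dirname(config)
    config <- yaml::read_yaml(config)
    config$paths <- rapply(config$paths, function(p)
      if (file.exists(p)) p else file.path(base, p), how = "replace")
  }
  unknown <- setdiff(names(config), CONFIG_SECTIONS)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  known_keys <- list(
    paths = c("annotation", "tracks", "genome", "expression", "presence",
              "mirna_expression", "probe_map", "control_probesets",
              "myelin_genes", "peaks", "pwms", "tree", "target_lists",
              "utrs", "mirna_seqs", "rp_track"),
    cluster = c("k", "alpha", "merge_r", "assign_r", "r_cut",
                "pre_timepoints", "post_timepoints", "timepoint_map"),
    tss = c("max_upstream", "window_size"),
    tfbs = c("cutoff", "n_perm", "alpha", "w_floor", "reference"),
    targets = c("mrna_upstream", "mrna_downstream", "mirna_upstream",
                "mirna_downstream", "min_methods", "min_overlap_bp"),
    master = c("n_random", "alpha", "correction"),
    network = c("keep_isolated", "r_threshold"))
  for (sec in names(known_keys)) {
    unknown <- setdiff(names(config[[sec]]), known_keys[[sec]])
    if (length(unknown))
      stop("unknown key(s) in config section '", sec, "': ",
           paste(unknown, collapse = ", "))
  }
  flat <- unlist(config$paths)
  missing <- flat[!file.exists(flat)]
  if (length(missing))
    stop("config references missing file(s): ",
         paste(missing, collapse = ", "))
  if (is.null(config$seed)) config$seed <- 1
  config
}

step_log <- function(step, ...) message("[step ", step, "] ", ...)

#' Run the full network inference pipeline
#'
#' Executes Steps 0-7 in order: expression clustering (0), regulator
#' correlation (1), ChIP-derived TF edges (2), predicted TF edges for TFs
#' without ChIP data (3), consensus miRNA targets (4), master TF and miRNA
#' discovery (5-6) and master-edge expansion (7), writing every intermediate
#' table plus the final network and motif report to `out_dir`. Identical
#' config and seed give byte-identical outputs; per-module seeds are derived
#' deterministically from the global seed. Missing optional inputs (peaks,
#' UTRs) degrade gracefully with a logged notice.
#'
#' @param config YAML config path or config list (see
#'   [read_pipeline_config()]).
#' @param out_dir output directory for intermediates and results.
#' @return object of class `pipeline_result`: list with the network, all
#'   intermediate tables, the motif report and the output manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  paths <- cfg$paths
  outputs <- list()
  save_tab <- function(df, name) {
    f <- file.path(out_dir, name)
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[name]] <<- f
    f
  }

  annotation <- read_annotation(paths$annotation)
  tracks <- read_feature_tracks(paths$tracks)
  genome <- Biostrings::readDNAStringSet(paths$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  expr <- read_expression(paths$expression, paths$presence)
  tf_ids <- annotation$genes$id[annotation$genes$gene_type == "TF"]
  mirna_ids <- annotation$mirnas$id

  ## Step 0: injury-response gene clusters
  expressed <- call_expressed(expr)
  step_log(0, length(expressed), " expressed features")
  myelin <- readLines(paths$myelin_genes)
  cl_cfg <- cfg$cluster
  gene_expr <- expr_set(expr$values[expressed, , drop = FALSE],
                        expr$presence[expressed, , drop = FALSE])
  irgcs <- find_irgcs(gene_expr, k = cl_cfg$k, myelin_genes = myelin,
                      pre_timepoints = unlist(cl_cfg$pre_timepoints),
                      post_timepoints = unlist(cl_cfg$post_timepoints),
                      alpha = cl_cfg$alpha, merge_r = cl_cfg$merge_r,
                      assign_r = cl_cfg$assign_r, seed = seed * 100 + 1)
  step_log(0, length(irgcs), " injury-response gene clusters")
  save_tab(do.call(rbind, lapply(names(irgcs), function(nm)
    data.frame(gene = irgcs[[nm]]$members, cluster = nm,
               class = irgcs[[nm]]$cluster_class))), "clusters.tsv")

  ## Step 1: correlated / anti-correlated regulators
  tp_map <- unlist(cl_cfg$timepoint_map)
  tf_rows <- intersect(tf_ids, rownames(expr$values))
  tf_expr <- expr_set(expr$values[tf_rows, , drop = FALSE])
  id_map <- setNames(colnames(expr$values), colnames(expr$values))
  tf_calls <- correlate_regulators(tf_expr, irgcs, id_map,
                                   r_cut = cl_cfg$r_cut,
                                   regulator_type = "TF")
  mirna_expr_raw <- read_expression(paths$mirna_expression)
  probe_map <- read.delim(paths$probe_map, stringsAsFactors = FALSE)
  controls <- readLines(paths$control_probesets)
  mirna_expr <- filter_mirna_expression(mirna_expr_raw, probe_map, controls,
                                        alpha = cl_cfg$alpha)
  step_log(1, nrow(mirna_expr$values), " miRNAs pass expression filtering")
  mirna_calls <- correlate_regulators(mirna_expr, irgcs, tp_map,
                                      r_cut = cl_cfg$r_cut,
                                      regulator_type = "miRNA")
  regulator_calls <- rbind(tf_calls, mirna_calls)
  step_log(1, nrow(regulator_calls), " regulator-cluster correlation calls")
  save_tab(regulator_calls, "regulator_calls.tsv")

  ## miRNA TSS prediction (feeds Steps 2, 3 and 7)
  tss_pred <- predict_all_tss(annotation, tracks,
                              chrom_lengths = chrom_lengths,
                              max_upstream = cfg$tss$max_upstream)
  save_tab(tss_pred, "tss_predictions.tsv")
  step_log("tss", nrow(tss_pred), " miRNA TSSs predicted")

  ## TSS tables for promoter windows
  gene_tab <- data.frame(target = annotation$genes$id,
                         chrom = annotation$genes$chrom,
                         tss = annotation$genes$tss,
                         strand = annotation$genes$strand)
  mir_tab <- data.frame(target = tss_pred$mirna, chrom = tss_pred$chrom,
                        tss = tss_pred$tss, strand = tss_pred$strand)

  ## Step 2: ChIP-derived edges
  tg_cfg <- cfg$targets
  chip_edges <- NULL
  chip_tfs <- character(0)
  if (!is.null(paths$peaks) && length(paths$peaks)) {
    for (tf in names(paths$peaks)) {
      peaks <- read_bed(paths$peaks[[tf]])
      e_g <- peaks_to_targets(peaks, gene_tab, tf = tf,
                              upstream = tg_cfg$mrna_upstream,
                              downstream = tg_cfg$mrna_downstream,
                              min_overlap_bp = tg_cfg$min_overlap_bp)
      e_m <- peaks_to_targets(peaks, mir_tab, tf = tf,
                              upstream = tg_cfg$mirna_upstream,
                              downstream = tg_cfg$mirna_downstream,
                              min_overlap_bp = tg_cfg$min_overlap_bp)
      chip_edges <- rbind(chip_edges, e_g, e_m)
      chip_tfs <- c(chip_tfs, tf)
    }
    step_log(2, nrow(chip_edges), " ChIP-derived candidate edges for ",
             length(chip_tfs), " TFs")
    save_tab(chip_edges, "chip_edges.tsv")
  } else {
    step_log(2, "no ChIP peaks supplied; skipping ChIP-derived edges")
  }

  ## Step 3: predicted TF edges (phylogenetically weighted PWM scan)
  pwms <- read_pwms(paths$pwms)
  tf_of <- vapply(pwms, `[[`, "", "tf")
  tree <- ape::read.tree(paths$tree)
  promoters <- promoter_sequences(annotation, tss_pred, genome,
                                  tg_cfg, chrom_lengths)
  tfbs <- cfg$tfbs
  binding <- predict_tf_targets(promoters, pwms, tf_of,
                                alignment = tracks$alignment, tree = tree,
                                reference = tfbs$reference,
                                cutoff = if (identical(tfbs$cutoff,
                                                       "default")) "default"
                                else as.numeric(tfbs$cutoff),
                                n_perm = tfbs$n_perm, seed = seed * 100 + 3,
                                alpha = tfbs$alpha, w_floor = tfbs$w_floor)
  predicted_edges <- binding$edges[, c("tf", "target")]
  step_log(3, nrow(predicted_edges), " predicted TF-target edges")
  save_tab(binding$results, "binding_results.tsv")
  save_tab(binding$edges, "predicted_tf_edges.tsv")

  ## Step 4: consensus miRNA targets
  target_sets <- lapply(paths$target_lists, function(f)
    read.delim(f, stringsAsFactors = FALSE))
  consensus <- consensus_mirna_targets(target_sets,
                                       min_methods = tg_cfg$min_methods)
  step_log(4, nrow(consensus), " consensus miRNA-target pairs")
  save_tab(consensus, "consensus_mirna_targets.tsv")

  ## Steps 5-6: master regulators
  ms <- cfg$master
  gene_universe <- c(annotation$genes$id)
  rtable <- list()
  for (pid in unique(binding$results$pwm)) {
    sc <- binding$results[binding$results$pwm == pid, ]
    sc <- sc[sc$target %in% gene_universe, ]
    rtable[[pid]] <- r_scores(setNames(sc$score, sc$target))
  }
  master_tf_calls <- NULL
  for (nm in names(irgcs)) {
    members <- intersect(irgcs[[nm]]$members, gene_universe)
    if (length(members) < 2) next
    res <- master_tfs(members, rtable, gene_universe,
                      n_random = ms$n_random, seed = seed * 100 + 5,
                      alpha = ms$alpha)
    res$tf <- unname(tf_of[res$regulator])
    res$cluster <- nm
    master_tf_calls <- rbind(master_tf_calls, res)
  }
  if (!is.null(master_tf_calls)) {
    # a TF is a master when any of its PWMs is enriched
    master_tf_calls$regulator <- master_tf_calls$tf
    step_log(5, sum(master_tf_calls$significant),
             " significant master-TF calls")
    save_tab(master_tf_calls, "master_tf_calls.tsv")
  }
  mirna_universe <- intersect(unique(consensus$gene), expressed)
  master_mirna_calls <- NULL
  if (length(mirna_universe)) {
    for (nm in names(irgcs)) {
      members <- intersect(irgcs[[nm]]$members, mirna_universe)
      if (!length(members)) next
      res <- master_mirnas(members, consensus, mirna_universe,
                           alpha = ms$alpha)
      res$cluster <- nm
      master_mirna_calls <- rbind(master_mirna_calls, res)
    }
  }
  if (!is.null(master_mirna_calls)) {
    step_log(6, sum(master_mirna_calls$significant),
             " significant master-miRNA calls")
    save_tab(master_mirna_calls, "master_mirna_calls.tsv")
  }

  ## Step 7 + assembly
  profiles <- expression_profiles(expr, mirna_expr, tp_map)
  net <- build_network(
    irgcs = irgcs, regulator_calls = regulator_calls,
    chip_edges = if (!is.null(chip_edges))
      chip_edges[, c("tf", "target")] else NULL,
    chip_tfs = chip_tfs,
    predicted_tf_edges = predicted_edges,
    mirna_edges = consensus[, c("mirna", "gene")],
    master_tf_calls = master_tf_calls,
    master_mirna_calls = master_mirna_calls,
    profiles = profiles, tf_ids = tf_ids, mirna_ids = mirna_ids,
    keep_isolated = isTRUE(cfg$network$keep_isolated),
    r_threshold = cfg$network$r_threshold)
  step_log(7, nrow(net$nodes), " nodes, ", nrow(net$edges),
           " edges in the final network")
  write_network(net, file.path(out_dir, "network.tsv"), "edge_tsv")
  outputs[["network.tsv"]] <- file.path(out_dir, "network.tsv")
  write_network(net, file.path(out_dir, "network.graphml"), "graphml")
  outputs[["network.graphml"]] <- file.path(out_dir, "network.graphml")

  ffls <- find_ffls(net)
  save_tab(ffls, "ffl_motifs.tsv")
  feedback <- find_feedback_loops(net)
  save_tab(feedback, "feedback_loops.tsv")
  step_log("motifs", nrow(ffls), " feedforward loops, ", nrow(feedback),
           " feedback loops")

  manifest <- data.frame(name = names(outputs), file = unlist(outputs))
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  structure(list(network = net, irgcs = irgcs,
                 regulator_calls = regulator_calls, tss = tss_pred,
                 binding = binding, chip_edges = chip_edges,
                 consensus = consensus, master_tf_calls = master_tf_calls,
                 master_mirna_calls = master_mirna_calls, ffls = ffls,
                 feedback = feedback, manifest = manifest, config = cfg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat("  clusters: ", length(x$irgcs), "\n")
  cat("  regulator calls: ", nrow(x$regulator_calls), "\n")
  cat("  network: ", nrow(x$network$nodes), " nodes, ",
      nrow(x$network$edges), " edges\n")
  cat("  feedforward loops: ", nrow(x$ffls), "\n")
  invisible(x)
}

# promoter search-space sequences: -10 kb/+5 kb around gene TSSs and
# -5 kb/+1 kb around predicted miRNA TSSs, clipped to chromosome bounds
promoter_sequences <- function(annotation, tss_pred, genome, tg_cfg,
                               chrom_lengths) {
  out <- list()
  grab <- function(chrom, start, end) {
    start <- max(0, start); end <- min(chrom_lengths[[chrom]], end)
    as.character(Biostrings::subseq(genome[[chrom]], start + 1, end))
  }
  for (i in seq_len(nrow(annotation$genes))) {
    g <- annotation$genes[i, ]
    w <- promoter_window(g$tss, g$strand, tg_cfg$mrna_upstream,
                         tg_cfg$mrna_downstream)
    st <- max(0, w[1, "start"]); en <- min(chrom_lengths[[g$chrom]],
                                           w[1, "end"])
    out[[g$id]] <- list(seq = grab(g$chrom, st, en), chrom = g$chrom,
                        start = st, strand = g$strand)
  }
  for (i in seq_len(nrow(tss_pred))) {
    m <- tss_pred[i, ]
    w <- promoter_window(m$tss, m$strand, tg_cfg$mirna_upstream,
                         tg_cfg$mirna_downstream)
    st <- max(0, w[1, "start"]); en <- min(chrom_lengths[[m$chrom]],
                                           w[1, "end"])
    out[[m$mirna]] <- list(seq = grab(m$chrom, st, en), chrom = m$chrom,
                           start = st, strand = m$strand)
  }
  out
}

# named profile list for edge signing: gene/TF rows on the mRNA timepoint
# grid; miRNA profiles renamed onto their mapped mRNA timepoints
expression_profiles <- function(expr, mirna_expr, timepoint_map) {
  profiles <- lapply(rownames(expr$values), function(id)
    expr$values[id, ])
  names(profiles) <- rownames(expr$values)
  if (!is.null(mirna_expr) && nrow(mirna_expr$values)) {
    for (id in rownames(mirna_expr$values)) {
      v <- mirna_expr$values[id, names(timepoint_map)]
      names(v) <- unname(timepoint_map)
      profiles[[id]] <- v
    }
  }
  profiles
}
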