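# Synthetic scenario generator with planted ground truth.
#
# Emits a complete, internally consistent toy dataset (annotation, feature
# tracks, alignments, PWMs, tree, genome, peaks, expression, target lists,
# UTRs) whose regulatory structure is known exactly, so every pipeline stage
# can be tested without external resources. The default scenario is sized for
# routine test runs: 2 chromosomes x 1 Mb, 60 genes (8 TFs), 12 miRNAs,
# 5 species, 7 mRNA timepoints.

#' Scenario configuration
#'
#' @param seed integer master seed (all randomness derives from it).
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_genes total genes including TFs.
#' @param n_tfs number of TFs (8: 2 ChIP-backed planted regulators, 1
#'   prediction-backed, 1 master, 4 background).
#' @param n_mirnas number of miRNAs (first 3 are planted regulators: 2
#'   anti-correlated, 1 master; 3 are intragenic).
#' @param n_species species count for the conservation model (first species
#'   is the reference).
#' @param cluster_size genes per planted coexpression cluster (2 clusters:
#'   one myelination-shaped, one proliferation-shaped).
#' @param sigma Gaussian expression noise sd (expression units; planted
#'   profiles have amplitude ~2).
#' @param peak_fnr,peak_fpr ChIP peak false-negative rate (per planted peak)
#'   and false-positive rate (noise peaks as a fraction of planted peaks).
#' @param edge_density scales every planted target-set size (0 plants no
#'   regulation at all).
#' @param sites_per_target conserved PWM sites planted per predicted-edge
#'   target promoter.
#' @param tss_feature_completeness probability that each TSS feature track is
#'   planted in a miRNA's true-TSS window.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1, n_chromosomes = 2, chrom_length = 1e6,
                            n_genes = 60, n_tfs = 8, n_mirnas = 12,
                            n_species = 5, cluster_size = 20, sigma = 0.1,
                            peak_fnr = 0.05, peak_fpr = 0.05,
                            edge_density = 1, sites_per_target = 12,
                            tss_feature_completeness = 1) {
  stopifnot(n_chromosomes >= 1, chrom_length >= 2e5, n_genes >= 52,
            n_tfs >= 8, n_mirnas >= 4, n_species >= 3, cluster_size >= 10,
            sigma >= 0, peak_fnr >= 0, peak_fnr <= 1, peak_fpr >= 0,
            peak_fpr <= 1, edge_density >= 0, sites_per_target >= 1,
            tss_feature_completeness >= 0, tss_feature_completeness <= 1)
  structure(as.list(environment()), class = "scenario_config")
}

MRNA_TIMEPOINTS <- c("d0a", "d0b", "d4", "d7", "d10", "d14", "d21")
PRE_TIMEPOINTS <- c("d0a", "d0b")
POST_TIMEPOINTS <- c("d4", "d7", "d10", "d14", "d21")
MIRNA_TIMEPOINTS <- c("m0", "m4", "m14")
MIRNA_TIMEPOINT_MAP <- c(m0 = "d0a", m4 = "d4", m14 = "d10")
# dip immediately after crush, recovery toward pre-injury level (myelination
# shape); the proliferation shape is its mirror
MGC_SHAPE <- c(1, 1, -1.5, -1.2, -0.8, -0.2, 0.6)

#' Generate a synthetic scenario with planted ground truth
#'
#' Writes every input file the pipeline consumes plus ground-truth TSVs and a
#' manifest into `out_dir`, and returns the paths, the ground truth, and a
#' ready-made pipeline configuration.
#'
#' @param config `scenario_config` object.
#' @param out_dir output directory (created if needed).
#' @return list (paths, truth, pipeline_config, config) of class `scenario`.
#' @export
generate_scenario <- function(config = scenario_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  cs <- config$cluster_size
  dens <- config$edge_density
  scale_n <- function(n) as.integer(round(n * dens))

  ## ---- identifiers -------------------------------------------------------
  n_coding <- config$n_genes - config$n_tfs
  gene_ids <- paste0("g", seq_len(n_coding))
  tf_ids <- paste0("tf", seq_len(config$n_tfs))
  mir_ids <- paste0("mir", seq_len(config$n_mirnas))
  species <- paste0("sp", seq_len(config$n_species))
  reference <- species[1]

  c1_genes <- gene_ids[seq_len(cs)]
  c2_genes <- gene_ids[cs + seq_len(cs)]
  rest <- setdiff(gene_ids, c(c1_genes, c2_genes))
  absent_genes <- tail(rest, 3)
  bg_genes <- setdiff(rest, absent_genes)
  host_genes <- bg_genes[seq_len(min(3, length(bg_genes)))]
  myelin_genes <- c(c1_genes[1], c2_genes[1])

  ## ---- genome layout -----------------------------------------------------
  # entity slots along each chromosome; intergenic miRNAs occupy interior
  # slots so an upstream gene always exists
  all_genes <- c(gene_ids, tf_ids)
  intra_mirs <- mir_ids[seq_len(min(3, length(host_genes)))]
  inter_mirs <- setdiff(mir_ids, intra_mirs)
  n_slots_per_chrom <- ceiling((length(all_genes) + length(inter_mirs)) /
                                 config$n_chromosomes)
  spacing <- floor((config$chrom_length - 40000) / n_slots_per_chrom)
  if (spacing < 18000)
    stop("infeasible config: chromosome too short for the entity count")
  slots <- data.frame(
    chrom = paste0("chr", rep(seq_len(config$n_chromosomes),
                              each = n_slots_per_chrom)),
    pos = 20000 + (rep(seq_len(n_slots_per_chrom),
                       config$n_chromosomes) - 1) * spacing)[
    seq_len(length(all_genes) + length(inter_mirs)), ]
  # interleave: miRNA slots at interior positions (never first/last of chrom)
  slot_in_chrom <- ave(seq_len(nrow(slots)), slots$chrom, FUN = seq_along)
  interior <- which(slot_in_chrom > 1 & slot_in_chrom < n_slots_per_chrom)
  mir_slots <- interior[floor(seq(2, length(interior) - 1,
                                  length.out = length(inter_mirs)))]
  gene_slots <- setdiff(seq_len(nrow(slots)), mir_slots)

  ann <- NULL
  strand_of_slot <- function(i) if (i %% 3 == 0) "-" else "+"
  for (i in seq_along(c(gene_ids, tf_ids))) {
    id <- all_genes[i]
    sl <- gene_slots[i]
    len <- if (id %in% host_genes) 22000 else 3000
    ann <- rbind(ann, data.frame(
      id = id, kind = if (id %in% tf_ids) "tf" else "gene",
      chrom = slots$chrom[sl], start0 = slots$pos[sl],
      end0 = slots$pos[sl] + len, strand = strand_of_slot(sl),
      host_gene = NA_character_))
  }
  for (j in seq_along(inter_mirs)) {
    sl <- mir_slots[j]
    st <- slots$pos[sl] + 12000
    ann <- rbind(ann, data.frame(
      id = inter_mirs[j], kind = "mirna", chrom = slots$chrom[sl],
      start0 = st, end0 = st + 80, strand = strand_of_slot(sl),
      host_gene = NA_character_))
  }
  for (j in seq_along(intra_mirs)) {
    h <- ann[ann$id == host_genes[j], ]
    st <- if (h$strand == "+") h$start0 + 15000 else h$end0 - 15080
    ann <- rbind(ann, data.frame(
      id = intra_mirs[j], kind = "mirna", chrom = h$chrom, start0 = st,
      end0 = st + 80, strand = h$strand, host_gene = h$id))
  }
  ann$tss0 <- ifelse(ann$strand == "+", ann$start0, ann$end0 - 1)

  ## ---- planted miRNA TSSs and feature tracks -----------------------------
  truth_tss <- NULL
  track_rows <- setNames(vector("list", 4),
                         c("transcript_EST", "CpG", "CAGE", "H3K4me3"))
  align_rows <- setNames(vector("list", config$n_species), species)
  for (m in mir_ids) {
    a <- ann[ann$id == m, ]
    win_i <- sample(5:20, 1)
    if (a$strand == "+") {
      w_start <- a$start0 - 100 * win_i
      w_end <- w_start + 100
      tss <- w_start
    } else {
      w_start <- a$end0 + 100 * (win_i - 1)
      w_end <- w_start + 100
      tss <- w_end - 1
    }
    for (feat in names(track_rows)) {
      if (runif(1) <= config$tss_feature_completeness)
        track_rows[[feat]] <- rbind(track_rows[[feat]], data.frame(
          chrom = a$chrom, start = w_start + 10, end = w_end - 40))
    }
    for (sp in species)
      align_rows[[sp]] <- rbind(align_rows[[sp]], data.frame(
        chrom = a$chrom, start = w_start, end = w_end))
    truth_tss <- rbind(truth_tss, data.frame(
      mirna = m, chrom = a$chrom, tss = tss, window_start = w_start,
      window_end = w_end, strand = a$strand))
  }

  ## ---- expression --------------------------------------------------------
  mgc <- MGC_SHAPE
  pgc <- -MGC_SHAPE
  base <- 8; amp <- 2
  profile_of <- list()
  for (g in c1_genes) profile_of[[g]] <- mgc
  for (g in c2_genes) profile_of[[g]] <- pgc
  for (g in c(bg_genes, absent_genes)) profile_of[[g]] <- rep(0, 7)
  profile_of[["tf1"]] <- mgc   # correlated with cluster 1, ChIP-backed
  profile_of[["tf2"]] <- pgc   # correlated with cluster 2, prediction-backed
  profile_of[["tf3"]] <- -mgc  # anti-correlated with cluster 1, ChIP-backed
  for (tf in tf_ids[4:length(tf_ids)]) profile_of[[tf]] <- rep(0, 7)
  expr_mat <- t(vapply(c(gene_ids, tf_ids), function(id)
    base + amp * profile_of[[id]] + rnorm(7, 0, config$sigma),
    numeric(7)))
  colnames(expr_mat) <- MRNA_TIMEPOINTS
  presence <- matrix(TRUE, nrow(expr_mat), ncol(expr_mat),
                     dimnames = dimnames(expr_mat))
  presence[absent_genes, ] <- FALSE

  # miRNA duplicate probesets at 3 injury timepoints; first species of junk:
  # a low-expressed probeset pair below the control mean
  mir_profile <- list(mir1 = -mgc, mir2 = -pgc)
  map_idx <- match(unname(MIRNA_TIMEPOINT_MAP), MRNA_TIMEPOINTS)
  mir_base <- 9; mir_amp <- 1.5
  probe_rows <- list()
  for (m in mir_ids) {
    pr <- if (!is.null(mir_profile[[m]])) mir_profile[[m]][map_idx] else
      rep(0, 3)
    for (d in 1:2)
      probe_rows[[paste0(m, "_p", d)]] <-
        mir_base + mir_amp * pr + rnorm(3, 0, config$sigma)
  }
  for (d in 1:2)
    probe_rows[[paste0("junklow_p", d)]] <- 2 + rnorm(3, 0, config$sigma)
  for (d in 1:4)
    probe_rows[[paste0("ctrl_p", d)]] <- 5 + rnorm(3, 0, config$sigma)
  mir_expr_mat <- do.call(rbind, probe_rows)
  colnames(mir_expr_mat) <- MIRNA_TIMEPOINTS
  probe_map <- data.frame(
    probeset = c(rbind(paste0(c(mir_ids, "junklow"), "_p1"),
                       paste0(c(mir_ids, "junklow"), "_p2"))),
    mirna = rep(c(mir_ids, "junklow"), each = 2))
  control_probesets <- paste0("ctrl_p", 1:4)

  ## ---- planted regulation ------------------------------------------------
  chip_targets <- list(
    tf1 = c(c1_genes[seq_len(scale_n(8))],
            if (dens > 0) "mir1"),
    tf3 = c1_genes[seq_len(scale_n(5))])
  predicted_targets <- list(
    tf1 = c1_genes[seq_len(scale_n(8))],       # sites back the ChIP validation
    tf2 = c(c2_genes[seq_len(scale_n(8))], if (dens > 0) "mir2"),
    tf4 = c1_genes[seq_len(scale_n(20))])
  mir_targets <- list(
    mir1 = c1_genes[seq_len(scale_n(6))],
    mir2 = c2_genes[seq_len(scale_n(5))],
    mir3 = c(c1_genes[seq_len(scale_n(10))],
             bg_genes[3 + seq_len(min(scale_n(2), length(bg_genes) - 3))]))
  if (dens == 0) {
    chip_targets <- list(tf1 = character(0), tf3 = character(0))
    predicted_targets <- list(tf1 = character(0), tf2 = character(0),
                              tf4 = character(0))
    mir_targets <- list(mir1 = character(0), mir2 = character(0),
                        mir3 = character(0))
  }

  ## ---- PWMs and planted binding sites ------------------------------------
  consensus_of <- list()
  taken <- character(0)
  for (tf in tf_ids) {
    repeat {
      cons <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                    collapse = "")
      if (!cons %in% taken) break
    }
    taken <- c(taken, cons)
    consensus_of[[tf]] <- cons
  }
  pwm_list <- list()
  for (tf in tf_ids) {
    counts <- matrix(1L, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
    cons_chars <- strsplit(consensus_of[[tf]], "")[[1]]
    for (j in 1:8) counts[cons_chars[j], j] <- 97L
    pwm_list[[paste0("M_", tf)]] <- list(id = paste0("M_", tf), tf = tf,
                                         counts = counts)
  }
  # second, unplanted matrix for tf2 exercises per-TF Bonferroni
  shuf <- matrix(1L, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons2 <- sample(c("A", "C", "G", "T"), 8, replace = TRUE)
  for (j in 1:8) shuf[cons2[j], j] <- 97L
  pwm_list[["M_tf2b"]] <- list(id = "M_tf2b", tf = "tf2", counts = shuf)

  # site coordinates: `sites_per_target` per (TF, target), spread over the
  # promoter search space, each fully covered by every species' alignment
  site_rows <- NULL
  promoter_window_of <- function(id) {
    a <- ann[ann$id == id, ]
    if (a$kind == "mirna") {
      tss <- truth_tss$tss[truth_tss$mirna == id]
      up <- 4500; down <- 800
    } else {
      tss <- a$tss0
      up <- 9000; down <- 4000
    }
    if (a$strand == "+") c(tss - up, tss + down) else c(tss - down, tss + up)
  }
  for (tf in names(predicted_targets)) {
    stagger <- 60 * match(tf, tf_ids)  # keeps different TFs' sites disjoint
    for (tg in predicted_targets[[tf]]) {
      w <- promoter_window_of(tg)
      at <- floor(seq(w[1] + stagger, w[2] - 300,
                      length.out = config$sites_per_target)) +
        sample(-15:15, config$sites_per_target, replace = TRUE)
      at <- pmin(pmax(at, w[1]), w[2] - 8)
      site_rows <- rbind(site_rows, data.frame(
        tf = tf, target = tg, chrom = ann$chrom[ann$id == tg],
        start = at, end = at + 8))
    }
  }
  if (!is.null(site_rows))
    for (sp in species)
      align_rows[[sp]] <- rbind(align_rows[[sp]], data.frame(
        chrom = site_rows$chrom, start = site_rows$start - 2,
        end = site_rows$end + 2))

  ## ---- genome sequence with planted sites --------------------------------
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  genome <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE))
  names(genome) <- chroms
  if (!is.null(site_rows)) {
    for (i in seq_len(nrow(site_rows))) {
      cons <- strsplit(consensus_of[[site_rows$tf[i]]], "")[[1]]
      genome[[site_rows$chrom[i]]][
        (site_rows$start[i] + 1):(site_rows$end[i])] <- cons
    }
  }
  genome <- vapply(genome, paste, "", collapse = "")

  ## ---- ChIP peaks --------------------------------------------------------
  peak_files <- list()
  for (tf in names(chip_targets)) {
    tgts <- chip_targets[[tf]]
    rows <- NULL
    for (tg in tgts) {
      a <- ann[ann$id == tg, ]
      tss <- if (a$kind == "mirna") truth_tss$tss[truth_tss$mirna == tg] else
        a$tss0
      if (runif(1) < config$peak_fnr) next
      rows <- rbind(rows, data.frame(chrom = a$chrom, start = tss - 150,
                                     end = tss + 50))
    }
    n_noise <- rbinom(1, max(1, length(tgts)), config$peak_fpr)
    if (n_noise > 0 && length(tgts)) {
      ch <- sample(chroms, n_noise, replace = TRUE)
      st <- floor(runif(n_noise, 0, config$chrom_length - 200))
      rows <- rbind(rows, data.frame(chrom = ch, start = st, end = st + 200))
    }
    peak_files[[tf]] <- if (is.null(rows))
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
    else rows
  }

  ## ---- miRNA target lists (3 methods, >=2-of-3 consensus plants) ---------
  methods <- c("methodA", "methodB", "methodC")
  lists <- setNames(lapply(methods, function(m)
    data.frame(mirna = character(0), gene = character(0))), methods)
  planted_pairs <- NULL
  for (m in names(mir_targets)) {
    for (g in mir_targets[[m]]) {
      in_methods <- sample(methods, sample(2:3, 1))
      for (mm in in_methods)
        lists[[mm]] <- rbind(lists[[mm]], data.frame(mirna = m, gene = g))
      planted_pairs <- rbind(planted_pairs, data.frame(mirna = m, gene = g))
    }
  }
  # background miRNAs: true targets among background genes only (>=2 methods)
  bg_mirs <- setdiff(mir_ids, names(mir_targets))
  if (dens > 0) {
    for (m in bg_mirs) {
      for (g in sample(bg_genes, min(6, length(bg_genes)))) {
        in_methods <- sample(methods, sample(2:3, 1))
        for (mm in in_methods)
          lists[[mm]] <- rbind(lists[[mm]], data.frame(mirna = m, gene = g))
        planted_pairs <- rbind(planted_pairs, data.frame(mirna = m, gene = g))
      }
    }
    # decoys appear in exactly one method and must not reach consensus
    for (d in seq_len(20)) {
      m <- sample(mir_ids, 1); g <- sample(gene_ids, 1)
      if (!is.null(planted_pairs) &&
          any(planted_pairs$mirna == m & planted_pairs$gene == g)) next
      mm <- sample(methods, 1)
      lists[[mm]] <- rbind(lists[[mm]], data.frame(mirna = m, gene = g))
    }
  }

  ## ---- UTRs and miRNA sequences ------------------------------------------
  mir_seq <- vapply(mir_ids, function(m)
    paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE), collapse = ""),
    "")
  utr <- vapply(gene_ids, function(g)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = ""),
    "")
  if (!is.null(planted_pairs)) {
    for (i in seq_len(nrow(planted_pairs))) {
      m <- planted_pairs$mirna[i]; g <- planted_pairs$gene[i]
      seed7 <- chartr("U", "T", substr(mir_seq[[m]], 2, 8))
      pad <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seed7)))
      at <- sample(1:(300 - 7), 1)
      substr(utr[[g]], at, at + 6) <- pad
    }
  }

  ## ---- species tree ------------------------------------------------------
  # ladder tree: reference sp1 closest to sp2, sp_n most distant
  tip <- paste0(species[1], ":0.1,", species[2], ":0.1")
  blen <- 0.1
  for (k in 3:config$n_species) {
    blen <- blen + 0.15
    tip <- paste0("(", tip, "):0.15,", species[k], ":", format(blen))
  }
  newick <- paste0("(", tip, ");")

  ## ---- ground truth ------------------------------------------------------
  truth_clusters <- rbind(
    data.frame(gene = c(c1_genes, "tf1"), cluster = "cluster1",
               class = "MGC"),
    data.frame(gene = c(c2_genes, "tf2"), cluster = "cluster2",
               class = "PGC"))
  edge_row <- function(reg, reg_type, tgt, sign, evidence) {
    tgt_type <- ifelse(tgt %in% mir_ids, "miRNA",
                       ifelse(tgt %in% tf_ids, "TF", "mRNA"))
    # planted regulator miRNAs run counter to their TF (anti-correlated), so
    # a TF -> miRNA edge is repressive under the expression-sign rule
    sign <- ifelse(tgt_type == "miRNA" & reg_type == "TF", "-", sign)
    data.frame(regulator = reg, regulator_type = reg_type, target = tgt,
               target_type = tgt_type, sign = sign, evidence = evidence)
  }
  truth_edges <- rbind(
    if (length(chip_targets$tf1))
      edge_row("tf1", "TF", chip_targets$tf1, "+", "chipseq"),
    if (length(chip_targets$tf3))
      edge_row("tf3", "TF", chip_targets$tf3, "-", "chipseq"),
    if (length(predicted_targets$tf2))
      edge_row("tf2", "TF", predicted_targets$tf2, "+", "predicted"),
    if (length(predicted_targets$tf4))
      edge_row("tf4", "TF", predicted_targets$tf4, "+", "predicted"),
    if (length(mir_targets$mir1))
      edge_row("mir1", "miRNA", mir_targets$mir1, "-", "predicted"),
    if (length(mir_targets$mir2))
      edge_row("mir2", "miRNA", mir_targets$mir2, "-", "predicted"),
    if (length(mir_targets$mir3))
      edge_row("mir3", "miRNA",
               intersect(mir_targets$mir3, c(c1_genes, c2_genes)), "-",
               "predicted"))
  if (is.null(truth_edges))
    truth_edges <- data.frame(regulator = character(0),
                              regulator_type = character(0),
                              target = character(0),
                              target_type = character(0),
                              sign = character(0), evidence = character(0))
  # tf1 has ChIP data, so its planted sites only back score validation, and
  # tf2/mir1 mirror-image correlation calls do not change the edge truth
  truth_masters <- if (dens > 0)
    data.frame(regulator = c("tf4", "mir3"), type = c("TF", "miRNA"),
               cluster = "cluster1")
  else
    data.frame(regulator = character(0), type = character(0),
               cluster = character(0))
  truth <- list(clusters = truth_clusters, tss = truth_tss,
                edges = truth_edges, masters = truth_masters,
                chip_targets = chip_targets,
                predicted_targets = predicted_targets,
                myelin_genes = myelin_genes)

  ## ---- write everything --------------------------------------------------
  p <- function(f) file.path(out_dir, f)
  paths <- list()
  ann_out <- data.frame(id = ann$id, kind = ann$kind, chrom = ann$chrom,
                        start = format_coord(ann$start0 + 1),
                        end = format_coord(ann$end0), strand = ann$strand,
                        host_gene = ifelse(is.na(ann$host_gene), ".",
                                           ann$host_gene))
  write.table(ann_out, paths$annotation <- p("annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (feat in names(track_rows)) {
    iv <- track_rows[[feat]]
    if (is.null(iv)) iv <- data.frame(chrom = character(0),
                                      start = numeric(0), end = numeric(0))
    write_bed(genomic_intervals(iv$chrom, iv$start, iv$end)[
      seq_len(nrow(iv)), , drop = FALSE],
      paths[[paste0("track_", feat)]] <- p(paste0("track_", feat, ".bed")))
  }
  for (sp in species)
    write_bed(genomic_intervals(align_rows[[sp]]$chrom,
                                align_rows[[sp]]$start,
                                align_rows[[sp]]$end),
              paths[[paste0("align_", sp)]] <- p(paste0("align_", sp,
                                                        ".bed")))
  write.table(data.frame(mirna = mir_ids,
                         species = paste(species, collapse = ",")),
              paths$conserved_species <- p("conserved_species.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tracks_yaml <- list(
    tracks = setNames(as.list(paste0("track_", names(track_rows), ".bed")),
                      names(track_rows)),
    alignment = setNames(as.list(paste0("align_", species, ".bed")),
                         species),
    conserved_species = "conserved_species.tsv")
  yaml::write_yaml(tracks_yaml, paths$tracks <- p("tracks.yaml"))
  write_pwms_jaspar(pwm_list, paths$pwms <- p("pwms.jaspar"))
  writeLines(newick, paths$tree <- p("tree.nwk"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome),
                              paths$genome <- p("genome.fasta"))
  write_expression(expr_set(expr_mat, presence),
                   paths$expression <- p("expression.tsv"),
                   paths$presence <- p("presence.tsv"))
  write_expression(expr_set(mir_expr_mat),
                   paths$mirna_expression <- p("mirna_expression.tsv"))
  write.table(probe_map, paths$probe_map <- p("probe_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(control_probesets,
             paths$control_probesets <- p("control_probesets.txt"))
  writeLines(myelin_genes, paths$myelin_genes <- p("myelin_genes.txt"))
  for (tf in names(peak_files)) {
    iv <- peak_files[[tf]]
    key <- paste0("peaks_", tf)
    if (nrow(iv))
      write_bed(genomic_intervals(iv$chrom, iv$start, iv$end),
                paths[[key]] <- p(paste0(key, ".bed")))
    else
      writeLines(character(0), paths[[key]] <- p(paste0(key, ".bed")))
  }
  for (mm in methods)
    write.table(lists[[mm]],
                paths[[paste0("targets_", mm)]] <-
                  p(paste0("targets_", mm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(utr),
                              paths$utrs <- p("utrs.fasta"))
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(mir_seq),
                              paths$mirna_seqs <- p("mirna_seqs.fasta"))
  write.table(truth_clusters, paths$truth_clusters <-
                p("ground_truth_clusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truth_tss, paths$truth_tss <- p("ground_truth_tss.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth_edges, paths$truth_edges <- p("ground_truth_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth_masters, paths$truth_masters <-
                p("ground_truth_masters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- data.frame(key = names(paths),
                         file = basename(unlist(paths)))
  write.table(manifest, paths$manifest <- p("manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  pipeline_config <- list(
    seed = config$seed,
    paths = list(
      annotation = paths$annotation, tracks = paths$tracks,
      genome = paths$genome, expression = paths$expression,
      presence = paths$presence,
      mirna_expression = paths$mirna_expression,
      probe_map = paths$probe_map,
      control_probesets = paths$control_probesets,
      myelin_genes = paths$myelin_genes,
      peaks = setNames(
        lapply(names(peak_files), function(tf) paths[[paste0("peaks_", tf)]]),
        names(peak_files)),
      pwms = paths$pwms, tree = paths$tree,
      target_lists = setNames(
        lapply(methods, function(mm) paths[[paste0("targets_", mm)]]),
        methods),
      utrs = paths$utrs, mirna_seqs = paths$mirna_seqs),
    cluster = list(k = 12, alpha = 0.05, merge_r = 0.85, assign_r = 0.8,
                   r_cut = 0.8, pre_timepoints = PRE_TIMEPOINTS,
                   post_timepoints = POST_TIMEPOINTS,
                   timepoint_map = as.list(MIRNA_TIMEPOINT_MAP)),
    tss = list(max_upstream = 100000, window_size = 100),
    tfbs = list(cutoff = "default", n_perm = 999, alpha = 0.005,
                w_floor = 0, reference = reference),
    targets = list(mrna_upstream = 10000, mrna_downstream = 5000,
                   mirna_upstream = 5000, mirna_downstream = 1000,
                   min_methods = 2, min_overlap_bp = 1),
    master = list(n_random = 999, alpha = 0.05),
    network = list(keep_isolated = FALSE, r_threshold = 0.3))

  structure(list(paths = paths, truth = truth,
                 pipeline_config = pipeline_config, config = config),
            class = "scenario")
}

#' Precision/recall of an inferred network against planted truth
#'
#' Edges are matched on the ordered (regulator, target) pair, ignoring sign;
#' sign accuracy is reported among matched edges. Metrics are given per edge
#' type (regulator type -> target type) and overall. An empty inferred edge
#' set has undefined precision (NA).
#'
#' @param network inferred `regnet`.
#' @param truth ground-truth list from [generate_scenario()] (or any list
#'   with an `edges` data.frame).
#' @return data.frame (edge_type, n_true, n_inferred, tp, precision, recall,
#'   sign_accuracy); the last row is "overall".
#' @export
score_recovery <- function(network, truth) {
  te <- truth$edges
  ie <- network$edges
  te_key <- paste(te$regulator, te$target)
  ie_key <- paste(ie$regulator, ie$target)
  etypes <- unique(c(paste(te$regulator_type, "->", te$target_type),
                     paste(ie$regulator_type, "->", ie$target_type)))
  one <- function(tsel, isel, label) {
    tk <- te_key[tsel]; ik <- ie_key[isel]
    tp <- length(intersect(tk, ik))
    matched <- intersect(tk, ik)
    sign_acc <- if (length(matched)) {
      ts <- setNames(te$sign[tsel], tk)[matched]
      is_ <- setNames(ie$sign[isel], ik)[matched]
      mean(ts == is_)
    } else NA_real_
    data.frame(edge_type = label, n_true = length(tk),
               n_inferred = length(ik), tp = tp,
               precision = if (length(ik)) tp / length(ik) else NA_real_,
               recall = if (length(tk)) tp / length(tk) else NA_real_,
               sign_accuracy = sign_acc, stringsAsFactors = FALSE)
  }
  rows <- lapply(sort(etypes), function(et) {
    one(paste(te$regulator_type, "->", te$target_type) == et,
        paste(ie$regulator_type, "->", ie$target_type) == et, et)
  })
  rows[[length(rows) + 1]] <- one(rep(TRUE, nrow(te)), rep(TRUE, nrow(ie)),
                                  "overall")
  do.call(rbind, rows)
}
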