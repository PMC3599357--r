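# Shared fixtures and independent oracles used across the suite.

.fixture_cache <- new.env(parent = emptyenv())

# default synthetic scenario + one pipeline run, generated once per session
scenario_fixture <- function() {
  if (is.null(.fixture_cache$scenario)) {
    dir <- file.path(tempdir(), "tfmirnet-scenario")
    .fixture_cache$scenario <- suppressMessages(
      generate_scenario(scenario_config(seed = 42), dir))
  }
  .fixture_cache$scenario
}

pipeline_fixture <- function() {
  if (is.null(.fixture_cache$pipeline)) {
    sc <- scenario_fixture()
    out <- file.path(tempdir(), "tfmirnet-pipeline")
    .fixture_cache$pipeline <- suppressMessages(suppressWarnings(
      run_pipeline(sc$pipeline_config, out)))
    .fixture_cache$pipeline_out <- out
  }
  .fixture_cache$pipeline
}

write_annotation_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# minimal annotation: one "+" gene, one "-" gene, configurable miRNAs
toy_annotation <- function(extra = NULL) {
  df <- data.frame(
    id = c("gA", "gB"), kind = c("gene", "tf"), chrom = "chr1",
    start = c(101, 501), end = c(200, 700), strand = c("+", "-"),
    host_gene = ".")
  if (!is.null(extra)) df <- rbind(df, extra)
  read_annotation(write_annotation_tsv(df))
}

make_pwm <- function(consensus, strong = 0.97, id = "P1", tf = "T1") {
  bases <- c("A", "C", "G", "T")
  L <- nchar(consensus)
  mat <- matrix(log(((1 - strong) / 3) / 0.25), 4, L,
                dimnames = list(bases, NULL))
  cc <- strsplit(consensus, "")[[1]]
  for (j in seq_len(L)) mat[cc[j], j] <- log(strong / 0.25)
  structure(list(id = id, tf = tf, mat = mat, background = rep(0.25, 4)),
            class = "pwm")
}

# random signed network over TF / miRNA / mRNA nodes
random_signed_network <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  types <- sample(c("TF", "miRNA", "mRNA"), n_nodes, replace = TRUE,
                  prob = c(0.3, 0.3, 0.4))
  ids <- paste0(substr(types, 1, 1), seq_len(n_nodes))
  nodes <- data.frame(id = ids, type = types, role = "target-only",
                      cluster_class = sample(c("MGC", "PGC", "none"),
                                             n_nodes, replace = TRUE))
  pairs <- expand.grid(i = seq_len(n_nodes), j = seq_len(n_nodes))
  pairs <- pairs[pairs$i != pairs$j, ]
  keep <- runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  # miRNA edges must repress
  sign <- ifelse(types[pairs$i] == "miRNA", "-",
                 sample(c("+", "-"), nrow(pairs), replace = TRUE))
  edges <- data.frame(regulator = ids[pairs$i], target = ids[pairs$j],
                      sign = sign, evidence = "predicted", step = 3L)
  regnet(nodes, if (nrow(edges)) edges else NULL)
}

# ---- independent oracles ---------------------------------------------------

# spanning-subtree branch length as union of root-to-tip edge paths
bf_subtree_weight <- function(tree, species) {
  species <- unique(species)
  if (length(species) <= 1) return(0)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- setNames(tree$edge.length, tree$edge[, 2])
  path_edges <- function(tip) {
    node <- which(tree$tip.label == tip)
    out <- integer(0)
    while (node != root) {
      out <- c(out, node)
      node <- parent_of[node]
    }
    out
  }
  paths <- lapply(species, path_edges)
  shared_depth <- Reduce(intersect, paths)  # edges on every path -> above MRCA
  used <- setdiff(unique(unlist(paths)), shared_depth)
  sum(elen[as.character(used)])
}

# exhaustive feedforward-loop enumeration over all node triples
bf_ffls <- function(network) {
  e <- network$edges
  nodes <- network$nodes
  has <- setNames(e$sign, paste(e$regulator, e$target))
  tfs <- nodes$id[nodes$type == "TF"]
  mirs <- nodes$id[nodes$type == "miRNA"]
  gset <- nodes$id[nodes$type != "miRNA"]
  out <- NULL
  for (Tn in tfs) for (Mn in mirs) for (Gn in setdiff(gset, Tn)) {
    s_tm <- has[paste(Tn, Mn)]
    s_mg <- has[paste(Mn, Gn)]
    s_tg <- has[paste(Tn, Gn)]
    if (any(is.na(c(s_tm, s_mg, s_tg)))) next
    indirect <- if (s_tm == s_mg) "+" else "-"
    out <- rbind(out, data.frame(
      tf = Tn, mirna = Mn, target = Gn,
      coherence = if (s_tg == indirect) "coherent" else "incoherent"))
  }
  out
}

pipeline_out_dir <- function() {
  pipeline_fixture()
  .fixture_cache$pipeline_out
}

# exhaustive simple-cycle enumeration up to length 3 via edge joins
bf_cycles <- function(network, max_len = 3) {
  e <- network$edges[, c("regulator", "target", "sign")]
  loop_sign <- function(...) {
    signs <- cbind(...)
    ifelse(rowSums(signs == "-") %% 2 == 0, "+", "-")
  }
  out <- data.frame(nodes = character(0), sign = character(0))
  key <- paste(e$regulator, e$target)
  # 2-cycles: edges whose reverse also exists, rooted at the smaller node
  rev_key <- paste(e$target, e$regulator)
  two <- e[rev_key %in% key & e$regulator < e$target, , drop = FALSE]
  if (nrow(two)) {
    back <- e$sign[match(paste(two$target, two$regulator), key)]
    out <- rbind(out, data.frame(
      nodes = paste(two$regulator, two$target, sep = "->"),
      sign = loop_sign(two$sign, back)))
  }
  if (max_len >= 3) {
    ab <- e; names(ab) <- c("a", "b", "s1")
    bc <- e; names(bc) <- c("b", "c", "s2")
    path <- merge(ab, bc, by = "b")
    path <- path[path$a != path$c, , drop = FALSE]
    if (nrow(path)) {
      s3 <- e$sign[match(paste(path$c, path$a), key)]
      cyc <- path[!is.na(s3) & path$a < path$b & path$a < path$c, ,
                  drop = FALSE]
      s3 <- s3[!is.na(s3) & path$a < path$b & path$a < path$c]
      if (nrow(cyc))
        out <- rbind(out, data.frame(
          nodes = paste(cyc$a, cyc$b, cyc$c, sep = "->"),
          sign = loop_sign(cyc$s1, cyc$s2, s3)))
    }
  }
  out
}

# exhaustive hypergeometric upper tail by subset enumeration
bf_hyper_tail <- function(k, N, K, n) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  subsets <- combn(N, n)
  succ <- colSums(subsets <= K)
  mean(succ >= k)
}

# brute-force TSS prediction: independent tiling, overlap and tie-break logic
bf_predict_tss <- function(range, tracks, mirna, window = 100) {
  width <- range$end - range$start
  if (width <= 0) return(NULL)
  n <- ceiling(width / window)
  best <- NULL
  weights <- c(transcript_EST = 2, CpG = 1, CAGE = 1, H3K4me3 = 1)
  five <- if (range$strand == "+") range$end else range$start
  for (i in seq_len(n)) {
    if (range$strand == "+") {
      en <- range$end - (i - 1) * window
      st <- max(range$start, en - window)
    } else {
      st <- range$start + (i - 1) * window
      en <- min(range$end, st + window)
    }
    sc <- 0
    for (feat in names(weights)) {
      track <- tracks$tracks[[feat]]
      hit <- FALSE
      if (!is.null(track) && nrow(track)) {
        for (r in seq_len(nrow(track)))
          if (track$chrom[r] == range$chrom && track$start[r] < en &&
              track$end[r] > st) { hit <- TRUE; break }
      }
      sc <- sc + if (hit) weights[[feat]] else 0
    }
    n_sp <- 0
    for (sp in names(tracks$alignment)) {
      blocks <- tracks$alignment[[sp]]
      hit <- FALSE
      if (!is.null(blocks) && nrow(blocks)) {
        for (r in seq_len(nrow(blocks)))
          if (blocks$chrom[r] == range$chrom && blocks$start[r] < en &&
              blocks$end[r] > st) { hit <- TRUE; break }
      }
      n_sp <- n_sp + hit
    }
    sc <- sc + n_sp / max(1, length(tracks$conserved_species[[mirna]]))
    cand <- list(start = st, end = en, score = sc,
                 dist = abs((st + en) / 2 - five))
    if (is.null(best) || cand$score > best$score ||
        (cand$score == best$score && cand$dist < best$dist) ||
        (cand$score == best$score && cand$dist == best$dist &&
         cand$start < best$start))
      best <- cand
  }
  tss <- if (range$strand == "+") best$start else best$end - 1
  list(tss = tss, score = best$score)
}

# random TSS locus: annotation with an upstream gene and one miRNA plus
# random feature/alignment tracks over the search range
random_tss_locus <- function(seed) {
  set.seed(seed)
  strand <- sample(c("+", "-"), 1)
  gene_start <- 1000
  gene_end <- gene_start + sample(500:2000, 1)
  gap <- sample(1500:6000, 1)
  if (strand == "+") {
    mir_start <- gene_end + gap
    df <- data.frame(
      id = c("up", "m1"), kind = c("gene", "mirna"), chrom = "chr1",
      start = c(gene_start + 1, mir_start + 1),
      end = c(gene_end, mir_start + 80), strand = strand, host_gene = ".")
  } else {
    mir_start <- 200
    gene_start2 <- mir_start + 80 + gap
    df <- data.frame(
      id = c("up", "m1"), kind = c("gene", "mirna"), chrom = "chr1",
      start = c(gene_start2 + 1, mir_start + 1),
      end = c(gene_start2 + 1000, mir_start + 80), strand = strand,
      host_gene = ".")
  }
  ann <- read_annotation(write_annotation_tsv(df))
  rng <- tss_search_range("m1", ann)
  rand_track <- function(n) {
    if (n == 0)
      return(data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), strand = character(0)))
    st <- sort(sample(seq(rng$start, rng$end - 30), n))
    genomic_intervals("chr1", st, st + sample(10:120, n, replace = TRUE))
  }
  tracks <- feature_tracks(
    tracks = list(transcript_EST = rand_track(sample(0:3, 1)),
                  CpG = rand_track(sample(0:3, 1)),
                  CAGE = rand_track(sample(0:3, 1)),
                  H3K4me3 = rand_track(sample(0:3, 1))),
    alignment = setNames(lapply(1:3, function(i) rand_track(sample(0:2, 1))),
                         paste0("sp", 1:3)),
    conserved_species = list(m1 = paste0("sp", seq_len(sample(1:3, 1)))))
  list(annotation = ann, tracks = tracks, range = rng)
}
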