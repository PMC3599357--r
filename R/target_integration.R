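# TF target derivation from ChIP-Seq peaks, consensus miRNA target lists,
# seed-match statistics and score-vs-ChIP validation.

#' Promoter window of a TSS (transcription-oriented)
#'
#' For a "+"-strand target the window is [tss - upstream, tss + downstream);
#' the "-"-strand window is mirrored. Unstranded TSSs are treated as "+"
#' with a warning.
#'
#' @param tss 0-based TSS position(s).
#' @param strand strand per TSS.
#' @param upstream,downstream window extents in bp (both >= 0).
#' @return matrix with columns start, end (0-based half-open), clipped at 0.
#' @export
promoter_window <- function(tss, strand, upstream, downstream) {
  stopifnot(upstream >= 0, downstream >= 0)
  if (any(strand == "*")) {
    warning("unstranded TSS treated as '+' for promoter arithmetic")
    strand[strand == "*"] <- "+"
  }
  start <- ifelse(strand == "+", tss - upstream, tss - downstream + 1)
  end <- ifelse(strand == "+", tss + downstream, tss + upstream + 1)
  cbind(start = pmax(0, start), end = end)
}

#' Derive TF targets from ChIP-Seq peaks
#'
#' A target is emitted when at least one peak overlaps its
#' transcription-oriented promoter window by `min_overlap_bp`. Default
#' windows: -10 kb/+5 kb for mRNA TSSs, -5 kb/+1 kb for predicted miRNA TSSs.
#'
#' @param peaks interval data.frame of ChIP-Seq peaks for one TF.
#' @param tss_table data.frame with columns target, chrom, tss, strand.
#' @param tf TF id recorded on each edge.
#' @param upstream,downstream promoter window extents (bp).
#' @param min_overlap_bp minimum peak-window overlap (default 1).
#' @return data.frame (tf, target, n_peaks, evidence = "chipseq").
#' @export
peaks_to_targets <- function(peaks, tss_table, tf = NA_character_,
                             upstream = 10000, downstream = 5000,
                             min_overlap_bp = 1) {
  win <- promoter_window(tss_table$tss, tss_table$strand, upstream,
                         downstream)
  n_peaks <- integer(nrow(tss_table))
  if (nrow(peaks)) {
    for (ch in unique(tss_table$chrom)) {
      ti <- which(tss_table$chrom == ch)
      pi <- which(peaks$chrom == ch)
      if (!length(pi)) next
      wr <- IRanges::IRanges(start = win[ti, "start"] + 1,
                             end = win[ti, "end"])
      pr <- IRanges::IRanges(start = peaks$start[pi] + 1,
                             end = peaks$end[pi])
      n_peaks[ti] <- IRanges::countOverlaps(wr, pr,
                                            minoverlap = min_overlap_bp)
    }
  }
  hit <- n_peaks >= 1
  data.frame(tf = rep(tf, sum(hit)), target = tss_table$target[hit],
             n_peaks = n_peaks[hit], evidence = rep("chipseq", sum(hit)),
             stringsAsFactors = FALSE)
}

#' Consensus miRNA target pairs
#'
#' Keeps (miRNA, gene) pairs predicted by at least `min_methods` of the
#' supplied prediction sets; the supporting method labels are recorded. The
#' result does not depend on input order.
#'
#' @param sets named list of data.frames with columns `mirna`, `gene` (one per
#'   prediction method; the study used three).
#' @param min_methods minimum number of supporting methods (default 2).
#' @return data.frame (mirna, gene, n_methods, methods, evidence =
#'   "predicted").
#' @export
consensus_mirna_targets <- function(sets, min_methods = 2) {
  if (min_methods > length(sets))
    stop("min_methods exceeds the number of prediction sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("method", seq_along(sets))
  tagged <- lapply(names(sets), function(nm) {
    s <- unique(sets[[nm]][, c("mirna", "gene")])
    if (nrow(s)) s$method <- nm
    s
  })
  all <- do.call(rbind, tagged)
  if (is.null(all) || !nrow(all))
    return(data.frame(mirna = character(0), gene = character(0),
                      n_methods = integer(0), methods = character(0),
                      evidence = character(0)))
  key <- paste(all$mirna, all$gene, sep = "\r")
  cnt <- table(key)
  keep_keys <- names(cnt)[cnt >= min_methods]
  if (!length(keep_keys))
    return(data.frame(mirna = character(0), gene = character(0),
                      n_methods = integer(0), methods = character(0),
                      evidence = character(0)))
  sup <- vapply(keep_keys, function(k)
    paste(sort(all$method[key == k]), collapse = ","), "")
  parts <- strsplit(keep_keys, "\r", fixed = TRUE)
  out <- data.frame(mirna = vapply(parts, `[[`, "", 1L),
                    gene = vapply(parts, `[[`, "", 2L),
                    n_methods = as.integer(cnt[keep_keys]),
                    methods = unname(sup), evidence = "predicted",
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Fraction of genes with a miRNA seed match in their 3'UTR
#'
#' A gene matches when its 3'UTR contains the reverse complement of at least
#' one miRNA's seed (positions 2-8, a 7-mer, exact match). Genes without a UTR
#' record are skipped with a warning.
#'
#' @param genes gene ids to consider.
#' @param mirnas miRNA ids to take seeds from.
#' @param utrs `DNAStringSet` of 3'UTR sequences named by gene id.
#' @param mirna_seqs `DNAStringSet`/`RNAStringSet` of mature miRNA sequences
#'   named by miRNA id.
#' @return percentage (0-100) of considered genes with >= 1 seed match.
#' @export
seed_match_fraction <- function(genes, mirnas, utrs, mirna_seqs) {
  if (!length(genes)) stop("empty gene set")
  if (!length(mirnas)) return(0)
  have_utr <- genes %in% names(utrs)
  if (any(!have_utr))
    warning(sum(!have_utr), " gene(s) without a UTR record skipped")
  genes <- genes[have_utr]
  if (!length(genes)) stop("no gene with a UTR record")
  seeds <- vapply(mirnas, function(m) {
    s <- as.character(mirna_seqs[[m]])
    s <- chartr("Uu", "Tt", s)
    substr(s, 2, 8)
  }, "")
  pads <- vapply(seeds, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))), "")
  matched <- vapply(genes, function(g) {
    utr <- as.character(utrs[[g]])
    any(vapply(pads, function(p) grepl(p, utr, fixed = TRUE), logical(1)))
  }, logical(1))
  100 * mean(matched)
}

#' Validate binding scores against ChIP-derived targets
#'
#' One-sided Mann-Whitney U test of whether ChIP-identified targets have
#' stochastically greater binding scores than the remaining scored targets.
#'
#' @param scores named numeric vector of binding scores (all scored targets of
#'   one TF).
#' @param chip_targets character vector of ChIP-derived target ids.
#' @return list(p, U, n_chip, n_rest). All-identical scores give p = 1 with a
#'   warning.
#' @export
validate_vs_chipseq <- function(scores, chip_targets) {
  is_chip <- names(scores) %in% chip_targets
  if (!any(is_chip) || all(is_chip))
    stop("need at least one ChIP target and one non-target with scores")
  x <- scores[is_chip]; y <- scores[!is_chip]
  if (length(unique(scores)) == 1) {
    warning("all binding scores identical; p = 1")
    return(list(p = 1, U = length(x) * length(y) / 2,
                n_chip = length(x), n_rest = length(y)))
  }
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "greater"))
  list(p = wt$p.value, U = unname(wt$statistic),
       n_chip = length(x), n_rest = length(y))
}
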