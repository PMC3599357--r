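# Feature-voting prediction of pri-miRNA transcription start sites.
#
# Each 100-bp window of the TSS search range receives
#   score = 2*d_transcript/EST + d_CpG + d_CAGE + d_H3K4me3 + conservation
# where d_feature is 1 when at least one interval of that track overlaps the
# window, and conservation is the number of species aligned over the window
# divided by the number of species in which the pre-miRNA is conserved.

TSS_FEATURES <- c("transcript_EST", "CpG", "CAGE", "H3K4me3")
FEATURE_WEIGHTS <- c(transcript_EST = 2, CpG = 1, CAGE = 1, H3K4me3 = 1)

#' Construct a feature track set
#'
#' @param tracks named list of interval data.frames; names must be a subset of
#'   `transcript_EST`, `CpG`, `CAGE`, `H3K4me3` (missing tracks count as
#'   empty).
#' @param alignment named list (per species id) of alignment-block interval
#'   data.frames.
#' @param conserved_species named list mapping miRNA id to the character
#'   vector of species in which its pre-miRNA is conserved.
#' @return object of class `feature_tracks`.
#' @export
feature_tracks <- function(tracks = list(), alignment = list(),
                           conserved_species = list()) {
  bad <- setdiff(names(tracks), TSS_FEATURES)
  if (length(bad)) stop("unknown feature track(s): ", paste(bad, collapse = ", "))
  structure(list(tracks = tracks, alignment = alignment,
                 conserved_species = conserved_species),
            class = "feature_tracks")
}

#' Read a feature track set from a YAML manifest
#'
#' The manifest maps track names (`transcript_EST`, `CpG`, `CAGE`,
#' `H3K4me3`) to BED paths, species ids to alignment-block BED paths (under
#' key `alignment`), and names a `conserved_species` TSV with columns
#' `mirna`, `species` (comma-separated list). Relative paths are resolved
#' against the manifest's directory.
#'
#' @param path YAML manifest path.
#' @return `feature_tracks` object.
#' @export
read_feature_tracks <- function(path) {
  spec <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  tracks <- lapply(spec$tracks, function(p) read_bed(resolve(p)))
  alignment <- lapply(spec$alignment, function(p) read_bed(resolve(p)))
  conserved <- list()
  if (!is.null(spec$conserved_species)) {
    tab <- read.delim(resolve(spec$conserved_species),
                      stringsAsFactors = FALSE)
    conserved <- setNames(strsplit(tab$species, ",", fixed = TRUE),
                          tab$mirna)
  }
  feature_tracks(tracks, alignment, conserved)
}

# transcription-oriented 5' end of a pre-miRNA (0-based position)
mirna_five_prime <- function(mir_row) {
  if (mir_row$strand == "+") mir_row$start else mir_row$end - 1
}

#' TSS search range of a miRNA
#'
#' Intergenic miRNAs (no same-strand gene spanning the pre-miRNA) are searched
#' from the end of the nearest upstream gene to the 5' end of the pre-miRNA;
#' intragenic miRNAs from the host gene's TSS to the pre-miRNA 5' end. A host
#' gene declared in the annotation takes precedence over spanning-overlap
#' detection; a declared host whose TSS lies downstream of the pre-miRNA 5'
#' end is an annotation inconsistency and errors. With no upstream gene the
#' range is capped at `max_upstream` bp. All arithmetic is strand-oriented.
#'
#' @param mirna miRNA id.
#' @param annotation `genome_annotation` object.
#' @param max_upstream upstream cap (bp) when no upstream gene exists.
#' @return list (mirna, chrom, start, end, strand, category) with a 0-based
#'   half-open range; `start == end` marks an empty range.
#' @export
tss_search_range <- function(mirna, annotation, max_upstream = 100000) {
  mi <- annotation$mirnas[annotation$mirnas$id == mirna, ]
  if (nrow(mi) != 1) stop("unknown miRNA: ", mirna)
  genes <- annotation$genes[annotation$genes$chrom == mi$chrom, ]
  five <- mirna_five_prime(mi)
  host <- if (!is.na(mi$host_gene)) {
    annotation$genes[annotation$genes$id == mi$host_gene, ]
  } else {
    genes[genes$strand == mi$strand & genes$start <= mi$start &
            genes$end >= mi$end, ]
  }
  if (nrow(host)) {
    host <- host[1, ]
    if (mi$strand == "+") {
      if (five < host$tss)
        stop("pre-miRNA 5' end upstream of host TSS for ", mirna)
      rng <- c(host$start, mi$start)
    } else {
      if (five > host$tss)
        stop("pre-miRNA 5' end upstream of host TSS for ", mirna)
      rng <- c(mi$end, host$end)
    }
    category <- "intragenic"
  } else {
    if (mi$strand == "+") {
      up_end <- genes$end[genes$end <= mi$start]
      lo <- if (length(up_end)) max(up_end) else max(0, mi$start - max_upstream)
      rng <- c(lo, mi$start)
    } else {
      up_start <- genes$start[genes$start >= mi$end]
      hi <- if (length(up_start)) min(up_start) else mi$end + max_upstream
      rng <- c(mi$end, hi)
    }
    category <- "intergenic"
  }
  list(mirna = mirna, chrom = mi$chrom, start = rng[1], end = max(rng),
       strand = mi$strand, category = category)
}

#' Conservation ratio of a sequence window
#'
#' Number of species whose alignment blocks overlap the window by at least
#' 1 bp, divided by the number of species in which the pre-miRNA is conserved
#' (floored at 1). The ratio may exceed 1; values above 1 are reported as-is.
#'
#' @param window one-row interval data.frame.
#' @param tracks `feature_tracks` object.
#' @param mirna miRNA id (keys `conserved_species`).
#' @return nonnegative ratio.
#' @export
conservation_score <- function(window, tracks, mirna) {
  n_aligned <- sum(vapply(tracks$alignment, function(blocks)
    any(overlaps_any(window, blocks)), logical(1)))
  denom <- max(1, length(tracks$conserved_species[[mirna]]))
  n_aligned / denom
}

#' Score all windows of a TSS search range
#'
#' Windows tile the range in non-overlapping 100-bp steps anchored at the
#' pre-miRNA-proximal edge and moving away; a final partial window at the
#' distal edge is scored over its actual length.
#'
#' @param range output of [tss_search_range()].
#' @param tracks `feature_tracks` object.
#' @param mirna miRNA id.
#' @param window_size window width in bp (100 in the method).
#' @return data.frame with one row per window: start, end, the four binary
#'   feature indicators, conservation, score, and `dist` (bp from window
#'   midpoint to the pre-miRNA 5' end).
#' @export
score_windows <- function(range, tracks, mirna, window_size = 100) {
  width <- range$end - range$start
  if (width <= 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      delta_transcript_EST = numeric(0), delta_CpG = numeric(0),
                      delta_CAGE = numeric(0), delta_H3K4me3 = numeric(0),
                      conservation = numeric(0), score = numeric(0),
                      dist = numeric(0)))
  n <- ceiling(width / window_size)
  if (range$strand == "+") {
    ends <- range$end - (seq_len(n) - 1) * window_size
    starts <- pmax(range$start, ends - window_size)
  } else {
    starts <- range$start + (seq_len(n) - 1) * window_size
    ends <- pmin(range$end, starts + window_size)
  }
  wins <- genomic_intervals(rep(range$chrom, n), starts, ends)
  deltas <- sapply(TSS_FEATURES, function(feat) {
    track <- tracks$tracks[[feat]]
    if (is.null(track) || !nrow(track)) rep(0, n) else
      as.numeric(overlaps_any(wins, track))
  })
  deltas <- matrix(deltas, nrow = n,
                   dimnames = list(NULL, TSS_FEATURES))
  cons <- vapply(seq_len(n), function(i)
    conservation_score(wins[i, , drop = FALSE], tracks, mirna), numeric(1))
  score <- as.vector(deltas %*% FEATURE_WEIGHTS[TSS_FEATURES]) + cons
  five <- if (range$strand == "+") range$end else range$start
  data.frame(start = starts, end = ends,
             delta_transcript_EST = deltas[, "transcript_EST"],
             delta_CpG = deltas[, "CpG"], delta_CAGE = deltas[, "CAGE"],
             delta_H3K4me3 = deltas[, "H3K4me3"],
             conservation = cons, score = score,
             dist = abs((starts + ends) / 2 - five))
}

#' Predict a miRNA's transcription start site
#'
#' The highest-scoring window wins; ties are broken by minimal distance from
#' the window midpoint to the pre-miRNA 5' end, then by smaller coordinate.
#' The TSS is reported as the winning window's transcription-oriented 5'
#' boundary and the promoter as the -5 kb..+1 kb region around it (clipped at
#' chromosome bounds when known). An empty search range yields a prediction at
#' the pre-miRNA 5' end with score 0 and a warning.
#'
#' @param mirna miRNA id.
#' @param annotation `genome_annotation` object.
#' @param tracks `feature_tracks` object.
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   promoter clipping.
#' @param max_upstream passed to [tss_search_range()].
#' @return one-row data.frame: mirna, category, tss, score, n_tied,
#'   promoter_start, promoter_end, strand.
#' @export
predict_tss <- function(mirna, annotation, tracks, chrom_lengths = NULL,
                        max_upstream = 100000) {
  range <- tss_search_range(mirna, annotation, max_upstream)
  mi <- annotation$mirnas[annotation$mirnas$id == mirna, ]
  ws <- score_windows(range, tracks, mirna)
  if (!nrow(ws)) {
    warning("empty TSS search range for ", mirna,
            ": predicting at the pre-miRNA 5' end")
    tss <- mirna_five_prime(mi)
    score <- 0; n_tied <- 0L
  } else {
    top <- ws[ws$score == max(ws$score), , drop = FALSE]
    n_tied <- nrow(top)
    top <- top[order(top$dist, top$start), , drop = FALSE]
    win <- top[1, ]
    tss <- if (range$strand == "+") win$start else win$end - 1
    score <- win$score
  }
  if (range$strand == "+") {
    prom <- c(tss - 5000, tss + 1000)
  } else {
    prom <- c(tss - 999, tss + 5001)
  }
  prom[1] <- max(0, prom[1])
  if (!is.null(chrom_lengths) && range$chrom %in% names(chrom_lengths))
    prom[2] <- min(prom[2], chrom_lengths[[range$chrom]])
  data.frame(mirna = mirna, category = range$category, chrom = range$chrom,
             tss = tss, score = score, n_tied = n_tied,
             promoter_start = prom[1], promoter_end = prom[2],
             strand = range$strand, stringsAsFactors = FALSE)
}

#' Predict TSSs for every annotated miRNA
#'
#' @inheritParams predict_tss
#' @return data.frame with one row per miRNA (see [predict_tss()]).
#' @export
predict_all_tss <- function(annotation, tracks, chrom_lengths = NULL,
                            max_upstream = 100000) {
  out <- lapply(annotation$mirnas$id, predict_tss, annotation = annotation,
                tracks = tracks, chrom_lengths = chrom_lengths,
                max_upstream = max_upstream)
  do.call(rbind, out)
}

#' Benchmark TSS predictions against validated start sites
#'
#' For user-supplied validated TSSs, reports the fraction of predictions
#' falling within each distance cutoff of the validated position.
#'
#' @param predictions data.frame from [predict_all_tss()].
#' @param validated data.frame with columns `mirna`, `tss` (validated
#'   0-based positions).
#' @param cutoffs distance cutoffs in bp.
#' @return data.frame (cutoff_bp, fraction_within, n).
#' @export
tss_benchmark <- function(predictions, validated,
                          cutoffs = c(500, 2500)) {
  m <- merge(predictions[, c("mirna", "tss")], validated,
             by = "mirna", suffixes = c("_pred", "_true"))
  if (!nrow(m)) stop("no miRNAs shared between predictions and validated set")
  d <- abs(m$tss_pred - m$tss_true)
  data.frame(cutoff_bp = cutoffs,
             fraction_within = vapply(cutoffs, function(cc) mean(d <= cc),
                                      numeric(1)),
             n = nrow(m))
}
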