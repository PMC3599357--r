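test_that("TSS search ranges follow strand-oriented gene context", {
  # "+" intergenic: from the upstream gene's end to the pre-miRNA start
  ann <- read_annotation(write_annotation_tsv(data.frame(
    id = c("up", "m1"), kind = c("gene", "mirna"), chrom = "chr1",
    start = c(20001, 50001), end = c(30000, 50080), strand = "+",
    host_gene = ".")))
  r <- tss_search_range("m1", ann)
  expect_equal(c(r$start, r$end), c(30000, 50000))
  expect_equal(r$category, "intergenic")

  # "+" intragenic: from the host TSS to the pre-miRNA start
  ann <- read_annotation(write_annotation_tsv(data.frame(
    id = c("host", "m1"), kind = c("gene", "mirna"), chrom = "chr1",
    start = c(10001, 18001), end = c(30000, 18080), strand = "+",
    host_gene = c(".", "host"))))
  r <- tss_search_range("m1", ann)
  expect_equal(c(r$start, r$end), c(10000, 18000))
  expect_equal(r$category, "intragenic")

  # "-" intergenic: mirrored, upstream gene at higher coordinates
  ann <- read_annotation(write_annotation_tsv(data.frame(
    id = c("up", "m1"), kind = c("gene", "mirna"), chrom = "chr1",
    start = c(60001, 39921), end = c(70000, 40000), strand = "-",
    host_gene = ".")))
  r <- tss_search_range("m1", ann)
  expect_equal(c(r$start, r$end), c(40000, 60000))

  # no upstream gene: capped at max_upstream
  ann <- read_annotation(write_annotation_tsv(data.frame(
    id = "m1", kind = "mirna", chrom = "chr1", start = 200001,
    end = 200080, strand = "+", host_gene = ".")))
  r <- tss_search_range("m1", ann, max_upstream = 100000)
  expect_equal(c(r$start, r$end), c(100000, 200000))

  # inconsistent annotation: a declared host whose TSS sits downstream of
  # the pre-miRNA 5' end
  ann <- read_annotation(write_annotation_tsv(data.frame(
    id = c("host", "m1"), kind = c("gene", "mirna"), chrom = "chr1",
    start = c(20001, 10001), end = c(30000, 10080), strand = "+",
    host_gene = c(".", "host"))))
  expect_error(tss_search_range("m1", ann), "upstream of host TSS")
})

test_that("conservation is aligned species over conserved species", {
  win <- genomic_intervals("chr1", 1000, 1100)
  mk_align <- function(n_hit, n_total) {
    al <- lapply(seq_len(n_total), function(i)
      if (i <= n_hit) genomic_intervals("chr1", 1050, 1060) else
        genomic_intervals("chr1", 5000, 5100))
    setNames(al, paste0("sp", seq_len(n_total)))
  }
  tr <- feature_tracks(alignment = mk_align(5, 10),
                       conserved_species = list(m = paste0("sp", 1:10)))
  expect_equal(conservation_score(win, tr, "m"), 0.5)
  tr <- feature_tracks(alignment = mk_align(0, 4),
                       conserved_species = list(m = paste0("sp", 1:4)))
  expect_equal(conservation_score(win, tr, "m"), 0)
  # ratio may exceed 1 when more species align than conserve the pre-miRNA
  tr <- feature_tracks(alignment = mk_align(8, 8),
                       conserved_species = list(m = paste0("sp", 1:4)))
  expect_equal(conservation_score(win, tr, "m"), 2)
  # unknown conservation set: denominator floored at 1
  expect_equal(conservation_score(win, tr, "other"), 8)
})

test_that("window scores decompose into weighted feature votes", {
  rng <- list(mirna = "m", chrom = "chr1", start = 0, end = 300,
              strand = "+")
  full <- genomic_intervals("chr1", 210, 290)
  tracks_all <- feature_tracks(
    tracks = list(transcript_EST = full, CpG = full, CAGE = full,
                  H3K4me3 = full),
    alignment = list(sp1 = full),
    conserved_species = list(m = "sp1"))
  ws <- score_windows(rng, tracks_all, "m")
  expect_equal(nrow(ws), 3)           # proximal-anchored tiling, 3 windows
  expect_equal(ws$score[1], 6)        # 2+1+1+1 + conservation 1
  expect_equal(ws$score[2], 0)
  # transcript/EST only with conservation 0.5
  tracks_te <- feature_tracks(
    tracks = list(transcript_EST = full),
    alignment = list(sp1 = full, sp2 = genomic_intervals("chr1", 1, 2)),
    conserved_species = list(m = c("sp1", "sp2")))
  expect_equal(score_windows(rng, tracks_te, "m")$score[1], 2.5)
  # removing a present feature drops the score by exactly its weight
  for (feat in c("transcript_EST", "CpG", "CAGE", "H3K4me3")) {
    reduced <- tracks_all
    reduced$tracks[[feat]] <- NULL
    drop <- ws$score[1] - score_windows(rng, reduced, "m")$score[1]
    expect_equal(drop, if (feat == "transcript_EST") 2 else 1)
  }
})

test_that("tie-break prefers the pre-miRNA-proximal window", {
  ann <- read_annotation(write_annotation_tsv(data.frame(
    id = c("up", "m1"), kind = c("gene", "mirna"), chrom = "chr1",
    start = c(1, 44001), end = c(4000, 44080), strand = "+",
    host_gene = ".")))
  hit <- function(start) genomic_intervals("chr1", start, start + 50)
  # identical feature stacks 200 bp and 5 kb away from the pre-miRNA
  tracks <- feature_tracks(tracks = list(
    CpG = rbind(hit(44000 - 250), hit(44000 - 5050)),
    CAGE = rbind(hit(44000 - 250), hit(44000 - 5050))))
  p <- predict_tss("m1", ann, tracks)
  expect_equal(p$tss, 44000 - 300)
  expect_equal(p$n_tied, 2)
  expect_equal(p$score, 2)
  expect_equal(c(p$promoter_start, p$promoter_end),
               c(p$tss - 5000, p$tss + 1000))
})

test_that("an empty search range predicts at the pre-miRNA 5' end", {
  ann <- read_annotation(write_annotation_tsv(data.frame(
    id = c("host", "m1"), kind = c("gene", "mirna"), chrom = "chr1",
    start = c(10001, 10001), end = c(30000, 10080), strand = "+",
    host_gene = c(".", "host"))))
  expect_warning(p <- predict_tss("m1", ann, feature_tracks()),
                 "empty TSS search range")
  expect_equal(p$tss, 10000)
  expect_equal(p$score, 0)
})

test_that("prediction equals exhaustive argmax with tie-breaks and is
           invariant to track interval order", {
  for (s in 1:25) {
    locus <- random_tss_locus(s)
    p <- predict_tss("m1", locus$annotation, locus$tracks)
    bf <- bf_predict_tss(locus$range, locus$tracks, "m1")
    expect_equal(p$tss, bf$tss, info = paste("locus", s))
    expect_equal(p$score, bf$score, info = paste("locus", s))
    # permute interval order in every track
    shuffled <- locus$tracks
    set.seed(s + 1000)
    shuffled$tracks <- lapply(shuffled$tracks, function(tr)
      tr[sample(nrow(tr)), , drop = FALSE])
    shuffled$alignment <- lapply(shuffled$alignment, function(tr)
      tr[sample(nrow(tr)), , drop = FALSE])
    p2 <- predict_tss("m1", locus$annotation, shuffled)
    expect_equal(p2$tss, p$tss)
  }
})

test_that("the benchmark harness scores distance-to-validated-TSS", {
  preds <- data.frame(mirna = c("m1", "m2"), tss = c(1000, 5000))
  valid <- data.frame(mirna = c("m1", "m2"), tss = c(1400, 8000))
  b <- tss_benchmark(preds, valid, cutoffs = c(500, 2500, 5000))
  expect_equal(b$fraction_within, c(0.5, 0.5, 1))
  expect_error(tss_benchmark(preds, data.frame(mirna = "mX", tss = 1)),
               "no miRNAs shared")
})
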