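test_that("PWM scanning scores log-odds on both strands", {
  # near-deterministic consensus AAAA at 2 bits/position against uniform
  # background: a full match scores 4*log(4) nats (= 8 bits)
  mat <- matrix(log(1e-9 / 0.25), 4, 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  mat["A", ] <- log(4)
  pwm <- structure(list(id = "p", tf = "t", mat = mat,
                        background = rep(0.25, 4)), class = "pwm")
  fwd <- scan_pwm("AAAA", pwm, cutoff = 0)
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$strand, "+")
  expect_equal(fwd$s, 4 * log(4))
  rev <- scan_pwm("TTTT", pwm, cutoff = 0)
  expect_equal(rev$strand, "-")
  expect_equal(rev$s, 4 * log(4))

  expect_error(scan_pwm("AAA", pwm, cutoff = 0), "shorter than the PWM")
  expect_warning(scan_pwm("AANNNN", pwm, cutoff = -1e6), "non-ACGT")
})

test_that("the default cutoff matches exhaustive word enumeration", {
  bases <- c("A", "C", "G", "T")
  words4 <- as.matrix(expand.grid(b1 = 1:4, b2 = 1:4, b3 = 1:4, b4 = 1:4))
  for (s in 1:5) {
    set.seed(s)
    cnt <- matrix(rpois(16, 20) + 1, 4, 4, dimnames = list(bases, NULL))
    prob <- sweep(cnt, 2, colSums(cnt), "/")
    mat <- log(sweep(prob, 1, rep(0.25, 4), "/"))
    pwm <- structure(list(id = "q", tf = "t", mat = mat,
                          background = rep(0.25, 4)), class = "pwm")
    cut <- pwm_default_cutoff(pwm)
    # oracle: discretize per-position scores, enumerate all 4^4 words under
    # the uniform background (each word probability 1/256) and find the
    # smallest achievable score with tail <= 1e-3
    scd <- apply(words4, 1, function(w)
      sum(round(mat[cbind(w, 1:4)] / 0.01)) * 0.01)
    cand <- sort(unique(scd))
    tail_ok <- vapply(cand, function(c0) mean(scd >= c0 - 1e-9) <= 1e-3,
                      logical(1))
    if (any(tail_ok)) {
      expect_equal(cut, min(cand[tail_ok]), tolerance = 1e-8)
    } else {
      # max-score words occur with probability (1/4)^4 = 0.0039 > 1e-3, so
      # no hit may be retained: the cutoff must exceed every achievable score
      expect_gt(cut, max(scd))
    }
  }
})

test_that("subtree weights equal the spanning-subtree branch length", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(subtree_weight(tree, c("A", "B")), 2)
  expect_equal(subtree_weight(tree, c("A", "C")), 4)
  expect_equal(subtree_weight(tree, "A"), 0)
  expect_error(subtree_weight(tree, c("A", "Z")), "unknown species")

  # brute-force union of root paths on random trees; invariance to leaf
  # rotations; monotone under set inclusion
  for (s in 1:10) {
    set.seed(s)
    tr <- ape::rtree(8)
    tips <- sample(tr$tip.label, sample(2:6, 1))
    expect_equal(subtree_weight(tr, tips), bf_subtree_weight(tr, tips))
    rot <- ape::rotate(tr, sample(9:15, 1))
    expect_equal(subtree_weight(rot, tips), subtree_weight(tr, tips))
    larger <- union(tips, sample(tr$tip.label, 1))
    expect_gte(subtree_weight(tr, larger), subtree_weight(tr, tips))
  }
})

test_that("binding scores follow the weighted-exponential closed form", {
  site <- function(w, s) data.frame(w = w, s = s)
  expect_equal(binding_score(site(1, 0)), 1)
  expect_equal(binding_score(site(c(1, 2), c(0, log(2)))), 5)
  expect_equal(binding_score(site(numeric(0), numeric(0))), 0)
  # monotone in sites; linear in w
  for (s in 1:20) {
    set.seed(s)
    n <- sample(1:50, 1)
    sites <- data.frame(w = runif(n, 0.01, 3), s = rnorm(n))
    b <- binding_score(sites)
    expect_gt(binding_score(rbind(sites, site(0.5, 0))), b)
    doubled <- sites; doubled$w <- 2 * doubled$w
    expect_equal(binding_score(doubled), 2 * b)
  }
})

test_that("site conservation weighting uses full block coverage", {
  tree <- ape::read.tree(text = "((ref:1,B:1):1,C:2);")
  sites <- data.frame(pwm = "p", target = "g", chrom = "chr1",
                      start = c(100, 200), end = c(108, 208),
                      strand = "+", s = c(1, 1))
  alignment <- list(
    B = genomic_intervals("chr1", 95, 120),    # covers site 1 only
    C = genomic_intervals("chr1", 203, 220))   # partial overlap of site 2
  ws <- weight_sites(sites, alignment, tree, reference = "ref")
  expect_equal(ws$w[1], subtree_weight(tree, c("ref", "B")))
  expect_equal(ws$w[2], 0)  # reference-only: default floor 0
  ws2 <- weight_sites(sites, alignment, tree, reference = "ref",
                      w_floor = 0.25)
  expect_equal(ws2$w[2], 0.25)
})

test_that("permutation p-values respect their estimator bounds", {
  lens <- setNames(rep(1000, 10), paste0("g", 1:10))
  # all sites concentrated on one target
  sites <- data.frame(target = "g1", w = 1, s = rep(1, 12))
  pv <- binding_pvalues(sites, lens, n_perm = 199, seed = 1)
  expect_gte(min(pv$raw_p), 1 / 200)
  expect_lt(pv$raw_p[pv$target == "g1"], 0.05)
  expect_equal(pv$raw_p[pv$target == "g2"], 1)  # observed 0: every null >= 0
  # empty site pool: p = 1 everywhere
  pv0 <- binding_pvalues(sites[0, ], lens, n_perm = 199, seed = 1)
  expect_true(all(pv0$raw_p == 1))
  expect_error(binding_pvalues(sites, lens, n_perm = 10), "at least 99")
})

test_that("Bonferroni target calls use the per-TF matrix count", {
  res <- data.frame(
    tf = c("T1", "T1", "T1", "T2", "T2", "T2"),
    pwm = c("a", "b", "c", "d", "d", "d"),
    target = c("g1", "g1", "g1", "g1", "g2", "g3"),
    n_sites = 1, score = 1,
    raw_p = c(0.001, 0.5, 0.9, 0.002, 0.5, 1))
  out <- tf_targets(res, alpha = 0.005)
  # T1 has 3 PWMs: 0.001 * 3 = 0.003 <= 0.005 -> target
  expect_equal(out$results$adjusted_p[1], 0.003)
  expect_true("g1" %in% out$edges$target[out$edges$tf == "T1"])
  # T2 has 1 PWM: 0.002 stays 0.002 -> target; 0.5 and 1 capped at 1
  expect_equal(out$results$adjusted_p[res$tf == "T2" & res$raw_p == 0.5],
               0.5)
  expect_true(all(out$results$adjusted_p <= 1))
  res3 <- data.frame(tf = "T3", pwm = paste0("m", 1:3),
                     target = "g1", n_sites = 1, score = 1, raw_p = 0.002)
  out3 <- tf_targets(res3, alpha = 0.005)
  expect_false(any(out3$results$is_target))  # 0.002 * 3 = 0.006 > 0.005
  res5 <- data.frame(tf = "T", pwm = paste0("m", 1:5), target = "g",
                     n_sites = 1, score = 1, raw_p = 0.5)
  expect_equal(unique(tf_targets(res5)$results$adjusted_p), 1)
})
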