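mk_clusters <- function() {
  structure(list(
    IRGC1 = list(members = c("g1", "g2"), centroid = c(a = 1, b = -1, c = 0),
                 cluster_class = "MGC"),
    IRGC2 = list(members = c("g3"), centroid = c(a = -1, b = 1, c = 0),
                 cluster_class = "PGC")), class = "gene_clusters")
}

test_that("edge signs follow miRNA repression and expression correlation", {
  profs <- list(t1 = c(a = 1, b = 2, c = 3), g1 = c(a = 2, b = 4, c = 6),
                g2 = c(a = 3, b = 2, c = 1))
  expect_equal(edge_sign("m1", "g1", profs, mirna_ids = "m1")$sign, "-")
  s <- edge_sign("t1", "g1", profs)
  expect_equal(s$sign, "+"); expect_false(s$low_confidence)
  s2 <- edge_sign("t1", "g2", profs)
  expect_equal(s2$sign, "-"); expect_false(s2$low_confidence)
  s3 <- edge_sign("t1", "gX", profs)
  expect_true(s3$low_confidence)
})

test_that("network assembly applies evidence precedence and provenance", {
  cl <- mk_clusters()
  calls <- data.frame(regulator = c("t1", "m1"),
                      regulator_type = c("TF", "miRNA"),
                      cluster = "IRGC1",
                      relation = c("correlated", "anti-correlated"),
                      r = c(0.95, -0.9))
  chip <- data.frame(tf = "t1", target = c("g1", "m1"))
  pred <- data.frame(tf = c("t1", "t2"), target = c("g1", "g2"))
  mir <- data.frame(mirna = "m1", gene = c("g1", "g2"))
  net <- suppressMessages(build_network(
    cl, calls, chip_edges = chip, chip_tfs = "t1",
    predicted_tf_edges = pred, mirna_edges = mir,
    tf_ids = c("t1", "t2"), mirna_ids = "m1"))
  e <- net$edges
  # t1 -> g1 supported by both: single edge with chipseq evidence
  tg <- e[e$regulator == "t1" & e$target == "g1", ]
  expect_equal(nrow(tg), 1)
  expect_equal(tg$evidence, "chipseq")
  expect_equal(tg$step, 2L)
  # t2 has no ChIP data but is not a node: its predicted edge is dropped
  expect_false("t2" %in% e$regulator)
  # provenance steps restricted to the realized workflow
  expect_true(all(e$step %in% c(2L, 3L, 4L, 7L)))
  # miRNA edges repress
  expect_true(all(e$sign[e$regulator == "m1"] == "-"))
})

test_that("isolated nodes are pruned unless kept and masters join at 7", {
  cl <- mk_clusters()
  empty <- suppressMessages(build_network(cl, NULL))
  expect_equal(nrow(empty$nodes), 0)
  kept <- suppressMessages(build_network(cl, NULL, keep_isolated = TRUE))
  expect_setequal(kept$nodes$id, c("g1", "g2", "g3"))
  expect_equal(nrow(kept$edges), 0)

  masters <- data.frame(regulator = "t9", significant = TRUE)
  chip <- data.frame(tf = "t9", target = c("g1", "g3"))
  net <- suppressMessages(build_network(
    cl, NULL, chip_edges = chip, chip_tfs = "t9",
    master_tf_calls = masters, tf_ids = "t9"))
  expect_true("t9" %in% net$nodes$id)
  expect_equal(net$nodes$role[net$nodes$id == "t9"], "master")
  # every step-7 edge touches the new master
  s7 <- net$edges[net$edges$step == 7L, ]
  expect_gt(nrow(s7), 0)
  expect_true(all(s7$regulator == "t9" | s7$target == "t9"))
  expect_error(build_network(cl, NULL, tf_ids = "x", mirna_ids = "x"),
               "both TF and miRNA")
})

test_that("rebuilding from emitted edge lists reproduces the network", {
  cl <- mk_clusters()
  calls <- data.frame(regulator = "t1", regulator_type = "TF",
                      cluster = "IRGC1", relation = "correlated", r = 0.9)
  chip <- data.frame(tf = "t1", target = c("g1", "g2"))
  net <- suppressMessages(build_network(cl, calls, chip_edges = chip,
                                        chip_tfs = "t1", tf_ids = "t1"))
  net2 <- suppressMessages(build_network(
    cl, calls,
    chip_edges = net$edges[net$edges$evidence == "chipseq",
                           c("regulator", "target")],
    chip_tfs = "t1", tf_ids = "t1"))
  expect_equal(net2$edges[, c("regulator", "target", "sign", "evidence")],
               net$edges[, c("regulator", "target", "sign", "evidence")])
})

test_that("ego subnetworks keep neighbors and the edges among them", {
  nodes <- data.frame(id = c("a", "f", "b", "z"),
                      type = c("TF", "TF", "mRNA", "mRNA"),
                      role = "target-only", cluster_class = "none")
  edges <- data.frame(regulator = c("a", "f", "a"),
                      target = c("f", "b", "b"),
                      sign = "+", evidence = "predicted", step = 3L)
  net <- regnet(nodes, edges)
  ego <- ego_subnetwork(net, "f")
  expect_setequal(ego$nodes$id, c("a", "f", "b"))
  expect_equal(nrow(ego$edges), 3)   # a->b is "among them"
  # idempotent
  ego2 <- ego_subnetwork(ego, "f")
  expect_equal(ego2$edges, ego$edges)
  # isolated focal node
  iso <- regnet(nodes, edges)
  expect_equal(nrow(ego_subnetwork(iso, "z")$edges), 0)
  expect_error(ego_subnetwork(net, "nope"), "unknown node")
})

test_that("feedforward loops classify coherence by sign algebra", {
  nodes <- data.frame(id = c("T", "M", "G1", "G2"),
                      type = c("TF", "miRNA", "mRNA", "mRNA"),
                      role = "target-only",
                      cluster_class = c("none", "none", "MGC", "PGC"))
  edges <- data.frame(
    regulator = c("T", "T", "M", "M"),
    target = c("G1", "M", "G1", "G2"),
    sign = c("+", "-", "-", "-"),
    evidence = "predicted", step = 3L)
  net <- regnet(nodes, edges)
  ff <- find_ffls(net)
  # T activates G1, represses M; M represses G1: (-)(-) = + = direct
  expect_equal(nrow(ff), 1)
  expect_equal(ff$coherence, "coherent")
  expect_equal(ff$category, "C1")
  # flip the direct edge: incoherent, and PGC targets map to I2/C2
  edges2 <- rbind(edges,
                  data.frame(regulator = "T", target = "G2", sign = "+",
                             evidence = "predicted", step = 3L))
  edges2$sign[edges2$target == "M"] <- "+"
  ff2 <- find_ffls(regnet(nodes, edges2))
  expect_setequal(ff2$coherence, "incoherent")
  expect_setequal(ff2$category, c("I1", "I2"))
  # unclassified targets are excluded but counted
  nodes3 <- nodes; nodes3$cluster_class[3] <- "none"
  ff3 <- find_ffls(regnet(nodes3, edges))
  expect_equal(nrow(ff3), 0)
  expect_equal(attr(ff3, "n_unclassified"), 1)
})

test_that("feedforward enumeration equals the exhaustive triple oracle", {
  for (s in 1:12) {
    net <- random_signed_network(sample(15:40, 1), 0.06, seed = s)
    found <- find_ffls(net)
    oracle <- bf_ffls(net)
    key <- function(df) if (is.null(df) || !nrow(df)) character(0) else
      sort(paste(df$tf, df$mirna, df$target, df$coherence))
    # compare on classified + unclassified alike: rebuild without class
    all_found <- nrow(found) + attr(found, "n_unclassified")
    expect_equal(all_found, if (is.null(oracle)) 0 else nrow(oracle),
                 info = paste("seed", s))
    if (nrow(found)) {
      ok <- merge(found, oracle, by = c("tf", "mirna", "target"))
      expect_equal(ok$coherence.x, ok$coherence.y)
    }
  }
})

test_that("feedback loops are canonical simple cycles with sign products", {
  nodes <- data.frame(id = c("A", "B", "C"), type = "TF",
                      role = "target-only", cluster_class = "none")
  e2 <- data.frame(regulator = c("A", "B"), target = c("B", "A"),
                   sign = c("+", "-"), evidence = "predicted", step = 3L)
  fb <- find_feedback_loops(regnet(nodes, e2))
  expect_equal(nrow(fb), 1)
  expect_equal(fb$sign, "-")
  expect_equal(fb$nodes, "A->B")
  e3 <- data.frame(regulator = c("A", "B", "C"), target = c("B", "C", "A"),
                   sign = c("+", "-", "-"), evidence = "predicted",
                   step = 3L)
  fb3 <- find_feedback_loops(regnet(nodes, e3))
  expect_equal(fb3$sign, "+")
  acyclic <- data.frame(regulator = c("A", "A"), target = c("B", "C"),
                        sign = "+", evidence = "predicted", step = 3L)
  expect_equal(nrow(find_feedback_loops(regnet(nodes, acyclic))), 0)
  expect_error(find_feedback_loops(regnet(nodes, e3), max_len = 1), ">= 2")
})

test_that("cycle enumeration equals the exhaustive oracle", {
  for (s in 1:12) {
    net <- random_signed_network(sample(10:25, 1), 0.12, seed = 100 + s)
    found <- find_feedback_loops(net, max_len = 3)
    oracle <- bf_cycles(net, max_len = 3)
    expect_setequal(paste(found$nodes, found$sign),
                    paste(oracle$nodes, oracle$sign))
  }
})

test_that("motif bias uses distinct targets and Fisher's exact test", {
  mk <- function(co, cl, tg) data.frame(
    tf = "T", mirna = "M", target = tg, sign_direct = "+", sign_tm = "-",
    sign_mg = "-", coherence = co, target_class = cl,
    category = paste0(ifelse(co == "incoherent", "I", "C"),
                      ifelse(cl == "myelination", "1", "2")))
  motifs <- rbind(
    mk("incoherent", "myelination", paste0("g", 1:5)),
    mk("coherent", "proliferation", paste0("h", 1:5)))
  out <- motif_bias_test(motifs)
  expect_equal(unname(out$table["incoherent", "myelination"]), 5)
  expect_equal(out$p, fisher.test(matrix(c(5, 0, 0, 5), 2))$p.value)
  expect_equal(out$p, 0.00793650793650794)
  expect_equal(sum(out$table), length(unique(motifs$target)))
  # one gene in many loops counts once per cell
  dup <- rbind(motifs, mk("incoherent", "myelination", "g1"))
  expect_equal(unname(motif_bias_test(dup)$table[1, 1]), 5)
  expect_equal(unname(motif_bias_test(dup)$motif_table[1, 1]), 6)
  flat <- rbind(mk("incoherent", "myelination", "a"),
                mk("incoherent", "proliferation", "b"),
                mk("coherent", "myelination", "c"),
                mk("coherent", "proliferation", "d"))
  expect_equal(motif_bias_test(flat)$p, 1)
  expect_warning(motif_bias_test(motifs[1:5, ]), "degenerate")
  expect_error(motif_bias_test(motifs[0, ]), "no motifs")
})
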