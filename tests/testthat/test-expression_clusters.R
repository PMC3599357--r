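tp <- c("d0a", "d0b", "d4", "d7", "d10", "d14", "d21")
pre <- c("d0a", "d0b"); post <- setdiff(tp, pre)
mgc <- c(1, 1, -1.5, -1.2, -0.8, -0.2, 0.6)

planted_expr <- function(n_per = 10, n_flat = 5, sigma = 0) {
  set.seed(99)
  shapes <- rbind(mgc, -mgc)
  rows <- list()
  for (i in 1:n_per) rows[[paste0("a", i)]] <- 8 + 2 * shapes[1, ] +
      rnorm(7, 0, sigma)
  for (i in 1:n_per) rows[[paste0("b", i)]] <- 8 + 2 * shapes[2, ] +
      rnorm(7, 0, sigma)
  for (i in 1:n_flat) rows[[paste0("f", i)]] <- 8 + rnorm(7, 0, sigma)
  m <- do.call(rbind, rows)
  colnames(m) <- tp
  expr_set(m)
}

test_that("expression calls require one positive presence call", {
  vals <- matrix(1, 3, 7, dimnames = list(c("g1", "g2", "g3"), tp))
  pres <- matrix(FALSE, 3, 7, dimnames = dimnames(vals))
  pres["g1", 3] <- TRUE
  expect_equal(call_expressed(expr_set(vals, pres)), "g1")
  pres["g1", 3] <- FALSE
  expect_length(call_expressed(expr_set(vals, pres)), 0)
})

test_that("noise-free planted clusters are recovered exactly", {
  expr <- planted_expr(sigma = 0)
  cl <- suppressMessages(
    find_irgcs(expr, k = 8, myelin_genes = c("a1", "b1"),
               pre_timepoints = pre, post_timepoints = post, seed = 5))
  expect_length(cl, 2)
  members <- lapply(cl, `[[`, "members")
  expect_setequal(members[[which(vapply(cl, `[[`, "", "cluster_class") ==
                                   "MGC")]], paste0("a", 1:10))
  expect_setequal(members[[which(vapply(cl, `[[`, "", "cluster_class") ==
                                   "PGC")]], paste0("b", 1:10))
  # deterministic under a fixed seed
  cl2 <- suppressMessages(
    find_irgcs(expr, k = 8, myelin_genes = c("a1", "b1"),
               pre_timepoints = pre, post_timepoints = post, seed = 5))
  expect_identical(cl, cl2)
  # memberships are disjoint
  expect_equal(anyDuplicated(unlist(members)), 0)
})

test_that("final membership follows the best-correlated centroid", {
  expr <- planted_expr(sigma = 0.05)
  cl <- suppressMessages(
    find_irgcs(expr, k = 6, myelin_genes = c("a1", "b1"),
               pre_timepoints = pre, post_timepoints = post, seed = 1))
  # a gene identical to a centroid joins it (r = 1 >= 0.8); flat genes
  # correlate with nothing and stay unassigned
  flat <- paste0("f", 1:5)
  expect_length(intersect(unlist(lapply(cl, `[[`, "members")), flat), 0)
})

test_that("clusters without myelin genes or pre/post change are dropped", {
  expr <- planted_expr(sigma = 0)
  expect_warning(
    cl <- suppressMessages(
      find_irgcs(expr, k = 8, myelin_genes = "not-there",
                 pre_timepoints = pre, post_timepoints = post, seed = 1)),
    "no cluster")
  expect_length(cl, 0)
  expect_error(find_irgcs(expr, k = 1000, myelin_genes = "a1",
                          pre_timepoints = pre, post_timepoints = post),
               "k exceeds")
})

test_that("duplicate-probeset filtering follows the stated rules", {
  tps <- paste0("t", 1:6)
  rows <- rbind(
    ok_p1 = c(9, 9, 9, 9, 9, 9), ok_p2 = c(9, 9, 9, 9, 9, 9),
    low_p1 = rep(2, 6), low_p2 = rep(2.2, 6),
    dis_p1 = c(10, 11, 12, 13, 14, 15),        # always above its duplicate
    dis_p2 = c(4, 5, 6, 7, 8, 9),
    ctrl_p1 = rep(5, 6), ctrl_p2 = rep(5, 6))
  colnames(rows) <- tps
  pm <- data.frame(probeset = c("ok_p1", "ok_p2", "low_p1", "low_p2",
                                "dis_p1", "dis_p2"),
                   mirna = rep(c("ok", "low", "dis"), each = 2))
  out <- filter_mirna_expression(expr_set(rows), pm, c("ctrl_p1", "ctrl_p2"))
  # identical duplicates survive and equal either duplicate
  expect_equal(rownames(out$values), "ok")
  expect_equal(unname(out$values["ok", ]), rep(9, 6))
  # complete separation at 6 timepoints: one-sided exact U p = 1/C(12,6)
  expect_equal(wilcox.test(rows["dis_p1", ], rows["dis_p2", ],
                           alternative = "greater")$p.value,
               1 / choose(12, 6))
  # surviving values are duplicate means, row by row
  rows2 <- rows; rows2["ok_p2", ] <- rows["ok_p1", ] + c(1, -1, 2, -2, 0, 1)
  out2 <- filter_mirna_expression(expr_set(rows2), pm,
                                  c("ctrl_p1", "ctrl_p2"))
  expect_equal(out2$values["ok", ],
               (rows2["ok_p1", ] + rows2["ok_p2", ]) / 2)
  # wrong probeset multiplicity errors
  pm_bad <- rbind(pm, data.frame(probeset = "ok_p1", mirna = "ok"))
  expect_error(filter_mirna_expression(expr_set(rows), pm_bad,
                                       c("ctrl_p1", "ctrl_p2")),
               "expected 2")
})

test_that("regulator correlation calls respect the cutoff and degeneracy", {
  expr <- planted_expr(sigma = 0)
  cl <- suppressMessages(
    find_irgcs(expr, k = 6, myelin_genes = c("a1", "b1"),
               pre_timepoints = pre, post_timepoints = post, seed = 1))
  cen <- cl[[1]]$centroid
  cand <- rbind(same = cen, anti = -cen + 2, flat = rep(3, 7))
  colnames(cand) <- tp
  map <- setNames(tp, tp)
  calls <- suppressMessages(
    correlate_regulators(expr_set(cand), cl[1], map, r_cut = 0.8,
                         regulator_type = "TF"))
  expect_equal(calls$relation[calls$regulator == "same"], "correlated")
  expect_equal(calls$r[calls$regulator == "same"], 1)
  expect_equal(calls$relation[calls$regulator == "anti"], "anti-correlated")
  expect_false("flat" %in% calls$regulator)  # zero variance: no call
  expect_error(correlate_regulators(expr_set(cand), cl[1], map[1:2]),
               "fewer than 3")
})
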