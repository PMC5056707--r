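test_that("misassignment graph weights follow the symmetric rate", {
  u <- c("A", "B", "C")
  diag_tab <- diag(c(10, 8, 6)); dimnames(diag_tab) <- list(u, u)
  w <- misassignment_graph(diag_tab, diag_tab)
  expect_true(all(w == 0))

  t1 <- matrix(c(6, 4, 0,
                 3, 7, 0,
                 0, 0, 9), 3, 3, byrow = TRUE, dimnames = list(u, u))
  t2 <- matrix(c(8, 2, 0,
                 1, 9, 0,
                 0, 1, 8), 3, 3, byrow = TRUE, dimnames = list(u, u))
  w2 <- misassignment_graph(t1, t2)
  # independent recount of the A-B edge
  m1 <- (t1["A", "B"] + t1["B", "A"]) / (sum(t1["A", ]) + sum(t1["B", ]))
  m2 <- (t2["A", "B"] + t2["B", "A"]) / (sum(t2["A", ]) + sum(t2["B", ]))
  expect_equal(w2["A", "B"], (m1 + m2) / 2, tolerance = 1e-12)
  expect_equal(w2, t(w2))
  # units exchanging errors exclusively with each other carry the max edge
  expect_equal(which.max(w2[upper.tri(w2)]), 1L)
  bad <- diag_tab; rownames(bad) <- c("A", "B", "X")
  expect_error(misassignment_graph(bad, diag_tab), "partition")
})

test_that("merge_step applies the dual-threshold rules in order", {
  u <- c("R1", "R2", "R3")
  w <- matrix(0, 3, 3, dimnames = list(u, u))
  w["R2", "R3"] <- w["R3", "R2"] <- 0.3
  cl <- c(R1 = 1, R2 = 2, R3 = 2)
  adj <- data.frame(unit1 = "R2", unit2 = "R3")
  res <- merge_step(c(R1 = 0.95, R2 = 0.60, R3 = 0.62),
                    c(R1 = 0.92, R2 = 0.55, R3 = 0.58),
                    w, cl, adj)
  expect_equal(unname(res$partition),
               c("R1", "R2+R3", "R2+R3"))
  expect_equal(res$ledger$decision, c("keep", "merge", "merge"))

  # all above threshold: fixed point
  res2 <- merge_step(c(R1 = 0.9, R2 = 0.85, R3 = 0.81),
                     c(R1 = 0.9, R2 = 0.85, R3 = 0.81), w, cl, adj)
  expect_equal(unname(res2$partition), u)
  expect_true(all(res2$ledger$decision == "keep"))
})

test_that("case-by-case margin keeps near-threshold units", {
  u <- c("R1", "R2")
  w <- matrix(0, 2, 2, dimnames = list(u, u))
  cl <- c(R1 = 1, R2 = 1)
  # one method 0.95, the other 0.79 (>= 0.75): kept case-by-case
  res <- merge_step(c(R1 = 0.95, R2 = 1.00), c(R1 = 0.93, R2 = 0.794),
                    w, cl)
  expect_equal(res$ledger$decision[2], "case_by_case_keep")
  expect_equal(unname(res$partition), u)
  # failing estimate far below the margin: merged
  res2 <- merge_step(c(R1 = 0.95, R2 = 1.00), c(R1 = 0.93, R2 = 0.60),
                     w, cl)
  expect_equal(res2$ledger$decision[2], "case_by_case_merge")
  # manual override wins
  res3 <- merge_step(c(R1 = 0.95, R2 = 1.00), c(R1 = 0.93, R2 = 0.60),
                     w, cl, overrides = c(R2 = "keep"))
  expect_equal(unname(res3$partition), u)
})

test_that("sub-threshold units without admissible partners stay isolated", {
  u <- c("R1", "R2")
  w <- matrix(0, 2, 2, dimnames = list(u, u))
  cl <- c(R1 = 1, R2 = 2)      # different clusters: no partner
  expect_warning(
    res <- merge_step(c(R1 = 0.9, R2 = 0.4), c(R1 = 0.9, R2 = 0.3), w, cl),
    "isolated")
  expect_equal(unname(res$partition), u)
  expect_match(res$ledger$evidence[2], "isolated")
})

test_that("ledger replay reproduces the partition bit-exactly", {
  u <- c("R1", "R2", "R3", "R4")
  w <- matrix(runif(16), 4, 4, dimnames = list(u, u))
  w <- (w + t(w)) / 2; diag(w) <- 0
  cl <- c(R1 = 1, R2 = 1, R3 = 1, R4 = 1)
  res <- merge_step(c(R1 = 0.5, R2 = 0.5, R3 = 0.9, R4 = 0.4),
                    c(R1 = 0.4, R2 = 0.6, R3 = 0.9, R4 = 0.3), w, cl)
  expect_identical(replay_ledger(res$ledger), res$partition)
})

test_that("iterate_units merges exactly the planted pairs and terminates", {
  bl <- planted_pair_baseline(seed = 11)
  pairs <- attr(bl, "planted_pairs")
  res <- iterate_units(bl, panel_size = 96, repeats = 4, max_iter = 6,
                       per_site_holdout = 4, seed = 3)
  expect_true(res$converged)
  part <- res$partition
  for (pr in pairs)
    expect_equal(part[pr[1]], part[pr[2]], ignore_attr = TRUE)
  merged_rivers <- names(part)[part %in% part[c(pairs[[1]][1], pairs[[2]][1])]]
  expect_setequal(merged_rivers, unlist(pairs))
  # every other river keeps its own unit
  singles <- setdiff(names(part), unlist(pairs))
  expect_equal(unname(part[singles]), singles)
  # unit count never increases across iterations
  expect_lte(length(unique(part)), length(part))
  expect_lte(res$iterations, length(part))
  # merging conserves individuals
  expect_equal(sum(table(group_labels(res$baseline, "unit"))),
               nrow(bl$genotypes))
})

test_that("well-separated rivers are a fixed point of the iteration", {
  cfg <- sim_config(n_regions = 1, rivers_per_region = 4,
                    sites_per_river = 2, fish_per_site = 15, n_loci = 120,
                    F_region = 0, F_river = 0.25, F_site = 0,
                    missing_rate = 0, seed = 19)
  bl <- simulate_baseline(cfg)
  res <- iterate_units(bl, panel_size = 96, repeats = 3, max_iter = 5,
                       per_site_holdout = 4, seed = 2)
  expect_true(res$converged)
  expect_equal(res$iterations, 1)
  expect_equal(unname(res$partition), names(res$partition))
})
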