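test_that("Weir-Cockerham components match the hand-worked example", {
  cts <- toy_two_river_counts()
  comp <- gsikit:::wc_components_per_locus(cts)
  expect_equal(unname(comp[1, ]), c(0.104167, -0.041667, 0.25),
               tolerance = 1e-5)
  expect_equal(unname(wc_theta_per_locus(cts)), 1 / 3, tolerance = 1e-12)
})

test_that("theta is 1 under complete fixation and NA when undefined", {
  g <- matrix(c(2L, 2L, 2L, 0L, 0L, 0L), ncol = 1)
  cts <- gsikit:::counts_by_labels(g, rep(c("r1", "r2"), each = 3))
  expect_equal(unname(wc_theta_per_locus(cts)), 1)
  # monomorphic across groups -> undefined
  g2 <- matrix(rep(2L, 6), ncol = 1)
  cts2 <- gsikit:::counts_by_labels(g2, rep(c("r1", "r2"), each = 3))
  expect_true(is.na(wc_theta_per_locus(cts2)))
})

test_that("theta equals an independent ANOVA oracle on random loci", {
  set.seed(14)
  for (i in 1:50) {
    r <- sample(2:6, 1)
    n_per <- sample(5:20, r, replace = TRUE)
    pops <- rep(paste0("p", seq_len(r)), n_per)
    p <- runif(r, 0.05, 0.95)
    g <- unlist(lapply(seq_len(r), function(k) rbinom(n_per[k], 2, p[k])))
    if (all(g == 0) || all(g == 2)) next
    cts <- gsikit:::counts_by_labels(matrix(as.integer(g), ncol = 1), pops)
    got <- wc_theta_per_locus(cts)
    expect_equal(unname(got), unname(wc_oracle(g, pops)["theta"]),
                 tolerance = 1e-12)
  }
})

test_that("theta is invariant to allele relabeling", {
  set.seed(25)
  g <- matrix(as.integer(rbinom(40, 2, rep(c(0.3, 0.7), each = 20))),
              ncol = 1)
  pops <- rep(c("a", "b"), each = 20)
  t1 <- wc_theta_per_locus(gsikit:::counts_by_labels(g, pops))
  t2 <- wc_theta_per_locus(gsikit:::counts_by_labels(2L - g, pops))
  expect_equal(unname(t1), unname(t2), tolerance = 1e-12)
  expect_lte(unname(t1), 1)
})

test_that("ranking sorts by theta with deterministic tie-breaks", {
  theta <- c(L1 = 0.1, L2 = 0.3, L3 = 0.2)
  p <- rank_and_select(theta, sizes = 2)
  expect_equal(panel_loci(p, 2), c("L2", "L3"))
  # ties broken by locus id ascending
  p2 <- rank_and_select(c(L2 = 0.5, L1 = 0.5, L3 = 0.1), sizes = 2)
  expect_equal(panel_loci(p2, 2), c("L1", "L2"))
  # default sizes are the seven platform panels
  expect_warning(p3 <- rank_and_select(setNames(runif(100), sprintf("L%03d", 1:100))))
  expect_equal(rank_and_select(theta, sizes = 3)$sizes, 3)
  d <- formals(rank_and_select)$sizes
  expect_equal(eval(d), c(12, 24, 96, 192, 288, 384, 480))
  # panels are nested and reproducible
  theta_r <- setNames(runif(50), sprintf("L%02d", 1:50))
  pr <- rank_and_select(theta_r, sizes = c(10, 25))
  expect_true(all(panel_loci(pr, 10) %in% panel_loci(pr, 25)))
  expect_identical(rank_and_select(theta_r, sizes = c(10, 25))$ranking,
                   pr$ranking)
  expect_error(rank_and_select(c(a = NA_real_)), "no loci")
})

test_that("negative theta estimates rank last, unclipped", {
  theta <- c(L1 = -0.02, L2 = 0.4, L3 = 0.01)
  p <- rank_and_select(theta, sizes = 3)
  expect_equal(p$ranking$locus_id, c("L2", "L3", "L1"))
  expect_equal(p$ranking$theta[3], -0.02)
})

test_that("outlier screen keeps its FDR on null loci and finds planted ones", {
  set.seed(41)
  r <- 10
  n_per <- 20
  pops <- rep(paste0("p", 1:r), each = n_per)
  theta <- vapply(1:500, function(i) {
    p <- runif(1, 0.2, 0.8)
    pk <- gsikit:::bn_draw(rep(p, r), 0.05)
    g <- unlist(lapply(pk, function(q) rbinom(n_per, 2, q)))
    unname(wc_theta_per_locus(
      gsikit:::counts_by_labels(matrix(as.integer(g), ncol = 1), pops)))
  }, numeric(1))
  names(theta) <- sprintf("L%03d", 1:500)
  scr <- detect_outlier_loci(theta, r = r)
  expect_lte(mean(scr$outlier, na.rm = TRUE), 0.10)   # <= 2x nominal FDR
  # plant one locus with theta ten times the mean
  theta2 <- theta
  theta2["L001"] <- 10 * mean(theta, na.rm = TRUE)
  scr2 <- detect_outlier_loci(theta2, r = r)
  expect_true(scr2$outlier[scr2$locus_id == "L001"])
  # degenerate: identical theta everywhere -> nothing flagged
  flat <- setNames(rep(0.05, 100), sprintf("F%03d", 1:100))
  expect_false(any(detect_outlier_loci(flat, r = 5)$outlier))
  expect_error(detect_outlier_loci(flat, r = 1), "at least 2")
})

test_that("SNP class is metadata only: theta ignores it", {
  bl <- small_sim_baseline(seed = 33)
  cts <- counts_by_group(bl, "river")
  t1 <- wc_theta_per_locus(cts)
  bl$loci$snp_class <- rev(bl$loci$snp_class)
  t2 <- wc_theta_per_locus(counts_by_group(bl, "river"))
  expect_identical(t1, t2)
  p <- rank_and_select(t1, sizes = 24)
  smry <- class_rank_summary(p, bl$loci)
  expect_true(all(c("mean_rank", "median_rank") %in% names(smry)))
})
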