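test_that("Rannala-Mountain genotype probabilities match direct evaluation", {
  p <- rm_genotype_probs(6, 4)
  expect_equal(unname(p[1, "g1"]), 2 * 6.5 * 4.5 / 132, tolerance = 1e-12)
  expect_equal(unname(p[1, "g2"]), 48.75 / 132, tolerance = 1e-12)
  expect_equal(unname(p[1, "g0"]), 0.1875, tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # empty reference: prior predictive
  p0 <- rm_genotype_probs(0, 0)
  expect_equal(unname(p0[1, ]), c(0.375, 0.25, 0.375), ignore_attr = TRUE)
  # normalization for random count pairs
  set.seed(2)
  x <- sample(0:200, 500, TRUE); y <- sample(0:200, 500, TRUE)
  expect_true(all(abs(rowSums(rm_genotype_probs(x, y)) - 1) < 1e-12))
})

test_that("genotype log-likelihood sums logs over non-missing loci", {
  x_a <- c(6, 10); x_b <- c(4, 0)
  g <- c(1L, NA)
  expect_equal(genotype_loglik(g, x_a, x_b), log(2 * 6.5 * 4.5 / 132))
  expect_true(is.na(genotype_loglik(c(NA, NA), x_a, x_b)))
})

test_that("assignment scores sum to 100 and follow the summation rule", {
  bl <- separable_baseline(2, fish_per_unit = 8)
  counts <- counts_by_group(bl, "site")
  # a fish of unit 1's pattern
  g <- matrix(c(2L, 2L, 2L, 2L, 2L, 0L, 0L, 0L, 0L, 0L), 1,
              dimnames = list("probe", colnames(bl$genotypes)))
  ass <- assign_individuals(g, counts, site_units(bl))
  sc <- as.numeric(ass[, grep("^score_", names(ass))])
  expect_equal(sum(sc), 100, tolerance = 1e-6)
  expect_equal(ass$best_unit, "river1")
  expect_true(ass$passes_cutoff)

  # symmetric two-site case: 50/50, tie flagged, fails cutoff 80
  g2 <- matrix(c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L), 1,
               dimnames = list("mid", colnames(bl$genotypes)))
  ass2 <- assign_individuals(g2, counts, site_units(bl))
  sc2 <- as.numeric(ass2[, grep("^score_", names(ass2))])
  expect_equal(sc2, c(50, 50), tolerance = 1e-9)
  expect_true(ass2$tie)
  expect_false(ass2$passes_cutoff)

  # unscorable fish: all loci missing
  g3 <- matrix(NA_integer_, 1, 10,
               dimnames = list("ghost", colnames(bl$genotypes)))
  ass3 <- assign_individuals(g3, counts, site_units(bl))
  expect_false(ass3$scorable)
  expect_true(is.na(ass3$best_unit))
})

test_that("unit scores are sums of site scores across the unit's sites", {
  bl <- small_sim_baseline(seed = 3)
  counts <- counts_by_group(bl, "site")
  u_of <- site_units(bl)
  g <- bl$genotypes[1:5, , drop = FALSE]
  ass <- assign_individuals(g, counts, u_of)
  # recompute from raw log-likelihoods
  ll <- gsikit:::loglik_matrix(g, counts)
  w <- exp(ll - apply(ll, 1, max))
  site_scores <- 100 * w / rowSums(w)
  for (u in unique(u_of)) {
    manual <- rowSums(site_scores[, names(u_of)[u_of == u], drop = FALSE])
    expect_equal(unname(ass[[paste0("score_", u)]]), unname(manual),
                 tolerance = 1e-9)
  }
  expect_true(all(abs(rowSums(
    as.matrix(ass[, grep("^score_", names(ass))])) - 100) < 1e-6))
})

test_that("holdout split is a reproducible partition", {
  bl <- small_sim_baseline(seed = 8)
  s1 <- holdout_split(bl, 6, seed = 5)
  s2 <- holdout_split(bl, 6, seed = 5)
  expect_identical(s1, s2)
  expect_length(intersect(s1$train, s1$holdout), 0)
  expect_setequal(c(s1$train, s1$holdout), bl$hierarchy$individual)
  # 8 sites x 6 fish
  expect_length(s1$holdout, 48)
  # boundary: zero holdout
  s0 <- holdout_split(bl, 0, seed = 1)
  expect_length(s0$holdout, 0)
  # short sites contribute all but one
  tiny <- separable_baseline(2, fish_per_unit = 4)
  st <- holdout_split(tiny, 6, seed = 1)
  expect_equal(length(st$holdout), 2 * 3)
  expect_length(st$log, 2)
})

test_that("hold-out evaluation is perfect on a separable baseline", {
  bl <- separable_baseline(2, fish_per_unit = 10)
  split <- holdout_split(bl, 3, seed = 2)
  ev <- evaluate_holdout(bl, split, colnames(bl$genotypes))
  expect_equal(ev$per_unit$precision, c(1, 1))
  expect_equal(ev$per_unit$proportion_assigned, c(1, 1))
  expect_equal(ev$overall$accuracy_all, 1)
})

test_that("per-unit metrics agree with an independent recount", {
  bl <- small_sim_baseline(seed = 12)
  split <- holdout_split(bl, 4, seed = 9)
  ev <- evaluate_holdout(bl, split, colnames(bl$genotypes), cutoff = 80)
  ass <- ev$assignments
  true_unit <- ev$true_unit
  for (u in sort(unique(bl$units))) {
    from_u <- true_unit == u
    pa <- sum(ass$passes_cutoff & from_u) / sum(from_u)
    assigned_to <- ass$passes_cutoff & ass$best_unit == u
    prec <- if (any(assigned_to)) mean(true_unit[assigned_to] == u)
            else NA_real_
    row <- ev$per_unit[ev$per_unit$unit == u, ]
    expect_equal(row$proportion_assigned, pa, tolerance = 1e-12)
    expect_equal(row$precision, prec, tolerance = 1e-12)
  }
  # unfiltered row sums = fish per true unit
  expect_equal(unname(rowSums(ev$table)),
               unname(table(factor(true_unit, sort(unique(bl$units))))),
               ignore_attr = TRUE)
})

test_that("training counts never contain the scored fish", {
  bl <- small_sim_baseline(seed = 2)
  split <- holdout_split(bl, 4, seed = 1)
  h <- bl$hierarchy
  train_idx <- h$individual %in% split$train
  counts <- gsikit:::counts_by_labels(bl$genotypes[train_idx, ],
                                      h$site[train_idx], "site")
  # adding any holdout fish changes its site's counts: totals must equal
  # the training fish tally exactly
  expect_equal(unname(colSums(counts$n)) / 2,
               rep(sum(train_idx), ncol(bl$genotypes)) -
                 unname(colSums(is.na(bl$genotypes[train_idx, ]))))
})

test_that("two-fold CV yields 2x repeats estimates and is seeded", {
  bl <- separable_baseline(2, fish_per_unit = 8)
  cv <- twofold_cv(bl, colnames(bl$genotypes), repeats = 10, seed = 3)
  expect_equal(ncol(cv$estimates), 20)
  expect_equal(unname(cv$per_unit$precision_mean), c(1, 1))
  expect_equal(unname(cv$per_unit$precision_sd), c(0, 0))
  cv2 <- twofold_cv(bl, colnames(bl$genotypes), repeats = 10, seed = 3)
  expect_identical(cv$estimates, cv2$estimates)
  cv3 <- twofold_cv(bl, colnames(bl$genotypes), repeats = 2, seed = 4)
  expect_equal(ncol(cv3$estimates), 4)
})

test_that("exclusion test is calibrated and catches mismatched fish", {
  set.seed(6)
  L <- 40
  x_a <- rbinom(L, 40, 0.5); x_b <- 40 - x_a
  f <- (x_a + 0.5) / (41)
  # null fish drawn from the same frequencies: p has near-uniform spread
  ps <- vapply(1:200, function(i) {
    g <- rbinom(L, 2, f)
    exclusion_test(g, x_a, x_b, n_sim = 200)
  }, numeric(1))
  expect_gt(mean(ps), 0.35); expect_lt(mean(ps), 0.65)
  # fish homozygous for alleles near-absent in the unit
  x_a2 <- rep(39, L); x_b2 <- rep(1, L)
  p_bad <- exclusion_test(rep(0L, L), x_a2, x_b2, n_sim = 1000, seed = 1)
  expect_lt(p_bad, 0.05)
  expect_error(exclusion_test(rep(1L, L), x_a, x_b, n_sim = 0), "n_sim")
})
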