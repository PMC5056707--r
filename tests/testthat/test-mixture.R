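test_that("EM recovers separable mixtures exactly", {
  f <- matrix(c(1, 0, 1, 0), 2, 2,     # u1 fixed for A, u2 fixed for B
              dimnames = list(c("u1", "u2"), c("L1", "L2")))
  g <- rbind(matrix(2L, 7, 2), matrix(0L, 3, 2))
  colnames(g) <- c("L1", "L2"); rownames(g) <- paste0("m", 1:10)
  fit <- em_mixture(g, f)
  expect_equal(unname(fit$pi), c(0.7, 0.3), tolerance = 1e-9)
  expect_true(fit$converged)
  # symmetric two-fish case
  g2 <- rbind(c(2L, 2L), c(0L, 0L))
  colnames(g2) <- c("L1", "L2")
  fit2 <- em_mixture(g2, f)
  expect_equal(unname(fit2$pi), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("EM stays on the simplex with a monotone log-likelihood", {
  set.seed(10)
  for (i in 1:100) {
    U <- sample(2:5, 1); L <- sample(5:30, 1); M <- sample(5:40, 1)
    f <- matrix(runif(U * L, 0.05, 0.95), U, L,
                dimnames = list(paste0("u", 1:U), paste0("L", 1:L)))
    pi0 <- as.vector(stats::rmultinom(1, 20, rep(1, U))) / 20
    origin <- sample(U, M, TRUE, prob = pi0 + 1e-9)
    g <- matrix(rbinom(M * L, 2, f[origin, ]), M, L,
                dimnames = list(paste0("m", 1:M), colnames(f)))
    fit <- em_mixture(g, f, tol = 1e-10)
    expect_true(all(fit$pi >= 0))
    expect_equal(sum(fit$pi), 1, tolerance = 1e-9)
    expect_true(all(diff(fit$loglik) > -1e-8))
  }
})

test_that("fish impossible in every unit are excluded with a warning", {
  f <- matrix(c(1, 0, 1, 0), 2, 2,
              dimnames = list(c("u1", "u2"), c("L1", "L2")))
  g <- rbind(c(2L, 2L), c(0L, 2L))   # second fish impossible everywhere
  colnames(g) <- c("L1", "L2")
  expect_warning(fit <- em_mixture(g, f), "zero likelihood")
  expect_equal(fit$n_used, 1)
})

test_that("posterior frequency draws have the right mean and conserve sizes", {
  bl <- separable_baseline(2, fish_per_unit = 10)
  cts <- counts_by_group(bl, "unit")
  real <- draw_realization(cts, seed = 1)
  expect_identical(real$sim_counts$n, cts$n)
  expect_true(all(real$sim_counts$n_a >= 0 &
                    real$sim_counts$n_a <= real$sim_counts$n))
  # near-fixed counts concentrate the drawn frequency near 1
  big <- structure(list(n_a = matrix(1e6, 1, 1, dimnames = list("u", "L")),
                        n = matrix(1e6, 1, 1, dimnames = list("u", "L")),
                        n_het = matrix(0, 1, 1), grouping = "unit"),
                   class = "allele_counts")
  fs <- vapply(1:100, function(i) draw_realization(big)$mix_freqs[1, 1],
               numeric(1))
  expect_true(all(abs(1 - fs) < 1e-3))
  # Dirichlet-mean oracle: mean draw ~ (x_A + 1/2)/(n + 1)
  set.seed(3)
  small <- structure(list(n_a = matrix(6, 1, 1, dimnames = list("u", "L")),
                          n = matrix(10, 1, 1, dimnames = list("u", "L")),
                          n_het = matrix(0, 1, 1), grouping = "unit"),
                     class = "allele_counts")
  draws <- vapply(1:2000, function(i) draw_realization(small)$mix_freqs[1, 1],
                  numeric(1))
  post_mean <- 6.5 / 11
  mc_se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - post_mean), 4 * mc_se)
  # baseline redraw and mixture draw are independent: correlation modest
  pairs <- t(vapply(1:500, function(i) {
    r <- draw_realization(small)
    c(r$sim_counts$n_a[1, 1], r$mix_freqs[1, 1])
  }, numeric(2)))
  expect_lt(abs(cor(pairs[, 1], pairs[, 2])), 0.15)
})

test_that("100% simulations are exact for perfectly separated units", {
  bl <- separable_baseline(2, fish_per_unit = 12)
  cts <- counts_by_group(bl, "unit")
  s <- sim_100pct(cts, B = 20, mix_size = 30, seed = 2)
  expect_equal(s$mean, c(1, 1), tolerance = 0.01)
  expect_true(all(s$ci_hi - s$ci_lo < 0.05))
  expect_error(sim_100pct(gsikit:::collapse_counts(
    cts, c(river1 = "x", river2 = "x"))), "at least 2")
})

test_that("fishery simulations cover the truth and vanish for absent units", {
  bl <- separable_baseline(3, fish_per_unit = 12)
  cts <- counts_by_group(bl, "unit")
  units <- rownames(cts$n_a)
  pi_true <- setNames(c(0.5, 0.5, 0), units)
  fs <- sim_fishery(cts, pi_true, B = 50, mix_size = 100, seed = 7)
  s <- fs$summary
  expect_true(all(s$ci_lo <= s$true_proportion + 1e-9 &
                    s$true_proportion <= s$ci_hi + 1e-9))
  expect_lt(s$mean[3], 0.01)
  expect_equal(sum(s$mean), 1, tolerance = 1e-6)
  expect_error(sim_fishery(cts, c(0.5, 0.5), B = 2), "one entry per unit")
})

test_that("estimator bias shrinks with mixture size", {
  cfg <- sim_config(n_regions = 1, rivers_per_region = 3,
                    sites_per_river = 1, fish_per_site = 30, n_loci = 60,
                    F_region = 0, F_river = 0.08, F_site = 0,
                    missing_rate = 0, seed = 15)
  bl <- simulate_baseline(cfg)
  cts <- counts_by_group(bl, "unit")
  units <- rownames(cts$n_a)
  pi_true <- setNames(c(0.6, 0.3, 0.1), units)
  small <- sim_fishery(cts, pi_true, B = 40, mix_size = 100, seed = 5)
  large <- sim_fishery(cts, pi_true, B = 40, mix_size = 1000, seed = 5)
  mad_small <- mean(abs(small$summary$mean - pi_true))
  mad_large <- mean(abs(large$summary$mean - pi_true))
  expect_lt(mad_large, mad_small + 0.01)
})
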