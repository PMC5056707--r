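# Fixtures and independent oracles shared across the suite.

# Two-river toy genotypes for the Weir-Cockerham worked example:
# river1 = {AA, AA, AB, AB}, river2 = {BB, BB, AB, AB}.
toy_two_river_counts <- function() {
  g <- matrix(c(2L, 2L, 1L, 1L, 0L, 0L, 1L, 1L), ncol = 1,
              dimnames = list(paste0("f", 1:8), "L1"))
  gsikit:::counts_by_labels(g, rep(c("r1", "r2"), each = 4))
}

# Independent Weir-Cockerham oracle via the ANOVA sums-of-squares route
# (mean squares between populations / individuals / gametes), a different
# derivation from the variance-component formulas in the package.
wc_oracle <- function(genotypes, pops) {
  pops <- factor(pops)
  ok <- !is.na(genotypes)
  genotypes <- genotypes[ok]; pops <- droplevels(pops[ok])
  r <- nlevels(pops)
  n_i <- as.vector(table(pops))
  n_tot <- sum(n_i)
  p_ind <- genotypes / 2
  p_i <- tapply(p_ind, pops, mean)
  pbar <- sum(n_i * p_i) / n_tot
  ssp <- sum(2 * n_i * (p_i - pbar)^2)
  ssi <- sum(2 * (p_ind - p_i[pops])^2)
  ssg <- sum(genotypes == 1) / 2
  msp <- ssp / (r - 1)
  msi <- ssi / (n_tot - r)
  msg <- ssg / n_tot
  nc <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
  a <- (msp - msi) / (2 * nc)
  b <- (msi - msg) / 2
  c <- msg
  c(a = a, b = b, c = c, theta = a / (a + b + c))
}

# Brute-force exact-HWE oracle: enumerate every admissible heterozygote
# count with plain factorials (safe for the small n used in tests).
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  if (n_a == 0 || n_b == 0) return(1)
  hs <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  prob <- sapply(hs, function(h) {
    factorial(n) / (factorial((n_a - h) / 2) * factorial(h) *
                      factorial((n_b - h) / 2)) * 2^h /
      (factorial(2 * n) / (factorial(n_a) * factorial(n_b)))
  })
  sum(prob[prob <= prob[hs == n_ab] * (1 + 1e-10)])
}

# A perfectly separable baseline: `n_units` rivers (one site each), every
# river fixed for its own block of loci. Precision must be 1 everywhere.
separable_baseline <- function(n_units = 2, fish_per_unit = 10,
                               loci_per_unit = 5) {
  L <- n_units * loci_per_unit
  geno <- matrix(0L, n_units * fish_per_unit, L)
  for (u in seq_len(n_units)) {
    rows <- (u - 1) * fish_per_unit + seq_len(fish_per_unit)
    cols <- (u - 1) * loci_per_unit + seq_len(loci_per_unit)
    geno[rows, cols] <- 2L
  }
  ids <- sprintf("u%d_f%02d", rep(seq_len(n_units), each = fish_per_unit),
                 rep(seq_len(fish_per_unit), n_units))
  rownames(geno) <- ids
  colnames(geno) <- sprintf("L%02d", seq_len(L))
  hierarchy <- data.frame(
    individual = ids,
    site = sprintf("site%d", rep(seq_len(n_units), each = fish_per_unit)),
    river = sprintf("river%d", rep(seq_len(n_units), each = fish_per_unit)),
    stringsAsFactors = FALSE)
  loci <- data.frame(locus_id = colnames(geno), snp_class = "SNP",
                     stringsAsFactors = FALSE)
  gsi_baseline(geno, hierarchy, loci)
}

# Small simulated baseline used by several module tests; `...` overrides
# the scaled-down defaults.
small_sim_baseline <- function(seed = 42, ...) {
  args <- list(n_regions = 2, rivers_per_region = 2, sites_per_river = 2,
               fish_per_site = 12, n_loci = 80, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  simulate_baseline(do.call(sim_config, args))
}

# Baseline with two planted undifferentiated river pairs: rivers 2 and 4
# are regenerated from the river frequencies of rivers 1 and 3.
planted_pair_baseline <- function(seed = 11) {
  cfg <- sim_config(n_regions = 1, rivers_per_region = 6,
                    sites_per_river = 2, fish_per_site = 15, n_loci = 100,
                    F_region = 0, F_river = 0.12, F_site = 0,
                    missing_rate = 0, seed = seed)
  bl <- simulate_baseline(cfg)
  tr <- bl$truth$river
  h <- bl$hierarchy
  set.seed(seed + 1000)
  for (pair in list(c(1, 2), c(3, 4))) {
    src <- rownames(tr)[pair[1]]
    dst <- rownames(tr)[pair[2]]
    idx <- which(h$river == dst)
    bl$genotypes[idx, ] <- matrix(
      rbinom(length(idx) * ncol(bl$genotypes), 2,
             rep(tr[src, ], each = length(idx))),
      nrow = length(idx))
  }
  attr(bl, "planted_pairs") <- list(rownames(tr)[1:2], rownames(tr)[3:4])
  bl
}

# The default desk-scale scenario used by the acceptance checks.
demo18_baseline <- function(seed = 1L) {
  simulate_baseline(sim_config(seed = seed))
}
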