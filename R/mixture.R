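# Per-fish log-likelihood matrix (fish x units) under HWE at fixed unit
# allele frequencies; missing loci are skipped.
hwe_loglik_matrix <- function(genotypes, unit_freqs) {
  f <- t(unit_freqs[, colnames(genotypes), drop = FALSE])   # L x U
  # impossible genotypes (frequency exactly 0 or 1) get a -1e10 penalty
  # instead of -Inf so the matrix products below stay NaN-free; one such
  # locus still forces a relative likelihood of exactly 0 after max
  # subtraction, and fish impossible in every unit are detectable as
  # ll < -1e9 across the board
  lp0 <- pmax(log((1 - f)^2), -1e10)
  lp1 <- pmax(log(2 * f * (1 - f)), -1e10)
  lp2 <- pmax(log(f^2), -1e10)
  i0 <- (genotypes == 0L); i0[is.na(i0)] <- FALSE
  i1 <- (genotypes == 1L); i1[is.na(i1)] <- FALSE
  i2 <- (genotypes == 2L); i2[is.na(i2)] <- FALSE
  ll <- (i0 + 0) %*% lp0 + (i1 + 0) %*% lp1 + (i2 + 0) %*% lp2
  rownames(ll) <- rownames(genotypes)
  colnames(ll) <- rownames(unit_freqs)
  ll
}

#' EM estimation of mixed-stock proportions
#'
#' Conditional maximum likelihood: baseline allele frequencies are held
#' fixed and the mixture proportions over units are estimated by EM from a
#' uniform start. Per-fish genotype likelihoods come from Hardy-Weinberg
#' proportions at the unit frequencies; responsibilities are proportional
#' to `pi_u * L_u(g)` and the M-step sets `pi` to the mean responsibility.
#' All likelihoods are handled in log space (per-fish max subtraction), so
#' long panels cannot underflow. The log-likelihood is non-decreasing over
#' iterations, as EM guarantees.
#'
#' @param genotypes mixture genotype matrix (fish x loci, 0/1/2/NA).
#' @param unit_freqs matrix of per-unit allele frequencies (units x loci),
#'   e.g. [posterior_mean_freqs()] of unit-level counts.
#' @param tol stop when `max |delta pi| < tol`.
#' @param max_iter iteration cap.
#' @return object of class `mixture_estimate`: list with `pi` (named
#'   simplex vector), `loglik` (trace, one entry per iteration),
#'   `converged`, `iterations`, `n_used` (fish with a finite likelihood in
#'   at least one unit; others are excluded with a warning).
#' @export
em_mixture <- function(genotypes, unit_freqs, tol = 1e-8, max_iter = 5000) {
  if (nrow(genotypes) < 1) stop("empty mixture")
  ll <- hwe_loglik_matrix(genotypes, unit_freqs)
  usable <- apply(ll, 1, function(x) any(x > -1e9))
  if (!all(usable)) {
    warning(sprintf("%d fish with zero likelihood in every unit excluded",
                    sum(!usable)))
    ll <- ll[usable, , drop = FALSE]
    if (nrow(ll) == 0) stop("no usable mixture fish")
  }
  U <- ncol(ll)
  mx <- apply(ll, 1, max)
  lik <- exp(ll - mx)                      # fish x units, rel. likelihoods

  pi <- rep(1 / U, U)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    denom <- as.vector(lik %*% pi)
    trace[it] <- sum(log(denom) + mx)
    r <- lik * rep(pi, each = nrow(lik)) / denom
    pi_new <- colMeans(r)
    if (max(abs(pi_new - pi)) < tol) {
      pi <- pi_new
      converged <- TRUE
      break
    }
    pi <- pi_new
  }
  structure(list(pi = stats::setNames(pi, colnames(ll)),
                 loglik = trace, converged = converged,
                 iterations = length(trace), n_used = nrow(ll)),
            class = "mixture_estimate")
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat(sprintf("mixture_estimate: %d units, %d fish, %d EM iterations%s\n",
              length(x$pi), x$n_used, x$iterations,
              if (x$converged) "" else " (not converged)"))
  print(round(x$pi, 4))
  invisible(x)
}

#' Parametric resampling of a baseline (one realization)
#'
#' Propagates baseline sampling uncertainty into the mixture simulations:
#' for every unit and locus a frequency is drawn from the
#' Dirichlet/Beta posterior `Beta(x_A + 1/2, x_B + 1/2)`, a NEW baseline
#' sample of the same gene count as the real data is binomially redrawn
#' from it, and an independent second posterior draw provides the
#' frequencies from which mixture genotypes are generated — so mixture
#' fish are never scored against frequencies fitted to their own realized
#' genotypes.
#'
#' @param counts `allele_counts` at unit level.
#' @param seed optional integer seed.
#' @return list with `sim_counts` (an `allele_counts` with redrawn `n_a`,
#'   original `n`) and `mix_freqs` (units x loci matrix for mixture
#'   generation).
#' @export
draw_realization <- function(counts, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x_a <- counts$n_a
  x_b <- counts$n - counts$n_a
  k <- length(x_a)
  f1 <- matrix(stats::rbeta(k, x_a + 0.5, x_b + 0.5),
               nrow = nrow(x_a), dimnames = dimnames(x_a))
  new_a <- matrix(stats::rbinom(k, as.vector(counts$n), as.vector(f1)),
                  nrow = nrow(x_a), dimnames = dimnames(x_a))
  f2 <- matrix(stats::rbeta(k, x_a + 0.5, x_b + 0.5),
               nrow = nrow(x_a), dimnames = dimnames(x_a))
  sim_counts <- structure(list(n_a = new_a, n = counts$n,
                               n_het = counts$n_het, grouping = counts$grouping),
                          class = "allele_counts")
  list(sim_counts = sim_counts, mix_freqs = f2)
}

summarize_replicates <- function(est, truth) {
  # est: replicates x units matrix of pi-hat
  data.frame(
    unit = colnames(est),
    true_proportion = unname(truth[colnames(est)]),
    mean = colMeans(est),
    ci_lo = apply(est, 2, stats::quantile, 0.025),
    ci_hi = apply(est, 2, stats::quantile, 0.975),
    se = apply(est, 2, stats::sd) / sqrt(nrow(est)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' 100% mixed-stock simulations
#'
#' For every unit, simulates `B` fisheries composed entirely of that unit
#' (`mix_size` fish each), re-estimating the mixture against a freshly
#' resampled baseline every replicate, and summarizes the estimated
#' proportion of the true unit.
#'
#' @param counts `allele_counts` at unit level.
#' @param B replicates per unit; default 1000.
#' @param mix_size fish per simulated fishery; default 200.
#' @param seed integer seed.
#' @return data.frame per unit: `unit`, `true_proportion` (= 1), `mean`,
#'   `ci_lo`, `ci_hi`, `se` of the true unit's estimated proportion.
#' @export
sim_100pct <- function(counts, B = 1000, mix_size = 200, seed = 1L) {
  units <- rownames(counts$n_a)
  if (length(units) < 2) stop("need at least 2 units")
  set.seed(seed)
  est <- matrix(NA_real_, B, length(units), dimnames = list(NULL, units))
  for (u_i in seq_along(units)) {
    pi_true <- stats::setNames(as.numeric(units == units[u_i]), units)
    for (b in seq_len(B)) {
      real <- draw_realization(counts)
      mix <- simulate_mixture(real$mix_freqs, pi_true, mix_size)
      fit <- em_mixture(mix$genotypes, posterior_mean_freqs(real$sim_counts))
      est[b, u_i] <- fit$pi[units[u_i]]
    }
  }
  data.frame(unit = units, true_proportion = 1,
             mean = colMeans(est),
             ci_lo = apply(est, 2, stats::quantile, 0.025),
             ci_hi = apply(est, 2, stats::quantile, 0.975),
             se = apply(est, 2, stats::sd) / sqrt(B),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Realistic fishery mixed-stock simulations
#'
#' Simulates `B` fisheries of `mix_size` fish with composition `pi_true`
#' (equal proportions, rod-catch-derived, or any other simplex vector),
#' each estimated by EM against a freshly resampled baseline, and reports
#' per-unit means, 95% percentile confidence intervals and standard
#' errors over replicates.
#'
#' @param counts `allele_counts` at unit level.
#' @param pi_true named mixture proportions over the units (sums to 1).
#' @param B replicates; default 1000.
#' @param mix_size fish per fishery sample; default 1000.
#' @param seed integer seed.
#' @return list with `summary` (per-unit data.frame: unit,
#'   true_proportion, mean, ci_lo, ci_hi, se) and `estimates`
#'   (B x units matrix of pi-hat).
#' @export
sim_fishery <- function(counts, pi_true, B = 1000, mix_size = 1000,
                        seed = 1L) {
  units <- rownames(counts$n_a)
  if (length(pi_true) != length(units))
    stop("pi_true must have one entry per unit")
  if (!is.null(names(pi_true))) pi_true <- pi_true[units]
  names(pi_true) <- units
  set.seed(seed)
  est <- matrix(NA_real_, B, length(units), dimnames = list(NULL, units))
  for (b in seq_len(B)) {
    real <- draw_realization(counts)
    mix <- simulate_mixture(real$mix_freqs, pi_true, mix_size)
    fit <- em_mixture(mix$genotypes, posterior_mean_freqs(real$sim_counts))
    est[b, ] <- fit$pi[units]
  }
  list(summary = summarize_replicates(est, pi_true), estimates = est)
}
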