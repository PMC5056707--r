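#' Rannala-Mountain genotype probabilities
#'
#' Compound-Dirichlet predictive probability of a diploid genotype given
#' reference allele counts, with a Dirichlet(1/2, 1/2) prior per biallelic
#' locus (lambda = 1/k, k = 2). With reference counts `(x_a, x_b)` and
#' `n = x_a + x_b`:
#' `P(AA) = (x_a + 1/2)(x_a + 3/2) / ((n + 1)(n + 2))`,
#' `P(AB) = 2 (x_a + 1/2)(x_b + 1/2) / ((n + 1)(n + 2))`,
#' `P(BB)` analogous. The three probabilities sum to 1 for any counts,
#' and an empty reference yields the prior predictive (3/8, 1/4, 3/8).
#'
#' @param x_a,x_b vectors of reference A and B allele copies (one entry
#'   per locus).
#' @return matrix with columns `g0`, `g1`, `g2` (probability of carrying
#'   0, 1, 2 copies of A), one row per locus.
#' @export
rm_genotype_probs <- function(x_a, x_b) {
  n <- x_a + x_b
  den <- (n + 1) * (n + 2)
  cbind(g0 = (x_b + 0.5) * (x_b + 1.5) / den,
        g1 = 2 * (x_a + 0.5) * (x_b + 0.5) / den,
        g2 = (x_a + 0.5) * (x_a + 1.5) / den)
}

#' Log-likelihood of one multilocus genotype against one reference sample
#'
#' Sum over non-missing loci of the log Rannala-Mountain genotype
#' probability. Loci missing in the individual are skipped.
#'
#' @param genotype integer vector of 0/1/2/NA codes over loci.
#' @param x_a,x_b reference allele counts per locus.
#' @return scalar log-likelihood; `NA` if no locus is usable (the
#'   individual is unscorable).
#' @export
genotype_loglik <- function(genotype, x_a, x_b) {
  ok <- !is.na(genotype)
  if (!any(ok)) return(NA_real_)
  p <- rm_genotype_probs(x_a[ok], x_b[ok])
  sum(log(p[cbind(seq_len(sum(ok)), genotype[ok] + 1L)]))
}

# Log genotype-probability arrays for a whole count table: a list of three
# L x G matrices (codes 0, 1, 2), used to score many fish by matrix
# multiplication.
reference_log_probs <- function(counts) {
  x_a <- t(counts$n_a)                 # L x G
  x_b <- t(counts$n - counts$n_a)
  n <- x_a + x_b
  den <- (n + 1) * (n + 2)
  list(lp0 = log((x_b + 0.5) * (x_b + 1.5) / den),
       lp1 = log(2 * (x_a + 0.5) * (x_b + 0.5) / den),
       lp2 = log((x_a + 0.5) * (x_a + 1.5) / den))
}

# Log-likelihood matrix (fish x reference groups) for a genotype matrix.
loglik_matrix <- function(genotypes, counts) {
  lp <- reference_log_probs(counts)
  i0 <- (genotypes == 0L); i0[is.na(i0)] <- FALSE
  i1 <- (genotypes == 1L); i1[is.na(i1)] <- FALSE
  i2 <- (genotypes == 2L); i2[is.na(i2)] <- FALSE
  ll <- (i0 + 0) %*% lp$lp0 + (i1 + 0) %*% lp$lp1 + (i2 + 0) %*% lp$lp2
  rownames(ll) <- rownames(genotypes)
  ll
}

#' Bayesian assignment of individuals to units via summed site scores
#'
#' Each fish's Rannala-Mountain likelihood is computed against every
#' baseline SITE; likelihoods are normalized over all sites to scores
#' summing to 100 (computed in log space with max-subtraction, so
#' underflow cannot produce NaN); site scores are then summed within each
#' assignment unit. The best unit is the score argmax (ties broken by unit
#' id ascending and flagged), and a fish passes the cut-off when its best
#' unit score reaches `cutoff`.
#'
#' @param genotypes matrix of fish x loci codes (0/1/2/NA); loci must be a
#'   subset of the columns of `site_counts`.
#' @param site_counts `allele_counts` at site level for the REFERENCE fish
#'   only (the scored fish must not contribute to these counts).
#' @param unit_of named vector site -> unit (see [site_units()]).
#' @param cutoff score threshold on the best unit; default 80.
#' @return data.frame, one row per fish: `individual`, `best_unit`,
#'   `best_score`, `passes_cutoff`, `tie`, `scorable`, plus one `score_*`
#'   column per unit. Unscorable fish (no usable loci) have `NA` scores.
#' @export
assign_individuals <- function(genotypes, site_counts, unit_of, cutoff = 80) {
  loci <- colnames(genotypes)
  stopifnot(all(loci %in% colnames(site_counts$n_a)))
  sc <- site_counts
  keep <- match(loci, colnames(sc$n_a))
  sc$n_a <- sc$n_a[, keep, drop = FALSE]
  sc$n <- sc$n[, keep, drop = FALSE]
  sc$n_het <- sc$n_het[, keep, drop = FALSE]

  sites <- rownames(sc$n_a)
  stopifnot(all(sites %in% names(unit_of)))
  units <- sort(unique(unname(unit_of[sites])))

  ll <- loglik_matrix(genotypes, sc)
  scorable <- rowSums(!is.na(genotypes)) > 0

  mx <- apply(ll, 1, max)
  w <- exp(ll - mx)                       # fish x sites, max = 1
  site_scores <- 100 * w / rowSums(w)
  unit_scores <- t(rowsum(t(site_scores),
                          factor(unname(unit_of[sites]), levels = units)))
  unit_scores[!scorable, ] <- NA_real_

  best_idx <- apply(unit_scores, 1, function(s)
    if (all(is.na(s))) NA_integer_ else which.max(s))  # first max = id asc
  best_score <- unit_scores[cbind(seq_len(nrow(unit_scores)), best_idx)]
  tie <- vapply(seq_len(nrow(unit_scores)), function(i) {
    s <- unit_scores[i, ]
    if (all(is.na(s))) return(FALSE)
    sum(abs(s - max(s)) < 1e-9) > 1
  }, logical(1))

  out <- data.frame(individual = rownames(genotypes),
                    best_unit = ifelse(is.na(best_idx), NA_character_,
                                       units[best_idx]),
                    best_score = best_score,
                    passes_cutoff = !is.na(best_score) & best_score >= cutoff,
                    tie = tie, scorable = scorable,
                    stringsAsFactors = FALSE)
  colnames(unit_scores) <- paste0("score_", units)
  cbind(out, as.data.frame(unit_scores))
}

#' Confusion tables and per-unit accuracy from an assignment list
#'
#' @param assignments data.frame from [assign_individuals()].
#' @param true_unit character vector of true units, aligned with
#'   `assignments` rows.
#' @param units unit universe for the table dimensions.
#' @return list with `table` (true x assigned counts, all scorable fish),
#'   `table_cutoff` (only fish passing the cut-off) and `per_unit`
#'   (data.frame: unit, n_fish, proportion_assigned, precision and
#'   precision_all; precision is computed on the cut-off-filtered table,
#'   `NA` when no fish is assigned to the unit).
#' @export
confusion_table <- function(assignments, true_unit, units = NULL) {
  if (is.null(units))
    units <- sort(unique(c(true_unit, assignments$best_unit)))
  f <- function(idx) table(factor(true_unit[idx], levels = units),
                           factor(assignments$best_unit[idx], levels = units))
  ok <- assignments$scorable & !is.na(assignments$best_unit)
  tab <- f(ok)
  tab_cut <- f(ok & assignments$passes_cutoff)

  prec <- function(tb) {
    assigned <- colSums(tb)
    ifelse(assigned > 0, diag(tb) / assigned, NA_real_)
  }
  n_fish <- as.vector(table(factor(true_unit, levels = units)))
  per_unit <- data.frame(
    unit = units,
    n_fish = n_fish,
    proportion_assigned = ifelse(n_fish > 0, rowSums(tab_cut) / n_fish,
                                 NA_real_),
    precision = prec(tab_cut),
    precision_all = prec(tab),
    stringsAsFactors = FALSE)
  rownames(per_unit) <- NULL
  m <- function(tb) matrix(tb, nrow(tb), dimnames = list(units, units))
  list(table = m(tab), table_cutoff = m(tab_cut), per_unit = per_unit)
}

#' Hold-out / training split of a baseline
#'
#' Removes `per_site_holdout` fish at random from every site into a
#' hold-out set; the remainder is the training set used to rank loci and
#' serve as reference. Sites with too few fish contribute all but one
#' (logged), so no site ever empties.
#'
#' @param baseline a [gsi_baseline()] object.
#' @param per_site_holdout fish removed per site; default 6.
#' @param seed integer seed.
#' @return list with character vectors `train` and `holdout` (individual
#'   ids; a partition of the baseline) and a `log` of short-handed sites.
#' @export
holdout_split <- function(baseline, per_site_holdout = 6, seed = 1L) {
  set.seed(seed)
  h <- baseline$hierarchy
  log <- character(0)
  holdout <- unlist(lapply(split(h$individual, h$site), function(ids) {
    k <- per_site_holdout
    if (length(ids) <= per_site_holdout) {
      k <- length(ids) - 1L
      log <<- c(log, sprintf("site of %s: only %d fish, holding out %d",
                             ids[1], length(ids), k))
    }
    if (k <= 0) return(character(0))
    sample(ids, k)
  }), use.names = FALSE)
  list(train = setdiff(h$individual, holdout), holdout = holdout, log = log)
}

#' Hold-out / training evaluation of assignment accuracy
#'
#' Assigns every hold-out fish to the training-set site references with
#' [assign_individuals()] and tallies confusion tables and per-unit
#' metrics. Training counts never include hold-out fish, so no fish is
#' scored against references containing its own genotype.
#'
#' @param baseline a [gsi_baseline()] object.
#' @param split list from [holdout_split()].
#' @param panel_loci character vector of locus ids to use.
#' @param cutoff score cut-off; default 80.
#' @return list as from [confusion_table()], plus `assignments`,
#'   `true_unit` and `overall` (data.frame with unfiltered and
#'   cut-off-filtered overall accuracy and the fraction of fish passing).
#' @export
evaluate_holdout <- function(baseline, split, panel_loci, cutoff = 80) {
  h <- baseline$hierarchy
  train_idx <- h$individual %in% split$train
  g <- baseline$genotypes[, panel_loci, drop = FALSE]
  counts <- counts_by_labels(g[train_idx, , drop = FALSE],
                             h$site[train_idx], "site")
  hold_idx <- which(h$individual %in% split$holdout)
  ass <- assign_individuals(g[hold_idx, , drop = FALSE], counts,
                            site_units(baseline), cutoff)
  true_unit <- unname(baseline$units[h$river[hold_idx]])
  res <- confusion_table(ass, true_unit, units = sort(unique(baseline$units)))
  res$assignments <- ass
  res$true_unit <- true_unit
  correct <- !is.na(ass$best_unit) & ass$best_unit == true_unit
  pass <- ass$passes_cutoff
  res$overall <- data.frame(
    accuracy_all = mean(correct[ass$scorable]),
    accuracy_cutoff = if (any(pass)) mean(correct[pass]) else NA_real_,
    proportion_assigned = mean(pass),
    n_holdout = length(hold_idx))
  res
}

#' Two-fold cross-validated assignment accuracy
#'
#' Fish are split at random into halves A and B, stratified by site so
#' that every site keeps references in both halves; A is assigned against
#' B's counts and vice versa, yielding two precision estimates per unit
#' per repeat (N = 2 x repeats in total).
#'
#' @param baseline a [gsi_baseline()] object.
#' @param panel_loci locus ids to use.
#' @param repeats number of repeats; default 10.
#' @param cutoff score cut-off; default 80.
#' @param seed integer seed.
#' @return list with `per_unit` (unit, mean/sd of precision and of
#'   proportion_assigned over the 2*repeats estimates), `estimates`
#'   (matrix units x 2*repeats of precision), and pooled confusion tables
#'   `table` / `table_cutoff` summed over all halves.
#' @export
twofold_cv <- function(baseline, panel_loci, repeats = 10, cutoff = 80,
                       seed = 1L) {
  set.seed(seed)
  h <- baseline$hierarchy
  g <- baseline$genotypes[, panel_loci, drop = FALSE]
  units <- sort(unique(baseline$units))
  u_of_site <- site_units(baseline)
  est <- matrix(NA_real_, length(units), 2 * repeats,
                dimnames = list(units, NULL))
  pa <- est
  tab <- matrix(0, length(units), length(units),
                dimnames = list(units, units))
  tab_cut <- tab

  for (rep_i in seq_len(repeats)) {
    in_a <- logical(nrow(g))
    for (ids in split(seq_len(nrow(g)), h$site)) {
      k <- length(ids)
      if (k == 1L) {        # lone fish alternates halves across repeats
        warning("site with a single fish in two-fold CV")
        in_a[ids] <- rep_i %% 2 == 0
      } else {
        in_a[sample(ids, floor(k / 2))] <- TRUE
      }
    }
    for (half in 1:2) {
      test <- if (half == 1) which(in_a) else which(!in_a)
      ref <- if (half == 1) which(!in_a) else which(in_a)
      counts <- counts_by_labels(g[ref, , drop = FALSE], h$site[ref], "site")
      ass <- assign_individuals(g[test, , drop = FALSE], counts, u_of_site,
                                cutoff)
      true_unit <- unname(baseline$units[h$river[test]])
      ct <- confusion_table(ass, true_unit, units)
      col <- 2 * (rep_i - 1) + half
      est[, col] <- ct$per_unit$precision
      pa[, col] <- ct$per_unit$proportion_assigned
      tab <- tab + ct$table
      tab_cut <- tab_cut + ct$table_cutoff
    }
  }
  per_unit <- data.frame(
    unit = units,
    precision_mean = rowMeans(est, na.rm = TRUE),
    precision_sd = apply(est, 1, stats::sd, na.rm = TRUE),
    proportion_assigned_mean = rowMeans(pa, na.rm = TRUE),
    stringsAsFactors = FALSE)
  rownames(per_unit) <- NULL
  list(per_unit = per_unit, estimates = est, table = tab,
       table_cutoff = tab_cut)
}

#' Monte-Carlo exclusion test for one individual against one unit
#'
#' Simulates `n_sim` genotypes from the unit's posterior-mean allele
#' frequencies (HWE per locus), scores them with the same
#' Rannala-Mountain likelihood as the test individual, and reports the
#' fraction of simulated likelihoods at or below the observed one — a
#' small p excludes the unit as origin. Diagnostic only; it does not gate
#' score-based assignment.
#'
#' @param genotype 0/1/2/NA codes over loci.
#' @param x_a,x_b reference allele counts of the unit per locus (the
#'   tested individual must not be included in them).
#' @param n_sim number of simulated genotypes; must be positive.
#' @param seed optional integer seed.
#' @return p-value: the fraction of simulated likelihoods at or below the
#'   observed one.
#' @export
exclusion_test <- function(genotype, x_a, x_b, n_sim = 1000, seed = NULL) {
  if (n_sim < 1) stop("n_sim must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ok <- !is.na(genotype)
  if (!any(ok)) stop("individual has no usable loci")
  x_a <- x_a[ok]; x_b <- x_b[ok]
  f <- (x_a + 0.5) / (x_a + x_b + 1)
  L <- length(f)
  sims <- matrix(stats::rbinom(n_sim * L, 2L, rep(f, each = n_sim)),
                 nrow = n_sim, ncol = L)
  lp <- log(rm_genotype_probs(x_a, x_b))        # L x 3
  obs <- sum(lp[cbind(seq_len(L), genotype[ok] + 1L)])
  sim_ll <- matrix(lp[cbind(rep(seq_len(L), each = n_sim),
                            as.vector(sims) + 1L)],
                   nrow = n_sim, ncol = L)
  sim_ll <- rowSums(sim_ll)
  mean(sim_ll <= obs)
}
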