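#' Call-rate locus filter
#'
#' Retains loci whose call rate is at least `threshold` (the rule is strict:
#' anything below the threshold is discarded) and whose class is SNP or
#' MSV-3.
#'
#' @param loci data.frame of locus metadata with `locus_id`, `snp_class`,
#'   `call_rate` columns (e.g. `baseline$loci`).
#' @param threshold minimum acceptable call rate; default 0.90.
#' @return list with `retained` and `removed` locus data.frames and a
#'   character `log` describing each removal.
#' @export
filter_call_rate <- function(loci, threshold = 0.90) {
  ok_class <- loci$snp_class %in% c("SNP", "MSV3")
  ok_rate <- loci$call_rate >= threshold
  keep <- ok_class & ok_rate
  log <- c(
    if (any(!ok_rate)) sprintf("removed %s: call rate %.3f < %.2f",
                               loci$locus_id[!ok_rate],
                               loci$call_rate[!ok_rate], threshold),
    if (any(!ok_class)) sprintf("removed %s: class %s not SNP/MSV3",
                                loci$locus_id[!ok_class],
                                loci$snp_class[!ok_class]))
  list(retained = loci[keep, , drop = FALSE],
       removed = loci[!keep, , drop = FALSE],
       log = if (is.null(log)) character(0) else log)
}

# Conditional distribution of the heterozygote count h given allele counts
# (n_a, n_b) in n individuals:
#   P(h | n_a, n_b) = n! / (n_aa! h! n_bb!) * 2^h / [ (2n)! / (n_a! n_b!) ]
# Support: h in {min parity .. min(n_a, n_b)}, stepping by 2, with
# n_aa = (n_a - h)/2 >= 0 and n_bb = (n_b - h)/2 >= 0.
hwe_het_distribution <- function(n_a, n_b) {
  n <- (n_a + n_b) / 2
  h <- seq.int(n_a %% 2, min(n_a, n_b), by = 2)
  n_aa <- (n_a - h) / 2
  n_bb <- (n_b - h) / 2
  logp <- lgamma(n + 1) - lgamma(n_aa + 1) - lgamma(h + 1) - lgamma(n_bb + 1) +
    h * log(2) - (lgamma(2 * n + 1) - lgamma(n_a + 1) - lgamma(n_b + 1))
  data.frame(h = h, prob = exp(logp))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test for a biallelic locus: conditioning on the
#' observed allele counts, the two-sided p-value sums the probabilities of
#' all heterozygote counts whose conditional probability does not exceed
#' that of the observed count (the standard exact-HWE convention).
#'
#' @param n_aa,n_ab,n_bb observed genotype counts.
#' @return p-value in (0, 1]. A monomorphic locus is uninformative and
#'   returns 1 with attribute `uninformative = TRUE`.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("at least one individual required")
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  if (n_a == 0 || n_b == 0)
    return(structure(1.0, uninformative = TRUE))
  d <- hwe_het_distribution(n_a, n_b)
  p_obs <- d$prob[d$h == n_ab]
  # tolerance guards ties computed in floating point
  min(1, sum(d$prob[d$prob <= p_obs * (1 + 1e-10)]))
}

#' Fisher's method for combining independent p-values
#'
#' @param pvals non-empty vector of p-values in (0, 1]; zeros are clipped
#'   to the smallest positive double.
#' @return list with the chi-square statistic `x2`, degrees of freedom `df`
#'   (= 2k) and the combined `p` (upper tail).
#' @export
combine_fisher <- function(pvals) {
  if (length(pvals) == 0) stop("no p-values to combine")
  if (any(pvals <= 0)) pvals <- pmax(pvals, .Machine$double.xmin)
  x2 <- -2 * sum(log(pvals))
  df <- 2L * length(pvals)
  list(x2 = x2, df = df, p = stats::pchisq(x2, df, lower.tail = FALSE))
}

#' Holm step-down (sequential Bonferroni) adjustment
#'
#' @param pvals non-empty vector of p-values.
#' @param alpha family-wise error rate for the reject flags.
#' @return list with `adjusted` p-values (same order as input) and logical
#'   `reject` flags (`adjusted < alpha`).
#' @export
holm_adjust <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0) stop("no p-values to adjust")
  adj <- stats::p.adjust(pvals, method = "holm")
  list(adjusted = adj, reject = adj < alpha)
}

#' Per-site Hardy-Weinberg screen
#'
#' For every site x locus combination, runs the exact HWE test on the
#' genotype counts at that site; per site, the per-locus p-values are
#' combined by Fisher's method into one site-level p; site-level p-values
#' are then Holm-adjusted across sites. Monomorphic (uninformative)
#' site-loci contribute p = 1 to the combination so that the degrees of
#' freedom stay comparable between sites; they are counted in the output.
#'
#' @param baseline a [gsi_baseline()] object.
#' @param alpha family-wise level for the site reject flags.
#' @return data.frame, one row per site: `site`, `n_loci`, `n_uninformative`,
#'   `x2`, `df`, `p_combined`, `p_adjusted`, `reject`.
#' @export
hwe_site_scan <- function(baseline, alpha = 0.05) {
  g <- baseline$genotypes
  sites <- unique(baseline$hierarchy$site)
  lab <- factor(baseline$hierarchy$site, levels = sites)
  obs <- !is.na(g)
  g0 <- g; g0[!obs] <- 0L
  n_aa <- rowsum((g0 == 2L & obs) + 0L, lab)
  n_ab <- rowsum((g0 == 1L & obs) + 0L, lab)
  n_bb <- rowsum((g0 == 0L & obs) + 0L, lab)

  res <- lapply(seq_along(sites), function(i) {
    ps <- vapply(seq_len(ncol(g)), function(j) {
      if (n_aa[i, j] + n_ab[i, j] + n_bb[i, j] == 0L) return(NA_real_)
      as.numeric(hwe_exact_p(n_aa[i, j], n_ab[i, j], n_bb[i, j]))
    }, numeric(1))
    uninf <- sum(vapply(seq_len(ncol(g)), function(j) {
      tot <- n_aa[i, j] + n_ab[i, j] + n_bb[i, j]
      tot > 0L && (2L * n_aa[i, j] + n_ab[i, j] == 0L ||
                   2L * n_bb[i, j] + n_ab[i, j] == 0L)
    }, logical(1)))
    ps <- ps[!is.na(ps)]
    fc <- combine_fisher(ps)
    data.frame(site = sites[i], n_loci = length(ps), n_uninformative = uninf,
               x2 = fc$x2, df = fc$df, p_combined = fc$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ha <- holm_adjust(out$p_combined, alpha)
  out$p_adjusted <- ha$adjusted
  out$reject <- ha$reject
  out
}
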