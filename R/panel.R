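# Weir-Cockerham (1984) variance components for one biallelic locus.
# Inputs are per-group vectors: n_i individuals genotyped, p_i A-allele
# frequency, h_i observed heterozygote proportion. Groups with no data are
# dropped by the caller. Returns c(a, b, c): between-population,
# between-individual-within-population, and within-individual components.
wc_components <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

#' Per-locus Weir-Cockerham theta
#'
#' The 1984 ratio-of-components estimator `theta = a / (a + b + c)` of F_ST
#' over the groups of a count table (typically rivers, pooling their
#' sites). Loci monomorphic across all groups, or observed in fewer than
#' two groups, have undefined theta and return `NA`. Negative estimates are
#' retained as-is; they simply rank last.
#'
#' @param counts an `allele_counts` object (with heterozygote counts, as
#'   produced by [counts_by_group()]).
#' @return named numeric vector of theta per locus (`NA` where undefined).
#' @export
wc_theta_per_locus <- function(counts) {
  comp <- wc_components_per_locus(counts)
  theta <- comp[, "a"] / (comp[, "a"] + comp[, "b"] + comp[, "c"])
  stats::setNames(theta, colnames(counts$n_a))
}

#' Multi-locus Weir-Cockerham theta
#'
#' Ratio-of-sums combination over loci, `sum(a) / sum(a + b + c)`, the
#' standard way to pool the per-locus variance components.
#'
#' @param counts an `allele_counts` object.
#' @return a single theta estimate.
#' @export
wc_theta_multilocus <- function(counts) {
  comp <- wc_components_per_locus(counts)
  ok <- stats::complete.cases(comp)
  sum(comp[ok, "a"]) / sum(comp[ok, c("a", "b", "c")])
}

wc_components_per_locus <- function(counts) {
  L <- ncol(counts$n_a)
  out <- matrix(NA_real_, L, 3, dimnames = list(colnames(counts$n_a),
                                                c("a", "b", "c")))
  for (l in seq_len(L)) {
    n <- counts$n[, l]
    use <- n > 0
    if (sum(use) < 2) next
    n_i <- n[use] / 2
    p_i <- counts$n_a[use, l] / n[use]
    if (all(p_i == 0) || all(p_i == 1)) next  # monomorphic across groups
    h_i <- counts$n_het[use, l] / n_i
    out[l, ] <- wc_components(n_i, p_i, h_i)
  }
  out
}

#' Rank loci by theta and cut nested panels
#'
#' Loci are ordered by descending theta (ties broken by locus id
#' ascending, so the ranking is reproducible); the panel of size m is the
#' first m loci, hence panels are nested. The default sizes are subsets or
#' multiples of 96, matching 96-well genotyping platforms.
#'
#' @param theta named vector from [wc_theta_per_locus()]; `NA` entries
#'   (undefined theta) are excluded from the ranking.
#' @param sizes panel sizes to expose; truncated (with a warning) to the
#'   number of rankable loci.
#' @return object of class `ranked_panel`: list with `ranking` (data.frame
#'   locus_id / theta / rank) and `sizes`; index with [panel_loci()].
#' @export
rank_and_select <- function(theta,
                            sizes = c(12, 24, 96, 192, 288, 384, 480)) {
  theta <- theta[!is.na(theta)]
  if (length(theta) == 0) stop("no loci with defined theta")
  ord <- order(-theta, names(theta))
  ranking <- data.frame(locus_id = names(theta)[ord],
                        theta = unname(theta[ord]),
                        rank = seq_along(ord), stringsAsFactors = FALSE)
  if (max(sizes) > nrow(ranking)) {
    warning(sprintf("only %d rankable loci; panel sizes truncated",
                    nrow(ranking)))
    sizes <- unique(pmin(sizes, nrow(ranking)))
  }
  structure(list(ranking = ranking, sizes = sizes), class = "ranked_panel")
}

#' Loci of a given panel size
#'
#' @param panel a `ranked_panel` from [rank_and_select()].
#' @param size panel size (any m up to the number of ranked loci).
#' @return character vector of the top `size` locus ids.
#' @export
panel_loci <- function(panel, size) {
  stopifnot(size >= 1, size <= nrow(panel$ranking))
  panel$ranking$locus_id[seq_len(size)]
}

#' @export
print.ranked_panel <- function(x, ...) {
  cat(sprintf("ranked_panel: %d loci, sizes %s\n", nrow(x$ranking),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Simplified F_ST outlier screen
#'
#' Loci under directional selection inflate theta and would be removed for
#' a neutral-only analysis. This screen models the neutral per-locus
#' statistic `theta * (r - 1) / mean_FST` as chi-square with `r - 1`
#' degrees of freedom, with the mean F_ST estimated as a trimmed mean of
#' theta (trimming keeps outliers from dragging the fit). Right-tail
#' p-values are converted to Benjamini-Hochberg q-values and loci with
#' `q < fdr` are flagged.
#'
#' @param theta named per-locus theta vector (`NA` ignored).
#' @param r number of groups theta was computed over.
#' @param trim fraction trimmed from each tail when estimating mean F_ST.
#' @param fdr flagging threshold on the q-value.
#' @return data.frame per locus: `locus_id`, `theta`, `p`, `q`, `outlier`,
#'   with the fitted mean as attribute `mean_fst`.
#' @export
detect_outlier_loci <- function(theta, r, trim = 0.05, fdr = 0.05) {
  if (r < 2) stop("need at least 2 groups")
  theta <- theta[!is.na(theta)]
  if (length(theta) < 50)
    warning("fewer than 50 loci; outlier screen is unreliable")
  fbar <- mean(theta, trim = trim)
  if (fbar <= 0) fbar <- max(mean(theta), 1e-6)
  stat <- theta * (r - 1) / fbar
  p <- stats::pchisq(stat, df = r - 1, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(locus_id = names(theta), theta = unname(theta),
                    p = unname(p), q = unname(q),
                    outlier = unname(q < fdr), stringsAsFactors = FALSE)
  attr(out, "mean_fst") <- fbar
  out
}

#' Descriptive rank comparison between SNP classes
#'
#' MSV-3 loci sit on duplicated genomic regions and could in principle
#' rank differently from ordinary SNPs; the classes are compared
#' descriptively (mean and median rank), with no inferential test.
#'
#' @param panel a `ranked_panel`.
#' @param loci locus metadata with `locus_id` and `snp_class`.
#' @return data.frame per class: n, mean_rank, median_rank.
#' @export
class_rank_summary <- function(panel, loci) {
  m <- merge(panel$ranking, loci[, c("locus_id", "snp_class")],
             by = "locus_id")
  do.call(rbind, lapply(split(m, m$snp_class), function(d)
    data.frame(snp_class = d$snp_class[1], n = nrow(d),
               mean_rank = mean(d$rank), median_rank = stats::median(d$rank),
               stringsAsFactors = FALSE)))
}
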