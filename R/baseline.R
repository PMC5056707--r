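#' Assemble a GSI baseline object
#'
#' A baseline bundles a diploid biallelic genotype matrix with the sampling
#' hierarchy (individual -> site -> river -> region) used throughout genetic
#' stock identification: allele-count extraction, locus ranking, assignment
#' and mixture analysis all resolve groups through it.
#'
#' @param genotypes integer matrix, individuals x loci; each cell counts
#'   copies of the designated A allele (0, 1, 2) with `NA` for missing.
#'   Row names are individual ids, column names locus ids.
#' @param hierarchy data.frame with columns `individual`, `site`, `river`
#'   and optionally `region`; one row per individual.
#' @param loci data.frame with columns `locus_id`, `snp_class`
#'   (`"SNP"` or `"MSV3"`), `call_rate`, and allele labels `allele_a`,
#'   `allele_b`. If `call_rate` is missing it is computed from `genotypes`.
#' @param units named character vector mapping each river to its assignment
#'   unit. Defaults to one unit per river (unit name = river name).
#' @param adjacency optional data.frame of undirected river pairs
#'   (columns `river1`, `river2`) encoding geographic neighbourhood.
#'
#' @return An object of class `gsi_baseline`: a list with elements
#'   `genotypes`, `hierarchy`, `loci`, `units`, `adjacency`.
#' @export
gsi_baseline <- function(genotypes, hierarchy, loci, units = NULL,
                         adjacency = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  stopifnot(is.data.frame(hierarchy),
            all(c("individual", "site", "river") %in% names(hierarchy)))
  hierarchy$individual <- as.character(hierarchy$individual)
  hierarchy$site <- as.character(hierarchy$site)
  hierarchy$river <- as.character(hierarchy$river)
  if (is.null(hierarchy$region)) hierarchy$region <- NA_character_

  if (anyDuplicated(hierarchy$individual))
    stop("duplicate individual ids in hierarchy")
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- hierarchy$individual
  if (!identical(sort(rownames(genotypes)), sort(hierarchy$individual)))
    stop("genotype rows and hierarchy individuals do not match")
  hierarchy <- hierarchy[match(rownames(genotypes), hierarchy$individual), ]

  # a site must sit in exactly one river, a river in one region
  s2r <- unique(hierarchy[, c("site", "river")])
  if (anyDuplicated(s2r$site)) stop("a site maps to more than one river")
  r2g <- unique(hierarchy[, c("river", "region")])
  if (anyDuplicated(r2g$river)) stop("a river maps to more than one region")

  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")

  loci <- as.data.frame(loci)
  stopifnot("locus_id" %in% names(loci))
  loci$locus_id <- as.character(loci$locus_id)
  if (anyDuplicated(loci$locus_id)) stop("duplicate locus ids")
  if (is.null(colnames(genotypes))) colnames(genotypes) <- loci$locus_id
  if (!identical(colnames(genotypes), loci$locus_id))
    loci <- loci[match(colnames(genotypes), loci$locus_id), ]
  if (is.null(loci$snp_class)) loci$snp_class <- "SNP"
  if (!all(loci$snp_class %in% c("SNP", "MSV3")))
    stop("snp_class must be 'SNP' or 'MSV3'")
  if (is.null(loci$call_rate))
    loci$call_rate <- colMeans(!is.na(genotypes))
  if (any(loci$call_rate < 0 | loci$call_rate > 1))
    stop("call_rate must lie in [0, 1]")
  if (is.null(loci$allele_a)) loci$allele_a <- "001"
  if (is.null(loci$allele_b)) loci$allele_b <- "002"

  rivers <- unique(hierarchy$river)
  if (is.null(units)) {
    units <- stats::setNames(rivers, rivers)
  } else {
    if (!all(rivers %in% names(units)))
      stop("units must cover every river in the hierarchy")
    units <- units[rivers]
  }

  if (!is.null(adjacency)) {
    adjacency <- as.data.frame(adjacency)
    names(adjacency)[1:2] <- c("river1", "river2")
    adjacency$river1 <- as.character(adjacency$river1)
    adjacency$river2 <- as.character(adjacency$river2)
  }

  structure(list(genotypes = genotypes, hierarchy = hierarchy, loci = loci,
                 units = units, adjacency = adjacency),
            class = "gsi_baseline")
}

#' @export
print.gsi_baseline <- function(x, ...) {
  h <- x$hierarchy
  cat(sprintf("gsi_baseline: %d individuals, %d loci\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  cat(sprintf("  %d sites, %d rivers, %d regions, %d assignment units\n",
              length(unique(h$site)), length(unique(h$river)),
              length(unique(h$region[!is.na(h$region)])),
              length(unique(x$units))))
  invisible(x)
}

#' Group label of every individual at a chosen level of the hierarchy
#'
#' @param baseline a [gsi_baseline()] object.
#' @param grouping one of `"site"`, `"river"`, `"unit"`, `"region"`.
#' @return character vector, one label per individual (genotype row order).
#' @export
group_labels <- function(baseline,
                         grouping = c("site", "river", "unit", "region")) {
  grouping <- match.arg(grouping)
  h <- baseline$hierarchy
  switch(grouping,
         site = h$site,
         river = h$river,
         unit = unname(baseline$units[h$river]),
         region = h$region)
}

#' Unit label of each site / river
#'
#' @param baseline a [gsi_baseline()] object.
#' @return named character vector site -> unit.
#' @export
site_units <- function(baseline) {
  s2r <- unique(baseline$hierarchy[, c("site", "river")])
  stats::setNames(unname(baseline$units[s2r$river]), s2r$site)
}

#' Subset a baseline to a set of individuals
#'
#' @param baseline a [gsi_baseline()] object.
#' @param individuals character vector of individual ids to keep.
#' @return a new `gsi_baseline` (call rates are recomputed).
#' @export
subset_individuals <- function(baseline, individuals) {
  keep <- rownames(baseline$genotypes) %in% individuals
  if (!any(keep)) stop("no individuals left after subsetting")
  loci <- baseline$loci
  loci$call_rate <- NULL     # force recomputation on the subset
  gsi_baseline(baseline$genotypes[keep, , drop = FALSE],
               baseline$hierarchy[keep, , drop = FALSE],
               loci,
               units = baseline$units[unique(baseline$hierarchy$river[keep])],
               adjacency = baseline$adjacency)
}

#' Subset a baseline to a set of loci
#'
#' @param baseline a [gsi_baseline()] object.
#' @param locus_ids character vector of locus ids to keep (order preserved).
#' @return a new `gsi_baseline`.
#' @export
subset_loci <- function(baseline, locus_ids) {
  stopifnot(all(locus_ids %in% colnames(baseline$genotypes)))
  gsi_baseline(baseline$genotypes[, locus_ids, drop = FALSE],
               baseline$hierarchy,
               baseline$loci[match(locus_ids, baseline$loci$locus_id), ],
               units = baseline$units, adjacency = baseline$adjacency)
}

#' Observed allele counts per group and locus
#'
#' Tallies, for every group at the requested hierarchy level, the number of
#' observed A and B allele copies at each locus together with the number of
#' genotyped individuals and observed heterozygotes (needed by the
#' Weir-Cockerham estimator). Missing genotypes remove both gene copies, so
#' the gene count `n` is always even.
#'
#' @param baseline a [gsi_baseline()] object.
#' @param grouping `"site"`, `"river"`, `"unit"` or `"region"`.
#' @return An object of class `allele_counts`: list with matrices
#'   `n_a`, `n` (gene counts) and `n_het` (heterozygote individuals), all
#'   groups x loci, plus the `grouping` used.
#' @export
counts_by_group <- function(baseline,
                            grouping = c("site", "river", "unit", "region")) {
  grouping <- match.arg(grouping)
  labels <- group_labels(baseline, grouping)
  counts_by_labels(baseline$genotypes, labels, grouping)
}

# Core tally used by counts_by_group and by the evaluators, which group
# arbitrary subsets of individuals.
counts_by_labels <- function(genotypes, labels, grouping = "custom") {
  labels <- factor(labels, levels = unique(labels))
  g <- genotypes
  obs <- !is.na(g)
  g0 <- g
  g0[!obs] <- 0L
  n_a <- rowsum(g0, labels)
  n <- 2L * rowsum(obs + 0L, labels)
  n_het <- rowsum((g0 == 1L & obs) + 0L, labels)
  structure(list(n_a = n_a, n = n, n_het = n_het, grouping = grouping),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("allele_counts (%s level): %d groups x %d loci\n",
              x$grouping, nrow(x$n_a), ncol(x$n_a)))
  invisible(x)
}

#' Observed allele frequencies from an allele-count table
#'
#' @param counts an `allele_counts` object.
#' @return matrix of A-allele frequencies (groups x loci); `NaN` where a
#'   group has no genotyped individuals at a locus.
#' @export
allele_freqs <- function(counts) {
  counts$n_a / counts$n
}

#' Posterior-mean allele frequencies
#'
#' Mean of the Dirichlet(1/2, 1/2) posterior given observed counts:
#' `(n_A + 1/2) / (n + 1)`. Never exactly 0 or 1, so downstream likelihoods
#' stay finite. This is the same per-locus prior used by the
#' Rannala-Mountain assignment likelihood.
#'
#' @param counts an `allele_counts` object.
#' @return matrix of frequencies (groups x loci).
#' @export
posterior_mean_freqs <- function(counts) {
  (counts$n_a + 0.5) / (counts$n + 1)
}

# Collapse a count table onto a coarser partition of its groups.
# `map` is a named vector old-group -> new-group.
collapse_counts <- function(counts, map) {
  stopifnot(all(rownames(counts$n_a) %in% names(map)))
  lab <- factor(map[rownames(counts$n_a)],
                levels = unique(map[rownames(counts$n_a)]))
  structure(list(n_a = rowsum(counts$n_a, lab),
                 n = rowsum(counts$n, lab),
                 n_het = rowsum(counts$n_het, lab),
                 grouping = "collapsed"),
            class = "allele_counts")
}
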