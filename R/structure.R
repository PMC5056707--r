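#' Nei's D_A distance between two allele-frequency vectors
#'
#' For biallelic loci, `D_A = 1 - (1/L) * sum_l (sqrt(x_l y_l) +
#' sqrt((1-x_l)(1-y_l)))` where `x_l`, `y_l` are A-allele frequencies.
#' Loci with no observed genes in either group (frequency `NaN`) are
#' excluded from the average. D_A is symmetric but not a metric (the
#' triangle inequality can fail), which is fine for ordination.
#'
#' @param x,y per-locus A-allele frequency vectors over the same loci.
#' @return D_A in `[0, 1]`.
#' @export
nei_da <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (!any(ok)) stop("no shared informative loci")
  x <- x[ok]; y <- y[ok]
  1 - mean(sqrt(x * y) + sqrt((1 - x) * (1 - y)))
}

#' Pairwise D_A matrix between groups
#'
#' @param counts an `allele_counts` object (typically at site level).
#' @return symmetric matrix of D_A values with zero diagonal.
#' @export
nei_da_matrix <- function(counts) {
  f <- allele_freqs(counts)
  g <- nrow(f)
  d <- matrix(0, g, g, dimnames = list(rownames(f), rownames(f)))
  for (i in seq_len(g - 1)) for (j in (i + 1):g)
    d[i, j] <- d[j, i] <- nei_da(f[i, ], f[j, ])
  d
}

#' Principal coordinates analysis (classical MDS)
#'
#' Torgerson scaling of a distance matrix: double-centre `-D^2/2`,
#' eigendecompose, and scale eigenvectors by the square root of their
#' (positive) eigenvalues. Negative eigenvalues — expected when the
#' distance is non-Euclidean, as D_A can be — are reported but excluded
#' from the coordinates.
#'
#' @param dm square symmetric distance matrix.
#' @param n_axes number of axes to return (capped at the number of
#'   positive eigenvalues).
#' @return list with `coords` (groups x axes) and `eigenvalues`
#'   (all of them, descending).
#' @export
pcoa <- function(dm, n_axes = 2) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-8))
    stop("distance matrix must be square and symmetric")
  k <- min(n_axes, nrow(dm) - 1)
  # cmdscale warns when fewer than k eigenvalues are positive; the axis
  # count is corrected below from the spectrum
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = k,
                                          eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- sum(fit$eig > 1e-12)
  coords <- fit$points[, seq_len(min(k, max(pos, 0))), drop = FALSE]
  if (is.null(coords) || ncol(coords) == 0)
    coords <- matrix(0, nrow(dm), 0, dimnames = list(rownames(dm), NULL))
  rownames(coords) <- rownames(dm)
  list(coords = coords, eigenvalues = eig)
}

#' Flag outlier sites in ordination space
#'
#' Sites far from the bulk of the baseline distort locus ranking, so they
#' are flagged for removal before panel selection (and returned to the
#' data afterwards). The default rule works on ordination axes 1-2: a site
#' is flagged when its Euclidean distance from the coordinate-wise median
#' exceeds the median distance plus `k_mad` MADs.
#'
#' @param coords site coordinates (axes in columns; axes 1-2 used).
#' @param k_mad multiplier on the MAD; default 3.
#' @param manual optional character vector of site ids that overrides the
#'   automatic rule entirely.
#' @return character vector of flagged site ids (possibly empty).
#' @export
flag_outlier_sites <- function(coords, k_mad = 3, manual = NULL) {
  if (!is.null(manual)) return(manual)
  if (nrow(coords) < 4) {
    warning("fewer than 4 sites; no outlier flags")
    return(character(0))
  }
  xy <- coords[, seq_len(min(2, ncol(coords))), drop = FALSE]
  centre <- apply(xy, 2, stats::median)
  d <- sqrt(rowSums(sweep(xy, 2, centre)^2))
  thr <- stats::median(d) + k_mad * stats::mad(d)
  rownames(coords)[d > thr]
}

#' K-means scan over principal components with BIC model choice
#'
#' Runs PCA on the mean-imputed genotype dosage matrix, then k-means for
#' `k = 1..k_max` on the leading components, scoring each solution with
#' `BIC(k) = n log(WSS_k / n) + k log(n)`. The chosen k is the elbow:
#' the smallest k whose improvement to k+1 falls below 5% of the BIC range
#' of the scan. Mean imputation is used for the PCA only, never for
#' likelihood computations.
#'
#' @param baseline a [gsi_baseline()] object.
#' @param k_max largest number of clusters scanned.
#' @param n_pcs number of principal components used; default: enough to
#'   explain 90% of variance.
#' @param n_restarts random restarts per k.
#' @param seed integer seed for the restarts.
#' @return list with `scan` (data.frame k / wss / bic), `chosen_k`,
#'   `labels` (per individual, at chosen k) and `n_pcs`.
#' @export
kmeans_bic_scan <- function(baseline, k_max = 10, n_pcs = NULL,
                            n_restarts = 20, seed = 1L) {
  if (k_max < 1) stop("k_max must be >= 1")
  g <- baseline$genotypes
  mu <- colMeans(g, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  gi <- g
  for (j in seq_len(ncol(gi))) gi[is.na(gi[, j]), j] <- mu[j]
  gi <- gi[, apply(gi, 2, stats::var) > 0, drop = FALSE]
  pc <- stats::prcomp(gi, center = TRUE, scale. = FALSE)
  if (is.null(n_pcs)) {
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    n_pcs <- max(1L, which(cum >= 0.90)[1])
  }
  n_pcs <- min(n_pcs, ncol(pc$x))
  x <- pc$x[, seq_len(n_pcs), drop = FALSE]
  n <- nrow(x)
  k_max <- min(k_max, n)

  set.seed(seed)
  fits <- lapply(seq_len(k_max), function(k)
    stats::kmeans(x, centers = k, nstart = n_restarts, iter.max = 100))
  wss <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  bic <- n * log(pmax(wss, 1e-12) / n) + seq_len(k_max) * log(n)

  rng <- diff(range(bic))
  chosen <- k_max
  if (k_max > 1 && rng > 0) {
    for (k in seq_len(k_max - 1)) {
      if (bic[k] - bic[k + 1] < 0.05 * rng) { chosen <- k; break }
    }
  } else if (rng == 0) chosen <- 1L

  labels <- stats::setNames(fits[[chosen]]$cluster, rownames(g))
  list(scan = data.frame(k = seq_len(k_max), wss = wss, bic = bic),
       chosen_k = chosen, labels = labels, n_pcs = n_pcs)
}

#' Majority cluster label per river (or unit)
#'
#' @param baseline a [gsi_baseline()] object.
#' @param labels per-individual cluster labels from [kmeans_bic_scan()].
#' @param grouping `"river"` or `"unit"`.
#' @return named integer vector group -> modal cluster label.
#' @export
cluster_labels_by_group <- function(baseline, labels, grouping = "river") {
  grp <- group_labels(baseline, grouping)
  tab <- table(grp, labels[rownames(baseline$genotypes)])
  stats::setNames(as.integer(colnames(tab)[apply(tab, 1, which.max)]),
                  rownames(tab))
}
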