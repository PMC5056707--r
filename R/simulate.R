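#' Configuration for the hierarchical baseline simulator
#'
#' The simulator draws allele frequencies down a region -> river -> site
#' hierarchy under the Balding-Nichols F-model: at each level the daughter
#' frequency is Beta-distributed around its parent with a differentiation
#' parameter F, i.e. `Beta(p(1-F)/F, (1-p)(1-F)/F)`, which has mean `p` and
#' F_ST-like variance `F p (1-p)`. `F = 0` copies the parent frequency
#' exactly, so the hierarchy is exactly nested.
#'
#' The default scenario ("demo18") is a desk-scale stand-in for a national
#' salmon baseline: 6 regions x 3 rivers x 2 sites x 24 fish at 300 loci,
#' with moderate differentiation between regions and rivers
#' (F = 0.03 at each level) and weak differentiation between sites of a
#' river (F = 0.005).
#'
#' @param n_regions,rivers_per_region,sites_per_river,fish_per_site
#'   dimensions of the sampling hierarchy.
#' @param n_loci number of biallelic loci.
#' @param F_region,F_river,F_site Balding-Nichols differentiation at each
#'   level, each in `[0, 1)`.
#' @param ancestral_freq_range interval from which ancestral A-allele
#'   frequencies are drawn uniformly; a subset of (0, 1).
#' @param missing_rate i.i.d. probability that a genotype call is missing.
#' @param msv3_fraction fraction of loci labelled MSV-3 (a SNP residing on
#'   one paralogue of a duplicated region; metadata only, no computation
#'   differs by class).
#' @param seed integer seed; the simulation is fully reproducible from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_regions = 6, rivers_per_region = 3,
                       sites_per_river = 2, fish_per_site = 24,
                       n_loci = 300,
                       F_region = 0.03, F_river = 0.03, F_site = 0.005,
                       ancestral_freq_range = c(0.1, 0.9),
                       missing_rate = 0.02, msv3_fraction = 0.16,
                       seed = 1L) {
  cfg <- list(n_regions = n_regions, rivers_per_region = rivers_per_region,
              sites_per_river = sites_per_river, fish_per_site = fish_per_site,
              n_loci = n_loci, F_region = F_region, F_river = F_river,
              F_site = F_site, ancestral_freq_range = ancestral_freq_range,
              missing_rate = missing_rate, msv3_fraction = msv3_fraction,
              seed = as.integer(seed))
  for (f in c("F_region", "F_river", "F_site"))
    if (cfg[[f]] < 0 || cfg[[f]] >= 1)
      stop(sprintf("config error: %s must lie in [0, 1)", f))
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("config error: missing_rate must lie in [0, 1)")
  if (cfg$msv3_fraction < 0 || cfg$msv3_fraction > 1)
    stop("config error: msv3_fraction must lie in [0, 1]")
  r <- cfg$ancestral_freq_range
  if (length(r) != 2 || r[1] <= 0 || r[2] >= 1 || r[1] > r[2])
    stop("config error: ancestral_freq_range must be an interval within (0,1)")
  if (cfg$n_loci < 1 || cfg$fish_per_site < 1)
    stop("config error: n_loci and fish_per_site must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

# One Balding-Nichols draw per element of p; F = 0 returns p unchanged.
bn_draw <- function(p, F) {
  if (F == 0) return(p)
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

#' Simulate a hierarchical SNP baseline with known structure
#'
#' Draws ancestral allele frequencies, pushes them through the
#' region/river/site Balding-Nichols hierarchy of `cfg`, genotypes
#' `fish_per_site` fish per site as Binomial(2, site frequency), and knocks
#' out calls i.i.d. at `missing_rate`. Row/column metadata and the true
#' frequency hierarchy are returned alongside.
#'
#' @param cfg a [sim_config()].
#' @return a [gsi_baseline()] with an extra element `truth` holding the
#'   ancestral, region, river and site frequency matrices used.
#' @export
simulate_baseline <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$n_loci
  regions <- sprintf("Reg%02d", seq_len(cfg$n_regions))
  rivers <- as.vector(t(outer(regions, seq_len(cfg$rivers_per_region),
                              function(g, i) sprintf("%s_R%d", g, i))))
  river_region <- rep(regions, each = cfg$rivers_per_region)
  sites <- as.vector(t(outer(rivers, seq_len(cfg$sites_per_river),
                             function(r, i) sprintf("%s_S%d", r, i))))
  site_river <- rep(rivers, each = cfg$sites_per_river)

  p_anc <- stats::runif(L, cfg$ancestral_freq_range[1],
                        cfg$ancestral_freq_range[2])
  p_region <- t(vapply(regions, function(g) bn_draw(p_anc, cfg$F_region),
                       numeric(L)))
  p_river <- t(vapply(seq_along(rivers), function(i)
    bn_draw(p_region[river_region[i], ], cfg$F_river), numeric(L)))
  rownames(p_river) <- rivers
  p_site <- t(vapply(seq_along(sites), function(i)
    bn_draw(p_river[site_river[i], ], cfg$F_site), numeric(L)))
  rownames(p_site) <- sites

  n_fish <- length(sites) * cfg$fish_per_site
  fish_site <- rep(sites, each = cfg$fish_per_site)
  ids <- paste0(fish_site, "_F",
                rep(seq_len(cfg$fish_per_site), times = length(sites)))
  geno <- matrix(stats::rbinom(n_fish * L, 2L,
                               p_site[fish_site, ]),
                 nrow = n_fish, ncol = L,
                 dimnames = list(ids, sprintf("L%04d", seq_len(L))))
  if (cfg$missing_rate > 0) {
    drop <- stats::runif(n_fish * L) < cfg$missing_rate
    geno[drop] <- NA_integer_
  }

  snp_class <- rep("SNP", L)
  n_msv <- round(cfg$msv3_fraction * L)
  if (n_msv > 0) snp_class[sample.int(L, n_msv)] <- "MSV3"

  hierarchy <- data.frame(
    individual = ids, site = fish_site,
    river = site_river[match(fish_site, sites)],
    region = river_region[match(site_river[match(fish_site, sites)], rivers)],
    stringsAsFactors = FALSE)
  loci <- data.frame(locus_id = colnames(geno), snp_class = snp_class,
                     allele_a = "001", allele_b = "002",
                     stringsAsFactors = FALSE)
  adjacency <- ring_adjacency(rivers)

  bl <- gsi_baseline(geno, hierarchy, loci, adjacency = adjacency)
  colnames(p_site) <- colnames(geno)
  colnames(p_river) <- colnames(geno)
  colnames(p_region) <- colnames(geno)
  rownames(p_region) <- regions
  bl$truth <- list(ancestral = p_anc, region = p_region,
                   river = p_river, site = p_site, config = cfg)
  bl
}

# Rivers listed in geographic order around a coastline: each river is
# adjacent to its list neighbours.
ring_adjacency <- function(rivers) {
  n <- length(rivers)
  if (n < 2) return(NULL)
  data.frame(river1 = rivers, river2 = rivers[c(2:n, 1L)],
             stringsAsFactors = FALSE)[seq_len(if (n == 2) 1L else n), ]
}

#' Simulate a fishery mixture of known composition
#'
#' Fish origins are multinomial over assignment units with probabilities
#' `pi_true`; each fish's genotype is Binomial(2, unit frequency) per locus.
#'
#' @param unit_freqs matrix of per-unit allele frequencies (units x loci).
#' @param pi_true named or ordered vector of mixture proportions over the
#'   rows of `unit_freqs`; must sum to 1.
#' @param n_fish number of fish in the mixture sample.
#' @param seed optional integer seed (omit to use the current RNG stream).
#' @return list with `genotypes` (n_fish x loci), `truth` (data.frame
#'   individual/unit), `pi_true` and `realized_counts` (the multinomial draw).
#' @export
simulate_mixture <- function(unit_freqs, pi_true, n_fish, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  units <- rownames(unit_freqs)
  if (is.null(units)) units <- paste0("unit", seq_len(nrow(unit_freqs)))
  if (!is.null(names(pi_true))) pi_true <- pi_true[units]
  if (any(pi_true < 0)) stop("config error: negative mixture proportions")
  if (abs(sum(pi_true) - 1) > 1e-8)
    stop("config error: mixture proportions must sum to 1")
  counts <- as.vector(stats::rmultinom(1L, n_fish, pi_true))
  origin <- rep(units, counts)
  L <- ncol(unit_freqs)
  geno <- matrix(stats::rbinom(n_fish * L, 2L, unit_freqs[origin, , drop = FALSE]),
                 nrow = n_fish, ncol = L,
                 dimnames = list(sprintf("mix_%04d", seq_len(n_fish)),
                                 colnames(unit_freqs)))
  list(genotypes = geno,
       truth = data.frame(individual = rownames(geno), unit = origin,
                          stringsAsFactors = FALSE),
       pi_true = stats::setNames(as.numeric(pi_true), units),
       realized_counts = stats::setNames(counts, units))
}
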