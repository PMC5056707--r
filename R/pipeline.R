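#' Pipeline configuration
#'
#' Collects every tunable of the six-step workflow with defaults matching
#' standard practice for SNP-baseline stock identification: call-rate
#' filter 0.90, HWE family-wise alpha 0.05, 6 hold-out fish per site,
#' panel sizes 12/24/96/192/288/384/480, score cut-off 80, unit accuracy
#' threshold 0.80, 10 CV repeats, and 1000-replicate mixture simulations
#' of 200 (100%) or 1000 (fishery) fish.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param call_rate_threshold minimum locus call rate.
#' @param hwe_alpha family-wise level of the per-site HWE screen.
#' @param per_site_holdout hold-out fish per site.
#' @param panel_sizes nested panel sizes evaluated for the accuracy curve.
#' @param eval_panel_size panel used for unit definition and simulations.
#' @param cutoff assignment score cut-off.
#' @param unit_threshold per-unit accuracy threshold.
#' @param cv_repeats two-fold CV repeats.
#' @param sim_B mixture simulation replicates.
#' @param mix_size_100pct,mix_size_fishery fish per simulated mixture.
#' @param k_max cluster-scan bound.
#' @param max_iter unit-iteration cap.
#' @param neutral_only drop F_ST-outlier loci before ranking.
#' @param outlier_sites manual outlier-site override (character vector),
#'   or `NULL` for the automatic MAD rule.
#' @param unit_overrides manual unit decisions (see [merge_step()]).
#' @return a `gsi_pipeline_config` list.
#' @export
gsi_pipeline_config <- function(seed = 1L,
                                call_rate_threshold = 0.90,
                                hwe_alpha = 0.05,
                                per_site_holdout = 6,
                                panel_sizes = c(12, 24, 96, 192, 288, 384, 480),
                                eval_panel_size = 288,
                                cutoff = 80,
                                unit_threshold = 0.80,
                                cv_repeats = 10,
                                sim_B = 1000,
                                mix_size_100pct = 200,
                                mix_size_fishery = 1000,
                                k_max = 8,
                                max_iter = 10,
                                neutral_only = FALSE,
                                outlier_sites = NULL,
                                unit_overrides = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$call_rate_threshold >= 0, cfg$call_rate_threshold <= 1,
            cfg$hwe_alpha > 0, cfg$hwe_alpha < 1,
            cfg$cutoff >= 0, cfg$cutoff <= 100,
            cfg$unit_threshold > 0, cfg$unit_threshold <= 1)
  class(cfg) <- "gsi_pipeline_config"
  cfg
}

#' Run the full stock-identification workflow on a baseline
#'
#' Executes, in order: locus QC (call rate, per-site HWE screen),
#' outlier-site flagging on the D_A ordination, hold-out split, F_ST locus
#' ranking on training fish (outlier sites excluded from ranking but
#' returned for evaluation), accuracy-vs-panel-size curves, regional
#' k-means scan, iterative assignment-unit definition with re-ranking,
#' final hold-out + two-fold CV evaluation on the definitive units, and
#' 100% plus equal-proportion fishery mixture simulations. With
#' `neutral_only = TRUE` the F_ST-outlier loci are removed before ranking.
#'
#' @param baseline a [gsi_baseline()] object.
#' @param cfg a [gsi_pipeline_config()].
#' @return a list of stage results (see element names); `log` records the
#'   seed, stage decisions and removals.
#' @export
run_gsi_pipeline <- function(baseline, cfg = gsi_pipeline_config()) {
  log <- c(sprintf("seed: %d", cfg$seed))

  ## QC ----------------------------------------------------------------
  qc <- filter_call_rate(baseline$loci, cfg$call_rate_threshold)
  log <- c(log, sprintf("call-rate filter: %d of %d loci retained",
                        nrow(qc$retained), nrow(baseline$loci)))
  bl <- subset_loci(baseline, qc$retained$locus_id)
  hwe <- hwe_site_scan(bl, alpha = cfg$hwe_alpha)
  hwe_sites <- hwe$site[hwe$reject]
  log <- c(log, sprintf("HWE screen: %d site(s) rejected", length(hwe_sites)))

  ## outlier sites on the D_A ordination --------------------------------
  site_counts <- counts_by_group(bl, "site")
  dm <- nei_da_matrix(site_counts)
  ord <- pcoa(dm, n_axes = 2)
  flagged <- flag_outlier_sites(ord$coords, manual = cfg$outlier_sites)
  drop_sites <- union(flagged, hwe_sites)
  log <- c(log, sprintf("outlier sites flagged: %s",
                        if (length(drop_sites)) paste(drop_sites, collapse = ", ")
                        else "none"))

  ## hold-out split and ranking (outlier sites out of the ranking only) --
  split <- holdout_split(bl, cfg$per_site_holdout, seed = cfg$seed)
  h <- bl$hierarchy
  rank_ids <- split$train[!(h$site[match(split$train, h$individual)]
                            %in% drop_sites)]
  rank_bl <- subset_individuals(bl, rank_ids)
  theta <- wc_theta_per_locus(counts_by_group(rank_bl, "river"))

  outliers <- detect_outlier_loci(theta, r = length(unique(h$river)))
  if (cfg$neutral_only) {
    drop_loci <- outliers$locus_id[outliers$outlier]
    theta <- theta[!(names(theta) %in% drop_loci)]
    log <- c(log, sprintf("neutral-only: %d outlier loci removed",
                          length(drop_loci)))
  }
  sizes <- cfg$panel_sizes[cfg$panel_sizes <= sum(!is.na(theta))]
  if (length(sizes) == 0) sizes <- sum(!is.na(theta))
  panel <- rank_and_select(theta, sizes = sizes)

  ## accuracy vs panel size ---------------------------------------------
  curve <- do.call(rbind, lapply(panel$sizes, function(m) {
    ev <- evaluate_holdout(bl, split, panel_loci(panel, m), cfg$cutoff)
    cbind(data.frame(panel_size = m), ev$overall)
  }))

  ## regional clustering -------------------------------------------------
  km <- kmeans_bic_scan(bl, k_max = cfg$k_max, seed = cfg$seed + 1L)
  log <- c(log, sprintf("k-means scan: chosen k = %d", km$chosen_k))

  ## iterative unit definition -------------------------------------------
  size0 <- min(cfg$eval_panel_size, sum(!is.na(theta)))
  units_res <- iterate_units(bl, panel_size = size0,
                             threshold = cfg$unit_threshold,
                             cutoff = cfg$cutoff, repeats = cfg$cv_repeats,
                             max_iter = cfg$max_iter,
                             per_site_holdout = cfg$per_site_holdout,
                             k_max = cfg$k_max, seed = cfg$seed,
                             overrides = cfg$unit_overrides)
  final_bl <- units_res$baseline
  log <- c(log, sprintf("unit definition: %d river(s) -> %d unit(s) in %d iteration(s)",
                        length(unique(names(final_bl$units))),
                        length(unique(final_bl$units)),
                        units_res$iterations))

  ## mixture simulations on the final units ------------------------------
  final_size <- min(cfg$eval_panel_size, nrow(units_res$panel$ranking))
  final_loci <- panel_loci(units_res$panel, final_size)
  unit_counts <- counts_by_group(subset_loci(final_bl, final_loci), "unit")
  s100 <- sim_100pct(unit_counts, B = cfg$sim_B,
                     mix_size = cfg$mix_size_100pct, seed = cfg$seed + 2L)
  units <- rownames(unit_counts$n_a)
  pi_eq <- stats::setNames(rep(1 / length(units), length(units)), units)
  fishery <- sim_fishery(unit_counts, pi_eq, B = cfg$sim_B,
                         mix_size = cfg$mix_size_fishery,
                         seed = cfg$seed + 3L)

  list(config = cfg,
       qc = qc, hwe = hwe,
       distance = dm, ordination = ord, outlier_sites = flagged,
       split = split, theta = theta, locus_outliers = outliers,
       panel = panel, accuracy_curve = curve,
       clusters = km,
       units = units_res,
       final_evaluation = units_res$evaluations,
       sim_100pct = s100, sim_fishery = fishery$summary,
       log = log)
}

#' Write the main pipeline tables to a directory
#'
#' @param result list from [run_gsi_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths written.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) {
    p <- file.path(dir, f)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    wt(result$hwe, "hwe_sites.tsv"),
    wt(result$panel$ranking, "panel_ranking.tsv"),
    wt(result$accuracy_curve, "accuracy_curve.tsv"),
    wt(result$clusters$scan, "bic_scan.tsv"),
    wt(do.call(rbind, result$units$ledgers), "unit_ledger.tsv"),
    wt(data.frame(river = names(result$units$partition),
                  unit = unname(result$units$partition)),
       "final_units.tsv"),
    wt(result$sim_100pct, "sim_100pct.tsv"),
    wt(result$sim_fishery, "sim_fishery.tsv"))
  writeLines(result$log, file.path(dir, "pipeline_log.txt"))
  invisible(c(paths, file.path(dir, "pipeline_log.txt")))
}
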