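#' Reciprocal misassignment graph between assignment units
#'
#' Edge weight between units u and v is the symmetric misassignment rate,
#' averaged over the two evaluation methods:
#' `[mis(u -> v) + mis(v -> u)] / [fish from u + fish from v]`,
#' computed on the cut-off-filtered confusion tables. Heavy edges identify
#' the natural merge partners when a unit fails the accuracy threshold.
#'
#' @param ct_holdout,ct_tfcv cut-off-filtered confusion count matrices
#'   (true x assigned) on the same unit partition, from
#'   [evaluate_holdout()] (`$table_cutoff`) and [twofold_cv()].
#' @return symmetric weight matrix over units (zero diagonal).
#' @export
misassignment_graph <- function(ct_holdout, ct_tfcv) {
  if (!identical(dimnames(ct_holdout), dimnames(ct_tfcv)))
    stop("confusion tables are not on the same unit partition")
  one <- function(tb) {
    fish <- rowSums(tb)
    u <- nrow(tb)
    w <- matrix(0, u, u, dimnames = dimnames(tb))
    for (i in seq_len(u)) for (j in seq_len(u)) {
      if (i == j) next
      den <- fish[i] + fish[j]
      w[i, j] <- if (den > 0) (tb[i, j] + tb[j, i]) / den else 0
    }
    w
  }
  (one(ct_holdout) + one(ct_tfcv)) / 2
}

#' One keep/merge decision pass over the current units
#'
#' Applies the dual-method accuracy rules, in order, to every unit:
#' (1) both precisions at or above `threshold` -> keep;
#' (2) both below -> merge with the admissible neighbour (same regional
#' cluster AND geographically adjacent if any, else same cluster) carrying
#' the heaviest misassignment edge;
#' (3) exactly one above -> "case_by_case": kept by default when the
#' failing estimate is within `margin` of the threshold, else merged as in
#' (2). Every decision is written to a ledger for manual override. A
#' sub-threshold unit with no admissible partner is kept and flagged
#' isolated. Undefined precision (no fish assigned) counts as failing.
#'
#' @param precision_holdout,precision_tfcv named vectors of per-unit
#'   precision from the two methods.
#' @param weights misassignment weight matrix from [misassignment_graph()].
#' @param cluster named vector unit -> regional cluster label.
#' @param adjacency_units optional data.frame of adjacent unit pairs
#'   (columns `unit1`, `unit2`).
#' @param threshold accuracy threshold; default 0.80.
#' @param margin case-by-case keep margin below threshold; default 0.05.
#' @param overrides optional named character vector unit -> "keep" or the
#'   name of a unit to merge with; wins over every rule.
#' @return list with `partition` (named vector old unit -> new unit) and
#'   `ledger` (data.frame: unit, precision_holdout, precision_tfcv,
#'   decision, target, evidence).
#' @export
merge_step <- function(precision_holdout, precision_tfcv, weights, cluster,
                       adjacency_units = NULL, threshold = 0.80,
                       margin = 0.05, overrides = NULL) {
  units <- names(precision_holdout)
  stopifnot(identical(units, names(precision_tfcv)),
            all(units %in% rownames(weights)),
            all(units %in% names(cluster)))
  ph <- ifelse(is.na(precision_holdout), -Inf, precision_holdout)
  pt <- ifelse(is.na(precision_tfcv), -Inf, precision_tfcv)

  adj <- matrix(FALSE, length(units), length(units),
                dimnames = list(units, units))
  if (!is.null(adjacency_units) && nrow(adjacency_units) > 0) {
    for (i in seq_len(nrow(adjacency_units))) {
      a <- adjacency_units[i, 1]; b <- adjacency_units[i, 2]
      if (a %in% units && b %in% units && a != b)
        adj[a, b] <- adj[b, a] <- TRUE
    }
  }

  pick_partner <- function(u) {
    others <- setdiff(units, u)
    same_cl <- others[cluster[others] == cluster[u]]
    cand <- same_cl[adj[u, same_cl]]
    if (length(cand) == 0) cand <- same_cl
    if (length(cand) == 0) return(NA_character_)
    w <- weights[u, cand]
    cand[order(-w, cand)][1]           # heaviest edge, ties by unit id
  }

  decision <- character(length(units)); names(decision) <- units
  target <- rep(NA_character_, length(units)); names(target) <- units
  evidence <- character(length(units)); names(evidence) <- units

  for (u in units) {
    ov <- if (!is.null(overrides) && u %in% names(overrides))
      overrides[[u]] else NULL
    if (!is.null(ov)) {
      if (identical(ov, "keep")) {
        decision[u] <- "keep"; evidence[u] <- "manual override"
      } else {
        decision[u] <- "merge"; target[u] <- ov
        evidence[u] <- "manual override"
      }
      next
    }
    both_ok <- ph[u] >= threshold && pt[u] >= threshold
    both_bad <- ph[u] < threshold && pt[u] < threshold
    if (both_ok) {
      decision[u] <- "keep"
    } else if (both_bad) {
      p <- pick_partner(u)
      if (is.na(p)) {
        decision[u] <- "keep"
        evidence[u] <- "isolated: no admissible merge partner"
        warning(sprintf("unit %s below threshold but isolated", u))
      } else {
        decision[u] <- "merge"; target[u] <- p
        evidence[u] <- sprintf("max reciprocal misassignment %.4f",
                               weights[u, p])
      }
    } else {
      low <- min(ph[u], pt[u])
      if (low >= threshold - margin) {
        decision[u] <- "case_by_case_keep"
        evidence[u] <- sprintf("failing estimate %.3f within %.2f of %.2f",
                               low, margin, threshold)
      } else {
        p <- pick_partner(u)
        if (is.na(p)) {
          decision[u] <- "case_by_case_keep"
          evidence[u] <- "isolated: no admissible merge partner"
        } else {
          decision[u] <- "case_by_case_merge"; target[u] <- p
          evidence[u] <- sprintf(
            "failing estimate %.3f; max misassignment %.4f", low,
            weights[u, p])
        }
      }
    }
  }

  partition <- union_merge(units, decision, target)
  ledger <- data.frame(unit = units,
                       precision_holdout = unname(precision_holdout[units]),
                       precision_tfcv = unname(precision_tfcv[units]),
                       decision = unname(decision),
                       target = unname(target),
                       evidence = unname(evidence),
                       stringsAsFactors = FALSE)
  list(partition = partition, ledger = ledger)
}

# Union-find over units: each merge decision links a unit to its target;
# chains and mutual picks collapse into one new unit named by its sorted
# members joined with "+".
union_merge <- function(units, decision, target) {
  parent <- stats::setNames(seq_along(units), units)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (u in units) {
    if (grepl("merge", decision[u]) && !is.na(target[u])) {
      ri <- find(match(u, units)); rj <- find(match(target[u], units))
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_along(units), find, numeric(1))
  new_name <- vapply(seq_along(units), function(i) {
    members <- sort(units[root == root[i]])
    paste(members, collapse = "+")
  }, character(1))
  stats::setNames(new_name, units)
}

#' Replay a decision ledger to reproduce a partition
#'
#' Audit helper: the ledger rows of one [merge_step()] contain everything
#' needed to rebuild its output partition.
#'
#' @param ledger data.frame as returned in `merge_step()$ledger`.
#' @return named vector old unit -> new unit, identical to the original
#'   `partition`.
#' @export
replay_ledger <- function(ledger) {
  union_merge(ledger$unit,
              stats::setNames(ledger$decision, ledger$unit),
              stats::setNames(ledger$target, ledger$unit))
}

#' Iterative definition of assignment units
#'
#' Starting from one unit per river, repeatedly: evaluate per-unit
#' precision with both the hold-out/training and two-fold cross-validation
#' methods on the current panel, apply [merge_step()], and — whenever the
#' partition changed — re-rank loci on the new units and re-evaluate.
#' Stops at a fixed point (all units kept) or after `max_iter` iterations
#' (then flagged non-converged). Unit count never increases, so the loop
#' terminates in at most one iteration per river.
#'
#' The hold-out split is drawn once and reused across iterations; locus
#' ranking always uses training fish only.
#'
#' @param baseline a [gsi_baseline()] object (units taken as the initial
#'   partition; default is one per river).
#' @param panel_size number of top-ranked loci used for evaluation.
#' @param threshold per-unit accuracy threshold; default 0.80.
#' @param margin case-by-case keep margin; default 0.05.
#' @param cutoff assignment score cut-off; default 80.
#' @param repeats two-fold CV repeats per iteration.
#' @param max_iter iteration cap.
#' @param per_site_holdout hold-out fish per site.
#' @param k_max cluster scan bound for the regional k-means labels.
#' @param seed integer seed driving the split, CV and clustering.
#' @param overrides optional per-unit manual decisions (see [merge_step()]).
#' @return list with `baseline` (units updated to the final partition),
#'   `partition` (river -> final unit), `ledgers` (one per iteration),
#'   `panel` (re-ranked on the final units), `evaluations` (final holdout
#'   and CV results), `iterations`, `converged`.
#' @export
iterate_units <- function(baseline, panel_size = 288, threshold = 0.80,
                          margin = 0.05, cutoff = 80, repeats = 10,
                          max_iter = 10, per_site_holdout = 6, k_max = 8,
                          seed = 1L, overrides = NULL) {
  split <- holdout_split(baseline, per_site_holdout, seed = seed)
  km <- kmeans_bic_scan(baseline, k_max = k_max, seed = seed + 1L)
  river_cluster <- cluster_labels_by_group(baseline, km$labels, "river")

  bl <- baseline
  ledgers <- list()
  converged <- FALSE
  panel <- NULL; ev_h <- NULL; ev_t <- NULL

  for (it in seq_len(max_iter)) {
    # rank loci at the current unit level on training fish only
    train_bl <- subset_individuals(bl, split$train)
    theta <- wc_theta_per_locus(counts_by_group(train_bl, "unit"))
    size <- min(panel_size, sum(!is.na(theta)))
    panel <- rank_and_select(theta, sizes = size)
    loci <- panel_loci(panel, size)

    ev_h <- evaluate_holdout(bl, split, loci, cutoff)
    ev_t <- twofold_cv(bl, loci, repeats = repeats, cutoff = cutoff,
                       seed = seed + 100L + it)

    units <- sort(unique(bl$units))
    ph <- stats::setNames(ev_h$per_unit$precision, ev_h$per_unit$unit)[units]
    pt <- stats::setNames(ev_t$per_unit$precision_mean,
                          ev_t$per_unit$unit)[units]
    w <- misassignment_graph(ev_h$table_cutoff, ev_t$table_cutoff)

    unit_cluster <- modal_unit_cluster(bl, river_cluster)
    adj_units <- adjacency_between_units(bl)

    step <- merge_step(ph, pt, w, unit_cluster, adj_units,
                       threshold = threshold, margin = margin,
                       overrides = overrides)
    step$ledger$iteration <- it
    ledgers[[it]] <- step$ledger

    if (all(step$partition == names(step$partition))) {
      converged <- TRUE
      break
    }
    bl$units <- stats::setNames(unname(step$partition[bl$units]),
                                names(bl$units))
  }
  if (!converged)
    warning("iterate_units: max_iter reached without a fixed point")

  list(baseline = bl,
       partition = bl$units,
       ledgers = ledgers,
       panel = panel,
       evaluations = list(holdout = ev_h, tfcv = ev_t),
       iterations = length(ledgers),
       converged = converged)
}

# Modal regional cluster of a unit = most common cluster among its rivers,
# weighted by river fish counts.
modal_unit_cluster <- function(baseline, river_cluster) {
  h <- baseline$hierarchy
  u <- unname(baseline$units[h$river])
  cl <- river_cluster[h$river]
  tab <- table(u, cl)
  stats::setNames(as.integer(colnames(tab)[apply(tab, 1, which.max)]),
                  rownames(tab))
}

# Two units are adjacent when any of their member rivers are adjacent.
adjacency_between_units <- function(baseline) {
  ra <- baseline$adjacency
  if (is.null(ra) || nrow(ra) == 0) return(NULL)
  u1 <- unname(baseline$units[ra$river1])
  u2 <- unname(baseline$units[ra$river2])
  keep <- u1 != u2
  if (!any(keep)) return(NULL)
  unique(data.frame(unit1 = pmin(u1[keep], u2[keep]),
                    unit2 = pmax(u1[keep], u2[keep]),
                    stringsAsFactors = FALSE))
}
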