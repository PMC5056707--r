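#' Write a baseline to Genepop format plus a hierarchy config
#'
#' The Genepop dialect is the common machine-written one: a title line,
#' one locus name per line, `POP` separators in upper case, one site per
#' POP block, individual lines `id ,  001002 ...` with 3-digit allele codes
#' and `000000` for missing. Genepop cannot express a three-level hierarchy,
#' so the site -> river -> region maps, the unit partition and the river
#' adjacency travel in a sidecar YAML written next to the genotype file.
#'
#' @param baseline a [gsi_baseline()] object.
#' @param path output Genepop file.
#' @param config_path output YAML; default `paste0(path, ".hierarchy.yaml")`.
#' @param title first line of the Genepop file.
#' @return invisibly, the paths written.
#' @export
write_genepop <- function(baseline, path,
                          config_path = paste0(path, ".hierarchy.yaml"),
                          title = "gsikit baseline export") {
  g <- baseline$genotypes
  loci <- baseline$loci
  h <- baseline$hierarchy

  code <- function(col, j) {
    a <- loci$allele_a[j]; b <- loci$allele_b[j]
    out <- character(length(col))
    out[is.na(col)] <- "000000"
    out[!is.na(col) & col == 2L] <- paste0(a, a)
    out[!is.na(col) & col == 1L] <- paste0(a, b)
    out[!is.na(col) & col == 0L] <- paste0(b, b)
    out
  }
  coded <- vapply(seq_len(ncol(g)), function(j) code(g[, j], j),
                  character(nrow(g)))
  if (nrow(g) == 1L) coded <- matrix(coded, nrow = 1L)

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(loci$locus_id, con)
  sites <- unique(h$site)
  for (s in sites) {
    writeLines("POP", con)
    idx <- which(h$site == s)
    writeLines(paste0(h$individual[idx], " ,  ",
                      apply(coded[idx, , drop = FALSE], 1L, paste,
                            collapse = " ")), con)
  }

  write_hierarchy_config(baseline, config_path, pop_sites = sites)
  invisible(c(genepop = path, config = config_path))
}

write_hierarchy_config <- function(baseline, path, pop_sites = NULL) {
  h <- baseline$hierarchy
  s2r <- unique(h[, c("site", "river")])
  r2g <- unique(h[, c("river", "region")])
  cfg <- list(
    pop_sites = as.list(if (is.null(pop_sites)) unique(h$site) else pop_sites),
    sites = as.list(stats::setNames(s2r$river, s2r$site)),
    rivers = as.list(stats::setNames(
      ifelse(is.na(r2g$region), "", r2g$region), r2g$river)),
    units = as.list(stats::setNames(unname(baseline$units),
                                    names(baseline$units))),
    adjacency = if (is.null(baseline$adjacency)) list() else
      lapply(seq_len(nrow(baseline$adjacency)), function(i)
        c(baseline$adjacency$river1[i], baseline$adjacency$river2[i])),
    locus_classes = as.list(stats::setNames(baseline$loci$snp_class,
                                            baseline$loci$locus_id)),
    allele_a = as.list(stats::setNames(baseline$loci$allele_a,
                                       baseline$loci$locus_id))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a Genepop file and its hierarchy config into a baseline
#'
#' @param path Genepop file in the dialect written by [write_genepop()].
#' @param config_path hierarchy YAML; default `paste0(path, ".hierarchy.yaml")`.
#'   The config maps POP blocks to sites (`pop_sites`, in file order), sites
#'   to rivers, rivers to regions/units, and lists river adjacency pairs.
#' @return a [gsi_baseline()] object. Call rates are computed from the data.
#'   Allele A at a locus is the allele named in the config, else the
#'   lexicographically smaller observed code.
#' @export
read_genepop <- function(path, config_path = paste0(path, ".hierarchy.yaml")) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("genepop parse error: file too short")
  cfg <- if (file.exists(config_path)) yaml::read_yaml(config_path) else NULL

  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop) || first_pop < 3L)
    stop("genepop parse error: no POP separator after locus list")
  locus_ids <- trimws(lines[2:(first_pop - 1L)])
  # allow the comma-separated single-line locus list some programs emit
  if (length(locus_ids) == 1L && grepl(",", locus_ids))
    locus_ids <- trimws(strsplit(locus_ids, ",")[[1]])
  n_loci <- length(locus_ids)

  block <- cumsum(is_pop)
  ind_lines <- which(block > 0L & !is_pop & nzchar(trimws(lines)))
  n_ind <- length(ind_lines)
  if (n_ind == 0L) stop("genepop parse error: no individuals")

  ids <- character(n_ind)
  pops <- integer(n_ind)
  raw <- matrix("", n_ind, n_loci)
  for (k in seq_len(n_ind)) {
    i <- ind_lines[k]
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      stop(sprintf("genepop parse error at line %d: missing comma", i))
    ids[k] <- trimws(parts[1L])
    alleles <- strsplit(trimws(paste(parts[-1L], collapse = ",")),
                        "[[:space:]]+")[[1]]
    if (length(alleles) != n_loci)
      stop(sprintf("genepop parse error at line %d: %d genotypes, expected %d",
                   i, length(alleles), n_loci))
    raw[k, ] <- alleles
    pops[k] <- block[i]
  }

  geno <- matrix(NA_integer_, n_ind, n_loci,
                 dimnames = list(ids, locus_ids))
  allele_a <- character(n_loci)
  allele_b <- character(n_loci)
  for (j in seq_len(n_loci)) {
    col <- raw[, j]
    if (any(nchar(col) != 6L))
      stop(sprintf("genepop parse error: locus %s has a non 6-digit genotype",
                   locus_ids[j]))
    a1 <- substr(col, 1L, 3L)
    a2 <- substr(col, 4L, 6L)
    obs <- a1 != "000"
    codes <- sort(unique(c(a1[obs], a2[obs])))
    if (length(codes) > 2L)
      stop(sprintf("data error: locus %s has %d allele codes",
                   locus_ids[j], length(codes)))
    a <- NULL
    if (!is.null(cfg$allele_a[[locus_ids[j]]]))
      a <- as.character(cfg$allele_a[[locus_ids[j]]])
    if (is.null(a) || !nzchar(a)) a <- codes[1L]
    if (length(codes) == 0L) a <- "001"
    allele_a[j] <- a
    allele_b[j] <- if (length(codes) >= 1L && any(codes != a))
      codes[codes != a][1L] else "002"
    geno[obs, j] <- (a1[obs] == a) + (a2[obs] == a)
  }

  sites <- if (!is.null(cfg$pop_sites) && length(cfg$pop_sites) >= max(pops)) {
    unlist(cfg$pop_sites)[pops]
  } else {
    paste0("pop", pops)
  }
  rivers <- if (!is.null(cfg$sites)) {
    r <- unlist(cfg$sites)[sites]
    ifelse(is.na(r), sites, r)
  } else sites
  regions <- if (!is.null(cfg$rivers)) {
    g <- unlist(cfg$rivers)[rivers]
    ifelse(is.na(g) | g == "", NA_character_, g)
  } else rep(NA_character_, n_ind)

  hierarchy <- data.frame(individual = ids, site = sites, river = rivers,
                          region = regions, stringsAsFactors = FALSE)

  snp_class <- rep("SNP", n_loci)
  if (!is.null(cfg$locus_classes)) {
    cls <- unlist(cfg$locus_classes)[locus_ids]
    snp_class[!is.na(cls)] <- cls[!is.na(cls)]
  }
  loci <- data.frame(locus_id = locus_ids, snp_class = snp_class,
                     allele_a = allele_a, allele_b = allele_b,
                     stringsAsFactors = FALSE)

  units <- NULL
  if (!is.null(cfg$units) && length(cfg$units))
    units <- stats::setNames(unlist(cfg$units), names(cfg$units))
  adjacency <- NULL
  if (!is.null(cfg$adjacency) && length(cfg$adjacency))
    adjacency <- data.frame(
      river1 = vapply(cfg$adjacency, `[`, "", 1L),
      river2 = vapply(cfg$adjacency, `[`, "", 2L),
      stringsAsFactors = FALSE)

  gsi_baseline(geno, hierarchy, loci, units = units, adjacency = adjacency)
}

#' Write / read a genotype matrix as TSV
#'
#' Plain tabular alternative to Genepop: columns `individual_id`, `site_id`,
#' then one column per locus holding 0/1/2/NA copies of allele A.
#'
#' @param baseline a [gsi_baseline()] object.
#' @param path TSV file path.
#' @return invisibly, `path`.
#' @export
write_genotype_tsv <- function(baseline, path) {
  df <- data.frame(individual_id = baseline$hierarchy$individual,
                   site_id = baseline$hierarchy$site,
                   baseline$genotypes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
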