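#!/usr/bin/env Rscript
# Stage 3: between-site distance geometry and regional clustering.
#
# Pairwise Nei's D_A between sites is ordinated by principal coordinates;
# sites far from the bulk (median + 3 MAD on axes 1-2) are flagged as
# outliers to be excluded from locus ranking. Individuals are then
# clustered by k-means on leading principal components, with the number
# of clusters chosen at the elbow of the BIC curve; the cluster labels
# provide the regional context used when merging assignment units.

library(gsikit)

bl <- read_genepop("results/data/baseline.gen")
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

dm <- nei_da_matrix(counts_by_group(bl, "site"))
write.table(round(dm, 5), "results/tables/site_da.tsv", sep = "\t",
            quote = FALSE, col.names = NA)

ord <- pcoa(dm, n_axes = 4)
coords <- data.frame(site = rownames(ord$coords), round(ord$coords, 5))
write.table(coords, "results/tables/site_pcoa.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

flagged <- flag_outlier_sites(ord$coords)
cat(sprintf("outlier sites: %s\n",
            if (length(flagged)) paste(flagged, collapse = ", ") else "none"))
writeLines(flagged, "results/tables/outlier_sites.txt")

km <- kmeans_bic_scan(bl, k_max = 8, seed = 2)
write.table(km$scan, "results/tables/bic_scan.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("k-means BIC scan: chosen k = %d (of %d scanned) on %d PCs\n",
            km$chosen_k, nrow(km$scan), km$n_pcs))
river_cl <- cluster_labels_by_group(bl, km$labels, "river")
write.table(data.frame(river = names(river_cl), cluster = river_cl),
            "results/tables/river_clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
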