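#!/usr/bin/env Rscript
# Stage 2: locus and site quality control.
#
# Loci with call rate below 0.90 are discarded; every site is tested for
# Hardy-Weinberg equilibrium (exact test per locus, Fisher's combination
# per site, Holm correction across sites). A site rejected here would be
# excluded from locus ranking in stage 4.

library(gsikit)

bl <- read_genepop("results/data/baseline.gen")
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

qc <- filter_call_rate(bl$loci, 0.90)
cat(sprintf("call-rate filter: %d of %d loci retained\n",
            nrow(qc$retained), nrow(bl$loci)))
writeLines(qc$log, "results/tables/callrate_removals.txt")
bl <- subset_loci(bl, qc$retained$locus_id)

hwe <- hwe_site_scan(bl, alpha = 0.05)
write.table(hwe, "results/tables/hwe_sites.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("HWE screen: %d of %d sites rejected after Holm correction\n",
            sum(hwe$reject), nrow(hwe)))
if (any(hwe$reject))
  cat("rejected:", paste(hwe$site[hwe$reject], collapse = ", "), "\n")
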