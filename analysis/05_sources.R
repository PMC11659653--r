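#!/usr/bin/env Rscript
# Source-term (EnvO-style) generalism: per-taxon term proportions at >= 99%
# identity, source richness/diversity, community means along the salinity
# gradient, the split by biome-overlap class, and the correlation between
# local specificity and global source richness at both ends of the gradient.

library(salinispec)

counts <- read_count_table("results/data/counts.tsv")
meta <- read_sample_metadata("results/data/metadata.tsv")
hits <- read_hit_table("results/data/hits.tsv")
mr <- as.matrix(read.delim("results/mean_rarefied.tsv", row.names = 1,
                           check.names = FALSE))
abund <- relative_abundance(mr)
labels <- venn_partition(counts, meta)

profiles <- build_source_profiles(hits, min_identity = 99,
                                  taxa = rownames(counts))
cat(sprintf("source profiles cover %.1f%% of taxa\n", 100 * profiles$coverage))
write.table(profiles$stats, "results/source_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

aq <- meta$sample_id[meta$biome == "aquatic"]
csm <- community_source_means(abund[, aq], profiles$stats)
csm$salinity <- meta$salinity[match(csm$sample, meta$sample_id)]
write.table(csm, "results/community_source_means.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
gd <- gradient_correlation(csm$mean_diversity, csm$salinity)
gr <- gradient_correlation(csm$mean_richness, csm$salinity)
cat(sprintf("mean source diversity vs salinity: rho = %.2f (p = %.2g)\n",
            gd$rho, gd$p))
cat(sprintf("mean source richness vs salinity: rho = %.2f (p = %.2g)\n",
            gr$rho, gr$p))

cls <- partition_source_comparison(profiles$stats, labels)
write.table(cls, "results/partition_source.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
med <- sort(tapply(cls$source_diversity, cls$class, median), decreasing = TRUE)
cat("median source diversity by overlap class (highest to lowest):\n")
print(round(med, 2))

spec_vals <- read.delim("results/specificity_values.tsv")
rich <- setNames(profiles$stats$source_richness, profiles$stats$taxon)
for (bin in c("slightly_brackish", "highly_hypersaline")) {
  sv <- spec_vals[spec_vals$category == bin, ]
  s <- setNames(sv$S_obs, sv$taxon)
  ct <- specificity_source_correlation(s, rich)
  cat(sprintf("specificity vs source richness in %s: rho = %.2f (p = %.2g, n = %d)\n",
              bin, ct$rho, ct$p, ct$n))
}
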