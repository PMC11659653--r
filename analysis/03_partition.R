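#!/usr/bin/env Rscript
# Classify taxa by the set of biomes they occur in (7 Venn classes), profile
# the classes along the aquatic salinity gradient, extract the abundant-taxon
# compartment matrix (heatmap input), and test the gradient trend of
# aquatic-specific taxa.

library(salinispec)

counts <- read_count_table("results/data/counts.tsv")
meta <- read_sample_metadata("results/data/metadata.tsv")
mr <- as.matrix(read.delim("results/mean_rarefied.tsv", row.names = 1,
                           check.names = FALSE))
abund <- relative_abundance(mr)

labels <- venn_partition(counts, meta)
write.table(data.frame(taxon = names(labels), label = as.character(labels)),
            "results/partition_labels.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("biome-overlap classes:\n")
print(table(labels))
cat(sprintf("%.1f%% of detected taxa occur in all three biomes\n",
            100 * mean(labels == "all_three")))

prof <- partition_profile(abund, labels, meta, restrict_biome = "aquatic")
prof$salinity <- meta$salinity[match(prof$sample, meta$sample_id)]
write.table(prof, "results/partition_profile.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

aq <- prof[prof$class == "aquatic_only", ]
ga <- gradient_correlation(aq$abundance, aq$salinity)
gp <- gradient_correlation(aq$richness_prop, aq$salinity)
cat(sprintf("aquatic-only abundance vs salinity: rho = %.2f (p = %.2g)\n",
            ga$rho, ga$p))
cat(sprintf("aquatic-only richness share vs salinity: rho = %.2f (p = %.2g)\n",
            gp$rho, gp$p))

ab <- abundant_taxa(abund, meta, threshold = 0.0025)
cat(length(ab$union), "abundant taxa (mean within-biome abundance >= 0.25%)\n")
groups <- make_group_assignment(meta, require_all = FALSE)
cmat <- compartment_mean_abundance(abund[ab$union, , drop = FALSE], groups)
write_count_table(cmat, "results/compartment_means.tsv")
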