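#!/usr/bin/env Rscript
# Build the rarefaction-averaged community table (100 rarefactions at the
# minimum sample depth), per-sample richness and Shannon diversity, and the
# Bray-Curtis dissimilarity matrix after Hellinger standardisation. The
# distance matrix is exported for external ordination (NMDS/PERMANOVA).

library(salinispec)

counts <- read_count_table("results/data/counts.tsv")
meta <- read_sample_metadata("results/data/metadata.tsv")

counts <- filter_min_depth(counts, min_depth = 9000)
cat(length(attr(counts, "removed")), "samples below the 9000-read QC cutoff\n")

depth <- min(colSums(counts))
mr <- mean_rarefied_table(counts, depth, reps = 100, seed = 101)
stopifnot(max(abs(colSums(mr) - depth)) < 1e-9)
write_count_table(mr, "results/mean_rarefied.tsv")

div <- data.frame(sample = colnames(mr),
                  biome = meta$biome[match(colnames(mr), meta$sample_id)],
                  richness = apply(mr, 2, richness),
                  shannon = apply(mr, 2, shannon))
write.table(div, "results/alpha_diversity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

bc <- bray_curtis(hellinger(mr))
write_distance_matrix(bc, "results/bray_curtis.tsv")

cat("rarefaction depth:", depth, "(100 averaged draws)\n")
cat("mean richness by biome:\n")
print(round(tapply(div$richness, div$biome, mean), 1))
cat("mean Shannon by biome:\n")
print(round(tapply(div$shannon, div$biome, mean), 2))
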