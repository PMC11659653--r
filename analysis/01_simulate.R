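#!/usr/bin/env Rscript
# Generate the default three-biome synthetic study (300 taxa; 60 aquatic
# samples on a 0.5-35 % w/v salinity grid, 20 airborne, 10 sediment; 10,000
# reads per sample) together with its seqenv-style source-hit table and the
# planted ground truth, and write the bundle under results/data/.

library(salinispec)

seed <- 1
ds <- generate_dataset(seed = seed)
paths <- write_dataset(ds, "results/data")

rep <- validate_inputs(ds$counts, ds$meta, ds$hits)
stopifnot(rep$ok)

cat("simulated", nrow(ds$counts), "taxa x", ncol(ds$counts), "samples",
    "(depth", ds$design$depth, "reads), seed", seed, "\n")
cat("taxon classes:\n")
print(table(ds$truth$class))
cat("files:\n")
for (p in paths) cat("  ", p, "\n")
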