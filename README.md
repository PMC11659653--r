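# salinispec

Microbial communities in and around athalassohaline lakes exchange organisms
across three connected compartments — the water column (plankton), dry lake
sediments, and the overlying air — while a steep salinity gradient
(roughly 0–40 % w/v salt) filters which immigrants can establish. A central
question for such systems is whether the taxa that dominate a given salinity
range are habitat generalists that happen to thrive locally, or specialists
confined to their niche both locally and at the global scale.

`salinispec` is an R package plus a scripted analysis workflow for addressing
that question with zOTU/ASV count tables. It provides:

* **Community tables** — TSV/BIOM readers, a minimum-depth QC filter,
  rarefaction without replacement (multivariate hypergeometric), and
  *rarefaction-averaged* tables (element-wise mean of 100 rarefactions at a
  common depth, which retains low-abundance taxa that a single draw loses),
  Hellinger standardisation, Bray–Curtis dissimilarities, richness and
  Shannon diversity.
* **Biome-overlap partitioning** — every taxon is assigned to one of 7
  classes by the set of compartments it is detected in (aquatic-only, …,
  all-three/cosmopolitan), aquatic samples are binned into five salt ranges
  (slightly brackish < 1.5 % w/v, brackish 1.5–3, marine 3–5, hypersaline
  5–15, highly hypersaline ≥ 15), and per-sample class profiles are tracked
  along the gradient.
* **A per-group specificity index with a permutation null** — for taxon *i*
  and sample category *j* (airborne, sediment, and the five salinity ranges),

  S<sub>ij</sub> = x̄<sub>ij</sub> / Σ<sub>k</sub> x̄<sub>ik</sub>,

  where x̄<sub>ij</sub> is the mean relative abundance of *i* over the
  samples of category *j*. This is the specificity ("A") component of the
  IndVal indicator statistic, retained for **all** groups rather than reduced
  to its maximum; rows sum to 1 and S<sub>ij</sub> = 1 marks exclusivity
  regardless of abundance. The null model reshuffles the sample→category
  labels (group sizes fixed, 999 permutations), specificity is regressed on
  log₁₀ local abundance per category, and the observed slope is compared with
  the null: a calibrated permutation p-value (default) and a Welch-style
  two-fit contrast are both reported.
* **Source-term generalism** — from a seqenv-style hit table
  (taxon, EnvO-like term, % identity, matched-sequence count), hits at
  ≥ 99 % identity are aggregated into per-taxon term proportions, source
  richness and Shannon source diversity (proxies for global habitat
  generalism), community-level means along the gradient, and correlations
  between local specificity and global source statistics.
* **A synthetic-data generator** — three-biome communities with planted
  Gaussian salinity niches, biome affinities, a generalism parameter wired to
  source-term counts, multinomial (optionally Dirichlet-multinomial)
  sequencing noise, and full ground truth for recovery testing.

## Worked example

Small text inputs ship with the package:

```r
library(salinispec)
ct   <- read_count_table(system.file("extdata/example_counts.tsv",  package = "salinispec"))
meta <- read_sample_metadata(system.file("extdata/example_metadata.tsv", package = "salinispec"))
hits <- read_hit_table(system.file("extdata/example_hits.tsv", package = "salinispec"))

table(venn_partition(ct, meta))
#>      aquatic_only     airborne_only     sediment_only  aquatic_airborne
#>                 1                 0                 0                 1
#>  aquatic_sediment airborne_sediment         all_three
#>                 2                 0                 2

rel <- relative_abundance(ct)
S <- specificity_index(group_mean_abundance(rel, make_group_assignment(meta, require_all = FALSE)))
round(S["zotu_002", ], 3)
#>          airborne          sediment slightly_brackish            marine
#>             0.000             0.000             0.000             0.041
#>       hypersaline highly_hypersaline
#>             0.384             0.575
```

`zotu_002` concentrates 96 % of its specificity in the two most saline
ranges and carries a single source term (`build_source_profiles(hits)` gives
it source richness 1, diversity 0) — the signature of a halophilic
specialist at both the local and the global scale.

The full analysis is the numbered scripts under `analysis/`, run from the
repository root in order:

```sh
Rscript analysis/01_simulate.R          # synthetic study + ground truth
Rscript analysis/02_tables_diversity.R  # rarefaction-averaged table, diversity, Bray-Curtis
Rscript analysis/03_partition.R         # biome-overlap classes along the gradient
Rscript analysis/04_specificity.R       # specificity index + permutation null + slopes
Rscript analysis/05_sources.R           # source generalism along the gradient
```

On the default synthetic study these print, among other things:

```
aquatic-only abundance vs salinity: rho = 0.96 (p = 1.5e-34)
mean source diversity vs salinity: rho = -0.98 (p = 1.7e-43)
specificity vs source richness in slightly_brackish:  rho = 0.54 (p = 0.00022, n = 43)
specificity vs source richness in highly_hypersaline: rho = -0.80 (p = 4.7e-40, n = 176)
```

i.e. aquatic-specific taxa take over as salt rises, community-level source
diversity falls, and the specificity–generalism correlation reverses sign
between the fresh and the hypersaline end of the gradient — dominants at low
salinity are global generalists, dominants at high salinity are specialists
everywhere. All tables land under `results/`; `run_pipeline()` performs the
same stages in one call with a JSON manifest.

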