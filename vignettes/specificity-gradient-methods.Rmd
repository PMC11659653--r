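---
title: "Specificity, dispersal and source generalism along a salinity gradient: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Specificity, dispersal and source generalism along a salinity gradient: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(salinispec)
```

This vignette is the package's own account of the models and procedures it
implements, the choices that were genuinely open, and what the synthetic
tests do and do not demonstrate about real data.

## The scientific setting

Saline and hypersaline lakes sit at the junction of three microbial
compartments: the plankton of the water column, the dry sediments that act
as a seed bank between inundations, and the air that continually deposits
cells from regional and long-range transport. Salinity (here in % w/v, from
slightly brackish to salt saturation) is the dominant environmental filter
on who can establish in the water. The package quantifies, for zOTU/ASV
count data from such a system, (i) how community membership partitions
across the three compartments along the gradient, (ii) how *locally
specific* the dominant taxa of each salinity range are, and (iii) whether
local dominants are *global* generalists or specialists, as judged by the
environmental-ontology source terms attached to high-identity database
matches of their sequences.

## Community tables

Counts are taxa × samples, non-negative integers. Samples below a
configurable QC depth (default 9000 reads) are dropped before rarefaction.
Rarefaction draws reads **without replacement** (multivariate hypergeometric
per sample) so every rarefied column sums exactly to the target depth and no
count can exceed its input; multinomial resampling is available behind a
flag but is not the default, matching the standard `rrarefy` semantics.
Because a single rarefaction draw loses rare taxa, community-level analyses
use the *rarefaction-averaged* table: the element-wise mean of 100
independent rarefactions at the common (minimum) depth. The average
preserves the column sum exactly and keeps a taxon at zero only if it was
absent from the input, which is the point: partition classes stay comparable
across compartments. Averaging is done globally at a single minimum depth;
whether to recompute per compartment is left as an option because nothing in
the downstream statistics depends on it when sample depths are similar.

Hellinger standardisation (square root of within-sample relative
abundances) followed by Bray–Curtis dissimilarity is provided for
ordination; the package deliberately stops at the distance matrix, since
NMDS/PERMANOVA are routine external steps. Shannon diversity uses natural
logarithms by default (base is a parameter); these standard computations are
delegated to `vegan`.

Seeding is counter-based: a master seed expands into per-replicate seeds
(`derive_seed`), so replicate *r* is reproducible independently of how many
replicates run before it, and parallel execution cannot change results.

## Biome-overlap partitioning and salinity ranges

Detection is "total count > 0 within the compartment" — a single read
suffices, with no occurrence-fraction threshold, because the partition is a
statement about presence, not dominance. Every detected taxon receives
exactly one of 7 labels (the non-empty subsets of
{airborne, sediment, aquatic}). Per-sample profiles re-normalise to the taxa
detected in that sample, so class shares of both richness and abundance sum
to 1 and samples of different depth are comparable. Profiles are computed
per sample and then summarised, rather than pooled per biome, so gradient
trends can be tested sample-wise (Spearman rank correlation with the t
approximation).

The five salt ranges are slightly brackish < 1.5 % w/v, brackish 1.5–3,
marine 3–5, hypersaline 5–15, and highly hypersaline ≥ 15. Published range
definitions leave a gap between "up to 14.9" and "above 15"; the package
uses half-open bins `[lower, upper)` so every non-negative salinity maps to
exactly one range and 15.0 falls in the highly hypersaline class.

"Abundant" taxa (the heatmap subset) are those with mean within-compartment
relative abundance ≥ 0.25 %; the taxon × compartment matrix of mean
abundances is exported for clustering, the rendering itself being out of
scope.

## The specificity index and its null

For taxon $i$ and category $j$ (airborne, sediment, and the five salinity
ranges; aquatic-detected taxa only):

$$S_{ij} = \frac{\bar{x}_{ij}}{\sum_k \bar{x}_{ik}}, \qquad
  \bar{x}_{ij} = \text{mean relative abundance of } i
  \text{ over samples of } j.$$

This is the specificity ("A") component of the IndVal indicator statistic,
kept for **every** group instead of collapsed to its maximum, and the
fidelity ("B") component is deliberately excluded: the object of interest is
how abundance concentrates across groups, not within-group occurrence
frequency. Rows sum to 1; $S_{ij}=1$ means exclusivity however rare the
taxon is — specificity and dominance are distinct by construction, which is
what makes their empirical correlation informative.

The null model reassigns samples to categories uniformly at random while
keeping every category's sample count fixed (a permutation of the observed
label vector, all 7 categories shuffled jointly), recomputes $S$, and
averages over 999 permutations.

**Specificity–dominance trend.** Within each category, $S_{\cdot j}$ is
regressed (OLS) on the local-abundance covariate: the within-category mean
relative abundance, log₁₀-transformed with a 10⁻⁶ pseudocount (the raw mean
is available as an option). Wording such as "mean abundance within each
sample" is ambiguous between per-sample and per-category means; the
within-category mean is used because it is the quantity $S$ itself is built
from, and the choice is recorded in the output settings. Taxa not detected
in a category are excluded from that category's fit by default: they would
pile up at the pseudocount floor with $S=0$ and manufacture slope. The null
trend fits the per-taxon *mean null* $S$ against the **observed** covariate
(abundance is not permuted), over the same taxon set. Because the OLS slope
is linear in the response, the null-fit slope equals the mean of the
per-permutation slopes — which the implementation also collects.

**Observed-vs-null slope comparison.** Two decisions are computed:

* a Welch-style two-fit contrast (difference of slopes over
  $\sqrt{SE_1^2+SE_2^2}$, Welch–Satterthwaite df), the conventional
  `lstrends`-like comparison;
* the permutation p-value: the observed slope referred to the distribution
  of per-permutation slopes (two-sided, centred at the permutation mean).

The package's default decision is the **permutation p**. The reason is
empirical: in a 200-dataset simulation with iid samples and exchangeable
labels (no specificity–abundance relationship), the Welch contrast rejected
at ≈ 14 % for nominal α = 0.05, while the permutation test rejected at
≈ 4–6 %. The anticonservatism has two sources: the OLS slope SE treats
across-taxa scatter as iid error although taxa share the same samples (the
$S$ values are coupled through the category means and row normalisation),
and the observed and null-mean slopes are positively correlated while the
contrast assumes independent fits. Both p-values are always reported, so the
conventional comparison remains available for compatibility. Per-category
fits are used rather than one pooled interaction model; with the permutation
decision the pooled model would add shared-variance assumptions without
adding information.

A practical consequence of the calibrated test: statistical power tracks the
category's sample count. Under the default synthetic design (60 aquatic
samples uniform in 0.5–35 % w/v), the slightly brackish range contains only
2 samples, and the permutation distribution of its slope is wide; a real
positive slope excess there typically yields p ≈ 0.13–0.16 while the (too
liberal) Welch contrast reports p ≪ 0.001. This is a power limitation of
sparse categories, not an absence of planted signal, and it disappears when
the low-salinity end is sampled more densely.

## Source-term generalism

The input is a seqenv-style hit table: (taxon, source term, % identity,
matched-sequence count). Hits at ≥ 99 % identity (near-exact matches) are
aggregated per taxon and term; the weight of a term is its share of the
taxon's matched sequences. Source **richness** (number of terms) and source
**Shannon diversity** proxy habitat generalism at the global scale. Terms
are opaque strings — no ontology graph traversal or parent/child collapsing
is attempted, because term semantics are not needed for the statistics.
Matched-sequence counts (not unique-sequence counts) are used as weights, as
that is what the hit-table format records.

Community-level means per sample average the per-taxon statistics over
detected taxa with a profile — unweighted by default, so the statistic
reflects membership rather than dominance; abundance weighting is an option
and both behave similarly on the synthetic data (the weighted version is
sharper, since dominants carry the signal). Coverage of the taxon set by the
hit table is always reported, and taxa without retained hits are flagged
rather than silently treated as zero-richness.

## The synthetic generator

Each taxon has a base log-abundance (Normal(log 3, 0.6)), affinity weights
for the three compartments, a Gaussian niche on the raw % w/v salinity axis
(optimum $\mu$, breadth $\sigma$; the raw axis is used because the salt
ranges are defined on it), and a generalism parameter $g \in [0,1]$ that
drives source-term counts: taxon $i$ draws $1 + \mathrm{Binomial}(39,\,
0.6\,g_i)$ distinct terms from a 40-term pool with Dirichlet-distributed
match counts and identities in [99, 100]. Sequencing is multinomial at
10,000 reads per sample (Dirichlet-multinomial under an overdispersion
option; the pure multinomial default keeps every criterion deterministic in
the seed).

The default community of 300 taxa:

* **30 habitat generalists** (10 %): positive weights in all three
  compartments, broad low-salinity niches ($\mu \sim U(0,5)$,
  $\sigma \sim U(8,18)$), high generalism ($g \sim U(0.5, 0.9)$). Their
  share echoes the small cosmopolitan fraction typical of three-compartment
  surveys, where only a few percent of taxa occur everywhere.
* **170 aquatic specialists**: aquatic-only, narrow niches
  ($\sigma \sim U(1,3)$) with optima spread over the saline portion of the
  gradient ($\mu \sim U(5,35)$), and generalism *declining with the
  optimum* (from ≈ 0.55 at $\mu = 5$ to ≈ 0.05 at $\mu = 35$).
* **60 airborne- and 40 sediment-specific taxa** with intermediate
  generalism.

Two structural choices deserve emphasis. First, specialist optima occupy the
saline portion rather than the whole gradient, leaving the fresh/brackish
end to the widespread generalists: communities at low salinity being
dominated by broadly distributed taxa is the empirically observed starting
point of this kind of gradient, and planting narrow low-salinity endemics
instead would build the opposite world. Second, the $\mu$–$g$ coupling
encodes that brackish-type habitats are globally common (taxa adapted to
them accumulate many source annotations) while hypersaline habitats are
globally rare; without the coupling, simulated community source diversity is
*non-monotone* along the gradient (an artefact of niche-optimum edge
effects), which contradicts the monotone decline such systems show.

Aquatic taxa also leak into airborne and sediment communities at 10⁻⁴ of
their weight, emulating trace dispersal of halophiles into the aerobiome and
sediments.

What the generator does **not** emulate: thousands-of-taxa richness (so
detected-set compositions shift less sharply than in real surveys),
temporal/hydroperiod dynamics, dormancy, taxonomy, and any structure in the
term vocabulary. Passing recovery tests therefore demonstrates that the
statistics recover planted gradient structure at desk scale — not that real
communities behave this way.

## Problem sizes and numerical choices

Test and acceptance runs use the default design (300 taxa, 90 samples,
depth 10⁴, 999 permutations), 200 null datasets of 30 taxa × 21 samples for
the type-I simulation, and 3000 replicate columns for the hypergeometric
check — sizes chosen so the whole suite runs in well under a minute while
keeping Monte-Carlo error far below the asserted margins. Tolerances: exact
conservation laws (column sums, row sums of $S$) at 10⁻⁹ or better;
hand-computed values at 10⁻¹²; Monte-Carlo comparisons at 3 standard errors.
Degenerate inputs error early and by name: zero-total samples, empty
categories, constant covariates, all-zero taxa (dropped with a warning in
`specificity_index`, refused in the permutation engine where silent dropping
would bias the null).

## Known limitations

* The permutation decision is exact only under exchangeability of samples
  across categories; gradients of sequencing depth or batch structure across
  categories would violate it (as they would the parametric alternative).
* Sparse categories have little power (see above); the index itself is
  unbiased but its trend test is not informative from 2–3 samples.
* Source statistics inherit every bias of database annotation: coverage is
  reported, but unannotated taxa are simply absent from community means.
* `compare_slopes` treats the two fits as independent; it is retained for
  compatibility and its miscalibration under the permutation null is
  documented rather than patched, since the permutation p supersedes it.
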