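# Synthetic three-biome communities along a salinity gradient.
#
# Each taxon carries a base log-abundance, affinity weights for the three
# compartments, a Gaussian salinity niche (optimum mu, breadth sigma, on the
# raw % w/v axis) acting on aquatic samples only, and a generalism parameter
# g in [0, 1] that controls how many environmental source terms its sequence
# is annotated with. Sequencing is multinomial (optionally
# Dirichlet-multinomial) at a configured depth. The planted parameters are
# returned as ground truth for recovery tests.
#
# The planted ecology mirrors the gradient structure the analysis targets:
# widespread generalists sit at the fresh/brackish end with broad niches and
# decline as salt rises, while narrow-niche aquatic specialists (halophiles)
# partition the saline portion of the gradient and carry few source terms.

#' Draw planted taxon parameters
#'
#' Four classes: habitat generalists (positive weight in all three biomes,
#' broad low-salinity niches, high generalism), aquatic specialists
#' (aquatic-only, narrow niches with optima spread over the saline portion of
#' the gradient, low generalism), and airborne- or sediment-specific taxa
#' (single compartment, intermediate generalism).
#'
#' @param n_generalist,n_specialist Numbers of generalist and aquatic
#'   specialist taxa.
#' @param n_airborne_specific,n_sediment_specific Numbers of single-biome
#'   taxa.
#' @param seed Optional seed (RNG state restored).
#' @return Data frame of `TaxonParams`: taxon, class, base, w_air, w_sed,
#'   w_aq, mu, sigma, g.
#' @export
generate_taxa <- function(n_generalist = 30, n_specialist = 170,
                          n_airborne_specific = 60, n_sediment_specific = 40,
                          seed = NULL) {
  ns <- c(n_generalist, n_specialist, n_airborne_specific, n_sediment_specific)
  if (any(ns < 0) || sum(ns) < 2) stop("need non-negative class counts totalling >= 2")
  with_seed(seed, {
    draw <- function(n, class, w_air, w_sed, w_aq, mu, sigma, g) {
      if (n == 0) return(NULL)
      data.frame(class = class, base = stats::rnorm(n, log(3), 0.6),
                 w_air = w_air(n), w_sed = w_sed(n), w_aq = w_aq(n),
                 mu = mu(n), sigma = sigma(n), g = g(n),
                 stringsAsFactors = FALSE)
    }
    u <- function(lo, hi) function(n) stats::runif(n, lo, hi)
    zero <- function(n) rep(0, n)
    # Specialist generalism declines with the salinity optimum: brackish-water
    # taxa inhabit globally common environments (many source terms) while
    # extreme halophiles are confined to rare hypersaline sites (few terms).
    spec_mu <- stats::runif(n_specialist, 5, 35)
    spec_g <- pmin(1, pmax(0, 0.5 * (35 - spec_mu) / 30 +
                                stats::runif(n_specialist, 0, 0.1)))
    taxa <- rbind(
      draw(n_generalist, "generalist", u(0.5, 1.5), u(0.5, 1.5), u(0.5, 1.5),
           u(0, 5), u(8, 18), u(0.5, 0.9)),
      draw(n_specialist, "aquatic_specialist", zero, zero, function(n) rep(1, n),
           function(n) spec_mu, u(1, 3), function(n) spec_g),
      draw(n_airborne_specific, "airborne_specific", u(0.5, 1.5), zero, zero,
           u(0, 35), u(5, 15), u(0.2, 0.5)),
      draw(n_sediment_specific, "sediment_specific", zero, u(0.5, 1.5), zero,
           u(0, 35), u(5, 15), u(0.2, 0.5))
    )
    taxa <- cbind(taxon = sprintf("T%04d", seq_len(nrow(taxa))), taxa)
    rownames(taxa) <- NULL
    taxa
  })
}

#' Study design for the synthetic dataset
#'
#' Defaults emulate a desk-scale version of a three-compartment survey: 60
#' aquatic samples on a uniform 0.5-35 % w/v salinity grid, 20 airborne and
#' 10 sediment samples, 10,000 reads per sample, pure multinomial noise, and
#' a trace leakage of aquatic taxa into airborne/sediment communities.
#'
#' @param n_aquatic,n_airborne,n_sediment Sample counts per compartment.
#' @param depth Reads per sample (>= 100).
#' @param salinity Salinities of the aquatic samples; default uniform grid.
#' @param overdispersion Dirichlet-multinomial overdispersion (0 = pure
#'   multinomial; larger values inflate between-replicate variance).
#' @param leakage Fraction of a taxon's aquatic weight that reaches airborne
#'   and sediment communities (default `1e-4`).
#' @param seed Master seed for count generation.
#' @return List of class `study_design`.
#' @export
study_design <- function(n_aquatic = 60, n_airborne = 20, n_sediment = 10,
                         depth = 10000,
                         salinity = seq(0.5, 35, length.out = n_aquatic),
                         overdispersion = 0, leakage = 1e-4, seed = 1) {
  if (any(c(n_aquatic, n_airborne, n_sediment) < 1)) stop("all sample counts must be >= 1")
  if (depth < 100) stop("depth must be >= 100")
  if (length(salinity) != n_aquatic) stop("salinity must have n_aquatic values")
  if (any(salinity < 0)) stop("negative salinity")
  if (overdispersion < 0) stop("overdispersion must be >= 0")
  structure(list(n_aquatic = n_aquatic, n_airborne = n_airborne,
                 n_sediment = n_sediment, depth = depth, salinity = salinity,
                 overdispersion = overdispersion, leakage = leakage,
                 seed = seed),
            class = "study_design")
}

#' Expected community composition for one sample
#'
#' Intensity \eqn{\lambda_i = e^{base_i} w_{biome}(i) \exp(-(salinity -
#' \mu_i)^2 / 2\sigma_i^2)} for aquatic samples (the Gaussian niche factor is
#' 1 for airborne/sediment), normalised to sum to 1. Airborne and sediment
#' intensities additionally receive `leakage` times the taxon's aquatic
#' weight, emulating trace dispersal of aquatic taxa into the other
#' compartments.
#'
#' @param taxa Taxon parameter data frame from [generate_taxa()].
#' @param biome `"airborne"`, `"sediment"` or `"aquatic"`.
#' @param salinity Salinity (% w/v); required for aquatic samples.
#' @param leakage Trace-dispersal fraction (default 0).
#' @return Named numeric vector of expected relative abundances.
#' @export
expected_composition <- function(taxa, biome, salinity = NA, leakage = 0) {
  biome <- match.arg(biome, BIOME_LEVELS)
  if (biome == "aquatic") {
    if (is.na(salinity)) stop("aquatic samples need a salinity")
    w <- taxa$w_aq
    niche <- exp(-(salinity - taxa$mu)^2 / (2 * taxa$sigma^2))
  } else {
    w <- (if (biome == "airborne") taxa$w_air else taxa$w_sed) +
      leakage * taxa$w_aq
    niche <- 1
  }
  lam <- exp(taxa$base) * w * niche
  if (sum(lam) <= 0) stop("all expected intensities are zero for this sample")
  stats::setNames(lam / sum(lam), taxa$taxon)
}

#' Simulate sequencing counts for a study design
#'
#' Per sample, counts are multinomial at the design depth around the expected
#' composition; with `overdispersion > 0` the composition is first perturbed
#' by a Dirichlet draw with concentration `composition / overdispersion`
#' (Dirichlet-multinomial). Per-sample seeds derive from the design's master
#' seed, so the table is reproducible and individual samples can be
#' regenerated independently.
#'
#' @param taxa Taxon parameters.
#' @param design A [study_design()].
#' @return List with `counts` (taxa x samples integer matrix) and `meta`
#'   (sample metadata data frame).
#' @export
generate_counts <- function(taxa, design) {
  stopifnot(inherits(design, "study_design"))
  meta <- data.frame(
    sample_id = c(sprintf("AQ%03d", seq_len(design$n_aquatic)),
                  sprintf("AIR%03d", seq_len(design$n_airborne)),
                  sprintf("SED%03d", seq_len(design$n_sediment))),
    biome = rep(c("aquatic", "airborne", "sediment"),
                c(design$n_aquatic, design$n_airborne, design$n_sediment)),
    salinity = c(design$salinity,
                 rep(NA_real_, design$n_airborne + design$n_sediment)),
    date = NA_character_,
    stringsAsFactors = FALSE
  )
  counts <- matrix(0L, nrow = nrow(taxa), ncol = nrow(meta),
                   dimnames = list(taxa$taxon, meta$sample_id))
  for (s in seq_len(nrow(meta))) {
    p <- expected_composition(taxa, meta$biome[s], meta$salinity[s],
                              leakage = design$leakage)
    counts[, s] <- with_seed(derive_seed(design$seed, s), {
      if (design$overdispersion > 0) {
        a <- p / design$overdispersion
        gam <- stats::rgamma(length(a), shape = a)
        if (sum(gam) <= 0) gam <- p
        p <- gam / sum(gam)
      }
      as.vector(stats::rmultinom(1L, design$depth, p))
    })
  }
  list(counts = counts, meta = meta)
}

#' Simulate a source-hit table from planted generalism
#'
#' Taxon `i` receives `1 + Binomial(n_terms_pool - 1, g_i * q)` distinct
#' terms from a fixed pool, with Dirichlet-distributed matched-sequence
#' counts (every assigned term keeps at least one match) and percent
#' identities drawn in \[99, 100\]. A taxon with `g = 0` therefore has exactly
#' one source term and zero source diversity.
#'
#' @param taxa Taxon parameters.
#' @param n_terms_pool Size of the term pool (default 40).
#' @param q Scale constant linking `g` to the expected term count
#'   (default 0.6).
#' @param mean_matches Mean number of additional matched sequences spread
#'   over a taxon's terms (default 150).
#' @param seed Optional seed.
#' @return Hit-table data frame (taxon, term, identity, count).
#' @export
generate_source_hits <- function(taxa, n_terms_pool = 40, q = 0.6,
                                 mean_matches = 150, seed = NULL) {
  if (n_terms_pool < 2) stop("n_terms_pool must be >= 2")
  pool <- sprintf("ENVO_term_%02d", seq_len(n_terms_pool))
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(taxa)), function(i) {
      pr <- min(1, taxa$g[i] * q)
      k <- 1L + stats::rbinom(1L, n_terms_pool - 1L, pr)
      terms <- sample(pool, k)
      dir <- stats::rgamma(k, shape = 1)
      extra <- stats::rpois(1L, mean_matches)
      cnt <- 1L + (if (extra > 0)
        as.vector(stats::rmultinom(1L, extra, dir / sum(dir))) else 0L)
      data.frame(taxon = taxa$taxon[i], term = terms,
                 identity = round(stats::runif(k, 99, 100), 2),
                 count = cnt, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Default synthetic-dataset configuration
#'
#' @return Nested list: `taxa` (class counts), `design` (sample layout,
#'   depth, overdispersion, leakage), `sources` (term pool, scale), `seed`.
#' @export
default_config <- function() {
  list(
    taxa = list(n_generalist = 30, n_specialist = 170,
                n_airborne_specific = 60, n_sediment_specific = 40),
    design = list(n_aquatic = 60, n_airborne = 20, n_sediment = 10,
                  depth = 10000, salinity_min = 0.5, salinity_max = 35,
                  overdispersion = 0, leakage = 1e-4),
    sources = list(n_terms_pool = 40, q = 0.6, mean_matches = 150),
    seed = 1
  )
}

#' Read a dataset configuration from YAML
#'
#' Unspecified fields fall back to [default_config()].
#' @param path Path to a YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  merge_config(yaml::read_yaml(path))
}

merge_config <- function(config) {
  base <- default_config()
  if (is.null(config)) return(base)
  utils::modifyList(base, config)
}

#' Generate a full synthetic dataset
#'
#' One call yields every pipeline input — count table, sample metadata,
#' source-hit table — plus the planted truth (taxon parameters) for recovery
#' tests. Sub-seeds for taxa, counts and hits derive from the master seed, so
#' the whole bundle is reproducible.
#'
#' @param config Optional (partial) configuration list; see
#'   [default_config()].
#' @param seed Optional master seed overriding `config$seed`.
#' @return List of class `salinispec_dataset`: `counts`, `meta`, `hits`,
#'   `truth`, `design`, `config`.
#' @export
generate_dataset <- function(config = NULL, seed = NULL) {
  cfg <- merge_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  taxa <- do.call(generate_taxa, c(cfg$taxa, list(seed = derive_seed(cfg$seed, 1L))))
  des <- study_design(
    n_aquatic = cfg$design$n_aquatic, n_airborne = cfg$design$n_airborne,
    n_sediment = cfg$design$n_sediment, depth = cfg$design$depth,
    salinity = seq(cfg$design$salinity_min, cfg$design$salinity_max,
                   length.out = cfg$design$n_aquatic),
    overdispersion = cfg$design$overdispersion, leakage = cfg$design$leakage,
    seed = derive_seed(cfg$seed, 2L)
  )
  cm <- generate_counts(taxa, des)
  hits <- generate_source_hits(taxa, n_terms_pool = cfg$sources$n_terms_pool,
                               q = cfg$sources$q,
                               mean_matches = cfg$sources$mean_matches,
                               seed = derive_seed(cfg$seed, 3L))
  structure(list(counts = cm$counts, meta = cm$meta, hits = hits,
                 truth = taxa, design = des, config = cfg),
            class = "salinispec_dataset")
}

#' Write a synthetic dataset bundle as TSV files
#'
#' @param dataset A `salinispec_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "salinispec_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             hits = file.path(dir, "hits.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_count_table(dataset$counts, paths[["counts"]])
  utils::write.table(dataset$meta, paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$hits, paths[["hits"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}
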