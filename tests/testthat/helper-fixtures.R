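# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

# random count table with guaranteed positive sample totals
random_counts <- function(n_taxa = 8, n_samples = 5, lambda = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
              dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                              sprintf("s%02d", seq_len(n_samples))))
  m[, colSums(m) == 0] <- m[, colSums(m) == 0] + 1
  m
}

# three-biome metadata for a given sample split
make_meta <- function(aquatic, airborne, sediment,
                      salinity = seq(0.5, 35, length.out = length(aquatic))) {
  data.frame(
    sample_id = c(aquatic, airborne, sediment),
    biome = rep(c("aquatic", "airborne", "sediment"),
                c(length(aquatic), length(airborne), length(sediment))),
    salinity = c(salinity, rep(NA_real_, length(airborne) + length(sediment))),
    stringsAsFactors = FALSE
  )
}

# small config for fast pipeline runs: 20 aquatic samples keep every salinity
# bin occupied on the default 0.5-35 grid
tiny_config <- function(seed = 1) {
  list(
    taxa = list(n_generalist = 8, n_specialist = 30,
                n_airborne_specific = 8, n_sediment_specific = 6),
    design = list(n_aquatic = 20, n_airborne = 5, n_sediment = 3,
                  depth = 2000, salinity_min = 0.5, salinity_max = 35,
                  overdispersion = 0, leakage = 1e-4),
    sources = list(n_terms_pool = 40, q = 0.6, mean_matches = 150),
    rarefaction = list(min_depth = 100, depth = 1500, reps = 10),
    specificity = list(n_perm = 99),
    seed = seed
  )
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
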