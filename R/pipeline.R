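# End-to-end orchestration: simulate (or load) -> validate -> rarefaction-
# averaged tables and diversity -> biome-overlap partition -> specificity ->
# source profiles, with every output registered in a JSON manifest.

#' Cross-validate pipeline inputs
#'
#' Checks that metadata covers exactly the samples of the count table, that
#' every biome present is legal, that aquatic samples carry salinities, and
#' (when a hit table is given) how much of the taxon set it covers. Problems
#' are split into fatal errors and warnings.
#'
#' @param counts Count matrix.
#' @param meta Sample metadata.
#' @param hits Optional hit table.
#' @param min_coverage Hit-table coverage below this fraction triggers a
#'   warning (default 0.8).
#' @return List of class `validation_report` with `errors` and `warnings`
#'   character vectors and `ok` flag.
#' @export
validate_inputs <- function(counts, meta, hits = NULL, min_coverage = 0.8) {
  errors <- character()
  warnings <- character()
  tryCatch(validate_count_table(counts),
           error = function(e) errors <<- c(errors, conditionMessage(e)))
  m <- tryCatch(validate_sample_metadata(meta),
                error = function(e) {
                  errors <<- c(errors, conditionMessage(e)); NULL
                })
  if (!is.null(m) && !length(errors)) {
    miss <- setdiff(colnames(counts), m$sample_id)
    if (length(miss))
      errors <- c(errors, paste0("metadata missing sample(s): ",
                                 paste(miss, collapse = ", ")))
    extra <- setdiff(m$sample_id, colnames(counts))
    if (length(extra))
      warnings <- c(warnings, paste0("metadata rows without counts: ",
                                     paste(extra, collapse = ", ")))
    covered <- intersect(m$sample_id, colnames(counts))
    biomes <- unique(m$biome[m$sample_id %in% covered])
    absent <- setdiff(BIOME_LEVELS, biomes)
    if (length(absent))
      warnings <- c(warnings, paste0("no samples for biome(s): ",
                                     paste(absent, collapse = ", ")))
  }
  if (!is.null(hits)) {
    h <- tryCatch(validate_hit_table(hits),
                  error = function(e) {
                    errors <<- c(errors, conditionMessage(e)); NULL
                  })
    if (!is.null(h)) {
      cov <- mean(rownames(counts) %in% h$taxon)
      if (cov < min_coverage)
        warnings <- c(warnings, sprintf(
          "hit table covers %.1f%% of taxa (below %.0f%%)",
          100 * cov, 100 * min_coverage))
    }
  }
  structure(list(errors = errors, warnings = warnings,
                 ok = length(errors) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok && !length(x$warnings)) cat("inputs valid; no warnings\n")
  if (length(x$errors)) cat("errors:\n", paste0("  - ", x$errors, "\n"), sep = "")
  if (length(x$warnings)) cat("warnings:\n", paste0("  - ", x$warnings, "\n"), sep = "")
  invisible(x)
}

pipeline_stage <- function(manifest, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  message("[", name, "] running")
  value <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  manifest$timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  list(manifest = manifest, value = value)
}

register_file <- function(manifest, key, path) {
  manifest$files[[key]] <- path
  manifest
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the inputs, validates them, builds the
#' rarefaction-averaged abundance table, per-sample diversity and the
#' Bray-Curtis matrix after Hellinger standardisation, the biome-overlap
#' partition with gradient profiles, the specificity analysis with its
#' permutation null, and the source-profile aggregates. All tables are
#' written as TSV under `out_dir` and registered in a JSON manifest.
#'
#' @param config Optional configuration list or YAML path. Recognised keys:
#'   those of [default_config()] plus `inputs` (list with `counts`, `metadata`
#'   and optionally `hits` paths; when present, files are read instead of
#'   simulated), `rarefaction` (list: `reps`, default 100; `depth`, default
#'   the minimum sample total; `min_depth` QC cutoff, default 9000),
#'   `specificity` (list: `n_perm`, default 999; `transform`; `pseudocount`),
#'   `sources` (`min_identity`, default 99; `weighting`).
#' @param out_dir Output directory.
#' @param seed Optional master seed overriding the config seed.
#' @return List of class `pipeline_result`: `manifest` plus the in-memory
#'   stage results (`dataset`, `abundance`, `labels`, `profile`,
#'   `specificity`, `sources`, ...).
#' @export
run_pipeline <- function(config = NULL, out_dir = "results", seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  rar <- utils::modifyList(list(reps = 100, depth = NULL, min_depth = 9000),
                           config$rarefaction %||% list())
  spec_cfg <- utils::modifyList(
    list(n_perm = 999, transform = "log10", pseudocount = 1e-6),
    config$specificity %||% list())
  src_cfg <- utils::modifyList(list(min_identity = 99,
                                    weighting = "detected_unweighted"),
                               config$sources_analysis %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "salinispec",
                   version = as.character(utils::packageVersion("salinispec")),
                   seed = cfg$seed, files = list(), timings = list())

  # -- inputs ----------------------------------------------------------------
  st <- pipeline_stage(manifest, "inputs", {
    if (!is.null(config$inputs)) {
      inp <- config$inputs
      for (f in unlist(inp)) if (!file.exists(f)) stop("file not found: ", f)
      list(counts = read_count_table(inp$counts),
           meta = read_sample_metadata(inp$metadata),
           hits = if (!is.null(inp$hits)) read_hit_table(inp$hits),
           truth = NULL)
    } else {
      ds <- generate_dataset(config, seed = cfg$seed)
      ds
    }
  })
  manifest <- st$manifest; ds <- st$value

  st <- pipeline_stage(manifest, "validate", {
    rep <- validate_inputs(ds$counts, ds$meta, ds$hits)
    if (!rep$ok) stop(paste(rep$errors, collapse = "; "))
    for (w in rep$warnings) warning(w, call. = FALSE)
    rep
  })
  manifest <- st$manifest

  # -- tables ----------------------------------------------------------------
  st <- pipeline_stage(manifest, "tables", {
    counts <- filter_min_depth(ds$counts, rar$min_depth)
    meta <- ds$meta[ds$meta$sample_id %in% colnames(counts), , drop = FALSE]
    depth <- rar$depth %||% min(colSums(counts))
    mr <- mean_rarefied_table(counts, depth, reps = rar$reps,
                              seed = derive_seed(cfg$seed, 101L))
    rel <- relative_abundance(mr)
    div <- data.frame(sample = colnames(mr),
                      richness = apply(mr, 2L, richness),
                      shannon = apply(mr, 2L, shannon))
    bc <- bray_curtis(hellinger(mr))
    write_count_table(mr, file.path(out_dir, "mean_rarefied.tsv"))
    utils::write.table(div, file.path(out_dir, "alpha_diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_distance_matrix(bc, file.path(out_dir, "bray_curtis.tsv"))
    list(counts = counts, meta = meta, depth = depth, mean_rarefied = mr,
         abundance = rel, diversity = div, bray_curtis = bc)
  })
  manifest <- st$manifest; tab <- st$value
  manifest <- register_file(manifest, "mean_rarefied",
                            file.path(out_dir, "mean_rarefied.tsv"))
  manifest <- register_file(manifest, "alpha_diversity",
                            file.path(out_dir, "alpha_diversity.tsv"))
  manifest <- register_file(manifest, "bray_curtis",
                            file.path(out_dir, "bray_curtis.tsv"))

  # -- partition -------------------------------------------------------------
  st <- pipeline_stage(manifest, "partition", {
    labels <- venn_partition(tab$counts, tab$meta)
    prof <- partition_profile(tab$abundance, labels, tab$meta,
                              restrict_biome = "aquatic")
    sal <- tab$meta$salinity[match(prof$sample, tab$meta$sample_id)]
    prof$salinity <- sal
    aq_only <- prof[prof$class == "aquatic_only", ]
    grad <- gradient_correlation(aq_only$abundance, aq_only$salinity)
    ab <- abundant_taxa(tab$abundance, tab$meta)
    gmap <- make_group_assignment(tab$meta, require_all = FALSE)
    cmat <- compartment_mean_abundance(
      tab$abundance[ab$union, , drop = FALSE], gmap)
    utils::write.table(
      data.frame(taxon = names(labels), label = as.character(labels)),
      file.path(out_dir, "partition_labels.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(prof, file.path(out_dir, "partition_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_count_table(cmat, file.path(out_dir, "compartment_means.tsv"))
    list(labels = labels, profile = prof, gradient = grad,
         abundant = ab, compartment_means = cmat)
  })
  manifest <- st$manifest; part <- st$value
  manifest <- register_file(manifest, "partition_labels",
                            file.path(out_dir, "partition_labels.tsv"))
  manifest <- register_file(manifest, "partition_profile",
                            file.path(out_dir, "partition_profile.tsv"))
  manifest <- register_file(manifest, "compartment_means",
                            file.path(out_dir, "compartment_means.tsv"))

  # -- specificity -----------------------------------------------------------
  st <- pipeline_stage(manifest, "specificity", {
    sa <- run_specificity_analysis(
      tab$abundance, tab$meta, n_perm = spec_cfg$n_perm,
      seed = derive_seed(cfg$seed, 102L), transform = spec_cfg$transform,
      pseudocount = spec_cfg$pseudocount)
    utils::write.table(specificity_table(sa),
                       file.path(out_dir, "specificity_values.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(slope_contrast_table(sa),
                       file.path(out_dir, "specificity_slopes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sa
  })
  manifest <- st$manifest; sa <- st$value
  manifest <- register_file(manifest, "specificity_values",
                            file.path(out_dir, "specificity_values.tsv"))
  manifest <- register_file(manifest, "specificity_slopes",
                            file.path(out_dir, "specificity_slopes.tsv"))

  # -- sources ---------------------------------------------------------------
  src <- NULL
  if (!is.null(ds$hits)) {
    st <- pipeline_stage(manifest, "sources", {
      prof <- build_source_profiles(ds$hits, min_identity = src_cfg$min_identity,
                                    taxa = rownames(tab$counts))
      aq <- tab$meta$sample_id[tab$meta$biome == "aquatic"]
      csm <- community_source_means(
        tab$abundance[, aq, drop = FALSE], prof$stats,
        weighting = src_cfg$weighting)
      csm$salinity <- tab$meta$salinity[match(csm$sample, tab$meta$sample_id)]
      grad_div <- gradient_correlation(csm$mean_diversity, csm$salinity)
      cls <- partition_source_comparison(prof$stats, part$labels)
      rich <- stats::setNames(prof$stats$source_richness, prof$stats$taxon)
      corr <- lapply(colnames(sa$S_obs), function(j)
        tryCatch(c(list(category = j),
                   specificity_source_correlation(sa$S_obs[, j], rich)),
                 error = function(e) NULL))
      corr <- do.call(rbind, lapply(Filter(Negate(is.null), corr), as.data.frame))
      utils::write.table(prof$stats, file.path(out_dir, "source_stats.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(csm, file.path(out_dir, "community_source_means.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cls, file.path(out_dir, "partition_source.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(corr, file.path(out_dir, "specificity_source_corr.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(profiles = prof, community_means = csm, gradient = grad_div,
           by_class = cls, correlations = corr)
    })
    manifest <- st$manifest; src <- st$value
    for (k in c("source_stats", "community_source_means", "partition_source",
                "specificity_source_corr"))
      manifest <- register_file(manifest, k, file.path(out_dir, paste0(k, ".tsv")))
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  structure(list(manifest = manifest, manifest_path = manifest_path,
                 dataset = ds, tables = tab, partition = part,
                 specificity = sa, sources = src),
            class = "pipeline_result")
}
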