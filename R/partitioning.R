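# Seven biome-overlap classes: which subset of the three compartments a taxon
# was ever detected in (any read counts as detection).
PARTITION_LABELS <- c("aquatic_only", "airborne_only", "sediment_only",
                      "aquatic_airborne", "aquatic_sediment",
                      "airborne_sediment", "all_three")

SALINITY_BIN_LEVELS <- c("slightly_brackish", "brackish", "marine",
                         "hypersaline", "highly_hypersaline")

#' Biome-overlap partition labels
#' @return Character vector of the 7 class names.
#' @export
partition_labels <- function() PARTITION_LABELS

#' Salinity bin levels
#' @return Character vector of the 5 bin names, fresh to hypersaline order.
#' @export
salinity_bin_levels <- function() SALINITY_BIN_LEVELS

#' Assign aquatic samples to salinity ranges
#'
#' Five salt ranges on % w/v: slightly brackish below 1.5, brackish 1.5 to
#' below 3, marine 3 to below 5, hypersaline 5 to below 15, highly hypersaline
#' 15 and above. Bins are half-open `[lower, upper)`, so the boundary values
#' 1.5, 3, 5 and 15 fall in the upper bin (15.0 is highly hypersaline).
#'
#' @param salinity Numeric vector of salinities (% w/v), all `>= 0`.
#' @param edges Interior bin boundaries, default `c(1.5, 3, 5, 15)`.
#' @return Ordered factor with levels [salinity_bin_levels()].
#' @export
assign_salinity_bin <- function(salinity, edges = c(1.5, 3, 5, 15)) {
  if (anyNA(salinity)) stop("salinity contains missing values")
  if (any(salinity < 0)) stop("negative salinity")
  cut(salinity, breaks = c(0, edges, Inf), labels = SALINITY_BIN_LEVELS,
      right = FALSE, include.lowest = TRUE, ordered_result = TRUE)
}

#' Partition taxa by the set of biomes they are detected in
#'
#' A taxon is detected in a biome when its total count over that biome's
#' samples is positive; the label names the subset of the three biomes with
#' detection. Taxa with zero total count everywhere are excluded and listed in
#' the `"dropped"` attribute.
#'
#' @param t Count matrix (taxa x samples).
#' @param meta Sample metadata covering every sample of `t`.
#' @return Named factor (taxon -> label) with levels [partition_labels()].
#' @export
venn_partition <- function(t, meta) {
  meta <- validate_sample_metadata(meta, sample_ids = colnames(t))
  biome <- meta$biome[match(colnames(t), meta$sample_id)]
  if (!all(BIOME_LEVELS %in% biome))
    stop("every biome needs at least one sample; missing: ",
         paste(setdiff(BIOME_LEVELS, biome), collapse = ", "))
  det <- vapply(BIOME_LEVELS, function(b)
    rowSums(t[, biome == b, drop = FALSE]) > 0, logical(nrow(t)))
  present <- rowSums(det) > 0
  key <- paste(det[, "aquatic"], det[, "airborne"], det[, "sediment"])
  lab <- c("TRUE FALSE FALSE" = "aquatic_only",
           "FALSE TRUE FALSE" = "airborne_only",
           "FALSE FALSE TRUE" = "sediment_only",
           "TRUE TRUE FALSE"  = "aquatic_airborne",
           "TRUE FALSE TRUE"  = "aquatic_sediment",
           "FALSE TRUE TRUE"  = "airborne_sediment",
           "TRUE TRUE TRUE"   = "all_three")[key]
  out <- factor(lab[present], levels = PARTITION_LABELS)
  names(out) <- rownames(t)[present]
  attr(out, "dropped") <- rownames(t)[!present]
  out
}

#' Per-sample partition-class profile
#'
#' For every sample, the share of its detected taxa (richness proportion) and
#' of its abundance falling in each biome-overlap class, re-normalised to the
#' taxa detected in that sample so both sets of proportions sum to 1.
#'
#' @param t Abundance matrix (taxa x samples); relative or rarefaction-averaged.
#' @param labels Taxon -> class factor from [venn_partition()]; must cover
#'   every taxon detected in `t`.
#' @param meta Optional metadata (required when `restrict_biome` is used).
#' @param restrict_biome Optional biome name; only its samples are profiled.
#' @return Long data frame: sample, class, richness_prop, abundance.
#' @export
partition_profile <- function(t, labels, meta = NULL, restrict_biome = NULL) {
  samples <- colnames(t)
  if (!is.null(restrict_biome)) {
    if (is.null(meta)) stop("metadata required to restrict by biome")
    meta <- validate_sample_metadata(meta, sample_ids = samples)
    biome <- meta$biome[match(samples, meta$sample_id)]
    samples <- samples[biome == restrict_biome]
    if (!length(samples)) stop("no samples in biome ", restrict_biome)
  }
  res <- lapply(samples, function(s) {
    x <- t[, s]
    det <- x > 0
    if (!any(det))
      return(data.frame(sample = s, class = PARTITION_LABELS,
                        richness_prop = NA_real_, abundance = NA_real_))
    lab <- labels[rownames(t)[det]]
    if (anyNA(lab))
      stop("unlabeled detected taxa in sample ", s, ": ",
           paste(rownames(t)[det][is.na(lab)], collapse = ", "))
    ab <- x[det] / sum(x[det])
    data.frame(
      sample = s,
      class = PARTITION_LABELS,
      richness_prop = as.vector(table(lab)[PARTITION_LABELS]) / sum(det),
      abundance = as.vector(tapply(ab, lab, sum, default = 0)[PARTITION_LABELS])
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Abundant taxa per biome
#'
#' Taxa whose mean relative abundance across a biome's samples reaches a
#' threshold (default 0.25%), per biome and as the union over biomes.
#'
#' @param t Relative-abundance matrix.
#' @param meta Sample metadata.
#' @param threshold Mean relative-abundance cutoff as a fraction.
#' @return List with one character vector per biome plus `union`.
#' @export
abundant_taxa <- function(t, meta, threshold = 0.0025) {
  meta <- validate_sample_metadata(meta, sample_ids = colnames(t))
  biome <- meta$biome[match(colnames(t), meta$sample_id)]
  out <- lapply(BIOME_LEVELS, function(b) {
    cols <- biome == b
    if (!any(cols)) return(character())
    rn <- rowMeans(t[, cols, drop = FALSE])
    rownames(t)[rn >= threshold]
  })
  names(out) <- BIOME_LEVELS
  out$union <- unique(unlist(out, use.names = FALSE))
  out
}

#' Mean abundance of each taxon within sample groups
#'
#' The taxon-by-compartment matrix of arithmetic mean relative abundances,
#' e.g. biomes with the aquatic biome split by salinity range; this is the
#' input matrix for heatmap clustering of the abundant taxa.
#'
#' @param t Abundance matrix.
#' @param groups Named factor or character vector, sample -> group, covering
#'   every sample column of `t`.
#' @return Matrix taxa x groups.
#' @export
compartment_mean_abundance <- function(t, groups) {
  if (is.null(names(groups))) stop("groups must be named by sample id")
  miss <- setdiff(colnames(t), names(groups))
  if (length(miss)) stop("ungrouped sample(s): ", paste(miss, collapse = ", "))
  g <- factor(groups[colnames(t)])
  if (any(table(g) == 0)) stop("empty group(s): ",
                               paste(levels(g)[table(g) == 0], collapse = ", "))
  out <- vapply(levels(g), function(lv)
    rowMeans(t[, g == lv, drop = FALSE]), numeric(nrow(t)))
  rownames(out) <- rownames(t)
  out
}

#' Spearman correlation along the salinity gradient
#'
#' Rank correlation (average ranks for ties) between a per-sample quantity and
#' salinity, with the two-sided p-value from the t approximation.
#'
#' @param x Per-sample values.
#' @param salinity Matching salinities.
#' @return List with `rho`, `p` and `n`.
#' @export
gradient_correlation <- function(x, salinity) {
  keep <- !is.na(x) & !is.na(salinity)
  x <- x[keep]; salinity <- salinity[keep]
  if (length(x) < 5L) stop("need at least 5 paired observations")
  if (stats::sd(x) == 0 || stats::sd(salinity) == 0)
    stop("Spearman correlation undefined for a constant input")
  ct <- suppressWarnings(
    stats::cor.test(x, salinity, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
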