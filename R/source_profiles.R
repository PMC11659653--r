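# Source profiles: each taxon carries a table of environmental-ontology terms
# recovered from high-identity database matches of its sequence. The weight of
# a term is the proportion of matched sequences reported from that source;
# the number (richness) and Shannon diversity of a taxon's terms proxy its
# habitat generalism at the global scale.

#' Validate a source-hit table
#'
#' Columns: `taxon`, `term`, `identity` (percent, 0-100), `count`
#' (matched sequences, positive integer). A (taxon, term) pair may repeat;
#' counts are aggregated downstream.
#'
#' @param h Data frame of hits.
#' @return Validated data frame.
#' @export
validate_hit_table <- function(h) {
  need <- c("taxon", "term", "identity", "count")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("hit table missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(h[need])) stop("hit table contains missing values")
  if (any(h$identity < 0 | h$identity > 100)) stop("identity must lie in [0, 100]")
  if (any(h$count < 1 | h$count != floor(h$count)))
    stop("count must be a positive integer")
  h
}

#' Read a source-hit table from TSV
#' @param path Path to TSV with columns taxon, term, identity, count.
#' @return Validated hit table.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_hit_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Filter hits by percent identity
#'
#' Retains rows whose identity reaches the threshold (default 99%, the
#' conventional cutoff for near-exact sequence matches).
#'
#' @param h Hit table.
#' @param min_identity Minimum percent identity.
#' @return Filtered hit table.
#' @export
filter_hits <- function(h, min_identity = 99) {
  h <- validate_hit_table(h)
  h[h$identity >= min_identity, , drop = FALSE]
}

#' Term proportions for one taxon
#'
#' The relative contribution of each source term: summed matched-sequence
#' count for the term divided by the taxon's total matched count.
#'
#' @param h Hit table (already identity-filtered if desired).
#' @param taxon Taxon id with at least one retained hit.
#' @return Named numeric vector of proportions summing to 1.
#' @export
term_proportions <- function(h, taxon) {
  h <- validate_hit_table(h)
  rows <- h[h$taxon == taxon, , drop = FALSE]
  if (!nrow(rows)) stop("no retained hits for taxon ", taxon)
  agg <- tapply(rows$count, rows$term, sum)
  p <- as.numeric(agg) / sum(agg)
  names(p) <- names(agg)
  p
}

#' Richness and Shannon diversity of a source profile
#'
#' @param p Term-proportion vector summing to 1.
#' @return List with `richness` (number of terms with positive weight) and
#'   `diversity` (Shannon H in nats).
#' @export
source_stats <- function(p) {
  if (any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("proportions must sum to 1")
  pos <- p[p > 0]
  list(richness = length(pos), diversity = -sum(pos * log(pos)))
}

#' Per-taxon source profiles
#'
#' Identity-filters the hit table, aggregates counts per (taxon, term), and
#' derives each taxon's term proportions, source richness and source Shannon
#' diversity. When a taxon universe is supplied, taxa without any retained
#' hit are flagged and a coverage fraction is reported.
#'
#' @param h Hit table.
#' @param min_identity Identity threshold (default 99).
#' @param taxa Optional character vector: the full taxon universe.
#' @return List: `stats` (data frame taxon, source_richness,
#'   source_diversity), `proportions` (long data frame taxon, term,
#'   proportion), `no_info` (taxa without retained hits), `coverage`
#'   (fraction of `taxa` with a profile, `NA` when `taxa` is missing).
#' @export
build_source_profiles <- function(h, min_identity = 99, taxa = NULL) {
  h <- filter_hits(h, min_identity)
  if (!nrow(h)) {
    stats <- data.frame(taxon = character(), source_richness = integer(),
                        source_diversity = numeric())
    return(list(stats = stats,
                proportions = data.frame(taxon = character(), term = character(),
                                         proportion = numeric()),
                no_info = taxa %||% character(),
                coverage = if (is.null(taxa)) NA_real_ else 0))
  }
  agg <- stats::aggregate(count ~ taxon + term, data = h, FUN = sum)
  tot <- tapply(agg$count, agg$taxon, sum)
  agg$proportion <- agg$count / as.numeric(tot[agg$taxon])
  per_taxon <- split(agg$proportion, agg$taxon)
  st <- data.frame(
    taxon = names(per_taxon),
    source_richness = vapply(per_taxon, length, integer(1)),
    source_diversity = vapply(per_taxon, function(p) -sum(p * log(p)), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(st) <- NULL
  no_info <- if (is.null(taxa)) character() else setdiff(taxa, st$taxon)
  coverage <- if (is.null(taxa)) NA_real_ else
    mean(taxa %in% st$taxon)
  list(stats = st,
       proportions = agg[order(agg$taxon, agg$term),
                         c("taxon", "term", "proportion")],
       no_info = no_info, coverage = coverage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Community-level mean source richness and diversity per sample
#'
#' For each sample, averages source richness and diversity over the taxa
#' detected in it that carry a source profile; either unweighted (default) or
#' weighted by the taxa's relative abundances in the sample.
#'
#' @param t Abundance matrix (taxa x samples).
#' @param stats Per-taxon stats data frame from [build_source_profiles()].
#' @param weighting `"detected_unweighted"` (default) or
#'   `"abundance_weighted"`.
#' @return Data frame: sample, n_detected, n_profiled, mean_richness,
#'   mean_diversity (NA when no detected taxon has a profile); overall
#'   profile coverage of detected taxa in attribute `"coverage"`.
#' @export
community_source_means <- function(t, stats,
                                   weighting = c("detected_unweighted",
                                                 "abundance_weighted")) {
  weighting <- match.arg(weighting)
  idx <- match(rownames(t), stats$taxon)
  rich <- stats$source_richness[idx]
  div <- stats$source_diversity[idx]
  res <- lapply(colnames(t), function(s) {
    x <- t[, s]
    det <- x > 0
    prof <- det & !is.na(rich)
    if (!any(prof))
      return(data.frame(sample = s, n_detected = sum(det), n_profiled = 0L,
                        mean_richness = NA_real_, mean_diversity = NA_real_))
    w <- if (weighting == "abundance_weighted") x[prof] / sum(x[prof])
         else rep(1 / sum(prof), sum(prof))
    data.frame(sample = s, n_detected = sum(det), n_profiled = sum(prof),
               mean_richness = sum(w * rich[prof]),
               mean_diversity = sum(w * div[prof]))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "coverage") <- sum(out$n_profiled) / max(sum(out$n_detected), 1L)
  if (any(out$n_profiled == 0))
    message(sum(out$n_profiled == 0), " sample(s) without any profiled taxon")
  out
}

#' Source diversity split by biome-overlap class
#'
#' Pairs each taxon's source statistics with its partition label, for
#' downstream boxplots or group tests (e.g. whether cosmopolitan taxa draw on
#' more global sources than compartment-specific ones).
#'
#' @param stats Per-taxon stats data frame.
#' @param labels Named factor taxon -> partition label.
#' @return Data frame: taxon, class, source_richness, source_diversity.
#' @export
partition_source_comparison <- function(stats, labels) {
  common <- intersect(stats$taxon, names(labels))
  if (!length(common)) {
    warning("no taxa shared between source profiles and partition labels")
    return(data.frame(taxon = character(), class = character(),
                      source_richness = integer(), source_diversity = numeric()))
  }
  idx <- match(common, stats$taxon)
  out <- data.frame(taxon = common,
                    class = as.character(labels[common]),
                    source_richness = stats$source_richness[idx],
                    source_diversity = stats$source_diversity[idx],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Correlation between local specificity and global source statistics
#'
#' Spearman rank correlation between one category's specificity values and a
#' per-taxon source statistic (richness or diversity), restricted to taxa
#' detected in the category (specificity above zero) that carry a profile.
#'
#' @param s Named per-taxon specificity vector for one category.
#' @param stat Named per-taxon source richness or diversity.
#' @param detected Optional logical (named like `s`) overriding the `s > 0`
#'   detection filter.
#' @return List with `rho`, `p` and `n`.
#' @export
specificity_source_correlation <- function(s, stat, detected = NULL) {
  common <- intersect(names(s), names(stat))
  s <- s[common]; stat <- stat[common]
  keep <- if (is.null(detected)) s > 0 else detected[common]
  keep <- keep & !is.na(s) & !is.na(stat)
  s <- s[keep]; stat <- stat[keep]
  if (length(s) < 5L) stop("need at least 5 taxa with both values")
  if (stats::sd(s) == 0 || stats::sd(stat) == 0)
    stop("Spearman correlation undefined for a constant input")
  ct <- suppressWarnings(
    stats::cor.test(s, stat, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(s))
}
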