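# Biome vocabulary used throughout: airborne (wet-deposition tropospheric),
# sediment (dry lake sediment) and aquatic (plankton).
BIOME_LEVELS <- c("airborne", "sediment", "aquatic")

#' Biome levels
#'
#' The three compartments a sample can belong to.
#' @return Character vector `c("airborne", "sediment", "aquatic")`.
#' @export
biome_levels <- function() BIOME_LEVELS

# ---- validation -------------------------------------------------------------

#' Validate a taxon-by-sample count table
#'
#' A count table is a numeric matrix of non-negative integer read counts with
#' taxa as rows and samples as columns, unique dimnames on both axes, and at
#' least one taxon and one sample.
#'
#' @param counts Numeric matrix, taxa in rows, samples in columns.
#' @return The validated matrix (invisibly unchanged).
#' @export
validate_count_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("count table must be a numeric matrix (taxa x samples)")
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("count table needs at least 1 taxon and 1 sample")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table must carry taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts)) stop("count table contains missing values")
  if (any(counts < 0)) stop("count table contains negative values")
  if (any(counts != floor(counts))) stop("count table contains non-integer values")
  invisible(counts)
}

# ---- I/O --------------------------------------------------------------------

#' Read a taxon-by-sample count table
#'
#' TSV dialect: first column taxon id, header row of sample ids, tab-separated
#' integer counts, UTF-8, no quoting. The BIOM reader accepts the JSON flavour
#' via the \pkg{biomformat} package.
#'
#' @param path Path to the table file.
#' @param format `"tsv"` (default) or `"biom_json"`.
#' @return Validated count matrix (taxa x samples), input order preserved.
#' @export
read_count_table <- function(path, format = c("tsv", "biom_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom_json") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    storage.mode(m) <- "double"
    return(validate_count_table(m))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("parse error in ", path, ": need a header line and at least one taxon row")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L)
    stop("parse error in ", path, " at line 1: header must name at least one sample")
  samples <- header[-1L]
  n <- length(lines) - 1L
  taxa <- character(n)
  counts <- matrix(NA_real_, nrow = n, ncol = length(samples))
  for (i in seq_len(n)) {
    fields <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != length(header))
      stop("parse error in ", path, " at line ", i + 1L, ": expected ",
           length(header), " fields, found ", length(fields))
    taxa[i] <- fields[[1L]]
    vals <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(vals))
      stop("parse error in ", path, " at line ", i + 1L, ": non-numeric count")
    counts[i, ] <- vals
  }
  dimnames(counts) <- list(taxa, samples)
  validate_count_table(counts)
}

#' Write a count or abundance table as TSV
#'
#' @param x Matrix with taxon rownames and sample colnames.
#' @param path Output path.
#' @param id_column Name of the leading taxon-id column (default `"taxon"`).
#' @export
write_count_table <- function(x, path, id_column = "taxon") {
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects TSV columns `sample_id`, `biome` and, for aquatic samples,
#' `salinity` (% w/v); an optional `date` column is passed through.
#'
#' @param path Path to metadata TSV.
#' @return Data frame with validated columns.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_metadata(meta)
}

#' Validate sample metadata
#'
#' Checks for the required columns, legal biome labels, uniqueness of sample
#' ids, non-negative salinity, and salinity present for every aquatic sample.
#' If `sample_ids` is given, additionally requires exactly one metadata row
#' per listed sample.
#'
#' @param meta Data frame of sample metadata.
#' @param sample_ids Optional character vector of sample ids that must be
#'   covered.
#' @return The validated metadata.
#' @export
validate_sample_metadata <- function(meta, sample_ids = NULL) {
  need <- c("sample_id", "biome")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(meta$biome), BIOME_LEVELS)
  if (length(bad))
    stop("unknown biome label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(BIOME_LEVELS, collapse = "/"), ")")
  if (!"salinity" %in% names(meta)) meta$salinity <- NA_real_
  meta$salinity <- as.numeric(meta$salinity)
  aq <- meta$biome == "aquatic"
  if (any(aq & is.na(meta$salinity)))
    stop("salinity missing for aquatic sample(s): ",
         paste(meta$sample_id[aq & is.na(meta$salinity)], collapse = ", "))
  if (any(!is.na(meta$salinity) & meta$salinity < 0))
    stop("negative salinity for sample(s): ",
         paste(meta$sample_id[!is.na(meta$salinity) & meta$salinity < 0], collapse = ", "))
  if (!is.null(sample_ids)) {
    missing_rows <- setdiff(sample_ids, meta$sample_id)
    if (length(missing_rows))
      stop("metadata missing sample(s): ", paste(missing_rows, collapse = ", "))
  }
  meta
}

#' Drop shallow samples before rarefaction
#'
#' Quality filter removing samples whose total read count falls below a
#' minimum sequencing depth (default 9000 reads).
#'
#' @param counts Count matrix.
#' @param min_depth Minimum total reads per retained sample.
#' @return Filtered count matrix; removed sample ids in attribute `"removed"`.
#' @export
filter_min_depth <- function(counts, min_depth = 9000) {
  validate_count_table(counts)
  keep <- colSums(counts) >= min_depth
  if (!any(keep)) stop("no sample reaches min_depth = ", min_depth)
  out <- counts[, keep, drop = FALSE]
  attr(out, "removed") <- colnames(counts)[!keep]
  out
}

# ---- normalisation and rarefaction -----------------------------------------

#' Relative abundance per sample
#'
#' Divides every sample column by its total so each column sums to 1.
#'
#' @param t Count (or abundance) matrix, taxa x samples.
#' @return Matrix of per-sample relative abundances.
#' @export
relative_abundance <- function(t) {
  tot <- colSums(t)
  if (any(tot <= 0))
    stop("zero-total sample(s): ", paste(colnames(t)[tot <= 0], collapse = ", "))
  sweep(t, 2L, tot, "/")
}

# Counter-based seed derivation so replicate r of a master seed is
# reproducible independently of how many replicates run before it.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 2147483647 + 48271 * as.numeric(i)) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

rarefy_column <- function(x, depth) {
  tot <- sum(x)
  if (tot == depth) return(x)
  pos <- sample.int(tot, depth)              # distinct read positions
  idx <- findInterval(pos - 0.5, c(0, cumsum(x)))
  tabulate(idx, nbins = length(x))
}

#' Rarefy a count table to a common depth
#'
#' Subsamples each sample's reads to `depth` without replacement (multivariate
#' hypergeometric per sample), so every output column sums exactly to `depth`
#' and no output count exceeds its input count. Multinomial resampling with
#' replacement is available behind `replace = TRUE`.
#'
#' @param t Count matrix.
#' @param depth Target reads per sample; must not exceed any sample total.
#' @param seed Optional integer seed for reproducibility (RNG state is
#'   restored afterwards).
#' @param replace Sample with replacement (multinomial) instead.
#' @return Rarefied count matrix.
#' @export
rarefy <- function(t, depth, seed = NULL, replace = FALSE) {
  validate_count_table(t)
  if (length(depth) != 1L || depth < 1 || depth != floor(depth))
    stop("depth must be a single positive integer")
  tot <- colSums(t)
  low <- tot < depth
  if (any(low))
    stop("depth ", depth, " exceeds total reads of sample(s): ",
         paste(colnames(t)[low], collapse = ", "))
  with_seed(seed, {
    out <- if (replace) {
      apply(t, 2L, function(x) as.vector(stats::rmultinom(1L, depth, x / sum(x))))
    } else {
      apply(t, 2L, rarefy_column, depth = depth)
    }
    dimnames(out) <- dimnames(t)
    out
  })
}

#' Rarefaction-averaged community table
#'
#' Repeats rarefaction at a common depth `reps` times (default 100) and
#' averages the tables element-wise, which retains low-abundance taxa that a
#' single rarefaction draw could lose. Every output column sums exactly to
#' `depth`; taxa absent from the input remain exactly 0.
#'
#' @inheritParams rarefy
#' @param reps Number of independent rarefactions to average.
#' @return Numeric matrix (taxa x samples) with column sums equal to `depth`.
#' @export
mean_rarefied_table <- function(t, depth, reps = 100, seed = NULL, replace = FALSE) {
  if (reps < 1) stop("reps must be >= 1")
  acc <- matrix(0, nrow = nrow(t), ncol = ncol(t), dimnames = dimnames(t))
  for (r in seq_len(reps)) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, r)
    acc <- acc + rarefy(t, depth, seed = s, replace = replace)
  }
  acc / reps
}

#' Hellinger standardisation
#'
#' Square root of within-sample relative abundances,
#' \eqn{x_{ij} \to \sqrt{x_{ij} / \sum_i x_{ij}}}, giving columns of unit
#' Euclidean norm; the conventional pre-treatment before Bray-Curtis or
#' Euclidean ordination of community data.
#'
#' @param t Non-negative matrix (taxa x samples) with no all-zero column.
#' @return Hellinger-transformed matrix.
#' @export
hellinger <- function(t) {
  if (any(t < 0)) stop("Hellinger standardisation needs non-negative input")
  tot <- colSums(t)
  if (any(tot <= 0))
    stop("all-zero sample column(s): ", paste(colnames(t)[tot <= 0], collapse = ", "))
  out <- t(vegan::decostand(t(t), method = "hellinger"))
  dimnames(out) <- dimnames(t)
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise \eqn{d(a,b) = \sum_i |a_i - b_i| / \sum_i (a_i + b_i)} between
#' sample columns; symmetric, zero diagonal, values in \[0, 1\].
#'
#' @param t Non-negative matrix, taxa x samples, at least 2 samples.
#' @return Square symmetric matrix with sample dimnames.
#' @export
bray_curtis <- function(t) {
  if (ncol(t) < 2L) stop("need at least 2 samples")
  if (any(t < 0)) stop("Bray-Curtis needs non-negative input")
  m <- as.matrix(suppressWarnings(vegan::vegdist(t(t), method = "bray")))
  if (any(!is.finite(m))) {
    empty <- colnames(t)[colSums(t) == 0]
    stop("Bray-Curtis undefined for pair(s) of empty samples: ",
         paste(empty, collapse = ", "))
  }
  m
}

#' Write a labelled square distance matrix as TSV
#' @param d Square matrix with sample dimnames.
#' @param path Output path.
#' @export
write_distance_matrix <- function(d, path) {
  write_count_table(d, path, id_column = "sample")
}

# ---- diversity --------------------------------------------------------------

#' Shannon diversity of a count or abundance vector
#'
#' \eqn{H = -\sum_i p_i \log p_i} over the non-zero proportions
#' \eqn{p_i = v_i / \sum v}; natural log by default.
#'
#' @param v Non-negative vector with positive sum.
#' @param base Logarithm base (default `exp(1)`, i.e. nats).
#' @return Shannon diversity.
#' @export
shannon <- function(v, base = exp(1)) {
  if (any(v < 0)) stop("negative entries in abundance vector")
  if (sum(v) <= 0) stop("Shannon diversity undefined for an all-zero vector")
  as.numeric(vegan::diversity(v, index = "shannon", base = base))
}

#' Taxon richness of a vector
#'
#' Number of strictly positive entries.
#' @param v Non-negative vector.
#' @return Integer count.
#' @export
richness <- function(v) {
  if (any(v < 0)) stop("negative entries in abundance vector")
  sum(v > 0)
}
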