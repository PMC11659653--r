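# Specificity of a taxon to a group of samples: the IndVal "A" component,
# retained for every group rather than reduced to its maximum. S_ij is the
# taxon's mean relative abundance in group j divided by the sum of its mean
# abundances over all groups, so each taxon's row sums to 1 and S_ij = 1
# marks exclusivity regardless of how abundant the taxon is.

#' Sample categories for the specificity analysis
#'
#' Airborne and sediment samples keep their biome as the category; aquatic
#' samples are categorised by salinity range, giving 7 categories in total.
#'
#' @param meta Sample metadata (aquatic rows need salinity).
#' @param edges Salinity bin boundaries, see [assign_salinity_bin()].
#' @param require_all Error when any of the 7 categories has no sample
#'   (default `TRUE`; the permutation design needs fixed group sizes).
#' @return Named factor sample -> category with levels airborne, sediment,
#'   then the five salinity bins.
#' @export
make_group_assignment <- function(meta, edges = c(1.5, 3, 5, 15),
                                  require_all = TRUE) {
  meta <- validate_sample_metadata(meta)
  lv <- c("airborne", "sediment", SALINITY_BIN_LEVELS)
  cat <- ifelse(meta$biome == "aquatic",
                as.character(assign_salinity_bin(
                  ifelse(meta$biome == "aquatic", meta$salinity, 0), edges)),
                meta$biome)
  g <- factor(cat, levels = lv)
  names(g) <- meta$sample_id
  if (require_all && any(table(g) == 0))
    stop("empty categor(ies): ", paste(lv[table(g) == 0], collapse = ", "))
  g
}

#' Mean relative abundance per taxon and category
#'
#' @param t Abundance matrix (taxa x samples).
#' @param g Named factor sample -> category covering all columns of `t`.
#' @return Matrix taxa x categories of arithmetic means.
#' @export
group_mean_abundance <- function(t, g) {
  g <- align_groups(t, g)
  t %*% group_weights(g)
}

align_groups <- function(t, g) {
  if (is.null(names(g))) stop("group assignment must be named by sample id")
  miss <- setdiff(colnames(t), names(g))
  if (length(miss)) stop("unassigned sample(s): ", paste(miss, collapse = ", "))
  g <- g[colnames(t)]
  g <- droplevels(factor(g))
  if (nlevels(g) < 2L) stop("need at least 2 categories")
  g
}

# samples x categories matrix with column j holding 1/n_j on group j's rows,
# so t %*% W is the matrix of group means.
group_weights <- function(g) {
  n <- table(g)
  if (any(n == 0)) stop("empty categor(ies): ",
                        paste(levels(g)[n == 0], collapse = ", "))
  W <- matrix(0, nrow = length(g), ncol = nlevels(g),
              dimnames = list(names(g), levels(g)))
  W[cbind(seq_along(g), as.integer(g))] <- 1 / as.numeric(n)[as.integer(g)]
  W
}

#' Per-group specificity index
#'
#' Row-normalises a taxon-by-category matrix of mean abundances:
#' \eqn{S_{ij} = \bar{x}_{ij} / \sum_k \bar{x}_{ik}}. Rows sum to 1; a value
#' of 1 means the taxon is exclusive to that category. Taxa with an all-zero
#' row are dropped with a warning.
#'
#' @param xbar Non-negative matrix taxa x categories, e.g. from
#'   [group_mean_abundance()].
#' @return Specificity matrix with the same dimnames (minus dropped taxa).
#' @export
specificity_index <- function(xbar) {
  if (any(xbar < 0)) stop("mean abundances must be non-negative")
  rs <- rowSums(xbar)
  if (any(rs == 0)) {
    warning("dropping ", sum(rs == 0), " taxa with zero abundance in every category")
    xbar <- xbar[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  xbar / rs
}

# Workhorse behind the permutation null: reshuffles the sample -> category
# labels (group sizes fixed), recomputes S each time, and accumulates the
# element-wise mean; optionally also accumulates linear functionals of each
# permutation's S columns (used for the permutation slope distribution, which
# is exact because the OLS slope is linear in the response).
permute_specificity_engine <- function(t, g, n_perm, seed = NULL, perms = NULL,
                                       slope_weights = NULL) {
  g <- align_groups(t, g)
  if (any(rowSums(t) == 0))
    stop("taxa with zero abundance in every sample cannot be permuted; drop them first")
  if (!is.null(perms)) n_perm <- length(perms)
  if (n_perm < 1) stop("n_perm must be >= 1")
  acc <- matrix(0, nrow = nrow(t), ncol = nlevels(g),
                dimnames = list(rownames(t), levels(g)))
  slopes <- if (!is.null(slope_weights))
    matrix(NA_real_, nrow = n_perm, ncol = length(slope_weights),
           dimnames = list(NULL, names(slope_weights)))
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      ord <- if (!is.null(perms)) perms[[k]] else sample.int(length(g))
      gk <- g
      levels_int <- as.integer(g)[ord]
      gk[] <- levels(g)[levels_int]
      Sk <- specificity_index(t %*% group_weights(gk))
      acc <- acc + Sk
      if (!is.null(slope_weights))
        for (j in names(slope_weights)) {
          w <- slope_weights[[j]]
          slopes[k, j] <- sum(w$w * Sk[w$taxa, j])
        }
    }
  })
  list(mean = acc / n_perm, slopes = slopes, n_perm = n_perm)
}

#' Permutation-null mean specificity
#'
#' Recomputes the specificity index after randomly reassigning each sample to
#' a category while keeping every category's sample count fixed (a uniform
#' random permutation of the observed label vector), and returns the
#' element-wise mean over `n_perm` permutations (default 999).
#'
#' @param t Abundance matrix; every taxon must be detected in at least one
#'   included sample.
#' @param g Named factor sample -> category.
#' @param n_perm Number of label permutations.
#' @param seed Optional seed (RNG state restored).
#' @param perms Optional list of explicit permutation vectors of
#'   `seq_len(ncol(t))`, overriding random generation (e.g.
#'   `list(seq_len(ncol(t)))` forces the identity permutation).
#' @return Matrix of per-taxon, per-category null mean specificity; attribute
#'   `"n_perm"` records the replicate count.
#' @export
permuted_specificity <- function(t, g, n_perm = 999, seed = NULL, perms = NULL) {
  res <- permute_specificity_engine(t, g, n_perm, seed = seed, perms = perms)
  out <- res$mean
  attr(out, "n_perm") <- res$n_perm
  out
}

#' Local abundance covariate
#'
#' Mean relative abundance of each taxon across one category's samples,
#' log10-transformed with a pseudocount by default (use `transform = "raw"`
#' for the untransformed mean).
#'
#' @param t Abundance matrix.
#' @param g Named factor sample -> category.
#' @param category Category name.
#' @param transform `"log10"` (default) or `"raw"`.
#' @param pseudocount Added before the log (default `1e-6`).
#' @return Named numeric vector per taxon.
#' @export
local_abundance <- function(t, g, category, transform = c("log10", "raw"),
                            pseudocount = 1e-6) {
  transform <- match.arg(transform)
  g <- align_groups(t, g)
  if (!category %in% levels(g)) stop("unknown category: ", category)
  m <- rowMeans(t[, g == category, drop = FALSE])
  if (transform == "log10") log10(m + pseudocount) else m
}

#' Linear trend of specificity against local abundance
#'
#' Ordinary least squares of one category's specificity values on the
#' (transformed) local-abundance covariate. By default only taxa detected in
#' the category (specificity above zero) enter the fit; taxa absent from a
#' category would otherwise pile up at the pseudocount floor and manufacture
#' slope.
#'
#' @param s Per-taxon specificity for one category.
#' @param a Matching local-abundance covariate.
#' @param detected_only Drop taxa with `s == 0` (default `TRUE`).
#' @param detected Optional logical vector overriding the detection filter.
#' @return Object of class `spec_linfit`: slope, intercept, se, df, n, exact.
#' @export
fit_specificity_trend <- function(s, a, detected_only = TRUE, detected = NULL) {
  if (length(s) != length(a)) stop("s and a must have equal length")
  keep <- !is.na(s) & !is.na(a)
  if (is.null(detected)) detected <- if (detected_only) s > 0 else rep(TRUE, length(s))
  keep <- keep & detected
  s <- s[keep]; a <- a[keep]
  if (length(s) < 3L) stop("need at least 3 taxa to fit a trend")
  if (stats::var(a) == 0) stop("abundance covariate has zero variance")
  fit <- stats::lm(s ~ a)
  sm <- suppressWarnings(summary(fit))
  exact <- sm$sigma < 1e-12
  se <- if (exact) 0 else sm$coefficients["a", "Std. Error"]
  structure(list(slope = unname(stats::coef(fit)[["a"]]),
                 intercept = unname(stats::coef(fit)[["(Intercept)"]]),
                 se = se, df = fit$df.residual, n = length(s),
                 exact = exact, taxa = names(s)),
            class = "spec_linfit")
}

#' Compare an observed and a null trend slope
#'
#' Welch-style contrast of two independent-fit slopes: difference of slopes,
#' standard error \eqn{\sqrt{SE_1^2 + SE_2^2}}, t statistic,
#' Welch-Satterthwaite degrees of freedom and two-sided p-value.
#'
#' @param obs,null `spec_linfit` objects on the same taxa and covariate.
#' @return Object of class `spec_slope_contrast`.
#' @export
compare_slopes <- function(obs, null) {
  if (obs$se == 0 && null$se == 0) {
    if (obs$slope == null$slope)
      return(structure(list(difference = 0, se = 0, t = 0, df = Inf, p = 1),
                       class = "spec_slope_contrast"))
    stop("both fits are exact with different slopes; contrast undefined")
  }
  d <- obs$slope - null$slope
  se <- sqrt(obs$se^2 + null$se^2)
  tt <- d / se
  df <- (obs$se^2 + null$se^2)^2 /
    (ifelse(obs$se > 0, obs$se^4 / obs$df, 0) +
     ifelse(null$se > 0, null$se^4 / null$df, 0))
  structure(list(difference = d, se = se, t = tt, df = df,
                 p = 2 * stats::pt(-abs(tt), df)),
            class = "spec_slope_contrast")
}

#' @export
print.spec_linfit <- function(x, ...) {
  cat(sprintf("linear trend: slope %.4g (SE %.3g), intercept %.4g, n = %d, df = %d\n",
              x$slope, x$se, x$intercept, x$n, x$df))
  invisible(x)
}

#' @export
print.spec_slope_contrast <- function(x, ...) {
  cat(sprintf("slope difference %.4g (SE %.3g), t = %.3f, df = %.1f, p = %.3g\n",
              x$difference, x$se, x$t, x$df, x$p))
  invisible(x)
}

#' Full specificity-versus-abundance analysis
#'
#' Restricts to taxa detected in aquatic samples, computes the observed
#' specificity matrix over the 7 categories (airborne, sediment and five
#' salinity ranges), the permutation-null mean specificity (999 label
#' reshuffles by default), and per category: the local-abundance covariate,
#' the observed and null linear trends, the Welch slope contrast, and an
#' exact permutation p-value for the slope difference.
#'
#' The null trend is the fit of the per-taxon mean null specificity against
#' the observed abundance covariate (abundance is not permuted), over the same
#' detected-taxon set as the observed fit; because the OLS slope is linear in
#' the response this equals the mean of the per-permutation slopes.
#'
#' @param t Abundance matrix over all samples (relative or
#'   rarefaction-averaged).
#' @param meta Sample metadata.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed.
#' @param edges Salinity bin boundaries.
#' @param transform,pseudocount Passed to [local_abundance()].
#' @param detected_only Passed to [fit_specificity_trend()].
#' @param p_method Primary significance decision for the slope contrast:
#'   `"permutation"` (default; the observed slope referred to the permutation
#'   slope distribution, which is calibrated under label exchangeability) or
#'   `"welch"` (the approximate two-fit contrast from [compare_slopes()],
#'   anticonservative under the permutation null).
#' @return List of class `spec_analysis`: `S_obs`, `S_null`, `groups`,
#'   per-category `fits` (obs, null, contrast, perm_p, p, covariate),
#'   `settings`.
#' @export
run_specificity_analysis <- function(t, meta, n_perm = 999, seed = NULL,
                                     edges = c(1.5, 3, 5, 15),
                                     transform = "log10", pseudocount = 1e-6,
                                     detected_only = TRUE,
                                     p_method = c("permutation", "welch")) {
  p_method <- match.arg(p_method)
  meta <- validate_sample_metadata(meta, sample_ids = colnames(t))
  g <- make_group_assignment(meta[match(colnames(t), meta$sample_id), ], edges)
  aq <- names(g)[g %in% SALINITY_BIN_LEVELS]
  keep <- rowSums(t[, aq, drop = FALSE]) > 0
  if (sum(keep) < 3L) stop("fewer than 3 taxa detected in aquatic samples")
  ta <- t[keep, , drop = FALSE]
  # drop taxa never seen in any retained sample (cannot be row-normalised)
  ta <- ta[rowSums(ta) > 0, , drop = FALSE]
  res <- specificity_trend_test(ta, g, n_perm = n_perm, seed = seed,
                                transform = transform,
                                pseudocount = pseudocount,
                                detected_only = detected_only,
                                p_method = p_method)
  res$settings$edges <- edges
  res
}

#' Specificity-trend permutation test for an arbitrary grouping
#'
#' The grouping-agnostic core of [run_specificity_analysis()]: observed and
#' permutation-null specificity over the categories of `g`, per-category
#' linear trends of specificity on local abundance, the Welch contrast and
#' the permutation p-value. Useful when the categories are not the standard
#' biome/salinity-range layout.
#'
#' @inheritParams run_specificity_analysis
#' @param g Named factor sample -> category covering all columns of `t`.
#' @return A `spec_analysis` object (see [run_specificity_analysis()]).
#' @export
specificity_trend_test <- function(t, g, n_perm = 999, seed = NULL,
                                   transform = "log10", pseudocount = 1e-6,
                                   detected_only = TRUE,
                                   p_method = c("permutation", "welch")) {
  p_method <- match.arg(p_method)
  ta <- t
  g <- align_groups(ta, g)
  xbar <- group_mean_abundance(ta, g)
  S_obs <- specificity_index(xbar)
  cats <- colnames(S_obs)

  covar <- vapply(cats, function(j)
    local_abundance(ta, g, j, transform = transform, pseudocount = pseudocount),
    numeric(nrow(ta)))
  rownames(covar) <- rownames(ta)

  # OLS slope as a linear functional of the response, per category, over the
  # observed detected-taxon set: slope = sum(w * s) with w = (a - mean a)/SSx.
  slope_w <- list()
  for (j in cats) {
    det <- if (detected_only) S_obs[, j] > 0 else rep(TRUE, nrow(S_obs))
    taxa <- rownames(S_obs)[det]
    if (length(taxa) >= 3L) {
      a <- covar[taxa, j]
      if (stats::var(a) > 0) {
        w <- (a - mean(a)) / sum((a - mean(a))^2)
        slope_w[[j]] <- list(taxa = taxa, w = w)
      }
    }
  }

  nul <- permute_specificity_engine(ta, g, n_perm, seed = seed,
                                    slope_weights = slope_w)
  S_null <- nul$mean

  fits <- list()
  for (j in cats) {
    if (is.null(slope_w[[j]])) next
    taxa <- slope_w[[j]]$taxa
    a <- covar[taxa, j]
    obs_fit <- fit_specificity_trend(S_obs[taxa, j], a, detected_only = FALSE)
    null_fit <- fit_specificity_trend(S_null[taxa, j], a, detected_only = FALSE)
    contrast <- compare_slopes(obs_fit, null_fit)
    bk <- nul$slopes[, j]
    perm_p <- (1 + sum(abs(bk - mean(bk)) >= abs(obs_fit$slope - mean(bk)))) /
      (nul$n_perm + 1)
    fits[[j]] <- list(category = j, obs = obs_fit, null = null_fit,
                      contrast = contrast, perm_p = perm_p,
                      p = if (p_method == "permutation") perm_p else contrast$p,
                      covariate = a, taxa = taxa)
  }

  structure(list(S_obs = S_obs, S_null = S_null, groups = g, fits = fits,
                 covariate = covar,
                 settings = list(n_perm = n_perm, seed = seed,
                                 transform = transform,
                                 pseudocount = pseudocount,
                                 detected_only = detected_only,
                                 p_method = p_method)),
            class = "spec_analysis")
}

#' Tidy table of slope contrasts
#'
#' @param x A `spec_analysis` object.
#' @return Data frame with one row per category: observed and null slopes and
#'   SEs, t, df, the Welch p (`p_welch`), the permutation p (`p_perm`) and
#'   the primary decision `p` per the analysis' `p_method`.
#' @export
slope_contrast_table <- function(x) {
  stopifnot(inherits(x, "spec_analysis"))
  out <- do.call(rbind, lapply(x$fits, function(f)
    data.frame(category = f$category, n = f$obs$n,
               slope_obs = f$obs$slope, se_obs = f$obs$se,
               slope_null = f$null$slope, se_null = f$null$se,
               t = f$contrast$t, df = f$contrast$df,
               p_welch = f$contrast$p, p_perm = f$perm_p, p = f$p)))
  rownames(out) <- NULL
  out
}

#' Tidy long table of specificity values
#'
#' @param x A `spec_analysis` object.
#' @return Data frame: taxon, category, S_obs, S_null_mean,
#'   abundance_covariate.
#' @export
specificity_table <- function(x) {
  stopifnot(inherits(x, "spec_analysis"))
  cats <- colnames(x$S_obs)
  out <- do.call(rbind, lapply(cats, function(j)
    data.frame(taxon = rownames(x$S_obs), category = j,
               S_obs = x$S_obs[, j], S_null_mean = x$S_null[, j],
               abundance_covariate = x$covariate[, j])))
  rownames(out) <- NULL
  out
}
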