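test_that("specificity index row-normalises group mean abundances", {
  expect_equal(unname(specificity_index(rbind(a = c(0.2, 0, 0)))[1, ]),
               c(1, 0, 0))
  expect_equal(unname(specificity_index(matrix(1 / 7, 1, 7))[1, ]), rep(1 / 7, 7))
  expect_equal(unname(specificity_index(rbind(a = c(0.3, 0.1)))[1, ]),
               c(0.75, 0.25))
  x <- matrix(rgamma(40, 1), 10, 4,
              dimnames = list(paste0("t", 1:10), paste0("g", 1:4)))
  S <- specificity_index(x)
  expect_equal(unname(rowSums(S)), rep(1, 10), tolerance = 1e-12)
  # invariant to rescaling all abundances
  expect_equal(specificity_index(x * 37.5), S, tolerance = 1e-12)
  # exclusivity means S = 1 regardless of magnitude
  y <- rbind(tiny = c(1e-9, 0, 0), big = c(0.9, 0, 0))
  expect_equal(unname(specificity_index(y)[, 1]), c(1, 1))
  z <- rbind(a = c(1, 1), b = c(0, 0))
  expect_warning(S2 <- specificity_index(z), "dropping 1 taxa")
  expect_identical(rownames(S2), "a")
})

test_that("specificity matches a brute-force oracle on a 5x12x3 fixture", {
  set.seed(41)
  m <- matrix(rgamma(60, 2), 5, 12,
              dimnames = list(paste0("t", 1:5), paste0("s", 1:12)))
  m <- sweep(m, 2, colSums(m), "/")
  g <- setNames(factor(rep(c("A", "B", "C"), each = 4)), colnames(m))
  S <- specificity_index(group_mean_abundance(m, g))
  # independent loop-based oracle
  for (i in rownames(m)) {
    xb <- sapply(c("A", "B", "C"), function(lv) mean(m[i, g == lv]))
    expect_equal(unname(S[i, ]), unname(xb / sum(xb)), tolerance = 1e-12)
  }
  expect_equal(unname(rowSums(S)), rep(1, 5), tolerance = 1e-12)
  # group mean oracle cases
  xb <- group_mean_abundance(m, g)
  expect_equal(xb["t2", "B"], mean(m["t2", 5:8]))
})

test_that("identity permutation and permutation-invariant taxa reproduce the observed index", {
  set.seed(43)
  m <- matrix(rgamma(48, 1), 6, 8,
              dimnames = list(paste0("t", 1:6), paste0("s", 1:8)))
  m[4, ] <- 0.2                   # identical abundance in every sample
  g <- setNames(factor(rep(c("A", "B"), c(5, 3))), colnames(m))
  S <- specificity_index(group_mean_abundance(m, g))
  ident <- permuted_specificity(m, g, perms = list(seq_len(ncol(m))))
  expect_equal(ident[, colnames(S)], S, tolerance = 1e-12,
               ignore_attr = TRUE)
  nul <- permuted_specificity(m, g, n_perm = 50, seed = 4)
  expect_equal(nul[4, colnames(S)], S[4, ], tolerance = 1e-12)
  expect_equal(unname(rowSums(nul)), rep(1, 6), tolerance = 1e-12)
})

test_that("sampled permutation null agrees with exhaustive enumeration", {
  set.seed(47)
  m <- matrix(rgamma(30, 1.5), 5, 6,
              dimnames = list(paste0("t", 1:5), paste0("s", 1:6)))
  m <- sweep(m, 2, colSums(m), "/")
  g <- setNames(factor(rep(c("A", "B", "C"), each = 2)), colnames(m))

  # oracle: enumerate all 90 distinct assignments of samples to group sizes
  # (2,2,2) by explicit set construction, equally weighted
  vals <- list()
  for (a in utils::combn(6, 2, simplify = FALSE)) {
    rest <- setdiff(1:6, a)
    for (b in utils::combn(rest, 2, simplify = FALSE)) {
      cc <- setdiff(rest, b)
      xb <- cbind(A = rowMeans(m[, a]), B = rowMeans(m[, b]),
                  C = rowMeans(m[, cc]))
      vals[[length(vals) + 1]] <- xb / rowSums(xb)
    }
  }
  expect_length(vals, 90)
  exact_mean <- Reduce(`+`, vals) / length(vals)
  exact_sd <- sqrt(Reduce(`+`, lapply(vals, function(v) (v - exact_mean)^2)) /
                     length(vals))

  nul <- permuted_specificity(m, g, n_perm = 999, seed = 5)
  mc_se <- exact_sd / sqrt(999)
  expect_true(all(abs(nul - exact_mean) <= 3 * mc_se + 1e-12))
})

test_that("local abundance applies the pseudocount floor and log transform", {
  m <- rbind(absent = c(0, 0, 0.5), constant = c(0.01, 0.01, 0.01))
  colnames(m) <- paste0("s", 1:3)
  g <- setNames(factor(c("A", "A", "B")), colnames(m))
  a <- local_abundance(m, g, "A")
  expect_equal(unname(a["absent"]), -6)
  expect_equal(unname(a["constant"]), log10(0.010001))
  expect_equal(local_abundance(m, g, "A", transform = "raw"),
               rowMeans(m[, 1:2]))
  set.seed(51)
  x <- matrix(rgamma(40, 1), 8, 5,
              dimnames = list(paste0("t", 1:8), paste0("s", 1:5)))
  g2 <- setNames(factor(c("A", "A", "A", "B", "B")), colnames(x))
  expect_equal(local_abundance(x, g2, "B"),
               log10(rowMeans(x[, 4:5]) + 1e-6))
})

test_that("trend fits agree with closed-form least squares", {
  f <- fit_specificity_trend(c(1, 3, 5), c(0, 1, 2), detected_only = FALSE)
  expect_equal(f$slope, 2)
  expect_true(f$exact)
  expect_equal(f$se, 0)

  set.seed(53)
  a <- rnorm(40); s <- 0.5 + 0.1 * a + rnorm(40, 0, 0.05)
  names(a) <- names(s) <- paste0("t", 1:40)
  f2 <- fit_specificity_trend(s, a, detected_only = FALSE)
  # normal equations oracle
  beta <- sum((a - mean(a)) * (s - mean(s))) / sum((a - mean(a))^2)
  alpha <- mean(s) - beta * mean(a)
  resid <- s - alpha - beta * a
  se <- sqrt(sum(resid^2) / (40 - 2) / sum((a - mean(a))^2))
  expect_equal(f2$slope, beta, tolerance = 1e-12)
  expect_equal(f2$intercept, alpha, tolerance = 1e-12)
  expect_equal(f2$se, se, tolerance = 1e-12)
  expect_equal(f2$df, 38)

  # detection filter drops zero-specificity taxa
  s3 <- c(0, 0, s[-(1:2)])
  names(s3) <- names(s)
  f3 <- fit_specificity_trend(s3, a)
  expect_equal(f3$n, 38)
  expect_error(fit_specificity_trend(c(1, 2), c(1, 2), detected_only = FALSE),
               "at least 3")
  expect_error(fit_specificity_trend(c(1, 2, 3), rep(1, 3),
                                     detected_only = FALSE), "zero variance")
})

test_that("slope CI covers a true zero slope at nominal rate", {
  set.seed(57)
  cover <- logical(100)
  for (r in 1:100) {
    a <- rnorm(30)
    s <- rnorm(30, 0.5, 0.1)      # no relationship
    f <- fit_specificity_trend(s, a, detected_only = FALSE)
    half <- qt(0.975, f$df) * f$se
    cover[r] <- abs(f$slope) <= half
  }
  expect_gte(sum(cover), 93)
})

test_that("Welch slope contrast matches hand computation", {
  f1 <- list(slope = 1.0, se = 0.1, df = 1000)
  f2 <- list(slope = 0.0, se = 0.1, df = 1000)
  ct <- compare_slopes(f1, f2)
  expect_equal(ct$t, 1 / sqrt(0.02), tolerance = 1e-12)
  expect_lt(ct$p, 1e-3)
  same <- compare_slopes(f1, f1)
  expect_equal(same$difference, 0)
  expect_equal(same$p, 1)
  ex <- list(slope = 1, se = 0, df = 10)
  expect_error(compare_slopes(ex, list(slope = 2, se = 0, df = 10)),
               "contrast undefined")
})

test_that("full analysis recovers planted specialists and rejects degenerate input", {
  ds <- generate_dataset(tiny_config(seed = 5))
  rel <- relative_abundance(ds$counts)
  sa <- run_specificity_analysis(rel, ds$meta, n_perm = 199, seed = 6)
  tab <- slope_contrast_table(sa)
  hi <- tab[tab$category == "highly_hypersaline", ]
  expect_gt(hi$slope_obs, hi$slope_null)
  expect_lt(hi$p, 0.05)
  # rows of observed and null matrices sum to one
  expect_equal(unname(rowSums(sa$S_obs)), rep(1, nrow(sa$S_obs)),
               tolerance = 1e-9)
  expect_equal(unname(rowSums(sa$S_null)), rep(1, nrow(sa$S_null)),
               tolerance = 1e-9)
  # welch and permutation p both reported; default decision is permutation
  expect_identical(tab$p, tab$p_perm)

  meta1 <- ds$meta[ds$meta$biome == "aquatic", ]
  expect_error(run_specificity_analysis(rel[, meta1$sample_id], meta1),
               "empty categor")
})

test_that("planted single-bin specialists attain high home-bin specificity", {
  # one specialist per salinity bin, narrow niches, 10 samples per bin
  taxa <- data.frame(
    taxon = c(sprintf("spec%d", 1:5), "flat"),
    class = "manual",
    base = log(3),
    w_air = 0, w_sed = 0, w_aq = 1,
    mu = c(0.75, 2.25, 4, 10, 25, 10),
    sigma = c(0.4, 0.4, 0.6, 2.5, 5, 1e6),
    g = 0.1
  )
  set.seed(59)
  sal <- c(runif(10, 0, 1.4), runif(10, 1.6, 2.9), runif(10, 3.1, 4.9),
           runif(10, 5.5, 14), runif(10, 16, 34))
  des <- study_design(n_aquatic = 50, n_airborne = 1, n_sediment = 1,
                      depth = 10000, salinity = sal, seed = 11)
  cm <- generate_counts(taxa, des)
  rel <- relative_abundance(cm$counts[, cm$meta$biome == "aquatic"])
  g <- setNames(as.character(assign_salinity_bin(sal)), colnames(rel))
  S <- specificity_index(group_mean_abundance(rel, factor(g, levels = salinity_bin_levels())))
  home <- c("slightly_brackish", "brackish", "marine", "hypersaline",
            "highly_hypersaline")
  expect_gt(mean(diag(S[sprintf("spec%d", 1:5), home])), 0.8)
})
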