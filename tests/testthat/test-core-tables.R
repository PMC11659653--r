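test_that("TSV count tables round-trip and parse errors name the offender", {
  path <- write_tsv_lines(c("taxon\ts1\ts2", "A\t3\t0", "B\t1\t2"))
  ct <- read_count_table(path)
  expect_identical(dimnames(ct), list(c("A", "B"), c("s1", "s2")))
  expect_equal(unname(ct), matrix(c(3, 1, 0, 2), 2, 2))

  out <- tempfile(fileext = ".tsv")
  write_count_table(ct, out)
  expect_equal(read_count_table(out), ct)

  expect_error(read_count_table(write_tsv_lines(c("taxon\ts1\ts1", "A\t1\t2"))),
               "duplicate sample")
  expect_error(read_count_table(write_tsv_lines(character())), "parse error")
  expect_error(read_count_table(write_tsv_lines(c("taxon\ts1", "A\t1\t2"))),
               "line 2")
  expect_error(read_count_table(write_tsv_lines(c("taxon\ts1", "A\t-1"))),
               "negative")
  expect_error(read_count_table(write_tsv_lines(c("taxon\ts1", "A\t1.5"))),
               "non-integer")
  expect_error(read_count_table(write_tsv_lines(c("taxon\ts1", "A\tx"))),
               "non-numeric")
})

test_that("BIOM JSON tables load through the biomformat reader", {
  skip_if_not_installed("biomformat")
  m <- random_counts(4, 3, seed = 11)
  b <- biomformat::make_biom(m)
  path <- tempfile(fileext = ".biom")
  biomformat::write_biom(b, path)
  got <- read_count_table(path, format = "biom_json")
  expect_equal(got[rownames(m), colnames(m)], m + 0)
})

test_that("metadata validation enforces biome labels and aquatic salinity", {
  meta <- make_meta(c("a1", "a2"), "b1", "c1", salinity = c(1, 20))
  expect_silent(validate_sample_metadata(meta, c("a1", "b1")))
  expect_error(validate_sample_metadata(meta, c("a1", "zz")), "missing sample")
  bad <- meta; bad$biome[1] <- "soil"
  expect_error(validate_sample_metadata(bad), "unknown biome")
  bad <- meta; bad$salinity[2] <- NA
  expect_error(validate_sample_metadata(bad), "salinity missing")
  bad <- meta; bad$salinity[1] <- -2
  expect_error(validate_sample_metadata(bad), "negative salinity")
})

test_that("relative abundance divides columns by their totals", {
  m <- matrix(c(3, 1, 5, 0), 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  r <- relative_abundance(m)
  expect_equal(r[, "s1"], c(A = 0.75, B = 0.25))
  expect_equal(r[, "s2"], c(A = 1, B = 0))
  x <- random_counts(10, 1, seed = 3)
  expect_equal(relative_abundance(x)[, 1], x[, 1] / sum(x[, 1]))
  z <- m; z[, 2] <- 0
  expect_error(relative_abundance(z), "s2")
})

test_that("rarefaction subsamples without replacement to the exact depth", {
  m <- matrix(c(10, 0), 2, 1, dimnames = list(c("A", "B"), "s1"))
  expect_equal(rarefy(m, 5)[, 1], c(A = 5, B = 0))
  m2 <- matrix(c(4, 4), 2, 1, dimnames = list(c("A", "B"), "s1"))
  expect_equal(rarefy(m2, 8)[, 1], c(A = 4, B = 4))

  x <- random_counts(12, 6, lambda = 30, seed = 5)
  d <- min(colSums(x)) - 3
  r1 <- rarefy(x, d, seed = 42)
  expect_true(all(colSums(r1) == d))
  expect_true(all(r1 <= x))
  expect_identical(rarefy(x, d, seed = 42), r1)
  expect_false(identical(rarefy(x, d, seed = 43), r1))
  expect_error(rarefy(x, max(colSums(x)) + 1), "exceeds total reads")
})

test_that("rarefied counts follow the hypergeometric expectation", {
  # 3000 identical [100, 100] samples at depth 50: per-sample first-taxon
  # count has mean 25 and SD sqrt(50 * .25 * 150/199) ~ 3.07
  reps <- 3000
  m <- matrix(rep(c(100, 100), reps), nrow = 2,
              dimnames = list(c("A", "B"), sprintf("r%04d", seq_len(reps))))
  r <- rarefy(m, 50, seed = 7)
  se <- sqrt(50 * 0.25 * (200 - 50) / (200 - 1)) / sqrt(reps)
  expect_lt(abs(mean(r["A", ]) - 25), 3 * se)
})

test_that("rarefaction-averaged tables conserve depth and zeros", {
  x <- random_counts(10, 4, lambda = 40, seed = 9)
  x[3, ] <- 0                       # absent taxon must stay exactly zero
  x[1, ] <- x[1, ] + 1              # keep totals positive
  d <- min(colSums(x)) - 5
  mr <- mean_rarefied_table(x, d, reps = 20, seed = 1)
  expect_equal(unname(colSums(mr)), rep(d, ncol(x)), tolerance = 1e-12)
  expect_true(all(mr[3, ] == 0))
  expect_true(all(mr <= x + 1e-12))
  # reps = 1 equals the single seeded draw it averages
  expect_equal(mean_rarefied_table(x, d, reps = 1, seed = 4),
               rarefy(x, d, seed = salinispec:::derive_seed(4, 1)) + 0)
})

test_that("Hellinger columns have unit Euclidean norm", {
  m <- matrix(c(1, 0, 1, 1), 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  h <- hellinger(m)
  expect_equal(h[, "s1"], c(A = 1, B = 0))
  expect_equal(h[, "s2"], c(A = sqrt(0.5), B = sqrt(0.5)))
  x <- random_counts(15, 6, seed = 13)
  expect_equal(unname(colSums(hellinger(x)^2)), rep(1, 6), tolerance = 1e-12)
  z <- m; z[, 1] <- 0
  expect_error(hellinger(z), "all-zero")
})

test_that("Bray-Curtis matches the hand formula and its metric properties", {
  m <- matrix(c(2, 1, 1, 1), 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_equal(bray_curtis(m)["s1", "s2"], 0.2)
  same <- cbind(s1 = c(1, 2), s2 = c(1, 2))
  rownames(same) <- c("A", "B")
  expect_equal(bray_curtis(same)["s1", "s2"], 0)
  disj <- cbind(s1 = c(1, 0), s2 = c(0, 1))
  rownames(disj) <- c("A", "B")
  expect_equal(bray_curtis(disj)["s1", "s2"], 1)

  for (i in 1:20) {
    x <- random_counts(10, 5, seed = 100 + i)
    d <- bray_curtis(x)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 5))
    expect_true(all(d >= 0 & d <= 1))
  }
  z <- cbind(s1 = c(0, 0), s2 = c(0, 0), s3 = c(1, 1))
  rownames(z) <- c("A", "B")
  expect_error(bray_curtis(z), "empty samples")
})

test_that("Shannon diversity matches closed forms and is maximal at uniformity", {
  expect_equal(shannon(c(1, 0, 0)), 0)
  expect_equal(shannon(rep(1, 4)), log(4))
  expect_equal(shannon(c(2, 1, 1)), 0.5 * log(2) + 0.5 * log(4),
               tolerance = 1e-12)
  expect_equal(shannon(rep(1, 8), base = 2), 3)
  expect_error(shannon(c(0, 0)), "all-zero")
  set.seed(21)
  for (i in 1:25) {
    k <- sample(3:10, 1)
    p <- rgamma(k, 1); p <- p / sum(p)
    expect_lte(shannon(p), shannon(rep(1 / k, k)) + 1e-12)
  }
})

test_that("richness counts positive entries", {
  expect_identical(richness(c(1, 0, 2)), 2L)
  expect_identical(richness(numeric(3)), 0L)
  set.seed(2)
  v <- rbinom(50, 1, 0.4)
  expect_identical(richness(v), as.integer(sum(v)))
})

test_that("minimum-depth QC drops shallow samples", {
  x <- random_counts(5, 4, lambda = 10, seed = 31)
  x[, 2] <- c(1, 0, 0, 0, 0)
  f <- filter_min_depth(x, min_depth = 10)
  expect_identical(attr(f, "removed"), colnames(x)[2])
  expect_identical(colnames(f), colnames(x)[-2])
  expect_error(filter_min_depth(x, min_depth = 1e9), "no sample")
})
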