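test_that("observed gaps are successive differences of sorted log masses", {
  expect_equal(observed_gaps(prepare_census(c(10, 100, 1000))), c(1, 1))
  expect_equal(observed_gaps(prepare_census(c(1, 1, 5), log_already = TRUE)),
               c(0, 4))
  vals <- c(1.02, 1.15, 1.31, 1.58, 1.60, 2.41, 2.63, 2.80, 3.55, 3.70)
  cen <- prepare_census(vals, log_already = TRUE)
  expect_equal(observed_gaps(cen),
               c(0.13, 0.16, 0.27, 0.02, 0.81, 0.22, 0.17, 0.75, 0.15))
  expect_equal(sum(observed_gaps(cen)), diff(range(cen$logmass)))
})

test_that("the zero-noise limit of a centers resample is a permutation of the centers", {
  cen <- two_cluster_census(seed = 2)
  nn <- select_null_bandwidth(cen)
  nn$h_star <- 1e-12
  x <- resample_null(nn, seed = 5)
  expect_equal(sort(x), sort(nn$centers), tolerance = 1e-9)
  expect_equal(diff(sort(x)), observed_gaps(cen), tolerance = 1e-9)
})

test_that("centers mode refuses to draw more points than there are centers", {
  nn <- select_null_bandwidth(normal_census(n = 10, seed = 1))
  expect_error(resample_null(nn, n = 11), "without replacement")
  expect_length(resample_null(nn, n = 11, mode = "iid", seed = 1), 11)
})

test_that("pooled resamples follow the fitted null distribution (KS check)", {
  cen <- normal_census(n = 25, sd = 0.5, seed = 11)
  nn <- select_null_bandwidth(cen)
  pooled <- unlist(lapply(1:2000, function(b)
    resample_null(nn, seed = 1000 + b)))
  # exact CDF of the kernel mixture the resampler targets
  null_cdf <- function(q) vapply(q, function(v)
    mean(pnorm((v - nn$centers) / nn$h_star)), numeric(1))
  s <- sort(pooled)
  n <- length(s)
  Fh <- null_cdf(s)
  D <- max(pmax(abs(seq_len(n) / n - Fh), abs(Fh - (seq_len(n) - 1) / n)))
  expect_lt(D, 1.63 / sqrt(n))  # 1% critical value
})

test_that("the gap matrix is the composition of seeded resamples", {
  cen <- normal_census(n = 12, seed = 4)
  nn <- select_null_bandwidth(cen)
  gm <- bootstrap_gap_matrix(nn, B = 100, seed = 99)
  for (b in c(1L, 37L, 100L)) {
    x <- resample_null(nn, seed = ddetector:::derive_seed(99, b))
    expect_equal(gm[b, ], diff(sort(x)))
  }
  expect_true(all(gm >= 0))
  # each row telescopes to that replicate's range
  for (b in 1:10) {
    x <- sort(resample_null(nn, seed = ddetector:::derive_seed(99, b)))
    expect_equal(sum(gm[b, ]), max(x) - min(x))
  }
})

test_that("growing B appends resamples without reshuffling earlier ones", {
  nn <- select_null_bandwidth(normal_census(n = 10, seed = 8))
  small <- bootstrap_gap_matrix(nn, B = 100, seed = 3)
  big <- bootstrap_gap_matrix(nn, B = 150, seed = 3)
  expect_equal(big[1:100, ], unclass(small)[1:100, ], ignore_attr = TRUE)
})

test_that("column means of a single-Gaussian gap matrix match order-statistic spacings", {
  # iid draws from one standard-normal kernel = iid N(0, 1) sample
  nn <- structure(list(centers = 0, h_star = 1), class = "neutral_null")
  n <- 10L
  gm <- bootstrap_gap_matrix(nn, n = n, B = 4000, mode = "iid", seed = 21)
  set.seed(907)  # independent large-sample simulation of normal spacings
  sim <- t(apply(matrix(rnorm(4000 * n), ncol = n), 1, function(x) diff(sort(x))))
  se <- sqrt(apply(sim, 2, var) / 4000 + apply(gm, 2, var) / 4000)
  expect_true(all(abs(colMeans(gm) - colMeans(sim)) < 5 * se))
})

test_that("percentiles use mid-rank counting and match hand values", {
  col <- matrix(seq(0.1, 1.0, by = 0.1), ncol = 1)
  expect_equal(gap_percentiles(0.55, col), 0.5)
  expect_equal(gap_percentiles(0.1, col), 0.05)   # one tie, none below
  expect_equal(gap_percentiles(2, col), 1)
  expect_equal(gap_percentiles(0, col), 0)
  mat <- matrix(c(1, 2, 3, 4, 0, 0, 0, 1), ncol = 2)
  expect_equal(gap_percentiles(c(2, 0), mat), c((1 + 0.5) / 4, (0.5 * 3) / 4))
  expect_error(gap_percentiles(c(1, 2, 3), mat), "columns")
})

test_that("detection is deterministic and monotone in the threshold", {
  cen <- two_cluster_census(n_per = 10, seed = 6)
  a <- detect_discontinuities(cen, B = 200, seed = 17)
  b <- detect_discontinuities(cen, B = 200, seed = 17)
  expect_identical(a$table, b$table)
  flags <- vapply(c(0.5, 0.8, 0.9, 0.99),
                  function(q) sum(a$table$percentile > q), numeric(1))
  expect_true(all(diff(flags) <= 0))
})

test_that("a planted between-cluster gap is flagged and tied ranks never are", {
  cen <- two_cluster_census(n_per = 15, centers = c(1.2, 3.4), sd = 0.15,
                            seed = 9)
  rep <- detect_discontinuities(cen, B = 500, seed = 31)
  gapn <- which.max(rep$table$gap_log10)  # the between-cluster gap
  expect_true(rep$table$discontinuity[gapn])
  expect_equal(rep$table$rank[gapn], 15)

  tied <- prepare_census(c(1, 1, 1.1, 1.2, 2.5, 2.6), log_already = TRUE)
  r2 <- detect_discontinuities(tied, B = 200, seed = 1)
  expect_false(r2$table$discontinuity[1])      # zero gap cannot be flagged
  expect_lte(r2$table$percentile[1], 0.5)
})

test_that("a threshold above the bootstrap resolution flags nothing", {
  cen <- normal_census(n = 20, seed = 13)
  rep <- detect_discontinuities(cen, threshold = 0.999999, B = 200, seed = 2)
  expect_equal(sum(rep$table$discontinuity), 0L)
  expect_error(detect_discontinuities(cen, threshold = 1, B = 200, seed = 2),
               "threshold")
})

test_that("flagged-gap midpoints are reported on the log scale", {
  cen <- two_cluster_census(n_per = 10, seed = 12)
  rep <- detect_discontinuities(cen, B = 300, seed = 3)
  locs <- discontinuity_locations(rep)
  hits <- rep$table[rep$table$discontinuity, ]
  expect_equal(locs, (hits$lower_logmass + hits$upper_logmass) / 2)
  expect_true(all(locs >= min(cen$logmass) & locs <= max(cen$logmass)))
})
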