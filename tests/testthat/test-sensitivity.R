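test_that("every detection carries complete provenance", {
  spec <- default_mixture()
  res <- run_sensitivity(spec, sample_sizes = c(40, 100),
                         successes = c(0.8, 1.0), replicates = 10,
                         B = 200, seed = 5)
  expect_equal(nrow(res$runs), 40L)
  expect_setequal(unique(res$runs$sample_size), c(40L, 100L))
  expect_setequal(unique(res$runs$census_success), c(0.8, 1.0))
  expect_true(all(table(res$runs$sample_size, res$runs$census_success) == 10))
  expect_true(all(c("sample_size", "census_success", "replicate", "seed",
                    "location") %in% names(res$detections)))
  # every detection row maps back to a run row by its provenance triple
  key <- function(d) paste(d$sample_size, d$census_success, d$replicate)
  expect_true(all(key(res$detections) %in% key(res$runs)))
  # detected locations lie within the simulated data range
  expect_true(all(res$detections$location > min(spec$means) - 1 &
                  res$detections$location < max(spec$means) + 1))
  # thinning really happened
  expect_true(all(res$runs$n_effective ==
                  round(res$runs$sample_size * res$runs$census_success)))
})

test_that("repeating the analysis of the same dataset gives the same discontinuities", {
  spec <- default_mixture()
  cen <- simulate_census(spec, n = 60, seed = 77)
  a <- detect_discontinuities(cen, B = 300, seed = 11)
  b <- detect_discontinuities(cen, B = 300, seed = 11)
  expect_identical(discontinuity_locations(a), discontinuity_locations(b))
  res1 <- run_sensitivity(spec, sample_sizes = 40, successes = 1,
                          replicates = 10, B = 200, seed = 9)
  res2 <- run_sensitivity(spec, sample_sizes = 40, successes = 1,
                          replicates = 10, B = 200, seed = 9)
  expect_identical(res1$detections, res2$detections)
})

test_that("gap recovery scores detections against true midpoints", {
  spec <- default_mixture(k = 3, mean_range = c(1, 3))
  # true midpoints at 1.5 and 2.5
  expect_equal(gap_recovery(c(1.52, 9), spec), 0.5)
  expect_equal(gap_recovery(c(1.5, 2.5), spec), 1)
  expect_equal(gap_recovery(numeric(0), spec), 0)
  expect_equal(gap_recovery(2.0, spec, tol = 0.1), 0)
})

test_that("per-gap spread summarises attributable detections only", {
  spec <- default_mixture(k = 3, mean_range = c(1, 3))  # midpoints 1.5, 2.5
  locs <- c(1.45, 1.50, 1.55, 2.5, 9)   # lone detection at 2.5, stray at 9
  sp <- true_gap_spread(locs, spec)
  expect_equal(sp[1], sd(c(1.45, 1.5, 1.55)))
  expect_true(is.na(sp[2]))
  expect_length(sp, 2)
})

test_that("locations from two separated groups cluster into two components", {
  set.seed(42)
  locs <- c(rnorm(40, 1.5, 0.05), rnorm(40, 3.5, 0.05))
  cl <- cluster_discontinuities(locs)
  expect_equal(cl$n_clusters, 2L)
  expect_equal(sort(cl$centers), c(1.5, 3.5), tolerance = 0.1)
  expect_equal(length(cl$assignments), 80L)
  expect_true(all(cl$spread < 0.1))
})

test_that("degenerate location sets collapse to one cluster", {
  cl <- cluster_discontinuities(rep(2.25, 12))
  expect_equal(cl$n_clusters, 1L)
  expect_equal(cl$spread, 0)
  # never more clusters than distinct locations
  cl2 <- cluster_discontinuities(rep(c(1, 3), each = 10))
  expect_lte(cl2$n_clusters, 2L)
  expect_error(cluster_discontinuities(c(1, 2, 3)), "at least 10")
})

test_that("clustering a sensitivity result annotates its detections", {
  spec <- default_mixture(k = 2, mean_range = c(1, 3))
  res <- run_sensitivity(spec, sample_sizes = 30, successes = 1,
                         replicates = 15, B = 200, seed = 31)
  expect_gte(nrow(res$detections), 10)
  res <- cluster_discontinuities(res)
  expect_s3_class(res$clusters, "discontinuity_clusters")
  expect_equal(nrow(res$detections), length(res$clusters$assignments))
  expect_true("cluster" %in% names(res$detections))
})
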