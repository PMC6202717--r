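test_that("bracketed selection matches the literal one-step scan", {
  for (seed in 1:4) {
    cen <- normal_census(n = 12, sd = 0.3, seed = seed)
    a <- select_null_bandwidth(cen, increment = 0.005, scan = "bisect")
    b <- select_null_bandwidth(cen, increment = 0.005, scan = "exhaustive")
    expect_equal(a$h_star, b$h_star)
  }
})

test_that("h* is the smallest unimodal lattice bandwidth", {
  cen <- prepare_census(c(1, 1.5, 2), log_already = TRUE)
  nn <- select_null_bandwidth(cen)
  expect_equal(kernel_density(cen$logmass, nn$h_star)$n_modes, 1L)
  if (nn$h_star > nn$increment)
    expect_gte(kernel_density(cen$logmass, nn$h_star - nn$increment)$n_modes, 2L)
  # refinement oracle: a 10x finer lattice brackets the same transition
  fine <- select_null_bandwidth(cen, increment = nn$increment / 10)
  expect_lte(fine$h_star, nn$h_star)
  expect_gt(fine$h_star, nn$h_star - nn$increment)
})

test_that("mode counts along the scan are non-increasing in h", {
  for (seed in 1:3) {
    cen <- two_cluster_census(n_per = 8, seed = seed)
    nn <- select_null_bandwidth(cen)
    scan <- nn$h_scan[order(nn$h_scan$h), ]
    expect_true(all(diff(scan$n_modes) <= 0))
  }
})

test_that("well-separated clusters force a bandwidth at the separation scale", {
  cen <- prepare_census(c(1.00, 1.01, 1.02, 4.00, 4.01, 4.02),
                        log_already = TRUE)
  nn <- select_null_bandwidth(cen)
  expect_gt(nn$h_star, 0.3)  # far above the within-cluster spread of 0.01
  expect_gte(kernel_density(cen$logmass, nn$h_star - nn$increment)$n_modes, 2L)
  expect_equal(nn$density$n_modes, 1L)
})

test_that("unimodal censuses select a bandwidth well below the cap", {
  cen <- normal_census(n = 40, sd = 0.4, seed = 7)
  nn <- select_null_bandwidth(cen)
  expect_lt(nn$h_star, nn$h_max / 2)
  expect_false(nn$cap_exceeded)
  after <- nn$h_scan[nn$h_scan$h >= nn$h_star, ]
  expect_true(all(after$n_modes == 1L))
})

test_that("the scan continues past the cap when necessary and records it", {
  # two tight pairs a log-unit apart need h near 0.5 to merge; cap at 0.2
  cen <- prepare_census(c(1, 1 + 1e-6, 2, 2 + 1e-6), log_already = TRUE)
  nn <- select_null_bandwidth(cen, increment = 0.05, h_max = 0.2)
  expect_equal(nn$density$n_modes, 1L)
  expect_gt(nn$h_star, 0.2)
  expect_true(nn$cap_exceeded)
})

test_that("degenerate censuses (zero range) are rejected", {
  cen <- prepare_census(c(5, 5, 5))
  expect_error(select_null_bandwidth(cen), "degenerate")
})

test_that("the null is deterministic: identical inputs give identical fits", {
  cen <- two_cluster_census(seed = 3)
  a <- select_null_bandwidth(cen)
  b <- select_null_bandwidth(cen)
  expect_identical(a, b)
})
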