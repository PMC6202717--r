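# shared fixture builders (all generated in code, deterministic per seed)

normal_census <- function(n = 30, mean = 2, sd = 0.4, seed = 1) {
  set.seed(seed)
  prepare_census(rnorm(n, mean, sd), log_already = TRUE)
}

two_cluster_census <- function(n_per = 15, centers = c(1.2, 3.4),
                               sd = 0.15, seed = 1) {
  set.seed(seed)
  prepare_census(c(rnorm(n_per, centers[1], sd), rnorm(n_per, centers[2], sd)),
                 log_already = TRUE)
}

# literal double-sum KDE, the independent oracle for kernel_density
kde_brute <- function(data, h, grid) {
  n <- length(data)
  out <- numeric(length(grid))
  for (g in seq_along(grid)) {
    s <- 0
    for (i in seq_len(n)) {
      z <- (grid[g] - data[i]) / h
      s <- s + exp(-0.5 * z^2) / sqrt(2 * pi)
    }
    out[g] <- s / (n * h)
  }
  out
}

# brute-force mid-rank percentile, the independent oracle for gap_percentiles
percentile_brute <- function(observed, mat) {
  B <- nrow(mat)
  vapply(seq_along(observed), function(r) {
    col <- mat[, r]
    (sum(col < observed[r]) + 0.5 * sum(col == observed[r])) / B
  }, numeric(1))
}

trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
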