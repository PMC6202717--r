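#' Observed rank-ordered gaps of a census
#'
#' Successive differences of the ascending log10 masses: \code{gap[r] =
#' logmass[r+1] - logmass[r]} for ranks \code{r = 1, ..., n-1}. Tied masses
#' give zero gaps.
#'
#' @param census a \code{ranked_census}.
#' @return numeric vector of \code{n - 1} non-negative gaps (log10 units).
#' @examples
#' observed_gaps(prepare_census(c(10, 100, 1000)))  # c(1, 1)
#' @export
observed_gaps <- function(census) {
  assert_census(census)
  diff(census$logmass)
}

#' Draw one resample from the neutral null
#'
#' Draws \code{n} points from the fitted null density. The default mode,
#' \code{"centers"}, realizes the method's "redrawn without replacement" at
#' the kernel-component level: \code{n} kernel centers are taken without
#' replacement from the null's centers (for \code{n} equal to the census
#' size, every center exactly once) and each is perturbed by an independent
#' \eqn{N(0, h_*^2)} deviate — a stratified draw from the kernel mixture.
#' Mode \code{"iid"} is ordinary KDE sampling: components drawn with
#' replacement, then perturbed.
#'
#' @param null a \code{neutral_null}.
#' @param n resample size; defaults to the number of centers (the census
#'   size). In \code{"centers"} mode \code{n} may not exceed the number of
#'   centers.
#' @param mode \code{"centers"} (component-level without replacement,
#'   default) or \code{"iid"}.
#' @param seed integer seed for this draw; \code{NULL} leaves the RNG state
#'   as-is.
#' @param lower_bound optional lower support bound (log10 units): kernel
#'   perturbations taking a point below it are redrawn. Off (\code{NULL}) by
#'   default.
#'
#' @return numeric vector of \code{n} unsorted draws (log10 units).
#' @export
resample_null <- function(null, n = length(null$centers),
                          mode = c("centers", "iid"), seed = NULL,
                          lower_bound = NULL) {
  if (!is_neutral_null(null))
    stop_dd("expected a `neutral_null` (see select_null_bandwidth())")
  mode <- match.arg(mode)
  n <- as.integer(check_scalar(n, "n"))
  nc <- length(null$centers)
  if (mode == "centers" && n > nc)
    stop_dd(sprintf(
      "cannot draw %d centers without replacement from %d (use mode = \"iid\")",
      n, nc))
  set_seed_maybe(seed)
  centers <- if (mode == "centers") {
    # sample() for n == nc is a permutation: each center used exactly once
    null$centers[sample.int(nc, n, replace = FALSE)]
  } else {
    null$centers[sample.int(nc, n, replace = TRUE)]
  }
  x <- centers + rnorm(n, mean = 0, sd = null$h_star)
  if (!is.null(lower_bound)) {
    for (safety in 1:1000) {
      low <- x < lower_bound
      if (!any(low)) break
      x[low] <- centers[low] + rnorm(sum(low), 0, null$h_star)
    }
    x[x < lower_bound] <- lower_bound
  }
  x
}

#' Bootstrap matrix of rank-ordered gaps under the null
#'
#' Resamples the neutral null \code{B} times at size \code{n}; each resample
#' is rank-ordered and differenced, giving row \code{b} of a \code{B x (n-1)}
#' matrix whose columns are the per-rank null gap distributions. Replicate
#' \code{b} is seeded deterministically from \code{seed} by a counter scheme,
#' so raising \code{B} appends new rows without changing existing ones.
#'
#' @inheritParams resample_null
#' @param B number of resamples (at least 100; the method's reference
#'   configuration uses 5000).
#' @param seed master integer seed (required: the matrix must be
#'   reproducible).
#' @return A \code{gap_matrix}: numeric \code{B x (n-1)} matrix with
#'   attributes \code{B}, \code{n}, \code{mode} and \code{seed}.
#' @export
bootstrap_gap_matrix <- function(null, n = length(null$centers), B = 5000L,
                                 mode = c("centers", "iid"), seed,
                                 lower_bound = NULL) {
  mode <- match.arg(mode)
  B <- as.integer(check_scalar(B, "B"))
  if (B < 100L)
    stop_dd("B must be at least 100 for a usable percentile resolution")
  if (missing(seed) || is.null(seed))
    stop_dd("a master `seed` is required")
  n <- as.integer(check_scalar(n, "n"))
  gaps <- matrix(NA_real_, nrow = B, ncol = n - 1L)
  for (b in seq_len(B)) {
    x <- resample_null(null, n = n, mode = mode,
                       seed = derive_seed(seed, b), lower_bound = lower_bound)
    gaps[b, ] <- diff(sort(x))
  }
  structure(gaps, B = B, n = n, mode = mode, seed = as.integer(seed),
            class = c("gap_matrix", "matrix", "array"))
}

#' Per-rank percentiles of observed gaps in the bootstrap distribution
#'
#' For each rank, the proportion of bootstrap gaps of the same rank that fall
#' below the observed gap, with mid-rank handling of ties:
#' \code{(\#below + 0.5 \#equal) / B}.
#'
#' @param observed numeric vector of observed gaps (length \code{n - 1}).
#' @param gap_matrix a \code{B x (n-1)} matrix from
#'   \code{\link{bootstrap_gap_matrix}}.
#' @return numeric vector of percentiles in \code{[0, 1]}.
#' @export
gap_percentiles <- function(observed, gap_matrix) {
  if (!is.matrix(gap_matrix))
    stop_dd("`gap_matrix` must be a matrix")
  B <- nrow(gap_matrix)
  if (length(observed) != ncol(gap_matrix))
    stop_dd(sprintf("length(observed) = %d but gap matrix has %d columns",
                    length(observed), ncol(gap_matrix)))
  obs <- matrix(observed, nrow = B, ncol = length(observed), byrow = TRUE)
  (colSums(gap_matrix < obs) + 0.5 * colSums(gap_matrix == obs)) / B
}

#' Detect discontinuities in a census
#'
#' The full pipeline: fit the neutral null (smallest unimodal bandwidth),
#' bootstrap per-rank gap distributions from it, compute the percentile of
#' each observed gap within its own rank's distribution, and flag gaps whose
#' percentile strictly exceeds \code{threshold}. A flagged gap is a
#' discontinuity: a spacing between adjacent ranked masses too large to be a
#' plausible draw from the continuous unimodal null.
#'
#' No multiple-testing correction is applied — the threshold plays the role
#' of an alpha level and is interpreted per gap. The report carries the
#' expected number of false flags under the null,
#' \code{(n-1) * (1-threshold)}, as guidance.
#'
#' @param census a \code{ranked_census}.
#' @param threshold flag a gap when its percentile exceeds this value
#'   (strict inequality); default 0.90.
#' @param B number of null resamples; default 5000.
#' @param increment bandwidth scan step; default 0.001.
#' @param mode resampling mode, \code{"centers"} or \code{"iid"} (see
#'   \code{\link{resample_null}}).
#' @param seed master integer seed (required).
#' @param h_max,grid_points passed to \code{\link{select_null_bandwidth}}.
#' @param lower_bound optional support truncation, see
#'   \code{\link{resample_null}}.
#'
#' @return An object of class \code{discontinuity_report}: list with
#'   \code{table} (data frame with one row per interior rank: \code{rank},
#'   \code{lower_label}, \code{upper_label}, \code{lower_mass},
#'   \code{upper_mass}, \code{lower_logmass}, \code{upper_logmass},
#'   \code{gap_log10}, \code{percentile}, \code{discontinuity}),
#'   \code{null} (the fitted \code{neutral_null}) and \code{meta}
#'   (h_star, B, threshold, mode, seed, increment, n, expected false-flag
#'   count).
#'
#' @examples
#' cen <- prepare_census(10^c(1.0, 1.1, 1.2, 2.8, 2.9, 3.0, 3.1))
#' rep <- detect_discontinuities(cen, B = 200, seed = 42)
#' subset(rep$table, discontinuity)
#'
#' @export
detect_discontinuities <- function(census, threshold = 0.90, B = 5000L,
                                   increment = 0.001,
                                   mode = c("centers", "iid"), seed,
                                   h_max = NULL, grid_points = 2048L,
                                   lower_bound = NULL) {
  assert_census(census)
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed))
    stop_dd("a master `seed` is required for a reproducible report")
  threshold <- check_scalar(threshold, "threshold")
  if (threshold >= 1)
    stop_dd("`threshold` must be in (0, 1)")

  null <- select_null_bandwidth(census, increment = increment, h_max = h_max,
                                grid_points = grid_points)
  gm <- bootstrap_gap_matrix(null, n = census$n, B = B, mode = mode,
                             seed = seed, lower_bound = lower_bound)
  obs <- observed_gaps(census)
  pct <- gap_percentiles(obs, gm)
  idx <- seq_len(census$n - 1L)
  tab <- data.frame(
    rank = idx,
    lower_label = census$labels[idx],
    upper_label = census$labels[idx + 1L],
    lower_mass = census$mass[idx],
    upper_mass = census$mass[idx + 1L],
    lower_logmass = census$logmass[idx],
    upper_logmass = census$logmass[idx + 1L],
    gap_log10 = obs,
    percentile = pct,
    discontinuity = pct > threshold,
    stringsAsFactors = FALSE)
  structure(
    list(table = tab,
         null = null,
         meta = list(n = census$n, h_star = null$h_star, B = attr(gm, "B"),
                     threshold = threshold, mode = mode,
                     seed = as.integer(seed), increment = increment,
                     expected_false_flags = (census$n - 1) * (1 - threshold))),
    class = "discontinuity_report")
}

#' @export
print.discontinuity_report <- function(x, ...) {
  m <- x$meta
  hits <- x$table[x$table$discontinuity, , drop = FALSE]
  cat(sprintf(
    "Discontinuity report: n = %d, h* = %g, B = %d, threshold = %g, mode = %s, seed = %d\n",
    m$n, m$h_star, m$B, m$threshold, m$mode, m$seed))
  cat(sprintf("  %d of %d gaps flagged (expected false flags under null: %.1f)\n",
              nrow(hits), nrow(x$table), m$expected_false_flags))
  if (nrow(hits)) {
    for (i in seq_len(nrow(hits)))
      cat(sprintf("  rank %3d: %s (%.3g g) | %s (%.3g g)  gap %.4f  pct %.4f\n",
                  hits$rank[i], hits$lower_label[i], hits$lower_mass[i],
                  hits$upper_label[i], hits$upper_mass[i],
                  hits$gap_log10[i], hits$percentile[i]))
  }
  invisible(x)
}

#' Midpoints of flagged gaps
#'
#' Scalar location of each detected discontinuity: the midpoint, on the log10
#' axis, of the flagged rank gap. A gap is an interval between two adjacent
#' masses; its midpoint is the natural single number to carry into clustering
#' across replicates.
#'
#' @param report a \code{discontinuity_report}.
#' @return numeric vector (possibly empty) of log10 locations.
#' @export
discontinuity_locations <- function(report) {
  if (!inherits(report, "discontinuity_report"))
    stop_dd("expected a `discontinuity_report`")
  hits <- report$table[report$table$discontinuity, , drop = FALSE]
  (hits$lower_logmass + hits$upper_logmass) / 2
}
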