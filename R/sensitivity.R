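#' Sensitivity experiment over sample size and census success
#'
#' Runs the simulation experiment that probes how reliably the
#' discontinuity test recovers known gaps as the census degrades: for every
#' combination of sample size and census success, and for each replicate, a
#' census is simulated from \code{spec}, thinned to the given success,
#' analysed with \code{\link{detect_discontinuities}}, and the log10
#' locations (flagged-gap midpoints) are harvested with full provenance.
#' The reference configuration is sample sizes 20–100 in steps of 10,
#' census success 0.75–1, and 1000 replicates; smaller designs run the same
#' code path.
#'
#' @param spec a \code{mixture_spec} (ground truth).
#' @param sample_sizes integer vector of simulated census sizes.
#' @param successes numeric vector of census-success fractions in (0, 1].
#' @param replicates replicates per (size, success) cell (at least 10).
#' @param threshold,B,increment,mode parameters forwarded to
#'   \code{\link{detect_discontinuities}}.
#' @param seed master seed; every replicate derives its own seeds from it.
#'
#' @return A \code{sensitivity_result}: list with \code{detections}
#'   (data frame: \code{sample_size}, \code{census_success},
#'   \code{replicate}, \code{seed}, \code{location}), \code{runs}
#'   (one row per detection run: provenance, effective n, h*, number of
#'   flagged gaps, recovery fraction against \code{spec}), \code{spec} and
#'   \code{params}. Clustering fields are added by
#'   \code{\link{cluster_discontinuities}}.
#'
#' @examples
#' \donttest{
#' res <- run_sensitivity(default_mixture(), sample_sizes = c(40, 100),
#'                        successes = 1, replicates = 10, B = 300, seed = 1)
#' aggregate(recovery ~ sample_size, res$runs, median)
#' }
#' @export
run_sensitivity <- function(spec, sample_sizes = seq(20L, 100L, by = 10L),
                            successes = seq(0.75, 1.0, by = 0.05),
                            replicates = 1000L, threshold = 0.90, B = 5000L,
                            increment = 0.001, mode = "centers", seed) {
  if (!inherits(spec, "mixture_spec")) stop_dd("expected a `mixture_spec`")
  replicates <- as.integer(check_scalar(replicates, "replicates"))
  if (replicates < 10L) stop_dd("at least 10 replicates per cell are required")
  if (missing(seed) || is.null(seed)) stop_dd("a master `seed` is required")

  grid <- expand.grid(sample_size = as.integer(sample_sizes),
                      census_success = as.numeric(successes),
                      replicate = seq_len(replicates))
  runs <- vector("list", nrow(grid))
  dets <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sz <- grid$sample_size[i]
    su <- grid$census_success[i]
    run_seed <- derive_seed(seed, i)
    cen <- simulate_census(spec, n = sz, seed = run_seed)
    cen <- apply_census_success(cen, su, seed = derive_seed(run_seed, 1L))
    rep_i <- detect_discontinuities(cen, threshold = threshold, B = B,
                                    increment = increment, mode = mode,
                                    seed = derive_seed(run_seed, 2L))
    loc <- discontinuity_locations(rep_i)
    runs[[i]] <- data.frame(
      sample_size = sz, census_success = su, replicate = grid$replicate[i],
      seed = run_seed, n_effective = cen$n, h_star = rep_i$meta$h_star,
      n_detected = length(loc),
      recovery = gap_recovery(loc, spec))
    dets[[i]] <- if (length(loc)) data.frame(
      sample_size = sz, census_success = su, replicate = grid$replicate[i],
      seed = run_seed, location = loc) else NULL
  }
  structure(
    list(detections = do.call(rbind, dets[!vapply(dets, is.null, logical(1))]),
         runs = do.call(rbind, runs),
         spec = spec,
         params = list(sample_sizes = as.integer(sample_sizes),
                       successes = as.numeric(successes),
                       replicates = replicates, threshold = threshold,
                       B = as.integer(B), increment = increment, mode = mode,
                       seed = as.integer(seed)),
         clusters = NULL),
    class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf(
    "Sensitivity result: %d runs (%d sizes x %d successes x %d replicates), %d detections\n",
    nrow(x$runs), length(x$params$sample_sizes), length(x$params$successes),
    x$params$replicates,
    if (is.null(x$detections)) 0L else nrow(x$detections)))
  if (!is.null(x$clusters))
    cat(sprintf("  clustered into %d location clusters (BIC-selected)\n",
                x$clusters$n_clusters))
  invisible(x)
}

#' Fraction of true gaps recovered by detected locations
#'
#' A true between-mode gap counts as recovered when some detected location
#' lies within \code{tol} of its midpoint; \code{tol} defaults to half the
#' mode spacing, so a detection is credited to at most the nearest true gap.
#'
#' @param locations numeric vector of detected gap locations (log10).
#' @param spec the generating \code{mixture_spec}.
#' @param tol matching tolerance (log10 units).
#' @return fraction in \code{[0, 1]} of \code{spec$true_gap_midpoints}
#'   recovered.
#' @export
gap_recovery <- function(locations, spec, tol = spec$spacing / 2) {
  if (!inherits(spec, "mixture_spec")) stop_dd("expected a `mixture_spec`")
  truth <- spec$true_gap_midpoints
  if (!length(locations)) return(0)
  hit <- vapply(truth, function(g) any(abs(locations - g) <= tol), logical(1))
  mean(hit)
}

#' Spread of detected locations around each true gap
#'
#' For each true between-mode gap of a generating mixture, the standard
#' deviation of the detected locations attributable to it (those within
#' \code{tol} of its midpoint) — the per-gap precision of the detector, the
#' quantity that tightens as sample size and census success grow. Gaps with
#' fewer than two attributable detections give \code{NA}.
#'
#' @param locations numeric vector of detected gap locations (log10).
#' @param spec the generating \code{mixture_spec}.
#' @param tol attribution window around each true midpoint; defaults to half
#'   the mode spacing.
#' @return numeric vector of length \code{spec$k - 1} of standard deviations.
#' @export
true_gap_spread <- function(locations, spec, tol = spec$spacing / 2) {
  if (!inherits(spec, "mixture_spec")) stop_dd("expected a `mixture_spec`")
  vapply(spec$true_gap_midpoints, function(g) {
    m <- locations[abs(locations - g) <= tol]
    if (length(m) >= 2L) sd(m) else NA_real_
  }, numeric(1))
}

#' Cluster detected discontinuity locations
#'
#' Groups independently detected gap locations into clusters by fitting
#' one-dimensional Gaussian mixtures (equal-variance and free-variance
#' families) for 1 to \code{k_max} components and selecting the component
#' count by BIC; each location is assigned to its maximum-responsibility
#' component. Because each simulated dataset is an independent draw, this is
#' how detections referring to the same underlying discontinuity are
#' identified across replicates.
#'
#' @param x numeric vector of at least 10 locations, or a
#'   \code{sensitivity_result} (whose pooled \code{detections$location} is
#'   used and whose \code{clusters} field is filled in).
#' @param k_max maximum number of clusters tried; capped at the number of
#'   distinct locations.
#'
#' @return For a numeric vector: a \code{discontinuity_clusters} object —
#'   list with \code{n_clusters}, \code{assignments}, \code{centers},
#'   \code{spread} (per-cluster sd of member locations; 0 for singletons or
#'   identical members), \code{sizes}, \code{model} and \code{bic}. For a
#'   \code{sensitivity_result}: the same result stored in \code{$clusters},
#'   with per-detection assignments appended to \code{detections$cluster}.
#' @export
cluster_discontinuities <- function(x, k_max = 15L) {
  if (inherits(x, "sensitivity_result")) {
    if (is.null(x$detections) || nrow(x$detections) < 10L)
      stop_dd("need at least 10 pooled detections to cluster")
    cl <- cluster_discontinuities(x$detections$location, k_max = k_max)
    x$detections$cluster <- cl$assignments
    x$clusters <- cl
    return(x)
  }
  locations <- as.numeric(x)
  if (length(locations) < 10L)
    stop_dd("need at least 10 locations to cluster")
  k_max <- as.integer(check_scalar(k_max, "k_max"))
  n_distinct <- length(unique(locations))
  if (n_distinct == 1L) {
    return(structure(
      list(n_clusters = 1L,
           assignments = rep(1L, length(locations)),
           centers = locations[1], spread = 0, sizes = length(locations),
           model = "degenerate", bic = NA_real_),
      class = "discontinuity_clusters"))
  }
  fit <- Mclust(locations, G = seq_len(min(k_max, n_distinct)),
                modelNames = c("E", "V"), verbose = FALSE)
  if (is.null(fit))
    stop_dd("mixture clustering failed to fit any model")
  assign <- as.integer(fit$classification)
  centers <- as.numeric(fit$parameters$mean)
  spread <- vapply(seq_len(fit$G), function(g) {
    mem <- locations[assign == g]
    if (length(mem) < 2L) 0 else sd(mem)
  }, numeric(1))
  structure(
    list(n_clusters = fit$G, assignments = assign, centers = centers,
         spread = spread, sizes = as.integer(table(factor(assign,
                                                          levels = seq_len(fit$G)))),
         model = fit$modelName, bic = as.numeric(fit$bic)),
    class = "discontinuity_clusters")
}

#' @export
print.discontinuity_clusters <- function(x, ...) {
  cat(sprintf("Discontinuity clusters: %d clusters (model %s, BIC %.1f)\n",
              x$n_clusters, x$model, x$bic))
  for (g in seq_len(x$n_clusters))
    cat(sprintf("  cluster %d: center %.3f, spread %.4f, size %d\n",
                g, x$centers[g], x$spread[g], x$sizes[g]))
  invisible(x)
}
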