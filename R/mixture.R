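#' Default multimodal mixture specification
#'
#' Builds the Gaussian mixture, on the log10-mass axis, used as ground truth
#' in the sensitivity experiments: \code{k} modes with means evenly spaced
#' and standard deviations increasing linearly along the axis (larger
#' animals, wider aggregations on the raw scale), equal weights, and a
#' separation-to-sd ratio of at least 4 so that adjacent modes remain
#' resolvable. The default range 0.5–5.0 log10 grams spans roughly
#' shrew-to-moose body masses. True discontinuity locations are the
#' midpoints between adjacent means.
#'
#' @param k number of modes (at least 2); default 10.
#' @param mean_range length-2 numeric: first and last mode means (log10
#'   grams); default \code{c(0.5, 5.0)}.
#' @param sd_range length-2 numeric: sd of the first and last mode; default
#'   \code{c(0.05, 0.125)} (worst-case separation/sd ratio exactly 4 at the
#'   defaults with k = 10).
#'
#' @return A \code{mixture_spec}: list with \code{k}, \code{means},
#'   \code{sds}, \code{weights} (all \code{1/k}),
#'   \code{true_gap_midpoints} (length \code{k - 1}) and \code{spacing}.
#' @examples
#' spec <- default_mixture()
#' spec$true_gap_midpoints
#' @export
default_mixture <- function(k = 10L, mean_range = c(0.5, 5.0),
                            sd_range = c(0.05, 0.125)) {
  k <- as.integer(check_scalar(k, "k"))
  if (k < 2L) stop_dd("a mixture needs at least 2 modes")
  if (length(mean_range) != 2L || diff(mean_range) <= 0)
    stop_dd("`mean_range` must be increasing of length 2")
  if (length(sd_range) != 2L || any(sd_range <= 0))
    stop_dd("`sd_range` must be positive of length 2")
  means <- seq(mean_range[1], mean_range[2], length.out = k)
  sds <- seq(sd_range[1], sd_range[2], length.out = k)
  spacing <- if (k > 1) means[2] - means[1] else NA_real_
  structure(
    list(k = k, means = means, sds = sds, weights = rep(1 / k, k),
         true_gap_midpoints = (means[-k] + means[-1]) / 2,
         spacing = spacing),
    class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf(
    "Gaussian mixture spec: %d modes, means %.2f..%.2f (spacing %.3f), sds %.3f..%.3f, equal weights\n",
    x$k, min(x$means), max(x$means), x$spacing, min(x$sds), max(x$sds)))
  invisible(x)
}

#' Analytic density of a mixture spec on the log10 axis
#'
#' @param spec a \code{mixture_spec}.
#' @param x numeric vector of log10-mass evaluation points.
#' @return numeric density values.
#' @export
mixture_density <- function(spec, x) {
  if (!inherits(spec, "mixture_spec")) stop_dd("expected a `mixture_spec`")
  rowSums(vapply(seq_len(spec$k),
                 function(j) spec$weights[j] * dnorm(x, spec$means[j], spec$sds[j]),
                 numeric(length(x))))
}

#' Simulate a census from a mixture specification
#'
#' Draws \code{n} species mean body masses from the mixture on the log10
#' scale, exponentiates to grams, and packages them as a
#' \code{ranked_census}. Component memberships (sorted in census order) are
#' kept as the \code{"component"} attribute for ground-truth bookkeeping.
#'
#' @param spec a \code{mixture_spec}.
#' @param n census size; default 100.
#' @param seed integer seed; identical seeds give identical censuses.
#' @return A \code{ranked_census} with attribute \code{component}.
#' @export
simulate_census <- function(spec, n = 100L, seed = NULL) {
  if (!inherits(spec, "mixture_spec")) stop_dd("expected a `mixture_spec`")
  n <- as.integer(check_scalar(n, "n"))
  if (n < 3L) stop_dd("n must be at least 3")
  set_seed_maybe(seed)
  comp <- sample.int(spec$k, n, replace = TRUE, prob = spec$weights)
  logm <- rnorm(n, mean = spec$means[comp], sd = spec$sds[comp])
  cen <- prepare_census(logm, labels = paste0("sim", seq_len(n)),
                        log_already = TRUE)
  attr(cen, "component") <- comp[order(logm)]
  cen
}

#' Thin a census to a given census success
#'
#' Simulates incomplete sampling of a community by retaining
#' \code{round(success * n)} entities chosen uniformly without replacement;
#' \code{success = 1} returns the census unchanged.
#'
#' @param census a \code{ranked_census}.
#' @param success fraction in (0, 1] of the community captured.
#' @param seed integer seed; the retained set is reproducible per seed.
#' @return A \code{ranked_census} of the retained entities.
#' @export
apply_census_success <- function(census, success, seed = NULL) {
  assert_census(census)
  success <- check_scalar(success, "success")
  if (success > 1)
    stop_dd("`success` must be in (0, 1]")
  if (success == 1) return(census)
  keep_n <- round(success * census$n)
  if (keep_n < 3L)
    stop_dd(sprintf("census success %.2f leaves fewer than 3 of %d entities",
                    success, census$n))
  set_seed_maybe(seed)
  keep <- sort(sample.int(census$n, keep_n, replace = FALSE))
  comp <- attr(census, "component")
  out <- prepare_census(census$logmass[keep], labels = census$labels[keep],
                        log_already = TRUE)
  if (!is.null(comp)) attr(out, "component") <- comp[keep]
  out
}
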