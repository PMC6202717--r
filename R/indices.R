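#' Holling difference index
#'
#' The classic body-mass difference index
#' \deqn{HI_k = \left(\frac{M_{k+1} - M_{k-1}}{M_k}\right)^\gamma}
#' computed on the raw (untransformed) masses at every interior rank. It is
#' descriptive only: the package deliberately attaches no significance
#' criterion to it, since criterion-based calls from difference indices are
#' subjective. Endpoints need both neighbours and are reported as \code{NA}.
#'
#' The historical transforms are 1.3 for birds and 1.1 for mammals; whether
#' the constant acts as the exponent \eqn{\gamma} or as a power
#' pre-transform of the masses is ambiguous in the older literature, so both
#' readings are available via \code{transform}.
#'
#' @param census a \code{ranked_census}.
#' @param gamma positive exponent (or pre-transform power); defaults to 1.
#' @param transform \code{"exponent"} (default): \code{gamma} is the exponent
#'   of the ratio. \code{"premass"}: masses are first raised to the power
#'   \code{gamma} and the index is computed with exponent 1.
#'
#' @return An \code{index_series}: list with \code{values} (length \code{n},
#'   \code{NA} at both endpoints), \code{method = "HI"}, \code{gamma},
#'   \code{transform}.
#' @examples
#' holling_index(prepare_census(c(1, 2, 3)))$values  # NA 1 NA
#' @export
holling_index <- function(census, gamma = 1,
                          transform = c("exponent", "premass")) {
  assert_census(census)
  transform <- match.arg(transform)
  gamma <- check_scalar(gamma, "gamma")
  m <- census$mass
  if (transform == "premass") m <- m^gamma
  n <- census$n
  k <- 2:(n - 1L)
  core <- (m[k + 1L] - m[k - 1L]) / m[k]
  vals <- rep(NA_real_, n)
  vals[k] <- if (transform == "exponent") core^gamma else core
  structure(list(values = vals, method = "HI", gamma = gamma,
                 transform = transform),
            class = "index_series")
}

#' Siemann-Brown difference index
#'
#' The log-ratio of adjacent ranked masses, \eqn{SB_r =
#' \log_{10}(M_{r+1}/M_r)} — algebraically identical to the observed
#' log10 rank gaps used by the discontinuity test, and non-negative for
#' sorted data.
#'
#' @param census a \code{ranked_census}.
#' @return An \code{index_series}: list with \code{values} (length
#'   \code{n - 1}) and \code{method = "SB"}.
#' @examples
#' siemann_brown_index(prepare_census(c(10, 100, 1000)))$values  # c(1, 1)
#' @export
siemann_brown_index <- function(census) {
  assert_census(census)
  structure(list(values = diff(census$logmass), method = "SB"),
            class = "index_series")
}

#' @export
print.index_series <- function(x, ...) {
  extra <- if (x$method == "HI")
    sprintf(" (gamma = %g, %s)", x$gamma, x$transform) else ""
  cat(sprintf("%s index series%s: %d values\n", x$method, extra,
              length(x$values)))
  print(head(x$values, 10))
  invisible(x)
}
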