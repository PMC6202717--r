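#' Prepare a ranked census from raw body masses
#'
#' Log10-transforms a vector of strictly positive masses, sorts it ascending,
#' and packages it with aligned labels as a \code{ranked_census} object — the
#' input every later stage of the discontinuity analysis consumes. Duplicate
#' masses are legitimate (species with equal mean mass) and are preserved.
#'
#' @param masses numeric vector of strictly positive, finite sizes
#'   (conventionally body mass in grams; the unit is the caller's
#'   responsibility). At least 3 values are required — with fewer there is no
#'   interior gap structure to test.
#' @param labels optional character vector of entity (species) identifiers,
#'   one per mass. Defaults to \code{"sp1"}, \code{"sp2"}, ... in the order
#'   supplied.
#' @param log_already logical; if \code{TRUE}, \code{masses} are taken to be
#'   log10-transformed already (negative values are then legitimate: masses
#'   below 1 g).
#'
#' @return An object of class \code{ranked_census}: a list with elements
#'   \code{labels}, \code{mass} (raw grams, sorted ascending), \code{logmass}
#'   (log10 grams, sorted ascending) and \code{n}.
#'
#' @examples
#' prepare_census(c(10, 100, 1000))
#' prepare_census(c(5.2, 2.0, 47.0), labels = c("a", "b", "c"))
#'
#' @seealso \code{\link{detect_discontinuities}}, \code{\link{observed_gaps}}
#' @export
prepare_census <- function(masses, labels = NULL, log_already = FALSE) {
  if (!is.numeric(masses))
    stop_dd("`masses` must be numeric")
  n <- length(masses)
  if (n < 3L)
    stop_dd(sprintf(
      "a census needs at least 3 records to have interior gap structure (got %d)",
      n))
  bad <- which(!is.finite(masses) | (!log_already & masses <= 0))
  if (length(bad))
    stop_dd(sprintf(
      "masses must be strictly positive and finite; offending record(s): %s",
      paste(bad, collapse = ", ")))
  if (is.null(labels)) {
    labels <- paste0("sp", seq_len(n))
  } else {
    labels <- as.character(labels)
    if (length(labels) != n)
      stop_dd("`labels` must align 1:1 with `masses`")
  }
  logmass <- if (log_already) as.numeric(masses) else log10(as.numeric(masses))
  ord <- order(logmass)
  structure(
    list(labels = labels[ord],
         mass = 10^logmass[ord],
         logmass = logmass[ord],
         n = n),
    class = "ranked_census")
}

#' @export
print.ranked_census <- function(x, ...) {
  cat(sprintf("Ranked census: %d entities\n", x$n))
  cat(sprintf("  log10 mass range: [%.4f, %.4f] (%.4f log10 units)\n",
              min(x$logmass), max(x$logmass), diff(range(x$logmass))))
  show_n <- min(5L, x$n)
  cat(sprintf("  smallest: %s\n",
              paste(sprintf("%s (%.3g g)", x$labels[seq_len(show_n)],
                            x$mass[seq_len(show_n)]), collapse = ", ")))
  invisible(x)
}

is_ranked_census <- function(x) inherits(x, "ranked_census")

assert_census <- function(census) {
  if (!is_ranked_census(census))
    stop_dd("expected a `ranked_census` (see prepare_census())")
  invisible(census)
}
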