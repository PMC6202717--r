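#' Read a census table from CSV or TSV
#'
#' Reads a delimited table with a required \code{mass} column (strictly
#' positive reals; grams by convention) and an optional \code{label} column,
#' sniffing the delimiter (comma or tab) from the header line, and applies
#' \code{\link{prepare_census}}. Row-level problems are reported with their
#' line numbers.
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param log_already logical; if \code{TRUE} the mass column is already
#'   log10-transformed.
#' @param mass_col,label_col column names; defaults \code{"mass"} and
#'   \code{"label"}.
#' @return A \code{ranked_census}.
#' @export
read_census <- function(path, log_already = FALSE, mass_col = "mass",
                        label_col = "label") {
  if (!file.exists(path)) stop_dd(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  if (!length(header) || !nzchar(header))
    stop_dd(sprintf("empty file: %s", path))
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    comment.char = "#", quote = "\"")
  if (!mass_col %in% names(tab))
    stop_dd(sprintf("no `%s` column in %s (found: %s)", mass_col, path,
                    paste(names(tab), collapse = ", ")))
  raw <- tab[[mass_col]]
  masses <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(masses))
  if (length(bad))
    stop_dd(sprintf("non-numeric mass value(s) at data line(s) %s of %s: %s",
                    paste(bad + 1L, collapse = ", "), path,
                    paste(raw[bad], collapse = ", ")))
  labels <- if (label_col %in% names(tab)) as.character(tab[[label_col]]) else NULL
  prepare_census(masses, labels = labels, log_already = log_already)
}

#' Write a discontinuity report to TSV
#'
#' Writes the per-rank table with a \code{#}-prefixed metadata header
#' (h*, B, threshold, mode, seed, increment, n) so a report can be re-run
#' exactly from its own file. Columns are in a fixed order and numbers in
#' full precision, so identical reports give byte-identical files. Round
#' trips through \code{\link{read_report}}.
#'
#' @param report a \code{discontinuity_report}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "discontinuity_report"))
    stop_dd("expected a `discontinuity_report`")
  m <- report$meta
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    stop_dd(sprintf("cannot write to %s: %s", path, conditionMessage(e))))
  on.exit(close(con))
  hdr <- c(sprintf("# n\t%d", m$n),
           sprintf("# h_star\t%.15g", m$h_star),
           sprintf("# B\t%d", m$B),
           sprintf("# threshold\t%.15g", m$threshold),
           sprintf("# mode\t%s", m$mode),
           sprintf("# seed\t%d", m$seed),
           sprintf("# increment\t%.15g", m$increment),
           sprintf("# expected_false_flags\t%.15g", m$expected_false_flags))
  tab <- report$table
  num <- function(v) sprintf("%.15g", v)
  body <- paste(tab$rank, tab$lower_label, tab$upper_label,
                num(tab$lower_mass), num(tab$upper_mass),
                num(tab$lower_logmass), num(tab$upper_logmass),
                num(tab$gap_log10), num(tab$percentile),
                as.integer(tab$discontinuity), sep = "\t")
  cols <- paste("rank", "lower_label", "upper_label", "lower_mass",
                "upper_mass", "lower_logmass", "upper_logmass", "gap_log10",
                "percentile", "discontinuity", sep = "\t")
  writeLines(c(hdr, cols, body), con = con, sep = "\n")
  invisible(path)
}

#' Read a discontinuity report written by write_report
#'
#' @param path path to a TSV written by \code{\link{write_report}}.
#' @return A \code{discontinuity_report} (without the fitted null object,
#'   which is not serialized).
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_dd(sprintf("file not found: %s", path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), "\t", fixed = TRUE))
  meta_raw <- stats::setNames(kv[, 2], kv[, 1])
  meta <- list(n = as.integer(meta_raw[["n"]]),
               h_star = as.numeric(meta_raw[["h_star"]]),
               B = as.integer(meta_raw[["B"]]),
               threshold = as.numeric(meta_raw[["threshold"]]),
               mode = meta_raw[["mode"]],
               seed = as.integer(meta_raw[["seed"]]),
               increment = as.numeric(meta_raw[["increment"]]),
               expected_false_flags = as.numeric(meta_raw[["expected_false_flags"]]))
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  tab$discontinuity <- as.logical(tab$discontinuity)
  structure(list(table = tab, null = NULL, meta = meta),
            class = "discontinuity_report")
}

#' Run configuration with documented defaults
#'
#' Collects every tunable of the pipeline in one validated flat list. The
#' defaults are the method's reference configuration: bandwidth increment
#' 0.001, bandwidth cap at half the data range, 2048-point density grid,
#' 5000 resamples, threshold 0.90, component-level without-replacement
#' resampling, and no support truncation on the log scale.
#'
#' @param ... named overrides of the defaults; unknown names are rejected.
#' @return A named list of class \code{dd_config}.
#' @export
dd_config <- function(...) {
  defaults <- list(
    bandwidth_increment = 0.001,
    h_max_fraction_of_range = 0.5,
    grid_points = 2048L,
    resamples = 5000L,
    threshold = 0.90,
    mode = "centers",
    truncate_at_zero = FALSE,
    seed = 1L)
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown) || is.null(names(over)) || any(names(over) == ""))
      stop_dd(sprintf("unknown config key(s): %s",
                      paste(if (length(unknown)) unknown else "<unnamed>",
                            collapse = ", ")))
    defaults[names(over)] <- over
  }
  structure(defaults, class = "dd_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file of config keys; unknown keys are rejected (see
#'   \code{\link{dd_config}} for the key set and defaults).
#' @return A \code{dd_config}.
#' @export
read_dd_config <- function(path) {
  if (!file.exists(path)) stop_dd(sprintf("file not found: %s", path))
  vals <- yaml::read_yaml(path)
  do.call(dd_config, vals)
}

#' Run the detector under a configuration
#'
#' Convenience wrapper tying \code{\link{dd_config}} to
#' \code{\link{detect_discontinuities}}.
#'
#' @param census a \code{ranked_census}.
#' @param config a \code{dd_config}; defaults to \code{dd_config()}.
#' @return A \code{discontinuity_report}.
#' @export
detect_with_config <- function(census, config = dd_config()) {
  if (!inherits(config, "dd_config")) stop_dd("expected a `dd_config`")
  detect_discontinuities(
    census,
    threshold = config$threshold,
    B = config$resamples,
    increment = config$bandwidth_increment,
    mode = config$mode,
    seed = config$seed,
    h_max = diff(range(census$logmass)) * config$h_max_fraction_of_range,
    grid_points = config$grid_points,
    lower_bound = if (isTRUE(config$truncate_at_zero)) 0 else NULL)
}
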