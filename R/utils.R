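#' scavsurv: survival and carcass-use analysis for scavenging experiments
#'
#' Event reconstruction from camera-trap photo streams, mixed-effects Cox
#' survival models for carcass discovery and persistence, leave-one-out
#' cross-validated model selection, hurdle GLMMs for carcass use and foraging
#' duration, bootstrap regional summaries, and a synthetic-study generator
#' with known ground truth.
#'
#' @keywords internal
#' @importFrom matrixStats colCumsums
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## reverse cumulative sum down the rows of a matrix (suffix sums)
rev_cumsum_rows <- function(m) {
  if (is.null(dim(m))) return(rev(cumsum(rev(m))))
  n <- nrow(m)
  if (n == 0L) return(m)
  matrixStats::colCumsums(m[n:1, , drop = FALSE])[n:1, , drop = FALSE]
}

stop_scav <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "scavsurv_error")))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_scav("%s table is missing column(s): %s", what,
              paste(missing, collapse = ", "), class = "scavsurv_schema_error")
  }
  invisible(df)
}

## minutes between two POSIXct vectors
diff_min <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "mins"))
}

diff_days <- function(later, earlier) {
  as.numeric(difftime(later, earlier, units = "days"))
}

parse_timestamp <- function(x, what = "timestamp") {
  x[!is.na(x) & x == ""] <- NA       # blank cells mean "no time recorded"
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"),
                    optional = TRUE)
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop_scav("unparseable %s on row(s): %s", what,
              paste(utils::head(bad, 10L), collapse = ", "),
              class = "scavsurv_parse_error")
  }
  out
}
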