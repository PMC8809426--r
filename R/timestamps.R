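#' Parse ISO-8601 timestamps
#'
#' Parses character timestamps as used in camera-trap photo tables.
#' Accepts `YYYY-MM-DDTHH:MM:SS` (or a space instead of `T`), optionally
#' followed by a numeric UTC offset (`+hh:mm`, `+hhmm` or `Z`). Values
#' without an offset are interpreted in `tz`; all results are returned in
#' `tz` so that events from different cameras order consistently.
#'
#' @param x character vector (or POSIXct, returned converted to `tz`).
#' @param tz Olson timezone name used for interpretation and display.
#' @return POSIXct vector in `tz`.
#' @export
parse_timestamps <- function(x, tz = "UTC") {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- tz
    return(x)
  }
  if (!is.character(x)) x <- as.character(x)
  x0 <- trimws(x)
  x0 <- sub(" ", "T", x0, fixed = TRUE)
  out <- rep(as.POSIXct(NA), length(x0))
  has_z <- grepl("Z$", x0)
  x0[has_z] <- sub("Z$", "+0000", x0[has_z])
  # normalize +hh:mm offsets to +hhmm for strptime's %z
  x0 <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x0)
  has_off <- grepl("[+-][0-9]{4}$", x0)
  if (any(has_off)) {
    p <- as.POSIXct(x0[has_off], format = "%Y-%m-%dT%H:%M:%OS%z", tz = tz)
    out[has_off] <- p
  }
  if (any(!has_off)) {
    p <- as.POSIXct(x0[!has_off], format = "%Y-%m-%dT%H:%M:%OS", tz = tz)
    out[!has_off] <- p
  }
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop_input(sprintf(
      "unparseable timestamp in record(s) %s: %s",
      paste(utils::head(bad, 5L), collapse = ", "),
      paste(sQuote(utils::head(x[bad], 5L)), collapse = ", ")))
  }
  attr(out, "tzone") <- tz
  out
}

# Condition helpers: distinct classes let the CLI map failures to exit codes.
stop_input <- function(msg) {
  stop(errorCondition(msg, class = c("facetrap_input_error", "facetrap_error")))
}
stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("facetrap_degenerate_error", "facetrap_error")))
}
stop_convergence <- function(msg) {
  stop(errorCondition(msg, class = c("facetrap_convergence_error", "facetrap_error")))
}
stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("facetrap_config_error", "facetrap_error")))
}
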