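`%||%` <- function(x, y) if (is.null(x)) y else x

#' Parse ISO-8601 timestamps
#'
#' Accepts `"YYYY-MM-DDTHH:MM:SS"` with an optional trailing `Z`; all times are
#' treated as UTC. `POSIXct` input is passed through unchanged.
#'
#' @param x character vector (or `POSIXct`).
#' @param field name used in error messages.
#' @return `POSIXct` vector in UTC.
#' @keywords internal
parse_ts <- function(x, field = "timestamp") {
  if (inherits(x, "POSIXct")) return(x)
  if (length(x) == 0) return(as.POSIXct(character(0), tz = "UTC"))
  x <- as.character(x)
  out <- as.POSIXct(sub("Z$", "", x), format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  # tolerate a space separator, as in flowsheet CSV exports
  retry <- is.na(out) & !is.na(x)
  if (any(retry)) {
    out[retry] <- as.POSIXct(x[retry], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  }
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop(sprintf("%s: cannot parse ISO-8601 timestamp '%s'", field, x[which(bad)[1]]),
         call. = FALSE)
  }
  out
}

format_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

# Map a raw enum value onto the allowed set; unknown values fall back with a
# warning rather than failing, mirroring the tolerance an EHR-embedded tool
# needs for dirty source data.
normalize_enum <- function(x, allowed, fallback, field) {
  x <- tolower(trimws(as.character(x)))
  bad <- !(x %in% allowed)
  if (any(bad)) {
    warning(sprintf("%s: unknown value(s) %s mapped to '%s'", field,
                    paste(sQuote(unique(x[bad])), collapse = ", "), fallback),
            call. = FALSE)
    x[bad] <- fallback
  }
  x
}

# data.frame constructor without the checks of data.frame(); used on hot
# simulation/scoring paths where columns are known-good equal-length vectors
fast_df <- function(...) {
  x <- list(...)
  structure(x, class = "data.frame",
            row.names = .set_row_names(length(x[[1]])))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == trunc(x)
}
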