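#' Read an Ohio-style CGM XML file
#'
#' Parses the public Ohio T1D schema: a `glucose_level` element whose `event`
#' children carry `ts` (timestamp) and `value` (mg/dL) attributes. Events are
#' sorted by time, snapped to the nearest 5-minute grid point (collisions keep
#' the earliest record) and gaps in the grid are materialised as unobserved
#' samples, so the result always sits on a regular 5-minute grid.
#'
#' @param path path to an XML file.
#' @return A [cgm_series()].
#' @export
read_ohio_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop(sprintf("malformed XML in '%s': %s", path, conditionMessage(e)), call. = FALSE)
  })
  events <- xml2::xml_find_all(doc, ".//glucose_level/event")
  if (length(events) == 0L) {
    stop(sprintf("no glucose_level events found in '%s'", path), call. = FALSE)
  }
  ts_raw <- xml2::xml_attr(events, "ts")
  val_raw <- xml2::xml_attr(events, "value")
  ts <- parse_ohio_timestamp(ts_raw)
  bad_ts <- which(is.na(ts))
  if (length(bad_ts)) {
    stop(sprintf(
      "unparseable timestamp '%s' in glucose_level event %d",
      ts_raw[bad_ts[1]], bad_ts[1]
    ), call. = FALSE)
  }
  val <- suppressWarnings(as.numeric(val_raw))
  bad_val <- which(is.na(val))
  if (length(bad_val)) {
    stop(sprintf(
      "non-numeric glucose value '%s' in glucose_level event %d (ts %s)",
      val_raw[bad_val[1]], bad_val[1], ts_raw[bad_val[1]]
    ), call. = FALSE)
  }
  ord <- order(ts)
  ts <- ts[ord]
  val <- val[ord]

  # snap to the nearest 5-min grid point; earliest record wins a collision
  snapped <- as.POSIXct(round(as.numeric(ts) / 300) * 300,
    origin = "1970-01-01", tz = "UTC"
  )
  keep <- !duplicated(snapped)
  snapped <- snapped[keep]
  val <- val[keep]

  grid <- seq(snapped[1], snapped[length(snapped)], by = 300)
  glucose <- rep(NA_real_, length(grid))
  glucose[match(as.numeric(snapped), as.numeric(grid))] <- val
  cgm_series(time = grid, glucose = glucose)
}

# Ohio files use day-first local timestamps; ISO-8601 is accepted too.
# Timestamps are treated as naive local time (no DST correction) and carried
# as UTC internally.
parse_ohio_timestamp <- function(x) {
  out <- as.POSIXct(x, tz = "UTC", format = "%d-%m-%Y %H:%M:%S")
  iso <- is.na(out)
  if (any(iso)) {
    out[iso] <- as.POSIXct(x[iso], tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  }
  iso <- is.na(out)
  if (any(iso)) {
    out[iso] <- as.POSIXct(x[iso], tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  }
  out
}

#' Write a CGM series to CSV
#'
#' One row per grid sample with columns `timestamp` (ISO-8601, UTC), `glucose`
#' (fixed two-decimal mg/dL, empty when unobserved) and `observed`
#' (`true`/`false`). Formatting is deterministic: the same series always
#' produces byte-identical files.
#'
#' @param series a [cgm_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "cgm_series"))
  gl <- ifelse(series$observed, sprintf("%.2f", series$glucose), "")
  lines <- c(
    "timestamp,glucose,observed",
    sprintf(
      "%s,%s,%s",
      format(series$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      gl,
      ifelse(series$observed, "true", "false")
    )
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a CGM series from CSV
#'
#' Reads the schema written by [write_series_csv()] and round-trips it
#' exactly: empty glucose cells become unobserved samples.
#'
#' @param path path to a CSV file.
#' @return A [cgm_series()].
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  needed <- c("timestamp", "glucose", "observed")
  if (!all(needed %in% names(df))) {
    stop(sprintf(
      "CSV must have columns %s; found %s",
      paste(needed, collapse = ", "), paste(names(df), collapse = ", ")
    ), call. = FALSE)
  }
  time <- as.POSIXct(df$timestamp, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  if (anyNA(time)) stop("unparseable timestamp in CSV", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  observed <- df$observed %in% c("true", "TRUE", "True", "1")
  glucose <- rep(NA_real_, nrow(df))
  glucose[observed] <- as.numeric(df$glucose[observed])
  cgm_series(time = time, glucose = glucose, observed = observed)
}
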