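#' Construct an activity series
#'
#' An activity series is one cow's timestamped stream of the dimensionless
#' activity index (1--100) recorded by a reticulorumen bolus at a nominal
#' 10-minute cadence. Gaps are permitted; timestamps must be strictly
#' increasing and values must lie inside the index range.
#'
#' @param cow_id Single character identifier.
#' @param time `POSIXct` vector of strictly increasing timestamps.
#' @param values Numeric vector in \[1, 100\], same length as `time`.
#' @return An object of class `activity_series`: a list with elements
#'   `cow_id`, `time`, `values` and the nominal sampling interval in
#'   seconds (`interval`).
#' @seealso [simulate_activity_series()], [read_activity_table()]
#' @export
activity_series <- function(cow_id, time, values) {
  if (!is.character(cow_id) || length(cow_id) != 1L || is.na(cow_id))
    stopf("`cow_id` must be a single character string")
  time <- as.POSIXct(time, tz = "UTC")
  values <- as.numeric(values)
  if (length(time) != length(values))
    stopf("cow %s: %d timestamps but %d values", cow_id, length(time), length(values))
  if (anyNA(time)) stopf("cow %s: missing timestamps", cow_id)
  if (anyNA(values)) stopf("cow %s: missing activity values", cow_id)
  if (length(time) > 1L && any(diff(as.numeric(time)) <= 0))
    stopf("cow %s: timestamps must be strictly increasing", cow_id)
  bad <- values < 1 | values > 100
  if (any(bad))
    stopf("cow %s: %d activity value(s) outside [1, 100] (first: %g)",
          cow_id, sum(bad), values[which(bad)[1L]])
  structure(list(cow_id = cow_id, time = time, values = values,
                 interval = .SAMPLE_SEC),
            class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf("<activity_series> cow %s: %d points", x$cow_id, length(x$values)))
  if (length(x$time)) {
    cat(sprintf(", %s .. %s UTC",
                format(min(x$time), "%Y-%m-%d %H:%M"),
                format(max(x$time), "%Y-%m-%d %H:%M")))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.activity_series <- function(x) length(x$values)

# Subset of a series restricted to a half-open interval [start, end).
window_series <- function(series, interval) {
  keep <- series$time >= interval[1L] & series$time < interval[2L]
  structure(list(cow_id = series$cow_id, time = series$time[keep],
                 values = series$values[keep], interval = series$interval),
            class = "activity_series")
}

#' Read per-cow activity series from a delimited table
#'
#' Expects the schema written by [write_activity_table()]: columns `cow_id`,
#' `timestamp` (ISO-8601, UTC) and `activity_index`. One series per cow is
#' returned, sorted by time and validated (range, duplicate timestamps).
#'
#' @param path Path to a tab- or comma-delimited text file.
#' @param strict If `TRUE` (default) any invalid row fails the whole file;
#'   if `FALSE` invalid rows are dropped with a warning.
#' @return Named list of [activity_series()], one per `cow_id`.
#' @export
read_activity_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stopf("activity table not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("cow_id", "timestamp", "activity_index")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("activity table missing column(s): %s",
                          paste(miss, collapse = ", "))
  tm <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  val <- suppressWarnings(as.numeric(df$activity_index))
  bad <- is.na(tm) | is.na(val) | val < 1 | val > 100
  dup <- rep(FALSE, nrow(df))
  for (id in unique(df$cow_id)) {
    i <- which(df$cow_id == id & !bad)
    dup[i[duplicated(tm[i])]] <- TRUE
  }
  bad <- bad | dup
  if (any(bad)) {
    msg <- sprintf("%d invalid row(s) (unparsable timestamp, value outside [1,100], or duplicate timestamp); first at line %d",
                   sum(bad), which(bad)[1L] + 1L)
    if (strict) stopf("%s: %s", path, msg) else warning(msg, call. = FALSE)
    df <- df[!bad, , drop = FALSE]; tm <- tm[!bad]; val <- val[!bad]
  }
  out <- lapply(unique(df$cow_id), function(id) {
    i <- which(df$cow_id == id)
    o <- order(tm[i])
    activity_series(as.character(id), tm[i][o], val[i][o])
  })
  names(out) <- unique(df$cow_id)
  out
}

#' Write activity series as a delimited table
#'
#' @param series_list One [activity_series()] or a list of them.
#' @param path Output path; tab-delimited with columns `cow_id`,
#'   `timestamp` (ISO-8601 UTC) and `activity_index`.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(series_list, path) {
  if (inherits(series_list, "activity_series")) series_list <- list(series_list)
  df <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(cow_id = s$cow_id,
               timestamp = format(s$time, "%Y-%m-%dT%H:%M:%S"),
               activity_index = s$values,
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
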