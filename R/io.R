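# Readers and writers for the pipeline's flat-file formats.

#' Write an acceleration trace as CSV
#'
#' Columns `horse_id`, `timestamp_iso`, `accel_g`; timestamps are rendered as
#' ISO-8601 UTC from a reference start time.
#'
#' @param trace Trace (`horse_id`, `timestamp` seconds, `accel`).
#' @param path Output file.
#' @param origin Reference POSIXct time of sample 0 (default 2014-03-01
#'   00:00 UTC; recordings start at midnight).
#' @export
write_trace_csv <- function(trace, path,
                            origin = as.POSIXct("2014-03-01", tz = "UTC")) {
  out <- data.frame(
    horse_id = trace$horse_id,
    timestamp_iso = format(origin + trace$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                           tz = "UTC"),
    accel_g = trace$accel
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Read an acceleration trace CSV
#'
#' Understands two dialects and normalises both to the internal trace layout:
#' the package's own comma-separated export (`horse_id`, `timestamp_iso`,
#' `accel_g`) and the MSR-logger export dialect (semicolon-separated, header
#' row, a timestamp column and one acceleration column named like "ACC z").
#'
#' @param path CSV file.
#' @param horse_id Identifier to assign when the file has none (MSR dialect).
#' @return Trace data frame (`horse_id`, `timestamp` seconds from first
#'   sample, `accel` g).
#' @export
read_trace_csv <- function(path, horse_id = NULL) {
  header <- readLines(path, n = 1L)
  if (grepl(";", header, fixed = TRUE)) {
    tab <- utils::read.csv2(path, stringsAsFactors = FALSE)
    acc_col <- grep("acc", names(tab), ignore.case = TRUE, value = TRUE)[1L]
    if (is.na(acc_col)) stop("no acceleration column found in MSR export")
    time_col <- grep("time", names(tab), ignore.case = TRUE, value = TRUE)[1L]
    ts <- if (!is.na(time_col)) {
      t0 <- as.POSIXct(tab[[time_col]][1L], tz = "UTC")
      as.numeric(difftime(as.POSIXct(tab[[time_col]], tz = "UTC"), t0,
                          units = "secs"))
    } else seq_len(nrow(tab)) - 1
    return(data.frame(
      horse_id = if (is.null(horse_id)) "unknown" else horse_id,
      timestamp = ts,
      accel = as.numeric(tab[[acc_col]]),
      stringsAsFactors = FALSE
    ))
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("horse_id", "timestamp_iso", "accel_g")
  if (!all(need %in% names(tab))) {
    stop("trace CSV must have columns ", paste(need, collapse = ", "))
  }
  t <- as.POSIXct(tab$timestamp_iso, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  data.frame(
    horse_id = tab$horse_id,
    timestamp = as.numeric(difftime(t, t[1L], units = "secs")),
    accel = tab$accel_g,
    stringsAsFactors = FALSE
  )
}

#' Write a detected-bout table as CSV
#'
#' Columns `horse_id`, `start_iso`, `end_iso`, `duration_s`.
#'
#' @param bouts Bout table.
#' @param path Output file.
#' @param origin POSIXct time of second 0.
#' @export
write_bouts_csv <- function(bouts, path,
                            origin = as.POSIXct("2014-03-01", tz = "UTC")) {
  out <- data.frame(
    horse_id = bouts$horse_id,
    start_iso = format(origin + bouts$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    end_iso = format(origin + bouts$end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    duration_s = bouts$duration
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}
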