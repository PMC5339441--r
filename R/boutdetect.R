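#' Classify 1 Hz acceleration samples as lying or standing
#'
#' Applies the posture threshold to a single-axis acceleration trace recorded
#' parallel to the vertical movement of a hind leg. With the leg vertical
#' (standing) the axis reads close to -1 g; with the leg horizontal (sternal or
#' lateral recumbency) gravity no longer loads the axis and readings sit close
#' to 0 g. A sample is classified as lying when its acceleration exceeds the
#' threshold and as standing otherwise; a sample exactly at the threshold is
#' assigned to standing, the conservative choice that avoids inflating
#' recumbency.
#'
#' @param trace Data frame with columns `horse_id`, `timestamp` (seconds,
#'   strictly increasing at 1 s spacing) and `accel` (g).
#' @param threshold Posture threshold in g. Default -0.75.
#' @return A state series: data frame with `timestamp` and `state`
#'   (`"lying"`/`"standing"`), one row per input sample.
#' @export
classify_samples <- function(trace, threshold = -0.75) {
  stopifnot(is.data.frame(trace), all(c("timestamp", "accel") %in% names(trace)))
  if (nrow(trace) == 0L) {
    return(data.frame(timestamp = numeric(0), state = character(0),
                      stringsAsFactors = FALSE))
  }
  bad <- which(!is.finite(trace$accel))
  if (length(bad) > 0L) {
    stop("non-finite acceleration value at index ", bad[1L])
  }
  data.frame(
    timestamp = trace$timestamp,
    state = ifelse(trace$accel > threshold, "lying", "standing"),
    stringsAsFactors = FALSE
  )
}

#' Smooth a binary posture series by moving-median majority vote
#'
#' A moving median over a binary (lying/standing) series is a majority vote:
#' each sample is set to whichever state the majority of samples in the 15 s
#' before and 15 s after (plus, by default, the sample itself) indicate. The
#' centred 31-sample window is odd and therefore tie-free in the interior;
#' at the series edges the window is truncated (no padding) and a tied vote
#' falls back to the sample's own raw state. The pass removes brief
#' threshold crossings caused by locomotion. Idempotent on constant series.
#'
#' @param states State series as returned by [classify_samples()].
#' @param half_window Samples on each side of the centre, default 15 (a 30 s
#'   span at 1 Hz).
#' @param include_center Include the centre sample in the vote (default TRUE,
#'   giving an odd window). With FALSE the vote runs over the 30 flanking
#'   samples only and interior ties also fall back to the raw state.
#' @return A state series of the same length.
#' @export
smooth_states <- function(states, half_window = 15L, include_center = TRUE) {
  n <- nrow(states)
  if (n == 0L) return(states)
  if (n > 1L && any(diff(states$timestamp) != 1)) {
    stop("state series must be uniformly spaced at 1 s; split at gaps first")
  }
  lying <- as.integer(states$state == "lying")
  k <- as.integer(half_window)
  cs <- cumsum(c(0L, lying))
  i <- seq_len(n)
  lo <- pmax(i - k, 1L)
  hi <- pmin(i + k, n)
  cnt <- cs[hi + 1L] - cs[lo]
  size <- hi - lo + 1L
  if (!include_center) {
    cnt <- cnt - lying
    size <- size - 1L
  }
  out <- states$state
  out[2L * cnt > size] <- "lying"
  out[2L * cnt < size] <- "standing"
  # ties (possible only in truncated/even windows) keep the raw state
  data.frame(timestamp = states$timestamp, state = out, stringsAsFactors = FALSE)
}

#' Segment a smoothed state series into lying bouts
#'
#' Maximal runs of lying samples become candidate bouts; candidates shorter
#' than the minimum duration are discarded. Intervals follow the half-open
#' convention: `start` is the timestamp of the first lying sample, `end` the
#' timestamp of the last lying sample plus one second, so `duration = end -
#' start` counts one second per sample.
#'
#' @param states Smoothed state series.
#' @param min_duration Minimum bout duration in seconds, default 30.
#' @param horse_id Identifier copied into the output.
#' @return Data frame with columns `horse_id`, `start`, `end`, `duration`,
#'   sorted by start, pairwise disjoint.
#' @export
segment_bouts <- function(states, min_duration = 30, horse_id = NA_character_) {
  empty <- data.frame(horse_id = character(0), start = numeric(0),
                      end = numeric(0), duration = numeric(0),
                      stringsAsFactors = FALSE)
  n <- nrow(states)
  if (n == 0L) return(empty)
  r <- rle(states$state)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  keep <- r$values == "lying"
  if (!any(keep)) return(empty)
  start <- states$timestamp[starts_idx[keep]]
  end <- states$timestamp[ends_idx[keep]] + 1
  dur <- end - start
  ok <- dur >= min_duration
  data.frame(horse_id = rep(horse_id, sum(ok)), start = start[ok],
             end = end[ok], duration = dur[ok], stringsAsFactors = FALSE)
}

#' Remove lying bouts that occurred on pasture
#'
#' Recumbency on pasture is not part of the stable lying-behaviour record and
#' is removed. A bout is attributed to pasture when its midpoint falls inside
#' any pasture-access interval; bouts straddling an interval boundary with the
#' midpoint outside are kept. Overlapping pasture intervals are merged with a
#' warning, and a daily pasture total above 4 h draws a warning (the husbandry
#' protocol caps pasture access at 4 h per day).
#'
#' @param bouts Bout table from [segment_bouts()].
#' @param pasture Data frame with columns `start`, `end` (seconds on the same
#'   clock as the bouts). NULL or empty means no exclusion.
#' @return The bout table without pasture bouts.
#' @export
exclude_pasture <- function(bouts, pasture = NULL) {
  if (is.null(pasture) || nrow(pasture) == 0L || nrow(bouts) == 0L) return(bouts)
  stopifnot(all(c("start", "end") %in% names(pasture)))
  if (any(pasture$end <= pasture$start)) stop("pasture interval with end <= start")
  iv <- pasture[order(pasture$start), c("start", "end")]
  # merge overlaps
  merged <- iv[1, , drop = FALSE]
  overlapped <- FALSE
  if (nrow(iv) > 1L) {
    for (j in 2:nrow(iv)) {
      last <- nrow(merged)
      if (iv$start[j] < merged$end[last]) {
        overlapped <- TRUE
        merged$end[last] <- max(merged$end[last], iv$end[j])
      } else {
        merged <- rbind(merged, iv[j, ])
      }
    }
  }
  if (overlapped) warning("overlapping pasture intervals merged")
  daily <- tapply(merged$end - merged$start, floor(merged$start / 86400), sum)
  if (any(daily > 4 * 3600)) warning("pasture access exceeds 4 h on some days")
  mid <- bouts$start + (bouts$end - bouts$start) / 2
  on_pasture <- vapply(mid, function(m) any(merged$start <= m & m < merged$end),
                       logical(1))
  bouts[!on_pasture, , drop = FALSE]
}

#' Detect lying bouts in a 1 Hz acceleration trace
#'
#' Full detector: threshold classification, moving-median majority smoothing,
#' run-length segmentation with a minimum-duration filter, and pasture
#' exclusion. Traces with missing seconds are handled by a gap policy: gaps of
#' at most `max_gap` seconds are filled by carrying the last observation
#' forward, longer gaps split the trace into segments that are smoothed and
#' segmented independently (no bout can span a long gap).
#'
#' @param trace Acceleration trace (`horse_id`, `timestamp`, `accel`).
#' @param threshold Posture threshold in g.
#' @param half_window Smoothing half-window in seconds.
#' @param min_duration Minimum bout duration in seconds.
#' @param pasture Optional pasture-access intervals, see [exclude_pasture()].
#' @param max_gap Longest gap (s) bridged by last-observation-carried-forward.
#' @param include_center Passed to [smooth_states()].
#' @return Bout table (`horse_id`, `start`, `end`, `duration`).
#' @export
detect_bouts <- function(trace, threshold = -0.75, half_window = 15L,
                         min_duration = 30, pasture = NULL, max_gap = 5,
                         include_center = TRUE) {
  stopifnot(is.data.frame(trace),
            all(c("horse_id", "timestamp", "accel") %in% names(trace)))
  horse <- if (nrow(trace) > 0L) as.character(trace$horse_id[1L]) else NA_character_
  if (nrow(trace) == 0L) {
    return(segment_bouts(classify_samples(trace), min_duration, horse))
  }
  if (is.unsorted(trace$timestamp, strictly = TRUE)) {
    stop("trace timestamps must be strictly increasing")
  }
  gaps <- diff(trace$timestamp)
  seg_id <- cumsum(c(0, gaps > max_gap))
  pieces <- split(trace[, c("timestamp", "accel")], seg_id)
  out <- lapply(pieces, function(piece) {
    # fill short gaps by LOCF so the smoother sees a uniform grid
    ts_full <- seq(piece$timestamp[1L], piece$timestamp[nrow(piece)])
    idx <- findInterval(ts_full, piece$timestamp)
    filled <- data.frame(timestamp = ts_full, accel = piece$accel[idx])
    st <- classify_samples(filled, threshold)
    st <- smooth_states(st, half_window, include_center)
    segment_bouts(st, min_duration, horse)
  })
  bouts <- do.call(rbind, out)
  rownames(bouts) <- NULL
  exclude_pasture(bouts, pasture)
}
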