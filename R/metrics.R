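# Per-horse per-24 h outcome metrics by lying surface.

SURFACES <- c("litter", "rubber_mats", "firm_ground")

#' Attach video annotations to detected bouts
#'
#' Joins an annotation table to a bout table on (`horse_id`, `start`). Because
#' detected bout starts can differ from the annotated (video) starts by a few
#' seconds, each bout is matched to the nearest annotation of the same horse
#' within `tol_s` seconds; each annotation is used at most once. Surfaces other
#' than litter or rubber mats (e.g. "outdoor run", "concrete") are mapped to
#' firm ground.
#'
#' @param bouts Bout table (`horse_id`, `start`, `end`, `duration`).
#' @param annotations Annotation table (`horse_id`, `start`, `surface`,
#'   `sternal_s`, `lateral_s`, `n_present`, `termination`).
#' @param tol_s Matching tolerance in seconds (0 = exact join).
#' @return The bout table with annotation columns appended. An unannotated
#'   bout is an error (its keys are listed); an annotation without a bout
#'   draws a warning and is ignored.
#' @export
match_annotations <- function(bouts, annotations, tol_s = 30) {
  stopifnot(all(c("horse_id", "start") %in% names(annotations)))
  ann <- annotations
  ann$surface <- ifelse(ann$surface %in% SURFACES[1:2], ann$surface, "firm_ground")
  idx <- rep(NA_integer_, nrow(bouts))
  used <- rep(FALSE, nrow(ann))
  for (i in seq_len(nrow(bouts))) {
    cand <- which(!used & ann$horse_id == bouts$horse_id[i] &
                    abs(ann$start - bouts$start[i]) <= tol_s)
    if (length(cand) > 0L) {
      j <- cand[which.min(abs(ann$start[cand] - bouts$start[i]))]
      idx[i] <- j
      used[j] <- TRUE
    }
  }
  if (anyNA(idx)) {
    miss <- bouts[is.na(idx), c("horse_id", "start")]
    stop("unannotated bouts: ",
         paste(sprintf("(%s, %s)", miss$horse_id, miss$start), collapse = " "))
  }
  if (any(!used)) {
    warning(sum(!used), " annotation(s) without a matching bout ignored")
  }
  sternal <- ann$sternal_s[idx]
  lateral <- ann$lateral_s[idx]
  tot <- sternal + lateral
  # positions are re-scaled to the detected duration (video and logger clocks
  # differ by a few seconds); the sternal+lateral = duration invariant holds
  scale <- ifelse(tot > 0, bouts$duration / tot, 1)
  out <- bouts
  out$surface <- ann$surface[idx]
  out$sternal_s <- sternal * scale
  out$lateral_s <- lateral * scale
  out$n_present <- ann$n_present[idx]
  out$terminated <- ann$termination[idx]
  out
}

#' Tag bouts with their 24 h day and split boundary-spanning bouts
#'
#' Days are consecutive 24 h blocks from `recording_start`. A bout spanning a
#' day boundary is split there; each fragment of at least 1 s is retained with
#' its duration credited to its own day (so per-day durations stay additive
#' over the window), and position durations are split proportionally.
#'
#' @param bouts Bout table; may carry annotation columns.
#' @param recording_start Start of the recording window (seconds).
#' @param recording_hours Window length, default 72.
#' @return The bout table with a `day_index` column, boundary bouts split.
#' @export
split_days <- function(bouts, recording_start = 0, recording_hours = 72) {
  n_days <- ceiling(recording_hours / 24)
  w_end <- recording_start + recording_hours * 3600
  if (nrow(bouts) == 0L) {
    out <- bouts
    out$day_index <- integer(0)
    return(out)
  }
  if (any(bouts$start < recording_start) || any(bouts$end > w_end)) {
    stop("bout outside the ", recording_hours, " h recording window")
  }
  pieces <- list()
  for (i in seq_len(nrow(bouts))) {
    s <- bouts$start[i]; e <- bouts$end[i]
    d1 <- floor((s - recording_start) / 86400) + 1
    d2 <- floor((e - recording_start - 1e-9) / 86400) + 1
    for (d in d1:d2) {
      lo <- max(s, recording_start + (d - 1) * 86400)
      hi <- min(e, recording_start + d * 86400)
      if (hi - lo < 1) next
      frag <- bouts[i, , drop = FALSE]
      frac <- (hi - lo) / (e - s)
      frag$start <- lo; frag$end <- hi; frag$duration <- hi - lo
      if ("sternal_s" %in% names(frag)) frag$sternal_s <- frag$sternal_s * frac
      if ("lateral_s" %in% names(frag)) frag$lateral_s <- frag$lateral_s * frac
      frag$day_index <- as.integer(d)
      pieces[[length(pieces) + 1L]] <- frag
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (max(out$day_index) > n_days) stop("bout beyond the final recording day")
  out
}

#' Outcome metrics for one horse-day
#'
#' Computes the per-24 h outcome vector from one horse-day's annotated bouts:
#' bout counts and recumbency durations (total and per surface), the
#' REM-deficiency flag (total recumbency below 30 min), the proportion of
#' lateral recumbency in total recumbency, the mean proportion of other group
#' members present at lie-down, and the proportion of forcedly terminated
#' bouts. Proportions with an empty denominator are NA (missing), not zero.
#'
#' @param day_bouts Annotated bouts of one horse-day (possibly 0 rows).
#' @param group_size Number of horses in the group.
#' @param horse_id,day_index Identifiers for the output row.
#' @param include_focal If TRUE the presence denominator is `group_size`
#'   instead of `group_size - 1` (the default excludes the focal horse so a
#'   fully attended lie-down scores 100%).
#' @return One-row data frame of class `horse_day_metrics` fields.
#' @export
compute_day_metrics <- function(day_bouts, group_size,
                                horse_id = NA_character_, day_index = NA_integer_,
                                include_focal = FALSE) {
  n_by <- function(surf) sum(day_bouts$surface == surf)
  dur_by <- function(surf) sum(day_bouts$duration[day_bouts$surface == surf]) / 60
  nb <- nrow(day_bouts)
  dur_tot <- sum(day_bouts$duration) / 60
  denom <- if (include_focal) group_size else group_size - 1L
  data.frame(
    horse_id = horse_id, day_index = day_index,
    n_bouts_total = nb,
    n_bouts_litter = n_by("litter"),
    n_bouts_rubber = n_by("rubber_mats"),
    n_bouts_firm = n_by("firm_ground"),
    dur_min_total = dur_tot,
    dur_min_litter = dur_by("litter"),
    dur_min_rubber = dur_by("rubber_mats"),
    dur_min_firm = dur_by("firm_ground"),
    under_30min = dur_tot < 30,
    pct_lateral = if (dur_tot > 0) 100 * sum(day_bouts$lateral_s) / (dur_tot * 60)
                  else NA_real_,
    pct_present = if (nb > 0) 100 * mean(day_bouts$n_present / denom)
                  else NA_real_,
    pct_forced = if (nb > 0) 100 * mean(day_bouts$terminated == "forced")
                 else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Per-horse per-24 h metrics for a set of annotated bouts
#'
#' Splits bouts into 24 h days and computes [compute_day_metrics()] for every
#' horse-day in the window, including empty ones (a horse with no bouts on a
#' day gets zero counts, zero duration and the under-30-min flag set).
#'
#' @param bouts Annotated bout table (see [match_annotations()]; schedules
#'   from [simulate_schedule()] already carry the columns).
#' @param group_size Group size used for the presence denominator.
#' @param horse_ids All horses that were recorded (so empty days appear);
#'   defaults to the horses present in `bouts`.
#' @param recording_start,recording_hours Recording window.
#' @param include_focal See [compute_day_metrics()].
#' @return Tidy data frame, one row per horse-day.
#' @export
horse_day_metrics <- function(bouts, group_size, horse_ids = NULL,
                              recording_start = 0, recording_hours = 72,
                              include_focal = FALSE) {
  need <- c("horse_id", "start", "end", "duration", "surface", "sternal_s",
            "lateral_s", "n_present", "terminated")
  miss <- setdiff(need, names(bouts))
  if (length(miss) > 0L) stop("bouts lack annotation columns: ",
                              paste(miss, collapse = ", "))
  if (is.null(horse_ids)) horse_ids <- sort(unique(bouts$horse_id))
  tagged <- split_days(bouts, recording_start, recording_hours)
  n_days <- ceiling(recording_hours / 24)
  rows <- vector("list", length(horse_ids) * n_days)
  k <- 0L
  for (h in horse_ids) {
    for (d in seq_len(n_days)) {
      db <- tagged[tagged$horse_id == h & tagged$day_index == d, , drop = FALSE]
      k <- k + 1L
      rows[[k]] <- compute_day_metrics(db, group_size, h, d, include_focal)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag horses recumbent for less than 30 min over the whole 72 h
#'
#' @param metrics Metrics table for one horse and treatment (three day rows).
#' @return TRUE iff the summed total recumbency over the window is below
#'   30 min.
#' @export
flag_under_72h <- function(metrics) {
  if (nrow(metrics) < 1L) stop("no day rows")
  sum(metrics$dur_min_total) < 30
}

#' Remove excluded horse/treatment combinations
#'
#' Drops every day row of each listed (horse, treatment) combination and
#' reports the exclusion count as a percentage of all horse-by-treatment
#' combinations in the input.
#'
#' @param metrics Metrics table with `horse_id` and `treatment` columns.
#' @param exclusions Data frame with `horse_id`, `treatment` and optionally
#'   `reason`.
#' @return List with `data` (filtered metrics) and `report` (`n_excluded`,
#'   `n_combinations`, `pct`).
#' @export
apply_exclusions <- function(metrics, exclusions) {
  n_comb <- length(unique(metrics$horse_id)) * length(unique(metrics$treatment))
  if (is.null(exclusions) || nrow(exclusions) == 0L) {
    return(list(data = metrics,
                report = list(n_excluded = 0L, n_combinations = n_comb, pct = 0)))
  }
  key <- paste(metrics$horse_id, metrics$treatment)
  ex_key <- unique(paste(exclusions$horse_id, exclusions$treatment))
  keep <- !(key %in% ex_key)
  list(
    data = metrics[keep, , drop = FALSE],
    report = list(n_excluded = length(ex_key), n_combinations = n_comb,
                  pct = 100 * length(ex_key) / n_comb)
  )
}

#' Exclusion percentage for a study design
#'
#' @param n_excluded Excluded horse/treatment combinations.
#' @param n_horses,n_treatments Design size.
#' @return Percentage of combinations excluded.
#' @export
exclusion_report <- function(n_excluded, n_horses, n_treatments) {
  100 * n_excluded / (n_horses * n_treatments)
}
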