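# Independent reference implementations used as oracles. They share no code
# with the package: explicit single-pass loops instead of vectorised passes.

# majority smoothing by full double loop (small n only)
oracle_majority <- function(states, k = 15L, include_center = TRUE) {
  n <- length(states)
  out <- character(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - k)
    hi <- min(n, i + k)
    nl <- 0L
    ns <- 0L
    for (j in lo:hi) {
      if (!include_center && j == i) next
      if (states[j] == "lying") nl <- nl + 1L else ns <- ns + 1L
    }
    out[i] <- if (nl > ns) "lying" else if (ns > nl) "standing" else states[i]
  }
  out
}

# single-pass brute-force detector: per-sample loops, window counted by a
# slice sum, run scanning by an explicit while loop. Timestamps 0-based.
oracle_detect <- function(accel, threshold = -0.75, k = 15L, min_dur = 30L) {
  n <- length(accel)
  raw <- logical(n) # TRUE = lying
  for (i in seq_len(n)) raw[i] <- accel[i] > threshold
  sm <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - k)
    hi <- min(n, i + k)
    nl <- sum(raw[lo:hi])
    ns <- (hi - lo + 1L) - nl
    sm[i] <- if (nl > ns) TRUE else if (ns > nl) FALSE else raw[i]
  }
  starts <- numeric(0)
  ends <- numeric(0)
  i <- 1L
  while (i <= n) {
    if (sm[i]) {
      j <- i
      while (j < n && sm[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_dur) {
        starts <- c(starts, i - 1L)
        ends <- c(ends, j) # last lying ts (j-1) + 1 s, half-open
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, end = ends, duration = ends - starts)
}

# adversarial random trace: alternating level segments with heavy noise that
# crosses the threshold, plus occasional samples exactly at the threshold
random_trace <- function(n = 7200L, horse_id = "X") {
  accel <- numeric(0)
  while (length(accel) < n) {
    len <- sample(1:300, 1L)
    level <- sample(c(-1, 0), 1L)
    accel <- c(accel, rnorm(len, level, 0.2))
  }
  accel <- accel[seq_len(n)]
  ties <- sample.int(n, 5L)
  accel[ties] <- -0.75
  data.frame(horse_id = horse_id, timestamp = seq_len(n) - 1L, accel = accel,
             stringsAsFactors = FALSE)
}
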