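# Synthetic-data generator: ground-truth behaviour schedules, acceleration
# traces, bout annotations, pasture logs and dyadic feeding-test outcomes with
# the statistical structure the analysis assumes.

# deterministic sub-stream seeds below 2^31
derive_seed <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) %% 100003) * 20011 + offset %% 20000)
}

#' Latent composition of one simulated group
#'
#' Draws, deterministically from the master seed, each horse's latent
#' dominance score (uniform), its rank class (low/high split at the group
#' median, mirroring the dichotomised rank used in the analysis), and
#' persistent horse- and group-level recumbency baselines. The same
#' `(config, group_id)` always yields the same horses, so schedules for
#' different treatments of one group share ranks and baselines.
#'
#' @param config A [sim_config()].
#' @param group_id Group index in `1:n_groups`.
#' @return Data frame: `horse_id`, `group`, `rank_score`, `rank_class`,
#'   `horse_effect`, `group_effect`.
#' @export
simulate_group <- function(config, group_id) {
  validate_sim_config(config)
  n <- config$group_sizes[[group_id]]
  set.seed(derive_seed(config$seed, group_id * 53L))
  group_effect <- stats::rnorm(1, 0, config$group_effect_sd)
  score <- stats::runif(n)
  horse_effect <- stats::rnorm(n, 0, config$horse_effect_sd)
  data.frame(
    horse_id = sprintf("G%d_H%d", group_id, seq_len(n)),
    group = sprintf("G%d", group_id),
    rank_score = score,
    rank_class = ifelse(score <= stats::median(score), "low", "high"),
    horse_effect = horse_effect,
    group_effect = group_effect,
    stringsAsFactors = FALSE
  )
}

place_bout <- function(dur_min, day0_min, config, occupied, avoid, tries = 100L) {
  # one start time (minutes from recording start) in the day/night mixture,
  # non-overlapping (60 s spacing) with already placed bouts, within the day
  for (t in seq_len(tries)) {
    u <- if (stats::runif(1) < config$dark_period_weight) {
      stats::runif(1, 0, 6 * 60)
    } else {
      stats::runif(1, 6 * 60, 24 * 60)
    }
    if (u + dur_min > 24 * 60) next
    s <- day0_min + u
    e <- s + dur_min
    clash <- FALSE
    if (nrow(occupied) > 0L) {
      clash <- any(s < occupied$end + 1 & e > occupied$start - 1)
    }
    if (!clash && !is.null(avoid) && nrow(avoid) > 0L) {
      clash <- any(s * 60 < avoid$end & e * 60 > avoid$start)
    }
    if (!clash) return(c(s, e))
  }
  NULL
}

#' Simulate ground-truth lying schedules for one group under one treatment
#'
#' Per horse and 24 h day, the number of bouts is Poisson with the configured
#' rate and bout durations are gamma (shape 2) truncated below at
#' `bout_min_s`, rescaled so that the expected total recumbency equals
#' `bout_rate_per_24h * bout_duration_mean` plus `treatment_effect` minutes per
#' unit treatment ratio, plus `rank_interaction` extra minutes per unit ratio
#' for low-ranking horses, plus the horse and group baselines. Bout starts
#' follow a day/night mixture (weight `dark_period_weight` on 00:00-06:00,
#' recording assumed to start at midnight), are non-overlapping with at least
#' 60 s spacing, and lie fully within their day. Surfaces depend on the
#' treatment (litter strongly preferred where present; only rubber mats and
#' firm ground at ratio 0). Forced terminations are more likely for
#' low-ranking horses.
#'
#' @param config A [sim_config()].
#' @param group_id Group index.
#' @param treatment Treatment label ("T0", "T0.5", ...) or numeric ratio.
#' @param avoid Optional data frame of intervals (`start`, `end`, seconds) in
#'   which no bout may be placed, e.g. a pasture log from
#'   [simulate_pasture_log()].
#' @return List with `bouts` (one row per true bout: `horse_id`, `start`,
#'   `end`, `duration` in seconds, `day_index`, `surface`, `sternal_s`,
#'   `lateral_s`, `n_present`, `terminated`) and `horses` (see
#'   [simulate_group()]).
#' @export
simulate_schedule <- function(config, group_id, treatment = "T1", avoid = NULL) {
  horses <- simulate_group(config, group_id)
  ratio <- if (is.numeric(treatment)) treatment else treatment_ratio(treatment)
  n_days <- floor(config$recording_hours / 24)
  group_size <- nrow(horses)
  set.seed(derive_seed(config$seed, group_id * 53L + round(ratio * 10) + 1L))

  acc <- list(horse_id = character(0), start = numeric(0), end = numeric(0),
              day_index = integer(0), surface = character(0),
              lat_share = numeric(0), n_present = integer(0),
              terminated = character(0))
  for (h in seq_len(group_size)) {
    low <- horses$rank_class[h] == "low"
    target <- config$bout_rate_per_24h * config$bout_duration_mean +
      config$treatment_effect * ratio +
      (if (low) config$rank_interaction * ratio else 0) +
      horses$horse_effect[h] + horses$group_effect[h]
    target <- max(target, 5)
    mean_dur <- target / config$bout_rate_per_24h
    p_forced <- if (low) config$forced_termination_prob_low else
      config$forced_termination_prob_high
    for (d in seq_len(n_days)) {
      nb <- stats::rpois(1, config$bout_rate_per_24h)
      if (nb == 0L) next
      dur <- stats::rgamma(nb, shape = 2, scale = mean_dur / 2)
      min_min <- config$bout_min_s / 60
      for (it in 1:50) {
        short <- dur < min_min
        if (!any(short)) break
        dur[short] <- stats::rgamma(sum(short), shape = 2, scale = mean_dur / 2)
      }
      dur[dur < min_min] <- min_min
      occupied <- data.frame(start = numeric(0), end = numeric(0))
      for (b in seq_len(nb)) {
        se <- place_bout(dur[b], (d - 1L) * 24 * 60, config, occupied, avoid)
        if (is.null(se)) next
        occupied <- rbind(occupied, data.frame(start = se[1], end = se[2]))
        acc$horse_id <- c(acc$horse_id, horses$horse_id[h])
        acc$start <- c(acc$start, se[1] * 60)
        acc$end <- c(acc$end, se[2] * 60)
        acc$day_index <- c(acc$day_index, d)
        acc$surface <- c(acc$surface, draw_surface(ratio))
        acc$lat_share <- c(acc$lat_share,
                           min(stats::rbeta(1, 2 * config$lateral_fraction,
                                            2 * (1 - config$lateral_fraction)), 1))
        acc$n_present <- c(acc$n_present, stats::rbinom(1, group_size - 1L, 0.55))
        acc$terminated <- c(acc$terminated,
                            if (stats::runif(1) < p_forced) "forced" else "self")
      }
    }
  }
  bouts <- data.frame(
    horse_id = acc$horse_id, start = acc$start, end = acc$end,
    duration = acc$end - acc$start, day_index = acc$day_index,
    surface = acc$surface,
    sternal_s = (acc$end - acc$start) * (1 - acc$lat_share),
    lateral_s = (acc$end - acc$start) * acc$lat_share,
    n_present = acc$n_present, terminated = acc$terminated,
    stringsAsFactors = FALSE
  )
  bouts <- bouts[order(bouts$horse_id, bouts$start), , drop = FALSE]
  rownames(bouts) <- NULL
  list(bouts = bouts, horses = horses)
}

draw_surface <- function(ratio) {
  if (ratio == 0) {
    sample(c("rubber_mats", "firm_ground"), 1L, prob = c(0.9, 0.1))
  } else if (ratio >= 1.5) {
    sample(c("litter", "firm_ground"), 1L, prob = c(0.95, 0.05))
  } else {
    sample(c("litter", "rubber_mats", "firm_ground"), 1L,
           prob = c(0.9, 0.08, 0.02))
  }
}

#' Render a 1 Hz acceleration trace from a bout schedule
#'
#' Inverts the logger physics: samples inside lying bouts are drawn around
#' `lying_level` (leg horizontal, no gravity on the axis), samples outside
#' around `standing_level`, with intermittent locomotion bursts modelled as a
#' bounded 4 s-period oscillation of amplitude `locomotion_amplitude` that
#' crosses the -0.75 g threshold only for isolated samples, so the detector's
#' smoothing pass (not chance) removes them. Bursts are kept clear of a 20 s
#' guard zone around each bout boundary: a crossing adjacent to a bout sits
#' in a majority-lying smoothing window and could not be removed, which would
#' break the generator's contract that locomotion never masquerades as
#' recumbency. Gaussian sensor noise `noise_sd` is added throughout.
#'
#' @param bouts Bout schedule for one horse (`start`, `end` in seconds);
#'   overlapping bouts are an error.
#' @param config A [sim_config()].
#' @param horse_id Identifier for the output trace.
#' @param seed Optional integer; defaults to a stream derived from the config
#'   seed and the horse id.
#' @return Acceleration trace: `horse_id`, `timestamp` (0-based seconds),
#'   `accel` (g); one sample per second over the full recording window.
#' @export
render_trace <- function(bouts, config, horse_id = "H1", seed = NULL) {
  validate_sim_config(config)
  n <- as.integer(round(config$recording_hours * 3600 * config$sample_rate))
  if (nrow(bouts) > 0L) {
    b <- bouts[order(bouts$start), , drop = FALSE]
    if (any(b$start[-1L] < b$end[-nrow(b)])) stop("overlapping bouts in schedule")
    if (any(b$start < 0) || any(b$end > n)) stop("bout outside recording window")
  } else b <- bouts
  if (is.null(seed)) {
    seed <- derive_seed(config$seed, sum(utf8ToInt(as.character(horse_id))) %% 19997L)
  }
  set.seed(seed)
  accel <- rep(config$standing_level, n)
  lying <- rep(FALSE, n)
  guard <- rep(FALSE, n) # lying plus a margin wider than the smoothing window
  for (i in seq_len(nrow(b))) {
    i1 <- max(0L, as.integer(ceiling(b$start[i])))
    i2 <- min(n - 1L, as.integer(ceiling(b$end[i])) - 1L)
    if (i2 >= i1) {
      lying[(i1 + 1L):(i2 + 1L)] <- TRUE
      guard[max(1L, i1 - 19L):min(n, i2 + 21L)] <- TRUE
    }
  }
  accel[lying] <- config$lying_level
  if (config$locomotion_amplitude > 0) {
    n_bursts <- stats::rpois(1, 20 * n / 3600)
    if (n_bursts > 0L) {
      starts <- sample.int(n, n_bursts, replace = TRUE)
      lens <- sample(10:40, n_bursts, replace = TRUE)
      for (j in seq_len(n_bursts)) {
        idx <- starts[j]:min(n, starts[j] + lens[j] - 1L)
        idx <- idx[!guard[idx]]
        if (length(idx) > 0L) {
          accel[idx] <- accel[idx] + config$locomotion_amplitude *
            sin(2 * pi * (idx - starts[j]) / 4)
        }
      }
    }
  }
  if (config$noise_sd > 0) accel <- accel + stats::rnorm(n, 0, config$noise_sd)
  data.frame(horse_id = horse_id, timestamp = seq_len(n) - 1L, accel = accel,
             stringsAsFactors = FALSE)
}

#' Video-style annotation table for a bout schedule
#'
#' Carries every ground-truth bout attribute into the layout of a video
#' annotation table keyed by (`horse_id`, `start`). Forced terminations get a
#' cause category (cycled deterministically over displacement/threat/
#' aggression).
#'
#' @param bouts Bout schedule from [simulate_schedule()].
#' @return Annotation data frame.
#' @export
render_annotations <- function(bouts) {
  causes <- c("displacement", "threat", "aggression")
  forced <- bouts$terminated == "forced"
  cause <- rep(NA_character_, nrow(bouts))
  if (any(forced)) cause[forced] <- causes[(seq_len(sum(forced)) - 1L) %% 3L + 1L]
  data.frame(
    horse_id = bouts$horse_id, start = bouts$start,
    surface = bouts$surface, sternal_s = bouts$sternal_s,
    lateral_s = bouts$lateral_s, n_present = bouts$n_present,
    termination = bouts$terminated, cause = cause,
    stringsAsFactors = FALSE
  )
}

#' Simulate paired feeding-test outcomes for one group
#'
#' Every unordered pair of group members meets once; the horse with the higher
#' latent dominance score wins, except that each outcome flips with
#' probability `upset_prob`.
#'
#' @param horses Data frame with `horse_id` and `rank_score` (see
#'   [simulate_group()]).
#' @param upset_prob Probability that an encounter outcome contradicts the
#'   latent order.
#' @param seed Optional integer seed.
#' @return Data frame `horse_a`, `horse_b`, `winner` ("a"/"b").
#' @export
simulate_dyads <- function(horses, upset_prob = 0, seed = NULL) {
  stopifnot(upset_prob >= 0, upset_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(horses)
  pairs <- utils::combn(n, 2)
  a_wins <- horses$rank_score[pairs[1, ]] > horses$rank_score[pairs[2, ]]
  if (upset_prob > 0) {
    flip <- stats::runif(ncol(pairs)) < upset_prob
    a_wins <- xor(a_wins, flip)
  }
  data.frame(
    horse_a = horses$horse_id[pairs[1, ]],
    horse_b = horses$horse_id[pairs[2, ]],
    winner = ifelse(a_wins, "a", "b"),
    stringsAsFactors = FALSE
  )
}

#' Daily pasture-access log
#'
#' One access interval per recording day, by default 2 h starting at 10:00
#' (the husbandry protocol caps pasture at 4 h per day).
#'
#' @param config A [sim_config()] (for the number of recording days).
#' @param start_hour Daily start of access, hours after midnight.
#' @param duration_h Access duration in hours.
#' @return Data frame `date` (day index), `start`, `end` (seconds from
#'   recording start).
#' @export
simulate_pasture_log <- function(config, start_hour = 10, duration_h = 2) {
  if (duration_h > 4) warning("pasture access exceeds the 4 h daily maximum")
  days <- seq_len(floor(config$recording_hours / 24))
  data.frame(
    date = days,
    start = (days - 1) * 86400 + start_hour * 3600,
    end = (days - 1) * 86400 + (start_hour + duration_h) * 3600
  )
}

#' Simulate the full study design
#'
#' All groups under all treatments: ground-truth schedules, annotation tables,
#' latent group compositions and dyadic feeding-test outcomes. Acceleration
#' traces are rendered on demand with [render_trace()] rather than stored.
#'
#' @param config A [sim_config()].
#' @param upset_prob Upset probability for the feeding tests.
#' @return List with `horses`, `bouts` (all groups and treatments, with
#'   `treatment` column), `annotations`, `dyads` (with `group` column).
#' @export
simulate_study <- function(config, upset_prob = 0.1) {
  validate_sim_config(config)
  horses <- list(); bouts <- list(); ann <- list(); dyads <- list()
  for (g in seq_len(config$n_groups)) {
    hg <- simulate_group(config, g)
    horses[[g]] <- hg
    dg <- simulate_dyads(hg, upset_prob, seed = derive_seed(config$seed, g * 53L + 47L))
    dg$group <- hg$group[1]
    dyads[[g]] <- dg
    for (r in config$treatment_ratios) {
      sch <- simulate_schedule(config, g, r)
      if (nrow(sch$bouts) > 0L) {
        b <- sch$bouts
        b$treatment <- treatment_label(r)
        b$group <- hg$group[1]
        bouts[[length(bouts) + 1L]] <- b
        a <- render_annotations(sch$bouts)
        a$treatment <- treatment_label(r)
        ann[[length(ann) + 1L]] <- a
      }
    }
  }
  list(horses = do.call(rbind, horses),
       bouts = do.call(rbind, bouts),
       annotations = do.call(rbind, ann),
       dyads = do.call(rbind, dyads))
}

#' Simulate a horse-day metrics table directly
#'
#' Aggregate twin of [simulate_schedule()]: draws the same per-horse-day bout
#' process (Poisson bout count, truncated-gamma durations scaled to the
#' treatment/rank/baseline target, surface preferences, lateral shares,
#' presence counts and rank-dependent forced terminations) but skips start-time
#' placement and trace rendering, returning the per-24 h outcome table the
#' mixed-model stage consumes. Used for simulation studies of the inference
#' design where thousands of replicate tables are needed.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer overriding the config-derived stream.
#' @return Data frame with one row per horse x treatment x day: identifiers
#'   (`horse_id`, `group`, `treatment`, `ratio`, `rank_class`, `day_index`)
#'   and the outcome columns of [compute_day_metrics()].
#' @export
simulate_metrics <- function(config, seed = NULL) {
  validate_sim_config(config)
  n_days <- floor(config$recording_hours / 24)
  horses <- do.call(rbind, lapply(seq_len(config$n_groups),
                                  function(g) simulate_group(config, g)))
  gs <- rep(config$group_sizes, config$group_sizes)
  set.seed(if (is.null(seed)) derive_seed(config$seed, 40009L) else seed)

  grid <- expand.grid(h = seq_len(nrow(horses)),
                      ratio = config$treatment_ratios,
                      day_index = seq_len(n_days), KEEP.OUT.ATTRS = FALSE)
  low <- horses$rank_class[grid$h] == "low"
  target <- config$bout_rate_per_24h * config$bout_duration_mean +
    config$treatment_effect * grid$ratio +
    ifelse(low, config$rank_interaction * grid$ratio, 0) +
    horses$horse_effect[grid$h] + horses$group_effect[grid$h]
  target <- pmax(target, 5)
  mean_dur <- target / config$bout_rate_per_24h

  nb <- stats::rpois(nrow(grid), config$bout_rate_per_24h)
  row_of <- rep(seq_len(nrow(grid)), nb)
  m <- length(row_of)
  scale <- mean_dur[row_of] / 2
  dur <- stats::rgamma(m, shape = 2, scale = scale)
  min_min <- config$bout_min_s / 60
  for (it in 1:50) {
    short <- dur < min_min
    if (!any(short)) break
    dur[short] <- stats::rgamma(sum(short), shape = 2, scale = scale[short])
  }
  dur[dur < min_min] <- min_min

  ratio_b <- grid$ratio[row_of]
  u <- stats::runif(m)
  surface <- character(m)
  z <- ratio_b == 0
  surface[z] <- ifelse(u[z] < 0.9, "rubber_mats", "firm_ground")
  f <- ratio_b >= 1.5
  surface[f] <- ifelse(u[f] < 0.95, "litter", "firm_ground")
  mid <- !z & !f
  surface[mid] <- ifelse(u[mid] < 0.9, "litter",
                         ifelse(u[mid] < 0.98, "rubber_mats", "firm_ground"))

  lat_share <- pmin(stats::rbeta(m, 2 * config$lateral_fraction,
                                 2 * (1 - config$lateral_fraction)), 1)
  p_forced <- ifelse(low[row_of], config$forced_termination_prob_low,
                     config$forced_termination_prob_high)
  forced <- stats::rbinom(m, 1L, p_forced)
  present <- stats::rbinom(m, gs[grid$h][row_of] - 1L, 0.55)

  agg <- function(x, subset = NULL) {
    v <- numeric(nrow(grid))
    xx <- if (is.null(subset)) x else x * subset
    s <- rowsum(xx, row_of)
    v[as.integer(rownames(s))] <- s[, 1L]
    v
  }
  dur_tot <- agg(dur)
  out <- data.frame(
    horse_id = horses$horse_id[grid$h],
    group = horses$group[grid$h],
    treatment = treatment_label(grid$ratio),
    ratio = grid$ratio,
    rank_class = horses$rank_class[grid$h],
    day_index = grid$day_index,
    n_bouts_total = nb,
    n_bouts_litter = agg(rep(1, m), surface == "litter"),
    n_bouts_rubber = agg(rep(1, m), surface == "rubber_mats"),
    n_bouts_firm = agg(rep(1, m), surface == "firm_ground"),
    dur_min_total = dur_tot,
    dur_min_litter = agg(dur, surface == "litter"),
    dur_min_rubber = agg(dur, surface == "rubber_mats"),
    dur_min_firm = agg(dur, surface == "firm_ground"),
    under_30min = dur_tot < 30,
    pct_lateral = ifelse(dur_tot > 0, 100 * agg(dur * lat_share) / dur_tot, NA),
    pct_present = ifelse(nb > 0,
                         100 * agg(present / pmax(gs[grid$h][row_of] - 1L, 1L)) / nb,
                         NA),
    pct_forced = ifelse(nb > 0, 100 * agg(forced) / nb, NA),
    stringsAsFactors = FALSE
  )
  out[order(out$group, out$horse_id, out$ratio, out$day_index), ]
}
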