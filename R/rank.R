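# Dominance rank from paired feeding encounters.

#' Schedule a round-robin of paired feeding encounters
#'
#' Orders all n(n-1)/2 dyads of a group randomly, under the welfare constraint
#' that no individual takes part in more than two consecutive encounters (a
#' horse gets a break after two tests). The order is seeded and deterministic.
#'
#' @param members Character vector of horse identifiers (length >= 2).
#' @param seed Integer seed.
#' @param max_tries Resampling attempts before giving up.
#' @return Data frame `horse_a`, `horse_b` in encounter order.
#' @export
schedule_encounters <- function(members, seed = 1L, max_tries = 10000L) {
  n <- length(members)
  stopifnot(n >= 2L)
  pairs <- utils::combn(members, 2)
  n_dyads <- ncol(pairs)
  if (n_dyads == 1L) {
    return(data.frame(horse_a = pairs[1, 1], horse_b = pairs[2, 1],
                      stringsAsFactors = FALSE))
  }
  set.seed(as.integer(seed))
  for (t in seq_len(max_tries)) {
    ord <- sample.int(n_dyads)
    if (valid_encounter_order(pairs[, ord, drop = FALSE])) {
      return(data.frame(horse_a = pairs[1, ord], horse_b = pairs[2, ord],
                        stringsAsFactors = FALSE))
    }
  }
  stop("no encounter order satisfying the two-consecutive rule found")
}

# TRUE iff no horse appears in three consecutive dyads
valid_encounter_order <- function(pairs) {
  m <- ncol(pairs)
  if (m < 3L) return(TRUE)
  for (i in 1:(m - 2L)) {
    trio <- c(pairs[, i], pairs[, i + 1L], pairs[, i + 2L])
    if (any(table(trio) >= 3L)) return(FALSE)
  }
  TRUE
}

#' Dominance ratio and rank class from round-robin outcomes
#'
#' For each horse, the ratio of dominated dyads to its total number of dyads
#' (group size minus one). Horses with a ratio in 0-0.5 are classed
#' low-ranking, above 0.5 high-ranking; a ratio of exactly 0.5 is low-ranking.
#'
#' @param dyads Data frame `horse_a`, `horse_b`, `winner` ("a"/"b"); every
#'   unordered pair of the group exactly once.
#' @return Data frame `horse_id`, `n_dominated`, `ratio`, `rank_class`,
#'   sorted by decreasing ratio.
#' @export
dominance_ratio <- function(dyads) {
  stopifnot(all(c("horse_a", "horse_b", "winner") %in% names(dyads)))
  if (!all(dyads$winner %in% c("a", "b"))) stop("winner must be 'a' or 'b'")
  horses <- sort(unique(c(dyads$horse_a, dyads$horse_b)))
  n <- length(horses)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  seen <- key(dyads$horse_a, dyads$horse_b)
  dup <- seen[duplicated(seen)]
  if (length(dup) > 0L) {
    stop("duplicated dyad: ", gsub("\r", " vs ", dup[1L]))
  }
  all_pairs <- utils::combn(horses, 2)
  expected <- key(all_pairs[1, ], all_pairs[2, ])
  missing <- setdiff(expected, seen)
  if (length(missing) > 0L) {
    stop("missing dyad: ", gsub("\r", " vs ", missing[1L]))
  }
  winner_id <- ifelse(dyads$winner == "a", dyads$horse_a, dyads$horse_b)
  wins <- table(factor(winner_id, levels = horses))
  ratio <- as.numeric(wins) / (n - 1L)
  out <- data.frame(
    horse_id = horses,
    n_dominated = as.integer(wins),
    ratio = ratio,
    rank_class = ifelse(ratio <= 0.5, "low", "high"),
    stringsAsFactors = FALSE
  )
  out[order(-out$ratio, out$horse_id), ]
}
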