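# Littered-area dimensioning per the Swiss welfare minima (FSVO): the minimal
# littered area of a group is the sum of per-horse minima, which depend on
# withers height; treatments scale the littered share of 1.5x that minimum.

#' Minimal littered-area requirement per withers-height category
#'
#' The per-horse minimal littered areas (m\eqn{^2}) by withers-height category
#' as set by the Swiss Federal Food Safety and Veterinary Office (FSVO). The
#' category table ships as versioned package data so that legislative
#' revisions are configuration, not code.
#'
#' @param path Optional path to an alternative category table (CSV with
#'   columns `category`, `area_m2`).
#' @return Named numeric vector of areas, names are height categories in cm.
#' @export
fsvo_areas <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "fsvo_withers_areas.csv", package = "equirest")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(tab$area_m2, tab$category)
}

#' Legally required minimal littered area for a group
#'
#' Sums the per-horse minima over a group's withers-height composition.
#'
#' @param counts Numeric vector of horses per height category, in the order of
#'   [fsvo_areas()] (`<120`, `120-134`, `134-148`, `148-162`, `162-175`,
#'   `>175` cm). Named vectors are matched by name.
#' @param areas Category areas, default the FSVO table.
#' @return Minimal area in m\eqn{^2}.
#' @export
minimal_area <- function(counts, areas = fsvo_areas()) {
  if (any(counts < 0)) stop("negative category count")
  if (!is.null(names(counts)) && all(names(counts) %in% names(areas))) {
    counts <- counts[names(areas)[names(areas) %in% names(counts)]]
    return(sum(counts * areas[names(counts)]))
  }
  if (length(counts) != length(areas)) {
    stop("need one count per height category (", length(areas), ")")
  }
  sum(counts * areas)
}

# round half away from zero to one decimal (the dimensioning convention;
# base round() rounds half to even)
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Littered and rubber-mat areas for one treatment
#'
#' Treatments are ratios of the legal minimum: the littered part is
#' `ratio x minimal`, the remainder of the constant `1.5 x minimal`
#' experimental area is covered with rubber mats (T0 has no litter, T1.5 no
#' rubber). Areas are rounded half-up to 0.1 m\eqn{^2}.
#'
#' @param minimal Minimal littered area in m\eqn{^2}.
#' @param treatment One of "T0", "T0.5", "T1", "T1.5" (or a numeric ratio).
#' @return Data frame `treatment`, `littered_m2`, `rubber_m2`.
#' @export
treatment_areas <- function(minimal, treatment) {
  stopifnot(minimal >= 0)
  ratio <- if (is.numeric(treatment)) treatment else treatment_ratio(treatment)
  if (ratio < 0 || ratio > 1.5) stop("treatment ratio outside [0, 1.5]")
  data.frame(
    treatment = if (is.numeric(treatment)) treatment_label(treatment) else treatment,
    littered_m2 = round_half_up(ratio * minimal),
    rubber_m2 = round_half_up((1.5 - ratio) * minimal),
    stringsAsFactors = FALSE
  )
}

#' Littered-area table for a set of groups
#'
#' Computes, for every group composition, the minimal area and the littered
#' dimensions under each treatment.
#'
#' @param groups Data frame with a `group` column and one column per
#'   withers-height category (`cat1` lowest to `cat6` highest, or the category
#'   names of [fsvo_areas()]).
#' @param treatments Treatment labels.
#' @return Data frame `group`, `minimal_m2`, then one littered-area column per
#'   treatment.
#' @export
littered_area_table <- function(groups,
                                treatments = c("T0", "T0.5", "T1", "T1.5")) {
  areas <- fsvo_areas()
  cat_cols <- intersect(c(paste0("cat", 1:6), names(areas)), names(groups))
  if (length(cat_cols) != length(areas)) {
    stop("groups must have one column per height category")
  }
  out <- data.frame(group = groups$group,
                    minimal_m2 = apply(groups[, cat_cols], 1,
                                       function(cc) minimal_area(as.numeric(cc), areas)))
  for (tr in treatments) {
    out[[tr]] <- vapply(out$minimal_m2,
                        function(m) treatment_areas(m, tr)$littered_m2, numeric(1))
  }
  out
}

#' Withers-height compositions of the study groups
#'
#' The eight group compositions (horses per height category) used in the
#' space-allowance experiment, shipped as package data.
#'
#' @return Data frame `farm`, `group`, `cat1`..`cat6`.
#' @export
study_groups <- function() {
  utils::read.csv(system.file("extdata", "study_groups.csv", package = "equirest"),
                  stringsAsFactors = FALSE)
}

#' Littered-area dimensions as published for the study groups
#'
#' The per-treatment littered dimensions reported for the eight study groups,
#' for validating [littered_area_table()] against the published table. Note
#' the published group-8/T0.5 cell reads 10.2 m2 where half-up rounding of
#' 20.5 x 0.5 = 10.25 gives 10.3 m2; this single cell is inconsistent with
#' the table's seven other half-cases and is treated as a typographical
#' anomaly.
#'
#' @return Data frame `group`, `T0`, `T0.5`, `T1`, `T1.5`.
#' @export
study_littered_areas <- function() {
  utils::read.csv(system.file("extdata", "study_littered_areas.csv",
                              package = "equirest"),
                  check.names = FALSE, stringsAsFactors = FALSE)
}
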