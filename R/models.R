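# Inference design: ordered-factor polynomial contrasts, outcome
# transformations, three-level nested random effects, and backward stepwise
# reduction with p > 0.1 as the exclusion criterion. Fitting delegates to
# nlme::lme (gaussian, marginal F tests) and lme4::glmer (binomial, LRT);
# the coding, transformation, marginality and reduction logic live here.

#' Orthonormal polynomial contrasts for an ordered factor
#'
#' Builds orthogonal polynomial contrast columns over equally spaced level
#' scores by Gram-Schmidt orthogonalisation (QR) of the Vandermonde matrix.
#' Column k has polynomial degree k, unit length, zero sum (orthogonal to the
#' intercept), and its last non-zero entry is positive (the conventional
#' sign).
#'
#' @param n_levels Number of ordered levels (4 for treatments T0-T1.5).
#' @param order Highest polynomial degree, must be < `n_levels`.
#' @return Matrix with `n_levels` rows and `order` columns named "lin",
#'   "quad", "cub", ...
#' @export
poly_contrasts <- function(n_levels = 4L, order = 3L) {
  if (order >= n_levels) stop("polynomial order must be below the number of levels")
  stopifnot(order >= 1L)
  x <- seq_len(n_levels) - (n_levels + 1) / 2
  V <- outer(x, 0:order, `^`)
  Q <- qr.Q(qr(V))[, -1L, drop = FALSE]
  for (j in seq_len(ncol(Q))) {
    nz <- which(abs(Q[, j]) > 1e-12)
    if (Q[max(nz), j] < 0) Q[, j] <- -Q[, j]
  }
  colnames(Q) <- c("lin", "quad", "cub", "quart", "quint")[seq_len(order)]
  rownames(Q) <- NULL
  Q
}

#' Transform an outcome for mixed-model fitting
#'
#' `log` applies `log(x + offset)` (offset 1 min by default so zero durations
#' stay finite); `logit` maps proportions in \[0, 1\] into (0, 1) by the
#' empirical shrink `p' = (p (n - 1) + 0.5) / n` and applies the log-odds.
#' Both are exactly invertible by [back_transform()] given the returned
#' parameters.
#'
#' @param x Numeric values (proportions in \[0, 1\] for logit).
#' @param kind "none", "log" or "logit".
#' @param offset Log offset.
#' @param shrink_n Logit shrink denominator; defaults to the number of
#'   non-missing values.
#' @return Transformed vector with attribute `params` (kind, offset,
#'   shrink_n).
#' @export
transform_outcome <- function(x, kind = c("none", "log", "logit"),
                              offset = 1, shrink_n = NULL) {
  kind <- match.arg(kind)
  params <- list(kind = kind, offset = offset, shrink_n = shrink_n)
  y <- switch(kind,
    none = x,
    log = {
      if (any(x + offset <= 0, na.rm = TRUE)) stop("log transform of value <= -offset")
      log(x + offset)
    },
    logit = {
      if (any(x < 0 | x > 1, na.rm = TRUE)) stop("logit needs values in [0, 1]")
      n <- if (is.null(shrink_n)) sum(!is.na(x)) else shrink_n
      params$shrink_n <- n
      stats::qlogis((x * (n - 1) + 0.5) / n)
    }
  )
  attr(y, "params") <- params
  y
}

#' Invert [transform_outcome()]
#'
#' @param y Transformed values.
#' @param params The `params` attribute returned by [transform_outcome()].
#' @return Values on the original response scale.
#' @export
back_transform <- function(y, params) {
  switch(params$kind,
    none = y,
    log = exp(y) - params$offset,
    logit = {
      n <- params$shrink_n
      (stats::plogis(y) * n - 0.5) / (n - 1)
    }
  )
}

#' Specification of one outcome model
#'
#' One row of the study's model catalogue: the outcome column, its
#' transformation, the model family, and the polynomial order for the ordered
#' treatment factor (third order for totals, second order for
#' location-specific outcomes).
#'
#' @param outcome Metrics column name (e.g. "dur_min_total"). The derived
#'   flags "under_30min" and "under_30min_litter" are also understood.
#' @param transformation "none", "log" or "logit".
#' @param family "gaussian-lme" or "binomial-glmm".
#' @param poly_order 2 or 3.
#' @param label Optional human-readable label.
#' @return A `model_spec` object.
#' @export
model_spec <- function(outcome, transformation = "none",
                       family = c("gaussian-lme", "binomial-glmm"),
                       poly_order = 3L, label = outcome) {
  family <- match.arg(family)
  stopifnot(poly_order %in% c(2L, 3L))
  structure(list(outcome = outcome, transformation = transformation,
                 family = family, poly_order = as.integer(poly_order),
                 percent = grepl("^pct_", outcome), label = label),
            class = "model_spec")
}

#' The study's model catalogue
#'
#' All outcome-by-location models: bout counts (total and per surface,
#' untransformed), recumbency durations (log on rubber mats and firm ground,
#' where zeros and skew dominate), the under-30-min flags (binomial), lateral
#' recumbency (logit), members present and forced terminations
#' (untransformed). Totals use a third-order treatment polynomial,
#' location-specific outcomes second order.
#'
#' @return Named list of [model_spec()] objects.
#' @export
default_model_specs <- function() {
  specs <- list(
    model_spec("n_bouts_total", "none", "gaussian-lme", 3L),
    model_spec("n_bouts_litter", "none", "gaussian-lme", 2L),
    model_spec("n_bouts_rubber", "none", "gaussian-lme", 2L),
    model_spec("n_bouts_firm", "none", "gaussian-lme", 2L),
    model_spec("dur_min_total", "none", "gaussian-lme", 3L),
    model_spec("dur_min_litter", "none", "gaussian-lme", 2L),
    model_spec("dur_min_rubber", "log", "gaussian-lme", 2L),
    model_spec("dur_min_firm", "log", "gaussian-lme", 2L),
    model_spec("under_30min", "none", "binomial-glmm", 3L),
    model_spec("under_30min_litter", "none", "binomial-glmm", 2L),
    model_spec("pct_lateral", "logit", "gaussian-lme", 3L),
    model_spec("pct_present", "none", "gaussian-lme", 3L),
    model_spec("pct_forced", "none", "gaussian-lme", 3L)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "outcome"))
}

# model frame with treatment polynomial columns, transformed outcome and the
# nesting identifiers; drops rows with missing outcome
prepare_model_frame <- function(spec, metrics) {
  need <- c("horse_id", "group", "treatment", "rank_class")
  miss <- setdiff(need, names(metrics))
  if (length(miss) > 0L) stop("metrics lack columns: ", paste(miss, collapse = ", "))
  y_raw <- if (spec$outcome %in% names(metrics)) {
    metrics[[spec$outcome]]
  } else if (spec$outcome == "under_30min_litter") {
    metrics$dur_min_litter < 30
  } else stop("unknown outcome: ", spec$outcome)
  ratios <- sort(unique(treatment_ratio(metrics$treatment)))
  lev <- treatment_label(ratios)
  C <- poly_contrasts(length(lev), spec$poly_order)
  ti <- match(metrics$treatment, lev)
  df <- data.frame(
    group = factor(metrics$group),
    horse_id = factor(metrics$horse_id),
    condition = factor(metrics$treatment, levels = lev),
    rank_class = factor(metrics$rank_class, levels = c("high", "low")),
    stringsAsFactors = FALSE
  )
  for (j in seq_len(ncol(C))) df[[colnames(C)[j]]] <- C[ti, j]
  if (spec$family == "binomial-glmm") {
    df$y <- as.numeric(y_raw)
    attr(df, "trans") <- list(kind = "binomial")
  } else {
    x <- if (spec$percent && spec$transformation == "logit") y_raw / 100 else y_raw
    y <- transform_outcome(x, spec$transformation)
    df$y <- as.numeric(y)
    attr(df, "trans") <- attr(y, "params")
  }
  keep <- !is.na(df$y)
  out <- df[keep, , drop = FALSE]
  attr(out, "trans") <- attr(df, "trans")
  attr(out, "levels") <- lev
  out
}

poly_terms <- function(order) c("lin", "quad", "cub")[seq_len(order)]

full_terms <- function(order) {
  pt <- poly_terms(order)
  c("rank_class", pt, paste0("rank_class:", pt))
}

# marginality: a term may leave only if nothing retained depends on it
droppable_terms <- function(terms, order) {
  pt <- poly_terms(order)
  ok <- character(0)
  ints <- paste0("rank_class:", pt)
  present_ints <- intersect(ints, terms)
  # highest-degree interaction present is droppable
  if (length(present_ints) > 0L) ok <- c(ok, present_ints[length(present_ints)])
  # a polynomial main effect: droppable if no higher-degree main effect and no
  # interaction of its own (or higher) degree remains
  present_pt <- intersect(pt, terms)
  if (length(present_pt) > 0L) {
    top <- present_pt[length(present_pt)]
    deg <- match(top, pt)
    blocked <- any(match(sub("rank_class:", "", present_ints), pt) >= deg)
    if (!blocked) ok <- c(ok, top)
  }
  if ("rank_class" %in% terms && length(present_ints) == 0L) {
    ok <- c(ok, "rank_class")
  }
  ok
}

fixed_formula <- function(terms) {
  rhs <- if (length(terms) == 0L) "1" else paste(terms, collapse = " + ")
  stats::as.formula(paste("y ~", rhs))
}

# fit one model, falling back to coarser random structures when the
# three-level nesting fails or is singular
fit_mixed <- function(terms, frame, family) {
  randoms <- list(
    gaussian = list(~1 | group / horse_id / condition,
                    ~1 | group / horse_id, ~1 | group),
    binomial = list("(1 | group / horse_id / condition)",
                    "(1 | group / horse_id)", "(1 | group)")
  )
  ff <- fixed_formula(terms)
  if (family == "gaussian-lme") {
    for (i in seq_along(randoms$gaussian)) {
      fit <- tryCatch(
        nlme::lme(ff, random = randoms$gaussian[[i]], data = frame,
                  method = "REML",
                  control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                             msMaxIter = 200, niterEM = 50,
                                             returnObject = TRUE)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        if (i > 1L) warning("random-effects nesting reduced to level ", 4L - i)
        attr(fit, "random_level") <- 4L - i
        return(fit)
      }
    }
    stop("no mixed-model fit converged")
  }
  for (i in seq_along(randoms$binomial)) {
    form <- stats::as.formula(paste(paste(deparse(ff), collapse = " "), "+",
                                    randoms$binomial[[i]]))
    fit <- tryCatch({
      f <- lme4::glmer(form, data = frame, family = stats::binomial(),
                       control = lme4::glmerControl(calc.derivs = FALSE,
                                                    check.conv.singular = "ignore"))
      if (lme4::isSingular(f, tol = 1e-4) && i < length(randoms$binomial)) NULL else f
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      if (i > 1L) warning("random-effects nesting reduced to level ", 4L - i)
      attr(fit, "random_level") <- 4L - i
      return(fit)
    }
  }
  stop("no binomial mixed-model fit converged")
}

# p-values for the given terms: marginal F tests (gaussian) or LRT (binomial).
# `model_terms` is the full fixed-term set of `fit` (needed to build the
# reduced binomial models).
term_pvalues <- function(fit, terms, frame, family, model_terms = terms) {
  if (length(terms) == 0L) return(numeric(0))
  if (family == "gaussian-lme") {
    an <- stats::anova(fit, type = "marginal")
    p <- an[terms, "p-value"]
    names(p) <- terms
    return(p)
  }
  p <- vapply(terms, function(tm) {
    red <- fit_mixed(setdiff(model_terms, tm), frame, "binomial-glmm")
    a <- stats::anova(red, fit)
    a[["Pr(>Chisq)"]][2L]
  }, numeric(1))
  p
}

#' Fit the full fixed-effects model for one outcome
#'
#' Fixed effects: rank class, the treatment polynomial columns, and their
#' interactions; random effects: experimental condition nested in horse
#' nested in group. Gaussian outcomes are fitted by [nlme::lme()] (REML,
#' marginal F tests), binomial flags by [lme4::glmer()] (Laplace, LRT).
#' Singular or non-convergent fits fall back to dropping the innermost
#' nesting level with a warning.
#'
#' @param spec A [model_spec()].
#' @param metrics Horse-day metrics table with `group`, `horse_id`,
#'   `treatment` and `rank_class` columns (at least 2 groups and 2 horses per
#'   group).
#' @return An `equirest_fit`: the fitted model, its term set, per-term
#'   p-values and the transformation parameters.
#' @export
fit_full_model <- function(spec, metrics) {
  frame <- prepare_model_frame(spec, metrics)
  check_design(frame)
  terms <- full_terms(spec$poly_order)
  fit <- fit_mixed(terms, frame, spec$family)
  new_equirest_fit(spec, fit, frame, terms, path = NULL)
}

check_design <- function(frame) {
  if (nlevels(droplevels(frame$group)) < 2L) stop("need at least 2 groups")
  per_group <- tapply(frame$horse_id, frame$group,
                      function(h) length(unique(h)))
  if (any(per_group < 2L, na.rm = TRUE)) stop("need at least 2 horses per group")
}

new_equirest_fit <- function(spec, fit, frame, terms, path) {
  # LRT p-values are only meaningful for droppable terms (a term nested under
  # a retained interaction cannot be removed on its own), so the binomial
  # family reports those; marginal F tests cover every term
  pv_terms <- if (spec$family == "binomial-glmm") {
    droppable_terms(terms, spec$poly_order)
  } else terms
  structure(list(spec = spec, fit = fit, frame = frame, terms = terms,
                 pvalues = term_pvalues(fit, pv_terms, frame, spec$family,
                                        model_terms = terms),
                 trans = attr(frame, "trans"),
                 treatment_levels = attr(frame, "levels"),
                 path = path),
            class = "equirest_fit")
}

#' @export
print.equirest_fit <- function(x, ...) {
  cat("<equirest_fit>", x$spec$label, "(", x$spec$family, ",",
      x$spec$transformation, ")\n")
  cat("  retained terms:",
      if (length(x$terms) == 0L) "(intercept only)" else
        paste(x$terms, collapse = ", "), "\n")
  if (length(x$pvalues) > 0L) {
    cat("  p-values:", paste(sprintf("%s=%.3g", names(x$pvalues), x$pvalues),
                             collapse = ", "), "\n")
  }
  if (!is.null(x$path) && nrow(x$path) > 0L) {
    cat("  dropped:", paste(sprintf("%s (p=%.3g)", x$path$term, x$path$p),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Backward stepwise reduction of the full model
#'
#' Starting from the full model, repeatedly drops the least significant
#' droppable term with p > `alpha_drop` and refits, respecting marginality:
#' an interaction leaves before its main effects, and the cubic polynomial
#' term before the quadratic before the linear (so the treatment relationship
#' is reported in its most parsimonious polynomial order). Ties are broken in
#' favour of the higher polynomial order. Stops when every remaining term has
#' p <= `alpha_drop`. The reduction path (term, p at removal) is recorded.
#'
#' @param spec A [model_spec()].
#' @param metrics Horse-day metrics table.
#' @param alpha_drop Exclusion criterion, default 0.1.
#' @return An `equirest_fit` of the final model, with the path in `$path`.
#' @export
stepwise_reduce <- function(spec, metrics, alpha_drop = 0.1) {
  frame <- prepare_model_frame(spec, metrics)
  check_design(frame)
  terms <- full_terms(spec$poly_order)
  pt <- poly_terms(spec$poly_order)
  term_order <- function(tm) {
    base <- sub("rank_class:", "", tm)
    ifelse(base %in% pt, match(base, pt), 0L)
  }
  path <- data.frame(step = integer(0), term = character(0), p = numeric(0))
  fit <- fit_mixed(terms, frame, spec$family)
  step <- 0L
  repeat {
    cand <- droppable_terms(terms, spec$poly_order)
    if (length(cand) == 0L) break
    p <- suppressWarnings(term_pvalues(fit, cand, frame, spec$family,
                                       model_terms = terms))
    over <- which(p > alpha_drop)
    if (length(over) == 0L) break
    pc <- p[over]
    worst <- pc == max(pc)
    pick <- names(pc)[worst]
    if (length(pick) > 1L) pick <- pick[which.max(term_order(pick))]
    pick <- pick[1L]
    step <- step + 1L
    path <- rbind(path, data.frame(step = step, term = pick, p = pc[[pick]]))
    terms <- setdiff(terms, pick)
    fit <- fit_mixed(terms, frame, spec$family)
  }
  new_equirest_fit(spec, fit, frame, terms, path = path)
}

#' Treatment-by-rank estimates on the response scale
#'
#' Computes linear-predictor estimates and 95% confidence intervals for every
#' treatment (by rank class if rank terms were retained) and back-transforms
#' them through the inverse outcome transformation. Under a log or logit
#' transformation (or the binomial link) the back-transformed estimates are
#' medians of the response distribution, not means; the output flags this.
#'
#' @param fitres An `equirest_fit`.
#' @param level Confidence level, default 0.95.
#' @return Data frame `treatment`, `rank_class`, `estimate`, `lower`,
#'   `upper`, with attribute `scale_note`.
#' @export
estimate_response_scale <- function(fitres, level = 0.95) {
  spec <- fitres$spec
  lev <- fitres$treatment_levels
  by_rank <- any(grepl("rank_class", fitres$terms))
  ranks <- if (by_rank) c("high", "low") else NA_character_
  grid <- expand.grid(treatment = lev, rank_class = ranks,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  Cfull <- poly_contrasts(length(lev), spec$poly_order)
  nd <- data.frame(rank_class = factor(
    ifelse(is.na(grid$rank_class), "high", grid$rank_class),
    levels = c("high", "low")))
  ti <- match(grid$treatment, lev)
  for (j in seq_len(ncol(Cfull))) nd[[colnames(Cfull)[j]]] <- Cfull[ti, j]
  ff <- fixed_formula(fitres$terms)
  X <- stats::model.matrix(stats::delete.response(stats::terms(ff)), nd)
  beta <- if (inherits(fitres$fit, "lme")) nlme::fixef(fitres$fit) else
    lme4::fixef(fitres$fit)
  V <- as.matrix(stats::vcov(fitres$fit))
  X <- X[, names(beta), drop = FALSE]
  est <- drop(X %*% beta)
  se <- sqrt(rowSums((X %*% V) * X))
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- est - z * se
  hi <- est + z * se
  inv <- function(v) {
    if (spec$family == "binomial-glmm") return(stats::plogis(v))
    out <- back_transform(v, fitres$trans)
    if (spec$percent && spec$transformation == "logit") out <- out * 100
    out
  }
  res <- data.frame(treatment = grid$treatment, rank_class = grid$rank_class,
                    estimate = inv(est), lower = inv(lo), upper = inv(hi),
                    stringsAsFactors = FALSE)
  attr(res, "scale_note") <- if (spec$transformation %in% c("log", "logit") ||
                                 spec$family == "binomial-glmm") {
    "back-transformed estimates are medians on the response scale, not means"
  } else "identity scale"
  res
}
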