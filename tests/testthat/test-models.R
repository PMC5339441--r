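test_that("polynomial contrasts are orthonormal with the conventional shape", {
  C <- poly_contrasts(4, 3)
  expect_equal(dim(C), c(4L, 3L))
  expect_equal(C[, "lin"], c(-3, -1, 1, 3) / sqrt(20), tolerance = 1e-12)
  expect_equal(C[, "quad"], c(1, -1, -1, 1) / 2, tolerance = 1e-12)
  expect_equal(crossprod(C), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(colSums(C), c(lin = 0, quad = 0, cub = 0), tolerance = 1e-12)
  # independent cross-check against the Gram-Schmidt construction in base R
  expect_equal(unname(C), unname(stats::contr.poly(4)), tolerance = 1e-9)
  expect_equal(unname(poly_contrasts(5, 2)),
               unname(stats::contr.poly(5)[, 1:2]), tolerance = 1e-9)
  expect_error(poly_contrasts(4, 4), "order")
})

test_that("outcome transformations are exactly invertible", {
  expect_equal(as.numeric(transform_outcome(0.5, "logit")), 0)
  expect_equal(as.numeric(transform_outcome(0, "log", offset = 1)), 0)
  expect_error(transform_outcome(1.2, "logit"), "\\[0, 1\\]")
  expect_error(transform_outcome(-2, "log", offset = 1), "log transform")

  set.seed(5)
  p <- runif(1000)
  y <- transform_outcome(p, "logit")
  expect_lt(max(abs(back_transform(y, attr(y, "params")) - p)), 1e-9)
  x <- rexp(1000) * 100
  yl <- transform_outcome(x, "log")
  expect_lt(max(abs(back_transform(yl, attr(yl, "params")) - x)), 1e-9)
})

test_that("the model catalogue maps outcomes to their transformation and order", {
  specs <- default_model_specs()
  expect_length(specs, 13L)
  expect_equal(specs[["dur_min_rubber"]]$transformation, "log")
  expect_equal(specs[["pct_lateral"]]$transformation, "logit")
  expect_equal(specs[["under_30min"]]$family, "binomial-glmm")
  totals <- c("n_bouts_total", "dur_min_total", "under_30min", "pct_lateral",
              "pct_present", "pct_forced")
  for (nm in names(specs)) {
    expect_equal(specs[[nm]]$poly_order, if (nm %in% totals) 3L else 2L,
                 info = nm)
  }
})

test_that("polynomial-contrast and dummy coding give identical fitted values", {
  cfg <- sim_config(seed = 301)
  m <- simulate_metrics(cfg)
  spec <- default_model_specs()[["dur_min_total"]]
  f <- fit_full_model(spec, m)
  frame <- f$frame
  alt <- nlme::lme(y ~ rank_class * condition, random = ~1 | group / horse_id / condition,
                   data = frame, method = "REML",
                   control = nlme::lmeControl(opt = "optim", returnObject = TRUE))
  # agreement up to optimiser stopping tolerance in the variance parameters
  expect_equal(unname(stats::fitted(f$fit, level = 0)),
               unname(stats::fitted(alt, level = 0)), tolerance = 1e-4)
})

test_that("backward reduction respects marginality and the exclusion criterion", {
  cfg <- sim_config(seed = 302)
  m <- simulate_metrics(cfg)
  spec <- default_model_specs()[["dur_min_total"]]
  f <- stepwise_reduce(spec, m)
  pt <- c("lin", "quad", "cub")
  # marginality: an interaction implies its main effects and all lower orders
  for (k in 1:3) {
    if (paste0("rank_class:", pt[k]) %in% f$terms) {
      expect_true("rank_class" %in% f$terms)
      expect_true(all(pt[1:k] %in% f$terms))
    }
  }
  for (k in 2:3) {
    if (pt[k] %in% f$terms) expect_true(all(pt[1:(k - 1)] %in% f$terms))
  }
  # every droppable retained term sits at or below the exclusion p
  cand <- equirest:::droppable_terms(f$terms, 3L)
  if (length(cand) > 0L) {
    p <- equirest:::term_pvalues(f$fit, cand, f$frame, spec$family)
    expect_true(all(p <= 0.1))
  }
  # all dropped terms exceeded the criterion when removed
  expect_true(all(f$path$p > 0.1))
})

test_that("a pure linear treatment effect reduces to a linear treatment model", {
  # no rank effects injected: the reduction should keep the linear treatment
  # term and prune the polynomial down to first order in most replicates
  reps <- 200
  keep_lin <- logical(reps)
  poly_order_final <- integer(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_groups = 10, group_sizes = 4, treatment_effect = 30,
                      rank_interaction = 0, seed = 5000 + r)
    m <- simulate_metrics(cfg)
    f <- suppressWarnings(
      stepwise_reduce(default_model_specs()[["dur_min_total"]], m))
    keep_lin[r] <- "lin" %in% f$terms
    poly_order_final[r] <- max(0L, which(c("lin", "quad", "cub") %in% f$terms))
  }
  # the true linear effect is essentially always kept ...
  expect_gte(mean(keep_lin), 0.8)
  # ... and first order is the most common final polynomial, as expected when
  # each of the four null hypotheses above it is pruned at the 0.1 criterion
  expect_gt(mean(poly_order_final == 1L), 0.5)
  expect_gt(mean(poly_order_final == 1L), mean(poly_order_final == 2L))
  expect_gt(mean(poly_order_final == 1L), mean(poly_order_final == 3L))
})

test_that("binomial flags are fitted by the nested logistic model", {
  cfg <- sim_config(seed = 305)
  m <- simulate_metrics(cfg)
  spec <- default_model_specs()[["under_30min"]]
  f <- suppressWarnings(fit_full_model(spec, m))
  expect_s4_class(f$fit, "glmerMod")
  expect_gt(length(f$pvalues), 0L)
  expect_true(all(f$pvalues > 0 & f$pvalues <= 1))
  est <- estimate_response_scale(f)
  expect_true(all(est$estimate >= 0 & est$estimate <= 1))
  expect_true(all(est$lower <= est$estimate & est$estimate <= est$upper))
})

test_that("response-scale estimates invert the transformation and keep CI order", {
  cfg <- sim_config(seed = 306)
  m <- simulate_metrics(cfg)

  spec_id <- default_model_specs()[["dur_min_total"]]
  f <- fit_full_model(spec_id, m)
  est <- estimate_response_scale(f)
  expect_equal(nrow(est), 8L) # 4 treatments x 2 rank classes
  expect_true(all(est$lower <= est$estimate & est$estimate <= est$upper))
  # identity transformation: estimates equal the linear predictor directly
  beta <- nlme::fixef(f$fit)
  expect_equal(est$estimate[est$treatment == "T0" & est$rank_class == "high"],
               sum(beta * c(1, 0, poly_contrasts(4, 3)[1, ], 0, 0, 0)),
               tolerance = 1e-8)

  spec_lg <- default_model_specs()[["pct_lateral"]]
  flg <- stepwise_reduce(spec_lg, m)
  elg <- estimate_response_scale(flg)
  expect_true(all(elg$estimate >= 0 & elg$estimate <= 100))
  expect_true(all(elg$lower <= elg$estimate & elg$estimate <= elg$upper))
  expect_match(attr(elg, "scale_note"), "median")
})

test_that("logit-scale group means are recovered on the response scale", {
  # proportions generated around known logit-scale means by rank class
  set.seed(307)
  n_h <- 40
  grid <- expand.grid(horse_id = sprintf("h%02d", 1:n_h),
                      treatment = c("T0", "T0.5", "T1", "T1.5"),
                      day_index = 1:3, stringsAsFactors = FALSE)
  hnum <- as.integer(sub("h", "", grid$horse_id))
  grid$group <- sprintf("G%d", (hnum - 1L) %% 8L + 1L)
  grid$rank_class <- ifelse(hnum <= 20, "low", "high")
  mu <- ifelse(grid$rank_class == "low", -2, -1)
  grid$pct_lateral <- 100 * plogis(rnorm(nrow(grid), mu, 0.3))
  f <- stepwise_reduce(default_model_specs()[["pct_lateral"]], grid)
  est <- estimate_response_scale(f)
  for (rc in c("low", "high")) {
    truth <- 100 * plogis(if (rc == "low") -2 else -1)
    got <- mean(est$estimate[est$rank_class == rc |
                               is.na(est$rank_class)])
    expect_lt(abs(got - truth) / truth, 0.15)
  }
})

test_that("degenerate designs are rejected", {
  cfg <- sim_config(seed = 310)
  m <- simulate_metrics(cfg)
  one_group <- m[m$group == "G1", ]
  expect_error(fit_full_model(default_model_specs()[["dur_min_total"]],
                              one_group), "2 groups")
})
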