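---
title: "Methods: recumbency analysis for group-housed horses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recumbency analysis for group-housed horses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equirest)
```

## The problem

Horses can doze and reach slow-wave sleep standing up, but REM sleep requires
recumbency — sternal with the muzzle resting, or lateral. A widely used rule
of thumb holds that about 30 min of recumbency per 24 h is the minimum needed
for adequate REM sleep. In group housing the littered (bedded) lying area is a
shared, potentially limited resource, and Swiss welfare law prescribes minimal
littered dimensions per group, summed from per-horse minima that depend on
withers height. `equirest` implements the full analysis chain for experiments
that vary the space allowance of the littered area and measure its effect on
lying behaviour: bout detection from leg-worn accelerometers, per-24 h
outcome metrics, dominance rank, area dimensioning, and the mixed-model
inference design.

## Bout detection from 1 Hz leg accelerometry

A single-axis logger on the metacarpus of a hind leg measures acceleration
parallel to the leg. Standing, gravity loads the axis (readings near −1 g);
recumbent, the leg is horizontal and readings sit near 0 g. The detector is a
four-stage pipeline (`detect_bouts()`):

1. **Threshold classification** (`classify_samples()`): a sample is *lying*
   when acceleration exceeds −0.75 g, *standing* when below. The two strict
   inequalities leave equality undefined; we assign −0.75 g exactly to
   *standing*, the conservative choice that cannot inflate recumbency.
2. **Moving-median majority smoothing** (`smooth_states()`): the median of a
   binary series is its majority vote. Each sample becomes the majority state
   of the 15 s before and after it. We include the centre sample, which makes
   the 31-sample window odd and tie-free in the interior; at the edges the
   window is truncated (no padding) and a tied vote keeps the raw state. Both
   choices are exposed (`include_center`, and the edge rule is fixed), because
   window parity and edge handling cannot be recovered from a verbal
   description of a smoother. The pass exists to absorb locomotion: brief
   threshold crossings never dominate a 31-sample window.
3. **Run-length segmentation** (`segment_bouts()`): maximal lying runs become
   bouts; runs shorter than 30 s are discarded. Intervals are half-open
   `[start, end)` with whole-second durations at 1 Hz, so durations are
   additive and each sample counts exactly once.
4. **Pasture exclusion** (`exclude_pasture()`): recumbency on pasture is not
   part of the stable record. A bout is attributed to pasture when its
   *midpoint* falls in a pasture-access interval — a deterministic proxy for
   the manual screening such studies apply; bouts straddling a boundary with
   the midpoint outside are kept.

**Gap policy.** Loggers drop samples. Gaps of at most 5 s are bridged by
carrying the last observation forward; longer gaps split the trace into
segments processed independently, so no bout can span an unobserved stretch.

## Per-24 h outcome metrics

`horse_day_metrics()` splits the 72 h recording window into three 24 h days.
A bout spanning a day boundary is split there, with each fragment credited to
its own day — this keeps per-day durations additive to the window total. Per
horse-day the package reports bout counts and recumbency durations in total
and per surface (litter, rubber mats, firm ground — anything else, e.g.
concrete or the outdoor run, maps to firm ground), the flag for less than
30 min of total recumbency (the REM-deficiency proxy), the percentage of
lateral recumbency in total recumbency, the mean percentage of other group
members present at lie-down, and the percentage of forcedly terminated bouts.

Proportions with an empty denominator (no recumbency, or no bouts) are
*missing*, not zero, so the model stage can drop them rather than bias the
fit. The presence denominator excludes the focal horse (`group_size − 1`);
including the focal would cap the proportion below 100 % artificially. The
flag `include_focal` restores the other reading.

## Dominance rank

Each pair of group members meets once in a paired feeding test;
`schedule_encounters()` orders the round robin randomly under the welfare
constraint that no horse takes part in more than two consecutive encounters.
`dominance_ratio()` computes, per horse, the ratio of dominated dyads to its
`n − 1` dyads — this per-horse denominator is the only reading that yields
the conventional 0–1 range — and classes 0–0.5 as low-ranking, above 0.5 as
high-ranking (0.5 itself is low, applying the interval rule literally). The
group mean ratio is exactly 0.5 for any complete round robin, a useful
invariant check. Encounter ties are not representable; the observational
protocol must adjudicate a winner.

## Littered-area dimensioning

`minimal_area()` is a dot product of the group's withers-height category
counts with the legal per-horse minima (4.0, 4.5, 5.5, 6.0, 7.5, 8.0 m²),
shipped as a versioned CSV so a legislative revision is configuration, not
code. Treatments are ratios of that minimum: littered area `ratio × minimal`,
the rest of the constant `1.5 × minimal` experimental area covered with
rubber mats. Areas are rounded **half-up** to 0.1 m²; this convention
reproduces seven of the eight half-way cells in the published dimensioning
table. The eighth (group 8, T0.5: 20.5 × 0.5 = 10.25 printed as 10.2) is
inconsistent with the other seven and is documented as a likely typographical
anomaly rather than matched.

## The synthetic-data generator

No raw recordings are publicly deposited, so the generator
(`sim_config()`, `simulate_schedule()`, `render_trace()`, `simulate_dyads()`)
stands in for them, reproducing the statistical structure the analysis
assumes: eight groups of 3–7 horses (default sizes 4, 4, 7, 4, 6, 6, 3, 4 —
38 horses), four treatments T0–T1.5, 72 h of 1 Hz recording per treatment
starting at midnight.

Default behavioural parameters, chosen once as a realistic study condition:

* **Bout process**: Poisson 5 bouts per 24 h, gamma (shape 2) durations
  truncated below at 60 s. Published distributional detail is absent; the
  truncation reflects that sub-minute recumbency events were negligible in
  such studies and keeps the ground truth within the detector's design range.
  Mean bout duration 4 min at T0, so baseline total recumbency is
  20 min/24 h — recumbency is rare without litter.
* **Effect structure**: total recumbency gains 25 min per unit treatment
  ratio, low-ranking horses gain a further 20 min per unit ratio (the
  rank × treatment interaction the inference stage must recover), with
  persistent horse (SD 10 min) and group (SD 5 min) baselines. These
  magnitudes keep totals in the 20–90 min/24 h range reported for stabled and
  feral horses.
* **Timing**: 60 % of bouts start in 00:00–06:00, a two-component day/night
  mixture standing in for the known concentration of equine sleep after
  midnight; bouts are non-overlapping with 60 s spacing and lie within their
  day.
* **Signal**: standing −1.0 g, lying 0.0 g, Gaussian noise SD 0.05 g (15
  standard deviations from the threshold, so noise alone essentially never
  flips a sample). Locomotion is a bounded oscillation of amplitude 0.35 g
  and 4 s period added around the standing level: it crosses −0.75 g only for
  isolated samples, so the smoothing stage — not luck — removes it. Bursts
  are kept out of a 20 s guard zone around bout boundaries (wider than the
  15 s smoothing half-window): a crossing adjacent to a bout sits in a
  majority-lying window and could not be removed, which would break the
  contract that locomotion never masquerades as recumbency.
* **Social structure**: latent dominance is a uniform score with the low/high
  split at the group median (the analysis dichotomises rank); forced
  termination probability 0.25 for low-ranking vs 0.05 for high-ranking
  horses; lateral share of a bout is beta-distributed with mean 0.1.

What the generator does *not* emulate: weather and season, age and sex
effects, habituation to rubber mats, inter-bout behavioural dependence, and
any imperfection of the video annotation itself. Passing end-to-end tests
therefore demonstrates the correctness of the pipeline's logic under the
stated signal model, not detector performance on real loggers.

`simulate_metrics()` is the generator's aggregate twin: the same per-horse-day
bout process without start-time placement or trace rendering, used where
thousands of replicate metric tables are needed.

## The inference design

Fixed effects are rank class, an ordered treatment factor coded as orthonormal
polynomial contrasts (`poly_contrasts()`, Gram–Schmidt over equally spaced
scores; third order for totals, second order for location-specific outcomes),
and their interaction; the random effect is experimental condition nested in
horse nested in group. Gaussian outcomes are fitted with `nlme::lme` (REML)
and tested with marginal F tests; binary outcomes (the under-30-min flags)
with `lme4::glmer` and likelihood-ratio tests — F for continuous and χ² for
binary mirrors the reporting convention of such studies, and the denominator
degrees of freedom are the fitting routine's defaults (an approximation, as
no df method is named in the source design). Singular or non-convergent fits
fall back to removing the innermost nesting level, with a warning.

Transformations (`transform_outcome()`): log with a 1 min offset for duration
outcomes containing zeros; logit with the empirical shrink
`p' = (p(n−1)+0.5)/n` for proportions containing exact 0 or 1. Both are
exactly invertible, and `estimate_response_scale()` back-transforms estimates
and confidence limits, flagging that under log/logit the results are medians,
not means, on the response scale.

**Backward reduction** (`stepwise_reduce()`): repeatedly drop the least
significant droppable term with p > 0.1, respecting marginality — an
interaction before its main effects, cubic before quadratic before linear —
with ties broken toward the higher polynomial order. In the full model the
only unconditionally droppable term is the highest-order interaction, so the
procedure is close to a fixed testing sequence.

Two consequences of this sequence are worth stating precisely, because they
set what simulation studies of the design can honestly claim:

* Under a null configuration the *first* exclusion candidate (the
  cubic × rank term) is retained at the nominal 10 % rate; the probability
  that *some* interaction column survives is larger (approximately
  1 − 0.9³ ≈ 27 %), because three terms get tested in turn. The package's
  null-rate checks therefore measure the first candidate.
* With a pure linear treatment effect, a final model containing *only* the
  linear term requires all seven null terms to be dropped, which happens in
  roughly 0.9⁷ ≈ 48 % of replicates even with perfectly calibrated tests.
  The honest statements are that the linear term is (essentially always)
  retained and that first order is the most common final polynomial order;
  the test suite asserts those.

## Problem sizes and numerical choices

The simulation studies in the test suite and the acceptance script use the
full 38-horse, 8-group, 4-treatment, 3-day design; 200 replicates for power,
300 for the null retention rate, and 1000 random 2 h traces for the
detector-vs-reference comparison — sizes chosen to keep Monte-Carlo error
well inside the asserted margins. Mixed models use `opt = "optim"` for
`nlme::lme` (markedly faster than the default on these small balanced
designs) and the Laplace approximation for `lme4::glmer`. Exact decimal
behaviour in the dimensioning module is guarded by a 10⁻⁹ epsilon inside the
half-up rounding, which is far below the 0.05 m² half-unit it adjudicates.

## Known limitations

* Sternal/lateral position cannot be inferred from the single-axis signal;
  position, surface, social context and termination cause come from video
  annotation tables, which the package joins but cannot generate from video.
* The detector's fixed threshold assumes the logger axis conventions above;
  other mounting orientations need their own threshold.
* The nested binomial model on Bernoulli horse-day flags is weakly
  identified at the condition level; the fallback chain makes this explicit
  rather than hiding it.
* Dominance ties and incomplete round robins are rejected, not imputed.
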