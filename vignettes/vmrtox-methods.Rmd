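---
title: "Methods: VMR behavior, dose-response and lipid statistics in vmrtox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VMR behavior, dose-response and lipid statistics in vmrtox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vmrtox analyses visual motor response (VMR) assays of larval zebrafish:
embryos in multi-well plates are video-tracked at 30 frames per second
while the illumination alternates between light and dark, and each
abrupt transition acts as a visual startle. The package covers the full
chain from raw centroid tracks to treatment-level inference, plus the
companion dose-mortality and lipidomics analyses that accompany such
exposure studies. This vignette records the models, the defaults, and
the design decisions, in enough detail that a maintainer can judge each
choice.

## The assay and its schedule

The standard protocol (`vmr_schedule()`) is a 10 min dark acclimation
(not recorded) followed by four cycles of alternating 3 min light and
3 min dark periods: eight 180 s intervals, 24 min of recorded data, and
eight startles (four dark-to-light including the onset at time zero,
four light-to-dark). The pre-recording state is kept on the schedule
object so the onset transition counts as a startle exactly when the
acclimation state differs from the first interval. All endpoint
computation is restricted to the recorded period; the acclimation never
enters any average.

## Track cleaning

Two classes of centroid-tracking error occur in this kind of video
tracking, and both present as single-frame out-and-back spikes:

* **Type 1** -- the tracked point switches between two parts of the
  fish body while the animal holds station. Flagged when the absolute
  turning angle at the frame exceeds 150 degrees *and* the distance
  between the previous and future locations is under 0.06 mm.
* **Type 2** -- a single-frame jump to the arena edge and back.
  Flagged when the turning angle exceeds 160 degrees, the
  previous-to-future distance is at most 0.6 mm, both legs of the spike
  are at least 2 mm, and the legs differ in length by at most 30%.

The "turning angle between previous and future location" is read as
the turning angle *at the candidate frame*, formed by the trajectories
previous-to-current and current-to-next; this matches the four-quadrant
arctangent definition used for the behavioral turning angle and makes
both detectors pure spike detectors. An angle is undefined when either
segment has zero length (a perfectly stationary fish); undefined angles
never flag. The relative leg difference is `|L1 - L2| / max(L1, L2)`,
symmetric and bounded in [0, 1]. A frame satisfying both detectors is
labelled type 2 (the larger displacement class); labels are mutually
exclusive. Angle thresholds are compared after wrapping to
`(-pi, pi]`, so a full reversal (the wrap boundary) always exceeds
both thresholds.

Flagged runs are corrected by equidistant interpolation between the
nearest clean locations on either side: a run of *k* flagged frames
between anchors A and B becomes `A + j (B - A) / (k + 1)`. Runs that
touch the track boundary have no two-sided anchors and are labelled
`ignored` instead, with a warning. Unflagged frames are bit-identical
before and after correction.

Two rules in the source protocol are under-specified and are therefore
explicit configuration:

* "Periods with high error occurrence" default to a sliding 1 s window
  containing at least 3 flagged frames (`high_error_window_s`,
  `high_error_min_flags`). Within such periods, inter-frame movement
  under 0.2 mm is ignored: those steps are zeroed and the positions in
  the window rebuilt from the retained steps, so sub-resolution jitter
  contributes nothing to path length. The suppression runs after
  interpolation by default; the order is a wrapper-level choice
  (`clean_track()`), not baked into either primitive.
* "Multiple seconds" of lost tracking defaults to a 2 s gap
  (`lost_fix_max_s`); subjects exceeding it are excluded with reason
  `tracking-loss`, alongside subjects flagged dead or deformed in the
  treatment design.

## Motion classification and endpoints

Per-frame kinematics attribute to frame *i* the step from frame
*i - 1*, its speed (step times frame rate), and the signed turning
angle (negative right, positive left, zero straight ahead). Swimming is
speed of at least 6 mm/s (0.2 mm/frame at 30 fps -- the configuration
warns if the pair is inconsistent) sustained for more than 5 frames;
resting is movement under 1 mm/s, or faster movement that fails the
5-frame duration rule. A run of exactly 5 frames is classified rest
(the two published definitions leave it ambiguous; we resolve toward
rest, the conservative side for swim-time endpoints). The definitions
also leave a sustained 1-6 mm/s regime unclassified; rather than
silently inflating either class, those frames form a third state,
**drift**, which contributes to distance but not to swim time or bout
counts, and whose prevalence can be audited. Resting frames have speed
and step zeroed before any endpoint computation.

A swimming bout is a maximal swim run. The ten whole-assay endpoints
are total distance, total time swimming, step-length mean and SD,
turning-angle mean and SD, bouts per second, and mean bout duration,
speed, and turning angle. The turning-angle SD is computed on the
circle (`sqrt(-2 log R)`), since angles near the wrap would inflate a
linear SD; whether the original analysis used a linear or circular
summary is not stated, and the circular choice is the defensible one
for a variable on `(-pi, pi]`. Bout turning angles are signed means
(absolute-value summaries can be derived from the per-bout table).

The four startle endpoints use the half-open window `(t_s, t_s + 5 s]`
after each transition at `t_s`, with "speed at the startle" taken from
the frame at or immediately before `t_s`, and ties for the maximum
broken by the earliest time (a reaction-time reading): response
magnitude (window maximum minus speed at startle), response time (time
of maximum minus `t_s`), startle distance (path up to the maximum), and
distance after startle (path over the whole window). Each is averaged
over the assay's startles; windows truncated by the end of recording
are used as-is and noted.

## Permutation ANOVA and Tukey HSD

Treatment effects are tested per endpoint with a one-way nonparametric
permutation ANOVA: the observed F statistic (for a single factor the
type-III and sequential decompositions coincide) is compared against
the distribution obtained by uniformly permuting group labels of the
raw observations -- exact under the null for a one-way layout.
Internally the between-group sum of squares is the comparison
statistic; it is a strictly increasing function of F under permutation,
so p-values are unchanged while each batch reduces to one matrix
product. Binary endpoints (malformation occurrence) use the deviance
statistic of a one-way logistic-link model, which depends on the data
only through per-group success counts.

The Monte Carlo p-value uses the add-one estimator `(b + 1) / (m + 1)`,
a valid permutation p-value that can never be zero. Sampling proceeds
in batches until the estimated standard error of P falls below
`P * se_ratio` (default `1e-5`, the reference analysis's rule) or the
iteration cap. The reference cap of 2e9 iterations is impractical at
workstation scale; the default cap is `1e5` (configurable), which under
the same SE rule means most runs stop at the cap -- `stopped_by`
reports which rule ended the run. Designs with at most
`exhaustive_limit` distinct label assignments are enumerated exactly
(`n! / prod(n_g!)` assignments for the linear case, the multivariate
hypergeometric lattice of per-group success counts for the binomial
case), giving exact p-values with zero standard error.

Pairwise treatment-versus-control calls use Tukey's honest significant
difference on the raw values (`stats::TukeyHSD`, unequal-n
generalization), mirroring its conventional use after the omnibus
test; the omnibus gates the pairwise stage (protected comparisons).
Per-subject non-independence across the endpoint battery is knowingly
ignored, matching the source analysis; `endpoint_battery()` therefore
reports the expected-by-chance count `alpha * n_tests` next to the
observed significant count so that a battery-wide excess can be judged.
No FDR procedure is applied.

## Dose-response

`fit_probit()` is maximum-likelihood probit regression of mortality on
log10 dose via `stats::glm`, the standard metameter for lethal
concentration estimation. `LCp = 10^((qnorm(p) - intercept) / slope)`;
confidence intervals use the delta method on the log10 scale
(profile-likelihood intervals are out of scope). Control (dose 0) rows
are excluded from the likelihood; Abbott's natural-mortality correction
is available but off by default since the source analysis does not
mention it. Fits whose LC50 lies outside the tested dose range are
flagged `extrapolated` -- the estimate then rests on the assumed probit
shape rather than an observed mortality crossing, the situation that
produced the high-uncertainty tissue-based estimates in this assay
family. Unit conversions treat ppm as mg/L (`uM = ppm / MW * 1000`),
and tissue/media lethality ratios are reported with the conventional
rounding (one decimal below 100, whole numbers above).

## Lipid statistics

Analytes whose coefficient of variation (sd/mean) across the QC
replicate pools exceeds 0.3 are eliminated; the rule is strict
("more than 0.3"), so a CV of exactly the threshold is kept, and
zero-mean analytes are dropped with a divide-by-zero caveat. Values are
normalized to pooled wet weight (nmol per mg). Per-species testing
follows the behavioral scheme -- permutation ANOVA, then Tukey HSD
against the designated control -- and significant control-vs-dose pairs
become trend-table cells: direction (Increase/Decrease of the treated
mean), tier (`p<0.05` vs `p<0.01` on the Tukey-adjusted p), and a
fold-change band. Fold change is defined symmetrically as
`max(mean_c, mean_t) / min(mean_c, mean_t)` with direction carried
separately, so halvings and doublings band alike; bands are half-open,
`[1, 2)` as "1-2" and `[2, Inf)` as ">2". The published tables' exact
numeric band boundaries are not printed; under the symmetric
definition the "0-1" label (their uncolored cells) cannot occur for a
significant cell and is retained only as the label for sub-threshold
changes. Pools are the unit of analysis (embryo-level resampling is out
of scope), and cells whose groups fall below `min_pools` (default 3)
carry a low-sample caveat flag, mirroring the published footnotes about
low-count pools.

## The synthetic-data generator

Every pipeline stage is validated against `simulate_*()` generators
with known ground truth; all are exactly reproducible from their seed.

`simulate_track()` implements a beat-and-glide model: an alternating
renewal process of rest and cruise-speed bouts, chosen because the
segmentation logic is defined by bout/rest alternation and must be
exercised by exactly that structure. Inter-bout gaps are a 0.2 s
minimum separation plus an exponential whose mean makes the realized
bout rate equal the planted `bout_rate_per_s`; durations are an
8-frame minimum (so every planted bout is detectable) plus an
exponential with overall mean `bout_duration_s`. Each light transition
triggers a startle bout whose speed ramps linearly to
`startle_peak_mm_s` at `startle_latency_s` and decays back to cruise.
The arena wall reflects specularly (path length preserved, the track
stays in-well with no absorbing state). Defaults: 5.5 mm arena radius
(48-well plates; well diameter is not standardized across vendors, so
the radius is always configurable), 30 fps, 0.8 bouts/s of mean length
0.4 s at 10 mm/s cruise -- the scale of larval beat-and-glide swimming
-- with a 0.5 s startle latency and 25 mm/s peak.

Two deliberate simplifications matter for interpreting green tests.
First, `rest_jitter_mm` defaults to 0: real tracks carry
sub-resolution centroid noise during rest, but uncorrelated jitter
headings would make roughly one rest frame in six exceed the 150
degree reversal criterion at near-zero net displacement -- i.e. the
type-1 detector fires on noise by construction. With zero jitter, rest
segments have zero length, turning angles there are undefined, nothing
flags, and equidistant correction is exact; jitter can be switched on
(up to the 0.2 mm step threshold) to study detector behavior under
noise. Second, the simulator plants artifacts whose geometry sits
strictly inside the flagging thresholds (`near_threshold = TRUE`
generates boundary cases instead). Passing recall/false-positive tests
therefore certify the detectors against the *defined* error taxonomy,
not against every failure mode of real tracker output; headings within
a bout are persistent with 15 degree/frame noise, there is no
hydrodynamics, posture, or multi-fish interaction, and light-period
activity modulation beyond the startle response is not modelled
(whole-assay summaries are the analysis target, so none is needed).

`simulate_mortality()` draws binomial deaths from a probit curve
(defaults: 5 doses spanning the curve, `log10_lc50 = 0.33`, slope 4,
200 per dose). `simulate_lipids()` draws lognormal pool values around
per-species baselines with CV 0.10 (the scale of pooled-sample spread)
and multiplicative planted effects; `cv = 0` collapses to exact means,
which pins down the fold-change arithmetic in tests.

## Validation problem sizes

The shipped test suite checks, among others: detector recall of 1.0,
false-positive rate under 1%, and strict RMSE improvement on 100
seeded assays; recovery of planted bout rate (within 10%), cruise
speed (within 5%), and startle latency (within one frame) on 100
seeded assays; exact agreement of exhaustive permutation p-values with
brute-force enumeration on all two-per-group compositions of n <= 8,
and a type-I error of 0.05 +/- 0.02 over 1000 null replicates at 2000
permutations; per-seed recovery of the planted log10 LC50 within 0.05
over 200 seeds at 200 subjects per dose; and recall of planted 6-SD
lipid decreases (0.4x at CV 0.10, five pools) of at least 0.95 over
100 seeds. `scripts/acceptance.R` recomputes the same quantities at
reduced replicate counts (30-50 seeds per block, 400 null replicates)
chosen to keep a full run under a minute while leaving Monte Carlo
error well inside each tolerance.

## Known limitations

* The cleaning rules are faithful to their published wording, but two
  operational details (the high-error-period definition and the
  lost-fix threshold) are this package's defaults, not published
  values; both are configurable and logged.
* Monte Carlo permutation p-values at the default cap carry a standard
  error around `sqrt(p(1-p)/1e5)`; raise `max_iter` when decisions sit
  near a threshold.
* Delta-method LC intervals are symmetric on the log scale and can be
  optimistic for extrapolated fits; the `extrapolated` flag marks
  exactly those cases.
* Mixed-effects structure (plate, breeding event) is not modelled, by
  design, matching the one-way reference analysis.
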