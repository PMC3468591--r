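---
title: "Modelling diel fish distribution from hydroacoustic transects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling diel fish distribution from hydroacoustic transects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In deep, transparent lakes, small zooplanktivorous fish play a daily game of
hide and seek with visual predators: zooplankton undertake diel vertical
migration (DVM), aggregating near the thermocline at night and dispersing
into deep water by day; their fish predators follow the food upward and
shoreward at dusk, accepting higher predation risk, and retreat at dawn.
Hydroacoustic transect surveys observe this game as counts of single fish
targets and volume backscatter from the plankton, repeated hourly over
24-hour periods.

`echogam` implements the full desk-scale analysis chain for such surveys:

1. **Echo processing** — blanking zones, target-strength (TS) thresholding,
   echo integration into 10 m x 100 m cells, a predation-risk index, and a
   zooplankton-availability index (MVBS).
2. **A four-family GAM ensemble** — quasi-Poisson and negative-binomial
   models for the zero-inflated counts, a binomial model for
   presence/absence, and a Gaussian model for ln-abundance on presence rows,
   each with k = 3 penalized smooths, forward selection by GCV/UBRE plus
   likelihood-ratio tests, and a hurdle (delta) combination.
3. **Diagnostics and validation** — Moran's I and Mantel permutation tests
   on residuals, day-1-fit/day-2-predict validation metrics, hourly diel
   trade-off summaries and permutation-based threshold detection.
4. **A synthetic lake generator** whose known response functions make every
   stage testable without any field data.

## The model

All four ensemble members share one additive structure on the link scale:

$$ g(E[F]) = a + \sum_i s(V_i) + \varepsilon $$

where `F` is the per-cell fish count (or presence, or ln-count on presence
cells), `a` an intercept, and each `s` a penalized thin-plate regression
spline constrained to basis dimension k = 3. The small basis deliberately
restricts each response to gentle curvature: a dome, a U, or a near-linear
trend — ecologically interpretable shapes. Predictors are zooplankton
availability (`Zpl`, MVBS in dB), predation risk (`Pred`, proportion of
large targets), cell mid-depth (`Depth`), distance to the nearer shore
(`Dist`), hour of day (`Hour`), and water temperature (`Temp`).

Smoothing parameters minimize GCV, `n D / (n - edf)^2`, when the scale is
estimated (quasi-Poisson, Gaussian), and UBRE, `D/n + 2 phi edf/n - phi`,
when the scale is fixed (binomial; negative binomial after its size
parameter is profiled by an outer likelihood search and then held fixed).
The backend is `mgcv::gam(method = "GCV.Cp")`, which implements exactly
these scores; forward selection, the step tests, the hurdle combination and
all diagnostics are implemented in this package.

Forward selection starts from the intercept-only model; each step fits all
remaining candidates, ranks them by score decrease, and accepts the best
one only if the score decreases *and* the added smooth's term-wise test
(the Marra-Wood test reported by the smoothing backend, the field's
standard significance test for penalized smooth terms) has `p < 0.05`.
Ties are broken in candidate order. A naive deviance-difference F or
chi-square test was implemented first and abandoned: against overdispersed
counts its realized size was about 20% at nominal 5%, because penalization
and estimated smoothing parameters break the chi-square approximation of
the deviance change. Two further safeguards: `gamma = 1.4` inflates the
effective-df cost in GCV/UBRE (the standard correction for those scores'
tendency to undersmooth and, in selection, to admit spurious terms), and a
backward prune after the forward pass drops any term whose term-wise test
is no longer significant given the others (a term that entered early as a
surrogate — e.g. temperature standing in for depth — becomes redundant
once the real predictor enters). For the negative binomial, theta is
profiled once per step on the current model and held fixed across that
step's candidates: UBRE scores are only comparable under a common theta
(per-candidate profiling silently breaks the score ranking — a bug found
and fixed during development). Even so, term-wise p-values for near-null
smooths under GCV/UBRE-estimated smoothing parameters remain somewhat
anti-conservative (measured null size ~12% at nominal 5%), so the
family-wise false-inclusion rate of any such selector exceeds its nominal
level; the package documents this rather than hiding it.

The hurdle combination estimates expected density as
`E[F] = p * exp(m + sigma^2/2)`, the log-normal mean correction applied to
the binomial presence probability `p` and the conditional ln-abundance
prediction `m`; a Duan smearing estimator is available as an option.

## The synthetic world

`scene_config()` and `true_response()` define a stated world, not a tuning
dial. Its defaults describe a 2000 m transect across a basin reaching
100 m, surveyed hourly for two 24-hour periods:

* **Light**: zero at night, a half-sinusoid between dawn (07:00) and dusk
  (19:00).
* **Zooplankton backscatter**: a Gaussian-in-depth layer over a -87 dB
  background, centred at 40 m (the thermocline) at night and 70 m by day,
  widening with daylight, with a mild (factor 1.1) night-time nearshore
  amplitude enhancement. Measured Sv adds 1 dB noise and is filtered to the
  -90 to -70 dB zooplankton band.
* **Prey counts**: negative binomial (size 2) around
  `lambda = exp(a + g_Zpl + g_Pred + g_Hour + g_Depth + g_Dist)` with a
  quadratic dome in Zpl peaking at -79 dB ("rich but not maximal" prey
  patches), linear link-scale risk decay (slope -3), a quadratic U over hour with
  minimum at 13:00, a quadratic depth dome peaking at 40 m, and a linear
  decline with distance from shore. The intercept (-0.8) puts presence
  around 50-60% — marked zero inflation, as in the survey the package
  emulates.
* **Predators**: a sparse class with TS above -40 dB whose per-cell Poisson
  rate is `lambda * pf/(1-pf)`, where `pf` is a risk field biased toward
  daylight and the shore; the realized fraction of large targets is then an
  unbiased measure of `pf`, and a -40 dB rule recovers the latent classes
  with zero error by construction.

Three generator choices deserve explanation because they were genuinely
open:

* **The depth response is a quadratic dome, not a Gaussian bump.** A k = 3
  smooth spans quadratics exactly. With a non-quadratic depth truth, the
  temperature profile — a deterministic monotone transform of depth — picks
  up the residual depth structure and enters the selected set even though
  it carries no independent effect. A world in which "selection drops Temp"
  is a meaningful property must keep the true depth effect inside the span
  of the depth smooth.
* **Effect sizes are anchored to about 45-50% deviance explained.** With
  much stronger gains the quasi-Poisson variance assumption
  (`var = phi mu`) is wrong enough against negative-binomial counts
  (`var = mu + mu^2/theta`) that the forward-selection F-test becomes
  anti-conservative and admits noise terms.
* **The generator's Zpl predictor is the noise-free linear-domain average
  of the field at exactly the sampler's (x, z) positions in each cell**, so
  the measured MVBS estimates the quantity fish actually respond to without
  a depth-correlated bias.

What the generator does *not* emulate: pulse-level acoustics (beam pattern,
TVG, single-echo detection), schooling beyond what negative-binomial
overdispersion captures, fish movement trajectories between hours, 2-D lake
geometry, or any feedback of fish on zooplankton. A green test therefore
establishes that the pipeline recovers a known additive intensity surface
under realistic measurement noise — not that it would be unbiased under
hyperaggregation or acoustic artefacts absent from this world.

## The predation-risk index

The index is the proportion of accepted targets stronger than -40 dB.  Two
measurement-model choices depart from the most literal per-cell reading and
are worth recording:

* **Scale.** Computed strictly per 10 m x 100 m cell, any cell containing a
  predator target necessarily also registers fish presence, so a
  presence/absence model can never show occupancy declining with risk — the
  relationship is degenerate by construction. Large salmonids hunt through
  the water column, so the default pools the proportion over the depth
  cells of each day x hour x distance column (`pred_scale = "column"`);
  `pred_scale = "cell"` restores the literal per-cell index with the
  empty-cell convention `Pred = 0`.
* **Shrinkage.** A column with one or two targets says almost nothing about
  local risk: its raw proportion is 0, 1/2 or 1 depending on which class
  happened to be detected, and at desk-scale densities such columns dominate
  the upper tail of the index. The pooled proportion is therefore shrunk
  toward the hour's transect-wide proportion with `pred_shrink = 4`
  pseudo-targets (an empirical-Bayes compromise); target-rich columns keep
  their own proportion essentially unchanged. Risk also does not vanish
  where fish hide: an empty column inherits the hourly proportion rather
  than zero.

## Numerical and protocol choices

* **Thresholds are closed intervals** (`[-58, -20]` dB for fish targets,
  `[-90, -70]` dB for zooplankton Sv); ties at -40 dB fall to the prey
  side. Binning uses half-open `[a, b)` intervals, 0-based indices, depth
  measured downward, `Dist = min(x, L - x)`, `Hour = floor(t)`.
* **Cells without any in-band Sv sample are dropped, never imputed**, with
  a logged count; an all-empty target file yields an all-zero `F` column
  with a warning.
* **Shape assessment.** `classify_shape()` tags a curve by total drawdown
  and run-up (sampling-density independent); `shape_conforms()`
  operationalizes the response tags the analysis expects: a dome or peak
  needs an interior maximum; "decay" requires the net fall to dominate
  (>= 60% of the range, curve-predictor correlation <= -0.8) while
  tolerating the shallow terminal bend that any quadratic-like basis
  produces when approximating a convex decay; a U needs an interior minimum
  with material arms. Assessment runs over the central 95% of the observed
  predictor values, where the smooth is supported.
* **Autocorrelation defaults.** Inverse-Euclidean weights over
  (Dist, Depth) within each hour for Moran's I (group-size-weighted
  average, within-hour permutations); standardized (Dist, Depth, Hour)
  Euclidean distances for the Mantel test, with a seeded subsample cap of
  400 rows because distance matrices grow quadratically; 999 permutations
  and the +1 correction throughout. Residual skewness and excess kurtosis
  serve as the normality check. Which residual type the original checks
  used is not stated; deviance residuals are used here. One subtlety worth
  knowing when interpreting these tests on this package's own synthetic
  surveys: the risk index is shared by all depth cells of a column, so its
  measurement error induces a small genuine within-column residual
  correlation even under the true model — the diagnostics are calibrated
  against exchangeable residuals, not against that measurement design.
* **Threshold detection** fits the best two-changepoint piecewise-constant
  model by exhaustive SSE minimization on prefix sums; a changepoint whose
  adjacent segment means coincide is degenerate and dropped (a pure step
  reports a single breakpoint), and significance comes from permuting the
  hour labels. This procedure is this package's own stand-in: the original
  study's threshold method lives in supporting material that is not
  available, so detected hours are comparable in spirit, not in algorithm.
  Survey-level detection runs on the `ln(N+1)` scale (the field's display
  scale), which keeps night-time aggregation spikes from dominating the
  segmentation. On a *smooth* diel cycle a piecewise-constant fit places
  its breakpoints inside the light ramps rather than exactly at dawn and
  dusk — exact recovery holds for step-like series, and the package's tests
  assert each regime accordingly.
* **Validation conventions.** `AVE = mean(predicted - observed)` (negative
  = underprediction); the regression is observed on predicted, so ideal
  intercept 0 and slope 1; `r2 = 100 r^2`. Day-1/day-2 validation selects
  and fits on day 1 only and predicts day 2 from the fitted functional
  relationships.
* **Model export.** The JSON model files store family, link, intercept,
  scale/theta, deviances, edf, score and each centred smooth on a dense
  200-point grid with standard errors. Re-evaluation by interpolation is
  exact at the grid nodes and approximate between them; the basis
  internals of the smoother backend are deliberately not serialized.
* **Hour is a plain (non-cyclic) smooth** on 0-23: the expected U shape
  would be re-parameterized by a cyclic basis. Configurable by swapping the
  candidate set.

## Known limitations

* Desk-scale surveys carry far fewer targets than a real survey hour, so
  the risk index is noisy despite pooling; the binomial family's risk
  effect is the weakest-identified quantity in the ensemble and can come
  out flat on unlucky replicates.
* The quasi-Poisson family's selection test is only approximately
  calibrated when counts are strongly overdispersed; the negative-binomial
  member of the ensemble is the better-specified count model, and their
  agreement (fitted-mean correlation > 0.95 in tests) is itself one of the
  checked properties.
* Temperature is collinear with depth by construction, so "Temp is
  dropped" is a statement about parsimony under near-redundancy, not about
  temperature being ecologically irrelevant.
* The 1-D bathymetry, single transect and hourly snapshots mean spatial
  autocorrelation enters only through the smooth intensity surface; the
  Moran/Mantel diagnostics on the true model are thus expected to be
  negative, and their power is demonstrated by injecting structure, not by
  real schooling dynamics.

## A worked run

```r
library(echogam)

cfg <- scene_config(seed = 1)          # two 24-h surveys, 2000 m transect
survey <- sample_survey(cfg)
table <- process_survey(survey)        # blanking, thresholds, integration

res <- split_fit_validate(table)       # four families, day-1 fit / day-2
res$fitting                            #   predict, Table-2-style metrics
res$validation

m <- res$models$quasipoisson
shape_recovery(m, "Zpl", true_response()$g_zpl)

diag <- residual_autocorrelation(m, m$data, n_perm = 199, seed = 1)
hourly <- diel_tradeoff(table)
detect_thresholds(hourly$mean_F, n_perm = 199, seed = 1)
```

The README shows the numbers this produces under seed 1.
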