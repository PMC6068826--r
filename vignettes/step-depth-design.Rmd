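---
title: "Designing stair step depth from dynamic stability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing stair step depth from dynamic stability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stairsafe)
```

## The problem

Crowd stampedes in primary schools typically begin with a single child
falling on a staircase during a dense, synchronized descent. Whether a
descending child can keep their balance step after step depends on the
geometry of the stair — above all on the step depth (the "going", `d`) —
relative to the child's body size and descent speed. `stairsafe`
implements a complete analysis chain from per-student gait observations
(real or synthetic) to a growth-adjusted recommended range of step depth
for school buildings.

## The stability model

During single support the body is an inverted pendulum pivoting about the
stance ankle. The dynamic stability reference point is the extrapolated
centre of mass (XCoM): the CoM projection plus the horizontal velocity
divided by the pendulum eigenfrequency `omega0 = sqrt(g / l)`, where `l`
is the CoM-to-ankle distance. Per step, the projected CoM therefore
drifts forward by

```
delta = v * sqrt(l / g)      # delta_com()
```

relative to the tread it lands on. A fall threatens when the XCoM passes
the base of support, bounded in front by the anterior tread edge. Walking
down a flight of `N` steps, the centre of pressure (CoP) starts
`PFC + eta` from the first riser — `PFC` is the posterior foot clearance
(riser-to-heel gap) and `eta` the heel-to-CoP distance, the CoP sitting
at the midfoot/forefoot junction — and must still lie within the `N`-th
tread after `N - 1` steps:

```
PFC + eta + (N - 1) * delta <= N * d        # lower bound on d
```

Conversely, a tread so deep that the step-by-step strategy fails is
excluded by requiring the CoP to have cleared the `(N - 1)`-th tread
after `N` steps, with the foot (length `L`) flat on the tread:

```
(N - 1) * d <= PFC + L + N * delta          # upper bound on d
```

`sdp_lower_bound()`, `sdp_upper_bound()` and `sdp_range()` are these
closed forms; `simulate_descent()` is an independent step-by-step
discrete oracle that accumulates the CoP position iteratively and flags
each step, and the test suite checks exact agreement between the two
routes over large random parameter grids. Equality — CoP exactly on the
edge — counts as safe, matching the non-strict inequalities. The anterior
foot clearance (AFC) describes the initial posture (toes typically
overhang, AFC < 0); following the reference analysis it is fixed at 0 and
does not enter the bounds.

### Parameters, units, defaults

| symbol | meaning | unit | default | origin |
|---|---|---|---|---|
| `v`   | horizontal CoM descent speed | m/s | 0.88 (SD 0.08) | evacuation-scenario cohort mean |
| `l`   | pendulum length (CoM-ankle)  | m   | 0.81 (SD 0.09) | cohort mean |
| `L`   | foot length                  | m   | 0.224 (SD 0.02)| cohort mean |
| `eta` | heel-to-CoP-junction distance| m   | 0.11 (SD 0.01) | cohort mean |
| `PFC` | posterior foot clearance     | m   | 0.08 (SD 0.02) | paired-scenario mean, table precision |
| `g`   | gravity                      | m/s^2 | 9.81 | constant, configurable |
| `N`   | consecutive steps            | —   | 7..12 | survey of school flights |

The evacuation scenario supplies `v` because stampedes happen in crowds;
the paired scenario supplies `PFC` because crowded-descent clearances are
not observable directly and pairs are the closest observable condition.
The source tables report two precisions for the same quantities (e.g.
PFC 0.084 vs 0.08); the `policy` switch makes this explicit — `"table5"`
rounds the selected means to the reference table's two-decimal precision
(the default, for reproduction), `"section43"` keeps full precision.

## Interval estimation and the combination rule

Each continuous parameter is treated as normally distributed; with the
cohort of `n = 72` students the population mean is interval-estimated by
the two-sided Student-t interval `mean ± t_{alpha/2}(n-1) * sd / sqrt(n)`
at `alpha = 0.05` (`t_interval()`, `parameter_table()`). The t-quantile
comes from `stats::qt`. Rounding to 3 decimals is display-only.

`combine_subranges()` turns the intervals into a design range by
one-at-a-time sweeps: each of `PFC`, `eta`, `v`, `l` in turn is set to
its CI endpoints (and `N` to each integer in 7..12) with the others at
their sample means; both bounds are evaluated over the whole `N` range at
every sweep point. The design range is the envelope
`[max(lower-bound values), min(upper-bound values)]` — the depths safe
under every excursion considered. `L` enters the upper bound at its
sample mean only. A full-factorial sweep over all CI-endpoint
combinations is available (`sweep = "factorial"`); it is more
conservative, and one-at-a-time is the default because it mirrors the
per-parameter floating-range structure of the reference table.

Two documented inconsistencies of the published reference values matter
here, and the package reports rather than reproduces them:

* the published speed interval (0.711, 0.745) does not follow from
  0.88 ± 0.08 with n = 72 under the stated formula (it does not even
  contain the mean); the package recomputes (0.861, 0.899) and flags the
  discrepancy in `render_table5()` and in the pipeline warnings;
* the published overall maximum 0.250/0.282 pair is not reachable from
  the published per-parameter rows (their minimum upper value is 0.291).
  Under the package's rule the totals land within ~0.003 m (lower) and
  ~0.016 m (upper) of the published ones; `render_table5()` prints the
  computed and published values side by side so the residuals are always
  visible.

## Growth projection and recommendation

Children grow, buildings stay. `fit_trend()` fits ordinary least squares
lines to height and foot-length records; the shipped defaults are
0.4359 cm/year for height and 0.1629 cm/year for foot length (no raw
national growth series are bundled — the defaults are the published
coefficients, and `fit_trend()` exists for user-supplied series). Height
maps to pendulum length through the cohort regression
`l = (0.3484 * height_cm + 33.518) / 100` (`l_from_height()`; fitted on
121–151 cm children, extrapolation below ~100 cm warns). Over a service
horizon (default 30 years) `project_params()` advances height and `L` by
their slopes and recomputes `l` from the projected height as an anchored
increment; `v`, `PFC` and `eta` are held fixed, since no trend is
established for them (configurable). `project_design_range()` re-runs the
interval estimation and combination at each decade.

`recommend_range()` merges horizons: the lower bound comes from the
end-of-horizon projection (taller future pupils drift further per step),
the upper bound from the current range (present construction
constraints). Within the recommended interval the larger depth is
preferred as a reserve against behavioural deviations; the preference is
attached to the result.

## The synthetic cohort generator

`generate_cohort()` / `generate_trials()` emulate the study conditions so
the full chain is testable without the original raw data:

* grade-stratified anthropometrics, 12 students per grade for grades 1–6,
  truncated-normal (at zero) per-grade distributions with the published
  means and SDs; `eta < L` is enforced by redraw. The published height
  table mixes scales implausibly ("0.121 ± 5.3" m); defaults use
  121–151 cm means, the grade-1 SD as 5.3 cm and the others as 3–8 cm,
  and the grade-5 foot-length SD as 0.017 m (the printed 0.17 m is seven
  times every other grade). All of this is configuration, not code.
* scenario-dependent descent speeds: alone 0.91 ± 0.13 m/s, paired
  0.82 ± 0.10 m/s (midpoint of the three observed site means), evacuation
  0.88 ± 0.08 m/s.
* foot clearances: PFC centred near 0.1 m (alone 0.094, paired 0.084),
  AFC centred slightly below zero; AFC is plain normal because negative
  values are meaningful.
* within-descent pauses only in the evacuation scenario: each inter-step
  interval independently carries a pause with probability 0.3, pause
  lengths 0.5 ± 0.2 s (truncated at zero). These three values are not
  published anywhere; they were fixed once as a plausible "subtle pause"
  scale for crowded stair descent.

Crossing times accumulate one dwell `d / v` per inter-step interval plus
any pauses. The step count in the speed formula `v = N d / (T - Tp)` is
the number of inter-event intervals, which makes speed recomputation on
pause-free trials an exact round trip. Pause time is removed only for
evacuation trials; descents alone and in pairs are continuous by
convention (`Tp = 0`). When pause times are not recorded (e.g. trials
read back from CSV), `detect_pauses()` scores the excess of each dwell
over a 0.8 s threshold — roughly mean dwell plus two SDs under typical
speeds — a definition this package had to fix because "subtle pause" is
not operationalised in the source. Threshold detection recovers only the
pause time in excess of the threshold, so pipelines that need unbiased
speeds should keep the generator's recorded pause times (the default,
`pause_handling = "recorded"`).

What the generator does *not* emulate: inter-subject correlation between
speed and body size, site-level speed differences within a scenario,
fatigue or learning across trials, and any video measurement error. A
passing parameter-recovery test therefore shows the estimators are
consistent with the generator's assumptions, not that real playground
data are this clean.

## Numerical choices

* All randomness flows from explicit integer seeds; cohort and trial
  streams are separated by deterministic seed offsets, and two runs of
  `run_pipeline()` with the same config produce byte-identical artifacts.
* Truncated normals use rejection by redraw — exact, and trivially fast
  for the mean/SD ratios involved here.
* Tie-break: CoP exactly on a tread edge is safe (non-strict
  inequalities throughout).
* Degenerate inputs: zero SDs give point distributions and zero-width
  intervals; single-trial groups report SD 0 with a `degenerate` flag and
  a warning; constant growth series report slope 0, R^2 0 with a flag.
* Display rounding is 3 decimals for metres and 2 for degrees; internal
  arithmetic is double precision end to end.
* Test problem sizes: the simulator/closed-form agreement sweep uses
  10,000 random parameter tuples; distributional-fidelity checks use a
  10,000-student grade; t-interval coverage uses 5,000 replicates of
  n = 20 samples. Each completes in seconds.

## A worked run

```{r pipeline, eval = FALSE}
report <- run_pipeline(pipeline_config(cohort = cohort_config(seed = 1)))
report
render_table5(report)
```

The report prints the current design range, the projection at the end of
the service life, the recommended interval with the preferred (larger)
value, and a per-site audit verdict for the three surveyed staircases.

## Known limitations

* The model is sagittal-plane single support only: no double support, no
  mediolateral balance, no handrail forces (the underlying trials
  prohibited handrail use).
* The published totals are reproduced approximately, not exactly; the
  residuals are reported, and the inconsistencies that cause them are
  documented above.
* Growth projection is linear; puberty spurts and cohort percentile
  structure are out of scope.
* The cohort describes primary-school students from one region;
  applying the defaults elsewhere means re-measuring the anthropometric
  and gait inputs.
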