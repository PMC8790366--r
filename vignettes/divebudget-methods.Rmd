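---
title: "Methods: from accelerometry to minimum dive-success rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from accelerometry to minimum dive-success rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divebudget)
```

`divebudget` estimates, for a plunge-diving seabird, the minimum fraction
of dives that must capture prey for the bird to meet its energetic
demands. This vignette documents the model at each stage, the tunable
parameters and their defaults, the numerical and design choices that were
genuinely open, what the synthetic-data generator does and does not
emulate, and the package's known limitations.

## Behaviour classification

Dives and take-offs are detected from 50 Hz tri-axial accelerometry
(units of g; X = surge, Y = sway, Z = heave) by thresholding centred
running statistics.

* **Dive start**: running mean of X over `mean_window_s` (default 2 s)
  below `dive_mean_x_max` (0 g) *and* running SD of X above
  `dive_sd_x_min` (1.4 g). The SD is taken over the raw X axis on the same
  2 s window as the mean: the threshold scheme names the window only for
  the mean, and applying the same window to the SD is the most economical
  reading; both windows are independently configurable
  (`sd_window_s`).
* **Dive end**: the "1 s lagged maximum of pitch change" within 60 s of
  the start. Pitch is not defined by the thresholding scheme itself, so
  the package uses the standard surge-axis inclination,
  `asin(static_X / ||static vector||)` in degrees, with the static vector
  estimated by the 2 s running mean; pitch change is evaluated at 1 s
  spacing. The "lag" admits two readings — offset the argmax time by 1 s
  (`dive_end_mode = "offset"`, the default, the most literal reading) or
  lag the pitch-change series before maximising
  (`"lagged_series"`) — and both are exposed. When no pitch extremum is
  available the dive is closed at the 60 s horizon and flagged.
* **Take-off**: from the dive end, starts at SD(Z) > 1.8 g and
  SD(X) > 1.0 g, ends when both SDs fall below 1.4 g. A dive with no
  take-off within `takeoff_horizon_s` (120 s) is flagged and costed over
  the dive alone.
* **Refractory rule**: a new dive cannot start before the previous dive's
  take-off has ended (or its horizon lapsed). Without it, one plunge can
  fragment into several events.
* **Dive type**: dives shorter than 5 s are plunge dives, the rest
  pursuit dives; the boundary value is assigned to pursuit by convention
  (durations are continuous, so the assignment is measure-zero).
* **TDR validation**: accelerometer dive starts are matched one-to-one to
  the times at which depth first exceeds the recorder's trigger threshold
  (0.5 or 1 m), greedily by time difference within `tdr_match_tol_s`
  (5 s). This automates what is usually a manual visual comparison; the
  tolerance is configurable.

Running statistics are computed within dropout segments only: any time
step larger than twice the sampling interval opens a new segment, so
logger gaps cannot fabricate threshold crossings. Edge samples shrink to
the largest available symmetric window; a segment shorter than the window
is flagged unusable. The detected dive end (pitch-argmax plus lag)
systematically exceeds the true surfacing time by roughly one second; this
matters when interpreting detected durations near the 5 s type boundary
(see the generator section).

## Energetics

VeDBA (vectorial dynamic body acceleration) is the Euclidean norm of the
gravity-removed axes, where gravity is the 2 s running mean
(`static_window_s`). Per-second VeDBA is the per-sample sum divided by the
sampling rate, in g-seconds; any accumulation convention differing by a
constant factor cancels through the calibration below, a property the
tests assert at machine precision. Seconds with under 50% sample coverage
are treated as missing and excluded from daily sums.

The conversion to kilojoules rests on three assumptions: (i) energy spent
on movement over a complete 24 h period equals the activity energy budget
AEE = FMR − BMR; (ii) zero VeDBA costs zero kJ; (iii) the kJ–VeDBA
relationship is linear. The individual gradient is then
`k = (FMR − BMR) / mean(VeDBA24)`, the line through the origin and the
bird's mean daily VeDBA total. Complete 24 h periods are aligned to
deployment start rather than calendar midnight, which maximises usable
periods for deployments of a few days; birds with no complete period are
excluded from energy analyses and flagged.

BMR and FMR come from allometric configuration
(`allometric_defaults()`): `BMR = a * mass_kg^b` and
`log10 FMR = b0 + b1 log10(mass_g) + b2 |latitude|`. The shipped
coefficients (`a = 381.8`, `b = 0.721`; `b0 = 1.02`, `b1 = 0.65`,
`b2 = 0.0049`) follow the functional forms of published seabird
allometries and give realistic magnitudes for a 2.7–3.0 kg gannet at
52°N — BMR near 780 kJ/day and FMR near 3.2–3.5 MJ/day — but they are
deliberately configuration, not code: users reproducing a specific study
should transcribe that study's coefficients. Construction fails unless
FMR > BMR across the 2–3.5 kg study range, which guards against sign and
unit errors.

Costs and demand:

* each prey-capture attempt costs `k × ΣVeDBA` over the half-open span
  from dive initiation to take-off completion (half-open so sums are
  additive over partitions);
* trip expenditure adds BMR prorated over the (fractional) tracking
  interval to the movement energy `k × ΣVeDBA`;
* total energetic demand (TED) adds the bird's share of the daily demand
  of a four-week-old chick, 1397.14 kJ/day, split 60% to females and 40%
  to males (`demand_defaults()`). Holding expenditure equal, female and
  male per-day TED differ by exactly 0.2 × 1397.14 kJ — the mechanism
  behind the sex difference in daily demand.

## Diet from stable isotopes

Prey sources are reduced to species recorded in **more than** 3% of the
historical diet (strict inequality), and δ¹³C is lipid-normalised from the
C:N ratio with a configurable linear-log correction
(`d13C + b0 + b1 log(C:N)` above a lipid-free threshold of 3.5, identity
below); the default coefficients are of the published family for fish
muscle and should be replaced by the variant matching the tissue.

The mixing model is a classic Bayesian stable-isotope mixing model with
fixed group structure: for group *g* and isotope *j*,

    x ~ Normal( sum_i p_gi (mu_ij + lambda_j),
                sqrt( sum_i p_gi^2 (sigma_ij^2 + tau_j^2) + xi_j^2 ) )

with discrimination mean/SD `lambda, tau` (defaults 2.25 ± 0.61‰ for
δ¹⁵N, 0.24 ± 0.79‰ for δ¹³C), a flat Dirichlet(1) prior on each
proportion vector (the conventional uninformative choice), and a
half-normal(5‰) prior on the residual SDs `xi_j`, which are shared across
groups; `residual = "process_only"` fixes `xi = 0`. Covariates are
implemented as fixed groups (one simplex per sex, year or sex × year
cell) rather than a continuous-covariate regression with random effects:
groups reproduce sex-by-year diet predictions at a fraction of the
machinery, and individual-level random-effect structures are out of
scope.

Sampling is blockwise adaptive random-walk Metropolis on
softmax-transformed proportions (one block per group, plus one for the
log residual SDs), with proposal scales adapted during burn-in towards
30% acceptance. Desk-scale defaults are 3 chains × 20,000 iterations
(5,000 burn-in, thinning 10); hours-scale settings can be configured.
Convergence is summarised by the Gelman–Rubin statistic for every
reported parameter and the fit is flagged (with a warning, never an
error) when any R̂ exceeds 1.05. The tests cross-check the sampler
against an independent grid-integration oracle on two-source problems,
so the posterior is validated by a second numerical route.

Covariate structures are ranked by WAIC computed from the pointwise
log-likelihood — the same asymptotic target as leave-one-out
cross-validation without importance-sampling machinery — and converted to
weights `w ∝ exp(−Δ/2)` over the candidate set; model comparison refuses
candidates fitted to different consumer data.

The kilojoule intake value (KIV) of one successful dive is the
diet-proportion-weighted mean of per-prey assimilable energy, with gross
energies discounted by the 76.1% assimilation efficiency and a successful
dive assumed to capture exactly one prey item.

## Demand, success rates and inference

`successful_dives_needed = TED / KIV` and
`min_success_pct = 100 × needed / n_dives`; the fractional count is
deliberately **not** rounded up before the percentage, matching the
arithmetic of the published per-bird table. Sex summaries are unweighted
per-bird means and SDs (not day-weighted), which is the convention that
reproduces the published sex-level statistics exactly; unknown-sex birds
are excluded from all sex contrasts. When a trip table arrives with a
printed per-day TED column, that column is retained rather than
recomputed from the rounded day lengths, which carry less precision.

The inferential layer mirrors standard practice: a Mann–Whitney–Wilcoxon
test with exact enumeration when the smaller sample has ≤ 8 observations
(the enumeration permutes observed ranks, so it remains valid under ties,
which is why it is implemented here rather than delegated) and a
tie-corrected normal approximation otherwise, with rank-biserial effect
size; a Welch t-test (the fractional degrees of freedom reported in this
literature indicate Welch); linear mixed models for per-attempt cost with
a random intercept per bird, fitted by **maximum likelihood** so AICs are
comparable across fixed-effect structures (a REML refit of the averaged
set is out of scope); all-subsets candidate generation respecting
marginality; retention within 6 AIC units of the best model; and
**conditional** ("natural") averaging — each term averaged over the
models that contain it — matching the conditional summaries this
literature reports, with both the square-root-of-weighted-variance SE and
the adjusted (weighted-average-of-roots) SE.

One published statistic is reported but not resolved: the dive-rate
F-test's printed subscript (13) does not match the error degrees of
freedom expected from 13 birds in a one-way model (1, 11). The package
computes and reports the standard (1, n − 2) test.

## The synthetic-data generator

`simulate_deployment()` emulates the study conditions as defaults: 14
birds (5 female, 8 male, 1 unknown), female mass 2.99 ± 0.15 kg and male
2.70 ± 0.19 kg, 3.7-day deployments, dive rates near 26/day (females) and
17/day (males), 24% pursuit dives, 50 Hz accelerometry, 4 Hz depth with a
0.5 m trigger. Each bird's random substream is derived by a stable hash
of its identifier, so results do not depend on simulation order.

Regime amplitudes (rest, flapping flight, dive, take-off) are
**synthetic**: no published amplitude statistics exist for these
behaviours, so levels are calibrated only to realise the classifier's
threshold contrasts — e.g. the dive regime carries an 8 Hz oscillation of
2.2 g on X about a −0.8 g static level, giving a running SD near 1.56 g
and a running mean below 0 g, while keeping the gravity estimate clean so
pitch transitions at entry and exit are sharp. Dive durations are drawn
from a two-component lognormal with modes at 2.0 s (plunge) and 8 s
(pursuit), giving a bimodal distribution with a trough at 5 s. The
plunge mode sits at 2.0 s rather than nearer the split because the
classifier's lagged dive-end definition lengthens detected durations by
about one second; with a 2.5 s mode an appreciable share of true plunges
would cross the 5 s boundary after the lag, violating the generator's own
contract that type assignment agrees with ground truth for at least 98%
of detected dives. Ground-truth type is the generating component, not a
threshold on the realised duration.

What the generator does **not** emulate: hydrodynamics, sea-swell
contamination of the acceleration signal, wind and wave noise beyond
stationary Gaussian-plus-sinusoid regimes, GPS movement, prey patchiness,
or any correlation between dive success and dive type. Passing classifier
tests on this generator therefore demonstrates that the thresholds and
event logic are implemented correctly, not that the thresholds themselves
are optimal for any particular field dataset.

`simulate_isotopes()` draws consumers from the mixing model's own
likelihood at known proportions, which makes posterior recovery scoring
exact but also means recovery tests validate the sampler, not the model's
adequacy for real tissues (no isotopic routing, turnover lag, or
concentration dependence).

## Numerical choices and problem sizes

* Running statistics use cumulative sums (O(n)); sample SDs need at least
  two points, so single-point edge windows are `NA`.
* Pitch at zero static magnitude is undefined and carried forward.
* Per-second VeDBA bins are half-open `[t, t+1)`; event spans are
  half-open so costs are additive over partitions.
* The Metropolis sampler proposes Gaussian steps on the unconstrained
  scale; the Dirichlet(1) prior enters through the softmax Jacobian
  `sum(log p)`, and the residual SDs through a log transform with its
  Jacobian.
* Weights are computed as `exp(-delta/2)` after subtracting the best
  criterion value, so they are invariant to constant shifts and immune to
  underflow for any retained model.
* Tests and the acceptance script run at deliberately modest problem
  sizes chosen to exercise every code path while keeping the whole suite
  in minutes: 25-minute deployments with 12 dives (20 seeds) for
  classifier recovery, 500 dives for the pursuit-fraction check, 30
  consumers and 3 × 6,000-iteration chains for mixing-model recovery, 50
  consumers per replicate for model selection. The published "long" MCMC
  settings (3 chains × 300,000, thinning 100) remain available through
  `mcmc_settings()`; the printed burn-in for those settings exceeds the
  chain length in the source material, evidently a transcription
  artefact, so both are left as ordinary configuration values.

## Known limitations

* The calibration assumes **all** acceleration is movement; periods of
  rest on a swelling sea inflate VeDBA and are not filtered.
* BMR and FMR are population-level allometric predictions driven by mass
  (and latitude); inter-individual and sex-specific metabolic variation
  beyond mass is ignored, so the approach suits groups of birds rather
  than individual-level inference.
* Success rates are **minima**: a bird catching more than one prey item
  per successful dive, or surplus-feeding its chick, breaks the
  one-prey-per-dive assumption in a conservative direction.
* The mixing model's fixed-group covariates cannot express
  individual-level random effects; the WAIC ranking is a LOO surrogate,
  not an exact replication of importance-sampled LOO.
* Logger clock drift between accelerometer and TDR is not modelled; the
  reader exposes a per-bird time offset instead of guessing.
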