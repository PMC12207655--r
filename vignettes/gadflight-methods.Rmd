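---
title: "From raw biologger streams to petrel activity budgets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw biologger streams to petrel activity budgets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gadflight` turns the three raw data streams produced by miniature
multi-sensor loggers on pelagic seabirds — 25 Hz tri-axial acceleration,
1 Hz depth, and GPS fixes — into behavioural ethograms, dive records, diel
activity models and foraging-trip metrics. The target system is a
central-place forager in the *Pterodroma* mould: a highly aerial petrel
that commutes hundreds of kilometres from a breeding colony, feeds at or
near the sea surface, and divides its time among burrow attendance,
sitting on the water, and two very different flight styles (dynamic
soaring and flap-gliding). This vignette explains each model in the
package, the tunable parameters and their defaults, what the synthetic
data generator does and does not emulate, and the numerical choices made
where the design was genuinely open.

## Accelerometer metrics

Raw tri-axial acceleration mixes two signals: the orientation of the bird
relative to gravity (the *static* component) and the accelerations it
generates by moving (the *dynamic* component). `decompose()` estimates the
static part of each axis as a centred moving mean over a 1-s window
(`window`, seconds) and defines the dynamic part as the remainder, so that
`static + dynamic` reconstructs the raw axis exactly at every sample.
Window alignment is centred and edge samples use truncated windows; this
keeps the metric series the same length as the trace, at the cost of
slightly noisier static estimates in the first and last half-window. The
1-s default is the convention for 25 Hz seabird loggers; whether the
smoothing window for the static estimate should be 1 s or 2 s varies
between labs, so it is exposed as a parameter rather than hard-coded.

From the components the package derives:

* **pitch** `= atan2(static_surge, sqrt(static_sway^2 + static_heave^2))`
  and **roll** `= atan2(static_sway, static_heave)`, in degrees. The axis
  order and sign conventions are fixed and documented (surge forward,
  sway right, heave dorsal); a bird sitting level reads (0, 0).
* **VeDBA**, the norm of the three dynamic components — an intensity-of-
  movement proxy; **VeSBA**, the norm of the three static components —
  close to 1 g at rest or in linear motion and fluctuating above 1.5 g in
  the banked, wind-energy-harvesting turns of dynamic soaring.
* **wingbeats**: local maxima of heave acceleration above `amp_threshold`
  (default 1 g, measured as the signal value at the peak against the
  ~1 g gravity baseline, not peak prominence — configurable), chained
  into bouts when successive peaks arrive at ≥ `min_rate` (default 4 Hz,
  i.e. inter-peak interval ≤ 0.25 s), keeping bouts of at least
  `min_successive` (default 2) peaks. Detection runs on raw heave by
  default (dynamic heave is available as an option). Peak finding uses
  `pracma::findpeaks`; bout chaining is the package's own.

## Dive analysis

Depth is recorded at 1 Hz with 0.005 m resolution, and the pressure
sensor's zero drifts slowly with temperature. The processing chain is:

1. **Outlier repair** (`repair_outliers`): isolated readings deeper than
   `max_plausible` (default 15 m — such spikes would imply vertical speeds
   far beyond a surface-feeding petrel) are replaced by linear
   interpolation. The rule is a pure magnitude threshold; a rate-of-change
   criterion would be an alternative reading and is noted as such.
2. **Zero-offset correction** (`zero_offset_correct`): the surface is
   estimated as the rolling 10th percentile of depth over a centred 10-min
   window (truncated at the edges, linear-interpolation quantiles) and
   subtracted; corrected values below 0 m are clamped to 0 m. Subtracting
   a rolling quantile makes the correction exactly invariant to any
   constant offset in the raw record.
3. **Dive detection** (`detect_dives`): a dive is a maximal run of samples
   at or deeper than 0.5 m; a single-sample run counts as a 1-s dive.
   Depth histograms (`depth_histogram`) use half-open 0.1 m bins.
4. **Pitch profiles** (`dive_pitch_profile`): surface dives show a
   sigmoidal pitch signature — a sharp drop below about −20° bracketed by
   near-level posture; the function flags whether that pattern is present
   around a dive.

The order (repair, then correction, then detection) matters: a 20 m spike
inside a 10-min window would otherwise drag the rolling percentile.

## Behaviour classification

The ethogram has nine classes in three modes: `burrow-still`,
`burrow-stirring`, `burrow-active`; `water-inactive`, `water-active`,
`water-intensive`; `flying-dynamic-soaring`, `flying-flap-glide`,
`flying-intensive`. Classification works on 15-s segments. Each segment is
summarised by 36 features: mean, inter-quartile range, 10th and 90th
quantile (linear-interpolation quantiles) of eight per-sample metrics
(dynamic surge/sway/heave, raw heave, pitch, roll, VeDBA, VeSBA), plus
mean raw surge, mean raw sway, mean temperature and the wingbeat count.
This map guarantees the predictors that dominate separation in practice
(mean VeDBA, 90th-quantile VeDBA, mean dynamic sway, mean dynamic heave,
IQR heave) exist by construction; the map is configurable.

`train_classifier()` implements the full supervised workflow:

* stratified 50/50 train/validation split (by class, and by class x bird
  when every cell has at least two segments);
* random grid search over 18 sampled combinations of `min.node.size`
  (1-20), `mtry` (2-p) and split rule (gini or extratrees), scored by
  repeated cross-validated Cohen's kappa (5 repeats of 10 folds), with
  minority classes up-sampled *inside each training fold only* — the
  leakage-safe reading of "up-sampling within the training data";
* recursive feature elimination: per fold, features are ranked by
  permutation importance of a full model and the forest is refit at
  subset sizes {4, 8, 12, 14, 18, 24, 30, 36}; the smallest subset whose
  cross-validated kappa is within 1% of the best is kept;
* a final `ranger` forest refit on the selected features.

Tuning and RFE use 100 trees and the final refit 500; forest size is not
a reported hyperparameter in this workflow and tuning with a smaller
forest is standard practice. Everything is deterministic given the config
seed, including the sampled grid.

Evaluation (`evaluate_classification`) reports overall accuracy with an
exact Clopper-Pearson binomial interval (the interval family is stated
because normal approximations differ at these sample sizes), Cohen's
kappa from the confusion-matrix marginals, and one-vs-rest precision,
recall and balanced accuracy per class. `collapse_modes()` maps the nine
classes onto burrow/water/flying; because within-mode confusions become
correct under the collapse, mode-level accuracy can never be lower than
class-level accuracy on the same predictions.

## Diel activity model

Hourly at-sea activity budgets (`hourly_budget`) are proportions of each
at-sea class over UTC clock hours, keeping hours with at least 50% at-sea
coverage (configurable: hours mixing burrow and sea time can either be
dropped or renormalised over the at-sea seconds; the default renormalises
within hours that pass the coverage threshold). The light covariate is
the solar elevation (radians) at the hour midpoint evaluated at the
colony: at this latitude the elevation differs by well under 0.001 rad
across a foraging range several degrees of longitude wide, so a single
reference location suffices. `sun_angle()` implements the standard
NOAA-style solar-position geometry (mean longitude and anomaly, equation
of time, declination, hour angle) and is tested against an independent
Astronomical Almanac routine to within 0.005 rad.

Hourly proportions are zero-inflated: a behaviour either does not occur
in an hour at all, or occupies a continuous fraction of it. `fit_zib()`
therefore maximises the joint likelihood of a two-part model: with
probability `pi(x) = plogis(g0 + g1 x)` the proportion is exactly zero;
otherwise it is Beta-distributed with `logit mu(x) = b0 + b1 x` and
precision `phi`. Proportions exactly equal to 1 are squeezed onto the
open interval by `y' = (y(n-1) + 0.5)/n` (the beta support is open; the
handling of exact ones must be stated explicitly because it is otherwise
an invisible choice). Optimisation is BFGS from moment-based starts with
a 1e-12 relative tolerance, standard errors come from the numerical
Hessian, and with no shared parameters the joint optimum provably equals
a Bernoulli GLM plus a separate beta fit — an identity the tests check to
1e-6. `predict_curves()` returns the occurrence probability `1 - pi(x)`,
the conditional proportion `mu(x)` and their product with delta-method
bands, and `leave_one_bird_out()` refits excluding each bird to check
that no single track drives the estimates.

A deliberate simplification: the fully specified field model would give
each bird random intercepts *and* slopes plus first-order autoregressive
errors. Those structures need more birds and longer series than a
desk-scale, recovery-testable implementation warrants, so the package
offers optional per-bird intercept offsets (sum-to-zero fixed effects) in
both submodels and omits the AR1 term. Consequences: standard errors are
mildly optimistic when hours are strongly autocorrelated, and bird-level
slope heterogeneity is absorbed into the residual. The leave-one-bird-out
diagnostic is the practical guard against the latter.

## Trip analysis

`segment_trips()` defines a foraging trip as a maximal run of GPS fixes
farther than 1 km from the colony (removing on-land positions and
near-colony rafting); a trip is complete when bracketed by within-radius
fixes on both sides, and its duration runs from the first to the last
at-sea fix. Distances are haversine on a sphere of radius 6371.0088 km
(the mean Earth radius; no particular geodesy is implied by the data).
Trips of at least 2 days are flagged "long" — the threshold cleanly
separates multi-day foraging excursions from brief near-colony trips in
the reference deployments and is configurable. `trip_summary()` reports
mean and sample SD (n−1). `exclusion_filter()` additionally drops fixes
within 50 km for distribution-level analyses. The colony used in examples
is Nonsuch Island, Bermuda (32.3333° N, 64.6667° W).

## The synthetic logger simulator

Every downstream stage is testable without field data because the package
ships generators for all three streams plus ground-truth labels.

**Accelerometer** (`gen_accel`): each class has a parametric signature —
resting posture, deterministic posture oscillations, smooth pseudo-random
drift (a sum of three low-frequency sinusoids, not white noise), an
oscillation of the gravity-vector norm (driving VeSBA fluctuations), axis
oscillations, a wingbeat pulse train, per-axis white noise, and a
temperature level (28 °C in the burrow versus 18 °C at sea; the burrow
level is not published anywhere we know of, so it is a configurable
default chosen to make the temperature channel informative). Defaults
are hand-tuned so that every class satisfies its qualitative movement
criteria in ≥ 95% of 15-s windows when passed through `compute_metrics()`
— e.g. burrow-still has near-zero VeDBA, dynamic soaring has VeSBA peaks
above 1.5 g with no wingbeat bouts, flap-glide contains bouts of ≥ 3
successive wingbeats. Two numerical points deserve mention. First,
flying-class heave carries *no* white noise: any additive white noise on
a slow crest above 1 g creates dense spurious local maxima that the
wingbeat detector would chain into phantom bouts; smooth sinusoidal
components keep the heave channel locally monotone between true peaks.
Second, burrow-still is given a slightly pitched-and-rolled resting
posture so its raw heave stays safely below the 1 g wingbeat threshold.

**Depth** (`gen_depth`): bounded smooth drift (default up to 0.49 m, the
upper end of zero offsets seen on these loggers), parabolic dive
excursions at scheduled times, Gaussian noise, quantised to 0.005 m.

**Diel behaviour** (`gen_diel_sequence`): for each clock hour, each
at-sea class draws its share of the hour from a zero-inflated beta
generator evaluated at the hour-midpoint sun angle; shares are
renormalised to sum to one and laid out as shuffled bouts (default mean
length 90 s). Renormalisation leaves each class's *occurrence* (zero
versus non-zero) exactly governed by its zero-inflation submodel, which
is what the parameter-recovery tests exploit. The generator is hour-level
rather than a per-second Markov chain: a Markov chain with sun-modulated
transitions cannot be constrained to hit configured zero-inflated-beta
hourly marginals, and recoverable marginals are the property the
downstream model needs. The default coefficients are the fitted diel
estimates for incubating Bermuda petrels (flight more likely and longer
at night, water behaviours during the day); by construction of that
model they reproduce an activity budget of roughly 80% of at-sea time in
flight dominated by dynamic soaring. The cost of this design is
unrealistic within-hour microstructure: real bout-length distributions
and serial dependence are not emulated, so tests passing on synthetic
data say nothing about autocorrelation-sensitive inference.

**GPS** (`gen_track`): a smooth parametric out-and-back loop — radial
profile `r(s) = peak * sin(pi s)^1.3` with a wandering bearing — rather
than a biased correlated random walk, because the generator must
*guarantee* its contract (departure and return within 1 km of the colony,
maximum range within 10% of the configured value) and a random walk
cannot. Loop shape is therefore stylised; only range, duration, cadence
and completeness are faithful.

**Seeds**: one global seed expands to per-stream sub-seeds by a fixed
documented rule (`stream_seed`), so streams are independently
reproducible and a rerun of `gen_logger_dataset` is byte-identical.

## What the tests do and do not show

The test suite validates the machinery: exact identities (conservation,
offset invariance), agreement with independent oracles (brute-force peak
counting and kappa, an independent almanac solar routine, a two-stage
likelihood fit, an established mixed-model package on shared cases), and
parameter recovery on data whose generating process is known. Problem
sizes were chosen at desk scale: classifier checks use 200 segments per
class over four synthetic birds, diel recovery uses 2000 hourly records
per replicate over 100 replicates, dive checks use six-hour deployments.
Because the synthetic classes are generated from well-separated
signatures, classifier accuracies near 1 on synthetic data are expected
and say nothing about accuracy on field data, where class boundaries are
genuinely ambiguous (especially the rare, heterogeneous
`flying-intensive` class). What the synthetic results do establish is
that the workflow — splitting, fold-internal up-sampling, tuning, RFE,
evaluation — is implemented correctly and deterministically.

## Known limitations

* No AR1 error structure or random slopes in the diel model (see above).
* Wingbeat detection on raw heave with an absolute threshold will flag
  incidental peaks for water classes whose heave hovers near 1 g; on
  synthetic data this is harmless (other features separate the classes),
  on field data the prominence-based option may be preferable.
* The simulator does not emulate wind, currents, prey fields, moonlight,
  magnetometer channels, or logger failure modes.
* Trip segmentation assumes fixes are dense enough that the 1 km
  bracketing fixes exist; sparse GPS duty cycles can turn a complete trip
  into an apparently incomplete one.
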