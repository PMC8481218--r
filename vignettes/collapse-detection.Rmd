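---
title: "Detecting community collapses in ordered abundance series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting community collapses in ordered abundance series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collapsescope)
```

## The problem

Paleoecological and paleolimnological records — benthic foraminifera through
the Cretaceous–Paleogene boundary, nannofossils across Early Miocene
glaciations, diatoms in warming Arctic lakes — preserve community collapses:
intervals in which the dominant taxon of an assemblage loses its dominance
to a successor, usually after one or more abrupt environmental events. Such
records are short (tens of samples), compositional (relative abundances
closing to 100%), and ordered by depth or age rather than by even time
steps. `collapsescope` implements a pipeline for these data:

1. **Zonation**: temporally constrained agglomerative clustering splits the
   ordered series into contiguous community zones.
2. **Boundary placement**: a dominance rule locates the collapse-zone
   boundary, letting the abundance record overrule the dendrogram when the
   dominance turnover precedes the cluster break.
3. **Indicators**: a univariate suite (total abundance, species richness,
   across-taxon standard deviation, rolling-window lag-1 autoregression,
   dominant-species relative abundance, taxon ratios) is computed along the
   axis.
4. **Signal detection**: each indicator is smoothed by loess; points outside
   a pointwise confidence band are *small-scale signals*, persistent trend
   or slope changes of the fitted curve are *large-scale signals*.
5. **Event classification**: co-occurring signatures are combined by a
   quorum rule into *pulse* (one-sample perturbation) and *step*
   (persistent shift) event calls with an auditable evidence ledger.

A labelled simulator (`simulate_community()`) generates series with the same
statistical structure plus ground truth, so every stage is testable without
external data.

## Data model

`community_ts()` holds a strictly monotonic axis, a samples-by-taxa matrix of
counts and/or relative abundances (percent), and a missing-cell mask. Two
conventions matter:

* **Orientation.** Analyses run oldest-to-youngest. Calendar-year axes
  increase; age (Ma) and depth (mbsf) axes decrease, because larger values
  are older. `read_community_table()` sorts accordingly, so "before the
  collapse" always means earlier time.
* **Closure tolerance.** Fully observed percent rows must sum to
  100 ± 0.5%: published tables are rounded to 0.1–1%, so exact closure
  cannot be demanded. Duplicated axis positions are an error rather than
  being averaged — zonation presumes a strict order.

Missing cells are filled by `interpolate_missing()`: per-taxon linear
interpolation against the *axis coordinate* (not the row index), with
nearest-value fill at the edges. Interpolating against the axis keeps the
operation honest under uneven stratigraphic spacing; rows that contained
gaps are exempted from the closure check afterwards, since per-taxon
interpolation does not preserve closure.

## Constrained clustering and zone cutting

`constrained_upgma()` is textbook average linkage (UPGMA: inter-cluster
distance is the arithmetic mean of all cross-pair Euclidean distances
between the samples' percent vectors), restricted so that only temporally
adjacent blocks may merge. Distances are computed on unstandardized percent
values. The implementation maintains distances with the exact Lance–Williams
update; the test suite checks it against an independent oracle that
recomputes every adjacent pair's full cross-pair average at every step.
Ties in candidate height merge the left-most (oldest) pair first, making the
tree deterministic.

Constrained trees can contain height reversals (a later merge lower than an
earlier one), so "cut at a height" is not always well defined.
`cut_zones()` therefore splits top-down: starting from the root, it
repeatedly undoes the highest merge among the current subtree tops (ties:
the later merge first). For monotone trees this equals undoing the k−1
highest merges, it remains well defined under reversals, and it makes cuts
nested in *k* — a property the tests assert.

One-sample perturbations appear in these trees as singletons that join at
unusually large heights. `detect_tree_outliers()` flags a sample when it
merges as a singleton above `factor` (default 2) times the median merge
height — a scale-free criterion, since absolute heights depend on the units
and richness of the record.

## Dominance and the collapse boundary

The per-sample dominant is the row-wise argmax (ties: first column in the
table); a zone's dominant is the taxon with the highest mean percent over
the zone. `collapse_boundary()` applies the dominance rule:

* zones sharing the first zone's dominant are all *pre-collapse*, even when
  the dendrogram separates them;
* the collapse zone starts at the first zone whose dominant differs;
* if the per-sample record shows the collapse dominant overtaking the old
  dominant strictly earlier — persisting up to the cluster break — the
  boundary moves to that sample (the abundance record outranks the
  dendrogram);
* later zones with yet another dominant are tagged *recovery*; trailing
  zones that keep the collapse dominant stay *collapse*.

Two refinements proved necessary. Single-sample zones that are dendrogram
outliers are treated as event samples, not communities, and are skipped when
scanning zone dominants — otherwise a strong pulse sample can masquerade as
a one-sample "collapse zone". And when the analyst does not fix the zone
count, `choose_zone_count()` picks the smallest *k* (up to 6) attaining the
*maximum* number of distinct zone dominants over the scan, rather than the
first *k* showing any change: in records with a strong recovery phase the
coarsest dominance contrast can be the recovery turnover, which would
otherwise hide the earlier collapse.

## The indicator suite

* `total_abundance()` — individuals per sample; requires counts, because
  percentages carry no information about assemblage size.
* `species_richness()` — taxa strictly above a presence threshold
  (default 0).
* `cross_sd()` — the sample standard deviation (divisor m − 1) of percent
  values *across taxa* within each sample, computed without any rolling
  window; masked cells are excluded and rows with fewer than two observed
  taxa are invalid. This row-wise reading is the only one that yields a
  series without a window.
* `rolling_ar1()` — for each right-aligned window (default 20 samples) the
  OLS slope, with intercept, of the value at *t* on the value at *t − 1*
  over the window's consecutive pairs; values before the first complete
  window and degenerate (zero lag-variance) windows are masked.
  Right-alignment means only past data inform each value. Lag-1
  autocorrelation rising toward a transition is the classic
  critical-slowing-down (CSD) indicator.
* `dominant_rel_abund()` and `species_ratio()` — pure projections of the
  matrix; a zero denominator masks the ratio at that sample.

The AR(1) target series is configurable; the pipeline default is the
pre-collapse dominant's percent series, with total abundance as the
alternative when counts exist. The window is clamped to the series length
for very short records, in which case estimates exist only at the final
sample.

## Loess band and signals

`loess_fit_with_se()` wraps the reference local-regression smoother with
exact (non-interpolated) evaluation and exact trace statistics, so the
fitted values, pointwise standard errors and effective degrees of freedom
agree with an explicit per-point weighted-least-squares hat matrix to
numerical precision — the suite asserts agreement within 1e−6 against an
independent oracle. Defaults are span 1 and local degree 2 (the smoother's
default polynomial degree). The neighbourhood holds `floor(span * n)`
points with tricube weights.

`confidence_band()` reproduces the band construction exactly as used in
this literature: `fitted ± qt(0.95, edf) * se`. Two caveats are deliberate
and documented rather than "fixed":

* The multiplier is the **one-sided** 0.95 Student-t quantile although the
  band is conventionally labelled a 95% band; `quantile_prob = 0.975` gives
  a true two-sided band.
* The band uses the standard error of the **fitted mean**, not of a new
  observation. On pure noise, individual points therefore fall outside far
  more often than the nominal label suggests (the acceptance script
  measures this exceedance on a Gaussian null). In practice the band is a
  device for ranking excursions of mostly smooth series, not a calibrated
  outlier test; the event-classification layer adds its own calibration
  (below).

`small_scale_signals()` flags valid samples strictly outside the band
(peaks above, troughs below; boundary ties are not signals).
`large_scale_signals()` works on first differences of the fitted curve: a
*trend change* is a sign flip whose new sign persists at least `min_run`
(default 3) intervals; a *slope change* is a ≥ 2-fold change between the
mean absolute slopes of the preceding and following `min_run` intervals
without a sign flip. Runs of adjacent qualifying boundaries are reported as
one signal with an axis interval. These thresholds operationalize
judgements the source literature makes by eye, and are exposed in the
configuration.

## Event classification

Pulses and steps are the two kinds of abrupt environmental event; what
separates them is persistence. Each call needs a quorum (default 2) of
three evidence flags, recorded per call so that every flag can be recomputed
from the inputs.

**Pulse** (`detect_pulse_events()`), at sample *t*:

1. *tree_outlier* — *t* is a dendrogram outlier;
2. *dominant_trough* — the dominant's series has a small-scale trough at
   *t* or at *t + 1* (the crash may register one step late);
3. *indicator_peak* — some non-dominant taxon blooms at *t*.

Three operational safeguards matter on noisy compositional data:

* *Transience.* A trough or peak only counts when it is a one-sample local
  extremum — the first sample of a step stays at the new level and fails
  this test, which is what keeps step onsets from being miscalled as
  pulses.
* *Robust band.* For evidence purposes the dominant's band is refit after
  masking first-pass excursions, so a single strong feature (an
  opportunist hump, a step plateau) cannot inflate the residual scale and
  hide a shallower pulse elsewhere.
* *Peak multiplicity.* The indicator-peak flag scans every candidate taxon,
  so it is gated by an exact binomial upper-tail test of the taxon's count
  against its local-window mean share, Bonferroni-corrected familywise over
  samples × candidates (`peak_alpha`, default 0.05). Small expected counts
  are strongly right-skewed, so a normal approximation would leak false
  peaks; the reference share is floored at half a count so sparse taxa with
  all-zero neighbourhoods cannot make a stray count look significant. For
  percent-only inputs a robust difference-scale gate (`pulse_sigma`
  MAD units) stands in. At these settings an event-free noisy series still
  produces a low-confidence false pulse call in a minority of runs; calls
  carry their evidence and a confidence fraction precisely so that such
  marginal calls can be audited.

**Step** (`detect_step_events()`), at sample *t*:

1. *subcluster_start* — *t* begins a new sub-cluster; by default
   sub-clusters start wherever adjacent blocks stay separated above 1.5×
   the median merge height (scale-free, like the outlier rule), or at an
   explicit fine cut `subcluster_k`;
2. *sustained_ratio* — a monitored taxon ratio crosses its critical
   threshold (default 0.5) upward at *t* and stays across it for at least
   `persist` (default 2) samples or to the series end;
3. *abundance_slope_drop* — the loess trend of total abundance has a
   "gentler" slope change within ±1 sample. The trend is refit after
   masking small-scale excursions so a pulse dip cannot bend it; the flag
   is inapplicable (NA) without counts.

When the collapse boundary is known, both detectors run on the pre-collapse
window only (samples strictly before the boundary): collapse-triggering
events are by definition earlier than the collapse, and the turnover itself
would otherwise satisfy step-like signatures. Finally,
`reconcile_events()` arbitrates kinds: a pulse call within ±1 sample of a
step call yields to the step, because a step onset can mimic a pulse for one
sample but not conversely.

The monitored ratio defaults to collapse-dominant over pre-collapse
dominant — the rising-taxon-to-declining-dominant ratio whose sustained
threshold crossing marks persistent environmental change in the
limnological literature.

## The simulator

`simulate_community()` generates the structures the detectors assume, with
ground truth:

* Latent log-abundance per taxon = baseline + Gaussian-niche response to an
  environmental driver `E_t` (constant; shifted permanently by `step_mag`
  at the step; spiked for one sample at pulses).
* The dominant sits on a high baseline (3 log-units over the background),
  declines after the first event, and crosses its successor half a sample
  before `collapse_time`, so the turnover is strict from the collapse
  sample on. The successor is suppressed 0.25 log-units below the
  dominant's baseline until the turnover and saturates one log-unit above
  it afterwards, keeping late assemblages mixed. Pulses multiply the
  dominant by `1 − pulse_dom_drop` and the indicator taxon by
  `pulse_ind_gain` for one sample. The opportunist flag instead boosts the
  dominant for `opp_lag` samples after the step — the delayed-decline
  pattern.
* Observation: counts are multinomial draws of size `total_count` × a
  deterministic activity factor (growing at `abund_growth` per sample,
  five-fold gentler after the step, halved at a pulse) over the softmax of
  the noisy latents, then closed to percent. 300 counted individuals per
  sample is the conventional micropaleontological counting effort;
  `noise_sd = 0.1` gives ±10% latent abundance noise. "Expectation mode"
  returns expected counts with the noise off, for exact-shape tests.
* With `csd = TRUE` the dominant's latent deviations become an AR(1) whose
  coefficient ramps linearly from `phi0` to `phi1` over the pre-collapse
  window, with innovation scale `csd_sd = 0.25` — larger than the
  background noise because fluctuations near a tipping point both slow and
  grow (flickering).

Four presets mirror the structure of classic records: `kpg_like` (one large
pulse, 26 samples), `pe_like` (small pulse, then a step with an opportunist
dominant and a recovery phase, 31 samples), `modern_like` (step only, ratio
pair monitored, 18 samples), `em_like` (pulse plus cooling-signed step,
33 samples). The pe-like pulse (`pulse_dom_drop = 0.5`,
`pulse_ind_gain = 3`) is deliberately smaller than the kpg-like one
(0.6, 4) while staying above the counting-noise floor: with the total count
halved at the pulse, a markedly weaker bloom would be statistically
indistinguishable from noise in 300-count data, and an undetectable event
would make end-to-end validation vacuous.

What the simulator does **not** emulate: uneven sample spacing, taphonomic
or dissolution bias, age-model error, autocorrelated noise in the
background taxa, and multi-sample (ramp-like) events. Passing the
end-to-end tests therefore shows the pipeline recovers its target
structures under compositional counting noise — not that it is robust to
every artefact of real records.

## Numerical choices and degenerate inputs

* Ties: equal merge heights merge the oldest pair first; dominance ties take
  the earlier table column; band membership uses strict inequalities, so
  exact-boundary points are not signals.
* The AR(1) of a constant (zero lag-variance) window is masked, not an
  error; a series shorter than the window yields an all-invalid series with
  a warning.
* Loess needs at least `degree + 2` valid points; data lying exactly on a
  polynomial of the local degree reproduce with zero standard error.
* Zero-residual bands collapse to the fitted curve; strictness then means
  no signals, which is the desired behaviour for constant series.
* All randomness in a simulation flows from one seed; identical
  configuration and seed give bit-identical output, and pipeline reports
  contain no timestamps so repeated runs are byte-identical.

## Validation sizes

The test suite validates the clustering against an exhaustive oracle on 100
random fixtures of up to 8 samples; the loess band against a hat-matrix
oracle on fixtures of up to 25 samples; AR(1) recovery at φ = 0.8 with
series of 500 and windows of 200 over 200 seeds; and end-to-end boundary,
pulse and step recovery over 100 seeds per preset. The CSD contrast is
evaluated on collapse-free 60-sample series (twice the default length) so
the 10-sample rolling window yields about 46 estimates: the window-10 AR(1)
estimator has a sampling standard deviation near 0.3 and a small-sample
bias of roughly −(1 + 3φ)/w that grows with φ, so first-versus-last
contrasts of its rolling means separate the ramp from the control clearly
in distribution while individual runs remain noisy. `scripts/acceptance.R`
recomputes all of these quantities from scratch.

## Known limitations

* The band is pointwise and mean-level; it is not a familywise outlier test
  and is not meant to be one.
* Event evidence thresholds (quorum, persistence, slope factor, outlier
  factor, peak alpha) operationalize qualitative descriptions; they are
  exposed in `pipeline_config()` and should be revisited for records unlike
  the calibration scenarios.
* `choose_zone_count()` caps at six zones; records with more than six
  communities need an explicit `k`.
* Rolling AR(1) on records of typical paleoecological length has wide
  sampling error; treat it as corroborating, not primary, evidence.
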