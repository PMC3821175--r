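---
title: "Methods: quantifying synaptic release, colocalization, and vesicle distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying synaptic release, colocalization, and vesicle distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synquant)
```

This vignette is the package's own account of its methods: the models
it fits, the assumptions behind each stage, the tunable parameters with
their defaults and units, what the synthetic generators emulate (and
what they deliberately do not), and the numerical choices made where a
design question was genuinely open.

## 1. Evoked charge decomposition

Evoked excitatory postsynaptic currents (eEPSCs) at the *C. elegans*
neuromuscular junction transfer charge in two kinetic phases — a fast,
synchronous component and a slow, desynchronized one. The package
integrates the baseline-subtracted current over the 50 ms after the
stimulus (trapezoid rule, inward current counted as positive charge,
pA·s = pC) and fits the cumulative charge with

$$Q(t) = A_{fast}\left(1 - e^{-(t-t_0)/\tau_{fast}}\right)
       + A_{slow}\left(1 - e^{-(t-t_0)/\tau_{slow}}\right).$$

The fit is a bounded Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nlsLM`) with $A \ge 0$ and
$0.1 \le \tau \le 500$ ms, run from eight deterministic log-spaced
$(\tau_{fast}, \tau_{slow})$ starts
($\tau_{fast} \in \{0.5, 2, 8, 30\}$ ms, slow/fast ratio
$\in \{8, 40\}$); the converged start with the smallest residual norm
wins, which makes the fit initialization-robust on clean curves (all
starts reach the same optimum) and deterministic on noisy ones.

**The subtraction rule.** The slow amplitude coefficient is never used
directly. The measured 50 ms charge `q50` is the anchor:
`a_slow_eff = q50 − a_fast` and `f_fast = a_fast / q50`. This makes the
two components sum to the measured charge exactly (a conservation
identity the test suite asserts with `expect_identical`), at the cost
of `f_fast` marginally exceeding 1 when the response is purely fast —
such fits are clipped and flagged rather than silently altered.

Degenerate inputs are handled explicitly rather than left to the
optimizer: when the fitted fast amplitude is below $10^{-6}$ of `q50`
the populated component is reported as the fast one, and when the two
time constants collide (relative gap below $10^{-4}$) the amplitudes
are merged into a single fast component; both cases carry a
`single_component` / `tau_collision` flag. Non-convergence of every
start yields a flagged, all-NA result, never an error deep inside a
batch run.

Unweighted fitting of the charge trace (rather than the current) is
assumed; the charge integral smooths high-frequency noise, and the
round-trip tests show the decomposition is unbiased under that choice.
A 0.5 ms stimulus artifact can be blanked by linear interpolation over
a configurable window (`blank_artifact()`, default 0.7 ms) before
integration.

Related metrics follow the same conventions: `decay_time_90_10()`
interpolates the decay-phase crossings of 90% and 10% of peak current
linearly between samples (no smoothing by default; a moving-average
width is available and recorded), reporting a censored lower bound
when the trace never reaches 10% within the record;
`windowed_charge()` integrates half-open windows such as 0–20 and
25–50 ms; `sucrose_charges()` compensates a 500 ms pre-application
baseline and integrates the first 1 s and 5 s of a hypertonic
application; `release_ratio()` is a genotype-level scalar — the ratio
of mean evoked to mean sucrose charge — and deliberately carries no
SEM.

## 2. Synthetic data: what the generators emulate

The generators stand in for raw recordings, images, and micrographs;
their defaults are the study conditions every recovery test runs
under, chosen once.

- **`sim_evoked_trace()`** produces the current that is the exact time
  derivative of the biexponential charge curve, on Gaussian baseline
  noise, at 10 kHz. `A_fast = f_fast · q_total`; the slow coefficient
  is normalized so the charge at `t0 + 50 ms` equals `q_total`
  *exactly*, which keeps the generated-charge invariant (0.1%
  agreement at 10 kHz) true across the whole $\tau$ grid, including
  slow fast-components whose own 50 ms charge falls measurably short
  of the asymptote. An optional first-order rise filter is off by
  default so charge identities stay exact.
- **`sim_tonic_trace()`** superimposes difference-of-exponential
  quantal currents (rise 0.5 ms, decay 3 ms, amplitude mean 25 pA with
  CV 0.3 from a gamma distribution — positive by construction) at
  homogeneous Poisson times, optionally thinned by a time-varying rate
  multiplier for illumination time courses. Event times are re-drawn
  on exact ties so ground truth is strictly ordered. The quantal shape
  is a modeling choice (real mini waveforms are not specified by any
  protocol here); it was picked because its decay statistic is
  analytically checkable.
- **`sim_profile_pair()`** lays Gaussian puncta (σ 200 nm, amplitudes
  80–150 AFU on a 5 AFU baseline, 100 nm pixels) along a line, giving
  each channel-1 punctum a channel-2 partner with probability
  `coloc_prob`, displaced by a Normal(offset) draw; unpartnered
  partners are re-placed independently. 100 nm pixels make the 600 nm
  threshold window 6 samples and a six-pixel width 600 nm, consistent
  with the printed nanometre figures.
- **`sim_em_dataset()`** draws per-profile vesicle counts from a
  Poisson and distances from a proximal-exponential + distal-Gaussian
  mixture truncated at zero; vesicle-free profiles are kept as NA rows
  so per-profile normalization uses the full census.

What the generators do *not* emulate: membrane biophysics, series
resistance, channel gating, 2-D image formation beyond line profiles,
or EM segmentation. Passing the recovery tests therefore shows the
estimators are correct on data matching their model assumptions — it
does not validate detection thresholds or threshold rules against the
noise structure of real rigs or microscopes.

## 3. Tonic event detection

No standard detection algorithm exists for this preparation, so the
detector is the package's own design, with every parameter snapshotted
into the result: the current is boxcar-smoothed (0.5 ms), differenced
over a 1 ms lag (matched to the quantal rise), and candidate events
are local minima of that difference below `threshold_sd` (default 4)
robust SDs, where the robust SD is the median absolute deviation
× 1.4826 so high event rates do not inflate the threshold. Local
minima — rather than threshold crossings — let events a couple of
milliseconds apart register separately. Amplitude is peak minus the
median of the 2 ms pre-onset baseline (a local measure, robust to
overlap); candidates under `min_amp_pA` (default 10) or within
`refractory_ms` (default 2) of a larger event are dropped. At SNR 10
the detector holds precision and recall above 0.95 up to 50 Hz; the
residual misses are genuinely overlapping events, which the ground
truth retains by design.

Per-event decay is a single-exponential fit starting 1 ms after the
peak — the blunt top, where the rising phase still contributes,
otherwise biases τ upward by several percent. The CALI readout
(`cali_timecourse()`) bins frequency (30 s bins) and divides the
frequency in the bin starting at `light_on + span` (span 2 min) by the
mean pre-illumination frequency; a zero pre-light rate is an error,
not an NaN.

## 4. Line-profile colocalization

The threshold rule is: find the lowest non-zero intensity, take the
sample SD (n−1; the convention is declared since either denominator is
defensible) of the trace within a 600 nm window centered there —
zero-valued pixels inside the window included — and set the threshold
at floor + 3.5 × SD. Manual per-profile overrides are accepted (and
recorded) to mirror practice, since an automatic floor can clip dim
puncta. Peaks are local maxima strictly above threshold; plateaus
report their centroid; maxima within 200 nm (≈ two pixels, a declared
default) merge keeping the higher.

Nearest-peak distances are directional (each reference peak to the
nearest other-channel peak), with pairs beyond 800 nm recorded as
unmatched and excluded from the distance list. Pixel correlation is
Pearson's r over retained pixels; retention defaults to *either*
channel above its threshold (the permissive reading of the ambiguous
software convention), with `both` and `all` available. The shuffled
null correlates channel 1 of animal *i* with channel 2 of animal
*j ≠ i* over all ordered mismatched pairs (profiles truncated to the
shorter length); a seeded random-pairing scheme exists for very large
cohorts. The animal is the unit of replication in all group summaries.

## 5. EM docked-vesicle statistics

Distances are consumed as measured scalars (no image processing).
Histograms use half-open 33 nm bins — one section thickness — with
counts divided by the total profile count, and the cumulative fraction
integrates the raw counts so it ends at exactly 1. Region summaries
treat the synapse (a contiguous set of serial profiles containing a
dense projection) as the data point: `<165` and `<231` are `[0, 165)`
and `[0, 231)`, and the outer regions are implemented as `[231, 330)`
and `[330, ∞)` so the printed 231/232 seam leaves no 1 nm hole — the
printed labels are integer-rounded coordinates, and the half-open
convention is the only one under which the three tiling regions sum
exactly to the per-synapse total (the per-synapse total is computed as
that sum, making the identity hold to the bit). Per-profile totals use
the profile as the unit instead, matching how single-profile averages
are reported.

## 6. Group statistics

`describe_group()` reports mean ± SEM (sample SD/√n; flagged NA at
n = 1). `group_t_test()` is the classic pooled-variance two-tailed
Student's t by default — Welch is behind a flag — with a paired
variant on difference scores. `anova_snk()` runs a one-way fixed-
effects ANOVA and the Student–Newman–Keuls stepwise procedure on the
ordered means: ranges of span *p* are compared against
`qtukey(1 − α, p, df_error)` (computed numerically, so any group size
works; unequal n uses the harmonic-mean standard error), and a
non-significant range silences every pair inside it, which guarantees
decisions consistent across spans and α levels and invariant to input
order. No correction beyond SNK is applied by default.

`run_pipeline()` ties the stages together from a YAML config: per
genotype it simulates or loads inputs, computes the stage measures
with the stage-fixed replication unit (animal for physiology and
colocalization, synapse for EM regions), applies a t test for two
groups or ANOVA + SNK for three or more, and writes a JSON report with
a config hash and a per-replicate seed registry, so a run is
bit-reproducible from (config, seed).

## 7. Problem sizes and numerical tolerances

The test suite verifies parameter recovery at sizes a desk-scale
simulation supports and that characterize each statistic well: the
noiseless kinetics grid spans $\tau_{fast} \in \{2,5,10\}$,
$\tau_{slow} \in \{30,40,80\}$ ms, $f_{fast} \in \{0.3,0.5,0.77,0.9\}$
with sub-1% recovery; noisy-fit medians use 60 replicates at SNR 20;
detection runs on 60 s traces at 20 and 50 Hz; frequency and CALI
recovery use 100 and 50 seeds of ground-truth event lists;
colocalization recovery uses 12 animals per offset and a 90-pair
shuffled null. Exact identities (charge conservation, histogram
counts, region tiling) are asserted bitwise, closed forms at 1e-6 to
1e-12, and stochastic recoveries at 3 standard errors of the relevant
oracle.

## 8. Known limitations

- The biexponential model assumes exactly two kinetic components; a
  third component or a drifting baseline will be absorbed into the
  slow term.
- The event detector is not a template matcher; amplitudes of heavily
  overlapping events are measured against a local baseline and can be
  biased for the later event of a pair.
- Line profiles assume co-registered channels on a uniform grid;
  non-uniform grids are resampled on read, and no chromatic
  registration is attempted.
- The shuffled null is computed on extracted profiles, not whole
  images; with very few animals its variance is large and the "near
  zero" check is correspondingly loose.
- Censored decay times (traces that never reach 10% of peak) are lower
  bounds and flagged as such; downstream summaries must decide how to
  treat them.
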