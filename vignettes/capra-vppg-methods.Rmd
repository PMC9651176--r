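---
title: "Methods: simulating and analysing Ca-Pra venous photoplethysmography"
author: "vppg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing Ca-Pra venous photoplethysmography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vppg)
```

## Background

Venous photoplethysmography (VPPG) records slow, low-pass-filtered
changes of limb volume in arbitrary units (AU). Because the optical gain
depends on the probe, its placement and the limb, VPPG is
semi-quantitative: amplitudes are not comparable between recordings. The
Candlestick–Prayer (Ca-Pra) maneuver makes the signal quantitative. The
recording starts with ~2 s at rest, arms alongside the torso, which
defines zero volume with the forearm full. The arm is then abducted to
90° (candlestick, "Ca", held until second 30): a patent venous outflow
empties the elevated forearm, and the PPG signal rises. Bringing the
elbows forward while keeping the hands elevated (prayer, "Pra", until
second 45) opens the costo-clavicular angle, releasing any positional
compression without losing elevation, so by the end of Pra the forearm
is completely empty. The maneuver maximum (`PPGmax`) therefore
represents 100 % emptying, and the value at the end of Ca
(`End-Ca-PPG`) can be normalized to it:

$$\%PPG_{max} = 100 \cdot \frac{\text{End-Ca-PPG}}{PPG_{max}}.$$

A low %PPGmax means emptying during abduction was incomplete — the
hemodynamic signature of a positional venous outflow impairment. A
negative value means the forearm swelled beyond its resting volume:
arterial inflow persisted while outflow was arrested.

## The hemodynamic model

No per-limb recordings are distributed with the package, so a forward
model generates them. We deliberately use the *minimal* model that
reproduces every clinically described trace morphology: a single venous
compartment with volume $V(t)$, first-order emptying, and
position-switched inflow and outflow.

* **Rest** ($t < t_{rest}$): $V = V_{full}$ (arms down, compartment
  full).
* **Ca** ($t_{rest} \le t < t_{Ca}$):
  $$\frac{dV}{dt} = q\,(1 - a) - k_0\,(1 - c(t))\,(V - V_{empty}),$$
  with $q$ the resting arterial inflow (volume-units/s), $a \in [0,1]$
  the fractional inflow block, $k_0$ (1/s) the emptying rate with patent
  outflow, and $c(t) \in [0,1]$ the fractional outflow block, optionally
  ramped over `onset_ramp` seconds after abduction (a compression that
  engages gradually lets the limb empty briefly before refilling — the
  classic "refill after initial emptying" trace).
* **Pra** ($t_{Ca} \le t < t_{Pra}$): the outflow block is released,
  $$\frac{dV}{dt} = q_{hyper}(t) - k_0\,\bigl(V - V_{empty}(1 + d\,a)\bigr),$$
  where $q_{hyper}(t) = q\,(1 + s\,a\,e^{-(t - t_{Ca})/\tau})$ is a
  reactive-hyperemia surge (present only after an ischemic Ca phase,
  i.e. when $a > 0$) and $d \ge 0$ scales the post-ischemic venodilation
  of the empty volume. A venodilated bed refills during Pra, which shows
  as a signal *decline* after complete emptying.
* **Post-maneuver** ($t \ge t_{Pra}$): the arms are lowered and the
  compartment refills at rate `refill_rate`. These samples are emitted
  with a flag and excluded from all analysis, since arm lowering is not
  standardized.

The optical readout is $PPG(t) = G\,(V_{full} - V(t))$ plus Gaussian
sensor noise, re-zeroed on the rest window, then quantized to the
device's display resolution.

Integration is explicit Euler on the 4 Hz sample grid (step 0.25 s).
This is trivially reproducible and stable for $k_0 < 4$/s; the
constructor caps cohort draws at 1.9/s and the documented operating
range is $k_0 \le 2$/s.

### Parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `outflow_block` ($c$) | fraction of outflow conductance lost in Ca | – | 0 |
| `inflow_block` ($a$) | fraction of arterial inflow lost in Ca | – | 0 |
| `venodilation` ($d$) | post-ischemic empty-volume increase | – | 0 |
| `outflow_rate` ($k_0$) | patent emptying rate | 1/s | 0.3 |
| `inflow` ($q$) | resting arterial inflow | vol/s | 0.02 |
| `gain` ($G$) | optical gain | AU/vol | 10 |
| `noise_sd` | sensor noise SD | AU | 0 (traces), 0.05 (cohorts) |
| `v_full`, `v_empty` | full / empty volume | vol | 1, 0.1 |
| `onset_ramp` | block onset time | s | 0 |
| `surge_gain` ($s$), `surge_tau` ($\tau$) | hyperemia surge | –, s | 6, 5 |
| `resolution` | device display grid | AU | 0.1 |

With the defaults, a patent limb ($c = a = 0$) settles at
$V = V_{empty} + q/k_0$, giving a noise-free amplitude of
$G\,(V_{full} - V_{empty} - q/k_0) \approx 8.3$ AU — the order of
magnitude of typical recorded maxima — and the Pra phase sits at the
same equilibrium, so the trace is flat and %PPGmax is exactly 100.

Device quantization matters more than it may seem. The maximum of ~170
noisy samples is biased upward by roughly $2.5\sigma$, so with
continuous noise *no* limb would ever reach %PPGmax = 100 and the whole
upper end of the distribution would smear downward. Quantizing to the
0.1 AU display grid (as clinical devices do — recorded values read
"6.0", "9.0") restores the exact ties seen in practice, including the
sizeable group of limbs at exactly 100 %PPGmax.

### Trace morphologies

`preset_pattern()` packages six canonical parameter sets: `A`/`B`
normal complete emptying, `C` incomplete emptying (partial block,
Pra reveals the residual volume), `D` refill after initial emptying
(severe block engaging over ~6 s; the trace can cross below zero),
`E` slowed outflow (low $k_0$, maximum only at the end of Ca), and `F`
post-ischemic venodilation filling (complete emptying with inflow
block; Pra declines). One morphology sometimes attributed to this
family — a Pra rise followed by a late Pra decline in a limb whose Ca
phase stayed flat at zero — is not reachable under this model: from a
full compartment the Pra solution approaches a monotonically decaying
target and cannot overshoot it in that order. The venodilation decline
therefore only follows *complete* Ca emptying (preset `F`), which
matches the physiological narrative (venodilation requires the
ischemia, and the decline requires an empty bed to refill).

## Feature extraction

* `End-Ca-PPG` is the **median of the final 1 s of Ca** (4 samples at
  4 Hz), not the single sample at second 30: a device displaying an
  instantaneous value is noise-sensitive, and the median is robust while
  changing nothing on clean traces. The window length is an argument.
* `PPGmax` is the maximum from abduction onset to the end of Pra.
  Rest and post-maneuver samples are excluded — "during the maneuver"
  excludes the baseline and the unstandardized arm lowering.
* If `PPGmax ≤ 0` the limb showed no detectable emptying anywhere and
  the normalization is undefined; the feature set is flagged invalid
  (with a reason code) rather than returning ±∞. Negative %PPGmax is
  *not* clipped: values below −100 are physiologically meaningful
  (inflow-driven swelling against a small maximum).

%PPGmax is invariant to the optical gain — the entire point of the
normalization — and ≤ 100 for every valid limb, because End-Ca lies
inside the maximum's window.

## Pattern classification

`classify_pattern()` applies three rules, all relative to the trace's
own `PPGmax` (hence gain-invariant), with defaults
`delta_rise = 0.13`, `delta_fall = 0.10`, `t_slow = 20` s:

1. a Pra rise above End-Ca by more than $0.13\,PPG_{max}$ ⇒ emptying was
   incomplete (`refill_incomplete` if an early Ca maximum also exceeded
   End-Ca by the same margin, else `incomplete_emptying`);
2. otherwise a Pra drawdown larger than $0.10\,PPG_{max}$ ⇒
   `venodilation_filling`;
3. otherwise complete: `slowed_outflow_complete` if 90 % of the End-Ca
   level was first reached later than 20 s after abduction, else
   `complete_emptying`.

`delta_rise = 0.13` is chosen to cohere with the 87 %PPGmax operating
threshold: a limb at 87 % is missing 13 points of its maximum, so the
qualitative and quantitative criteria agree on what "incomplete" means.
When both the rise and the fall rules fire, incompleteness wins —
residual volume is the primary clinical question. The slowed-outflow
label is kept distinct rather than merged into either neighbour,
because such limbs are complete by the emptying criterion yet clearly
abnormal in dynamics, and merging would silently discard that
information.

## ROC analysis and the optimal cutoff

The ROC unit of analysis is the limb; the two limbs of a patient are
treated as independent (no clustering correction), matching how such
cohorts are analysed limb-by-limb.

* **Orientation**: low score ⇒ test positive. Impaired emptying lowers
  %PPGmax, so the decision rule is "positive iff score < cutoff",
  strictly. Cutoffs are the observed values themselves plus an infinite
  endpoint — no midpoints between observed scores — matching the
  convention of the common clinical statistics software.
* **AUC**: tie-corrected Mann–Whitney statistic computed from mid-ranks,
  which equals the trapezoidal area under the empirical curve; the test
  suite asserts this equivalence to 1e−12 against brute-force pair
  enumeration.
* **Standard error**: Hanley–McNeil with $Q_1 = A/(2-A)$,
  $Q_2 = 2A^2/(1+A)$ — the nonparametric default of that software
  family — with the DeLong covariance estimate available via
  `method = "delong"` (cross-checked against pROC in the tests). The two
  differ in the third decimal at realistic sizes; neither is asserted
  against published rounding.
* **Optimal cutoff**: the point minimizing the Euclidean distance to
  (sensitivity, specificity) = (100 %, 100 %), i.e. equal costs of
  false positives and false negatives. Ties break toward higher
  sensitivity (favouring detection), then lower cutoff.

## The synthetic cohort and its calibration

`cohort_spec()` defaults encode the reference study conditions: 424
patients / 848 limbs with side-status counts 41 right-only / 44
left-only / 61 bilateral / 278 none, hence 102 right-positive, 105
left-positive and 207 positive limbs, and 146 patients with at least one
compression.

Per-limb parameters come from `severity_sampler()`s. The outflow block
is a **two-component Beta mixture**: a mild-to-moderate main component
and a minority "severe" component (deep blocks, %PPGmax far below the
threshold). Both labels use the same structure with different
constants; limbs additionally receive an inflow block with probability
`a_prob`, and the emptying rate, inflow and gain are log-normal across
limbs (the semi-quantitative gain spread).

A single Beta per class cannot reproduce the reference operating point:
the closest-corner optimum sits where the positive/negative density
ratio crosses $(1-spec)/(1-sens) \approx 1.3$, while the class CDFs at
the 87 % threshold must be ~0.61 and ~0.52. Fixing both requires mass
far below the threshold that does not distort the density balance near
it — exactly what the severe component provides. The frozen defaults
(`severity_sampler_positive()` / `severity_sampler_negative()`) were
chosen once so that, at the default configuration, the 848-limb pipeline
recovers an optimal cutoff within 3 points of 87 %PPGmax and
sensitivity/specificity at 87 within 5 points of 60.9 %/47.6 % — the
documented calibration tolerances asserted by the test suite. Making the
negative class's severe component shallower than the positive one's
(Beta(9, 1.8) vs Beta(16, 1.2)) preserves those margins while keeping
the two classes ordered within the low range.

What the generator emulates: the timing protocol, per-limb gain
heterogeneity, sensor noise and display quantization, all described
trace morphologies including negative excursions, and the cohort's
label structure. What it does **not** emulate: movement artifacts,
probe repositioning drift, within-patient correlation of the two limbs,
arterial (pulsatile) contamination, and the deep negative outliers of
real referral populations (the simulated floor is near −100 rather
than several hundred negative). Consequently, passing the calibration
tests shows the *pipeline* is correct and the study conditions are
representable — not that the model captures every feature of clinical
recordings. The calibrated cohort's AUC runs near 0.52–0.58, at the
lower edge of what weakly discriminating clinical data show; the
corner-distance profile is flat near its minimum, so the selected
cutoff moves by a few %PPGmax points between seeds even at n = 848.
This fragility of the corner criterion on flat profiles is a property
of the method itself, not of the implementation.

## Numerical choices and degenerate inputs

* Explicit Euler at 0.25 s; all rates validated finite and non-negative,
  blocks validated in [0, 1]; `v_empty < v_full` enforced.
* Problem sizes: every simulation-based test and the acceptance script
  use the 848-limb default cohort (a few seconds) or smaller; property
  suites use n ≤ 30 with brute-force oracles.
* ROC requires both classes; single-class input is rejected (and the
  pipeline reports the skipped stage rather than failing).
* All-tied scores yield AUC 0.5 with only the trivial ROC points.
* Published-percentage arithmetic uses half-up rounding
  (`round_half_up()`), since base R's half-to-even disagrees on exact
  halves with the convention of printed clinical tables.
* Table reconstruction (`reconstruct_table()`) enumerates all integer
  tables compatible with the rounded marginals; non-unique solutions
  are returned in full (never silently picked) and an empty candidate
  set is reported as an inconsistency.
* Seeds: one master seed per cohort; per-limb noise substreams are
  derived deterministically from it, and seeded draws are isolated with
  `withr::with_seed()` so the ambient RNG state is never touched.

## Known limitations

* The hemodynamic model is a deliberate minimal construction; its
  parameters are effective, not measured physiology.
* Limb independence is assumed throughout; bilateral compression
  induces within-patient correlation that a clustered analysis would
  handle more honestly.
* The slowed-outflow criterion depends on elevation speed, which cannot
  be standardized; the label is qualitative evidence, not a
  quantitative slope estimate (deliberately out of scope).
* No reader for proprietary device formats: CSV plus a JSON sidecar is
  the ingestion contract.
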