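---
title: "Modelling cognitive workload as a digital twin: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cognitive workload as a digital twin: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwtwin)
```

## The problem

First responders work under cognitive workload (CW) — the measurable
cognitive effort a person exerts in response to task demands — and sustained
high workload degrades vision, decision-making and motor performance exactly
when they matter most. `cwtwin` implements a desk-scale version of an
ensemble monitoring formalism for CW: three streams of evidence
(demographics, psychological traits, wearable physiology) are each processed
by a suitable learner, and their outputs are aggregated by a discrete
Bayesian causal network into a continuously updated probabilistic picture of
one person's workload — a "digital twin" that evolves with the monitored
person and reports back to an operator.

The package is organised around three statistical cores:

1. a **structural path model** linking demographics and the six HEXACO
   personality domains to a composite psychological trait and onward to the
   CW response (`fit_path_model()`);
2. **per-sensor probabilistic classifiers** over windowed features of 1 Hz
   wristband channels (GSR, heart rate, RR intervals, skin temperature),
   fused by unweighted averaging (`train_sensor_classifier()`,
   `fuse_average()`);
3. a **discrete Bayesian network** with exact variable-elimination inference
   under hard and soft (virtual) evidence (`build_network()`, `infer()`,
   `reasoning()`), feeding a perception–action monitoring loop
   (`cw_monitor()`).

Because the underlying wristband study data are external, the package ships
a first-class synthetic cohort generator whose defaults *are* the study
conditions assumed by the analysis; every downstream stage is tested against
it.

## The structural path model

The generator and estimator share one model class: a recursive linear path
model on the standardized scale,

$$ y_v = \sum_{u \in \mathrm{pa}(v)} \beta_{uv}\, z_u + \varepsilon_v,
   \qquad \varepsilon_v \sim N(0, \sigma_v^2), $$

where every variable enters as a z-score. The default structure
(`default_path_spec()`) has the six HEXACO domains plus standardized age and
sex as direct parents of the composite trait `psych_trait` (higher = more
Stressed), and a composite demographic score `demog` (an equal-weight blend
of age and sex, weights 0.5/0.5 with disturbance $\sqrt{0.5}$ — plumbing, not
a quantity of interest) carrying the single demographics arc into the CW
response `cw`. The nine substantive coefficients are the published
standardized estimates: emotionality/dependence 0.310, extraversion 0.156,
agreeableness −0.250, openness −0.025, conscientiousness −0.298,
honesty–humility −0.263, age −0.011, sex −0.145, and demographics → CW
−0.938.

Two conventions make these numbers exact population truths for the
generator:

* **Unit-variance construction.** Each default disturbance sd is
  $\sqrt{1 - \sum_u \beta_{uv}^2}$; since parents are independent by
  construction, every endogenous variable has population variance 1 and the
  coefficients are standardized coefficients exactly.
* **Exogenous defaults.** Age is uniform over whole years 20–59, sex is
  Bernoulli(0.5) coded 0 = female / 1 = male, and HEXACO domains are
  standard normal. None of these distributions are reported for the original
  cohort; they are declared here once as plausible defaults, not inferred.

### Estimation

The model is recursive with observed variables only, so full-information SEM
estimation reduces to equation-wise least squares: each endogenous variable
is regressed on its parents (`stats::lm`). This is deliberate — it yields
the same path coefficients as an SEM optimizer for this model class, with no
convergence concerns. Standard errors and p-values are the classical
per-equation t-statistics. A chi-square fit statistic is computed from the
maximum-likelihood discrepancy between the sample covariance and the
model-implied covariance $(I-B)^{-1}\Psi(I-B)^{-\top}$; the constraints it
tests are the zero covariances among exogenous variables.

**Standardization convention.** `fit_path_model(standardize = TRUE)`
(default) sample-z-scores every column, so estimates are standardized
coefficients regardless of raw scales (age in years, sex in 0/1). One
consequence worth knowing: on noise-free data the sample scale ratios
$s_x/s_y$ make re-standardized estimates differ from the generating values
(a deterministic single-parent equation has standardized coefficient exactly
±1). Exact noiseless recovery therefore holds on the already-standardized
scale (`standardize = FALSE`), which is how the tests exercise it;
statistical recovery of the published values is checked at n = 5000, where
all nine estimates land within ±0.05 of the truth (sampling error at that
size is roughly 0.014).

## The synthetic physiology

`simulate_recording()` draws each channel i.i.d. Gaussian around resting
baselines typical of wrist wearables (GSR 2 ± 0.4 µS, HR 70 ± 5 bpm, RR
850 ± 50 ms, skin temperature 33 ± 0.3 °C, clamped to physical ranges).
During Load blocks of the protocol, a configurable mean shift in
baseline-sd units is applied — by default GSR +1, HR +1, RR −1, temperature
−0.5, the physiologically conventional directions under cognitive load — with
an optional Load-variance multiplier and an optional linear gain by the
subject's trait score (off by default). The default protocol alternates four
300 s Rest/Load blocks at 1 Hz.

What this emulates: labelled, aligned, fixed-rate multichannel recordings
with a condition-dependent location shift. What it deliberately does not
emulate: autocorrelation, circadian drift, motion artefacts, sensor
dropouts, or inter-channel correlation. Passing tests therefore demonstrate
that the pipeline recovers what it assumes — not that the classifiers would
reach the same accuracy on field recordings, where feature engineering and
artefact handling dominate.

All randomness flows from a single top-level seed; per-subject recording
seeds are split deterministically as `(seed + 1000003·i) mod (2^31 − 1)`.

## Preprocessing and the sensor classifiers

Signals are min–max normalized to [0, 1] and then standardized to mean 0,
sd 1 (divisor n − 1), in that order. The normalization scope is per subject
and per channel, fitted on a training segment only and applied to later data
with the stored parameters (`channel_scaler()`); this prevents test-segment
leakage. Windows default to 30 s with a 15 s stride — unstated in the source
analysis, chosen as a conventional compromise between responsiveness and
feature stability at 1 Hz. A window's label is the majority of its
per-second labels, with exact ties going to Rest so that boundary windows
cannot inflate the Load class.

Each window is summarised by six features (mean, sd, min, max, least-squares
slope, mean absolute first difference). The per-sensor classifier is a
ridge-penalized logistic regression (`glmnet`, α = 0, fixed λ = 0.01) over
those features: deterministic, well-calibrated for location-shift Gaussians
(where the logistic posterior is the correct functional form), and honouring
the same probability-pair contract as the deep sequence models used on the
real data, which are out of scope here. One classifier is trained per sensor
channel, and fusion is the unweighted arithmetic mean of the Load
probabilities — exactly the aggregation the published probability pairs
imply (a single sensor at 0.8607 averaged with three sensors at
(4·0.4714 − 0.8607)/3 reproduces the published 0.4714).

## The causal network

`build_network()` turns a fitted path model into a discrete network:
`Age` (binned decades, uniform prior) and `Sex` are parents of
`Personality_trait` (Restful/Neutral/Stressed); the trait drives `Workload`
(Rest/Load); and each sensor has a marker node (`GSR_marker`, …) as a child
of Workload. Three mappings are not derivable from the source analysis and
are therefore explicit calibration choices (`network_config()`):

* **Trait CPT** — an ordered-logistic link on the model-implied latent mean
  of each Age × Sex configuration (bin midpoints standardized with the
  fit's scaling), thresholds at ±1 and scale 1 by default. Zero coefficients
  give identical rows; flipping all signs reverses the P(Stressed) ordering.
* **Workload CPT** — P(Load) of 0.85/0.50/0.15 for Stressed/Neutral/Restful.
* **Marker reliabilities** — symmetric agreement probabilities per sensor
  (GSR 0.80, HR 0.80, RR 0.86, temperature 0.75), ordered to reflect the
  reported standing of RR as the strongest workload predictor.

Classifier outputs enter as **soft (virtual) evidence**: a likelihood vector
on a marker node, preserving the probability pair instead of rounding it to
a hard state. Inference is exact variable elimination with a greedy
smallest-factor ordering; the test suite checks it against full-joint
enumeration on random networks to 1e-9. Argmax decisions break ties toward
the less alarming state (states are ordered Restful < Neutral < Stressed and
Rest < Load).

The scenario fixture `example_network()` additionally pins the
(30–39, Male) trait row to the published scenario posterior
(0, 0.82, 0.18) — those posteriors are calibration targets, not derivable
constants, since the original CPTs are unpublished — and
`trait_likelihood()`'s default Stressed odds of 41/18 turn that posterior
into exactly (0, 2/3, 1/3) under soft Stressed evidence, matching the
published what-if row. The four reasoning modes are: I (demographics only →
trait), II (demographics + trait evidence → trait), III (sensor evidence
only → Workload) and composite (all streams → Workload). With uninformative
sensor likelihoods the composite Workload posterior coincides with the
posterior given only the demographic and trait evidence, which the suite
checks to 1e-9.

## The monitoring loop

`cw_monitor()` implements the perception–action cycle: each interval
(default 300 s) appends a fused P(Load), maps it to a 1–5 level by a
monotone step function with cuts at 0.2/0.4/0.6/0.8 (level 3 = "medium"),
and renders a stable operator message such as *"The CW increased by 20% and
reached level 3 (medium on the scale of 1-5) in the past time interval
(5 min)."* The relative change is computed on P(Load), not on the discrete
level — the convention that reproduces the published example arithmetic
(0.5 → 0.6 is a 20% increase). Updates are pure (a new state is returned),
so replaying a stream reproduces the final state bit for bit. Whether the
1–5 level should come from a separate multi-class model is left open by the
source; the step mapping is this package's declared convention. Mission-halt
policy is out of scope: the decision object reports "High CW Risk" when
P(Load) reaches the threshold (default 0.8) and leaves the action to the
operator.

## Problem sizes and numerical choices

The package's own reference experiments, reproduced by `scripts/acceptance.R`
and the test suite, use: 5000 subjects for coefficient recovery (±0.05
bands; estimates are typically within 0.03); 16 subjects × 1200 s recordings
(10 train / 6 test, ≥ 200 held-out windows per class) for the classifier
shift-response ladder at 0.5/1/2 sd; 100 random ≤ 8-node networks for the
inference oracle; and a 20-subject cohort for the end-to-end pipeline
(`cw_pipeline()`), which runs in seconds. Degenerate inputs fail loudly:
constant series cannot be normalized or standardized, single-class training
data are rejected, contradictory hard evidence raises an inconsistency
error, and cyclic structures are refused at construction.

## Known limitations

* The physiological generator's i.i.d. Gaussian noise flatters any
  window-mean classifier; field accuracy claims cannot be transferred.
* The network's CPT calibration (thresholds, reliabilities, Workload rows)
  is declared, not estimated; conclusions from `example_network()` are
  scenario reproductions, not data analysis.
* Only the nine published arcs define the path structure; the original
  model is shown only in fragments, and no latent measurement models or fit
  indices beyond the chi-square are provided.
* Team-level workload, transport/encryption layers, and deep sequence
  classifiers are explicitly out of scope.
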