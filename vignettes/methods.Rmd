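---
title: "Mapping cardiorespiratory information flow with breathTE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cardiorespiratory information flow with breathTE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathTE)
```

## The problem

During exposure to normobaric hypoxia and during exercise, the
cardiorespiratory system does not respond one variable at a time: heart rate,
breathing frequency and depth, gas exchange and end-tidal pressures adjust
together, and the *interactions* among them carry information that averaged
values miss. breathTE maps those interactions as a directed weighted network.
Nodes are seven breath-by-breath variables — heart rate (HR), respiratory
frequency (RF), minute ventilation (VE), tidal volume (VT), oxygen consumption
(VO2), and end-tidal O2 and CO2 pressures (PETO2, PETCO2) — and edges are
transfer-entropy (TE) estimates of directed information flow, screened for
significance by a Monte-Carlo shuffle test. Networks from different
experimental conditions (normoxic control `CTR` and two hypoxia levels `HY1`,
`HY2`; rest vs. isometric exercise) are then compared with the weighted
Jaccard similarity index, and cohort-level questions are answered with
repeated-measures ANOVA, chi-square/McNemar symptom tests, and logistic
regressions.

Because breath-by-breath recordings are event-sampled — one observation per
respiratory cycle — every stage works on the breath index, not wall-clock
time. A 5-minute window at 20 breaths/min gives 100 samples; everything in
the package is designed around that sample-size regime.

## Transfer entropy: estimator and choices

For source $X$ and target $Y$ the package estimates, in bits,

$$TE_{X \to Y} = \sum p(y_{t+\lambda}, y_t, x_t)\,
  \log_2 \frac{p(y_{t+\lambda} \mid y_t, x_t)}{p(y_{t+\lambda} \mid y_t)},$$

with embedding dimension 1 for both histories and a fixed lag $\lambda$ of 5
respiratory cycles by default (about 15 s at resting breathing frequencies,
inside the 5–25 s memory length reported for cardiorespiratory series).
`lagScan()` computes the TE profile over lags 1–5 and reports the plateau
lag — the first lag from which successive relative changes stay below 10% —
for checking that a fixed lag of 5 is on the flat part of the profile.

Choices that matter, and why:

* **Discretization.** Default is equal-frequency binning computed from ranks:
  sample $i$'s bin depends only on the rank of its value, so the assignment
  is exactly invariant under strictly monotone transforms of a channel, and
  tied values always fall in the lower bin (deterministic). If a series has
  no more distinct values than `nBins`, each distinct value becomes its own
  bin, so genuinely discrete inputs are tabulated exactly. An adaptive mode
  (recursive per-axis splitting with a chi-square uniformity stop) is
  available in `teConfig()` for users who want a data-driven partition; all
  package defaults use quantile mode.
* **Bin count.** The default is `nBins = 4`. The plug-in estimator's
  small-sample bias grows with the number of occupied cells: at $n \approx
  100$ samples, 6 bins per dimension (216 cells for ~95 triplets) push the
  bias near a full bit and drown planted couplings; at 4 bins a strong
  planted edge (strength 0.8 at the estimation lag) is detected in ~98% of
  seeded runs while the surrogate test stays exactly at its nominal level.
  This is the package's own calibration for the 60–150-sample regime;
  `nBins` is configurable.
* **Conditioning convention.** The history pair $(y_t, x_t)$ and the future
  $y_{t+\lambda}$ share the same origin $t$. The alternative (history at
  $t+\lambda-1$) is a legitimate variant; it is not implemented because a
  single convention keeps edge weights comparable and the choice does not
  affect any of the calibration properties.
* **Degeneracy.** Empty cells contribute 0 ($0 \log 0 \equiv 0$), the
  estimate is clipped at 0 from below, and a constant source or target
  returns 0 with a warning rather than NaN.

The inner tabulation runs in compiled code (Rcpp); in quantile mode a
permutation of the source series induces the identical permutation of its bin
assignments, so the surrogate loop permutes the discretized series directly.

## Surrogate screening

Each directed pair is screened by recomputing TE after uniformly permuting
the full source series 100 times (the target, and hence its autocorrelation,
is untouched — that is the null being tested: no directed dependence of the
target's future on the source's past beyond the target's own history). The
threshold is the 95th-percentile of the null by the nearest-rank convention
(the 95th order statistic of 100 sorted values) and the observed value must
be *strictly* greater; otherwise the edge weight is set to 0. Nearest-rank
avoids interpolation ambiguity and the strict inequality makes the test
conservative on tied values. With 100 shuffles the realized false-positive
rate of this rule is about 5–6% per pair; no multiple-testing correction is
applied across the 42 pairs, deliberately mirroring the screening procedure
the package reproduces, and the per-network consequence (about 2 spurious
edges under complete independence) is verified by simulation in the test
suite.

All randomness is derived from one master seed through counter-based
substreams (`childSeed()`), so any recording, pair or shuffle can be
reproduced in isolation.

## Networks, centrality and comparison

`participantNetwork()` assembles the 42 screened values into a 7×7 directed
adjacency matrix (zero diagonal). Group networks are element-wise medians
across participants *including* the zeroed entries, so an edge absent in the
majority vanishes — this is what makes sparsely-coupled conditions visibly
sparse at the group level; an even participant count uses the midpoint of the
central values. Weighted in-degree (column sums: the network's influence on a
node) and out-degree (row sums: a node's influence on the network) summarise
each node, `rankNodes()` orders them with ties broken by the fixed channel
order, and `totalTE()` is the common sum.

Similarity between two networks on the same nodes:

* `jsi()` — binarize (edge iff weight > 0) and take shared over total edges;
* `wjsi()` — $\sum_i \min(a_i, b_i) / \sum_i \max(a_i, b_i)$ over the 42
  off-diagonal entries.

Both are 1 for identical networks and the two coincide on 0/1 matrices. Two
empty networks compare as 1 (identical by emptiness); this convention is the
package's, chosen so that similarity is always defined. The nine standard
comparisons (rest–exercise within each condition; the three condition pairs
within rest and within exercise) are fixed in `comparisonSchema()` and
evaluated per participant by `similarityTable()` using each participant's own
surrogate-thresholded matrices.

## Cohort statistics

`rmAnovaGG()` implements the one-way repeated-measures decomposition from
first principles: $F = MS_{effect}/MS_{error}$ and partial eta squared
$SS_{effect}/(SS_{effect}+SS_{error})$. Mauchly's W is computed on the
orthonormal-contrast covariance with the first-order chi-square
approximation, and when its p-value falls below 0.05 (configurable) both
degrees of freedom are multiplied by the Greenhouse–Geisser
$\varepsilon = \mathrm{tr}(T)^2 / ((k-1)\,\mathrm{tr}(T^2))$ before the F
p-value is computed. With two levels sphericity is trivially satisfied
($\varepsilon = 1$, Mauchly skipped). W, $\varepsilon$ and F agree with the
`stats` multivariate-linear-model machinery to numerical precision
(cross-checked in the tests); complete cases are required — no imputation.

Symptom occurrence under a test condition is compared to control with a
goodness-of-fit chi-square against the control proportion
($\chi^2 = \sum (O-E)^2/E$, 1 df) — with 4/12 symptomatic under control and
8/12 under the stronger hypoxia this gives exactly $\chi^2 = 6$. Headache, a
paired yes/no across conditions, uses McNemar's statistic
$(b-c)^2/(b+c)$ without continuity correction, plus an exact binomial
p-value when the discordant count is below 25. Logistic symptom regressions
report Wald p-values and odds ratios per predictor, a likelihood-ratio model
p-value, McFadden's $R^2$, AIC/BIC, the Mann–Whitney AUC of fitted
probabilities, and VIFs (diagonal of the inverse predictor correlation
matrix); perfect separation is detected and flagged. Predictors enter in raw
units by default (odds ratios per unit), with a `standardize` flag.
`correlationMatrix()` reports Pearson's r and tie-corrected Kendall's
$\tau_B$ with two-sided p-values, and `sfRatio()` /
`spo2Fio2Regression()` cover the SpO2/FiO2 summaries (SF uses SpO2 in
percent over FiO2 as a fraction; the regression reports slope, intercept,
r and the residual SD with an $n-2$ denominator).

## The synthetic cohort generator

No raw recordings ship with the package, so every downstream stage is
exercised against a generator with known ground truth. One recording is a
vector autoregression on standardized deviations: each channel is AR(1)
around a plausible physiological level (HR 80 beats/min, RF 16 breaths/min,
VE 12 L/min, VT 0.75 L, VO2 0.35 L/min, PETO2 100 mmHg, PETCO2 38 mmHg),
plus directed cross-channel couplings of chosen strength and lag, rescaled
by channel scales so strengths are comparable. Stationarity (companion
spectral radius < 1) is enforced at construction, a burn-in of at least ten
times the maximum lag (and at least 100 samples) is discarded, and the
long-run channel variance stays within 3× the uncoupled AR level (a test
asserts this).

Defaults, chosen once to emulate the study conditions the package targets:

* **Design.** 12 participants (balanced sex labels) × 3 conditions × 2
  phases; 5-minute windows; breathing frequency drawn per recording from
  N(16, 3) breaths/min, truncated at 8 — so windows hold roughly 60–150
  samples.
* **Topology.** Ten directed couplings mirroring resting cardiorespiratory
  control qualitatively (end-tidal pressures driving HR, VT driving RF,
  VE driving PETO2, RF driving VE, ...), strengths 0.40–0.45, AR 0.35,
  spectral radius 0.955.
* **Coupling lags of 4–5 cycles.** The network mapper estimates TE at a
  fixed lag of 5 cycles (~15 s, where cardiorespiratory influence is
  reported to peak). Couplings planted at 1–3 cycles with weak source
  memory are nearly invisible to a lag-5 estimator, which would contradict
  the regime being emulated (densely significant control networks); placing
  the generative lags at 4–5 cycles makes the planted system the kind of
  system the fixed-lag mapper is built for.
* **Condition effects.** Strength multipliers CTR = 1, HY1 = 0.5,
  HY2 = 0.9: the mild-hypoxia condition is markedly decoupled while the
  stronger one stays near control — the counter-intuitive ordering the
  package's comparison stage must be able to resolve. Exercise scales
  strengths by 1.1, and in HY1 the exercise-phase edge set is additionally
  rewired deterministically (targets shifted three places along the channel
  order), so HY1's rest and exercise networks differ structurally, not just
  in strength.
* **Symptoms.** Bernoulli draws from a logistic model on ground-truth total
  coupling strength with slope 0 by default and per-condition intercepts at
  rates 4/12, 6/12, 8/12 — a null association, so the regression stage can
  be calibration-tested; setting a nonzero slope turns the same machinery
  into a power study.
* **Artifacts.** `injectArtifacts()` replaces a chosen fraction of samples
  with ±(10 MAD) spikes and returns the ground-truth indices, so the
  Hampel + interpolation stage can be scored exactly.

What the generator does **not** emulate: chemoreflex or ventilatory-response
mechanisms, nonstationary drifts within a window, inter-breath-interval
irregularity (a Gamma-jitter flag exists but is off: the analysis is
event-indexed, so jitter does not change it), SpO2 traces, or
measurement-device artifacts beyond additive spikes. Passing tests therefore
demonstrate that the pipeline recovers known linear lagged couplings and
holds its error rates at realistic sample sizes — not that real recordings
satisfy the linear model.

## Preprocessing choices

Outliers are flagged by a centred rolling Hampel rule
(|value − rolling median| > 3 × rolling MAD, window 11 breaths, shrunk at the
edges). The MAD uses the Gaussian consistency constant and a finite-sample
correction $n/(n-0.8)$ per window — without the correction an 11-point MAD
under-estimates the scale and clean series are over-flagged. The inequality
is strict, so constant windows (MAD 0) flag only values different from the
window median. Flagged samples are linearly interpolated over the breath
index between nearest clean neighbours; leading/trailing gaps take the
nearest clean value, and a fully-masked series is an error rather than a
guess. On clean autoregressive series under 2% of samples are flagged, and
re-running the filter on cleaned output flags under 1% (both verified by
simulation).

## Problem sizes and determinism

The test-suite simulations use the sizes at which the method's properties
are statable and stable: 100-sample windows for detection and calibration
checks, 1000 independent pairs for the nominal-level check of the surrogate
screen, 50 full 12-participant cohorts for end-to-end recovery of the
decoupled condition, 200–500 replicates for coverage and null-rate checks of
the regression stage. Every stochastic check runs from fixed seeds through
`childSeed()` substreams, so results are bit-reproducible.

## Known limitations

* TE here is pairwise: redundancy among sources can double-count shared
  information and synergy can be missed; conditional/multivariate TE is out
  of scope.
* Whole-series permutation destroys source autocorrelation, so the null
  tests exchangeability of the source, not a phase- or block-preserving
  null; block surrogates are out of scope.
* The plug-in estimator is biased at small n; the surrogate comparison
  absorbs the bias for screening purposes, but raw TE magnitudes should not
  be compared across very different window lengths.
* The generator is linear; detection-power figures quoted here do not
  transfer to strongly nonlinear couplings.
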