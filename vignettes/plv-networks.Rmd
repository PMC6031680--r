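---
title: "Phase-locking networks from event-related EEG: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-locking networks from event-related EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plvnet)
```

## The analysis this package implements

`plvnet` implements a source-level weighted functional-network analysis of
event-related EEG in the response-inhibition (Go/NoGo) setting. The chain
is:

1. stimulus-locked epoching (−100 to 900 ms, half-open window), ±75 µV
   amplitude artifact rejection, and selection of correct NoGo trials;
2. optional minimum-norm mapping of sensor epochs onto cortical nodes;
3. band-limited instantaneous phases (alpha 8–12, low beta 12–18, high
   beta 18–30, gamma 30–55 Hz) in the late inhibitory window 200–700 ms,
   and a phase-locking-value (PLV) adjacency matrix per subject and band;
4. four weighted global network indices (strength, clustering, path
   length, efficiency) plus nodal clustering;
5. trauma-score quartile grouping and covariate-adjusted group statistics
   with Bonferroni familywise control, partial η² effect sizes, post-hoc
   pairwise contrasts, and partial Pearson correlations with trauma
   measures.

Delta and theta are excluded by default: the 500 ms analysis window holds
only one or two full cycles of those rhythms, which biases PLV estimates.

Because no recorded data ship with the package, a phase-coupled oscillator
simulator generates cohorts with *known* coupling structure; every claim
the test suite makes is checked against closed forms or enumeration on
those cohorts.

## The phase-locking value and its conventions

For nodes $i,j$ with instantaneous phases $\varphi_i(t,k)$ on trial $k$,
the across-trials PLV at sample $t$ is

$$\mathrm{PLV}_{ij}(t) = \Bigl|\tfrac{1}{N}\sum_{k=1}^{N}
  e^{\,\mathrm{i}(\varphi_i(t,k) - \varphi_j(t,k))}\Bigr|,$$

averaged over the 200–700 ms window. This is the standard form for
event-locked data: it asks whether the phase *difference* is reproducible
across trials at each moment. The averaging order (across trials per
sample, then over the window) is a package choice — the construct's source
does not pin it down — and a within-trial-over-time mode is available via
`plv_matrix(..., convention = "within_trial")` for single-trial use.
Values lie in $[0,1]$ and enter the network analysis directly as edge
weights; the diagonal is forced to zero. With a single trial the
across-trials PLV is identically 1, so that case is rejected with
guidance rather than returned.

Phases come from the analytic signal of zero-phase band-filtered epochs.
Filtering is applied to whole epochs *before* cropping to the analysis
window, so filter transients sit outside the window.

## Zero-phase filtering

All band-passes use the squared magnitude response of an order-4
Butterworth, applied in the frequency domain on odd-reflection-padded
signals. This has exactly the transfer magnitude of forward–backward
(filtfilt-style) filtering — the field's standard when pre-stimulus phase
must not be displaced — while letting one FFT serve every trial, node and
subject of a batch; the compiled kernel in `src/` does that batching. The
pass band is therefore −6 dB at the band edges and the effective roll-off
is 8th order. Reflection padding spans one full cycle of the band's low
edge, and the analysis window sits ≥ 75 ms inside the epoch, so boundary
effects are negligible at the window (verified by the pass-band/stop-band
tests). The filter order is configurable; 4 is the default single-pass
order.

## The synthetic cohort generator

Each subject's node signal on trial $k$ is, per band $b$ with carrier
$f_b \in \{10, 15, 24, 40\}$ Hz,

$$x_i(t,k) = \sum_b A\cos\bigl(2\pi f_b t + \theta_{kb} +
  \varepsilon_{ikb}\bigr) + \eta(t),$$

with a common uniform trial phase $\theta_{kb}$, wrapped-normal node
jitter $\varepsilon_{ikb} \sim \mathcal{WN}(0, \sigma_i^2)$ independent
across nodes, trials and bands, amplitude $A = 10$ µV per band and
Gaussian sample noise $\eta$ (SD 2 µV). The wrapped-normal law was chosen
over von Mises because it gives the closed-form population PLV

$$\mathrm{E}\,\mathrm{PLV}_{ij} = \exp\!\bigl(-(\sigma_i^2 +
  \sigma_j^2)/2\bigr),$$

which the whole pipeline can be validated against (`expected_plv()`).
Per-node jitter keeps the expected adjacency analytic; an optional
multivariate-normal jitter covariance (`phase_cov`) provides a per-edge
coupling mode with expectation
$\exp(-(\Sigma_{ii}+\Sigma_{jj}-2\Sigma_{ij})/2)$.

**What the generator emulates:** 300 trials with an 80/20 Go/NoGo split,
correct-response flags (hit rate 0.94, NoGo correct rate 0.88), the
−100..900 ms epoch at a configurable sampling rate, trauma-questionnaire
subscales (each 5–25) whose totals fall in the three quartile intervals
(≤ 34, 34–47.5, ≥ 47.5) that define the low/middle/high groups, and
covariates (state/trait anxiety, depression, ADHD traits) whose means
rise with trauma load while activation drive falls. **What it does not
emulate:** ERP component morphology (no N2/P3 peaks), volume-conduction
leakage, ocular artifacts, non-stationary coupling within a trial, or
heavy-tailed amplitude artifacts. Passing tests therefore demonstrate the
*statistical machinery* — filtering, phase extraction, PLV estimation,
graph indices, covariate adjustment — not robustness to the full
messiness of recorded EEG.

### Calibration of the group effect

The group jitter defaults are $\sigma_g = (0.900, 0.919, 0.938)$ rad,
i.e. expected mean PLV 0.445 / 0.430 / 0.415: coupling *decreases* with
the trauma analog, a low-vs-high gap of 0.03. The between-subject jitter
SD (0.01 rad) was set from a variance budget: through the sensitivity
$|\mathrm{d}\,\mathrm{PLV}/\mathrm{d}\sigma| \approx 0.8$ it contributes
≈ 0.008 to the subject-level SD of the global clustering coefficient,
which combines with ≈ 0.017 of trial-sampling noise at 48 trials to a
total of ≈ 0.02 — the magnitude a low-beta clustering coefficient shows
between subjects in cohorts of this kind.

The questionnaire covariates shift between groups at 0.35 of the
illustrative score-table gaps (`covariate_group_shift`), preserving every
direction. Full-scale shifts would make group membership about half
predictable from the covariates alone; adjusting for covariates that
strong (which carry no independent information about the outcome in this
generator) inflates the variance of the adjusted group contrast by
$1/(1-R^2)$ and would mask the planted effect — a property of covariate
adjustment, not of the network statistics. These are fixed study
conditions of the simulation, not tuning knobs; the directional-recovery
rate is evaluated in the low beta band, the headline band of the effect
being emulated.

## Source model and inverse

The forward model is deliberately synthetic: unit-norm dipole columns with
random fixed orientations on an inner Fibonacci sphere, sensors on an
outer sphere (`synthetic_gain()`); a real head model cannot be rebuilt
without template assets and is out of scope. The inverse is the classic
regularized minimum-norm operator
$W = G^\top (G G^\top + \lambda^2 I)^{-1}$, with the usual SNR heuristic
$\lambda^2 = \mathrm{tr}(G G^\top)/(n_{\mathrm{sensors}}\,\mathrm{SNR}^2)$,
SNR = 3, when $\lambda$ is not given. No depth weighting or noise
whitening is applied. Node series are taken at selected vertices, and the
node subset is chosen by farthest-point sampling: the source nearest the
centroid anchors the first selection but is not itself returned (unless
every source is requested), so the selected set is maximally spread —
on collinear candidates with two nodes requested this yields the two
endpoints, which plain anchored greedy would not. Ties break to the
lowest index, making the selection deterministic. Dense source counts
(the thousands of cortical vertices of a template mesh, reduced to a few
hundred nodes) are configuration scales, not constants, so tests run with
tens of sources.

## Statistical model

Group comparisons use a univariate general linear model per index:
covariates (SAI, TAI, BDI, CAARS total) enter first, the three-level
group factor last, so the group F test is covariate-adjusted; partial
η² = SS(group)/(SS(group)+SS(error)). A Wilks-lambda multivariate test
across the four indices is available behind `multivariate = TRUE`, but
the univariate table is the reported surface since per-index p values are
what a group-comparison table prints. The state and trait anxiety scores
enter as two separate covariates, and the ADHD score enters as its total.
Familywise control is Bonferroni throughout: 0.05/16 for the global cells
(4 indices × 4 bands), 0.05/*n*(nodes) at the nodal level, 0.05/60 for
the trauma correlations; post-hoc pairwise contrasts multiply p by 3 and
cap at 1, with contrast standard errors taken from the full
three-group model's pooled error term, the convention of standard
post-hoc machinery. Quartile cuts use R's inclusive linear-interpolation quantile
(type 7), with boundary ties assigned to the outer groups. ANOVA power
uses the noncentral F with $\lambda = f^2 n$.

## Numerical choices and degenerate inputs

* Epochs use the half-open window $[t_{\min}, t_{\max})$, so sample
  counts are unambiguous (exactly 1000 samples at 1000 Hz).
* "Amplitude exceeding ±75 µV" is read strictly: a sample equal to the
  threshold is retained. Both the reading and the threshold are
  configurable.
* PLV matrices are symmetrized, clamped to $[0,1]$ and zero-diagonal
  before any graph computation; weights outside $[0,1]$ are a contract
  violation and raise an error in the clustering coefficient.
* Weight-to-length mapping for shortest paths is $\ell = 1/w$
  (configurable to $-\log w$); disconnected graphs raise an error naming
  the components for path length, while efficiency uses the
  0-contribution convention. Global strength is reported as the *mean*
  nodal strength, the only reading on which a complete unit-weight graph
  gives strength $n-1$ alongside clustering and efficiency 1. Onnela
  clustering is used without max-weight renormalization since PLV weights
  are already in $[0,1]$; renormalizing would force uniform graphs to
  clustering 1.
* An identically zero signal has no phase and raises an error; a subject
  with fewer than two usable NoGo epochs is dropped with a warning; a
  fully covariate-explained variable has partial correlation 0 by
  convention, while a constant input is an error.
* All randomness funnels through the master seed of the simulation
  config; cohort generation, per-subject signals and every downstream
  stage reproduce bitwise under a fixed seed.

## Problem sizes used in the checks

The simulation studies in the test suite and acceptance script run desk-
scale cohorts chosen to make their Monte-Carlo error small while keeping
a laptop-friendly footprint: 15/25/15 subjects, 20 nodes, 48 NoGo trials
per subject at a 125 Hz simulation rate (Nyquist 62.5 Hz comfortably
above the 55 Hz gamma edge), with 100 replicate cohorts for the type-I
study and 50 for the directional-recovery study; the PLV-law check uses
2000 trials, and partial-correlation recovery uses 25 cohorts of n = 150.
The analytic PLV law makes these sizes sufficient: expected effects are
known exactly, so the studies measure estimator behaviour, not discovery.

## Known limitations

* The generator's per-trial phase offsets are constant within a trial, so
  time-resolved coupling dynamics inside the window are not exercised.
* PLV is used as-is, with no leakage-corrected variants (imaginary
  coherence, PLI, wPLI); on real source estimates, minimum-norm leakage
  would inflate short-range edges. That parity with the emulated analysis
  is intentional.
* The synthetic forward model is spatially smooth but anatomically
  meaningless; localization accuracy claims are limited to round-trip
  recovery of row-space sources.
* Group labels are re-derived from empirical quartiles, so a subject near
  a cut point can land on the other side of it than the generative label;
  with the truncated group-conditional score distributions this affects
  at most the boundary subjects.
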