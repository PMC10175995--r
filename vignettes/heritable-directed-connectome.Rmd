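---
title: "Methods: heritability of directed functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heritability of directed functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcherit)
```

This vignette documents the models, the estimation choices, and the places
where the design was genuinely open, in enough detail that a maintainer can
judge what each passing test does and does not establish.

## The analysis in one paragraph

Per subject, network time-series from several resting-state sessions are
deconvolved node-by-node with a blindly estimated hemodynamic response
function (HRF), a vector autoregression (VAR) is fitted by pooling all
sessions, and state-space Granger causality (GC) assigns every ordered
network pair a non-negative directed strength. Each directed connection is
then an "endophenotype": across a cohort of MZ/DZ twins, siblings and
singletons, its variance is decomposed into additive-genetic, shared-
environment and unique components on the kinship structure, giving a
narrow-sense heritability per connection, a boundary-corrected
likelihood-ratio test, FDR control across connections, and a
discovery/replication overlap on a kinship-aware matched split.

## Hemodynamic model and blind deconvolution

The forward model per node is `b(t) = (h * n)(t) + noise`, with `h` a
double-gamma kernel (positive lobe with configurable time-to-peak, an
undershoot near 16 s, support 24 s) and `n` the latent neural activity.
Regional variation of the peak latency (the generator jitters it uniformly
over 4–7 s) creates spurious lead/lag structure: a target with a faster HRF
appears to *precede* its source, which inverts naive lag-based causality.

`detect_pseudo_events()` marks supra-threshold local maxima (default 1.0
SD, margins of one kernel length) as spontaneous events.
`estimate_hrf_blind()` is the single-series estimator: candidate
event-to-response lags are scanned with a latency-matched kernel (detected
events sit at response peaks, so the lag and the kernel peak are one
quantity), then the shape is refined with a canonical-plus-derivatives
basis at the selected latency; a fit explaining less than 20% of variance
(`min_r2`) falls back to the canonical kernel, which is what pure noise
produces. An identifiability point worth stating: for a *Gaussian*
stationary process the convolution phase is not identifiable at all — every
estimator of HRF latency implicitly exploits the sparse, positively skewed
character of spontaneous activity.

That observation motivates the pooled estimator the pipeline uses by
default (`estimate_hrf_pooled()`): all sessions of a subject-node pair
share one kernel, whose peak latency is chosen from a 3–10 s family (step
0.25 s) by **maximizing the skewness of the Wiener-deconvolved proxy** at
light regularization (ridge 0.01 of the spectral peak). The correct kernel
re-concentrates the signal into sharp positive events; a mis-specified one
smears them. Unlike derivative-basis regression, whose latency estimates
shrink toward the canonical 6 s peak, this criterion uses every sample and
is unbiased enough to correct a 2 s latency difference between nodes (the
direction-rescue experiment below). The selected kernel is then anchored by
the pseudo-event regression (lag, residual, fallback flag).

`wiener_deconvolve()` inverts the kernel in the frequency domain,
`N = conj(H) B / (|H|^2 + lambda)` with `lambda` defaulting to
`0.1 max |H|^2`. The series is padded by *odd* (anti-symmetric) reflection:
the near-inverse filter amplifies any junction discontinuity globally, and
odd reflection keeps both value and slope continuous, which is what makes
the noiseless round-trip correlate at 0.95+ with the input. `lambda = 0` is
refused when the kernel spectrum has near-zero bins.

## State-space Granger causality

`fit_var_pooled()` stacks lagged predictor/target rows across sessions —
no row spans a session boundary — and solves one least-squares problem, so
four sessions inform a single model per subject. Order selection (AIC
default, BIC available) minimizes `log det Sigma_ML + pen * p N^2 / M`.
The fitted VAR becomes an innovations state-space model
(`var_to_state_space()`): companion transition matrix, observation matrix
`(A_1 ... A_p)`, gain injecting the innovation into the first block, and
innovations covariance equal to the residual covariance.

For a source `j`, the reduced model observes the same state process
without row `j`. Its steady-state innovations covariance `V^R` solves a
discrete algebraic Riccati equation with state/observation noise
cross-correlation; `solve_dare()` eliminates the cross term and runs the
structured doubling iteration (tolerance 1e-12, at most 500 doublings —
convergence is quadratic and typically takes ~15). Then
`F(j -> i | rest) = ln(V^R_ii / V_ii)`, one Riccati solve serving all
targets of a source. Theory makes `F >= 0`; values in `(-1e-10, 0)` are
numerical and clipped, with a counter kept. The default conditions on all
remaining nodes; an unconditional pairwise mode reduces the same full state
process to each pair.

Two numerical safeguards: per-source Riccati failures produce `NaN` rows
rather than aborting a run, and a fitted VAR with spectral radius at or
above 1 (occasional at short series) is rescaled — lag-`k` coefficients
multiplied by `(0.98/rho)^k`, the unique lag-operator rescaling that moves
every companion eigenvalue inside the unit circle — before the state-space
step. Both events are logged per subject.

Correctness is pinned by two independent oracles: the analytic
autocovariance sequence of the state-space form against the discrete
Lyapunov solution, and GC against a brute-force reduced-autoregression
oracle (fit a long AR to the analytically derived autocovariance of the
target alone and compare innovation variances), which agrees to ~1e-15 on
random stable bivariate systems.

## The quantitative-genetic stage

Preprocessing order: ordinary least-squares residualization against
intercept, age, sex, handedness and education first, then the rank-based
inverse normal transform with Blom constants,
`qnorm((rank - 3/8)/(n + 1/4))`, mean ranks for ties. Constant covariate
columns are dropped silently (they carry nothing beyond the intercept);
genuine collinearity is an error naming the columns.

The covariance model for one trait vector `y` over the pedigree is
`sigma_p^2 * M(h2, c2)` with `M = h2 (2 Phi) + c2 H + (1 - h2 - c2) I`.
Families are independent blocks, so the likelihood factorizes; families
with identical (kinship, household) block structure share all matrix work,
and the total variance is profiled out analytically. The variance shares
are maximized on a simplex grid of step 0.01 (capped at 0.99 so MZ blocks
stay invertible), then refined by nested local grids to 1e-4 resolution
(`vc_design()` precomputes the per-structure inverses and log-determinants
once, which is what makes a 1,000-trait null calibration run in seconds).
Boundary solutions (`sigma_g^2 = 0`, `sigma_c^2 = 0`) are legitimate
outcomes; an essentially flat profile — e.g. an all-singleton pedigree,
where `2 Phi = I` makes genetic and unique variance inseparable — is
flagged `unidentifiable` and returned at the zero-heritability boundary.

The heritability test compares the full fit with the `sigma_g^2 = 0` null
(E-only under AE, CE under ACE). Because the null is on the boundary, the
statistic is referred to the 50:50 mixture of a point mass at zero and
chi-square(1): `p = 0.5 P(chi2_1 >= Lambda)`, `p = 0.5` at `Lambda = 0`.
FDR is Benjamini–Hochberg within each cohort across all N(N-1)
connections; connections whose optimizer fails (full likelihood below the
null) are excluded from the FDR family and counted. The replication
percentage is `100 * |both| / |discovery|`, rounded to the nearest integer
— with 152 discovery-significant connections of which 58 replicate this is
38%; with 56 and 8 it is 14%.

## Cohort split

`split_cohort()` groups families by exact composition (one MZ pair, three
siblings, ...) and randomly halves every composition class, which makes
identical group counts on both sides a construction invariant rather than
an optimization target; an odd class count is an error naming the class.
Covariate balance (absolute standardized mean difference with pooled SD,
sex/handedness on numeric codes) is brought under the tolerance (default
0.05) by restarting the randomization, and only if that fails by excluding
matched same-class family pairs — one from each side, preserving the
counts — until balance is reached. The exclusion rule is a reproducible
stand-in for interactive matching software; which subjects a human
operator would have excluded is not reconstructible. `balance_report()`
uses Welch t for the continuous covariates and chi-square for the
categorical ones.

## What the generator emulates, and what it does not

`simulate_pedigree()` draws a cohort of configurable composition (defaults:
62 MZ pairs, 25 DZ pairs, 197 siblings in groups of 2–3, 78 singletons —
449 individuals) with young-adult demographics (age ~29 ± 4, clustered
within family; education ~15 ± 2; ~90% right-handed; co-twins share sex).
`simulate_ace_traits()` draws each connection's latent coupling trait from
the exact model covariance, so the variance decomposition is true by
construction. `build_subject_var()` plants the traits on a sparse directed
edge set (default: a ring) as `coupling = base * (1 + trait)`, trait
clipped to ±0.8 to preserve edge sign, spectral radius capped at 0.95.
`generate_bold()` runs the VAR at TR resolution (no super-resolution;
burn-in 200 steps), convolves each node with its jittered-latency kernel,
adds white observation noise (default SD 0.5 of the signal), and
standardizes.

Neural innovations default to a **burst** model: Gaussian background (SD
0.5) plus sparse positive exponential spikes (probability 0.04 per sample —
about one event per 10 s at TR 0.72 s — mean amplitude 4), standardized to
unit variance. This is deliberate: spontaneous resting-state activity is
event-like, and (see above) a purely Gaussian latent process would make
blind HRF estimation impossible in principle; a `gaussian` option exists
for experiments where spikiness is irrelevant (e.g. the GC consistency
checks).

Not emulated: physiological noise structure (cardiac/respiratory),
head-motion artefacts, spatial ICA mixing, session-to-session
non-stationarity, and any nonlinearity in the hemodynamic coupling.
Passing tests therefore demonstrate correctness of the estimators under
this generative family, not robustness to everything real fMRI contains.

## Problem sizes and calibration experiments

The suite and the acceptance script use desk-scale versions of the study
design, chosen so each experiment is statistically decisive:

* GC oracle agreement: 20 random stable bivariate VAR(1) systems,
  tolerance 1e-3 (observed ~1e-15).
* Estimation consistency: 5-node random VARs, 20 replicates; the median
  absolute GC error at T = 4,000 is ~0.25–0.35 of its T = 1,000 value
  (both noise, which scales as T^-1/2, and plug-in bias, which scales as
  T^-1, shrink).
* Direction rescue: 2 nodes, coupling 1→2 (0.4), source HRF peak 7 s vs
  target 5 s, 4 sessions × 1,200 points, observation noise 0.2; over 50
  replicates raw-BOLD GC picks the true direction essentially never, the
  deconvolved pipeline in ≥90% (typically 96–100%).
* Variance-component recovery: the 449-subject default cohort; 50 traits
  at h² = 0.40 (AE) recover a mean within [0.35, 0.45] with RMSE < 0.15;
  ACE at (0.35, 0.20) recovers both means within ±0.07.
* Null calibration: 1,008 null traits on the same cohort; the
  boundary-corrected test rejects at nominal 0.05 with empirical rate
  0.04–0.06.
* End-to-end determinism: the full synthetic pipeline (120 subjects, 10
  nodes, 2 × 400 points) run twice writes byte-identical result files.

## Known limitations

* Heritability of *estimated* GC is attenuated relative to the latent
  coupling heritability because connectivity estimation noise loads on the
  unique-environment component; at the demonstration scale (60 subjects
  per cohort) few connections survive FDR. This mirrors the real analysis,
  where power comes from cohort size.
* Kinship is derived from group labels (MZ/DZ/sibling within family); the
  framework does not cover multi-generation pedigrees, half-siblings or
  inbreeding, and household defaults to family (overridable via `hhid`).
* The ACE model with household = family leaves `c²` partially confounded
  with the sibling kinship term; MZ pairs carry most of the separating
  information, and ACE estimates are correspondingly noisier than AE ones.
* The lag grid (0–14 samples), kernel support (24 s), event threshold
  (1 SD) and the 0.01 selection ridge are documented defaults, not
  universal constants; cohorts with very different TR or SNR may need
  different values.
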