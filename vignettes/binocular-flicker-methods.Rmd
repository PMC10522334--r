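---
title: "Binocular combination of luminance flicker: models and methods"
author: "ssflicker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binocular combination of luminance flicker: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssflicker)
```

## The scientific problem

When both eyes view the same flickering light, is the neural (or
pupillary, or perceptual) response larger than for one eye alone — and by
how much?  For spatial patterns the visual system shows *ocularity
invariance*: interocular suppression normalises the two eyes' inputs so
that binocular and monocular responses are nearly equal at high contrast.
Whether the same rule governs spatially uniform luminance flicker, in the
cortical pathway and in the subcortical circuit that drives the pupil, is
an empirical question.  This package provides the modelling and analysis
machinery to ask it: a binocular gain-control model, steady-state Fourier
analysis for flicker-entrained responses, complex-domain test statistics,
a dichoptic contrast-matching toolchain, and hierarchical Bayesian
parameter estimation — together with synthetic-data generators so the
entire pipeline runs end to end without any recorded data.

## The gain-control model

Each eye's channel divides its squared contrast by a gain pool containing
its own contrast and a weighted copy of the other eye's contrast:

$$Resp_L = \frac{L^2}{Z + L + wR}, \qquad
  Resp_R = \frac{R^2}{Z + R + wL},$$

with the binocular output

$$Resp_B = R_{max}\,(Resp_L + Resp_R) + n.$$

Parameters, with units and their roles:

* `Z` — saturation constant (% contrast).  Shifts the contrast-response
  function laterally; larger `Z` delays saturation.
* `w` — interocular suppression weight (dimensionless).  The parameter of
  scientific interest: `w ≈ 1` abolishes the binocular advantage at high
  contrast (ocularity invariance); `w ≈ 0` gives near-linear binocular
  facilitation (a response ratio of 2).
* `n` — noise parameter.  For amplitude data it is both the additive
  response offset and the residual scale of the likelihood; for matching
  data it is the decision-noise SD of the observer.
* `Rmax` — output scaling (response units per model unit: mm for pupil
  diameter, µV for EEG).  Omitted for matching data, where a common
  scaling cancels in the response comparison.

The numerator exponent is fixed at 2 because a free exponent trades off
with `w`; the second gain-control stage of the ancestral two-stage model
is deliberately omitted.  The noise-free binocular:monocular response
ratio is $2(Z+c)/(Z+c(1+w))$, which lies in $(2/(1+w), 2]$ — a useful
sanity bound that the test suite checks.

### Waveform mode and its rectification convention

For time-varying inputs the same equations are applied at every time
point.  The equations are written for non-negative contrast signals, but
sinusoidal luminance modulation is signed; how signed contrast enters
them has to be decided.  We half-wave rectify each eye's signal into an
on-channel before the equations (negative lobes to zero).  Pure squaring
of a signed sinusoid would generate only even harmonics, which would
contradict the strong first-harmonic responses such experiments measure;
rectification followed by the quotient nonlinearity yields both odd and
even harmonics, and — only when `w > 0` couples the eyes —
intermodulation components at the sums and differences of dichoptic
input frequencies (3.6 Hz and 0.4 Hz for 2 and 1.6 Hz inputs).  An
off-channel is not modelled; this is the main open choice in waveform
mode and is confined to `responseWaveform()`.

Whether `n` is added before or after the `Rmax` scaling is ambiguous in
the usual typography; we implement it as written above (after scaling).

```{r model-demo}
p <- gainParams(Z = 2.62, w = 0.02, n = 0.15, Rmax = 0.00336)
binocularResponse(96, 96, p)
binocularRatio(96, p)
```

## Steady-state spectral analysis

The analysis path is fixed: read → interpolate dropped frames (pupil) →
epoch → Fourier transform → pool eyes (pupil) or average the four
occipital electrodes POz/Oz/O1/O2 (EEG) → coherent averaging with
outlier exclusion.  A 5 Hz zero-phase Butterworth filter exists for
waveform display only and is provably absent from this path (a unit test
inspects the pipeline trace).

Numerical conventions:

* **Epochs** skip the first 2 s after stimulus onset (onset transient)
  and keep 10 s, giving 0.1 Hz spectral resolution, which cleanly
  separates 2, 1.6, 0.4 and 3.6 Hz bins.
* **Spectral scaling** is the sine-amplitude convention (`2/N` off-DC): a
  sinusoid of amplitude *A* yields a bin of modulus *A*, so recovered
  amplitudes are directly comparable to stimulus contrasts, and total
  off-DC power equals the time-domain variance (Parseval, asserted to
  1e-6 relative).
* **Coherent averaging** means averaging complex Fourier coefficients;
  phase-inconsistent noise cancels at $1/\sqrt{M}$.
* **Outlier exclusion** removes points with Mahalanobis distance > 3 from
  the complex mean, one pass per averaging stage (trials→participant,
  participants→group), never iterated — this keeps the estimator
  deterministic.  Below 5 points the covariance is too unstable and the
  filter passes data through; a singular covariance falls back to pooled
  isotropic variance.
* **Gap interpolation** is linear, with a 0.5 s repairable-gap ceiling
  (a typical blink); longer gaps mark the trial unusable.  Interpolation
  operates on pupil diameter directly.
* **Bootstrap SEs** resample participants (never trials) with
  replacement, 1000 iterations by default.

### Complex-domain statistics

`tcirc2()` tests a sample of complex coefficients for non-zero mean
assuming isotropic complex Gaussian noise; the statistic
$M(M-1)|\bar z|^2 / \sum|z_i - \bar z|^2$ is F(2, 2M−2) under the null.
`anova2circ()` extends this to factorial designs: sums of squares are
squared complex moduli and every df count doubles (each observation has a
real and an imaginary part).  For a 2-condition × 5-contrast design with
30 participants the contrast effect has df (8, 580) under the default
within-cell error stratum; passing a `subject` factor removes
between-subject variance and gives the repeated-measures stratum
(df (8, 232) for one factor at five levels).  Both error strata appear in
published analyses of this design family; we default to the within-cell
stratum and expose the other.  Because closed-form small-sample
behaviour is delicate, both tests are validated by Monte Carlo
calibration (type-I error within ±0.015 of the 5% nominal level) rather
than against printed formulas alone.

## Contrast matching

The matching experiment asks which of two flickering discs appears more
intense: a binocular standard (24% or 48%) versus a target split between
the eyes at one of nine ratio/side conditions.  Target contrast follows a
1-up/1-down staircase in dB steps (3 dB, halved to 1.5 dB after two
reversals; step size is an efficiency choice only, since the PSE is
re-estimated by maximum likelihood over all trials).  The simulated
observer judges the target more intense with probability
$\Phi((Resp_T - Resp_S)/n)$ — a single-interval probit rule; any
two-interval $\sqrt2$ factor is absorbed into `n`, affecting its scale
but not the ordering of `w` or `Z` across datasets.  Lapse rate is fixed
at 0.  Psychometric functions are cumulative normals fitted by probit
GLM; the PSE is the 50% point and may extrapolate beyond 100% contrast.
PSEs are averaged across participants in dB.  Mirror-symmetric left/right
conditions can be averaged before contour assembly via
`assembleContour(averageSides = TRUE)`; both behaviours are supported
because published contour figures are ambiguous on this point.

The canonical references are the linear-summation locus
$c_L + c_R = 2 \cdot \text{standard}$ and the winner-take-all locus
$\max(c_L, c_R) = \text{standard}$.  A near-linear observer
(`w ≈ 0.09`) produces a contour hugging the linear locus with a
monocular:binocular PSE ratio just above 1.8; at `w = 1` the ordering
reverses toward winner-take-all.

## Hierarchical Bayesian fitting

A single group-level parameter set is fitted per dataset kind — there are
no per-participant parameters.  This flat structure is a deliberate
reconstruction: the group-noise correction (dividing `n` by $\sqrt N$
when fitting coherently averaged group data) only makes sense if the
likelihood operates at the group level with one noise parameter, so we
adopt the structure that correction implies.  Likelihoods are Student-t
(ν = 5, fixed — heavy-tailed robustness without another free parameter)
for steady-state amplitudes, centred on the model amplitude with scale
`n`, and Bernoulli with the probit decision rule for single-trial
matching data (both 24% and 48% standards fitted jointly).  Priors are
positive-truncated Gaussians: mean 1, SD 0.5 for `w` and `Rmax`; mean 5,
SD 2 for `Z` and `n`.

Sampling is adaptive random-walk Metropolis on log-transformed
parameters (component-wise proposals tuned toward 44% acceptance during
warmup).  Cluster-scale chains are replaced by a convergence-diagnostic
contract: split R-hat below 1.05 (fits failing it are returned but
flagged), effective sample sizes reported.  Posterior medians are the
point estimates.  The sampler is cross-checked in the test suite against
a dense-grid quadrature posterior, by simulation-based calibration (rank
uniformity of the true `w` across 200 prior-draw replicates), and by
prior recovery on uninformative data.

```{r fit-demo, eval = FALSE}
p <- gainParams(Z = 3.44, w = 0.61, n = 0.01, Rmax = 0.00023)
d <- generateAmplitudeDataset(ampConfig(p, seed = 1))
ga <- groupAmplitudes(participantAmplitudes(d), seed = 1)
fit <- samplePosterior(ga, kind = "pupil", groupN = 30, seed = 1)
posteriorSummary(fit)
```

## What the synthetic data emulate — and what they do not

The generators reproduce the study design: 6 ocular configurations
(monocular, binocular, dichoptic, and their cross-frequency variants) ×
5 contrasts (6, 12, 24, 48, 96%), mask fixed at 48%, 30 participants,
six trials per cell (three 60-trial blocks over 30 cells), 12-s trials
at 120 Hz (pupil, mm) or 1 kHz (EEG, µV), and the full 54-block × 50-trial
matching session.  Defaults chosen once where the design is silent:

* trial-level complex noise SD defaults to $n\sqrt{T}$ for $T$ trials
  per cell, so a participant's trial-averaged amplitude carries residual
  noise `n` — the level the model's likelihood assumes (the dual role of
  `n` as offset and scale makes this the self-consistent choice);
* participant heterogeneity is a log-normal amplitude scale (sdlog 0.2)
  with phases clustered across participants (jitter SD 0.3 rad) —
  cross-participant phase coherence is what makes group-level coherent
  averaging meaningful, and the real pipeline relies on it;
* pupil onset transient: one exponential constriction of 0.4 mm with a
  1-s time constant, so the 2-s epoch skip is exercised realistically;
  dropped frames occur independently per sample at probability 0.02;
* broadband white noise of 0.03 mm (pupil) / 5 µV (EEG) per sample.

Trial noise is isotropic complex Gaussian by construction — exactly the
assumption under which the T²circ family is calibrated, which is why the
calibration tests are meaningful.  The generators do **not** emulate 1/f
EEG background spectra, ocular artifacts, nonstationary pupil drift, or
harmonic/intermodulation energy in raw traces (raw traces are built from
scalar model amplitudes; harmonics and IM terms are predictions of the
waveform-mode model, exercised directly on `responseWaveform()` output).
Passing tests therefore demonstrate correctness of the machinery under
the study's statistical assumptions, not robustness to every real-data
pathology.

## Problem sizes and reproducibility

The test suite and the acceptance script use desk-scale problem sizes
chosen as this package's own defaults: 10-s waveforms at 1 kHz for
spectral structure; 10⁴ null replicates for T²circ calibration and
2×10³ for ANOVA²circ; the full N = 30 design for parameter recovery with
4 chains × 1500 draws; 200 reduced-draw replicates for simulation-based
calibration; one simulated observer's full 2700-trial session for
matching recovery.  Every stochastic stage derives its seed from a single
top-level seed through a counter-based scheme, so stages are reproducible
independently of execution order, and every generator is a pure function
of (config, seed).

## Known limitations

* The flat group-level hierarchy cannot describe between-participant
  parameter differences; `w` heterogeneity would be absorbed into the
  residual.
* Fitting uses scalar contrast values (as the tractability of the
  waveform likelihood dictates); waveform-domain fitting is out of scope.
* The amplitude likelihood operates on moduli of coherent means, whose
  small-sample (Rice) bias at low signal-to-noise is mitigated — not
  removed — by fitting group-averaged data with the $\sqrt N$ noise
  correction.
* `anova2circ` requires balanced designs; when exclusion empties a cell
  the function errors rather than imputing or rebalancing.
* The matching observer has no lapse rate and no interval-order effects.
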