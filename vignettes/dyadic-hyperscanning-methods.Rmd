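---
title: "Methods: simulation, QC and inter-brain synchrony for dual-subject fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, QC and inter-brain synchrony for dual-subject fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadfmri)
```

# The problem

Hyperscanning fMRI acquires BOLD time series from two interacting subjects
in one scanner bore, splits the shared field of view into one dataset per
subject, reorients both to a common radiological convention, and asks which
spatially analogous voxels carry *synchronous* activity. Alongside the
synchrony statistic, the same acquisitions support conventional QC (temporal
SNR, receive-array noise correlation, head motion) and block-design task
analysis. Because the interesting quantities — an inter-brain correlation, a
task beta, a motion bound — are unobservable in real data, this package
pairs the full analysis chain with a synthetic generator whose ground truth
is known exactly, so every stage can be validated by parameter recovery and
null calibration rather than by eye.

# The generator

Each in-mask voxel $v$ of subject $s$ in run $k$ follows

$$ y_{s,v}(t) \;=\; B\,\bigl(1 + d(t)\bigr) \;+\; c(v)\,g_k(t)
   \;+\; \beta(v)\,x(t) \;+\; \varepsilon_{s,v}(t), $$

with

* $B$ — baseline intensity (default 100, arbitrary units);
* $d(t)$ — polynomial drift on time normalized to $[-1,1]$ (default
  $0.01u - 0.005u^2$, i.e. about a percent of baseline — typical slow
  scanner drift). The polynomial form matches the detrending basis, so
  noise-free recovery is exact. Note the drift is deterministic and
  therefore *common to both subjects*: this is deliberately the worst case
  for the synchrony null, and it is why every analysis route removes trends
  by regression (below);
* $g_k(t)$ — a shared latent: white Gaussian noise restricted to
  0.01–0.1 Hz in the Fourier domain and standardized per run. Spatially
  analogous ROI voxels of *both* subjects receive the same $g_k$; runs get
  independent latents;
* $c(v)$ — coupling amplitude, nonzero only inside the designated ROI. For
  a target inter-brain correlation $\rho$ it is set to
  $c = \sigma\sqrt{\rho/(1-\rho)}$, which makes the correlation of two
  voxels observing $c\,g + \text{noise}(\sigma)$ exactly
  $c^2/(c^2+\sigma^2) = \rho$;
* $\beta(v)\,x(t)$ — the task response: the condition indicator of a block
  design convolved with the HRF kernel (below), scaled by $\beta$ inside a
  task ROI;
* $\varepsilon$ — stationary AR(1) Gaussian noise with SD $\sigma$
  (default 2.2, giving tSNR $\approx 100/2.2 \approx 45$, the level a
  close-fitting dual receive array attains in vivo) and coefficient
  $\varphi$ (default 0.1, see *Numerical and calibration choices*).

Out-of-mask voxels receive small independent noise rather than zeros, so
temporal-SNR maps stay finite and masking is genuinely exercised. Motion
traces are smoothed, bounded random walks (zero at the middle reference
volume), emulating the residual motion of a rigid four-point head fixation;
defaults bound them by 140 µm and 0.6° — the levels that make motion
negligible at 1-mm voxels. Receiver noise samples are multivariate Gaussian
draws from a channel covariance; `example_noise_covariance()` is a
*synthetic* 10-channel fixture whose summary magnitudes (intra-coil
mean/max ≈ 12 %/28 % and 13 %/29 %, inter-coil max 2.3 %, 9.7 % noise-level
difference) match published values for a dual five-element array, because
the raw samples behind those summaries are not distributed.

All randomness derives from one master seed through stable subject/run/stage
labels (`derive_seed()`), so each run is independent yet the whole dataset
is bit-reproducible.

**What the generator does not emulate:** physiological (cardiac,
respiratory) noise and its spatial structure, EPI geometric distortion and
k-space effects, spatially correlated noise, hemodynamic nonlinearity,
registration error. Passing recovery tests therefore demonstrates that the
*analysis* is correct and calibrated under the stated noise model — not that
real marmoset data meet that model.

# Default study conditions

| Parameter | Default | Why |
|---|---|---|
| TR | 1.5 s | whole-brain EPI repetition time of the emulated acquisitions |
| Resting run | 4 runs × 400 volumes (10 min) | matches the dual resting acquisition |
| Task run | 172 volumes: 17 alternating blocks, 18 s opaque / 12 s transparent | the social-viewing block paradigm |
| Temporal band | 0.01–0.1 Hz | resting-state filtering band |
| Smoothing | 1.5 mm FWHM (resting), 2.0 mm (task) | the two pipelines' kernels |
| Detrending | order 5 (GLM and filtering), order 2 (tSNR) | fifth-order matches the GLM design; tSNR needs only slow-drift removal |
| Synchrony threshold | z ≥ 3.1, one-sided | synchrony is reported as positive shared activity; two-sided available |
| Contrast thresholds | \|t\| > 2.26 (df = 9), \|z\| > 1.96 | two-sided 5 % points; df = 9 corresponds to a paired test across 10 runs |
| Motion bounds | 140 µm, 0.6° | restraint performance bound |
| Subject separation | 11 cm, face-to-face (layout metadata) | the distance at which natural social interaction is possible |

# The synchrony statistic

Per run, each voxel's time course is normalized to mean 0 and SD 1
(population SD; the convention is recorded in provenance) — this prevents
inter-run differences in mean and scale from biasing the correlation. Runs
are concatenated voxel-wise, and the Pearson correlation $r_v$ is computed
between the two subjects' series at each in-mask voxel index (both subjects
having been reoriented to one convention, index $v$ is spatially analogous
across subjects).

The map is then Fisher-Z transformed. A threshold of 3.1 is only meaningful
on a standard-normal scale — plain $\operatorname{atanh}(r) = 3.1$ would
require $r \approx 0.9996$, implausible for BOLD at any series length — so
the package uses the variance-stabilized form

$$ z_v = \operatorname{atanh}(r_v)\,\sqrt{n-3}, $$

with $n$ the raw concatenated time-point count and $r$ clipped to
$\pm(1-10^{-12})$ so identical series stay finite. Plain
$\operatorname{atanh}$ is available via `fisher_z(..., scaled = FALSE)`.

**Effective degrees of freedom.** No autocorrelation correction is applied
to $n$. Under AR(1) noise the null SD of $z$ is inflated by
$\sqrt{(1+\varphi^2)/(1-\varphi^2)}$, and band-pass filtering to a width-$W$
band shrinks the effective df towards $\approx 2WT$, inflating $z$ by
roughly $\sqrt{n/n_\mathrm{eff}}$ (about two-fold for 0.01–0.1 Hz at
TR 1.5 s). Supra-threshold extent after filtering is therefore
anticonservative; the calibrated route (used by the acceptance checks)
removes trends by regression and correlates the unfiltered residuals.

# Preprocessing choices

* **Filter realization.** The band-pass is a zero-phase frequency-domain
  mask with cosine-tapered transitions extending outward by 30 % of each
  edge frequency: unit pass-band gain, > 20 dB attenuation one octave past
  either edge, no phase distortion, and trivially testable against an FFT
  oracle. Because the transform is circular, aperiodic trends would leak
  across the pass band, so pipelines detrend by regression *before*
  filtering.
* **Detrending basis.** Orthogonal (Legendre-style) polynomials on
  $[-1,1]$ per run — numerically stable to order 5.
* **Smoothing.** Separable Gaussian with
  $\sigma_\mathrm{mm} = \mathrm{FWHM}/(2\sqrt{2\ln 2})$, renormalized
  within the mask as $\mathrm{sm}(y\,w)/\mathrm{sm}(w)$: constant in-mask
  images are preserved exactly and no out-of-mask signal bleeds in.
  Renormalization breaks kernel symmetry near mask edges, so the in-mask
  *mean* of a non-constant image is conserved only approximately (exactly
  for constants); out-of-mask voxels are returned unchanged.
* **Normalization.** Population SD (divide by $n$); zero-variance voxels
  are zeroed and flagged rather than fatal, since background voxels are
  expected.
* **Ordering.** The synchrony stage applies smoothing → detrend →
  band-pass → per-run normalization; the task stage smooths (2.0 mm) and
  leaves trend/drift handling to the GLM's own regressors. The stage
  orderings are recorded in each output's provenance sidecar.

# The task GLM

The design matrix contains, per run: one HRF-convolved indicator per
condition (both conditions are modelled), orthogonal polynomials to order 5,
cosine drift regressors for every frequency below 0.01 Hz
($\cos(\pi k (t+\tfrac12)/n)$, $k < 0.02\,nT_R$), and the six motion
parameters. Constant motion columns are dropped with a warning; the matrix
is rank-checked with offending columns named. The HRF is the fixed-shape
gamma variate

$$ h(t) = \frac{t^4 e^{-t}}{4^4 e^{-4}}, $$

unit peak at $t = 4$ s, truncated below $10^{-4}$ of peak — a
parameter-free stand-in for tool-specific block bases whose exact
parameterization is rarely reported. Fitting is voxel-wise OLS; paired
stimulus-versus-baseline contrasts across runs use the one-sample t on
per-run coefficient differences (df = runs − 1; 2.26 at 10 runs), and the
between-paradigm contrast is a pooled-variance two-sample t (Welch behind a
flag) mapped to z by tail-probability equivalence
($z = \Phi^{-1}(F_t(t;\nu))$, evaluated through the upper tail for
stability). Thresholds are two-sided and uncorrected by default, mirroring
how such maps are reported.

Because the two convolved condition indicators sum to a nearly constant
series, the design is ill-conditioned in the individual condition columns
(their *difference* is well conditioned); estimates remain unbiased with
inflated single-condition variance, which the paired difference contrast
avoids.

# QC conventions

* **tSNR** is $|\mu_\mathrm{orig}| / \mathrm{SD}(\text{detrended})$ per
  voxel (absolute mean keeps background voxels nonnegative; in-brain values
  are unaffected). The detrend order defaults to 2: enough to remove slow
  drift without modelling the full GLM basis.
* **Between-subject tSNR difference** uses the symmetric-mean denominator
  $|\mu_a-\mu_b| / \bigl((\mu_a+\mu_b)/2\bigr) \times 100$. For whole-brain
  means 46.4 and 44.5 this gives 4.18 %, which published summaries round to
  4 %; the convention is logged, not silently matched.
* **Noise correlation** is the Pearson matrix of noise-only channel samples
  (in percent), summarized as intra-coil mean/max and inter-coil max of the
  absolute off-diagonals; per-coil noise level is the mean channel SD with
  the same symmetric difference convention. Low inter-coil correlation is
  what rules out coil coupling as the source of apparent inter-brain
  synchrony.
* **Motion summaries** are per-axis and overall maxima of absolute
  displacement; a run passes when every maximum is within the configured
  bounds.

# Numerical and calibration choices

* $r$ is clipped to $\pm(1-10^{-12})$ before $\operatorname{atanh}$;
  zero-variance voxels are flagged and excluded from summaries; degenerate
  (rank-deficient) nuisance or design sets are errors naming the columns.
* AR(1) innovations are Gaussian with variance scaled so the stationary SD
  equals $\sigma$, keeping the coupling-amplitude formula exact. The
  default $\varphi = 0.1$ keeps the noise near-white so that the raw-df
  Fisher-Z null calibration holds within the ±5 % band the package's
  acceptance checks assert: the inflation factor
  $\sqrt{(1+\varphi^2)/(1-\varphi^2)}$ is 1.01 at $\varphi = 0.1$ but
  already 1.10 at $\varphi = 0.3$. Strongly autocorrelated data would
  require an effective-df correction the pipeline (by design) does not
  apply.
* The canonical orientation convention is configurable and defaults to an
  LAS radiological display convention; the exact triplet used by any given
  site is a declaration, not something the pipeline infers.
* The synchrony threshold is one-sided at +3.1 by default; whether published
  analyses thresholded one- or two-sided is typically unstated, so the
  choice is documented and configurable.

# Problem sizes in tests and acceptance checks

The package's own validation uses reduced spatial grids (the statistics are
voxel-wise, so grid size only sets the Monte-Carlo resolution): null
calibration on a 25 × 25 × 16 grid (10⁴ voxels) at the full temporal design
(4 × 400 or 5 + 5 × 172 volumes, TR 1.5 s); coupling recovery on 12 × 12 × 8
with a 144-voxel ROI; beta recovery on 10 × 10 × 6 over 10 runs; 10⁵–10⁶
samples for channel-noise summaries. These sizes give Monte-Carlo error
comfortably inside the asserted tolerances (e.g. median-$r$ SE
$\approx 0.002$ at $n = 1600$ over 144 voxels against a ±0.02 band).

# Known limitations

* The noise model is AR(1) + polynomial drift; real BOLD noise has
  physiological structure and spatial correlation the generator omits.
* The raw-df Fisher-Z is anticonservative after band-limiting (documented
  above); region-level inference on filtered data should not take z ≥ 3.1
  at face value.
* No multiple-comparison correction anywhere, matching the uncorrected
  reporting convention of the emulated analyses.
* Registration, distortion correction, brain extraction and ICA estimation
  are upstream of this package: inputs are assumed already on a common grid
  per subject, with nuisance component *time courses* supplied, not
  estimated.
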