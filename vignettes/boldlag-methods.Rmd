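---
title: "Time-lag mapping of BOLD signals: models, parameters and design choices"
author: "boldlag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-lag mapping of BOLD signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldlag)
```

## The model

Low-frequency (0.01–0.1 Hz) BOLD fluctuations at voxel $v$ are modeled as a
mixture of shared band-limited sources, each delayed by a voxel-specific
hemodynamic delay $d_v$:

$$y_v(t) \;=\; \sum_k w_{kv}\, s_k(t - d_v) \;+\; \varepsilon_v(t).$$

The delay field $d_v$ varies smoothly over space by up to a few seconds and
is the quantity of scientific interest: under the local-hemodynamics view
the *same* field should be recovered whether the reference signal is the
global mean signal (GMS), a temporally independent network component, a
task-evoked response to simultaneous stimulation, or (with inverted sign)
an arterial inflow signal. The package implements both the estimators and a
generator for exactly this model, so recovery can be scored against known
ground truth.

## The lag estimator

`computeLagMap()` estimates $d_v$ by lagged correlation:

* both series are upsampled by band-limited (Fourier) interpolation to a
  grid of TR/4 (0.18 s at TR = 0.72 s). A cubic-spline alternative exists
  (`upsampleSeries(method = "spline")`), but Fourier interpolation is the
  default because the signals live far below Nyquist, where it is exact.
* for each candidate shift within $\pm 5.8$ s, the Pearson correlation is
  computed **over the overlapping segment only**, with means and SDs
  recomputed per shift. Zero-padded correlation is deliberately avoided: it
  shrinks the correlation at large shifts and biases the argmax toward 0.
  Shifts retaining less than 80% of the series are excluded, bounding the
  variance at the window edges.
* the reported lag is the shift maximizing $r$ **among positive fits**
  ($r > 0$); a voxel with no positive fit is flagged invalid rather than
  given a meaningless extremum. Exact ties resolve to the smaller $|lag|$,
  then to the negative lag, making the output deterministic.
* the valid mask keeps voxels with magnitude $r > 0.3$. An
  autocorrelation-adjusted Z score (below) is available as an independent
  switch; the default mirrors the common practice of thresholding on $r$
  with the adjusted Z reported as a diagnostic, since published use of the
  two rules together is ambiguous about which gates which.

Sign convention throughout: positive lag = the voxel (or artery) series
occurs *later* than the reference.

The search half-width is a parameter. 5.8 s equals 8 TR at TR = 0.725 s;
for other TRs the package keeps seconds (5.8) as the default rather than
8 TR, because the window should be set by hemodynamic delay ranges, not by
sampling. Both conventions are reachable by passing `searchHalfwidth`.

## Autocorrelation-adjusted significance

Band-limited series are strongly autocorrelated, so the nominal variance
$1/n$ of a sample correlation is far too small. `autocorrAdjustedZ()`
estimates $\mathrm{var}(\hat r)$ from the two sample ACFs and the sample
cross-correlation function (a Roy-type expansion whose white-noise limit is
$(1-r^2)^2/n$), truncating the lag sums adaptively at the first lag where
the ACF stays inside its $\pm 2/\sqrt{n}$ band for two consecutive lags.
The published method this emulates is cited rather than restated in the
source literature; the truncation rule here is our operationalization of
"adaptive truncation" and is recorded as an approximation. Monte-Carlo
checks in the test suite show the $|Z|>3$ rule holds its nominal level
($p < 0.0027$, measured $\le 0.005$) for white noise and stays far closer
to nominal than the naive Fisher Z under AR(1) noise ($\varphi = 0.5$,
where the naive rule inflates to $\approx 0.02$). The statistic is capped
at $|Z| = 38$ and flagged for degenerate $r \to 1$ inputs.

## Preprocessing

Order: linear detrend, then zero-phase band-pass. The band-pass is a
4th-order Butterworth applied forward and backward (`signal::filtfilt`)
after odd-reflection padding by one settling length ($\approx 1/f_{low}$).
Zero phase is not cosmetic here: any group delay would add directly to
every estimated lag. The passband is transparent at 0.05 Hz (amplitude
error $< 10^{-5}$, phase shift $\ll$ 1/4 grid step) and attenuates 0.5 Hz
by $> 40$ dB. Voxels left with zero variance are dropped from the valid
mask because their correlations are undefined. GMS is computed from the
detrended, filtered data; whether the original analyses filtered before or
after averaging is not documented, and this choice is recorded as ours.

## Two-stage temporal ICA with Icasso

Temporal ICA on voxel data is ill-posed at desk scale, so the package
follows the standard two-stage recipe: group **spatial** ICA (FastICA,
deflation, log-cosh) reduces the data to a small set of spatial components
and their time courses; temporal FastICA is then run on those time courses.
Two implementation constraints matter:

* spatial-stage centering is per **voxel time series**, never per time
  point across voxels — the latter subtracts the spatial mean and silently
  removes any spatially uniform (global) source.
* the fixed-point iteration sign-aligns successive estimates and, if a
  2-cycle persists past 50 iterations, averages the last two iterates;
  plain iteration can oscillate between basins and would otherwise be
  discarded as non-convergent.

Reproducibility is assessed Icasso-style: `temporalICAIcasso()` repeats the
decomposition (default 20 times) from random initializations with
per-repeat seeds derived from the master seed by a counter scheme, pools
all estimates, clusters them by average-linkage agglomeration on
$1 - |r|$, cuts at the requested number of components and returns one
centrotype per cluster. The quality index iq (mean intra-cluster minus
mean extra-cluster similarity) is near 1 for components that reappear in
every repeat; time-shuffled surrogates yield visibly lower iq. Model order
is an input, not estimated: order selection on real data is a
data-analysis decision outside this package's scope.

Local/global labeling (`classifyComponents()`) uses gray-matter coverage of
the magnitude map at $r > 0.3$ against a cutoff (default 0.5). This is an
explicit stand-in for the visual spatial-pattern judgement used in
practice, not a literature rule; the cutoff only needs to fall between the
coverage clusters, which the tests verify on constructed cases.

## Task GLM

The activation pipeline is a conventional block-design GLM: double-gamma
canonical HRF (response shape 6, undershoot shape 16, ratio 1/6, 32 s
support, unit peak), boxcar convolution, orthonormal DCT drift columns
implementing a 1/128 Hz high-pass, optional nuisance regressors, voxelwise
OLS, and a t map for the task column. Serial correlation is ignored by
default (OLS): the calibration tests use white noise, and accuracy on real
autocorrelated data is out of scope. Activation masks use a voxel
t-threshold plus a cluster-extent rule (26-connectivity, clusters
$> 10$ voxels) — a deterministic desk-scale replacement for random-field
family-wise-error correction, which targets real group data and is
deliberately not implemented. The task reference signal is the mean series
over the mask, applied per run.

## Arterial analysis

Arteries are bright on mean EPI/T1 images (time-of-flight inflow), so ROIs
are extracted by intensity thresholding within a search region, keeping the
largest 26-connected component (ties: smallest linear index). The
peripheral ROI is a 6-connectivity dilation (default radius 2 voxels — no
published radius exists) minus the artery. Artery-minus-periphery mean
intensities are compared with a paired t test. Unlike the voxelwise
estimator, `arteryGmsXcorr()` searches **both signs** of correlation and
reports both signed extrema plus the largest-magnitude peak, because the
finding of interest is a *negative* coupling; masking either sign would
prejudge it. Group summaries report all-artery and negative-coupled-only
($r < -0.3$) averages separately, since how discordant arteries should
enter a group mean is genuinely ambiguous.

## Comparison statistics and composite maps

`compareLagMaps()` correlates two maps over the intersection of their valid
masks (fewer than 10 joint voxels is flagged low-confidence);
`groupTest()` is the textbook one-sample two-tailed t on Fisher-Z
transformed per-run correlations. `centerLags()` mean-centers the valid
lags: the phrase "zero-centered by linear detrending" has no natural axis
on an unordered voxel set, so mean-centering is implemented and a spatial
detrend is deliberately not attempted; centering is immaterial to the
correlations themselves. In `buildComposite()`, "mean of the lag range" is
read as the midpoint $(\min+\max)/2$ of the valid lags (a `"mean"` option
computes the alternative reading); overlap voxels go to the component with
the larger magnitude, offsets are per-component constants, and within-
component lag contrasts are therefore never distorted.

## The synthetic generator

`makeSources()` band-limits white Gaussian noise with a zero-phase
raised-cosine spectral mask supported exactly on the analysis band, flat
over its interior 40% and tapering to zero at the edges. The interior
margin keeps $\ge 95\%$ of the source power inside the Butterworth
passband on refiltering (a brick-wall at the nominal edges would lose
$\approx 10\%$ in the filter's transition regions). Each source is
amplitude-modulated by a slow positive envelope (squared low-pass noise),
producing burst-like, super-Gaussian signals (excess kurtosis $\approx 6$)
— both a qualitative feature of real network activity and a requirement
for ICA identifiability, which Gaussian sources would void. Sources are
drawn independently (never orthogonalized, which would mix them and break
independence); a redraw rule keeps finite-sample pairwise $|r| < 0.2$.

`makeDelayField()` builds smooth fields (neighbor differences
$\le 0.5$ s; the spatial covariance of real delay fields is unquantified,
so the smoothness constant is a free parameter chosen once): a monotone
ramp ("gradient"), the ramp plus late Gaussian zones at fixed fractional
coordinates emulating watershed areas ("watershed"), or a constant. Delays
are applied by frequency-domain phase shift with odd-reflection padding —
nearest-sample shifting would quantize the ground truth coarser than the
estimator's own grid and make sub-grid accuracy untestable.

Noise is i.i.d. Gaussian per voxel (optionally AR(1), for the
autocorrelation-corrected threshold tests). The default
`noiseSigma = sqrt(1/0.36 - 1) ≈ 1.33` sets the raw voxel-versus-source
correlation to 0.6 for unit-variance signal; after band-pass filtering the
magnitude maps sit near 0.9, comparable to task-reference magnitudes on
real data. Arterial voxels are rendered as baseline + inflow intensity
offset + (negative gain) × time-shifted global source; the default shift
of −2.7 s and the negative gain reproduce the empirically reported inverse
arterial coupling scenario.

Default geometry is 20×20×12 voxels and 400–1200 frames at TR = 0.72 s:
every stage runs in seconds while leaving enough frames (432–864 s) for
stable lagged correlations. The temporal-ICA validation uses 1200 frames —
the standard resting-state run length at this TR — because ICA rotation
error is governed by the effective number of independent samples
($\approx 2 \cdot BW \cdot T \approx 150$ at 1200 frames).

## What the tests do and do not show

Passing recovery tests show the estimators are correct **under the model
they assume**: shared band-limited sources, a common per-voxel delay for
all sources, stationary additive noise. Real fMRI violates all three in
places (motion and physiological artifacts, source-specific delays,
nonstationarity), and the generator deliberately does not simulate motion,
physiological aliasing, multiband reconstruction artifacts, or biophysical
(balloon-type) hemodynamics. Results on synthetic data bound what the
pipeline can do, not what real data will give it.

Two quantitative limits surfaced by the validation are worth knowing:

* at 600 frames and raw SNR giving voxel correlation 0.6, the per-voxel
  lag error SD is $\approx 0.16$ s; the *worst* voxel among thousands
  therefore errs by $\approx 3$–4 grid steps even though the recovered
  field correlates with truth at $r \approx 0.99$. Worst-case per-voxel
  bounds tighter than that require more frames or higher SNR — this is
  estimation variance, not implementation error (an independent
  brute-force estimator shows the same tails).
* a lag map measured against a *mixed* reference (e.g. the GMS over
  regions whose network sources dominate the global one) acquires small
  region-wise offsets, because the reference carries each region's
  delay-smeared source. The composite-closure validation tiles network
  components orthogonally to the delay gradient so the half-means agree;
  with parallel tiling the same effect that makes real composite maps
  imperfect appears in miniature.

## Numerical choices

Fourier upsampling splits the Nyquist bin so the interpolant is real and
passes through the original samples exactly; output length is
$4(n-1)+1$. Phase shifting pads by odd reflection before the FFT so
wrap-around leakage stays below $10^{-2}$ of signal amplitude for delays
up to a quarter of the padded support. Correlations per shift are computed
from cumulative sums ($O(1)$ per segment) and one matrix product per
shift; ties in the argmax are resolved exactly, not by floating-point
accident, by the ordering rule above. FastICA is implemented inside the
package (whitening by SVD, log-cosh contrast); where an external ICA is
available it can serve as a cross-check but the Icasso clustering layer is
the package's own in either case.
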