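# boldlag

Voxelwise time-lag mapping of BOLD fMRI signals, with the reference-signal
machinery, temporal ICA, task GLM and arterial analyses needed to study
where the lag comes from — plus a synthetic 4D BOLD generator with known
ground-truth delay fields so every stage can be validated end to end.

## The scientific problem

Resting-state BOLD fMRI signals do not rise and fall simultaneously across
the brain: relative to the global mean signal (GMS, the average time series
over a gray-matter mask), individual voxels lead or lag by up to several
seconds, in a spatial pattern that tracks vascular anatomy (late signal in
watershed zones at the borders of arterial territories). Whether this lag
pattern reflects a traveling stimulus or the local variance of hemodynamic
responses can be probed by comparing lag maps measured against very
different reference signals — the GMS, temporally independent network
components, task-evoked responses to simultaneous wide-field stimulation,
and the (inversely coupled) internal carotid artery signal. If the lag
pattern is a property of local hemodynamics, all of these references should
yield the same map.

`boldlag` implements that comparison pipeline for researchers in fMRI
methods and cerebrovascular physiology.

## The method

For voxel time series *y<sub>v</sub>(t)* and reference *s(t)* (both
detrended and band-pass filtered to 0.01–0.1 Hz, zero-phase), both series
are upsampled to TR/4 resolution by band-limited interpolation, and for
every candidate shift *τ* on that grid within ±5.8 s the Pearson
correlation *r(τ)* is computed over the overlapping segment (means and SDs
recomputed per shift). The voxel's lag is

&nbsp;&nbsp;&nbsp;&nbsp;*t<sub>v</sub>* = argmax<sub>τ</sub> *r(τ)* among
shifts with *r* > 0,

its magnitude is *r(t<sub>v</sub>)*, and voxels with magnitude below
*r* = 0.3 (or, as a diagnostic, an autocorrelation-adjusted Z below 3) are
excluded. Positive lag means the voxel occurs later than the reference.
Lag maps from different references are compared by voxelwise Pearson
correlation over the joint valid mask, Fisher-Z transformed and tested over
runs with a two-tailed one-sample t test. Per-component lag maps from a
two-stage temporal ICA (group spatial ICA, then temporal FastICA with
Icasso reproducibility clustering) are assembled into a composite map by
per-component offset alignment.

The synthetic generator renders the model the analysis assumes:
*y<sub>v</sub>(t)* = Σ<sub>k</sub> *w<sub>kv</sub> s<sub>k</sub>(t −
d<sub>v</sub>)* + ε, with band-limited sources *s<sub>k</sub>*, a smooth
delay field *d<sub>v</sub>* applied by spectral phase shifting, and
configurable noise — so recovery of *d<sub>v</sub>* can be scored exactly.

## Worked example

```r
library(boldlag)

gt  <- makeGroundTruth(shape = c(12, 12, 8), nTimepoints = 400,
                       pattern = "watershed", range = c(-2, 2), seed = 42)
run <- renderRestingRun(gt)
pp  <- preprocessRun(run)                       # detrend + 0.01-0.1 Hz
gms <- computeGMS(pp, array(TRUE, c(12, 12, 8)))
lag <- computeLagMap(pp, gms, searchHalfwidth = 5.8)
lag
#> LagMap vs GMS: 12 x 12 x 8 grid, 1152 valid voxels
#>   search +/- 5.8 s on a 0.18 s grid
#>   lag range [-2.34, 1.98] s, median magnitude 0.88

ok <- validMask(lag)
cor(lagSeconds(lag)[ok], delayValues(gt@delayField)[ok])
#> 0.987
median(abs(lagSeconds(lag)[ok] - delayValues(gt@delayField)[ok]))
#> 0.129
```

The run carries a ground-truth delay field spanning ±2 s with late
watershed-like zones and additive noise; the estimated lag map correlates
with that field at r = 0.987 with a median absolute error of 0.13 s (below
one 0.18 s grid step). The magnitude map (median 0.88) is what the
*r* > 0.3 validity threshold acts on.

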