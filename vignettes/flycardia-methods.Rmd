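---
title: "Methods: synthetic OCM phenotyping of the fly dorsal vessel"
author: "flycardia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic OCM phenotyping of the fly dorsal vessel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`flycardia` implements a complete, fully synthetic analysis chain for
cardiac phenotyping of the *Drosophila melanogaster* dorsal vessel with
spectral-domain optical coherence microscopy (SD-OCM). The dorsal vessel is
the fly's single contractile cardiac tube; in M-mode OCM it appears in
cross-section as a dark lumen enclosed by a bright wall, beating at roughly
2 Hz. The standard read-outs are the end-diastolic area (EDA, the mean
lumen area at beat maxima), the end-systolic area (ESA, at beat minima),
the heart rate (HR), the fractional shortening
$\mathrm{FS}(\%) = 100\,(\mathrm{EDA}-\mathrm{ESA})/\mathrm{EDA}$, and an
arrhythmicity index (AI) measuring beat-period dispersion.

Because live-fly recordings are not publicly available, the package
replaces acquisition with a seeded ground-truth simulator and tests every
downstream stage against that ground truth. All empirical numbers quoted
below are computed by the test suite or by `scripts/acceptance.R`; nothing
is asserted that the code does not itself measure.

## The beat model

`area_waveform()` generates the true lumen area per frame. Each beat is a
raised-cosine contraction pulse from EDA down to ESA and back, occupying
`systole_fraction` (default 0.4) of the beat period, followed by a
diastolic plateau at EDA. Per-beat periods are drawn as
$T_i = r^{-1}(1 + c\,Z_i)$ with rate $r$, jitter coefficient of variation
$c$, and $Z_i$ standard normal truncated at $\pm 2$ SD (truncation keeps
periods strictly positive; one uniform draw per beat keeps RNG consumption
deterministic). Contraction pulses are centred on integer frames so the
trace equals ESA *exactly* at each recorded valley frame and EDA exactly
at each recorded peak frame — this makes marker-level assertions exact
rather than approximate.

Default kinematics (`kinematics_preset("WT-1wk-male")`): EDA
$7.7\times10^3\,\mu m^2$, ESA $2.9\times10^3\,\mu m^2$ — the reported
1-week-old wild-type male group means for this model system — with rate
2.0 Hz and jitter CV 0.05 as simulator defaults (no heart-rate values are
printed for any genotype, so the rate cannot be anchored further).
Recordings default to 2000 frames at 125 frames/s, i.e. 16 s.

A consequence of sampling at 125 fps: a jitter-free 2 Hz beat has a period
of 62.5 frames, so recorded valley spacings alternate 62/63 and even a
"perfectly regular" simulated rhythm carries a quantization AI floor of
about $0.5/62.5 \approx 0.008$. Tests assert AI $< 0.01$ for the
jitter-free case rather than exactly zero for this reason.

## Image formation

`render_bscan()` draws the vessel as a hollow ellipse: a bright wall
(thickness 12 µm, relative intensity 1.0) around a dark lumen (0.05) on a
darker background (0.15), with a fixed 2:1 lateral:axial aspect ratio.
The fixed aspect makes every requested area correspond to one analytic
ellipse ($A = \pi a b$, $a = 2b$), which gives closed-form expectations
for segmentation tests (e.g. $a=50, b=25 \Rightarrow A \approx 3927\,
\mu m^2$). Edges are anti-aliased with a one-pixel linear ramp, the image
is blurred by a Gaussian PSF whose sigmas derive from the 2.8 µm lateral /
3.3 µm axial FWHM resolutions, and fully developed speckle is applied as
unit-mean exponential multiplicative intensity noise — the standard
statistic for coherent imaging.

The native pixel pitch is 2.0 µm laterally (256 µm field over 128
A-scans) and 2.2 µm axially (matching the spectral depth-pixel size, see
below), so the image-level and spectral simulation paths share one
geometry. All randomness of a recording (beat jitter first, then
per-frame speckle in frame order) comes from one seed; identical seeds
give bit-identical stacks.

The wall thickness default deserves a note: with an 8 µm wall, the
segmentation pre-smoothing blurs the thin bright band enough that the
threshold crossing shifts measurably into the lumen (9–15% area
underestimation). At 12 µm the same chain is accurate to ~2%; the value
was fixed from that noise-free bias analysis.

## Spectral forward model and reconstruction

`synthesize_spectra()` implements the textbook SD-OCT forward model: per
A-scan, $I(k) = S(k)\,[1 + \sum_j r_j \cos(2 k z_j)]$ sampled uniformly
in wavelength over an 850 nm / 165 nm band on a 2048-pixel grid, with a
Gaussian source envelope $S(k)$. Dispersion, sensitivity fall-off and
autocorrelation terms are deliberately omitted; this is a desk-scale
model, adequate for exercising the reconstruction chain, and is the main
respect in which the synthetic raw data are simpler than real
interferograms.

Reconstruction follows the conventional chain (the processing used for
real recordings is unpublished lab code, so a standard chain is the honest
choice): background subtraction (`preprocess_spectrum()`, default
background = mean spectrum over the frame), linear interpolation onto a
uniform wavenumber grid (`resample_to_k()`; cubic deliberately not the
default), Hann window and FFT magnitude (`ascan()`). The depth pixel is
$\delta z = \pi/(k_{max}-k_{min}) \approx 2.17\,\mu m$ — set by the
spectral span only, not the sample count. Point reflectors are recovered
within $\pm 1$ depth pixel across the unambiguous range, and the full
synthesize → reconstruct → segment round trip recovers the area trace
with ≤5% mean relative error (both measured in the test suite).
Log-compression is presentation-only; segmentation always operates on
linear intensity.

## Segmentation and calibration

`segment_lumen()` replaces the deep-learning segmenter used with real
recordings (out of scope here) by a classical chain that is adequate for
synthetic images: Gaussian pre-smoothing (sigma 3 µm), a global Otsu
threshold, a 3×3 morphological opening then closing of the dark mask,
selection of the largest dark component that does not touch the image
border (this is what distinguishes the lumen from the dark background),
and hole filling. By default a second *midlevel* pass re-thresholds at
$\ell + 0.55\,(w - \ell)$, where $\ell$ is the median intensity inside
the first-pass mask and $w$ the 0.85 quantile of a surrounding ring —
this centres the boundary on the wall–lumen edge and compensates the
small inward crossing shift that smoothing a thin bright band produces.
The opening step is the one addition to the textbook recipe: speckle
occasionally punches a thin dark bridge through the wall, which would
either merge the lumen with the background or invalidate the frame;
opening removes such bridges and raised the valid-frame rate from ~89% to
~96% at default noise.

Frames with no adequate interior component are *flagged*, never raised:
`extract_area_trace()` linearly interpolates invalid frames from valid
neighbours, keeps the flags, and refuses recordings with more than 20%
invalid frames. Masks are resampled to the 1 µm/pixel convention by
nearest-neighbour index mapping (`calibrate_resize()`), after which area
equals pixel count; physical area is conserved to ≤2% under resampling.

At the native 2 µm pitch, pixel quantization (~9 µm² per pixel) slightly
scrambles the *ranks* of near-identical areas even in noise-free data, so
the rank-fidelity test (Spearman ρ ≥ 0.99) is run at a 1 µm native pitch
where it holds exactly, while linear fidelity (Pearson ≥ 0.999, mean
relative error ≤5%) is asserted at the default pitch.

## Beat detection and read-outs

`detect_beats()` finds local maxima/minima subject to: topographic
prominence at least a fraction (default 0.25) of the trace's global
range; minimum same-type separation `fps / hr_max_hz` (default bound
8 Hz), with taller candidates claiming their neighbourhood first; plateau
and tie resolution to the leftmost frame; discard of boundary extrema;
and strict peak/valley alternation enforced by keeping the more extreme
of adjacent same-type extrema. The detector is verified against a
brute-force scan that re-implements these rules with naive loops on
random rounded traces (plateaus and ties included).

`cardiac_report()` runs detection on a trace smoothed by a centred moving
average (default 0.04 s) but measures EDA/ESA on the *unsmoothed* trace
at the detected frames. The reason is quantitative: a moving average
biases a cosine valley upward by $\approx f''\,(w^2-1)/24$, about 5% of
ESA at the default kinematics — detection benefits from smoothing, but
the areas must not inherit its bias. Heart rate is the mean of per-beat
rates $fps/\Delta_{\text{valley}}$; AI is SD/median of the inter-valley
periods (the dispersion form standard in the fly-heart literature; the
index is named but not defined in the source material). Per-recording FS
is computed from that recording's mean EDA and ESA.

One unit inconsistency is worth recording: the source methods give EDA and
ESA in $\mu m^3$ while all results use $\mu m^2$; areas are
two-dimensional and $\mu m^2$ is used throughout.

## Organismal statistics

The climbing index is the per-vial percentage of flies crossing the
2.5 cm line within 10 s, summarized as mean ± SD/SEM over vials (both
dispersions are always reported since figures in this literature mix
them). Two-sample comparisons use the *Welch* unequal-variance t-test —
the source says only "two-sample student's t tests … 95% confidence",
and the unequal-variance form is the robust default. Survival uses the
Kaplan–Meier product-limit estimator and the standard (ρ = 0) log-rank
test, both via the `survival` package, with hand-worked product-limit and
O−E/variance oracles in the tests. Right censoring is supported
(accidental loss is realistic) although the emulated assay observes all
deaths. The companion lifespan t-test is run on per-fly lifespans — the
source does not say which quantity its t-test addressed; this is the
interpretation implemented. Significance stars follow the conventional
0.05/0.01/0.001/0.0001 thresholds with no multiplicity correction
(matching the emulated analysis convention).

`simulate_cohort()` draws lifespans from a Gompertz model (shape
0.1/day, rate $1.72\times10^{-4}$/day ≈ 60-day median — a realistic
adult-fly mortality law at 25 °C), climbing counts as binomial draws per
vial of 20 flies, and per-fly cardiac parameters log-normally around the
group means with a 25% between-fly CV (consistent with the spread of the
reported group SEMs at n ≈ 30). Group effects enter as multipliers
(e.g. `lifespan_scale = 0.8`, `eda_um2 = 0.75 * 7.7e3`); the log-rank
test attains its nominal 5% size on null cohorts (measured: within
[3.5%, 6.5%] over 1000 replicates of 100 flies/group).

## Pipeline, problem sizes, and determinism

`run_pipeline()` executes simulate → (reconstruct) → segment → analyze →
stats from a single seed; per-recording seeds are `seed + 1000*group +
recording`. The image-level path is the default; the spectral path
(synthesis + reconstruction) is opt-in and slower but satisfies the same
downstream contract — the two paths agree on EDA/ESA/HR to within 5% and
FS to within 5 points on a shared recording. `validate_report()`
re-reads every manifest output and checks the applicable contracts
(frame counts, monotone timestamps, non-negative areas, ESA ≤ EDA,
FS ∈ [0, 100), AI ≥ 0, HR vs beat count).

Problem sizes used by the tests and the acceptance script are the
package's choices for a desk-scale study: full 2000-frame recordings for
the parameter-recovery study (30 recordings) and the demo pipeline (2
groups × 5 recordings), 1-second recordings for the spectral round trip
(synthesis is the expensive stage), 512-sample spectra where only the
reconstruction geometry matters (the depth pixel is bandwidth-limited
and unchanged), and 1000 replicates for test-size estimates.

## Known limitations

* The rendered vessel is a clean ellipse with a fixed aspect ratio; real
  cross-sections are irregular, move laterally, and sit in scattering
  tissue. Passing tests demonstrate the *chain* is correct, not that the
  classical segmenter would match a trained network on real data.
* The spectral model omits dispersion, fall-off, autocorrelation and shot
  noise; reconstruction accuracy on real interferograms would be lower.
* The beat model has a single contraction mode; no diastolic interval
  structure, no retrograde/anterograde direction, no partial beats.
* Cohort-level cardiac values are drawn from distributions rather than
  re-simulated per fly at image level (the pipeline does image-level
  simulation per recording; the cohort simulator serves the statistics
  stage, where only the distributions matter).
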