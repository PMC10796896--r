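---
title: "Models and methods behind bilistrip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bilistrip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilistrip)
```

`bilistrip` quantifies direct bilirubin from photographs of reagent test
papers illuminated by narrow-band LEDs. This vignette documents the
models, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical choices — the
package's own account of its methods.

## The measurement model

On the paper, direct bilirubin is oxidized to biliverdin, whose deposition
darkens the paper with concentration. The camera integrates the source
emission spectrum $P(\lambda)$ reflected off the stained paper
$R(\lambda; c)$, channel by channel; over the working range the average
channel grayscale is well described by a straight line in concentration,

$$\bar v_k(c) = m_k\,c + b_k,$$

which is the empirical calibration the analysis rests on. The package
treats the straight line — not the full radiometric chain — as the
quantitative model, and the spectral chain as a *forward model* used to
generate physically plausible synthetic data and to sanity-check channel
ordering (e.g. that a stain absorbing mainly in the red makes the R
channel the steepest).

### Channel statistics

A photograph is reduced to per-channel averages over a fixed sampling
region: each channel's pixel sum divided by the sampling pixel number.
The region is a centered 257 × 693 pixel rectangle by default, which on
the default 297 × 733 fixture contains exactly 178,101 pixels — the
sampling-point count the package's fixtures are standardized on. Whether
such a count arises from a rectangular or circular crop is not material to
the statistics; the rectangle is the simplest shape with an exact count.
The luminance $Y = 0.2989R + 0.5870G + 0.1140B$ is computed *in addition
to* the raw channel means, never instead of them: the per-channel analyses
use raw channel intensities, and Y is carried as a fourth derived channel.
The chrominance rows of the YUV transform sum to zero, so gray inputs must
give $U = V = 0$; U and V are evaluated in a factored form
($U = -0.148(R-B) - 0.289(G-B)$, $V = 0.615(R-G) - 0.100(B-G)$) so the
annihilation is exact in floating point, not merely to rounding error.

### Calibration, dispersion and limits

`calib()` fits ordinary least squares of grayscale on concentration via
`lm()`, with $R^2 = 1 - SSE/SST$ (defined as 1 in the degenerate
$SST = SSE = 0$ case, e.g. exactly collinear points). Two dispersion
conventions are offered:

* `blank_sd` (default): the sample standard deviation ($n-1$ denominator)
  of blank replicate channel *means*. This is the dispersion that the
  detection limit concept refers to — shot-to-shot variation of the
  measured signal on analyte-free paper.
* `residual_se`: $\sqrt{SSE/(n-2)}$ from the calibration fit itself, for
  runs without blank replicates.

Limits follow the 3σ/10σ convention: $\mathrm{LOD} = 3\sigma/|m|$ and
$\mathrm{LOQ} = 10\sigma/|m|$, hence $\mathrm{LOQ}/\mathrm{LOD} = 10/3$
exactly. The alternative 3.3σ detection convention is deliberately not
used: the package standardizes on the pair (3, 10), under which a blank
dispersion of 2.3974 grayscale units with slope −15.669 gives
LOD = 0.459 and LOQ = 1.530 mg/dL — the working point of the green-LED
G-channel configuration. Inverse prediction $\hat c = (y-b)/m$ clamps
negative estimates to zero and reports `below_lod`,
`detected_not_quantifiable` ($\mathrm{LOD} \le \hat c < \mathrm{LOQ}$) or
`quantifiable`.

### Ranking sources and channels

`select_best()` sorts curves by descending $R^2$. Ties — which occur
systematically on noiseless synthetic data, where every fitted curve has
$R^2 = 1$ — are broken by preferring the channel matching the source's
colour name (G under a green LED), then the fixed channel order G, R, B,
Y, then the source name. The rationale for the colour-matching preference
is physical: the like-coloured channel receives the most signal under a
narrow-band source and is the intended analysis channel.

## The spectral forward model

* **LED lines.** Monochromatic LEDs are modelled as Gaussians fully
  determined by peak wavelength and FWHM
  ($\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2}$), normalized to unit maximum.
  Real LED spectra are asymmetric — a sharp band-gap onset on the long
  wavelength side and a thermal tail toward shorter wavelengths — so the
  symmetric Gaussian is a declared surrogate, not an inference. The
  practical consequence is visible in chromaticity: the red surrogate
  (636.1 nm, FWHM 21 nm) integrates to CIE $x \approx 0.714$, whereas the
  measured LED (whose short-wavelength tail pulls $x$ down) was reported
  at 0.6971; an asymmetric band-gap × Boltzmann shape fit to the same
  peak/FWHM lands on the other side at $x \approx 0.687$. The Gaussian is
  retained because it is completely determined by the two printed numbers,
  at the cost of ~0.017 in $x$ for this reddest source; green and blue
  are much closer to their loci.
* **Cool white.** A pump (446.8 nm, FWHM 25 nm) plus phosphor (550 nm,
  FWHM 110 nm) two-Gaussian model. The phosphor ratio 0.22 was fixed once
  so the chromaticity lands near the measured (0.2345, 0.2067); the model
  gives (0.2360, 0.2087). The broad phosphor tail shifts the summed
  maximum less than 0.2 nm off the pump peak.
* **Observer.** No tabulated colorimetric dataset is bundled with the
  package's dependencies, so the CIE 1931 2° color-matching functions are
  represented by the published multi-lobe piecewise-Gaussian analytic
  approximation, rescaled to equal trapezoidal integrals over 380–780 nm
  so the equal-energy spectrum maps to exactly (1/3, 1/3). Against known
  spectral-locus values the representation agrees to a few parts in a
  thousand of chromaticity — well below the Gaussian-surrogate line-shape
  error above. The table is also shipped as a CSV asset
  (`inst/extdata/cie1931_cmf_2deg_approx.csv`), clearly an analytic
  approximation rather than the tabulated observer.
* **Stain.** $R(\lambda; c) = R_{paper}\,10^{-c A(\lambda)}$ with a flat
  $R_{paper} = 0.9$ and absorbance bands at 680 nm (FWHM 120 nm,
  amplitude 0.25/(mg/dL)) and 377 nm (FWHM 80, amplitude 0.35) — a
  biliverdin-like template chosen so the red band bleaches fastest,
  matching the observed ordering of channel slopes (the red channel's
  slope magnitude is the largest among the monochromatic fits). The
  amplitudes are free configuration parameters, not fitted constants.
* **Camera.** Linear sensitivities (CMFs mapped to sRGB primaries,
  negative lobes clipped at zero), scalar gain, hard clip at 255. The
  true smartphone sensor response is unknown; in spectral rendering mode
  the gain is auto-calibrated so blank paper puts the brightest channel
  at 240 — the "close to 255 but not overexposed" operating point the
  exposure QC enforces.
* **Grid and integration.** 1-nm steps over 380–780 nm, trapezoidal rule.
  Spectral products require identical grids; mismatches are an error, not
  a silent interpolation.

## The synthetic-data generator

The generator's defaults are the study conditions the analysis is
validated under: 12 standards evenly spaced over 0.1–2.0 mg/dL (the range
and count of the calibration design; the exact 12 values are not
published, so an even grid is used), a 297 × 733 image with the centered
257 × 693 ROI (178,101 sampling pixels), and per-source ground-truth
lines. All three channels of the cool-white source and the like-coloured
channel of each monochromatic source carry the published calibration
lines verbatim; the remaining monochromatic off-channels (e.g. G and B
under the red LED) are not published and default to weak plausible
responses — dim channels with small negative slopes — chosen once:
red: G (−5.0, 80), B (−2.5, 40); green: R (−6.0, 90), B (−4.0, 70);
blue: R (−3.0, 50), G (−6.5, 110).

Noise has three components, each seeded and switchable:

1. **Illumination offset** — one $N(0, s_o)$ draw per image added to all
   channels, modelling shot-to-shot drift of source intensity and
   exposure. Default $s_o = 2.3974$ grayscale units, the blank dispersion
   at the green-LED working point. This component is essential: purely
   pixel-level noise averages away over a 178k-pixel ROI
   ($2/\sqrt{178101} < 0.005$ grayscale) and could not produce the
   calibration scatter actually observed on measured data, so the blank σ
   must live at the image level.
2. **Coloration non-uniformity** — the dominant error source named for
   this kind of assay: a Gaussian-smoothed white-noise field (correlation
   length 40 px, amplitude 4 grayscale units by default), exactly
   zero-mean over the image and shared across channels. It perturbs local
   pixels strongly but ROI means only weakly, which is precisely its
   observed character.
3. **Pixel noise** — i.i.d. $N(0, 2)$ per pixel and channel (sensor shot
   and read noise).

Rendering then quantizes to integers (default on) and clips to [0, 255].
With the defaults, a simulated green-LED run fits with $R^2 \approx 0.95$
and LOD ≈ 0.43 mg/dL — the same order as the measured run's 0.9523 and
0.459 — without any per-outcome tuning of the noise levels.

What the generator does **not** emulate: paper texture and fibre
structure, perspective and lens distortion, JPEG artifacts, the sensor's
colour filter array and white-balance processing, and chemical kinetics
(the concentration → darkness map is phenomenological). Tests passing on
synthetic data therefore validate the statistical pipeline — estimators,
limits, selection, determinism — not the photometric fidelity of any
particular phone.

## Pipeline and numerical choices

`run_analysis()` performs, per source: exposure QC on the
lowest-concentration image (the brightest; if it is not overexposed,
higher concentrations cannot be), statistics for every image, fits for
channels R, G, B, Y, limits, then a cross-source ranking. A QC failure
aborts only the affected source, because exposure is calibrated per
source (each LED was driven and ISO-set individually). QC thresholds
(clipped fraction > 0.01 or any mean ≥ 254 fails; analysis-channel mean
< 200 warns) are package defaults exposed in `qc_params()`. Note that
sources whose intercepts sit below 200 — as the published blue and
cool-white lines do — legitimately draw the underexposure *warning* while
still being analysed.

Determinism: every stochastic path takes an explicit seed; per-image
seeds are `base_seed + index`; simulated sources are offset by 1000 per
source and blanks by 100000, keeping all derived seeds well inside the
32-bit integer range. Helpers save and restore the caller's RNG state.
Reports carry an md5 provenance hash over the numeric tables, so
identical configuration + seed implies an identical hash.

Problem sizes in the test-suite: unit and property tests run on reduced
geometries (tens of pixels per side) where the statistics under test are
size-independent — channel means, OLS estimates and offset-noise
dispersion do not depend on image area once pixel noise is off — while
fixture-count checks use the full 297 × 733 geometry. The blank-replicate
dispersion check uses 500 replicates, for a ~3% sampling error on σ;
slope-recovery uses 200 replicates of 12-point fits.

## Known limitations

* The straight-line calibration is assumed, not tested against curvature;
  weighted, robust, or four-parameter-logistic calibration is out of
  scope.
* Measurement uncertainty is not propagated to predicted concentrations;
  the status classification uses the point estimate only.
* The spectral mode's camera is a standard-observer surrogate; absolute
  channel values in spectral renderings are not comparable to any
  specific phone, only their ordering and trends.
* The published per-run $R^2$ values cannot be recomputed exactly from
  first principles because the underlying 12 measured grayscale values
  per run are not available; the generator reproduces their statistical
  character, not their realized values.
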