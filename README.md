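# bilistrip

Quantitative smartphone colorimetry of direct-bilirubin test papers.

Direct (conjugated) bilirubin on a reagent test paper is oxidized to
biliverdin, which darkens the paper in proportion to concentration. The
change is too subtle for reliable visual reading, but a smartphone
photograph taken under a narrow-band LED carries it in the image's colour
channels. `bilistrip` implements the full analysis chain for such
paper-based assays:

* **Imaging** — read the photograph, place a fixed sampling region (ROI)
  on the paper, and compute each channel's *average grayscale*
  \(\bar v_k = \frac{1}{N}\sum_{i \in \mathrm{ROI}} v_{k,i}\) over the
  \(N\) sampling pixels, together with the YUV luminance
  \(Y = 0.2989\,R + 0.5870\,G + 0.1140\,B\) and an overexposure check.
* **Calibration** — ordinary least squares of average grayscale on
  concentration, \(y = m\,c + b\), with \(R^2\), the blank dispersion
  \(\sigma\) (standard deviation of blank replicate means, or the residual
  standard error), the detection and quantification limits
  \(\mathrm{LOD} = 3\sigma/|m|\), \(\mathrm{LOQ} = 10\sigma/|m|\), and
  inverse prediction \(\hat c = (y - b)/m\) with a status against those
  limits.
* **Spectral forward model** — Gaussian LED emission lines \(P(\lambda)\)
  built from peak wavelength and FWHM, a Beer–Lambert stained-paper
  reflectance \(R(\lambda; c) = R_{paper}(\lambda)\,10^{-c\,A(\lambda)}\),
  their product (the light reflected off the paper), CIE 1931 chromaticity,
  and a linear camera model.
* **Synthetic data** — a seeded generator of test-paper images whose
  channel means follow configured ground-truth calibration lines, with a
  three-component noise model: per-image illumination drift, a smooth
  zero-mean coloration non-uniformity field, and per-pixel noise, plus
  8-bit quantization and clipping.
* **Pipeline** — `run_analysis()` ties it together per light source
  (exposure QC → per-image statistics → per-channel fits → cross-source
  ranking) and `write_report()` exports CSV/JSON/log files. A thin CLI
  ships at `system.file("cli", "bilistrip", package = "bilistrip")`.

## Worked example

Simulate a 12-point calibration run (0.1–2.0 mg/dL) under the green LED
with the default noise model, analyse it end to end, and quantify three
unknown grayscale readings:

```r
library(bilistrip)
scene <- scene_config("green")                 # default synthetic scene
cfg   <- run_config(scenes = list(scene), seed = 1, log_level = "quiet")
rep   <- run_analysis(cfg)
print(rep)
#> Analysis report
#> QC:  green=pass
#>   source channel peak_nm   slope intercept r_squared sigma    lod   loq  n n_pixels
#> 1  green       G   518.5 -15.804    239.75    0.9482 2.250 0.4270 1.423 12   178101
#> 2  green       Y   518.5 -11.581    175.37    0.9077 2.252 0.5832 1.944 12   178101
#> 3  green       R   518.5  -6.133     89.41    0.7340 2.255 1.1032 3.677 12   178101
#> 4  green       B   518.5  -4.135     69.41    0.5556 2.255 1.6362 5.454 12   178101
#> Best combination: green / G (R-squared 0.9482, LOD 0.427 mg/dL)

cv <- rep$curve_objects[["green_G"]]
predict(cv, c(235, 224, 210))
#>   concentration_estimate                    status
#> 1              0.3005690                 below_lod
#> 2              0.9965816 detected_not_quantifiable
#> 3              1.8824159              quantifiable
```

Reading the output: the G channel under the green LED is the most linear
channel (ranked first), its fitted line is close to the generator's
ground truth \(y = -15.669\,c + 240.34\), and the blank dispersion
\(\sigma \approx 2.25\) grayscale units translates into a detection limit
of \(3\sigma/|m| \approx 0.43\) mg/dL and a quantification limit of
\(10\sigma/|m| \approx 1.42\) mg/dL. The three unknowns fall below the
LOD, between LOD and LOQ, and above the LOQ respectively.

The same analysis runs from the shell:

```sh
bilistrip simulate --config scene.yaml --out run/
bilistrip analyze  --manifest run/manifest.csv --out report/
bilistrip limits   --sigma 2.3974 --slope -15.669
```

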