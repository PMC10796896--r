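# Spectral forward model: LED emission lines, stained-paper reflectance,
# CIE 1931 chromaticity and camera RGB formation.

VISIBLE_LO <- 380
VISIBLE_HI <- 780

#' Wavelength grid for spectral computations
#'
#' @param from,to Grid limits in nm.
#' @param by Step in nm.
#' @return Numeric vector of wavelengths (nm), strictly ascending, uniform.
#' @export
default_grid <- function(from = VISIBLE_LO, to = VISIBLE_HI, by = 1) {
  seq(from, to, by = by)
}

#' Construct a spectrum
#'
#' A wavelength-sampled curve: an LED emission line \eqn{P(\lambda)}, a
#' stained-paper reflectance \eqn{R(\lambda)}, or their pointwise product
#' (the light reflected off the test paper).
#'
#' @param wavelengths_nm Strictly ascending, uniformly spaced grid (nm).
#' @param values Non-negative values; reflectance additionally must be
#'   \eqn{\le 1}; emission spectra are expected normalized to max 1.
#' @param kind One of `"emission"`, `"reflectance"`, `"reflected"`.
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(wavelengths_nm, values,
                     kind = c("emission", "reflectance", "reflected")) {
  kind <- match.arg(kind)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) != length(values))
    stop("wavelengths and values must have equal length")
  if (length(wavelengths_nm) < 2L)
    stop("a spectrum needs at least two samples")
  dw <- diff(wavelengths_nm)
  if (any(dw <= 0)) stop("wavelength grid must be strictly ascending")
  if (any(abs(dw - dw[1L]) > 1e-9 * dw[1L]))
    stop("wavelength grid must be uniform")
  if (any(!is.finite(values)) || any(values < 0))
    stop("spectrum values must be finite and non-negative")
  if (kind == "reflectance" && any(values > 1 + 1e-12))
    stop("reflectance values must not exceed 1")
  structure(list(wavelengths_nm = wavelengths_nm, values = values, kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d samples over %g-%g nm, max %.4g>\n",
              x$kind, length(x$values), min(x$wavelengths_nm),
              max(x$wavelengths_nm), max(x$values)))
  invisible(x)
}

# trapezoidal integral on a (possibly non-uniform) grid
trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)

#' Describe an LED light source
#'
#' Holds the printed optical parameters of a highly collimated mini-LED and
#' the capture settings used with it. Electrical drive settings and the
#' reference chromaticity are carried as inert metadata (the reference
#' chromaticity is the measured value used only for validation).
#'
#' @param name Source label, e.g. `"green"`.
#' @param peak_wavelength_nm Emission peak (nm), within 380--780.
#' @param fwhm_nm Full width at half maximum (nm), positive.
#' @param wavelength_range_nm Length-2 numeric, `lo < hi` (nm).
#' @param chromaticity_ref Optional `(x, y)` reference chromaticity.
#' @param drive_current_mA,drive_voltage_V,camera_iso Metadata.
#' @return An object of class `"led_source"`.
#' @export
led_source <- function(name, peak_wavelength_nm, fwhm_nm,
                       wavelength_range_nm = c(VISIBLE_LO, VISIBLE_HI),
                       chromaticity_ref = NULL,
                       drive_current_mA = NA_real_, drive_voltage_V = NA_real_,
                       camera_iso = 100) {
  if (peak_wavelength_nm < VISIBLE_LO || peak_wavelength_nm > VISIBLE_HI)
    stop("peak wavelength must lie in the visible range 380-780 nm")
  if (fwhm_nm <= 0) stop("FWHM must be positive")
  if (wavelength_range_nm[1L] >= wavelength_range_nm[2L])
    stop("wavelength range must satisfy lo < hi")
  if (!is.na(camera_iso) && camera_iso <= 0) stop("camera ISO must be positive")
  structure(list(name = name, peak_wavelength_nm = peak_wavelength_nm,
                 fwhm_nm = fwhm_nm, wavelength_range_nm = wavelength_range_nm,
                 chromaticity_ref = chromaticity_ref,
                 drive_current_mA = drive_current_mA,
                 drive_voltage_V = drive_voltage_V, camera_iso = camera_iso),
            class = "led_source")
}

#' The four mini-LED sources used in the study design
#'
#' Red, green and blue monochromatic sources plus a phosphor-converted cool
#' white, with their printed peak wavelengths, line widths, measured
#' chromaticities, drive settings and the camera ISO each was captured at.
#' The cool-white FWHM is not printed; the stored value is the pump-band
#' default of the two-band surrogate model.
#'
#' @return Named list of [led_source()] objects.
#' @export
led_sources <- function() {
  list(
    red = led_source("red", 636.1, 21, c(575, 675),
                     chromaticity_ref = c(0.6971, 0.3021),
                     drive_current_mA = 30, drive_voltage_V = 1.9,
                     camera_iso = 200),
    green = led_source("green", 518.5, 38, c(450, 625),
                       chromaticity_ref = c(0.1677, 0.7050),
                       drive_current_mA = 30, drive_voltage_V = 2.8,
                       camera_iso = 100),
    blue = led_source("blue", 452.9, 30, c(400, 525),
                      chromaticity_ref = c(0.1496, 0.0314),
                      drive_current_mA = 5, drive_voltage_V = 2.6,
                      camera_iso = 25),
    white = led_source("white", 446.8, 25, c(VISIBLE_LO, VISIBLE_HI),
                       chromaticity_ref = c(0.2345, 0.2067),
                       drive_current_mA = 10, drive_voltage_V = 2.7,
                       camera_iso = 25)
  )
}

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))  # sigma = fwhm / 2.3548

#' Gaussian emission line
#'
#' Models a monochromatic LED emission spectrum as a Gaussian line fully
#' determined by its peak wavelength and FWHM, normalized to unit maximum.
#'
#' @param peak_nm Peak wavelength (nm); must be covered by the grid.
#' @param fwhm_nm Full width at half maximum (nm), positive.
#' @param grid Wavelength grid (nm), see [default_grid()].
#' @return An emission [spectrum()] with maximum value 1.
#' @export
gaussian_emission <- function(peak_nm, fwhm_nm, grid = default_grid()) {
  if (fwhm_nm <= 0) stop("FWHM must be positive")
  if (peak_nm < min(grid) || peak_nm > max(grid))
    stop("grid does not cover the peak wavelength")
  sigma <- fwhm_nm * FWHM_TO_SIGMA
  v <- exp(-0.5 * ((grid - peak_nm) / sigma)^2)
  spectrum(grid, v / max(v), kind = "emission")
}

#' Two-band cool-white emission
#'
#' Surrogate for a phosphor-converted white LED: a blue pump line plus a
#' broad phosphor band, each Gaussian, summed and normalized so the global
#' maximum (at the pump peak for the defaults) is 1. The default phosphor
#' ratio is calibrated once so the chromaticity lands near the measured
#' cool-white coordinates (0.2345, 0.2067).
#'
#' @param pump_peak_nm,pump_fwhm_nm Blue pump line parameters (nm).
#' @param phosphor_peak_nm,phosphor_fwhm_nm Phosphor band parameters (nm).
#' @param phosphor_ratio Peak ratio of phosphor band to pump line, >= 0.
#' @param grid Wavelength grid (nm).
#' @return An emission [spectrum()].
#' @export
cool_white_emission <- function(pump_peak_nm = 446.8, pump_fwhm_nm = 25,
                                phosphor_peak_nm = 550, phosphor_fwhm_nm = 110,
                                phosphor_ratio = 0.22, grid = default_grid()) {
  if (phosphor_ratio < 0) stop("phosphor ratio must be non-negative")
  pump <- gaussian_emission(pump_peak_nm, pump_fwhm_nm, grid)
  if (phosphor_ratio == 0) return(pump)
  phos <- gaussian_emission(phosphor_peak_nm, phosphor_fwhm_nm, grid)
  v <- pump$values + phosphor_ratio * phos$values
  spectrum(grid, v / max(v), kind = "emission")
}

#' Stain absorbance template parameters
#'
#' The oxidized stain (biliverdin deposited on the paper) is modelled with a
#' fixed non-negative absorbance template built from two Gaussian bands, by
#' default at 680 nm and 377 nm, scaled per unit concentration (mg/dL).
#'
#' @param base_reflectance Unstained paper reflectance (flat), in (0, 1].
#' @param band_peaks_nm,band_fwhms_nm,band_amplitudes Band parameters; the
#'   amplitudes are absorbance per (mg/dL) at each band peak.
#' @return A list of class `"stain_params"`.
#' @export
stain_params <- function(base_reflectance = 0.9,
                         band_peaks_nm = c(680, 377),
                         band_fwhms_nm = c(120, 80),
                         band_amplitudes = c(0.25, 0.35)) {
  stopifnot(base_reflectance > 0, base_reflectance <= 1,
            length(band_peaks_nm) == length(band_fwhms_nm),
            length(band_peaks_nm) == length(band_amplitudes),
            all(band_fwhms_nm > 0), all(band_amplitudes >= 0))
  structure(list(base_reflectance = base_reflectance,
                 band_peaks_nm = band_peaks_nm, band_fwhms_nm = band_fwhms_nm,
                 band_amplitudes = band_amplitudes), class = "stain_params")
}

#' Concentration-dependent stained-paper reflectance
#'
#' Beer-Lambert-style model: \eqn{R(\lambda; c) = R_{paper}(\lambda)\,
#' 10^{-c\,A(\lambda)}} with a fixed non-negative absorbance template
#' \eqn{A(\lambda)}. Reflectance is pointwise non-increasing in
#' concentration, so higher concentrations render darker paper.
#'
#' @param concentration_mgdl Concentration (mg/dL), >= 0.
#' @param params A [stain_params()] object.
#' @param grid Wavelength grid (nm).
#' @return A reflectance [spectrum()].
#' @export
stain_reflectance <- function(concentration_mgdl, params = stain_params(),
                              grid = default_grid()) {
  if (concentration_mgdl < 0) stop("concentration must be non-negative")
  absorb <- rep(0, length(grid))
  for (i in seq_along(params$band_peaks_nm)) {
    s <- params$band_fwhms_nm[i] * FWHM_TO_SIGMA
    absorb <- absorb + params$band_amplitudes[i] *
      exp(-0.5 * ((grid - params$band_peaks_nm[i]) / s)^2)
  }
  v <- params$base_reflectance * 10^(-concentration_mgdl * absorb)
  spectrum(grid, v, kind = "reflectance")
}

#' Pointwise spectral product
#'
#' Multiplies an emission spectrum \eqn{P(\lambda)} with a reflectance
#' spectrum \eqn{R(\lambda)}: the spectrum of the light reflected off the
#' stained test paper. The two grids must be identical; no silent
#' interpolation is performed.
#'
#' @param emission,reflectance [spectrum()] objects on the same grid.
#' @return A [spectrum()] of kind `"reflected"`.
#' @export
multiply_spectra <- function(emission, reflectance) {
  check_grids(emission$wavelengths_nm, reflectance$wavelengths_nm)
  spectrum(emission$wavelengths_nm, emission$values * reflectance$values,
           kind = "reflected")
}

check_grids <- function(a, b) {
  if (length(a) != length(b) || any(abs(a - b) > 1e-9))
    stop("wavelength grids do not match (no silent interpolation)")
  invisible(TRUE)
}

# Analytic multi-lobe piecewise-Gaussian representation of the CIE 1931
# 2-degree color-matching functions, rescaled to equal trapezoidal integrals
# on the canonical 1-nm grid so an equal-energy spectrum maps to exactly
# (1/3, 1/3). Agrees with the tabulated observer to a few parts in a
# thousand of chromaticity across the visible range.
piecewise_gauss <- function(x, mu, s1, s2) {
  s <- ifelse(x < mu, s1, s2)
  exp(-0.5 * ((x - mu) / s)^2)
}

cmf_raw <- function(wl) {
  xb <- 1.056 * piecewise_gauss(wl, 599.8, 37.9, 31.0) +
        0.362 * piecewise_gauss(wl, 442.0, 16.0, 26.7) -
        0.065 * piecewise_gauss(wl, 501.1, 20.4, 26.2)
  yb <- 0.821 * piecewise_gauss(wl, 568.8, 46.9, 40.5) +
        0.286 * piecewise_gauss(wl, 530.9, 16.3, 31.1)
  zb <- 1.217 * piecewise_gauss(wl, 437.0, 11.8, 36.0) +
        0.681 * piecewise_gauss(wl, 459.0, 26.0, 13.8)
  cbind(xbar = pmax(xb, 0), ybar = yb, zbar = zb)
}

#' CIE 1931 2-degree color-matching functions
#'
#' Evaluates the standard observer on an arbitrary wavelength grid, using an
#' analytic multi-lobe Gaussian representation normalized so the three
#' curves integrate equally over 380--780 nm. The same table is shipped as a
#' CSV asset (`inst/extdata/cie1931_cmf_2deg_approx.csv`).
#'
#' @param wavelengths_nm Wavelengths (nm).
#' @return Matrix with columns `xbar`, `ybar`, `zbar`.
#' @export
cie_cmf <- function(wavelengths_nm = default_grid()) {
  wl0 <- default_grid()
  m0 <- cmf_raw(wl0)
  ints <- apply(m0, 2L, function(v) trapz(wl0, v))
  k <- ints["ybar"] / ints
  m <- cmf_raw(wavelengths_nm)
  sweep(m, 2L, k, "*")
}

#' CIE 1931 chromaticity of a spectrum
#'
#' Integrates the spectrum against the 2-degree color-matching functions
#' (trapezoidal rule) and normalizes the tristimulus values:
#' \eqn{x = X/(X+Y+Z)}, \eqn{y = Y/(X+Y+Z)}.
#'
#' @param spec A [spectrum()] covering 380--780 nm.
#' @return A list of class `"chromaticity_point"` with elements `x`, `y`.
#' @export
chromaticity <- function(spec) {
  wl <- spec$wavelengths_nm
  if (min(wl) > VISIBLE_LO || max(wl) < VISIBLE_HI)
    stop("spectrum must cover the full 380-780 nm range")
  cmf <- cie_cmf(wl)
  X <- trapz(wl, spec$values * cmf[, "xbar"])
  Y <- trapz(wl, spec$values * cmf[, "ybar"])
  Z <- trapz(wl, spec$values * cmf[, "zbar"])
  tot <- X + Y + Z
  if (tot <= 0) stop("chromaticity undefined for an all-zero spectrum")
  structure(list(x = X / tot, y = Y / tot), class = "chromaticity_point")
}

#' @export
print.chromaticity_point <- function(x, ...) {
  cat(sprintf("CIE 1931 chromaticity (x, y) = (%.4f, %.4f)\n", x$x, x$y))
  invisible(x)
}

#' Camera model
#'
#' Linear (gamma-less) three-channel camera: per-channel spectral
#' sensitivities on a wavelength grid, a scalar exposure gain, and hard
#' clipping at the 8-bit ceiling. The default sensitivities are the CIE 1931
#' color-matching functions mapped linearly to sRGB primaries with negative
#' lobes clipped at zero (the true smartphone sensor response is unknown;
#' this standard surrogate keeps the channel ordering of real sensors).
#'
#' @param grid Wavelength grid (nm).
#' @param sensitivities Optional matrix (length(grid) x 3, columns R,G,B) of
#'   non-negative sensitivities; default as described above.
#' @param gain Linear exposure multiplier, > 0.
#' @param clip_level Saturation ceiling, default 255.
#' @return An object of class `"camera_model"`.
#' @export
camera_model <- function(grid = default_grid(), sensitivities = NULL,
                         gain = 1, clip_level = 255) {
  if (gain <= 0) stop("gain must be positive")
  if (is.null(sensitivities)) {
    xyz2srgb <- rbind(c(3.2406, -1.5372, -0.4986),
                      c(-0.9689, 1.8758, 0.0415),
                      c(0.0557, -0.2040, 1.0570))
    sensitivities <- pmax(cie_cmf(grid) %*% t(xyz2srgb), 0)
    colnames(sensitivities) <- c("R", "G", "B")
  }
  if (nrow(sensitivities) != length(grid) || ncol(sensitivities) != 3L)
    stop("sensitivities must be a length(grid) x 3 matrix")
  if (any(sensitivities < 0)) stop("sensitivities must be non-negative")
  structure(list(grid = grid, sensitivities = sensitivities, gain = gain,
                 clip_level = clip_level), class = "camera_model")
}

#' Camera RGB response to a spectrum
#'
#' Each channel is \eqn{gain \cdot \int S(\lambda)\,s_k(\lambda)\,d\lambda},
#' clipped to `[0, clip_level]`; linear in the spectrum below clip.
#'
#' @param spec A [spectrum()] on the camera's grid.
#' @param cam A [camera_model()].
#' @return Named numeric triple `(R, G, B)` (real-valued, pre-quantization).
#' @export
camera_rgb <- function(spec, cam) {
  check_grids(spec$wavelengths_nm, cam$grid)
  raw <- vapply(1:3, function(k)
    cam$gain * trapz(cam$grid, spec$values * cam$sensitivities[, k]),
    numeric(1))
  out <- pmin(pmax(raw, 0), cam$clip_level)
  names(out) <- c("R", "G", "B")
  out
}

#' Exposure gain hitting a target level
#'
#' Utility for the spectral rendering mode: the gain that maps the brightest
#' channel of a reference spectrum (typically the source reflected off blank
#' paper) to a target grayscale level, mimicking per-source exposure
#' calibration against overexposure.
#'
#' @param spec Reference [spectrum()].
#' @param cam A [camera_model()]; its gain is ignored.
#' @param target Target level for the brightest channel (default 240).
#' @return Positive scalar gain.
#' @export
calibrate_gain <- function(spec, cam, target = 240) {
  cam$gain <- 1
  cam$clip_level <- Inf
  peak <- max(camera_rgb(spec, cam))
  if (peak <= 0) stop("reference spectrum produces no camera response")
  target / peak
}

#' Read / write a spectrum as two-column CSV
#'
#' Plain-text serialization: columns `wavelength_nm`, `value`.
#'
#' @param path File path.
#' @param spec A [spectrum()] (for writing).
#' @param kind Spectrum kind assumed on read.
#' @return `read_spectrum_csv` returns a [spectrum()]; `write_spectrum_csv`
#'   returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path, kind = "emission") {
  d <- utils::read.csv(path)
  spectrum(d$wavelength_nm, d$value, kind = kind)
}

#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(spec, path) {
  utils::write.csv(data.frame(wavelength_nm = spec$wavelengths_nm,
                              value = spec$values),
                   path, row.names = FALSE)
  invisible(path)
}
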