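# Seeded synthetic test-paper image generator: ground-truth calibration
# lines (or the spectral forward model) plus a three-component noise model
# -- per-image illumination offset, smooth coloration non-uniformity
# ("blotch" field), and i.i.d. pixel noise -- with quantization and clipping.

#' Default 12-point concentration series
#'
#' Twelve evenly spaced standards over 0.1--2.0 mg/dL.
#'
#' @return Numeric vector of length 12.
#' @export
default_concentrations <- function() seq(0.1, 2.0, length.out = 12)

#' Ground-truth calibration lines per light source
#'
#' Per-channel `(slope, intercept)` pairs used by the linear rendering
#' mode. The channels with published calibration lines carry them verbatim
#' (all three channels for cool white; the like-coloured channel for each
#' monochromatic source). The remaining monochromatic off-channels are not
#' published; they default to plausible weak responses (dim channels under
#' narrow-band light), documented in the methods vignette.
#'
#' @param source Source name: `"red"`, `"green"`, `"blue"`, `"white"`.
#' @return 3 x 2 matrix, rows R, G, B, columns `m`, `b`.
#' @export
truth_lines <- function(source = c("green", "red", "blue", "white")) {
  source <- match.arg(source)
  lines <- switch(source,
    white = rbind(R = c(-21.373, 142.28),
                  G = c(-11.972, 166.73),
                  B = c(-14.932, 207.43)),
    red   = rbind(R = c(-39.708, 250.92),
                  G = c(-5.0, 80),
                  B = c(-2.5, 40)),
    green = rbind(R = c(-6.0, 90),
                  G = c(-15.669, 240.34),
                  B = c(-4.0, 70)),
    blue  = rbind(R = c(-3.0, 50),
                  G = c(-6.5, 110),
                  B = c(-16.253, 174.29))
  )
  colnames(lines) <- c("m", "b")
  lines
}

#' Configure a synthetic calibration scene
#'
#' Full generative description of a synthetic run for one light source.
#' In `"linear"` mode each channel's noiseless value is `m * c + b` from
#' the ground-truth lines; in `"spectral"` mode it is the camera response
#' to the source spectrum multiplied by the concentration-dependent stain
#' reflectance. On top of the base value the renderer adds one global
#' illumination offset per image (`offset_noise_sd`), a smooth zero-mean
#' coloration non-uniformity field (`blotch_amplitude`, correlation length
#' `blotch_scale` pixels), and i.i.d. pixel noise (`pixel_noise_sd`), then
#' quantizes and clips to the 8-bit range.
#'
#' @param source A source name or [led_source()] object.
#' @param mode `"linear"` or `"spectral"`.
#' @param lines Ground-truth lines for linear mode; default
#'   [truth_lines()] for the source.
#' @param stain [stain_params()] for spectral mode.
#' @param camera [camera_model()] for spectral mode; by default its gain is
#'   calibrated so blank paper maps the brightest channel to 240.
#' @param height,width Image size in pixels.
#' @param roi Sampling-region spec, see [roi_rect()].
#' @param pixel_noise_sd,offset_noise_sd,blotch_amplitude Noise standard
#'   deviations in grayscale units.
#' @param blotch_scale Smoothing length of the non-uniformity field (px).
#' @param quantize Round to integers before clipping (default TRUE).
#' @param seed Default seed for rendering.
#' @param metadata Inert capture metadata (shutter, focal length,
#'   lens/source geometry, ISO).
#' @return A list of class `"scene_config"`.
#' @export
scene_config <- function(source = "green", mode = c("linear", "spectral"),
                         lines = NULL, stain = stain_params(), camera = NULL,
                         height = 297, width = 733, roi = roi_default(),
                         pixel_noise_sd = 2, offset_noise_sd = 2.3974,
                         blotch_amplitude = 4, blotch_scale = 40,
                         quantize = TRUE, seed = 1234,
                         metadata = list(shutter_s = 1 / 15, focal_mm = 10,
                                         H1_cm = 10, H2_cm = 15)) {
  mode <- match.arg(mode)
  if (is.character(source)) {
    src <- led_sources()[[source]]
    if (is.null(src)) stop("unknown source: ", source)
  } else src <- source
  stopifnot(inherits(src, "led_source"),
            pixel_noise_sd >= 0, offset_noise_sd >= 0, blotch_amplitude >= 0,
            blotch_scale > 0, height >= 1, width >= 1)
  if (is.null(lines) && mode == "linear") lines <- truth_lines(src$name)
  if (!is.null(lines)) {
    lines <- as.matrix(lines)
    if (nrow(lines) != 3L || ncol(lines) != 2L)
      stop("ground-truth lines must be a 3 x 2 matrix (rows R, G, B)")
    dimnames(lines) <- list(c("R", "G", "B"), c("m", "b"))
  }
  emission <- NULL
  if (mode == "spectral") {
    emission <- if (src$name == "white") cool_white_emission()
                else gaussian_emission(src$peak_wavelength_nm, src$fwhm_nm)
    if (is.null(camera)) camera <- camera_model()
    blank <- multiply_spectra(emission, stain_reflectance(0, stain))
    camera$gain <- camera$gain * calibrate_gain(blank, camera)
  }
  metadata$camera_iso <- src$camera_iso
  structure(list(source = src, mode = mode, lines = lines, stain = stain,
                 camera = camera, emission = emission,
                 height = height, width = width, roi = roi,
                 pixel_noise_sd = pixel_noise_sd,
                 offset_noise_sd = offset_noise_sd,
                 blotch_amplitude = blotch_amplitude,
                 blotch_scale = blotch_scale, quantize = quantize,
                 seed = seed, metadata = metadata),
            class = "scene_config")
}

# Noiseless per-channel base values (R, G, B) for a concentration.
scene_base <- function(scene, concentration) {
  if (scene$mode == "linear") {
    base <- scene$lines[, "m"] * concentration + scene$lines[, "b"]
    if (any(base < 0) || any(base > 255))
      warning("linear-mode base value outside [0, 255]: clipping risk",
              call. = FALSE)
    base
  } else {
    refl <- stain_reflectance(concentration, scene$stain,
                              grid = scene$camera$grid)
    camera_rgb(multiply_spectra(scene$emission, refl), scene$camera)
  }
}

# Separable Gaussian smoothing with truncated, per-row renormalized kernels
# (no wrap-around, no edge darkening).
gaussian_smooth <- function(mat, sigma) {
  smooth_one <- function(n) {
    idx <- seq_len(n)
    K <- exp(-0.5 * outer(idx, idx, "-")^2 / sigma^2)
    K / rowSums(K)
  }
  Sr <- smooth_one(nrow(mat))
  Sc <- smooth_one(ncol(mat))
  Sr %*% mat %*% t(Sc)
}

#' Render a synthetic test-paper image
#'
#' Deterministic given `(scene, concentration, seed)`: the same inputs
#' always produce a bit-identical image. See [scene_config()] for the
#' generative model.
#'
#' @param scene A [scene_config()].
#' @param concentration Analyte concentration (mg/dL), >= 0.
#' @param seed Integer seed; defaults to the scene's seed.
#' @return An [rgb_image()] (quantized) or a numeric `h x w x 3` array in
#'   `[0, 255]` when `quantize` is off.
#' @export
render_strip <- function(scene, concentration, seed = scene$seed) {
  if (concentration < 0) stop("concentration must be non-negative")
  base <- scene_base(scene, concentration)
  h <- scene$height; w <- scene$width
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  offset <- if (scene$offset_noise_sd > 0)
    stats::rnorm(1, 0, scene$offset_noise_sd) else 0
  blotch <- 0
  if (scene$blotch_amplitude > 0 && h * w > 1) {
    f <- gaussian_smooth(matrix(stats::rnorm(h * w), h, w),
                         scene$blotch_scale)
    f <- f - mean(f)
    s <- stats::sd(as.vector(f))
    if (s > 0) blotch <- f * (scene$blotch_amplitude / s)
  }
  img <- array(0, dim = c(h, w, 3L))
  for (k in 1:3) {
    ch <- base[k] + offset + blotch
    if (length(ch) == 1L) ch <- matrix(ch, h, w)
    if (scene$pixel_noise_sd > 0)
      ch <- ch + stats::rnorm(h * w, 0, scene$pixel_noise_sd)
    img[, , k] <- ch
  }
  if (scene$quantize) img <- round(img)
  img <- pmin(pmax(img, 0), 255)
  if (scene$quantize) rgb_image(img) else img
}

#' Generate a full synthetic calibration run on disk
#'
#' Renders one PNG per concentration (per-image seeds `base_seed + index`)
#' and writes a manifest CSV mapping each file to its light source, known
#' concentration, seed and ground-truth channel means.
#'
#' @param scene A [scene_config()] (quantization must be on to write PNG).
#' @param concentrations Concentration series; default
#'   [default_concentrations()].
#' @param base_seed First seed; image `i` uses `base_seed + i - 1`.
#' @param outdir Output directory (created if missing).
#' @return The manifest as a data frame of class `"run_manifest"`,
#'   invisibly; also written as `manifest.csv` in `outdir`.
#' @export
generate_calibration_run <- function(scene,
                                     concentrations = default_concentrations(),
                                     base_seed = scene$seed, outdir) {
  if (!length(concentrations)) stop("empty concentration list")
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  rows <- lapply(seq_along(concentrations), function(i) {
    conc <- concentrations[i]
    seed <- base_seed + i - 1L
    img <- render_strip(scene, conc, seed = seed)
    file <- file.path(outdir, sprintf("%s_%02d.png", scene$source$name, i))
    write_strip_image(img, file)
    base <- scene_base(scene, conc)
    data.frame(file = file, source = scene$source$name,
               concentration_mgdl = conc, seed = seed,
               truth_r = base[[1L]], truth_g = base[[2L]],
               truth_b = base[[3L]], stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  if (anyDuplicated(manifest$file)) stop("manifest paths are not unique")
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  class(manifest) <- c("run_manifest", "data.frame")
  invisible(manifest)
}

#' Simulate blank replicates and measure them
#'
#' Renders `n` blank (zero-concentration) strips with seeds
#' `base_seed, base_seed + 1, ...` and runs each through the imaging stage
#' (scene ROI), returning the per-image channel statistics. With only the
#' per-image illumination offset active, the standard deviation of the
#' returned channel means converges to `offset_noise_sd` -- the dispersion
#' that the 3-sigma detection limit is built on.
#'
#' @param scene A [scene_config()].
#' @param n Number of blank replicates, >= 2.
#' @param base_seed First seed.
#' @return List of `"channel_stats"` (class `"blank_stats"`); see
#'   [stats_table()] to tabulate.
#' @export
generate_blanks <- function(scene, n, base_seed = scene$seed) {
  if (n < 2L) stop("at least 2 blank replicates are required")
  mask <- build_roi(c(scene$height, scene$width), scene$roi)
  out <- lapply(seq_len(n), function(i) {
    img <- render_strip(scene, 0, seed = base_seed + i - 1L)
    channel_means(img, mask)
  })
  class(out) <- "blank_stats"
  out
}

#' Tabulate channel statistics
#'
#' @param stats A list of `"channel_stats"` objects.
#' @return Data frame with one row per image.
#' @export
stats_table <- function(stats) {
  do.call(rbind, lapply(stats, function(s)
    data.frame(mean_r = s$mean_r, mean_g = s$mean_g, mean_b = s$mean_b,
               mean_y = s$mean_y, n_pixels = s$n_pixels,
               clipped_fraction = s$clipped_fraction)))
}

#' Solution preparation helpers
#'
#' `stock_concentration()` converts a weighed mass dissolved in a volume to
#' mg/dL (mass in mg / volume in mL x 100, since 1 dL = 100 mL);
#' `dilution_series()` gives the dilution factor of the stock needed for
#' each target concentration.
#'
#' @param mass_mg Analyte mass (mg), > 0.
#' @param volume_ml Solvent volume (mL), > 0.
#' @return `stock_concentration`: concentration in mg/dL.
#' @examples
#' stock_concentration(0.5, 25)  # 2 mg/dL
#' dilution_series(2, c(0.1, 1, 2))
#' @export
stock_concentration <- function(mass_mg, volume_ml) {
  if (mass_mg <= 0 || volume_ml <= 0)
    stop("mass and volume must be positive")
  mass_mg * 100 / volume_ml
}

#' @rdname stock_concentration
#' @param stock_mgdl Stock concentration (mg/dL).
#' @param targets Target concentrations (mg/dL), each in (0, stock].
#' @export
dilution_series <- function(stock_mgdl, targets) {
  if (any(targets > stock_mgdl))
    stop("infeasible dilution: target exceeds stock concentration")
  if (any(targets <= 0)) stop("targets must be positive")
  stats::setNames(stock_mgdl / targets, paste0(targets, " mg/dL"))
}

#' Serialize a scene to / from YAML
#'
#' Plain-text round trip of the generative scene description (linear mode;
#' the spectral camera and stain objects are reconstructed from defaults
#' unless overridden in the YAML).
#'
#' @param scene A [scene_config()].
#' @param path YAML file path.
#' @return `scene_to_yaml` returns `path` invisibly; `scene_from_yaml`
#'   returns a [scene_config()].
#' @export
scene_to_yaml <- function(scene, path) {
  x <- list(source = scene$source$name, mode = scene$mode,
            height = scene$height, width = scene$width,
            roi = unclass(scene$roi),
            pixel_noise_sd = scene$pixel_noise_sd,
            offset_noise_sd = scene$offset_noise_sd,
            blotch_amplitude = scene$blotch_amplitude,
            blotch_scale = scene$blotch_scale,
            quantize = scene$quantize, seed = scene$seed,
            metadata = scene$metadata)
  if (scene$mode == "linear") {
    x$lines <- apply(scene$lines, 1L, as.list, simplify = FALSE)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname scene_to_yaml
#' @export
scene_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  roi <- if (is.null(x$roi)) roi_default()
         else structure(x$roi, class = "roi_spec")
  lines <- NULL
  if (!is.null(x$lines)) {
    lines <- do.call(rbind, lapply(x$lines, function(l) c(l$m, l$b)))
    dimnames(lines) <- list(names(x$lines), c("m", "b"))
  }
  scene_config(source = x$source, mode = x$mode, lines = lines,
               height = x$height, width = x$width, roi = roi,
               pixel_noise_sd = x$pixel_noise_sd,
               offset_noise_sd = x$offset_noise_sd,
               blotch_amplitude = x$blotch_amplitude,
               blotch_scale = x$blotch_scale, quantize = x$quantize,
               seed = x$seed,
               metadata = x$metadata %||% list())
}
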