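# Small scene builders shared across tests. Noise defaults off so each test
# switches on exactly the component it probes.
tiny_scene <- function(source = "green", height = 24, width = 36,
                       roi = roi_full(), pixel_noise_sd = 0,
                       offset_noise_sd = 0, blotch_amplitude = 0,
                       quantize = FALSE, ...) {
  scene_config(source = source, height = height, width = width, roi = roi,
               pixel_noise_sd = pixel_noise_sd,
               offset_noise_sd = offset_noise_sd,
               blotch_amplitude = blotch_amplitude, quantize = quantize, ...)
}

# Minimal curve object for selection tests where the printed R^2 values are
# the inputs (the underlying per-point data are not published).
curve_stub <- function(source, channel, r_squared, m = -1, b = 200) {
  structure(list(m = m, b = b, r_squared = r_squared, n = 12,
                 sigma = NA_real_, sigma_method = "none",
                 lod = NA_real_, loq = NA_real_,
                 source = source, channel = channel),
            class = "calib")
}

# Closed-form OLS via the normal equations, independent of lm().
normal_eq_fit <- function(x, y) {
  n <- length(x)
  m <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  b <- (sum(y) - m * sum(x)) / n
  c(intercept = b, slope = m)
}
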