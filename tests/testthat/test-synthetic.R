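test_that("noiseless linear rendering reproduces the ground-truth line exactly", {
  sc <- tiny_scene("green")
  img <- render_strip(sc, 1.0)
  expect_equal(dim(img), c(24, 36, 3))
  # every G pixel sits exactly on the line: -15.669 * 1 + 240.34
  expect_true(all(img[, , 2] == -15.669 * 1.0 + 240.34))
  expect_equal(unique(as.vector(img[, , 2])), 224.671)

  # zero concentration: uniform intercept values per channel
  img0 <- render_strip(sc, 0)
  tl <- truth_lines("green")
  for (k in 1:3) expect_true(all(img0[, , k] == tl[k, "b"]))

  expect_error(render_strip(sc, -0.5), "non-negative")
})

test_that("rendering is bit-identical under a fixed seed and differs across seeds", {
  sc <- tiny_scene("green", pixel_noise_sd = 2, offset_noise_sd = 2.4,
                   blotch_amplitude = 3, quantize = TRUE)
  a <- render_strip(sc, 0.7, seed = 77)
  b <- render_strip(sc, 0.7, seed = 77)
  expect_identical(a, b)
  expect_false(identical(a, render_strip(sc, 0.7, seed = 78)))
  # rendering does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(render_strip(sc, 0.7, seed = 5)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("imaging recovers the generator line within quantization error", {
  conc <- default_concentrations()
  mask_scene <- tiny_scene("white", quantize = FALSE)
  mask <- build_roi(c(mask_scene$height, mask_scene$width), mask_scene$roi)
  tl <- truth_lines("white")
  for (quant in c(FALSE, TRUE)) {
    sc <- tiny_scene("white", quantize = quant)
    tol <- if (quant) 0.5 else 1e-9
    for (c0 in conc[c(1, 6, 12)]) {
      st <- channel_means(render_strip(sc, c0), mask)
      means <- c(st$mean_r, st$mean_g, st$mean_b)
      expect_true(all(abs(means - (tl[, "m"] * c0 + tl[, "b"])) <= tol))
    }
  }
})

test_that("mean grayscale decreases with concentration in both modes", {
  conc <- c(0.1, 0.5, 1.0, 1.5, 2.0)
  for (mode in c("linear", "spectral")) {
    sc <- tiny_scene("green", mode = mode)
    g <- vapply(conc, function(c0) {
      st <- channel_means(render_strip(sc, c0),
                          build_roi(c(sc$height, sc$width), sc$roi))
      st$mean_g
    }, numeric(1))
    expect_true(all(diff(g) < 0), info = mode)
  }
})

test_that("the blotch field is smooth, zero-mean and scaled to its amplitude", {
  sc <- tiny_scene("green", height = 30, width = 40,
                   blotch_amplitude = 5, blotch_scale = 4)
  img <- render_strip(sc, 1.0, seed = 1)  # G base 224.671: no clipping risk
  field <- img[, , 2] - 224.671
  expect_equal(mean(field), 0, tolerance = 1e-9)
  expect_equal(sd(as.vector(field)), 5, tolerance = 1e-9)
  # smoothing leaves neighbouring pixels correlated
  expect_gt(cor(as.vector(field[-1, ]), as.vector(field[-30, ])), 0.5)

  # ROI sub-means are unbiased over seeds: |bias| < 3 SE over 200 seeds
  roi <- build_roi(c(30, 40), roi_rect(14, 20))
  devs <- vapply(1:200, function(s) {
    channel_means(render_strip(sc, 1.0, seed = s), roi)$mean_g - 224.671
  }, numeric(1))
  expect_lt(abs(mean(devs)), 3 * sd(devs) / sqrt(200))
})

test_that("calibration runs render to disk reproducibly", {
  outdir <- withr::local_tempdir()
  sc <- tiny_scene("green", quantize = TRUE, pixel_noise_sd = 1,
                   offset_noise_sd = 1, blotch_amplitude = 2)
  man <- generate_calibration_run(sc, base_seed = 10,
                                  outdir = file.path(outdir, "a"))
  expect_equal(nrow(man), 12L)
  expect_true(all(file.exists(man$file)))
  expect_true(file.exists(file.path(outdir, "a", "manifest.csv")))
  expect_false(anyDuplicated(man$file) > 0)
  expect_equal(man$seed, 10:21)

  man2 <- generate_calibration_run(sc, base_seed = 10,
                                   outdir = file.path(outdir, "b"))
  expect_identical(unname(tools::md5sum(man$file)),
                   unname(tools::md5sum(man2$file)))

  expect_error(generate_calibration_run(sc, concentrations = numeric(0),
                                        outdir = outdir),
               "empty")
})

test_that("blank replicates carry the illumination-offset dispersion", {
  sc0 <- tiny_scene("green", quantize = TRUE)
  blanks <- generate_blanks(sc0, 5, base_seed = 3)
  g <- vapply(blanks, `[[`, numeric(1), "mean_g")
  expect_equal(sd(g), 0)  # no noise at all: identical means
  expect_identical(g, vapply(generate_blanks(sc0, 5, base_seed = 3),
                             `[[`, numeric(1), "mean_g"))
  expect_error(generate_blanks(sc0, 1), "at least 2")

  # offset noise only: sd of blank means estimates the offset sd
  sc <- tiny_scene("green", offset_noise_sd = 2.3974, quantize = FALSE)
  g2 <- vapply(generate_blanks(sc, 300, base_seed = 11),
               `[[`, numeric(1), "mean_g")
  expect_lt(abs(sd(g2) - 2.3974) / 2.3974, 0.15)
})

test_that("solution preparation arithmetic is exact", {
  expect_identical(stock_concentration(0.5, 25), 2)
  expect_error(stock_concentration(0, 25), "positive")

  f <- dilution_series(2, c(0.1, 2))
  expect_equal(unname(f), c(20, 1))
  expect_error(dilution_series(2, 2.5), "infeasible")
})

test_that("scenes round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  sc <- tiny_scene("blue", pixel_noise_sd = 1.5, offset_noise_sd = 2,
                   blotch_amplitude = 3, quantize = TRUE, seed = 42)
  scene_to_yaml(sc, path)
  back <- scene_from_yaml(path)
  expect_identical(back$source$name, "blue")
  expect_equal(back$lines, sc$lines)
  expect_identical(render_strip(back, 1.2, seed = 9),
                   render_strip(sc, 1.2, seed = 9))
})
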