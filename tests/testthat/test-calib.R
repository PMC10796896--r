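printed_lines <- list(
  green = c(m = -15.669, b = 240.34),
  white = c(m = -11.972, b = 166.73),
  red   = c(m = -39.708, b = 250.92),
  blue  = c(m = -16.253, b = 174.29)
)

test_that("noiseless calibration series are fitted exactly", {
  conc <- default_concentrations()
  for (nm in names(printed_lines)) {
    ln <- printed_lines[[nm]]
    d <- data.frame(concentration = conc,
                    gray = ln[["m"]] * conc + ln[["b"]])
    cv <- calib(gray ~ concentration, d, sigma_method = "none")
    expect_equal(cv$m, ln[["m"]], tolerance = 1e-9)
    expect_equal(cv$b, ln[["b"]], tolerance = 1e-9)
    expect_equal(cv$r_squared, 1)
  }

  # two points: exact interpolation
  d2 <- data.frame(concentration = c(0.5, 1.5), gray = c(100, 60))
  cv2 <- calib(gray ~ concentration, d2, sigma_method = "none")
  expect_equal(unname(coef(cv2)), c(120, -40))
  expect_equal(cv2$r_squared, 1)

  expect_error(calib(gray ~ concentration,
                     data.frame(concentration = c(1, 1), gray = c(5, 9)),
                     sigma_method = "none"),
               "degenerate")
})

test_that("OLS matches the normal-equation oracle on random designs", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(3:15, 1)
    x <- runif(n, 0, 2)
    y <- runif(n, 0, 255)
    cv <- calib(gray ~ concentration,
                data.frame(concentration = x, gray = y),
                sigma_method = "none")
    oracle <- normal_eq_fit(x, y)
    expect_equal(cv$m, oracle[["slope"]], tolerance = 1e-8)
    expect_equal(cv$b, oracle[["intercept"]], tolerance = 1e-8)
  }
})

test_that("sigma estimators follow their stated conventions", {
  expect_equal(estimate_sigma(c(238, 240, 242), "blank_sd"), 2.0)
  expect_equal(estimate_sigma(c(240, 240, 240, 240), "blank_sd"), 0)
  expect_error(estimate_sigma(240, "blank_sd"), "at least 2")

  conc <- default_concentrations()
  noiseless <- calib(gray ~ concentration,
                     data.frame(concentration = conc,
                                gray = -15.669 * conc + 240.34),
                     sigma_method = "none")
  expect_equal(estimate_sigma(noiseless, "residual_se"), 0, tolerance = 1e-9)

  two <- calib(gray ~ concentration,
               data.frame(concentration = c(0, 1), gray = c(1, 2)),
               sigma_method = "none")
  expect_error(estimate_sigma(two, "residual_se"), "at least 3")
})

test_that("detection limits follow the 3-sigma/10-sigma convention", {
  lim <- detection_limits(2.3974, -15.669)
  expect_equal(lim[["lod"]], 0.459, tolerance = 1e-3)
  expect_equal(lim[["loq"]], 1.530, tolerance = 1e-3)
  expect_equal(lim[["loq"]] / lim[["lod"]], 10 / 3)

  expect_equal(unname(detection_limits(0, -15.669)), c(0, 0))
  expect_error(detection_limits(2, 0), "zero slope")
  expect_error(detection_limits(-1, 2), "non-negative")

  # the 10/3 ratio is universal across sigma/slope pairs
  set.seed(5)
  for (i in 1:25) {
    l <- detection_limits(runif(1, 0.1, 10), runif(1, -50, -0.5))
    expect_equal(l[["loq"]] / l[["lod"]], 10 / 3)
  }
})

test_that("best-combination selection ranks by R-squared with the stated tie-breaks", {
  curves <- list(curve_stub("red", "R", 0.9365),
                 curve_stub("green", "G", 0.9523),
                 curve_stub("blue", "B", 0.9224),
                 curve_stub("white", "G", 0.9289))
  sel <- select_best(curves)
  expect_identical(sel$best$source, "green")
  expect_identical(sel$best$channel, "G")
  expect_identical(sel$ranking$source, c("green", "red", "white", "blue"))

  # exact tie between channels of the green source: G preferred
  tie <- select_best(list(curve_stub("green", "R", 0.95),
                          curve_stub("green", "G", 0.95)))
  expect_identical(tie$best$channel, "G")

  single <- curve_stub("green", "G", 0.5)
  expect_identical(select_best(list(single))$best$r_squared, 0.5)
  expect_error(select_best(list()), "no calibration")
})

test_that("inverse prediction classifies against the detection limits", {
  conc <- default_concentrations()
  d <- data.frame(concentration = conc, gray = -15.669 * conc + 240.34)
  cv <- calib(gray ~ concentration, d, blanks = c(238.22, 240.25, 242.99),
              sigma_method = "blank_sd")
  expect_equal(cv$sigma, sd(c(238.22, 240.25, 242.99)))

  at_intercept <- invert_concentration(cv, cv$b)
  expect_equal(at_intercept$concentration_estimate, 0)
  expect_identical(at_intercept$status, "below_lod")

  # forward-then-invert round trip at 1.8 mg/dL: quantifiable (> 1.530)
  cv2 <- calib(gray ~ concentration, d, sigma_method = "residual_se")
  cv2$sigma <- 2.3974
  lim <- detection_limits(cv2$sigma, cv2$m)
  cv2$lod <- lim[["lod"]]; cv2$loq <- lim[["loq"]]
  y18 <- predict(cv2, 1.8, type = "response")
  res <- invert_concentration(cv2, y18)
  expect_equal(res$concentration_estimate, 1.8, tolerance = 1e-9)
  expect_identical(res$status, "quantifiable")

  # 1.0 mg/dL sits between LOD 0.459 and LOQ 1.530
  res1 <- invert_concentration(cv2, predict(cv2, 1.0, type = "response"))
  expect_identical(res1$status, "detected_not_quantifiable")

  # round trip is exact across the working range
  for (c0 in seq(0, 2, by = 0.25)) {
    r <- invert_concentration(cv2, cv2$m * c0 + cv2$b)
    expect_equal(r$concentration_estimate, c0, tolerance = 1e-9)
  }

  no_lim <- calib(gray ~ concentration, d, sigma_method = "none")
  expect_error(invert_concentration(no_lim, 200), "limits")
})

test_that("calib methods expose the fit consistently", {
  conc <- default_concentrations()
  set.seed(9)
  d <- data.frame(concentration = conc,
                  gray = -15.669 * conc + 240.34 + rnorm(12, 0, 2.4))
  cv <- calib(gray ~ concentration, d, sigma_method = "residual_se",
              source = "green", channel = "G")
  expect_equal(unname(coef(cv)), unname(c(cv$b, cv$m)))
  expect_equal(sum(residuals(cv)), 0, tolerance = 1e-9)
  expect_gt(cv$r_squared, 0.9)
  s <- summary(cv)
  expect_true(s$slope_se > 0)
  expect_output(print(cv), "R-squared")

  sims <- simulate(cv, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(12L, 3L))
  expect_identical(sims, simulate(cv, nsim = 3, seed = 1))

  pdf_file <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(pdf_file)
  plot(cv)
  grDevices::dev.off()
  expect_true(file.size(pdf_file) > 0)
})
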