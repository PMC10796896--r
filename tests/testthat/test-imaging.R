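random_image <- function(h, w, seed = 1) {
  set.seed(seed)
  rgb_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3)))
}

test_that("PNG write/read round-trips exactly and rejects grayscale input", {
  img <- random_image(20, 31)
  path <- withr::local_tempfile(fileext = ".png")
  write_strip_image(img, path)
  back <- read_strip_image(path)
  expect_identical(unclass(back), unclass(img))

  # fixture-sized image reports its dimensions faithfully
  big <- rgb_image(array(128L, c(257, 693, 3)))
  path2 <- withr::local_tempfile(fileext = ".png")
  write_strip_image(big, path2)
  dims <- dim(read_strip_image(path2))
  expect_equal(dims[1:2], c(257, 693))

  gray <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(runif(50), 5, 10), gray)
  expect_error(read_strip_image(gray), "single-channel")
  expect_error(read_strip_image("no/such/file.png"), "not found")
})

test_that("ROI masks count pixels exactly", {
  full <- build_roi(c(100, 80), roi_full())
  expect_identical(attr(full, "pixel_count"), 8000L)

  dflt <- build_roi(c(297, 733), roi_default())
  expect_identical(attr(dflt, "pixel_count"), 178101L)

  # brute-force cell count oracle on a disc
  disc <- build_roi(c(41, 41), roi_disc(12))
  count <- 0L
  for (r in 1:41) for (c in 1:41)
    if ((r - 21)^2 + (c - 21)^2 <= 144) count <- count + 1L
  expect_identical(attr(disc, "pixel_count"), count)
  expect_identical(sum(disc), count)

  expect_error(build_roi(c(100, 80), roi_rect(257, 693)), "bounds")
  expect_error(build_roi(c(20, 20), roi_disc(15)), "bounds")
})

test_that("channel means equal the per-pixel loop oracle", {
  img <- random_image(15, 22, seed = 42)
  mask <- build_roi(c(15, 22), roi_rect(9, 14))
  st <- channel_means(img, mask)

  sums <- c(0, 0, 0); n <- 0L
  for (r in 1:15) for (c in 1:22) if (mask[r, c]) {
    sums <- sums + c(img[r, c, 1], img[r, c, 2], img[r, c, 3])
    n <- n + 1L
  }
  expect_identical(st$n_pixels, n)
  expect_equal(st$mean_r, sums[1] / n, tolerance = 1e-9)
  expect_equal(st$mean_g, sums[2] / n, tolerance = 1e-9)
  expect_equal(st$mean_b, sums[3] / n, tolerance = 1e-9)
  expect_equal(st$mean_y,
               0.2989 * st$mean_r + 0.5870 * st$mean_g + 0.1140 * st$mean_b)

  uni <- rgb_image(array(37L, c(4, 5, 3)))
  stu <- channel_means(uni, build_roi(c(4, 5), roi_full()))
  expect_equal(c(stu$mean_r, stu$mean_g, stu$mean_b), c(37, 37, 37))

  half <- array(0L, c(2, 2, 3)); half[1, , ] <- 255L
  sth <- channel_means(rgb_image(half), build_roi(c(2, 2), roi_full()))
  expect_equal(sth$mean_r, 127.5)
  expect_equal(sth$clipped_fraction, 0.5)

  empty <- build_roi(c(4, 5), roi_full())
  empty[] <- FALSE
  attr(empty, "pixel_count") <- 0L
  expect_error(channel_means(uni, empty), "empty mask")
})

test_that("the YUV transform uses the printed coefficients exactly", {
  expect_identical(rgb_to_yuv(1, 0, 0)$y, 0.2989)
  expect_identical(rgb_to_yuv(0, 1, 0)$y, 0.5870)
  expect_identical(rgb_to_yuv(0, 0, 1)$y, 0.1140)
  expect_equal(rgb_to_yuv(255, 255, 255)$y, 254.9745)  # hand multiplication

  # chrominance rows annihilate gray inputs exactly
  for (g in c(0, 1, 77.7, 255)) {
    yuv <- rgb_to_yuv(g, g, g)
    expect_identical(yuv$u, 0)
    expect_identical(yuv$v, 0)
  }

  # linearity: transform of the means equals the mean of the transforms
  set.seed(3)
  px <- matrix(runif(300, 0, 255), ncol = 3)
  via_means <- rgb_to_yuv(mean(px[, 1]), mean(px[, 2]), mean(px[, 3]))
  per_pixel <- rgb_to_yuv(px[, 1], px[, 2], px[, 3])
  expect_equal(via_means$y, mean(per_pixel$y))
  expect_equal(via_means$u, mean(per_pixel$u))
  expect_equal(via_means$v, mean(per_pixel$v))
})

test_that("exposure QC classifies over-, well- and under-exposed blanks", {
  stats_of <- function(v) {
    channel_means(rgb_image(array(as.integer(v), c(3, 3, 3))),
                  build_roi(c(3, 3), roi_full()))
  }
  expect_identical(exposure_qc(stats_of(255)), "fail_overexposed")
  expect_identical(exposure_qc(stats_of(240)), "pass")
  expect_identical(exposure_qc(stats_of(150)), "warn_underexposed")

  # clipped fraction alone can fail a run
  mixed <- array(240L, c(10, 10, 3)); mixed[1, 1:2, 1] <- 255L
  st <- channel_means(rgb_image(mixed), build_roi(c(10, 10), roi_full()))
  expect_identical(exposure_qc(st), "fail_overexposed")
})

test_that("auto ROI centers the configured rectangle inside the bright strip", {
  arr <- array(20L, c(60, 80, 3))
  arr[11:50, 11:70, ] <- 220L
  img <- rgb_image(arr)
  mask <- build_roi(img, roi_auto(20, 40), image = img)
  expect_identical(attr(mask, "pixel_count"), 800L)
  hit <- which(mask, arr.ind = TRUE)
  expect_equal(range(hit[, 1]), c(21, 40))   # centered on rows 11:50
  expect_equal(range(hit[, 2]), c(21, 60))   # centered on cols 11:70
  expect_true(all(img[, , 1][mask] == 220L))
})

test_that("TIFF and JPEG inputs decode to the same raster as PNG", {
  img <- random_image(16, 25, seed = 8)
  tif <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(unclass(img) / 255, tif)
  expect_identical(unclass(read_strip_image(tif)), unclass(img))

  # smooth gradient for the lossy codec (JPEG decimates pixel noise)
  grad <- array(0, c(16, 25, 3))
  grad[, , 1] <- matrix(seq(40, 200, length.out = 25), 16, 25, byrow = TRUE)
  grad[, , 2] <- matrix(seq(220, 90, length.out = 16), 16, 25)
  grad[, , 3] <- 120
  grad <- round(grad)
  jpg <- withr::local_tempfile(fileext = ".jpg")
  EBImage::writeImage(EBImage::Image(aperm(grad / 255, c(2, 1, 3)),
                                     colormode = "Color"),
                      jpg, quality = 100)
  back <- read_strip_image(jpg)
  expect_equal(dim(back), c(16, 25, 3))
  expect_lt(mean(abs(unclass(back) - grad)), 3)
})
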