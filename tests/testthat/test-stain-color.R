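test_that("rgb_to_hsi matches the definition on canonical pixels", {
  hsi <- rgb_to_hsi(flat_image(c(255, 0, 0), 1, 1))
  expect_equal(hsi$hue[1, 1], 0)
  expect_equal(hsi$saturation[1, 1], 1)
  expect_equal(hsi$intensity[1, 1], 85)

  hsi <- rgb_to_hsi(flat_image(c(100, 100, 100), 1, 1))
  expect_true(is.na(hsi$hue[1, 1]))
  expect_equal(hsi$saturation[1, 1], 0)
  expect_equal(hsi$intensity[1, 1], 100)

  # arbitrary chromatic pixel against the independent scalar formula
  ref <- hsi_scalar(c(30, 60, 200))
  hsi <- rgb_to_hsi(flat_image(c(30, 60, 200), 1, 1))
  expect_equal(hsi$hue[1, 1], ref$h)
  expect_equal(hsi$saturation[1, 1], ref$s)
  expect_equal(hsi$intensity[1, 1], ref$i)
})

test_that("rgb_to_hsi agrees with the scalar oracle on random rasters", {
  set.seed(11)
  img <- random_raster(32, 32)
  hsi <- rgb_to_hsi(img)
  for (idx in sample(32 * 32, 200)) {
    i <- ((idx - 1) %% 32) + 1; j <- ((idx - 1) %/% 32) + 1
    ref <- hsi_scalar(img[i, j, ])
    expect_equal(hsi$hue[i, j], ref$h)
    expect_equal(hsi$saturation[i, j], ref$s)
    expect_equal(hsi$intensity[i, j], ref$i)
  }
})

test_that("rgb_to_hsi rejects malformed input", {
  expect_error(rgb_to_hsi(matrix(1, 3, 3)), "3 array")
  expect_error(rgb_to_hsi(array(300, c(2, 2, 3))), "0, 255")
})

test_that("circular hue distance wraps, is symmetric and bounded", {
  expect_equal(circular_hue_distance(0.96, 0.02), 0.06)
  expect_equal(circular_hue_distance(0.5, 0.5), 0)
  expect_equal(circular_hue_distance(0.1, 0.9), 0.2)
  set.seed(4)
  h1 <- runif(200); h2 <- runif(200)
  d <- circular_hue_distance(h1, h2)
  expect_true(all(d >= 0 & d <= 0.5))
  expect_equal(d, circular_hue_distance(h2, h1))
  expect_equal(circular_hue_distance(h1, h1), rep(0, 200))
  expect_error(circular_hue_distance(1.2, 0.5), "\\[0, 1\\)")
})

test_that("classification partitions the mask and ignores everything else", {
  set.seed(21)
  profile <- default_stain_profiles()$pas
  img <- random_raster(40, 40)
  mask <- matrix(runif(1600) < 0.6, 40, 40)
  pc <- classify_pixels(img, profile, mask)
  total <- pc$n_weak + pc$n_medium + pc$n_strong + pc$n_negative + pc$n_background
  expect_identical(total, sum(mask))
  expect_identical(sum(pc$labels != PIXEL_CLASS_CODES[["outside"]]), sum(mask))

  # padding with glass-bright pixels outside the mask changes nothing
  img2 <- img
  img2[!mask] <- 255
  for (k in 1:3) {
    ch <- img2[, , k]; ch[!mask] <- 255; img2[, , k] <- ch
  }
  pc2 <- classify_pixels(img2, profile, mask)
  expect_identical(pc[c("n_weak", "n_medium", "n_strong", "n_negative", "n_background")],
                   pc2[c("n_weak", "n_medium", "n_strong", "n_negative", "n_background")])

  # determinism
  pc3 <- classify_pixels(img, profile, mask)
  expect_identical(pc$labels, pc3$labels)
})

test_that("white glass is background and an empty mask yields zero counts", {
  img <- flat_image(c(255, 255, 255), 10, 10)
  pc <- classify_pixels(img, default_stain_profiles()$trichrome_blue)
  expect_equal(pc$n_background, 100)
  expect_equal(pc$n_weak + pc$n_medium + pc$n_strong + pc$n_negative, 0)

  pc0 <- classify_pixels(img, default_stain_profiles()$pas,
                         mask = matrix(FALSE, 10, 10))
  expect_equal(pc0$n_background + pc0$n_negative + pc0$n_weak +
                 pc0$n_medium + pc0$n_strong, 0)
  expect_error(classify_pixels(img, default_stain_profiles()$pas,
                               mask = matrix(TRUE, 5, 5)),
               "does not match")
})

test_that("painted rasters are counted exactly under a narrow-band profile", {
  # 3,000 pixels at the PAS hue centre, 7,000 tissue pixels at the opposite hue
  profile <- default_stain_profiles()$pas
  on_hue <- rgb_exact_hue(0.86)
  off_hue <- rgb_exact_hue((0.86 + 0.5) %% 1)
  img <- array(0, c(100, 100, 3))
  set.seed(5)
  pos_idx <- sample(10000, 3000)
  for (k in 1:3) {
    ch <- matrix(off_hue[k], 100, 100)
    ch[pos_idx] <- on_hue[k]
    img[, , k] <- ch
  }
  pc <- classify_pixels(img, profile)
  expect_identical(pc$n_weak + pc$n_medium + pc$n_strong, 3000L)
  expect_identical(pc$n_negative, 7000L)
  expect_equal(percent_positive(pc), 30)
})

test_that("a brownish pixel near the DAB hue centre is positive", {
  rgb <- rgb_exact_hue(0.06, lo = 60, hi = 170)  # hue 0.06, distance 0.04
  expect_identical(classify_scalar(rgb, default_stain_profiles()$dab), "medium")
  pc <- classify_pixels(flat_image(rgb, 1, 1), default_stain_profiles()$dab)
  expect_identical(pc$n_weak + pc$n_medium + pc$n_strong, 1L)
})

test_that("classify_pixels matches the scalar oracle exactly on random rasters", {
  profiles <- default_stain_profiles()
  set.seed(99)
  for (rep in 1:6) {
    img <- random_raster(24, 24)
    pr <- profiles[[(rep %% length(profiles)) + 1]]
    expect_identical(unname(classify_pixels(img, pr)$labels),
                     unname(classify_raster_scalar(img, pr)))
  }
})

test_that("percent_positive excludes background and flags empty tissue", {
  pc <- structure(list(n_weak = 1000L, n_medium = 1000L, n_strong = 1000L,
                       n_negative = 7000L, n_background = 500L),
                  class = "pixel_count")
  expect_equal(percent_positive(pc), 30)
  pc$n_weak <- pc$n_medium <- pc$n_strong <- 0L
  expect_equal(percent_positive(pc), 0)
  pc$n_negative <- 0L
  expect_true(is.na(percent_positive(pc)))
})

test_that("hue calibration is a circular mean", {
  img <- flat_image(rgb_exact_hue(0.62), 10, 10)
  expect_equal(calibrate_hue(img, matrix(TRUE, 10, 10)), 0.62)

  # equal mix of 0.58 and 0.62 averages to 0.60
  img2 <- array(0, c(10, 10, 3))
  a <- rgb_exact_hue(0.58); b <- rgb_exact_hue(0.62)
  for (k in 1:3) img2[, , k] <- matrix(rep(c(a[k], b[k]), each = 50), 10)
  expect_equal(calibrate_hue(img2, matrix(TRUE, 10, 10)), 0.60)

  # mix straddling the wrap: 0.98 and 0.02 average to 0.00, not 0.50
  img3 <- array(0, c(10, 10, 3))
  a <- rgb_exact_hue(0.98); b <- rgb_exact_hue(0.02)
  for (k in 1:3) img3[, , k] <- matrix(rep(c(a[k], b[k]), each = 50), 10)
  expect_equal(calibrate_hue(img3, matrix(TRUE, 10, 10)), 0, tolerance = 1e-12)

  # no qualifying pixels
  grey <- flat_image(c(120, 120, 120), 4, 4)
  expect_error(calibrate_hue(grey, matrix(TRUE, 4, 4)), "calibration")
})

test_that("stain profiles validate their invariants and round-trip via YAML", {
  expect_error(stain_profile("x", 1.2, 0.1), "hue_center")
  expect_error(stain_profile("x", 0.5, 0), "hue_width")
  expect_error(stain_profile("x", 0.5, 0.1, intensity_strong_upper = 200,
                             intensity_medium_upper = 150), "strong")
  p <- default_stain_profiles()
  expect_named(p, c("trichrome_blue", "trichrome_red", "pas", "dab", "cd34"))
  expect_equal(p$trichrome_blue$hue_center, 0.60)
  expect_equal(p$pas$hue_width, 0.05)
  expect_equal(p$trichrome_red$hue_center, 0.96)
  expect_equal(p$dab$hue_center, 0.10)

  path <- tempfile(fileext = ".yaml")
  write_stain_profiles(p, path)
  p2 <- read_stain_profiles(path)
  expect_equal(lapply(p2, unclass), lapply(p, unclass))

  # degrees accepted in config
  writeLines("mystain:\n  hue_center_degrees: 216\n  hue_width: 0.1", path)
  expect_equal(read_stain_profiles(path)$mystain$hue_center, 0.6)
})
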