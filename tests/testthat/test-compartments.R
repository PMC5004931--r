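test_that("compartment masks validate codes and resolution", {
  expect_error(compartment_mask(matrix(9L, 2, 2), 1), "unknown compartment")
  expect_error(compartment_mask(matrix(0L, 2, 2), 0), "microns_per_pixel")
  m <- compartment_mask(matrix(c(0L, 1L, 3L, 5L), 2, 2), 0.5)
  expect_s3_class(m, "compartment_mask")
})

test_that("label PNG round-trips through load_compartments", {
  lab <- matrix(0L, 20, 30)
  lab[3:10, 4:20] <- 1L   # cortex
  lab[12:18, 4:20] <- 3L  # inner stripe
  path <- tempfile(fileext = ".png")
  png::writePNG(lab / 255, path)
  m <- load_compartments(path, microns_per_pixel = 2)
  expect_identical(m$labels, lab)
  expect_equal(m$microns_per_pixel, 2)
})

test_that("polygons rasterize exactly on pixel centres, overlaps rejected", {
  sq <- list(compartment = "cortex",
             coordinates = cbind(c(10, 110, 110, 10), c(5, 5, 105, 105)))
  lab <- rasterize_polygons(list(sq), height = 120, width = 130)
  expect_identical(sum(lab == COMPARTMENT_CODES[["cortex"]]), 10000L)

  tri <- list(compartment = "inner_stripe",
              coordinates = cbind(c(10, 50, 10), c(110, 110, 118)))
  lab2 <- rasterize_polygons(list(sq, tri), 120, 130)
  expect_gt(sum(lab2 == COMPARTMENT_CODES[["inner_stripe"]]), 0)

  clash <- list(compartment = "outer_stripe",
                coordinates = cbind(c(100, 150, 150, 100), c(50, 50, 90, 90)))
  expect_error(rasterize_polygons(list(sq, clash), 120, 160), "overlapping")
  expect_error(rasterize_polygons(list(list(compartment = "wherever",
                                            coordinates = sq$coordinates)),
                                  120, 130), "unknown compartment")
})

test_that("polygon JSON annotations load into a mask", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(width = 50, height = 40, polygons = list(
    list(compartment = "cortex",
         coordinates = list(c(0, 0), c(50, 0), c(50, 20), c(0, 20))),
    list(compartment = "outer_stripe",
         coordinates = list(c(0, 20), c(50, 20), c(50, 40), c(0, 40))))),
    path, auto_unbox = TRUE)
  m <- load_compartments(path, 1)
  expect_identical(sum(m$labels == 1L), 50L * 20L)
  expect_identical(sum(m$labels == 2L), 50L * 20L)
})

test_that("compartment fractions cover tissue and exclude glomeruli", {
  lab <- matrix(0L, 100, 100)
  lab[1:50, ] <- 1L   # cortex
  lab[51:100, ] <- 3L # inner stripe
  f <- compartment_fractions(compartment_mask(lab, 1))
  expect_equal(f[["cortex"]], 50)
  expect_equal(f[["medulla"]], 50)
  expect_equal(f[["cortex"]] + f[["medulla"]], 100, tolerance = 1e-9)

  lab[1:10, 1:10] <- 5L  # excluded region must leave the denominator
  f2 <- compartment_fractions(compartment_mask(lab, 1))
  expect_equal(f2[["cortex"]], 100 * (5000 - 100) / (10000 - 100))
  expect_equal(f2[["cortex"]] + f2[["medulla"]], 100, tolerance = 1e-9)

  lab3 <- matrix(1L, 10, 10)
  expect_equal(compartment_fractions(compartment_mask(lab3, 1))[["cortex"]], 100)

  # cohort-scale split: 45,400 cortex px + 54,600 medulla px
  lab4 <- matrix(c(rep(1L, 45400), rep(4L, 54600)), 1000, 100)
  f4 <- compartment_fractions(compartment_mask(lab4, 1))
  expect_equal(f4[["cortex"]], 45.4)
  expect_equal(f4[["medulla"]], 54.6)

  expect_warning(f0 <- compartment_fractions(compartment_mask(matrix(0L, 5, 5), 1)),
                 "no tissue")
  expect_true(all(is.na(f0)))
})

test_that("stripe width recovers parallel separations exactly", {
  a <- cbind(x = c(0, 200), y = c(50, 50))
  b <- cbind(x = c(0, 200), y = c(150, 150))
  expect_equal(stripe_width(a, b, 1)$width_mm, 0.100)
  # scale of a thick inner stripe: 4,400 px at 1 um/px is 4.4 mm
  b2 <- cbind(x = c(0, 200), y = c(4450, 4450))
  expect_equal(stripe_width(a, b2, 1)$width_mm, 4.4)
  # resolution scales linearly
  expect_equal(stripe_width(a, b, 2.5)$width_mm, 0.250)
})

test_that("stripe width of a wavy boundary matches a dense closed-form median", {
  xs <- seq(0, 400, by = 1)
  amp <- 4; period <- 70  # period coprime to the sampling interval
  a <- cbind(x = xs, y = 100 + amp * sin(2 * pi * xs / period))
  b <- cbind(x = c(-50, 450), y = c(220, 220))
  got <- stripe_width(a, b, 1)$width_mm * 1000

  # oracle: 10,000 dense samples; perpendicular distance to the line y = 220
  # from a point on the sinusoid has the closed form (220 - y) / |n_y|
  ts <- seq(0, 400, length.out = 10000)
  y <- 100 + amp * sin(2 * pi * ts / period)
  slope <- amp * (2 * pi / period) * cos(2 * pi * ts / period)
  ny <- 1 / sqrt(1 + slope^2)  # |y-component| of the unit normal
  oracle <- median((220 - y) / ny)
  expect_equal(got, oracle, tolerance = 0.01)
})

test_that("stripe width is symmetric for near-parallel boundaries", {
  a <- cbind(x = seq(0, 300, by = 5), y = 50 + 0.02 * seq(0, 300, by = 5))
  b <- cbind(x = seq(0, 300, by = 5), y = 170 - 0.01 * seq(0, 300, by = 5))
  w1 <- stripe_width(a, b, 1)$width_mm
  w2 <- stripe_width(b, a, 1)$width_mm
  expect_equal(w1, w2, tolerance = 0.02)
})

test_that("degenerate ruler geometry is rejected", {
  a <- cbind(x = c(0, 100), y = c(0, 100))
  b <- cbind(x = c(0, 100), y = c(100, 0))
  expect_error(stripe_width(a, b, 1), "intersect")
  # perpendicular boundaries: normals never meet b
  c1 <- cbind(x = c(0, 100), y = c(50, 50))
  c2 <- cbind(x = c(200, 200), y = c(60, 160))
  expect_error(stripe_width(c1, c2, 1), "parallel")
  expect_error(stripe_width(a[1, , drop = FALSE], b, 1), "2 vertices")
})
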