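# Independent scalar oracles, deliberately written as per-pixel branchy code
# rather than the package's vectorised arithmetic.

# scalar HSI of one RGB triplet
hsi_scalar <- function(rgb) {
  r <- rgb[1]; g <- rgb[2]; b <- rgb[3]
  i <- (r + g + b) / 3
  mn <- min(r, g, b)
  mx <- max(r, g, b)
  s <- if (i == 0) 0 else 1 - mn / i
  if (mx == mn) return(list(h = NA_real_, s = s, i = i))
  d <- mx - mn
  h6 <- if (mx == r) {
    hh <- (g - b) / d
    if (hh < 0) hh + 6 else hh
  } else if (mx == g) {
    (b - r) / d + 2
  } else {
    (r - g) / d + 4
  }
  list(h = h6 / 6, s = s, i = i)
}

hue_dist_scalar <- function(h1, h2) {
  d <- abs(h1 - h2)
  min(d, 1 - d)
}

# scalar five-class decision for one pixel under a stain profile
classify_scalar <- function(rgb, profile) {
  px <- hsi_scalar(rgb)
  if (px$i > profile$tissue_intensity_max) return("background")
  if (is.na(px$h)) return("negative")
  if (hue_dist_scalar(px$h, profile$hue_center) > profile$hue_width)
    return("negative")
  if (px$s < profile$saturation_min) return("negative")
  if (px$i > profile$intensity_weak_upper) return("negative")
  if (px$i < profile$intensity_strong_upper) return("strong")
  if (px$i < profile$intensity_medium_upper) return("medium")
  "weak"
}

# label raster of a whole image via the scalar oracle
classify_raster_scalar <- function(image, profile) {
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- matrix(NA_integer_, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      out[i, j] <- PIXEL_CLASS_CODES[[classify_scalar(image[i, j, ], profile)]]
    }
  }
  out
}

# RGB triplet whose hexcone hue is exactly `h` (constructed, not converted)
rgb_exact_hue <- function(h6_over_6, lo = 100, hi = 200) {
  h6 <- h6_over_6 * 6
  sector <- floor(h6)
  f <- h6 - sector
  d <- hi - lo
  switch(as.character(sector %% 6),
         "0" = c(hi, lo + f * d, lo),
         "1" = c(hi - f * d, hi, lo),
         "2" = c(lo, hi, lo + f * d),
         "3" = c(lo, hi - f * d, hi),
         "4" = c(lo + f * d, lo, hi),
         "5" = c(hi, lo, hi - f * d))
}

# uniform-colour image
flat_image <- function(rgb, h = 4, w = 5) {
  img <- array(0, c(h, w, 3))
  for (k in 1:3) img[, , k] <- rgb[k]
  img
}

random_raster <- function(h = 64, w = 64) {
  array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
}
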