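#' Convert an 8-bit RGB raster to hue/saturation/intensity
#'
#' Converts a 3-channel brightfield image to the HSI representation used by
#' positive-pixel-count stain classification.  Hue is expressed as a fraction
#' of the color circle in `[0, 1)` with pure red at 0 (the hexcone hue),
#' saturation as `1 - min(R,G,B) / mean(R,G,B)` in `[0, 1]`, and intensity as
#' the channel mean `(R + G + B) / 3` on the original `[0, 255]` scale.
#' Achromatic pixels (`R = G = B`) have saturation 0 and an undefined hue,
#' reported as `NA`.
#'
#' @param image numeric array of dimension `height x width x 3` with values in
#'   `[0, 255]` (as returned by [read_image()]).
#' @return An object of class `hsi_raster`: a list with matrices `hue`
#'   (fraction in `[0, 1)`, `NA` where undefined), `saturation` (`[0, 1]`) and
#'   `intensity` (`[0, 255]`).
#' @examples
#' img <- array(0, c(1, 1, 3)); img[1, 1, ] <- c(255, 0, 0)
#' rgb_to_hsi(img)$hue  # 0: pure red is the hue origin
#' @export
rgb_to_hsi <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("'image' must be a height x width x 3 array of 8-bit RGB values")
  if (min(image) < 0 || max(image) > 255)
    stop("RGB values must lie in [0, 255]")
  dm <- dim(image)[1:2]
  r <- matrix(image[, , 1], dm[1], dm[2])
  g <- matrix(image[, , 2], dm[1], dm[2])
  b <- matrix(image[, , 3], dm[1], dm[2])
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  delta <- mx - mn
  intensity <- (r + g + b) / 3
  saturation <- ifelse(intensity > 0, 1 - mn / intensity, 0)
  # hexcone hue; guard the 0/0 cases with delta = 1 (hue set NA afterwards)
  d <- ifelse(delta == 0, 1, delta)
  hue <- ifelse(mx == r, ((g - b) / d) %% 6,
         ifelse(mx == g, (b - r) / d + 2,
                         (r - g) / d + 4)) / 6
  hue[delta == 0] <- NA_real_
  structure(list(hue = hue, saturation = saturation, intensity = intensity),
            class = "hsi_raster")
}

#' Circular distance between two hues
#'
#' Hue lives on a circle where 0 and 1 are identified, so the distance between
#' two hue fractions is the shorter arc, `min(|h1 - h2|, 1 - |h1 - h2|)`,
#' always in `[0, 0.5]`.  Vectorised; `NA` propagates.
#'
#' @param h1,h2 hue fractions in `[0, 1)`.
#' @return Circular distance(s) in `[0, 0.5]`.
#' @examples
#' circular_hue_distance(0.96, 0.02)  # 0.06, across the wrap
#' @export
circular_hue_distance <- function(h1, h2) {
  ok1 <- is.na(h1) | (h1 >= 0 & h1 < 1)
  ok2 <- is.na(h2) | (h2 >= 0 & h2 < 1)
  if (!all(ok1, ok2))
    stop("hue fractions must lie in [0, 1)")
  d <- abs(h1 - h2)
  pmin(d, 1 - d)
}

#' Circular mean hue of a dye sample
#'
#' Estimates the hue centre of a dye from a sample of pixels, the per-slide
#' calibration step used to tune stain profiles (per-slide hue estimates can
#' then be averaged into a panel-wide centre with [mean_hue()]).  The mean is
#' circular: hues straddling the red wrap average correctly (0.98 and 0.02
#' average to 0.00, not 0.50).
#'
#' @param image RGB array (see [rgb_to_hsi()]).
#' @param sample_mask logical matrix marking the pixels of the dye to
#'   calibrate; same height/width as `image`.
#' @param saturation_min minimum saturation for a pixel to enter the mean;
#'   achromatic and near-achromatic pixels carry no usable hue.
#' @return A hue fraction in `[0, 1)`.
#' @export
calibrate_hue <- function(image, sample_mask, saturation_min = 0.04) {
  hsi <- rgb_to_hsi(image)
  if (!identical(dim(sample_mask), dim(hsi$saturation)))
    stop("'sample_mask' must match the image height/width")
  keep <- sample_mask & !is.na(hsi$hue) & hsi$saturation >= saturation_min
  if (!any(keep))
    stop("calibration failed: no masked pixel has saturation >= saturation_min")
  mean_hue(hsi$hue[keep])
}

#' Circular mean of hue fractions
#'
#' @param h vector of hue fractions in `[0, 1)`; `NA` dropped.
#' @return Circular mean as a fraction in `[0, 1)`.
#' @export
mean_hue <- function(h) {
  h <- h[!is.na(h)]
  if (!length(h)) stop("no hues to average")
  a <- 2 * pi * h
  m <- (atan2(mean(sin(a)), mean(cos(a))) / (2 * pi)) %% 1
  if (m >= 1) 0 else m  # float wrap: -eps %% 1 rounds to 1.0
}

#' Convert a hue given in degrees to a fraction of the color circle
#'
#' Configuration files may state hue in degrees (0-360); internally all hues
#' are fractions in `[0, 1)`.
#'
#' @param degrees hue angle(s) in degrees.
#' @return Hue fraction(s) in `[0, 1)`.
#' @export
hue_from_degrees <- function(degrees) (degrees / 360) %% 1
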