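#' Pixel class codes emitted by the classifier
#'
#' Integer codes of the label raster returned by [classify_pixels()]:
#' 0 = outside the analysis mask (not examined), 1 = background (glass),
#' 2 = negative tissue, 3 = weak positive, 4 = medium positive,
#' 5 = strong positive.
#'
#' @format Named integer vector.
#' @export
PIXEL_CLASS_CODES <- c(outside = 0L, background = 1L, negative = 2L,
                       weak = 3L, medium = 4L, strong = 5L)

#' Classify pixels of a stained image as positive / negative / background
#'
#' The positive-pixel-count classifier: within the analysis mask, each pixel
#' is glass background if brighter than the profile's tissue cutoff; otherwise
#' positive for the stain when its hue falls within the profile's circular hue
#' band, its saturation reaches `saturation_min` and its intensity is at most
#' the weak-bin upper bound, with positives split into weak / medium / strong
#' intensity bins (strong = darkest); otherwise negative tissue.  See
#' [stain_profile()] for the exact rule.
#'
#' @param image RGB array, `height x width x 3`, values in `[0, 255]`.
#' @param profile a [stain_profile()].
#' @param mask logical matrix (same height/width) restricting the analysis
#'   region; `NULL` analyses every pixel.  An empty mask yields all-zero
#'   counts.
#' @param region_label identifier stored with the result (e.g. a compartment
#'   name).
#' @return An object of class `pixel_count`: a list with counts `n_weak`,
#'   `n_medium`, `n_strong`, `n_negative`, `n_background`, the `region_label`,
#'   the `stain` name, and `labels`, an integer matrix coded as in
#'   [PIXEL_CLASS_CODES] (the five-class markup raster).
#' @export
classify_pixels <- function(image, profile, mask = NULL, region_label = "all") {
  stopifnot(inherits(profile, "stain_profile"))
  hsi <- rgb_to_hsi(image)
  dm <- dim(hsi$intensity)
  if (is.null(mask)) mask <- matrix(TRUE, dm[1], dm[2])
  if (!identical(dim(mask), dm))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match image shape ", paste(dm, collapse = "x"))
  mask <- mask & !is.na(mask)

  labels <- matrix(PIXEL_CLASS_CODES[["outside"]], dm[1], dm[2])
  bg <- mask & hsi$intensity > profile$tissue_intensity_max
  hue_ok <- !is.na(hsi$hue) &
    circular_hue_distance(ifelse(is.na(hsi$hue), 0, hsi$hue),
                          profile$hue_center) <= profile$hue_width
  pos <- mask & !bg & hue_ok &
    hsi$saturation >= profile$saturation_min &
    hsi$intensity <= profile$intensity_weak_upper
  strong <- pos & hsi$intensity < profile$intensity_strong_upper
  medium <- pos & !strong & hsi$intensity < profile$intensity_medium_upper
  weak <- pos & !strong & !medium
  neg <- mask & !bg & !pos

  labels[bg] <- PIXEL_CLASS_CODES[["background"]]
  labels[neg] <- PIXEL_CLASS_CODES[["negative"]]
  labels[weak] <- PIXEL_CLASS_CODES[["weak"]]
  labels[medium] <- PIXEL_CLASS_CODES[["medium"]]
  labels[strong] <- PIXEL_CLASS_CODES[["strong"]]

  structure(list(n_weak = sum(weak), n_medium = sum(medium),
                 n_strong = sum(strong), n_negative = sum(neg),
                 n_background = sum(bg),
                 region_label = region_label, stain = profile$name,
                 labels = labels),
            class = "pixel_count")
}

#' @export
print.pixel_count <- function(x, ...) {
  cat(sprintf("pixel_count [%s, region '%s']\n", x$stain, x$region_label))
  cat(sprintf("  positive: %d weak + %d medium + %d strong = %d\n",
              x$n_weak, x$n_medium, x$n_strong,
              x$n_weak + x$n_medium + x$n_strong))
  cat(sprintf("  negative tissue: %d   background: %d\n",
              x$n_negative, x$n_background))
  pp <- percent_positive(x)
  cat(sprintf("  %% positive: %s\n", if (is.na(pp)) "undefined (no tissue)"
              else sprintf("%.2f", pp)))
  invisible(x)
}

#' Percent stain-positive tissue
#'
#' `100 * positive / (positive + negative)`.  Glass background is excluded
#' from the denominator: positivity is a fraction of tissue, not of the slide.
#' With no tissue pixels at all the percentage is undefined and returned as
#' `NA` (never silently 0).
#'
#' @param result a `pixel_count` from [classify_pixels()].
#' @return Percentage in `[0, 100]`, or `NA` if the region holds no tissue.
#' @export
percent_positive <- function(result) {
  stopifnot(inherits(result, "pixel_count"))
  pos <- result$n_weak + result$n_medium + result$n_strong
  tissue <- pos + result$n_negative
  if (tissue == 0) return(NA_real_)
  100 * pos / tissue
}

#' Render the five-class markup raster as an RGB image
#'
#' Colour coding follows the conventional positive-pixel-count markup:
#' weak positives yellow, medium orange, strong red, negative tissue blue,
#' background white, outside-mask black.
#'
#' @param result a `pixel_count`.
#' @return RGB array in `[0, 255]` suitable for [write_image()].
#' @export
markup_image <- function(result) {
  stopifnot(inherits(result, "pixel_count"))
  pal <- rbind(outside = c(0, 0, 0), background = c(255, 255, 255),
               negative = c(70, 70, 220), weak = c(255, 255, 0),
               medium = c(255, 150, 0), strong = c(200, 0, 0))
  lab <- result$labels
  out <- array(0, c(nrow(lab), ncol(lab), 3))
  for (k in seq_len(3)) out[, , k] <- matrix(pal[lab + 1L, k], nrow(lab))
  out
}
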