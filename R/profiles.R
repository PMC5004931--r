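#' Stain profile: circular-hue classification parameters for one chromogen
#'
#' A stain profile holds everything the positive-pixel classifier needs for
#' one dye or chromogen: the hue band (centre and half-band tolerance on the
#' color circle), the minimum saturation for a pixel to carry hue information,
#' the intensity thresholds that split positive pixels into weak / medium /
#' strong bins (strong is darkest), and the background cutoff above which a
#' pixel is glass rather than tissue.
#'
#' A pixel inside the analysis region is classified as:
#' \itemize{
#'   \item background, if `intensity > tissue_intensity_max`;
#'   \item positive, if its circular hue distance to `hue_center` is
#'     `<= hue_width` (boundary inclusive), `saturation >= saturation_min`,
#'     and `intensity <= intensity_weak_upper`; binned strong
#'     (`< intensity_strong_upper`), medium (`< intensity_medium_upper`)
#'     or weak otherwise;
#'   \item negative tissue otherwise.
#' }
#' Note a width of 0.5 covers the whole hue circle (the maximal circular
#' distance), so such profiles select on saturation and intensity only.
#'
#' @param name stain name.
#' @param hue_center hue fraction in `[0, 1)`; use [hue_from_degrees()] for
#'   degree-valued configuration.
#' @param hue_width circular-distance tolerance in `(0, 0.5]`.
#' @param saturation_min minimum saturation in `[0, 1]`.
#' @param intensity_weak_upper,intensity_medium_upper,intensity_strong_upper
#'   intensity bin thresholds on `[0, 255]`; must satisfy
#'   `strong < medium < weak <= tissue_intensity_max`.  No vendor values are
#'   published for these; the defaults are package choices exposed here and in
#'   the YAML profile format.
#' @param tissue_intensity_max background (glass) cutoff on `[0, 255]`.
#' @return An object of class `stain_profile`.
#' @seealso [default_stain_profiles()], [classify_pixels()]
#' @export
stain_profile <- function(name, hue_center, hue_width,
                          saturation_min = 0.04,
                          intensity_weak_upper = 220,
                          intensity_medium_upper = 175,
                          intensity_strong_upper = 100,
                          tissue_intensity_max = 240) {
  stopifnot(is.character(name), length(name) == 1L)
  if (hue_center < 0 || hue_center >= 1)
    stop("hue_center must be a fraction in [0, 1)")
  if (hue_width <= 0 || hue_width > 0.5)
    stop("hue_width must lie in (0, 0.5] (0.5 spans the whole circle)")
  if (saturation_min < 0 || saturation_min > 1)
    stop("saturation_min must lie in [0, 1]")
  thr <- c(intensity_strong_upper, intensity_medium_upper,
           intensity_weak_upper, tissue_intensity_max)
  if (any(thr < 0) || any(thr > 255))
    stop("intensity thresholds must lie in [0, 255]")
  if (!(intensity_strong_upper < intensity_medium_upper &&
        intensity_medium_upper < intensity_weak_upper &&
        intensity_weak_upper <= tissue_intensity_max))
    stop("need intensity_strong_upper < intensity_medium_upper < ",
         "intensity_weak_upper <= tissue_intensity_max")
  structure(list(name = name,
                 hue_center = hue_center,
                 hue_width = hue_width,
                 saturation_min = saturation_min,
                 intensity_weak_upper = intensity_weak_upper,
                 intensity_medium_upper = intensity_medium_upper,
                 intensity_strong_upper = intensity_strong_upper,
                 tissue_intensity_max = tissue_intensity_max),
            class = "stain_profile")
}

#' @export
print.stain_profile <- function(x, ...) {
  cat(sprintf("stain_profile '%s': hue %.3f +/- %.3f, sat >= %.2f,\n",
              x$name, x$hue_center, x$hue_width, x$saturation_min))
  cat(sprintf("  intensity bins strong < %g <= medium < %g <= weak <= %g, background > %g\n",
              x$intensity_strong_upper, x$intensity_medium_upper,
              x$intensity_weak_upper, x$tissue_intensity_max))
  invisible(x)
}

#' Shipped stain profiles for the renal morphometry panel
#'
#' The five profiles used throughout the package, with the tuned hue
#' parameters of the quantification panel: aniline-blue collagen of the
#' Masson trichrome (hue 0.60, default width 0.50), Biebrich-scarlet
#' epithelium of the trichrome (0.96, width 0.20), PAS magenta basement
#' membrane (0.86, narrow width 0.05 so only basement-membrane pink passes),
#' DAB brown chromogen for collagen III / cytokeratin immunohistochemistry
#' (0.10, width 0.50), and the same DAB parameters under the name `cd34` for
#' microvessel endothelium.
#'
#' @return Named list of [stain_profile()] objects with names
#'   `trichrome_blue`, `trichrome_red`, `pas`, `dab`, `cd34`.
#' @export
default_stain_profiles <- function() {
  list(
    trichrome_blue = stain_profile("trichrome_blue", 0.60, 0.50),
    trichrome_red  = stain_profile("trichrome_red",  0.96, 0.20),
    pas            = stain_profile("pas",            0.86, 0.05),
    dab            = stain_profile("dab",            0.10, 0.50),
    cd34           = stain_profile("cd34",           0.10, 0.50)
  )
}

#' Read stain profiles from a YAML file
#'
#' The file maps stain name to a mapping with keys `hue_center` (fraction, or
#' `hue_center_degrees`), `hue_width`, and optionally `saturation_min` and
#' the intensity thresholds; omitted keys take the [stain_profile()] defaults.
#'
#' @param path YAML file path.
#' @return Named list of `stain_profile` objects.
#' @export
read_stain_profiles <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!length(raw) || is.null(names(raw)))
    stop("profile YAML must map stain names to parameter mappings")
  out <- lapply(names(raw), function(nm) {
    p <- raw[[nm]]
    if (!is.null(p$hue_center_degrees)) {
      p$hue_center <- hue_from_degrees(p$hue_center_degrees)
      p$hue_center_degrees <- NULL
    }
    do.call(stain_profile, c(list(name = nm), p))
  })
  stats::setNames(out, names(raw))
}

#' Write stain profiles to a YAML file
#'
#' @param profiles named list of `stain_profile` objects.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_stain_profiles <- function(profiles, path) {
  lst <- lapply(profiles, function(p) unclass(p)[setdiff(names(p), "name")])
  yaml::write_yaml(lst, path)
  invisible(path)
}
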