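#' Read an 8-bit RGB region export
#'
#' Reads a plain TIFF or PNG region export (pyramidal whole-slide containers
#' are out of scope) and returns the `height x width x 3` array on the
#' `[0, 255]` scale used throughout the package.  Greyscale images are
#' expanded to three channels; an alpha channel, if present, is dropped.
#'
#' @param path image path (`.png`, `.tif`, `.tiff`).
#' @return Numeric RGB array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext))
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3), c(dim(raw), 3))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  round(raw * 255)
}

#' Write an RGB array as PNG or TIFF
#'
#' @param image RGB array on `[0, 255]`.
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  scaled <- image / 255
  switch(ext,
         png = png::writePNG(scaled, path),
         tif = ,
         tiff = tiff::writeTIFF(scaled, path),
         stop("unsupported image format: .", ext))
  invisible(path)
}

#' Quantify one case end to end
#'
#' Orchestrates the morphometry pipeline for a single case: classifies each
#' supplied stain image against its profile per compartment (`All`, `Ctx`,
#' `Med`), derives trichrome-minus-PAS fibrosis and the cytokeratin average,
#' runs microvessel detection on the CD34 image if present, and assembles the
#' per-case metric row.  Stains not supplied simply stay missing in the row.
#' With an `out_dir`, the row is written as `metrics_<case>.csv`, per-stain
#' five-class markup PNGs are emitted, and a JSON provenance sidecar records
#' the profiles, parameters and package version; reruns on identical inputs
#' are byte-identical.
#'
#' @param case_id case identifier.
#' @param images named list of RGB arrays or image paths.  Recognised names:
#'   `trichrome` (quantified with both the blue and red profiles), `pas`,
#'   `collagen3`, `cd34`, and any number of names starting `cytokeratin`
#'   (averaged).
#' @param mask a [compartment_mask()] (or path to one; see
#'   [load_compartments()], in which case `microns_per_pixel` must be given).
#' @param profiles named list of [stain_profile()]s; defaults to
#'   [default_stain_profiles()].
#' @param microns_per_pixel used only when `mask` is a path.
#' @param os_width_mm,is_width_mm stripe widths measured with
#'   [stripe_width()] (optional).
#' @param visual,creatinine passed to [assemble_slide_metrics()].
#' @param closing_radius_px,min_area_um2,max_area_um2 vessel parameters, see
#'   [detect_vessels()].
#' @param out_dir optional output directory.
#' @return The one-row metric `data.frame`, invisibly carrying attribute
#'   `vessels` (the vessel table) when CD34 was analysed.
#' @export
run_quantify <- function(case_id, images, mask,
                         profiles = default_stain_profiles(),
                         microns_per_pixel = NULL,
                         os_width_mm = NA_real_, is_width_mm = NA_real_,
                         visual = NULL, creatinine = NA_real_,
                         closing_radius_px = 2, min_area_um2 = 10,
                         max_area_um2 = 10000, out_dir = NULL) {
  if (is.character(mask))
    mask <- load_compartments(mask, microns_per_pixel)
  stopifnot(inherits(mask, "compartment_mask"))
  images <- lapply(images, function(im) if (is.character(im)) read_image(im) else im)
  for (nm in names(images))
    if (!identical(dim(images[[nm]])[1:2], dim(mask$labels)))
      stop(sprintf("image '%s' (%s) is not aligned to the compartment mask (%s)",
                   nm, paste(dim(images[[nm]])[1:2], collapse = "x"),
                   paste(dim(mask$labels), collapse = "x")))

  comp_sel <- c(All = "all", Ctx = "cortex", Med = "medulla")
  stain_pct <- lapply(comp_sel, function(cp) {
    out <- list()
    if (!is.null(images$trichrome)) {
      out$Tri <- quantify_stain(images$trichrome, profiles$trichrome_blue, mask, cp)
      out$RedTri <- quantify_stain(images$trichrome, profiles$trichrome_red, mask, cp)
    }
    if (!is.null(images$pas))
      out$PAS <- quantify_stain(images$pas, profiles$pas, mask, cp)
    if (!is.null(images$collagen3))
      out$Col <- quantify_stain(images$collagen3, profiles$dab, mask, cp)
    ck <- grep("^cytokeratin", names(images), value = TRUE)
    if (length(ck))
      out$CK <- vapply(ck, function(nm)
        quantify_stain(images[[nm]], profiles$dab, mask, cp), numeric(1))
    out
  })

  vessel_stats <- NULL
  vessels <- NULL
  if (!is.null(images$cd34)) {
    vessels <- detect_vessels(images$cd34, profiles$cd34, mask,
                              closing_radius_px = closing_radius_px,
                              min_area_um2 = min_area_um2,
                              max_area_um2 = max_area_um2)
    vessel_stats <- lapply(comp_sel, function(cp)
      microvessel_stats(vessels, mask, cp))
  }

  row <- assemble_slide_metrics(case_id, stain_pct, vessel_stats,
                                os_width_mm = os_width_mm,
                                is_width_mm = is_width_mm,
                                visual = visual, creatinine = creatinine)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(row, file.path(out_dir, sprintf("metrics_%s.csv", case_id)),
                     row.names = FALSE)
    if (!is.null(vessels))
      utils::write.csv(vessels, file.path(out_dir, sprintf("vessels_%s.csv", case_id)),
                       row.names = FALSE)
    for (nm in names(images)) {
      pr <- switch(nm, trichrome = profiles$trichrome_blue, pas = profiles$pas,
                   collagen3 = profiles$dab, cd34 = profiles$cd34, profiles$dab)
      pc <- classify_pixels(images[[nm]], pr, compartment_selector(mask, "all"))
      write_image(markup_image(pc),
                  file.path(out_dir, sprintf("markup_%s_%s.png", case_id, nm)))
    }
    write_provenance(file.path(out_dir, sprintf("provenance_%s.json", case_id)),
                     list(case_id = case_id, stains = names(images),
                          microns_per_pixel = mask$microns_per_pixel,
                          profiles = lapply(profiles, unclass),
                          vessel_params = list(closing_radius_px = closing_radius_px,
                                               min_area_um2 = min_area_um2,
                                               max_area_um2 = max_area_um2)))
  }
  attr(row, "vessels") <- vessels
  row
}

#' Cohort-level statistics, end to end
#'
#' Runs the statistical layer on a cohort metric table (path to a CSV in the
#' panel schema, or a `data.frame`): per-column summary, pairwise-complete
#' Pearson correlation report, hierarchical variable clustering, and the
#' cortex/medulla correlation ranking.  With an `out_dir`, writes
#' `summary.csv`, `correlations.csv` (long format), `compartment_ranking.csv`,
#' the clustered colour map `correlation_map.png`, and a provenance sidecar;
#' reruns on identical inputs are byte-identical.
#'
#' @param table cohort `data.frame` or CSV path (>= 3 cases).
#' @param pairs pair table for the ranking (default [compartment_pairs()];
#'   pairs absent from the table are skipped with a warning).
#' @param min_pairs,p_adjust passed to [pearson_matrix()].
#' @param out_dir optional output directory.
#' @return List of class `cohort_report`: `summary`, `report`
#'   (the `correlation_report`), `clustering`, `ranking`.
#' @export
run_cohort <- function(table, pairs = compartment_pairs(), min_pairs = 3,
                       p_adjust = "none", out_dir = NULL) {
  if (is.character(table))
    table <- utils::read.csv(table, check.names = FALSE)
  if (nrow(table) < 3) stop("need at least 3 cases for cohort statistics")
  all_na <- vapply(table, function(v) is.numeric(v) && all(is.na(v)), logical(1))
  if (any(all_na)) {
    warning("skipping all-missing column(s): ",
            paste(names(table)[all_na], collapse = ", "))
    table <- table[!all_na]
  }
  summ <- summarize_cohort(table)
  rep <- pearson_matrix(table, min_pairs = min_pairs, p_adjust = p_adjust)
  cl <- cluster_variables(rep)
  pairs <- pairs[pairs$var1 %in% rep$variables & pairs$var2 %in% rep$variables, ,
                 drop = FALSE]
  ranking <- if (nrow(pairs)) rank_compartment_correlations(rep, pairs) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
    utils::write.csv(correlation_long(rep),
                     file.path(out_dir, "correlations.csv"), row.names = FALSE)
    if (!is.null(ranking))
      utils::write.csv(ranking, file.path(out_dir, "compartment_ranking.csv"),
                       row.names = FALSE)
    grDevices::png(file.path(out_dir, "correlation_map.png"),
                   width = 900, height = 900)
    plot(rep)
    grDevices::dev.off()
    write_provenance(file.path(out_dir, "provenance_cohort.json"),
                     list(n_cases = nrow(table), min_pairs = min_pairs,
                          p_adjust = p_adjust))
  }
  structure(list(summary = summ, report = rep, clustering = cl,
                 ranking = ranking),
            class = "cohort_report")
}

write_provenance <- function(path, info) {
  info$package <- "renomorph"
  info$version <- as.character(utils::packageVersion("renomorph"))
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
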