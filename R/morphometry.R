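#' Percent stain positivity within one anatomic compartment
#'
#' Runs the positive-pixel classifier restricted to the selected compartment
#' (excluded regions such as annotated glomeruli never enter the analysis)
#' and returns the percentage of tissue pixels positive for the stain.
#' `"all"` selects the union of cortex and medulla.
#'
#' @param image RGB array of the stained section.
#' @param profile a [stain_profile()].
#' @param mask a [compartment_mask()] aligned to `image`.
#' @param compartment selector (see [compartment_selector()]).
#' @return Percentage, or `NA` (with a warning) when the compartment holds no
#'   tissue pixels in this section.
#' @export
quantify_stain <- function(image, profile, mask, compartment = "all") {
  sel <- compartment_selector(mask, compartment)
  if (!any(sel)) {
    warning(sprintf("compartment '%s' holds no pixels; %% positivity undefined",
                    compartment))
    return(NA_real_)
  }
  pc <- classify_pixels(image, profile, mask = sel, region_label = compartment)
  percent_positive(pc)
}

#' Trichrome-minus-PAS fibrosis
#'
#' The derived interstitial-fibrosis statistic: percent trichrome-positive
#' tissue minus percent PAS-positive tissue in the same compartment,
#' subtracting the basement-membrane (and shared proteinaceous-cast) signal
#' from the collagen estimate.  Negative values are meaningful and preserved
#' (cohorts do show negative minima when PAS positivity exceeds trichrome
#' positivity).
#'
#' @param tri_pct,pas_pct percentages for the same compartment; either `NA`
#'   makes the result `NA`.
#' @return `tri_pct - pas_pct`, in `[-100, 100]`.
#' @export
tp_fibrosis <- function(tri_pct, pas_pct) {
  ifelse(is.na(tri_pct) | is.na(pas_pct), NA_real_, tri_pct - pas_pct)
}

#' Average multiple cytokeratin quantitations
#'
#' When a case was stained with more than one cytokeratin antibody the
#' epithelial-cell-mass estimate is the arithmetic mean of the available
#' quantitations for the compartment.
#'
#' @param values numeric vector of percentages; `NA`s dropped.
#' @return Mean percentage, or `NA` if no value is available.
#' @export
average_cytokeratin <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Assemble one per-case row of the morphometry panel
#'
#' Materialises a single case's measurements into the cohort-table schema:
#' per-compartment (`All-`/`Ctx-`/`Med-` prefixes) stain percentages, the
#' derived `T-P` fibrosis, the cytokeratin average, microvessel density and
#' mean vessel area, the outer/inner stripe widths, optional pathologist
#' visual scores, and optional serum creatinine.  Metrics not measured for a
#' case stay `NA`; per-metric missingness is expected and tracked downstream.
#'
#' @param case_id unique case identifier.
#' @param stain_pct named list by compartment (`All`, `Ctx`, `Med`), each a
#'   named list with any of `Tri`, `RedTri`, `PAS`, `Col`, and `CK` (a vector
#'   of one or more cytokeratin percentages).  `T-P` and `CKAvg` are derived
#'   here, never supplied.
#' @param vessel_stats named list by compartment of
#'   [microvessel_result][microvessel_stats] objects (or `NULL`).
#' @param os_width_mm,is_width_mm stripe widths in mm (or `NA`).
#' @param visual named numeric vector of visual-assessment columns, already
#'   in schema names (e.g. `Vis-Ctx-Tri`); optional.
#' @param creatinine serum creatinine (mg/dL); optional.
#' @return One-row `data.frame` (`check.names = FALSE`) in the panel schema.
#' @export
assemble_slide_metrics <- function(case_id, stain_pct,
                                   vessel_stats = NULL,
                                   os_width_mm = NA_real_,
                                   is_width_mm = NA_real_,
                                   visual = NULL,
                                   creatinine = NA_real_) {
  stopifnot(length(case_id) == 1L)
  comp <- c("All", "Ctx", "Med")
  stains <- c("Tri", "RedTri", "PAS", "T-P", "Col", "CKAvg", "MVD", "MVA")
  row <- stats::setNames(
    as.list(rep(NA_real_, length(comp) * length(stains))),
    as.vector(t(outer(comp, stains, paste, sep = "-"))))
  any_measured <- FALSE
  for (cp in comp) {
    sp <- stain_pct[[cp]]
    if (!is.null(sp)) {
      for (st in c("Tri", "RedTri", "PAS", "Col")) {
        if (!is.null(sp[[st]])) {
          row[[paste(cp, st, sep = "-")]] <- sp[[st]]
          any_measured <- any_measured || !is.na(sp[[st]])
        }
      }
      if (!is.null(sp$CK)) {
        row[[paste0(cp, "-CKAvg")]] <- average_cytokeratin(sp$CK)
        any_measured <- TRUE
      }
      row[[paste0(cp, "-T-P")]] <-
        tp_fibrosis(row[[paste0(cp, "-Tri")]], row[[paste0(cp, "-PAS")]])
    }
    vs <- vessel_stats[[cp]]
    if (!is.null(vs)) {
      stopifnot(inherits(vs, "microvessel_result"))
      row[[paste0(cp, "-MVD")]] <- vs$mvd
      row[[paste0(cp, "-MVA")]] <- vs$mva
      any_measured <- TRUE
    }
  }
  if (!any_measured)
    stop("no stain or vessel measurement supplied for case ", case_id)
  out <- data.frame(case_id = as.character(case_id), check.names = FALSE,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(row, check.names = FALSE, optional = TRUE))
  out[["Out-Stri"]] <- os_width_mm
  out[["Inn-Stri"]] <- is_width_mm
  vis_cols <- as.vector(outer(c("All", "Ctx", "Med"),
                              c("Tri", "PAS-TA", "Tri-Epithel"),
                              function(a, b) paste0("Vis-", a, "-", b)))
  for (vc in vis_cols)
    out[[vc]] <- if (!is.null(visual) && vc %in% names(visual))
      unname(visual[[vc]]) else NA_real_
  out[["Creatinine"]] <- creatinine
  out
}

#' Bind per-case rows into a cohort table
#'
#' @param rows list of one-row data frames from [assemble_slide_metrics()].
#' @return Cohort `data.frame`; duplicate `case_id`s are an error.
#' @export
bind_cohort <- function(rows) {
  tab <- do.call(rbind, rows)
  dup <- tab$case_id[duplicated(tab$case_id)]
  if (length(dup))
    stop("duplicate case_id in cohort: ", paste(unique(dup), collapse = ", "))
  rownames(tab) <- NULL
  tab
}
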