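#' Compartment label codes
#'
#' Integer codes of a compartment label raster: 0 = background (no tissue),
#' 1 = cortex, 2 = medullary outer stripe, 3 = medullary inner stripe,
#' 4 = other medulla, 5 = excluded (e.g. manually excluded glomeruli).
#' "Medulla" is always the union of outer stripe, inner stripe and other
#' medulla.
#'
#' @format Named integer vector.
#' @export
COMPARTMENT_CODES <- c(background = 0L, cortex = 1L, outer_stripe = 2L,
                       inner_stripe = 3L, other_medulla = 4L, excluded = 5L)

MEDULLA_CODES <- c(2L, 3L, 4L)
TISSUE_CODES <- c(1L, 2L, 3L, 4L)  # analysable tissue: not background/excluded

#' Construct a compartment mask
#'
#' A pixel-aligned label map assigning every pixel of a region export to one
#' anatomic compartment (or background / excluded), together with the scan
#' resolution.
#'
#' @param labels integer matrix with values from [COMPARTMENT_CODES].
#' @param microns_per_pixel scan resolution, micrometres per pixel (> 0).
#' @return An object of class `compartment_mask`.
#' @export
compartment_mask <- function(labels, microns_per_pixel) {
  if (!is.matrix(labels)) stop("'labels' must be a matrix")
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  bad <- setdiff(unique(as.vector(labels)), unname(COMPARTMENT_CODES))
  if (length(bad))
    stop("unknown compartment label code(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0)
    stop("'microns_per_pixel' must be > 0")
  structure(list(labels = labels, microns_per_pixel = microns_per_pixel),
            class = "compartment_mask")
}

#' @export
print.compartment_mask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = COMPARTMENT_CODES,
                      labels = names(COMPARTMENT_CODES)))
  cat(sprintf("compartment_mask %dx%d @ %g um/px\n",
              nrow(x$labels), ncol(x$labels), x$microns_per_pixel))
  print(tab)
  invisible(x)
}

#' Logical selector for a compartment group
#'
#' Resolves the compartment selectors used throughout the package: a code
#' name from [COMPARTMENT_CODES], or the groups `"medulla"` (outer stripe +
#' inner stripe + other medulla) and `"all"` (all analysable tissue, i.e.
#' cortex + medulla, excluded regions omitted).
#'
#' @param mask a `compartment_mask`.
#' @param compartment selector string.
#' @return Logical matrix.
#' @export
compartment_selector <- function(mask, compartment = "all") {
  stopifnot(inherits(mask, "compartment_mask"))
  compartment <- tolower(compartment)
  lab <- mask$labels
  switch(compartment,
         all = matrix(lab %in% TISSUE_CODES, nrow(lab)),
         medulla = matrix(lab %in% MEDULLA_CODES, nrow(lab)),
         {
           if (!compartment %in% names(COMPARTMENT_CODES))
             stop("unknown compartment selector: ", compartment)
           lab == COMPARTMENT_CODES[[compartment]]
         })
}

#' Load compartment annotations from a label PNG or polygon JSON
#'
#' Label PNGs are 8-bit greyscale images whose pixel values are the
#' [COMPARTMENT_CODES] integers.  Polygon files are JSON of the form
#' `{"width": W, "height": H, "polygons": [{"compartment": "cortex",
#' "coordinates": [[x, y], ...]}, ...]}` with vertices in pixel coordinates
#' (x right, y down, origin at the image corner); polygons are rasterized by
#' an even-odd test on pixel centres, without anti-aliasing, so an axis-
#' aligned `100 x 100` px square yields exactly 10,000 labelled pixels.
#' Overlapping polygons of different compartments are an error.
#'
#' @param path file path (`.png`, or `.json`/`.geojson`).
#' @param microns_per_pixel scan resolution (um/px).
#' @return A [compartment_mask()].
#' @export
load_compartments <- function(path, microns_per_pixel) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path)
    if (length(dim(raw)) == 3L) raw <- raw[, , 1]
    labels <- matrix(as.integer(round(raw * 255)), nrow(raw))
    return(compartment_mask(labels, microns_per_pixel))
  }
  if (ext %in% c("json", "geojson")) {
    ann <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
    polys <- ann$polygons
    if (is.data.frame(polys))
      polys <- lapply(seq_len(nrow(polys)), function(i)
        list(compartment = polys$compartment[[i]],
             coordinates = polys$coordinates[[i]]))
    labels <- rasterize_polygons(polys, height = ann$height, width = ann$width)
    return(compartment_mask(labels, microns_per_pixel))
  }
  stop("unsupported annotation format: .", ext)
}

#' Rasterize named compartment polygons to a label matrix
#'
#' @param polygons list of `list(compartment =, coordinates =)` where
#'   `coordinates` is an n x 2 matrix of (x, y) vertices in pixel coordinates.
#' @param height,width raster dimensions in pixels.
#' @return Integer label matrix.
#' @export
rasterize_polygons <- function(polygons, height, width) {
  labels <- matrix(COMPARTMENT_CODES[["background"]], height, width)
  owner <- matrix(NA_character_, height, width)
  px <- matrix(rep(seq_len(width) - 0.5, each = height), height)
  py <- matrix(rep(seq_len(height) - 0.5, times = width), height)
  for (p in polygons) {
    nm <- tolower(p$compartment)
    if (!nm %in% names(COMPARTMENT_CODES) || nm == "background")
      stop("unknown compartment name in polygon file: ", nm)
    xy <- p$coordinates
    if (is.list(xy)) xy <- do.call(rbind, lapply(xy, unlist))
    xy <- as.matrix(xy)
    inside <- point_in_polygon(px, py, xy)
    clash <- inside & !is.na(owner) & owner != nm
    if (any(clash))
      stop(sprintf("overlapping polygons of different compartments: '%s' vs '%s' (%d px)",
                   nm, owner[which(clash)[1]], sum(clash)))
    labels[inside] <- COMPARTMENT_CODES[[nm]]
    owner[inside] <- nm
  }
  labels
}

# even-odd crossing test at points (px, py); vertices closed implicitly
point_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- matrix(FALSE, nrow(px), ncol(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- xy[j, 1]; y1 <- xy[j, 2]; x2 <- xy[i, 1]; y2 <- xy[i, 2]
    if (y1 != y2) {
      cross <- ((y1 > py) != (y2 > py)) &
        (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

#' Tissue fractions per compartment
#'
#' Percentages of analysable tissue (background and excluded regions omitted
#' from the denominator) in each compartment, plus the cortex / medulla
#' grouping; with only cortex and medulla present the two add to 100.
#'
#' @param mask a `compartment_mask`.
#' @return Named numeric vector of percentages: `cortex`, `outer_stripe`,
#'   `inner_stripe`, `other_medulla`, `medulla`.  All `NA` (with a warning)
#'   when the mask holds no tissue.
#' @export
compartment_fractions <- function(mask) {
  stopifnot(inherits(mask, "compartment_mask"))
  lab <- mask$labels
  tissue <- sum(lab %in% TISSUE_CODES)
  nm <- c("cortex", "outer_stripe", "inner_stripe", "other_medulla", "medulla")
  if (tissue == 0) {
    warning("compartment mask holds no tissue; fractions undefined")
    return(stats::setNames(rep(NA_real_, 5), nm))
  }
  f <- function(codes) 100 * sum(lab %in% codes) / tissue
  stats::setNames(c(f(1L), f(2L), f(3L), f(4L), f(MEDULLA_CODES)), nm)
}

#' Measure stripe width between two annotated boundaries
#'
#' The digital-ruler measurement of medullary stripe width: polyline `a` is
#' resampled at regular arc-length intervals, a perpendicular is cast at each
#' sample (both directions), and the distance to its nearest intersection
#' with polyline `b` is recorded.  The reported width is the median of those
#' perpendicular distances, converted to millimetres; the per-sample
#' distances are returned so the spread of the stripe can be inspected.
#'
#' @param a,b boundary polylines: n x 2 matrices of (x, y) vertices in pixel
#'   coordinates.  They must not cross each other, and must be roughly
#'   parallel (a perpendicular from `a` must meet `b` for at least half the
#'   samples).
#' @param microns_per_pixel scan resolution (um/px).
#' @param sample_interval_px arc-length spacing of the perpendicular samples.
#' @return List of class `stripe_width`: `width_mm` (median), `distances_px`,
#'   `distances_mm`, `n_samples`, `n_missed`.
#' @export
stripe_width <- function(a, b, microns_per_pixel, sample_interval_px = 20) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) < 2 || nrow(b) < 2) stop("polylines need at least 2 vertices")
  if (microns_per_pixel <= 0) stop("'microns_per_pixel' must be > 0")
  if (polylines_cross(a, b))
    stop("boundary polylines intersect each other; not a stripe")
  s <- resample_polyline(a, sample_interval_px)
  d <- numeric(nrow(s$points))
  for (k in seq_len(nrow(s$points))) {
    t <- s$tangents[k, ]
    nrm <- c(-t[2], t[1])
    d[k] <- ray_polyline_distance(s$points[k, ], nrm, b)
  }
  miss <- is.na(d)
  if (mean(miss) > 0.5)
    stop("perpendiculars from 'a' miss 'b' for more than half the samples; ",
         "boundaries are not parallel enough to define a width")
  dp <- d[!miss]
  structure(list(width_mm = stats::median(dp) * microns_per_pixel / 1000,
                 distances_px = dp,
                 distances_mm = dp * microns_per_pixel / 1000,
                 n_samples = length(d), n_missed = sum(miss)),
            class = "stripe_width")
}

#' @export
print.stripe_width <- function(x, ...) {
  cat(sprintf("stripe width: %.3f mm (median of %d perpendicular samples, %d missed)\n",
              x$width_mm, x$n_samples - x$n_missed, x$n_missed))
  cat(sprintf("  sample range: %.3f - %.3f mm\n",
              min(x$distances_mm), max(x$distances_mm)))
  invisible(x)
}

# resample polyline at regular arc length; the tangent at each sample is the
# direction of the original segment containing it (coarser estimates, e.g.
# differences of the resampled points, visibly tilt the perpendiculars on
# curved annotations)
resample_polyline <- function(xy, interval) {
  seg <- diff(xy)
  len <- sqrt(rowSums(seg^2))
  keep <- len > 0
  seg <- seg[keep, , drop = FALSE]
  len <- len[keep]
  cs <- c(0, cumsum(len))
  total <- cs[length(cs)]
  ts <- seq(0, total, by = interval)
  if (length(ts) < 2) ts <- c(0, total)
  pts <- cbind(stats::approx(cs, xy[c(TRUE, keep), 1], xout = ts)$y,
               stats::approx(cs, xy[c(TRUE, keep), 2], xout = ts)$y)
  si <- pmin(pmax(findInterval(ts, cs, rightmost.closed = TRUE), 1), nrow(seg))
  tg <- seg[si, , drop = FALSE] / len[si]
  list(points = pts, tangents = tg)
}

# smallest |t| with p + t*dir meeting polyline xy; NA if no intersection
ray_polyline_distance <- function(p, dir, xy) {
  q1 <- xy[-nrow(xy), , drop = FALSE]
  e <- diff(xy)
  w <- sweep(q1, 2, p)
  denom <- dir[1] * e[, 2] - dir[2] * e[, 1]
  ok <- abs(denom) > .Machine$double.eps
  t <- (w[, 1] * e[, 2] - w[, 2] * e[, 1]) / denom
  u <- (w[, 1] * dir[2] - w[, 2] * dir[1]) / denom
  hit <- ok & u >= 0 & u <= 1
  if (!any(hit)) return(NA_real_)
  min(abs(t[hit]))
}

# do two polylines share any point?
polylines_cross <- function(a, b) {
  for (i in seq_len(nrow(a) - 1)) {
    for (j in seq_len(nrow(b) - 1)) {
      if (segments_intersect(a[i, ], a[i + 1, ], b[j, ], b[j + 1, ]))
        return(TRUE)
    }
  }
  FALSE
}

segments_intersect <- function(p1, p2, q1, q2) {
  o <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  (o1 != o2 && o3 != o4) ||
    (o1 == 0 && on_segment(p1, p2, q1)) || (o2 == 0 && on_segment(p1, p2, q2)) ||
    (o3 == 0 && on_segment(q1, q2, p1)) || (o4 == 0 && on_segment(q1, q2, p2))
}

on_segment <- function(a, b, c) {
  min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
    min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
}
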