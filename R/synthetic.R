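#' Stain-class palette of the synthetic tissue renderer
#'
#' One exact 8-bit RGB triplet per stain class, derived by inverting the
#' hexcone hue formula so each triplet's computed hue lands exactly on the
#' corresponding shipped profile centre: aniline blue at hue 0.60, Biebrich
#' scarlet red at 0.96, PAS magenta at 0.86, DAB brown at 0.10.  Neutral
#' tissue is an achromatic grey (saturation 0, so it is hue-negative for
#' every profile) and glass is pure white (intensity 255, above every tissue
#' cutoff).
#'
#' @return Named list of RGB triplets (`blue`, `red`, `pink`, `dab`,
#'   `neutral`, `glass`).
#' @export
stain_palette <- function() {
  list(blue    = c(40, 104, 200),   # hue (4 - 64/160)/6 = 0.60
       red     = c(220, 70, 106),   # hue ((70-106)/150 mod 6)/6 = 0.96
       pink    = c(210, 60, 186),   # hue ((60-186)/150 mod 6)/6 = 0.86
       dab     = c(150, 102, 30),   # hue ((102-30)/120)/6 = 0.10
       neutral = c(200, 200, 200),
       glass   = c(255, 255, 255))
}

SYN_CLASS_CODES <- c(glass = 0L, neutral = 1L, blue = 2L, red = 3L,
                     pink = 4L, dab = 5L)

#' Specification of a synthetic stained-tissue image
#'
#' Describes a rectangular region export with a cortical band on top and the
#' medullary outer and inner stripes below it (a glass margin all around),
#' populated with tubule profiles (pink basement-membrane rings around red
#' epithelium), DAB-ringed microvessels with open lumens, excluded glomerular
#' discs in the cortex, and scattered stain-class pixels topping each
#' compartment up to an exact target fraction per class.  Nothing is
#' anti-aliased, so every class count in the rendered ground truth is exact.
#'
#' @param width_px interior tissue width.
#' @param cortex_px,os_px,is_px band heights of cortex, outer stripe, inner
#'   stripe.  The defaults give a 45.4% / 54.6% cortex/medulla split, the
#'   cohort-mean tissue composition of native renal biopsies with medulla.
#' @param margin_px glass border width.
#' @param microns_per_pixel scan resolution (um/px).
#' @param fractions named list per compartment (`cortex`, `outer_stripe`,
#'   `inner_stripe`), each a named vector of target tissue fractions for the
#'   painted classes `blue`, `red`, `pink`, `dab` (each compartment's sum
#'   must stay below 1 to leave room for neutral tissue).
#' @param n_tubules tubule profiles scattered over the tissue.
#' @param tubule_radius_px centreline radius range of tubule rings.
#' @param tubule_wall_px tubule basement-membrane ring thickness.
#' @param n_vessels microvessel count.
#' @param vessel_radius_px centreline radius range of vessel rings (pixels).
#' @param vessel_wall_px vessel wall thickness (pixels; even widths make the
#'   distance-transform wall estimate exact).
#' @param n_glomeruli excluded glomerular discs (cortex only).
#' @param glomerulus_radius_px radius range of glomerular discs.
#' @param hue_jitter_sd optional hue noise (SD in hue fraction) applied to
#'   stained pixels; 0 preserves the exact-count contract.
#' @param seed RNG seed; rendering is bit-reproducible given the seed.
#' @return Object of class `tissue_spec`.
#' @export
tissue_spec <- function(width_px = 260, cortex_px = 127, os_px = 56,
                        is_px = 97, margin_px = 8, microns_per_pixel = 1,
                        fractions = list(
                          cortex       = c(blue = 0.20, red = 0.35, pink = 0.16, dab = 0.05),
                          outer_stripe = c(blue = 0.25, red = 0.30, pink = 0.16, dab = 0.05),
                          inner_stripe = c(blue = 0.30, red = 0.25, pink = 0.16, dab = 0.05)),
                        n_tubules = 12, tubule_radius_px = c(4, 6),
                        tubule_wall_px = 2,
                        n_vessels = 8, vessel_radius_px = c(6, 9),
                        vessel_wall_px = 4,
                        n_glomeruli = 3, glomerulus_radius_px = c(8, 11),
                        hue_jitter_sd = 0, seed = 1) {
  spec <- list(width_px = width_px, cortex_px = cortex_px, os_px = os_px,
               is_px = is_px, margin_px = margin_px,
               microns_per_pixel = microns_per_pixel, fractions = fractions,
               n_tubules = n_tubules, tubule_radius_px = tubule_radius_px,
               tubule_wall_px = tubule_wall_px, n_vessels = n_vessels,
               vessel_radius_px = vessel_radius_px,
               vessel_wall_px = vessel_wall_px, n_glomeruli = n_glomeruli,
               glomerulus_radius_px = glomerulus_radius_px,
               hue_jitter_sd = hue_jitter_sd, seed = seed)
  for (cp in names(spec$fractions)) {
    f <- spec$fractions[[cp]]
    if (any(f < 0) || sum(f) >= 1)
      stop(sprintf("fractions for '%s' must be non-negative and sum below 1", cp))
  }
  stopifnot(width_px > 40, cortex_px > 20, os_px > 10, is_px > 20,
            margin_px >= 1, microns_per_pixel > 0)
  structure(spec, class = "tissue_spec")
}

#' Render a synthetic stained-tissue image with exact ground truth
#'
#' Deterministically (given `spec$seed`) renders the image described by a
#' [tissue_spec()]: the RGB raster, its [compartment_mask()], the stain-class
#' label raster, and a ground-truth object holding exact per-compartment
#' class counts, the expected positive-pixel-count result for every shipped
#' stain profile (obtained by classifying the palette colours with the same
#' rule the classifier applies per pixel), the rendered vessel records, true
#' compartment fractions and true stripe widths.
#'
#' Structured objects (tubules, vessels, glomeruli) are placed first by
#' rejection sampling with a separation margin so vessels never touch; each
#' compartment is then topped up with scattered single pixels of each stain
#' class to hit `round(fraction * tissue_px)` exactly.  If the structured
#' objects already overshoot a target, or do not fit, rendering stops with an
#' infeasibility error.
#'
#' @param spec a [tissue_spec()].
#' @return Object of class `synthetic_tissue`: list with `image` (the
#'   all-class panel raster), `cd34_image` (a CD34-style view where only the
#'   vessel rings are stained, as on a real single-stain slide), `mask`
#'   ([compartment_mask()]), `class_raster` (codes: 0 glass, 1 neutral,
#'   2 blue, 3 red, 4 pink, 5 dab), `ground_truth`, `spec`.
#' @export
render_tissue <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  set.seed(spec$seed)
  m <- spec$margin_px
  W <- spec$width_px + 2 * m
  H <- spec$cortex_px + spec$os_px + spec$is_px + 2 * m
  comp <- matrix(COMPARTMENT_CODES[["background"]], H, W)
  rows_ctx <- (m + 1):(m + spec$cortex_px)
  rows_os <- (m + spec$cortex_px + 1):(m + spec$cortex_px + spec$os_px)
  rows_is <- (m + spec$cortex_px + spec$os_px + 1):(H - m)
  cols_tis <- (m + 1):(W - m)
  comp[rows_ctx, cols_tis] <- COMPARTMENT_CODES[["cortex"]]
  comp[rows_os, cols_tis] <- COMPARTMENT_CODES[["outer_stripe"]]
  comp[rows_is, cols_tis] <- COMPARTMENT_CODES[["inner_stripe"]]

  cls <- matrix(SYN_CLASS_CODES[["glass"]], H, W)
  cls[comp != COMPARTMENT_CODES[["background"]]] <- SYN_CLASS_CODES[["neutral"]]

  cc <- col(cls); rr <- row(cls)
  occupied <- matrix(FALSE, H, W)  # structured-object halo, for separation

  place_disc <- function(rows, radius, halo) {
    # sample a centre whose disc + halo fits in `rows` band, off occupied area
    for (try in 1:300) {
      cy <- sample(rows[rows > min(rows) + radius + halo - 1 &
                          rows < max(rows) - radius - halo + 1], 1)
      cx <- sample((m + 1 + radius + halo):(W - m - radius - halo), 1)
      d2 <- (rr - cy)^2 + (cc - cx)^2
      zone <- d2 <= (radius + halo)^2
      if (!any(occupied & zone)) {
        occupied <<- occupied | zone
        return(list(cx = cx, cy = cy, d2 = d2))
      }
    }
    stop("could not place a structured object; geometry infeasible for spec")
  }

  band_rows <- list(cortex = rows_ctx, outer_stripe = rows_os,
                    inner_stripe = rows_is)

  # deterministic largest-remainder allocation of object counts to bands,
  # proportional to band area, so small bands are not overloaded by chance
  allocate <- function(n_total) {
    w <- vapply(band_rows, length, numeric(1))
    w <- w / sum(w)
    base <- floor(n_total * w)
    rem <- n_total - sum(base)
    if (rem > 0) {
      extra <- order(n_total * w - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    stats::setNames(base, names(band_rows))
  }

  # glomeruli: excluded discs in cortex
  gtab <- list()
  for (i in seq_len(spec$n_glomeruli)) {
    r <- round(stats::runif(1, spec$glomerulus_radius_px[1],
                            spec$glomerulus_radius_px[2]))
    p <- place_disc(rows_ctx, r, halo = 3)
    comp[p$d2 <= r^2] <- COMPARTMENT_CODES[["excluded"]]
    gtab[[i]] <- data.frame(cx = p$cx - 0.5, cy = p$cy - 0.5, r_px = r)
  }
  glomeruli <- if (length(gtab)) do.call(rbind, gtab) else
    data.frame(cx = numeric(), cy = numeric(), r_px = numeric())

  # vessels: DAB annuli with open (glass) lumens, non-touching
  ring_mask <- lumen_mask <- matrix(FALSE, H, W)
  halo_v <- 5  # > closing radius so closing cannot merge vessels
  v_alloc <- allocate(spec$n_vessels)
  v_comp <- rep(names(v_alloc), v_alloc)
  vtab <- list()
  for (i in seq_len(spec$n_vessels)) {
    cp <- v_comp[i]
    r <- round(stats::runif(1, spec$vessel_radius_px[1], spec$vessel_radius_px[2]))
    w <- spec$vessel_wall_px
    p <- place_disc(band_rows[[cp]], r + ceiling(w / 2), halo = halo_v)
    d <- sqrt(p$d2)
    ring <- abs(d - r) <= w / 2
    lumen <- d < r - w / 2
    cls[ring] <- SYN_CLASS_CODES[["dab"]]
    cls[lumen] <- SYN_CLASS_CODES[["glass"]]
    ring_mask <- ring_mask | ring
    lumen_mask <- lumen_mask | lumen
    vtab[[i]] <- data.frame(compartment = cp, cx = p$cx - 0.5, cy = p$cy - 0.5,
                            r_px = r, wall_px = w,
                            filled_px = sum(d <= r + w / 2),
                            ring_px = sum(ring), stringsAsFactors = FALSE)
  }
  vessels <- if (length(vtab)) do.call(rbind, vtab) else
    data.frame(compartment = character(), cx = numeric(), cy = numeric(),
               r_px = numeric(), wall_px = numeric(), filled_px = integer(),
               ring_px = integer())

  # tubules: pink basement-membrane ring around red epithelium
  t_alloc <- allocate(spec$n_tubules)
  t_comp <- rep(names(t_alloc), t_alloc)
  for (i in seq_len(spec$n_tubules)) {
    cp <- t_comp[i]
    r <- round(stats::runif(1, spec$tubule_radius_px[1], spec$tubule_radius_px[2]))
    w <- spec$tubule_wall_px
    p <- place_disc(band_rows[[cp]], r + ceiling(w / 2), halo = 2)
    d <- sqrt(p$d2)
    cls[abs(d - r) <= w / 2] <- SYN_CLASS_CODES[["pink"]]
    cls[d < r - w / 2] <- SYN_CLASS_CODES[["red"]]
  }

  # top up each compartment to exact class targets with scattered pixels
  for (cp in names(spec$fractions)) {
    in_cp <- comp == COMPARTMENT_CODES[[cp]]
    tissue_px <- sum(in_cp & cls != SYN_CLASS_CODES[["glass"]])
    for (klass in names(spec$fractions[[cp]])) {
      target <- round(spec$fractions[[cp]][[klass]] * tissue_px)
      painted <- sum(in_cp & cls == SYN_CLASS_CODES[[klass]])
      need <- target - painted
      if (need < 0)
        stop(sprintf(
          "structured objects overshoot the '%s' target in '%s' (%d > %d); fractions infeasible",
          klass, cp, painted, target))
      pool <- which(in_cp & cls == SYN_CLASS_CODES[["neutral"]])
      if (need > length(pool))
        stop(sprintf("not enough free tissue in '%s' for class '%s'; fractions infeasible",
                     cp, klass))
      if (need > 0)
        cls[sample(pool, need)] <- SYN_CLASS_CODES[[klass]]
    }
  }

  paint <- function(klasses) {
    pal <- stain_palette()
    img <- array(0, c(H, W, 3))
    for (klass in names(SYN_CLASS_CODES)) {
      sel <- klasses == SYN_CLASS_CODES[[klass]]
      for (k in 1:3) {
        ch <- img[, , k]; ch[sel] <- pal[[klass]][k]; img[, , k] <- ch
      }
    }
    img
  }
  img <- paint(cls)
  if (spec$hue_jitter_sd > 0)
    img <- jitter_hue(img, cls, spec$hue_jitter_sd)

  # CD34-style view: only the vessel chromogen is stained (real slides carry
  # one stain each; the panel raster packs all classes for PPC ground truth)
  cls_cd34 <- matrix(SYN_CLASS_CODES[["glass"]], H, W)
  cls_cd34[comp != COMPARTMENT_CODES[["background"]]] <- SYN_CLASS_CODES[["neutral"]]
  cls_cd34[ring_mask] <- SYN_CLASS_CODES[["dab"]]
  cls_cd34[lumen_mask] <- SYN_CLASS_CODES[["glass"]]
  cd34_image <- paint(cls_cd34)

  mask <- compartment_mask(comp, spec$microns_per_pixel)
  gt <- tissue_ground_truth(cls, mask, vessels, spec)
  gt$glomeruli <- glomeruli
  structure(list(image = img, cd34_image = cd34_image, mask = mask,
                 class_raster = cls, ground_truth = gt, spec = spec),
            class = "synthetic_tissue")
}

# rotate hue of chromatic pixels by N(0, sd), preserving s and v
jitter_hue <- function(img, cls, sd) {
  stained <- cls %in% SYN_CLASS_CODES[c("blue", "red", "pink", "dab")]
  idx <- which(stained)
  if (!length(idx)) return(img)
  n <- nrow(cls)
  flat <- rbind(img[, , 1][idx], img[, , 2][idx], img[, , 3][idx])
  hsv <- grDevices::rgb2hsv(flat, maxColorValue = 255)
  hsv[1, ] <- (hsv[1, ] + stats::rnorm(ncol(hsv), 0, sd)) %% 1
  rgb <- grDevices::col2rgb(grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ]))
  for (k in 1:3) { ch <- img[, , k]; ch[idx] <- rgb[k, ]; img[, , k] <- ch }
  img
}

# exact recount of the emitted rasters + expected classifier output per profile
tissue_ground_truth <- function(cls, mask, vessels, spec) {
  comp <- mask$labels
  pal <- stain_palette()
  profiles <- default_stain_profiles()
  comps <- c("cortex", "outer_stripe", "inner_stripe", "medulla", "all")

  class_counts <- lapply(comps, function(cp) {
    sel <- compartment_selector(mask, cp)
    vapply(names(SYN_CLASS_CODES),
           function(k) sum(cls[sel] == SYN_CLASS_CODES[[k]]), integer(1))
  })
  names(class_counts) <- comps

  # classify each palette colour once per profile; counts follow by summing
  palette_class <- lapply(profiles, function(pr) {
    vapply(names(SYN_CLASS_CODES), function(k) {
      px <- array(pal[[k]], c(1, 1, 3))
      pc <- classify_pixels(px, pr)
      names(PIXEL_CLASS_CODES)[match(pc$labels[1, 1], PIXEL_CLASS_CODES)]
    }, character(1))
  })

  expected <- lapply(comps, function(cp) {
    cc <- class_counts[[cp]]
    out <- lapply(names(profiles), function(pn) {
      cl <- palette_class[[pn]]
      n_of <- function(bin) sum(cc[names(cl)[cl == bin]])
      pos <- n_of("weak") + n_of("medium") + n_of("strong")
      tissue <- pos + n_of("negative")
      list(n_weak = n_of("weak"), n_medium = n_of("medium"),
           n_strong = n_of("strong"), n_negative = n_of("negative"),
           n_background = n_of("background"),
           percent_positive = if (tissue > 0) 100 * pos / tissue else NA_real_)
    })
    stats::setNames(out, names(profiles))
  })
  names(expected) <- comps

  list(class_counts = class_counts,
       expected_ppc = expected,
       vessels = vessels,
       compartment_fractions = compartment_fractions(mask),
       os_width_px = spec$os_px, is_width_px = spec$is_px,
       os_width_mm = spec$os_px * spec$microns_per_pixel / 1000,
       is_width_mm = spec$is_px * spec$microns_per_pixel / 1000)
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf("synthetic_tissue %dx%d px (seed %d): %d vessels, %d glomeruli\n",
              nrow(x$class_raster), ncol(x$class_raster), x$spec$seed,
              nrow(x$ground_truth$vessels), x$spec$n_glomeruli))
  invisible(x)
}

#' Boundary polylines of the rendered compartment bands
#'
#' Returns the horizontal boundary polylines (cortex/outer-stripe,
#' outer/inner-stripe, inner-stripe/margin) of a rendered tissue, in pixel
#' coordinates, for use with [stripe_width()].
#'
#' @param tissue a `synthetic_tissue`.
#' @return Named list of 2 x 2 polyline matrices: `ctx_os`, `os_is`,
#'   `is_end`.
#' @export
band_boundaries <- function(tissue) {
  sp <- tissue$spec
  m <- sp$margin_px
  W <- sp$width_px + 2 * m
  hline <- function(y) cbind(x = c(m, W - m), y = c(y, y))
  list(ctx_os = hline(m + sp$cortex_px),
       os_is = hline(m + sp$cortex_px + sp$os_px),
       is_end = hline(m + sp$cortex_px + sp$os_px + sp$is_px))
}
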