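## Synthetic colon-wall slide generator.
##
## Anatomy is rendered as horizontal bands (surface epithelium at the top,
## then mucosa/lamina propria, submucosa, muscularis propria, serosa, and
## unused background below) so the layer ground truth is exact.  All
## structures are painted in stain-concentration space and converted to RGB
## through the fixed H&E model in stains.R; Gaussian texture noise is added
## to the concentration maps at the end.

## Per-layer base stain concentrations (hematoxylin, eosin), in OD units.
## These are also the reference signatures used by segment_layers().
LAYER_PALETTE <- rbind(
  background = c(0.00, 0.00),
  epithelium = c(0.90, 0.35),
  mucosa     = c(0.55, 0.45),
  submucosa  = c(0.15, 0.35),
  muscularis = c(0.25, 0.75),
  serosa     = c(0.30, 0.50)
)
colnames(LAYER_PALETTE) <- c("H", "E")

## Object morphology at the reference magnification where a mature ganglion
## soma spans ~100 px (all radii in px; scaled by pixel size).
GANGLION_GEOM <- list(
  mature   = list(soma_r = 48, nucleus_r = 20, nucleolus_r = 5, poly_r = 52,
                  soma = c(0.35, 0.85), nucleus = c(0.05, 0.08),
                  nucleolus = c(1.60, 0.10), margin = 56),
  immature = list(soma_r = 16, nucleus_r = 8, poly_r = 20,
                  soma = c(0.80, 0.60), nucleus = c(1.10, 0.40), margin = 22),
  mimic    = list(r = 7, poly_r = 10, conc = c(1.40, 0.10))
)

#' Specification of one synthetic slide
#'
#' Parameters of the synthetic colon-wall generator.  Defaults emulate an
#' adequate rectal/colonic specimen at a magnification where a mature
#' ganglion soma spans roughly 100 x 100 px: five anatomical bands, mature
#' ganglion cells clustered in the submucosa/muscularis near vessels and
#' Schwann-like companions, a few immature ganglion cells (smaller, darker,
#' scant intensely stained cytoplasm), and plasma-cell/lymphocyte-like
#' mimics confined to layers where ganglion cells never occur.
#'
#' @param width_px,height_px image dimensions in pixels.
#' @param pixel_size_um physical pixel size; the mature soma is modelled as
#'   25 um across, so the default 0.25 um/px gives the reference ~100 px
#'   soma.
#' @param layer_band_fractions named fractions of the image height for
#'   `epithelium`, `mucosa`, `submucosa`, `muscularis`, `serosa` (top to
#'   bottom); must be nonnegative and sum to at most 1, the remainder being
#'   background.
#' @param n_mature_ganglia,n_immature_ganglia,n_mimics object counts.
#' @param cluster_size_mean mean number of mature ganglia per cluster.
#' @param vessel_density extra vessels per megapixel beyond the one placed
#'   next to each ganglion cluster.
#' @param noise_level standard deviation of Gaussian texture noise added to
#'   the stain concentration maps (OD units).
#' @param seed integer seed; together with the other fields it fully
#'   determines the generated bundle.
#' @return an object of class `slide_spec`.
#' @export
#' @examples
#' spec <- slide_spec(n_mature_ganglia = 4, seed = 7)
#' spec$layer_band_fractions
slide_spec <- function(width_px = 768L, height_px = 768L, pixel_size_um = 0.25,
                       layer_band_fractions = c(epithelium = 0.08, mucosa = 0.22,
                                                submucosa = 0.30, muscularis = 0.30,
                                                serosa = 0.10),
                       n_mature_ganglia = 8L, n_immature_ganglia = 2L,
                       n_mimics = 6L, cluster_size_mean = 3,
                       vessel_density = 2, noise_level = 0.05, seed = 1L) {
  stopifnot(is_count(width_px), width_px > 0, is_count(height_px), height_px > 0,
            pixel_size_um > 0, is_count(n_mature_ganglia), is_count(n_immature_ganglia),
            is_count(n_mimics), cluster_size_mean > 0, vessel_density >= 0,
            noise_level >= 0, is_count(abs(seed)))
  lf <- layer_band_fractions
  need <- c("epithelium", "mucosa", "submucosa", "muscularis", "serosa")
  if (!all(need %in% names(lf))) {
    abort(paste("layer_band_fractions must name all of:", paste(need, collapse = ", ")))
  }
  lf <- lf[need]
  if (any(lf < 0) || sum(lf) > 1 + 1e-9) {
    abort("layer band fractions must be nonnegative and sum to at most 1")
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         pixel_size_um = pixel_size_um, layer_band_fractions = lf,
         n_mature_ganglia = as.integer(n_mature_ganglia),
         n_immature_ganglia = as.integer(n_immature_ganglia),
         n_mimics = as.integer(n_mimics), cluster_size_mean = cluster_size_mean,
         vessel_density = vessel_density, noise_level = noise_level,
         seed = as.integer(seed)),
    class = "slide_spec"
  )
}

#' @export
print.slide_spec <- function(x, ...) {
  cat(sprintf("<slide_spec> %d x %d px @ %.3g um/px, seed %d\n",
              x$width_px, x$height_px, x$pixel_size_um, x$seed))
  cat(sprintf("  ganglia: %d mature, %d immature; mimics: %d; noise %.3g\n",
              x$n_mature_ganglia, x$n_immature_ganglia, x$n_mimics, x$noise_level))
  invisible(x)
}

## Band geometry: 0-based half-open row ranges [y0, y1) per layer, top down.
band_rows <- function(spec) {
  lf <- spec$layer_band_fractions
  hts <- round(lf * spec$height_px)
  y1 <- cumsum(hts)
  y0 <- c(0, y1[-length(y1)])
  tibble::tibble(layer = names(lf), y0 = as.numeric(y0), y1 = as.numeric(y1),
                 height = as.numeric(hts))
}

layer_map_from_bands <- function(spec) {
  lab <- matrix(LAYER_LEGEND[["background"]], nrow = spec$height_px,
                ncol = spec$width_px)
  b <- band_rows(spec)
  for (i in seq_len(nrow(b))) {
    if (b$height[i] > 0) lab[(b$y0[i] + 1):b$y1[i], ] <- LAYER_LEGEND[[b$layer[i]]]
  }
  new_layer_map(lab)
}

## -- painting ---------------------------------------------------------------

## Overwrite an elliptical region of the concentration maps (in place via
## return).  cx, cy 0-based; theta in radians.
paint_ellipse <- function(H, E, cx, cy, a, b, theta, conc) {
  r <- max(a, b) + 1
  nr <- nrow(H); nc <- ncol(H)
  x0 <- max(0, floor(cx - r)); x1 <- min(nc - 1, ceiling(cx + r))
  y0 <- max(0, floor(cy - r)); y1 <- min(nr - 1, ceiling(cy + r))
  if (x1 < x0 || y1 < y0) return(list(H = H, E = E))
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE) - cx
  gy <- matrix(ys, nrow = length(ys), ncol = length(xs)) - cy
  u <- gx * cos(theta) + gy * sin(theta)
  v <- -gx * sin(theta) + gy * cos(theta)
  mask <- (u / a)^2 + (v / b)^2 <= 1
  rows <- ys + 1; cols <- xs + 1
  subH <- H[rows, cols, drop = FALSE]; subE <- E[rows, cols, drop = FALSE]
  subH[mask] <- conc[1]; subE[mask] <- conc[2]
  H[rows, cols] <- subH; E[rows, cols] <- subE
  list(H = H, E = E)
}

paint_disk <- function(H, E, cx, cy, r, conc) {
  paint_ellipse(H, E, cx, cy, r, r, 0, conc)
}

## -- placement --------------------------------------------------------------

## Sample a position in `band` (row of band_rows) with vertical margin,
## keeping `spacing` px from previously placed points (n x 2 matrix).
place_point <- function(band, width, margin_x, margin_y, placed, spacing,
                        center = NULL, radius = Inf, tries = 600L) {
  grow <- 0
  for (t in seq_len(tries)) {
    if (t %% 50 == 0) grow <- grow + 25
    if (is.null(center)) {
      x <- runif(1, margin_x, width - 1 - margin_x)
      y <- runif(1, band$y0 + margin_y, band$y1 - 1 - margin_y)
    } else {
      rr <- runif(1, 0, radius + grow); th <- runif(1, 0, 2 * pi)
      x <- min(max(center[1] + rr * cos(th), margin_x), width - 1 - margin_x)
      y <- min(max(center[2] + rr * sin(th), band$y0 + margin_y),
               band$y1 - 1 - margin_y)
    }
    ok <- nrow(placed) == 0 ||
      min(sqrt((placed[, 1] - x)^2 + (placed[, 2] - y)^2)) >= spacing
    if (ok) return(c(x, y))
  }
  NULL
}

#' Generate one synthetic slide with ground truth
#'
#' Renders an H&E-palette RGB image of a layered colon wall together with
#' its exact layer map and polygon annotations.  Mature ganglion cells
#' (~100 px soma, large pale nucleus, prominent dark nucleolus, abundant
#' pink cytoplasm) are grouped into clusters inside the submucosa or
#' muscularis propria, each cluster accompanied by a vessel and Schwann-like
#' elongated companions; immature ganglion cells are smaller with darker,
#' scant cytoplasm; mimics are placed only in epithelium/mucosa/serosa.
#' Output is fully determined by the spec (including its seed).
#'
#' @param spec a [slide_spec()].
#' @return an object of class `gt_bundle`: list with `image` (RGB array),
#'   `layers` ([new_layer_map()] ground truth), `annotations`
#'   ([annotation_set()]), and `spec`.
#' @export
#' @examples
#' b <- generate_slide(slide_spec(width_px = 480, height_px = 480,
#'                                n_mature_ganglia = 3, n_immature_ganglia = 1,
#'                                n_mimics = 3, seed = 11))
#' dplyr::count(b$annotations, label)
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  withr::with_seed(spec$seed, generate_slide_impl(spec))
}

generate_slide_impl <- function(spec) {
  w <- spec$width_px; h <- spec$height_px
  s <- (25 / spec$pixel_size_um) / 100   # geometry scale: 1 at 0.25 um/px
  b <- band_rows(spec)
  gm <- GANGLION_GEOM$mature; gi <- GANGLION_GEOM$immature; gk <- GANGLION_GEOM$mimic

  ## base tissue
  H <- matrix(0, h, w); E <- matrix(0, h, w)
  for (i in seq_len(nrow(b))) {
    if (b$height[i] > 0) {
      rows <- (b$y0[i] + 1):b$y1[i]
      H[rows, ] <- LAYER_PALETTE[b$layer[i], "H"]
      E[rows, ] <- LAYER_PALETTE[b$layer[i], "E"]
    }
  }

  perm <- b[b$layer %in% PERMISSIBLE_LAYERS, ]
  eligible <- function(bands, margin) bands[bands$height >= 2 * margin + 2, ]

  polys <- list(); labels <- character(0)
  add_poly <- function(p, lab) {
    polys[[length(polys) + 1]] <<- p
    labels <<- c(labels, lab)
  }

  ## cluster centers for mature ganglia
  placed <- matrix(numeric(0), ncol = 2)   # all ganglion centers
  centers <- matrix(numeric(0), ncol = 3)  # cluster x, y, band index
  m_margin <- ceiling(gm$margin * s)
  if (spec$n_mature_ganglia > 0) {
    bands_m <- eligible(perm, m_margin)
    if (nrow(bands_m) == 0) {
      abort("no permissible band is tall enough to contain a mature ganglion cell")
    }
    k <- max(1L, as.integer(round(spec$n_mature_ganglia / spec$cluster_size_mean)))
    for (j in seq_len(k)) {
      bi <- sample.int(nrow(bands_m), 1, prob = bands_m$height)
      prev <- if (nrow(centers) > 0) centers[, 1:2, drop = FALSE] else
        matrix(numeric(0), ncol = 2)
      p <- place_point(bands_m[bi, ], w, 70 * s, m_margin, prev, 230 * s) %||%
        place_point(bands_m[bi, ], w, 70 * s, m_margin, prev, 120 * s)
      if (is.null(p)) abort("could not place a ganglion cluster; bands too crowded")
      centers <- rbind(centers, c(p, bi))
    }
    for (i in seq_len(spec$n_mature_ganglia)) {
      ci <- ((i - 1) %% k) + 1
      band <- bands_m[centers[ci, 3], ]
      p <- place_point(band, w, 62 * s, m_margin, placed, 108 * s,
                       center = centers[ci, 1:2], radius = 90 * s)
      ## crowded cluster: fall back to anywhere eligible, then to a spacing
      ## that still keeps one candidate per soma after suppression
      for (spacing in c(108, 72) * s) {
        if (!is.null(p)) break
        for (bj in seq_len(nrow(bands_m))) {
          p <- place_point(bands_m[bj, ], w, 62 * s, m_margin, placed, spacing)
          if (!is.null(p)) break
        }
      }
      if (is.null(p)) abort("could not place a mature ganglion cell; bands too crowded")
      placed <- rbind(placed, p)
      add_poly(circle_polygon(p[1], p[2], gm$poly_r * s), "mature_ganglion")
    }
  }
  n_mature_placed <- nrow(placed)

  ## immature ganglia near clusters (or anywhere permissible)
  if (spec$n_immature_ganglia > 0) {
    i_margin <- ceiling(gi$margin * s)
    bands_i <- eligible(perm, i_margin)
    if (nrow(bands_i) == 0) {
      abort("no permissible band is tall enough to contain an immature ganglion cell")
    }
    for (i in seq_len(spec$n_immature_ganglia)) {
      if (nrow(centers) > 0) {
        ci <- sample.int(nrow(centers), 1)
        cband <- bands_m[centers[ci, 3], ]
        band <- if (cband$height >= 2 * i_margin + 2) cband else bands_i[1, ]
        p <- place_point(band, w, 24 * s, i_margin, placed, 62 * s,
                         center = centers[ci, 1:2], radius = 120 * s)
      } else {
        bi <- sample.int(nrow(bands_i), 1, prob = bands_i$height)
        p <- place_point(bands_i[bi, ], w, 24 * s, i_margin, placed, 62 * s)
      }
      if (is.null(p)) {
        bi <- sample.int(nrow(bands_i), 1, prob = bands_i$height)
        p <- place_point(bands_i[bi, ], w, 24 * s, i_margin, placed, 62 * s)
      }
      if (is.null(p)) abort("could not place an immature ganglion cell")
      placed <- rbind(placed, p)
      add_poly(circle_polygon(p[1], p[2], gi$poly_r * s), "immature_ganglion")
    }
  }

  ## vessels: one per cluster plus density-driven extras
  vessel_pts <- matrix(numeric(0), ncol = 2)
  vessels <- list()
  add_vessel <- function(p, band) {
    a <- runif(1, 10, 14) * s; bb <- runif(1, 18, 26) * s; th <- runif(1, 0, pi)
    vessels[[length(vessels) + 1]] <<- list(x = p[1], y = p[2], a = a, b = bb, th = th)
    vessel_pts <<- rbind(vessel_pts, p)
    add_poly(ellipse_polygon(p[1], p[2], a + 4 * s, bb + 4 * s, th), "vessel")
  }
  v_margin <- ceiling(30 * s)
  bands_v <- eligible(perm, v_margin)
  if (nrow(centers) > 0 && nrow(bands_v) > 0) {
    for (j in seq_len(nrow(centers))) {
      band <- bands_m[centers[j, 3], ]
      if (band$height < 2 * v_margin + 2) band <- bands_v[1, ]
      p <- place_point(band, w, v_margin, v_margin, placed, 75 * s,
                       center = centers[j, 1:2],
                       radius = 140 * s, tries = 120L)
      if (!is.null(p)) add_vessel(p, band)
    }
  }
  n_extra <- as.integer(round(spec$vessel_density * w * h / 1e6))
  if (n_extra > 0 && nrow(bands_v) > 0) {
    for (j in seq_len(n_extra)) {
      bi <- sample.int(nrow(bands_v), 1, prob = bands_v$height)
      p <- place_point(bands_v[bi, ], w, v_margin, v_margin,
                       rbind(placed, vessel_pts), 75 * s, tries = 120L)
      if (!is.null(p)) add_vessel(p, bands_v[bi, ])
    }
  }

  ## schwann-like companion streaks around each cluster
  schwann <- list()
  if (nrow(centers) > 0) {
    for (j in seq_len(nrow(centers))) {
      band <- bands_m[centers[j, 3], ]
      cl_pt <- centers[j, 1:2]
      for (q in 1:6) {
        p <- place_point(band, w, 10 * s, ceiling(8 * s), placed, 35 * s,
                         center = cl_pt, radius = 150 * s, tries = 80L)
        if (!is.null(p)) {
          schwann[[length(schwann) + 1]] <- list(x = p[1], y = p[2],
                                                 th = runif(1, 0, pi))
        }
      }
      add_poly(circle_polygon(cl_pt[1], cl_pt[2], 150 * s, width = w, height = h),
               "schwann_cluster")
    }
  }

  ## mimics: only epithelium / mucosa / serosa
  if (spec$n_mimics > 0) {
    bands_k <- b[b$layer %in% c("epithelium", "mucosa", "serosa") &
                   b$height >= 2 * ceiling(12 * s) + 2, ]
    if (nrow(bands_k) > 0) {
      mk_pts <- matrix(numeric(0), ncol = 2)
      for (i in seq_len(spec$n_mimics)) {
        bi <- sample.int(nrow(bands_k), 1, prob = bands_k$height)
        p <- place_point(bands_k[bi, ], w, 12 * s, ceiling(12 * s), mk_pts, 25 * s,
                         tries = 120L)
        if (!is.null(p)) {
          mk_pts <- rbind(mk_pts, p)
          add_poly(circle_polygon(p[1], p[2], gk$poly_r * s), "mimic")
        }
      }
    }
  }

  ## -- render (vessels, schwann, then cells on top) -------------------------
  for (v in vessels) {
    pe <- paint_ellipse(H, E, v$x, v$y, v$a + 4 * s, v$b + 4 * s, v$th, c(0.10, 0.95))
    pe <- paint_ellipse(pe$H, pe$E, v$x, v$y, v$a, v$b, v$th, c(0, 0))
    H <- pe$H; E <- pe$E
  }
  for (sw in schwann) {
    pe <- paint_ellipse(H, E, sw$x, sw$y, 11 * s, 1.8 * s, sw$th, c(1.00, 0.45))
    H <- pe$H; E <- pe$E
  }
  gpolys <- which(labels %in% c("mature_ganglion", "immature_ganglion"))
  gidx <- 0
  for (i in gpolys) {
    gidx <- gidx + 1
    p <- placed[gidx, ]
    if (labels[i] == "mature_ganglion") {
      pe <- paint_disk(H, E, p[1], p[2], gm$soma_r * s, gm$soma)
      pe <- paint_disk(pe$H, pe$E, p[1], p[2], gm$nucleus_r * s, gm$nucleus)
      pe <- paint_disk(pe$H, pe$E, p[1], p[2], gm$nucleolus_r * s, gm$nucleolus)
    } else {
      pe <- paint_disk(H, E, p[1], p[2], gi$soma_r * s, gi$soma)
      pe <- paint_disk(pe$H, pe$E, p[1], p[2], gi$nucleus_r * s, gi$nucleus)
    }
    H <- pe$H; E <- pe$E
  }
  for (i in which(labels == "mimic")) {
    cen <- polygon_centroid(polys[[i]])
    pe <- paint_disk(H, E, cen[1], cen[2], gk$r * s, gk$conc)
    H <- pe$H; E <- pe$E
  }

  if (spec$noise_level > 0) {
    H <- pmax(H + matrix(rnorm(w * h, 0, spec$noise_level), h, w), 0)
    E <- pmax(E + matrix(rnorm(w * h, 0, spec$noise_level), h, w), 0)
  }

  image <- rgb_from_concentrations(H, E)
  attr(image, "pixel_size_um") <- spec$pixel_size_um

  structure(
    list(image = image, layers = layer_map_from_bands(spec),
         annotations = annotation_set(labels, polys), spec = spec),
    class = "gt_bundle"
  )
}

#' @export
print.gt_bundle <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<gt_bundle> %d x %d px; %d annotations (%s)\n", d[2], d[1],
              nrow(x$annotations),
              paste(sprintf("%s: %d", names(table(x$annotations$label)),
                            table(x$annotations$label)), collapse = ", ")))
  invisible(x)
}
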