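## Internal geometry helpers.
##
## Coordinate convention (recorded in every annotation file): 0-based pixel
## coordinates, x to the right, y down.  A pixel (x, y) maps to matrix
## element [y + 1, x + 1].  Polygons are open rings (closure implied).

clamp01 <- function(x) pmin(pmax(x, 0), 1)   # x first: keeps dims

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

#' Polygon area (shoelace)
#' @param poly two-column matrix of x, y vertices (open ring).
#' @return nonnegative area in square pixels.
#' @keywords internal
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x); j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x); j <- c(n, seq_len(n - 1))
  cr <- x[j] * y - x * y[j]
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(c(mean(x), mean(y)))
  c(sum((x[j] + x) * cr) / (6 * a), sum((y[j] + y) * cr) / (6 * a))
}

## TRUE for each row of xy (n x 2) lying inside the polygon.
points_in_polygon <- function(xy, poly) {
  if (!is.matrix(xy)) xy <- matrix(xy, ncol = 2)
  ring <- rbind(poly, poly[1, , drop = FALSE])
  mgcv::in.out(ring, xy)
}

## Regular n-gon approximating a circle; clamped to the image frame and
## deduplicated so clipping at a border cannot create degenerate edges.
circle_polygon <- function(cx, cy, r, n = 20L, width = NULL, height = NULL) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  p <- cbind(x = cx + r * cos(th), y = cy + r * sin(th))
  if (!is.null(width)) p[, 1] <- pmin(pmax(p[, 1], 0), width - 1)
  if (!is.null(height)) p[, 2] <- pmin(pmax(p[, 2], 0), height - 1)
  keep <- c(TRUE, rowSums(abs(diff(p))) > 1e-9)
  p[keep, , drop = FALSE]
}

ellipse_polygon <- function(cx, cy, a, b, theta, n = 24L) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x0 <- a * cos(th); y0 <- b * sin(th)
  cbind(x = cx + x0 * cos(theta) - y0 * sin(theta),
        y = cy + x0 * sin(theta) + y0 * cos(theta))
}

## Uniform points inside a polygon by bounding-box rejection.
sample_in_polygon <- function(poly, n, max_tries = 200L) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  bb <- apply(poly, 2, range)
  out <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(out) < n && tries < max_tries) {
    m <- max(2L * (n - nrow(out)), 16L)
    cand <- cbind(runif(m, bb[1, 1], bb[2, 1]), runif(m, bb[1, 2], bb[2, 2]))
    out <- rbind(out, cand[points_in_polygon(cand, poly), , drop = FALSE])
    tries <- tries + 1L
  }
  if (nrow(out) < n) abort("could not sample enough points inside polygon")
  out[seq_len(n), , drop = FALSE]
}
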