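## Hierarchical analysis: anatomical layer segmentation and the
## permissibility veto.  Ganglion cells occur only in the submucosa and
## muscularis propria; any candidate whose centroid falls in another layer
## is eliminated outright.  This single anatomical fact removes the large
## majority of false alarms before any scoring happens.

#' Construct a layer map
#'
#' @param labels integer matrix (rows = y, cols = x) of per-pixel layer
#'   codes from the legend `background = 0, epithelium = 1, mucosa = 2,
#'   submucosa = 3, muscularis = 4, serosa = 5`.
#' @return an object of class `layer_map` with elements `labels` and
#'   `legend`.
#' @export
new_layer_map <- function(labels) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  if (!all(labels %in% LAYER_LEGEND)) abort("layer labels outside the legend")
  structure(list(labels = labels, legend = LAYER_LEGEND), class = "layer_map")
}

#' @export
print.layer_map <- function(x, ...) {
  tb <- table(factor(x$labels, levels = x$legend,
                     labels = names(x$legend)))
  cat(sprintf("<layer_map> %d x %d px\n", ncol(x$labels), nrow(x$labels)))
  print(tb)
  invisible(x)
}

#' @export
dim.layer_map <- function(x) dim(x$labels)

#' Layer name at a pixel
#'
#' @param layers a [new_layer_map()].
#' @param x,y 0-based pixel coordinates (vectorized).
#' @return character vector of layer names.
#' @export
layer_at <- function(layers, x, y) {
  lab <- layers$labels
  if (any(x < 0 | y < 0 | x > ncol(lab) - 1 | y > nrow(lab) - 1)) {
    abort("point outside image bounds")
  }
  codes <- lab[cbind(floor(y) + 1, floor(x) + 1)]
  names(layers$legend)[match(codes, layers$legend)]
}

#' Is a location permissible for a ganglion cell?
#'
#' TRUE exactly when the layer at the point is submucosa or muscularis
#' propria; every other layer of the bowel wall is normally devoid of
#' ganglion cells, so anything found there is read as negative.
#'
#' @param point numeric length-2 vector `c(x, y)` (0-based) or an `n x 2`
#'   matrix of points.
#' @inheritParams layer_at
#' @return logical vector.
#' @export
is_permissible_location <- function(point, layers) {
  if (!is.matrix(point)) point <- matrix(point, ncol = 2)
  layer_at(layers, point[, 1], point[, 2]) %in% PERMISSIBLE_LAYERS
}

#' Segment a colon-wall image into anatomical layers
#'
#' Classifies each image row by its mean hematoxylin/eosin optical density
#' against the fixed per-layer stain signatures, smooths the sequence with
#' a running median, and expands to a full-coverage per-pixel map.  Rows
#' that are essentially unstained are background; an image with no stained
#' tissue at all yields an all-background map with a warning.
#'
#' @param image RGB array in `[0, 1]`.
#' @return a [new_layer_map()] with the image's dimensions.
#' @export
segment_layers <- function(image) {
  st <- separate_stains(image)
  h <- nrow(st$hematoxylin); w <- ncol(st$hematoxylin)
  ## medians, not means: cells and vessels cover a minority of a row and
  ## must not drag it toward another layer's signature
  mh <- apply(st$hematoxylin, 1, stats::median)
  me <- apply(st$eosin, 1, stats::median)
  white_frac <- rowMeans(st$hematoxylin + st$eosin < 0.12)

  sig <- LAYER_PALETTE[setdiff(rownames(LAYER_PALETTE), "background"), , drop = FALSE]
  d2 <- outer(mh, sig[, "H"], "-")^2 + outer(me, sig[, "E"], "-")^2
  best <- rownames(sig)[apply(d2, 1, which.min)]
  lab <- LAYER_LEGEND[best]
  lab[white_frac > 0.6] <- LAYER_LEGEND[["background"]]

  if (all(lab == LAYER_LEGEND[["background"]])) {
    warn("no stained tissue detected; returning an all-background layer map")
  } else if (h >= 15) {
    lab <- as.integer(round(stats::runmed(lab, k = 15)))
    lab[!lab %in% LAYER_LEGEND] <- LAYER_LEGEND[["background"]]
  }
  new_layer_map(matrix(rep(as.integer(lab), w), nrow = h, ncol = w))
}

#' Apply the hierarchical veto to candidates
#'
#' Keeps exactly the candidates whose centroid lies in a permissible layer
#' (submucosa or muscularis propria), preserving order, and fills their
#' `layer` column.  Idempotent.
#'
#' @param candidates candidate tibble with 0-based `x`, `y` columns (as
#'   returned by [detect_candidates()]).
#' @param layers a [new_layer_map()].
#' @return the surviving rows of `candidates`, with `layer` set.
#' @export
#' @examples
#' lm <- new_layer_map(matrix(rep(c(2L, 3L), each = 50), nrow = 10))
#' cand <- tibble::tibble(x = c(2, 7), y = c(5, 5), base_score = c(.9, .8))
#' hierarchical_filter(cand, lm)   # only the submucosal candidate survives
hierarchical_filter <- function(candidates, layers) {
  stopifnot(is.data.frame(candidates), inherits(layers, "layer_map"))
  if (nrow(candidates) == 0) {
    candidates$layer <- character(0)
    return(candidates)
  }
  lay <- layer_at(layers, candidates$x, candidates$y)
  out <- candidates[lay %in% PERMISSIBLE_LAYERS, , drop = FALSE]
  out$layer <- lay[lay %in% PERMISSIBLE_LAYERS]
  out
}
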