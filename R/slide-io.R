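## File formats: 8-bit RGB TIFF for slide images, single-channel 8-bit TIFF
## plus a JSON legend sidecar for layer maps, CSV for candidate tables and
## cohort manifests.

#' Write / read a slide image as 8-bit RGB TIFF
#'
#' @param image RGB array in `[0, 1]` (height x width x 3).
#' @param path file path; the layer-map legend sidecar of
#'   [write_layer_map()] uses `<path>.legend.json`.
#' @param pixel_size_um optional pixel size recorded as an attribute on
#'   read (TIFF tags are not relied upon).
#' @return `write_slide_image()` the path invisibly; `read_slide_image()`
#'   the image array.
#' @export
write_slide_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  tiff::writeTIFF(image, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' @rdname write_slide_image
#' @export
read_slide_image <- function(path, pixel_size_um = NULL) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (!is.null(pixel_size_um)) attr(img, "pixel_size_um") <- pixel_size_um
  img
}

#' Write / read a layer map as single-channel TIFF + JSON legend
#'
#' Layer codes are stored in the 8-bit channel directly (value = code) with
#' the integer-to-name legend in a `<path>.legend.json` sidecar.
#'
#' @param layers a [new_layer_map()].
#' @inheritParams write_slide_image
#' @return `write_layer_map()` the path invisibly; `read_layer_map()` a
#'   [new_layer_map()].
#' @export
write_layer_map <- function(layers, path) {
  stopifnot(inherits(layers, "layer_map"))
  tiff::writeTIFF(layers$labels / 255, path, bits.per.sample = 8L,
                  compression = "none")
  jsonlite::write_json(as.list(layers$legend), paste0(path, ".legend.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_layer_map
#' @export
read_layer_map <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  codes <- matrix(as.integer(round(m * 255)), nrow = nrow(m))
  legend_path <- paste0(path, ".legend.json")
  if (file.exists(legend_path)) {
    legend <- unlist(jsonlite::read_json(legend_path))
    if (!identical(sort(as.integer(legend)), sort(as.integer(LAYER_LEGEND)))) {
      abort("layer legend sidecar does not match the package legend")
    }
  }
  new_layer_map(codes)
}

#' Serialize candidates to CSV
#'
#' Schema: `case_id, slide_id, x, y, box_w, box_h, base_score,
#' contextual_score, layer` (same schema before and after contextual
#' re-scoring).
#'
#' @param candidates candidate tibble.
#' @param path file path.
#' @return `write_candidates()` the path invisibly; `read_candidates()` a
#'   tibble.
#' @export
write_candidates <- function(candidates, path) {
  cols <- c("case_id", "slide_id", "x", "y", "box_w", "box_h",
            "base_score", "contextual_score", "layer")
  out <- candidates
  for (cc in setdiff(cols, names(out))) out[[cc]] <- NA
  utils::write.csv(out[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Export candidates as ASAP-style XML overlay
#'
#' Writes each candidate's patch box as a rectangular polygon so detection
#' output can be inspected in an annotation viewer.
#'
#' @inheritParams write_candidates
#' @export
write_candidate_overlay <- function(candidates, path) {
  polys <- purrr::pmap(
    list(candidates$x, candidates$y, candidates$box_w, candidates$box_h),
    function(x, y, bw, bh) {
      cbind(x = c(x - bw / 2, x + bw / 2, x + bw / 2, x - bw / 2),
            y = c(y - bh / 2, y - bh / 2, y + bh / 2, y + bh / 2))
    })
  write_annotations(annotation_set(rep("candidate", length(polys)), polys), path)
}
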