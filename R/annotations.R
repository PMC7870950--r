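## Polygon annotations and their ASAP-style XML serialization.
##
## One dialect only: <ASAP_Annotations><Annotations><Annotation
## PartOfGroup=label Type="Polygon"><Coordinates><Coordinate Order X Y/>...
## Coordinates are 0-based (x right, y down), printed at 2 decimals, rings
## open (closure implied) — stated in a comment header of every file.

ANNOTATION_CLASSES <- c("mature_ganglion", "immature_ganglion", "mimic",
                        "vessel", "schwann_cluster", "candidate")

#' Build an annotation set
#'
#' @param labels character vector of class labels, one of
#'   `mature_ganglion`, `immature_ganglion`, `mimic`, `vessel`,
#'   `schwann_cluster`, `candidate`.
#' @param polygons list of two-column `x, y` matrices (0-based pixel
#'   coordinates, open rings).  Each polygon must have at least 3 vertices,
#'   positive area and no self-intersections.
#' @return a tibble of class `annotation_set` with columns `label` and
#'   `polygon` (list column).
#' @export
#' @examples
#' sq <- cbind(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100))
#' annotation_set("mimic", list(sq))
annotation_set <- function(labels = character(0), polygons = list()) {
  stopifnot(length(labels) == length(polygons))
  if (length(labels) > 0) {
    bad <- setdiff(unique(labels), ANNOTATION_CLASSES)
    if (length(bad) > 0) {
      abort(paste("unknown annotation class(es):", paste(bad, collapse = ", ")))
    }
    for (i in seq_along(polygons)) {
      p <- polygons[[i]]
      if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3) {
        abort(sprintf("polygon %d must be a matrix with >= 3 rows and 2 columns", i))
      }
      if (polygon_area(p) <= 0) abort(sprintf("polygon %d has zero area", i))
      if (!is_simple_polygon(p)) abort(sprintf("polygon %d is self-intersecting", i))
      colnames(polygons[[i]]) <- c("x", "y")
    }
  }
  out <- tibble::tibble(label = as.character(labels), polygon = polygons)
  class(out) <- c("annotation_set", class(out))
  out
}

## Segment-intersection test between all non-adjacent edge pairs.
is_simple_polygon <- function(p) {
  n <- nrow(p)
  if (n < 4) return(TRUE)
  a <- p; b <- p[c(2:n, 1), ]
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in 1:(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    for (j in js) {
      d1 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
      d2 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
      d3 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
      d4 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
      if (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
          ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))) return(FALSE)
    }
  }
  TRUE
}

#' Write / read annotations as ASAP-style XML
#'
#' `write_annotations()` serializes an [annotation_set()] to the
#' Annotation/Coordinates XML dialect used by the ASAP slide annotation
#' tool, with coordinates printed at 2 decimals; `read_annotations()`
#' parses it back.  `read_annotations(write_annotations(a))` reproduces the
#' coordinates exactly at that precision.
#'
#' @param annotations an [annotation_set()].
#' @param path file path.
#' @return `write_annotations()` the path, invisibly; `read_annotations()`
#'   an [annotation_set()].
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  doc <- xml2::xml_new_root("ASAP_Annotations")
  xml2::xml_add_child(doc, xml2::xml_comment(
    " coordinates: 0-based pixels, x right, y down; rings open (closure implied) "))
  anns <- xml2::xml_add_child(doc, "Annotations")
  for (i in seq_len(nrow(annotations))) {
    ann <- xml2::xml_add_child(anns, "Annotation",
                               Name = sprintf("Annotation %d", i - 1),
                               Type = "Polygon",
                               PartOfGroup = annotations$label[i],
                               Color = "#F4FA58")
    coords <- xml2::xml_add_child(ann, "Coordinates")
    p <- annotations$polygon[[i]]
    for (j in seq_len(nrow(p))) {
      xml2::xml_add_child(coords, "Coordinate", Order = as.character(j - 1),
                          X = sprintf("%.2f", p[j, 1]),
                          Y = sprintf("%.2f", p[j, 2]))
    }
  }
  groups <- xml2::xml_add_child(doc, "AnnotationGroups")
  for (g in unique(annotations$label)) {
    xml2::xml_add_child(groups, "Group", Name = g, PartOfGroup = "None",
                        Color = "#F4FA58")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(paste("malformed annotation XML:",
                                                  conditionMessage(e))))
  nodes <- xml2::xml_find_all(doc, ".//Annotation")
  labels <- character(0); polys <- list()
  for (k in seq_along(nodes)) {
    node <- nodes[[k]]
    name <- xml2::xml_attr(node, "Name") %||% sprintf("Annotation %d", k - 1)
    lab <- xml2::xml_attr(node, "PartOfGroup")
    if (is.na(lab)) abort(sprintf("malformed XML: element '%s' lacks PartOfGroup", name))
    cs <- xml2::xml_find_all(node, ".//Coordinate")
    if (length(cs) < 3) {
      abort(sprintf("malformed XML: element '%s' has fewer than 3 Coordinate children", name))
    }
    x <- as.numeric(xml2::xml_attr(cs, "X"))
    y <- as.numeric(xml2::xml_attr(cs, "Y"))
    if (anyNA(x) || anyNA(y)) {
      abort(sprintf("malformed XML: element '%s' has non-numeric coordinates", name))
    }
    ord <- suppressWarnings(as.numeric(xml2::xml_attr(cs, "Order")))
    if (!anyNA(ord)) { x <- x[order(ord)]; y <- y[order(ord)] }
    labels <- c(labels, lab)
    polys[[length(polys) + 1]] <- cbind(x = x, y = y)
  }
  annotation_set(labels, polys)
}
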