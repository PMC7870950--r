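## Triage: turn the scored candidates of a case (all of its slides pooled)
## into the ranked sets of three images a pathologist reviews, and derive
## the case-level AI score from the top three sets.  Constants follow the
## validation protocol: up to 36 images per case, sets of 3, up to 12 sets,
## ordered from highest to lowest score.

#' Build ranked image sets from a case's candidates
#'
#' Takes the `top_k` candidates by contextual score (stable tie-break:
#' score descending, then y, then x — candidates from every slide of the
#' case compete in one ranking), groups consecutive ranks into sets of
#' `set_size`, and scores each set by its best member (a set is reviewed
#' for *any* ganglion cell, so its evidence is its strongest image).  A
#' partial final set is kept: discarding candidates could hide the only
#' ganglion cell of the case.
#'
#' @param candidates candidate tibble across the case's slides, with
#'   `contextual_score` (and optionally `slide_id`).
#' @param top_k,set_size,max_sets triage constants (defaults 36, 3, 12).
#' @return a tibble of class `image_sets`: `set_rank`, `set_score`,
#'   `n_patches`, `members` (nested tibble of the member candidates with an
#'   `ai_score` column).  Set scores are nonincreasing in rank.
#' @export
#' @examples
#' cand <- tibble::tibble(x = seq(0, 60, 10), y = 0,
#'                        contextual_score = c(.95, .9, .8, .7, .6, .5, .4))
#' build_image_sets(cand)[, c("set_rank", "set_score", "n_patches")]
build_image_sets <- function(candidates, top_k = 36L, set_size = 3L,
                             max_sets = 12L) {
  stopifnot(is_count(top_k), is_count(set_size), set_size > 0, is_count(max_sets))
  if (nrow(candidates) == 0) {
    out <- tibble::tibble(set_rank = integer(0), set_score = numeric(0),
                          n_patches = integer(0), members = list())
    class(out) <- c("image_sets", class(out))
    return(out)
  }
  cand <- candidates[order(-candidates$contextual_score, candidates$y, candidates$x), ]
  cand <- utils::head(cand, top_k)
  cand$ai_score <- cand$contextual_score
  set_of <- ceiling(seq_len(nrow(cand)) / set_size)
  keep <- set_of <= max_sets
  cand <- cand[keep, ]; set_of <- set_of[keep]
  out <- tibble::tibble(
    set_rank = sort(unique(set_of)),
    members = lapply(sort(unique(set_of)), function(s) cand[set_of == s, ])
  )
  out$set_score <- vapply(out$members, function(m) max(m$ai_score), numeric(1))
  out$n_patches <- vapply(out$members, nrow, integer(1))
  out <- out[, c("set_rank", "set_score", "n_patches", "members")]
  class(out) <- c("image_sets", class(out))
  out
}

#' Case-level AI score
#'
#' Mean of the three highest set scores; with fewer than three sets the
#' mean of what exists, and 0 for a case with no sets at all (nothing was
#' found, nothing to average).
#'
#' @param sets an [build_image_sets()] result, or a bare numeric vector of
#'   set scores.
#' @return a number in `[0, 1]`.
#' @export
#' @examples
#' case_ai_score(c(0.9, 0.8, 0.7, 0.2))   # 0.8
case_ai_score <- function(sets) {
  scores <- if (is.numeric(sets)) sets else sets$set_score
  if (length(scores) == 0) return(0)
  mean(sort(scores, decreasing = TRUE)[seq_len(min(3, length(scores)))])
}

#' Extract an image patch around a candidate
#'
#' The crop covers the candidate's full patch box plus a context margin,
#' clipped at the image borders (pathologists should always see a find in
#' its immediate surroundings).
#'
#' @param image RGB array.
#' @param x,y candidate centroid (0-based).
#' @param box_px patch box side; `margin_px` context margin on each side.
#' @return RGB array crop.
#' @export
extract_patch <- function(image, x, y, box_px = 100, margin_px = 50) {
  d <- dim(image)
  half <- box_px / 2 + margin_px
  x0 <- max(0, floor(x - half)); x1 <- min(d[2] - 1, ceiling(x + half))
  y0 <- max(0, floor(y - half)); y1 <- min(d[1] - 1, ceiling(y + half))
  image[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), , drop = FALSE]
}

#' Export a case's image sets as PNG patches plus a JSON manifest
#'
#' Writes one PNG per patch under `dir/<case_id>/set<k>_img<j>.png` and a
#' `sets.json` manifest (ranks, scores, member provenance, config hash if
#' given).
#'
#' @param record a [case_record()].
#' @param image_access function(slide_id) returning the RGB array of a
#'   slide, or a single RGB array for one-slide cases.
#' @param dir output directory (created).
#' @param config_hash optional provenance string stored in the manifest.
#' @return the manifest path, invisibly.
#' @export
export_image_sets <- function(record, image_access, dir, config_hash = NULL) {
  stopifnot(inherits(record, "case_record"))
  case_dir <- file.path(dir, record$case_id)
  dir.create(case_dir, recursive = TRUE, showWarnings = FALSE)
  get_image <- if (is.function(image_access)) image_access else function(id) image_access
  manifest <- list(case_id = record$case_id, avg_top3_ai = record$avg_top3_ai,
                   config_hash = config_hash, sets = list())
  sets <- record$sets
  for (i in seq_len(nrow(sets))) {
    m <- sets$members[[i]]
    files <- character(nrow(m))
    for (j in seq_len(nrow(m))) {
      sid <- if ("slide_id" %in% names(m)) m$slide_id[j] else "slide_1"
      patch <- extract_patch(get_image(sid), m$x[j], m$y[j],
                             box_px = max(m$box_w[j], m$box_h[j]))
      files[j] <- sprintf("set%02d_img%d.png", sets$set_rank[i], j)
      png::writePNG(patch, file.path(case_dir, files[j]))
    }
    manifest$sets[[i]] <- list(set_rank = sets$set_rank[i],
                               set_score = sets$set_score[i],
                               images = files,
                               x = m$x, y = m$y, ai_score = m$ai_score)
  }
  path <- file.path(case_dir, "sets.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
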