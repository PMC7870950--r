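## Cell-level detection metrics and cohort-level consultation statistics.

#' Cell-by-cell sensitivity and specificity
#'
#' A ground-truth ganglion polygon counts as detected iff at least one
#' detection centroid lies inside it (multiple detections in one polygon
#' count once, mirroring the one-circle-per-cell annotation convention).
#' Sensitivity is `100 * detected / total` ganglion polygons, or `NA` when
#' there are none (undefined, never reported as 0).  The negative unit is
#' an explicit decoy location: decoys are sampled uniformly in the given
#' ganglion-free regions (points falling inside a truth polygon are
#' rejected), and a decoy is correctly rejected iff no detection centroid
#' lies within `decoy_radius_px` of it; specificity is `100 *
#' correctly_rejected / n_decoys`.
#'
#' @param detections candidate tibble with `x`, `y` (the detections the
#'   pipeline reports).
#' @param truth an [annotation_set()]; only `mature_ganglion` /
#'   `immature_ganglion` polygons are targets.
#' @param negative_regions list of polygons (two-column matrices) known to
#'   be free of ganglion cells, e.g. rectangles of permissible tissue away
#'   from the annotated cells.
#' @param n_decoys number of decoy locations (default 10 per truth cell,
#'   minimum 50).
#' @param decoy_radius_px tolerance radius around a decoy.
#' @param seed seed for decoy sampling.
#' @param decoys optional explicit decoy locations (`n x 2` matrix of x, y);
#'   when given, sampling (and `negative_regions`) is bypassed.
#' @return a tibble with `sensitivity_pct`, `specificity_pct`,
#'   `n_truth`, `n_detected`, `n_decoys`, `n_false_alarm`.
#' @export
cell_level_metrics <- function(detections, truth, negative_regions = NULL,
                               n_decoys = NULL, decoy_radius_px = 50,
                               seed = 1L, decoys = NULL) {
  stopifnot(inherits(truth, "annotation_set"))
  gpolys <- truth$polygon[truth$label %in% c("mature_ganglion", "immature_ganglion")]
  n_truth <- length(gpolys)
  pts <- cbind(detections$x, detections$y)

  detected <- 0L
  if (n_truth > 0 && nrow(pts) > 0) {
    detected <- sum(vapply(gpolys, function(p) any(points_in_polygon(pts, p)),
                           logical(1)))
  }
  sens <- if (n_truth == 0) NA_real_ else 100 * detected / n_truth

  if (is.null(n_decoys)) {
    n_decoys <- if (!is.null(decoys)) nrow(decoys) else max(50L, 10L * n_truth)
  }
  if (is.null(decoys)) {
    if (is.null(negative_regions)) {
      abort("either negative_regions or explicit decoys must be given")
    }
    decoys <- sample_decoys(negative_regions, n_decoys, gpolys, seed)
  }
  decoys <- utils::head(decoys, n_decoys)
  n_dec <- nrow(decoys)
  false_alarm <- 0L
  if (n_dec > 0 && nrow(pts) > 0) {
    false_alarm <- sum(vapply(seq_len(n_dec), function(i) {
      any(sqrt((pts[, 1] - decoys[i, 1])^2 + (pts[, 2] - decoys[i, 2])^2)
          <= decoy_radius_px)
    }, logical(1)))
  }
  spec <- if (n_dec == 0) NA_real_ else 100 * (n_dec - false_alarm) / n_dec

  tibble::tibble(sensitivity_pct = sens, specificity_pct = spec,
                 n_truth = n_truth, n_detected = as.integer(detected),
                 n_decoys = n_dec, n_false_alarm = as.integer(false_alarm))
}

## Uniform decoy locations across the negative regions (area-proportional),
## rejecting points that fall inside a truth polygon.
sample_decoys <- function(negative_regions, n_decoys, truth_polys, seed) {
  withr::with_seed(seed, {
    areas <- vapply(negative_regions, polygon_area, numeric(1))
    per <- pmax(1L, as.integer(round(n_decoys * areas / sum(areas))))
    got <- purrr::map2(negative_regions, per, function(poly, k) {
      cand <- sample_in_polygon(poly, k * 2L)
      if (length(truth_polys) > 0) {
        inside <- rep(FALSE, nrow(cand))
        for (p in truth_polys) inside <- inside | points_in_polygon(cand, p)
        cand <- cand[!inside, , drop = FALSE]
      }
      utils::head(cand, k)
    })
    do.call(rbind, got)
  })
}

#' Fraction of tissue area presented to the pathologist
#'
#' Total patch-box area of the presented image sets divided by the total
#' stained-tissue area of the case's slides.  On clinical whole slides
#' this fraction is tiny (the triage shows well under a percent of the
#' tissue); on desk-scale synthetic slides it is reported rather than
#' asserted small, since the patch box is a fixed physical size.
#'
#' @param sets an [build_image_sets()] result.
#' @param layers list of [new_layer_map()]s (one per slide) or a single
#'   layer map.
#' @return a tibble with `patch_area_px`, `tissue_area_px`, `fraction`.
#' @export
patch_area_fraction <- function(sets, layers) {
  if (inherits(layers, "layer_map")) layers <- list(layers)
  tissue <- sum(vapply(layers, function(l) sum(l$labels != LAYER_LEGEND[["background"]]),
                       numeric(1)))
  patch <- 0
  for (m in sets$members) patch <- patch + sum(m$box_w * m$box_h)
  tibble::tibble(patch_area_px = patch, tissue_area_px = tissue,
                 fraction = patch / tissue)
}

#' Consultation rate as a printed percentage
#'
#' `100 * count / denominator`, rounded to 2 decimals — the precision the
#' cohort report prints.
#' @param count,denominator nonnegative counts.
#' @return numeric percentage.
#' @export
#' @examples
#' consultation_rate(9, 48)   # 18.75
consultation_rate <- function(count, denominator) {
  stopifnot(denominator > 0)
  round(100 * count / denominator, 2)
}

#' Cohort consultation statistics
#'
#' From per-case, per-observer consultation flags computes per-observer
#' counts and rates, and the cross-observer distribution: how many cases
#' required consultation by exactly k of the observers.  Percentages are
#' printed at 2 decimals with denominators reported explicitly.
#'
#' @param flags tibble with columns `case_id`, `observer`,
#'   `needs_consultation` (logical).  Every observer must cover the same
#'   case set.
#' @return an object of class `cohort_report`: list with `per_observer`
#'   tibble (`observer`, `n_consult`, `n_cases`, `rate_pct`),
#'   `cross_observer` tibble (`k`, `n_cases_exactly_k`, `n_cases`, `pct`),
#'   `n_cases`, `n_observers`.
#' @export
consultation_statistics <- function(flags) {
  stopifnot(all(c("case_id", "observer", "needs_consultation") %in% names(flags)))
  obs <- sort(unique(flags$observer))
  case_sets <- lapply(obs, function(o) sort(unique(flags$case_id[flags$observer == o])))
  for (i in seq_along(obs)[-1]) {
    if (!identical(case_sets[[i]], case_sets[[1]])) {
      abort(sprintf("observers '%s' and '%s' cover different case sets",
                    obs[1], obs[i]))
    }
  }
  n_cases <- length(case_sets[[1]])
  per_observer <- flags |>
    dplyr::group_by(.data$observer) |>
    dplyr::summarise(n_consult = sum(.data$needs_consultation), .groups = "drop") |>
    dplyr::mutate(n_cases = n_cases,
                  rate_pct = consultation_rate(.data$n_consult, n_cases))

  by_case <- flags |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(k = sum(.data$needs_consultation), .groups = "drop")
  cross <- tibble::tibble(k = 0:length(obs)) |>
    dplyr::mutate(n_cases_exactly_k = vapply(.data$k, function(kk) sum(by_case$k == kk),
                                             numeric(1)),
                  n_cases = n_cases,
                  pct = consultation_rate(.data$n_cases_exactly_k, n_cases))

  structure(list(per_observer = per_observer, cross_observer = cross,
                 n_cases = n_cases, n_observers = length(obs)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d cases, %d observers\n", x$n_cases, x$n_observers))
  print(x$per_observer)
  print(x$cross_observer)
  invisible(x)
}

#' @rdname consultation_statistics
#' @param x a `cohort_report`.
#' @param ... unused.
#' @method tidy cohort_report
#' @export
tidy.cohort_report <- function(x, ...) x$per_observer

#' @rdname consultation_statistics
#' @method glance cohort_report
#' @export
glance.cohort_report <- function(x, ...) {
  tibble::tibble(n_cases = x$n_cases, n_observers = x$n_observers,
                 max_rate_pct = max(x$per_observer$rate_pct),
                 min_rate_pct = min(x$per_observer$rate_pct),
                 all_observer_pct = x$cross_observer$pct[x$cross_observer$k ==
                                                           x$n_observers])
}

#' Write a cohort report as JSON and CSV
#'
#' @param report a [consultation_statistics()] result.
#' @param path_json,path_csv output paths (either may be `NULL`).
#' @return invisibly, the report.
#' @export
write_cohort_report <- function(report, path_json = NULL, path_csv = NULL) {
  stopifnot(inherits(report, "cohort_report"))
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(n_cases = report$n_cases, n_observers = report$n_observers,
           per_observer = report$per_observer,
           cross_observer = report$cross_observer),
      path_json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(path_csv)) {
    utils::write.csv(report$per_observer, path_csv, row.names = FALSE)
  }
  invisible(report)
}
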