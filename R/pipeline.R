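## Run orchestration: one config object, three entry points
## (simulate / case / evaluate), deterministic outputs with the config
## hash embedded for provenance.

#' Default run configuration
#'
#' One nested list holding every tunable of the pipeline: synthetic-cohort
#' settings, detector parameters, contextual parameters, triage constants
#' (top 36 candidates, sets of 3, up to 12 sets) and decision thresholds
#' (score-5 rules, the 0.6 Doubt boundary).  Round-trips losslessly
#' through YAML via [write_config()] / [read_config()].
#'
#' @param seed integer master seed.
#' @return a list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    log_level = "info",
    simulate = list(n_cases = 8L, hscr_fraction = 0.4, inadequate_fraction = 0.1,
                    slide = list(width_px = 768L, height_px = 768L,
                                 pixel_size_um = 0.25,
                                 n_mature_ganglia = 8L, n_immature_ganglia = 2L,
                                 n_mimics = 6L, cluster_size_mean = 3,
                                 vessel_density = 2, noise_level = 0.05)),
    detector = list(blur_sigma = 3, seed_window = 15L, seed_threshold = 0.6,
                    patch_px = 100L, nms_radius_px = 50),
    context = list(radius_px = 300, alpha = 0.25, beta = 0.15, gamma = 0.10,
                   floor_score = 0.05, max_iters = 10L),
    triage = list(top_k = 36L, set_size = 3L, max_sets = 12L),
    decision = list(doubt_threshold = 0.6, expert_positive_score = 5L,
                    nonexpert_positive_count = 2L)
  ), class = "run_config")
}

#' @rdname default_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  ## named atomic vectors must be YAML maps, not bare sequences
  lbf <- cfg$simulate$slide$layer_band_fractions
  if (!is.null(lbf)) cfg$simulate$slide$layer_band_fractions <- as.list(lbf)
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- utils::modifyList(unclass(default_config()), yaml::read_yaml(path))
  ## YAML maps come back as lists; band fractions are a named numeric vector
  lbf <- cfg$simulate$slide$layer_band_fractions
  if (!is.null(lbf)) cfg$simulate$slide$layer_band_fractions <- unlist(lbf)
  structure(cfg, class = "run_config")
}

#' @rdname default_config
#' @export
config_hash <- function(config) rlang::hash(unclass(config))

config_spec <- function(config, seed = NULL) {
  s <- config$simulate$slide
  do.call(slide_spec, c(s, list(seed = seed %||% config$seed)))
}

config_detection_params <- function(config) {
  do.call(detection_params, config$detector)
}

config_context_params <- function(config) {
  do.call(context_params,
          config$context[setdiff(names(config$context), "max_iters")])
}

pipeline_log <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible(NULL))
  message(sprintf(...))
}

#' Simulate a cohort to disk
#'
#' Generates a labelled synthetic cohort and writes, per case, the slide
#' image (`image.tiff`), the ground-truth layer map (`layers.tiff` +
#' legend sidecar) and annotations (`annotations.xml`), plus a
#' `manifest.csv` (case_id, label, paths, per-case seed) and the config
#' YAML with its hash.  Rerunning with the same config reproduces every
#' byte.
#'
#' @param config a [default_config()].
#' @param out_dir output directory (created).
#' @return the manifest tibble, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create output directory '%s'", out_dir))
  cohort <- generate_cohort(config$simulate$n_cases,
                            config$simulate$hscr_fraction,
                            config$simulate$inadequate_fraction,
                            seed = config$seed,
                            base_spec = config_spec(config))
  rows <- purrr::pmap(list(cohort$case_id, cohort$label, cohort$bundle),
                      function(cid, lab, b) {
    cdir <- file.path(out_dir, cid)
    dir.create(cdir, showWarnings = FALSE)
    write_slide_image(b$image, file.path(cdir, "image.tiff"))
    write_layer_map(b$layers, file.path(cdir, "layers.tiff"))
    write_annotations(b$annotations, file.path(cdir, "annotations.xml"))
    tibble::tibble(case_id = cid, label = lab, seed = b$spec$seed,
                   image = file.path(cid, "image.tiff"),
                   layers = file.path(cid, "layers.tiff"),
                   annotations = file.path(cid, "annotations.xml"))
  })
  manifest <- dplyr::bind_rows(rows)
  manifest$config_hash <- config_hash(config)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  write_config(config, file.path(out_dir, "config.yaml"))
  pipeline_log(config, "simulated %d cases into %s", nrow(manifest), out_dir)
  invisible(manifest)
}

#' Run the detection pipeline on one case
#'
#' Chains [segment_layers()] (the algorithm's own layer map, not the
#' ground truth), [detect_candidates()], [contextual_rescore()],
#' [build_image_sets()] and [case_ai_score()] for every slide of a case,
#' pooling candidates across slides into one ranking.
#'
#' @param config a [default_config()].
#' @param case_id case to run.
#' @param cohort_dir directory written by [run_simulate()] (or laid out
#'   the same way).
#' @param out_dir if given, image-set patches and a JSON manifest are
#'   exported there.
#' @return a [case_record()] with an extra `candidates` element (the
#'   rescored candidate tibble).
#' @export
run_case <- function(config, case_id, cohort_dir, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  manifest_path <- file.path(cohort_dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    abort(sprintf("no manifest at '%s'", manifest_path))
  }
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  row <- manifest[manifest$case_id == case_id, ]
  if (nrow(row) == 0) abort(sprintf("case '%s' not in manifest", case_id))
  images <- list()
  cand_all <- list()
  for (i in seq_len(nrow(row))) {
    img_path <- file.path(cohort_dir, row$image[i])
    if (!file.exists(img_path)) abort(sprintf("missing slide file '%s'", img_path))
    img <- read_slide_image(img_path)
    slide_id <- sprintf("slide_%d", i)
    images[[slide_id]] <- img
    layers <- segment_layers(img)
    cand <- detect_candidates(img, layers, config_detection_params(config))
    cand <- contextual_rescore(cand, img, layers,
                               max_iters = config$context$max_iters,
                               params = config_context_params(config))
    if (nrow(cand) > 0) {
      cand$case_id <- case_id
      cand$slide_id <- slide_id
    }
    cand_all[[i]] <- cand
  }
  cand <- dplyr::bind_rows(cand_all)
  sets <- build_image_sets(cand, top_k = config$triage$top_k,
                           set_size = config$triage$set_size,
                           max_sets = config$triage$max_sets)
  record <- case_record(case_id, sets)
  record$candidates <- cand
  if (!is.null(out_dir)) {
    export_image_sets(record, function(id) images[[id]], out_dir,
                      config_hash = config_hash(config))
  }
  pipeline_log(config, "case %s: %d candidates, %d sets, avg_top3_ai %.3f",
               case_id, nrow(cand), nrow(sets), record$avg_top3_ai)
  record
}

#' Evaluate observer scores over a cohort
#'
#' Applies the expert rule to the expert observer and the non-expert rule
#' (with each case's `avg_top3_ai`) to all others, resolves Doubt cases by
#' the expert's labels, and computes consultation statistics over the
#' non-experts.
#'
#' @param config a [default_config()].
#' @param records list of [case_record()]s (one per case).
#' @param scores tibble with columns `case_id`, `observer`, `set_rank`,
#'   `score` covering every set of every case for every observer.
#' @param expert_observer the observer classified under the expert rule.
#' @param out_json optional path for the JSON report.
#' @return a list of class `evaluation` with `classifications` (per
#'   observer per case, including `final_label` for non-experts), `report`
#'   (a [consultation_statistics()] result) and `audit` (per
#'   classification: rule fired, inputs).
#' @export
run_evaluate <- function(config, records, scores, expert_observer,
                         out_json = NULL) {
  stopifnot(inherits(config, "run_config"),
            all(c("case_id", "observer", "set_rank", "score") %in% names(scores)))
  recs <- setNames(records, vapply(records, function(r) r$case_id, character(1)))
  observers <- sort(unique(scores$observer))
  if (!expert_observer %in% observers) {
    abort(sprintf("expert observer '%s' has no scores", expert_observer))
  }
  cls <- list(); audit <- list()
  for (obs in observers) {
    for (cid in names(recs)) {
      sc <- scores[scores$observer == obs & scores$case_id == cid, ]
      sc <- sc[order(sc$set_rank), ]
      rec <- record_pathologist_scores(recs[[cid]], obs, sc$score)
      recs[[cid]] <- rec
      if (obs == expert_observer) {
        cl <- classify_expert(sc$score)
        needs <- FALSE
      } else {
        cl <- classify_nonexpert(sc$score, rec$avg_top3_ai)
        needs <- isTRUE(cl$needs_consultation)
      }
      cls[[length(cls) + 1]] <- tibble::tibble(
        case_id = cid, observer = obs, label = cl$label,
        needs_consultation = needs, avg_top3_ai = rec$avg_top3_ai)
      audit[[length(audit) + 1]] <- list(case_id = cid, observer = obs,
                                         rule = if (obs == expert_observer) "expert" else "nonexpert",
                                         scores = sc$score,
                                         avg_top3_ai = rec$avg_top3_ai,
                                         label = cl$label, basis = cl$basis)
    }
  }
  cls <- dplyr::bind_rows(cls)
  expert_labels <- cls[cls$observer == expert_observer, c("case_id", "label")]
  nonexp <- cls[cls$observer != expert_observer, ]
  resolved <- nonexp |>
    dplyr::group_by(.data$observer) |>
    dplyr::group_modify(~ resolve_consultations(.x, expert_labels)) |>
    dplyr::ungroup()
  report <- consultation_statistics(nonexp[, c("case_id", "observer",
                                               "needs_consultation")])
  out <- structure(list(classifications = resolved, expert = expert_labels,
                        report = report, audit = audit, records = recs),
                   class = "evaluation")
  if (!is.null(out_json)) {
    jsonlite::write_json(
      list(config_hash = config_hash(config),
           per_observer = report$per_observer,
           cross_observer = report$cross_observer,
           classifications = resolved),
      out_json, auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.evaluation <- function(x, ...) {
  cat(sprintf("<evaluation> %d cases x %d observers (+ expert)\n",
              x$report$n_cases, x$report$n_observers))
  print(x$report$per_observer)
  invisible(x)
}
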