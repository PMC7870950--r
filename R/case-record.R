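## Case records: the per-case unit of the validation workflow — ranked
## image sets, the case-level AI score, immutable per-observer 1-5 scores
## and per-observer classifications.

#' Create a case record
#'
#' @param case_id case identifier.
#' @param sets an [build_image_sets()] result.
#' @return an object of class `case_record` with `avg_top3_ai` computed by
#'   [case_ai_score()], an empty score book and an empty classification
#'   list.
#' @export
case_record <- function(case_id, sets) {
  stopifnot(inherits(sets, "image_sets"))
  structure(
    list(case_id = as.character(case_id), sets = sets,
         avg_top3_ai = case_ai_score(sets),
         pathologist_scores = list(), classifications = list()),
    class = "case_record"
  )
}

#' Record a pathologist's set scores for a case
#'
#' Scores use the 1-5 scale (1 = no ganglion cells seen, certain; 5 =
#' ganglion cells seen, certain), one score per image set.  Scores are
#' immutable once recorded: re-recording the same observer is an error, so
#' the audit trail cannot be silently rewritten.
#'
#' @param record a [case_record()].
#' @param observer observer identifier.
#' @param scores integer vector in 1..5, one per set of the case.
#' @return the updated `case_record`.
#' @export
#' @examples
#' sets <- build_image_sets(tibble::tibble(x = c(0, 200), y = 0,
#'                                         contextual_score = c(.9, .2)))
#' rec <- case_record("case_001", sets)
#' rec <- record_pathologist_scores(rec, "p2", c(5))
record_pathologist_scores <- function(record, observer, scores) {
  stopifnot(inherits(record, "case_record"))
  observer <- as.character(observer)
  if (observer %in% names(record$pathologist_scores)) {
    abort(sprintf("observer '%s' already scored case %s; scores are immutable",
                  observer, record$case_id))
  }
  n_sets <- nrow(record$sets)
  if (length(scores) != n_sets) {
    abort(sprintf("case %s has %d sets but %d scores were given",
                  record$case_id, n_sets, length(scores)))
  }
  bad <- which(!(scores %in% 1:5))
  if (length(bad) > 0) {
    abort(sprintf("score for set rank %d is %s; scores must be integers 1..5",
                  bad[1], format(scores[bad[1]])))
  }
  record$pathologist_scores[[observer]] <- as.integer(scores)
  record
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case_record> %s: %d sets, avg_top3_ai = %.3f, %d observer(s)\n",
              x$case_id, nrow(x$sets), x$avg_top3_ai,
              length(x$pathologist_scores)))
  invisible(x)
}

#' @rdname case_record
#' @param x a `case_record`.
#' @param ... unused.
#' @method tidy case_record
#' @export
tidy.case_record <- function(x, ...) {
  out <- x$sets[, c("set_rank", "set_score", "n_patches")]
  out$case_id <- x$case_id
  obs <- names(x$pathologist_scores)
  for (o in obs) out[[paste0("score_", o)]] <- x$pathologist_scores[[o]]
  tibble::as_tibble(out[, c("case_id", setdiff(names(out), "case_id"))])
}

#' @rdname case_record
#' @method glance case_record
#' @export
glance.case_record <- function(x, ...) {
  tibble::tibble(case_id = x$case_id, n_sets = nrow(x$sets),
                 n_patches = sum(x$sets$n_patches),
                 avg_top3_ai = x$avg_top3_ai,
                 n_observers = length(x$pathologist_scores))
}
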