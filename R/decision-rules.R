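## Classification criteria from the validation protocol.
##
## Expert rule: one certain ganglion cell (a single set scored 5) is
## enough to call the case positive for ganglion cells (non-HSCR);
## otherwise negative (HSCR).
##
## Non-expert rule: positive only for two or more sets scored 5; otherwise
## negative when the case's average AI score is < 0.6 and Doubt (expert
## consultation required) when it is >= 0.6.  The boundary is
## Doubt-inclusive.  The rule's known failure mode — a false positive if a
## score of 5 is given inaccurately to two candidates — is implemented as
## stated, not patched.

DOUBT_THRESHOLD <- 0.6

new_classification <- function(label, basis) {
  structure(list(label = label, basis = basis), class = "hca_classification")
}

#' @export
print.hca_classification <- function(x, ...) {
  cat(sprintf("<%s> %s\n", x$label, x$basis))
  invisible(x)
}

check_set_scores <- function(set_scores) {
  if (length(set_scores) > 0 && !all(set_scores %in% 1:5)) {
    abort("set scores must be integers in 1..5")
  }
}

#' Expert classification rule
#'
#' Positive (non-HSCR) iff any set was scored 5; otherwise Negative
#' (HSCR).  An empty score list (a case with no image sets: nothing was
#' found, nothing was seen) is Negative, with that convention recorded in
#' the basis.  Never yields Doubt.
#'
#' @param set_scores integer vector of 1-5 set scores (possibly empty).
#' @return an `hca_classification` with fields `label`
#'   (`"Positive"`/`"Negative"`) and `basis`.
#' @export
#' @examples
#' classify_expert(c(1, 1, 5))$label   # "Positive"
#' classify_expert(c(4, 4, 4))$label   # "Negative"
classify_expert <- function(set_scores) {
  check_set_scores(set_scores)
  if (length(set_scores) == 0) {
    return(new_classification("Negative", "no image sets; nothing to score (vacuous negative)"))
  }
  if (any(set_scores == 5)) {
    new_classification("Positive",
                       sprintf("set(s) %s scored 5 (single certain ganglion cell suffices)",
                               paste(which(set_scores == 5), collapse = ",")))
  } else {
    new_classification("Negative", "all set scores < 5")
  }
}

#' Non-expert classification rule
#'
#' Positive iff two or more sets were scored 5; otherwise Negative when
#' `avg_top3_ai < 0.6` and Doubt when `avg_top3_ai >= 0.6` (boundary
#' inclusive).  Doubt means expert consultation is required; the
#' `needs_consultation` field is set accordingly.  A case with no sets is
#' Negative under the same vacuous convention as [classify_expert()].
#'
#' @param set_scores integer vector of 1-5 set scores (possibly empty).
#' @param avg_top3_ai case-level AI score in `[0, 1]` from
#'   [case_ai_score()].
#' @return an `hca_classification` with `label` (`"Positive"`,
#'   `"Negative"` or `"Doubt"`), `basis` and `needs_consultation`.
#' @export
#' @examples
#' classify_nonexpert(c(5, 5, 1), 0.2)$label    # "Positive"
#' classify_nonexpert(c(5, 4, 1), 0.55)$label   # "Negative"
#' classify_nonexpert(c(5, 4, 1), 0.60)$label   # "Doubt"
classify_nonexpert <- function(set_scores, avg_top3_ai) {
  check_set_scores(set_scores)
  stopifnot(length(avg_top3_ai) == 1, avg_top3_ai >= 0, avg_top3_ai <= 1)
  n5 <- sum(set_scores == 5)
  out <- if (n5 >= 2) {
    new_classification("Positive",
                       sprintf("%d sets scored 5 (two or more suffice)", n5))
  } else if (avg_top3_ai < DOUBT_THRESHOLD) {
    basis <- sprintf("fewer than two sets scored 5 and average AI score %.3f < %.1f",
                     avg_top3_ai, DOUBT_THRESHOLD)
    if (length(set_scores) == 0) basis <- paste(basis, "(no image sets; vacuous negative)")
    new_classification("Negative", basis)
  } else {
    new_classification("Doubt",
                       sprintf("fewer than two sets scored 5 and average AI score %.3f >= %.1f: expert consultation required",
                               avg_top3_ai, DOUBT_THRESHOLD))
  }
  out$needs_consultation <- out$label == "Doubt"
  out
}

#' Resolve Doubt cases by expert consultation
#'
#' Replaces each non-expert Doubt label by the expert's label for that
#' case; Positive and Negative pass through unchanged (no consultation was
#' requested).  A Doubt case without an expert label is an error — under
#' the safety design a case with high AI score can never be finalized
#' Negative without an expert looking at it.
#'
#' @param nonexpert tibble with columns `case_id`, `label` (and anything
#'   else, preserved).
#' @param expert tibble with columns `case_id`, `label`; must cover every
#'   Doubt case.
#' @return `nonexpert` with a `final_label` column and a `consulted` flag.
#' @export
resolve_consultations <- function(nonexpert, expert) {
  stopifnot(all(c("case_id", "label") %in% names(nonexpert)),
            all(c("case_id", "label") %in% names(expert)))
  doubt <- nonexpert$case_id[nonexpert$label == "Doubt"]
  missing <- setdiff(doubt, expert$case_id)
  if (length(missing) > 0) {
    abort(paste("Doubt case(s) without an expert label:",
                paste(missing, collapse = ", ")))
  }
  out <- nonexpert
  out$consulted <- out$label == "Doubt"
  out$final_label <- out$label
  idx <- match(out$case_id[out$consulted], expert$case_id)
  out$final_label[out$consulted] <- expert$label[idx]
  out
}
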