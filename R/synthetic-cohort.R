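## Synthetic validation cohorts.
##
## Case labels follow the clinical reading: an HSCR case is aganglionic
## (zero ganglion cells anywhere), a non-HSCR case contains at least one,
## and an inadequate case is a superficial biopsy with no submucosa or
## muscularis at all — which therefore must contain no ganglion cells and
## should be classified negative.

#' Generate a labelled synthetic cohort
#'
#' @param n_cases number of cases (0 gives an empty cohort).
#' @param hscr_fraction,inadequate_fraction fractions of cases rendered
#'   aganglionic (HSCR) and superficial (inadequate); must sum to at most
#'   1, the remainder being ganglionic non-HSCR cases.
#' @param seed integer seed; determines case order, per-case seeds and
#'   therefore every pixel of every slide.
#' @param base_spec [slide_spec()] template for adequate cases; per-case
#'   specs vary only in counts, band layout and seed.
#' @return a tibble of class `cohort` with columns `case_id`, `label`
#'   (`HSCR`, `non-HSCR`, `inadequate`) and `bundle` (list of
#'   [generate_slide()] bundles).
#' @export
#' @examples
#' co <- generate_cohort(4, hscr_fraction = 0.5, seed = 3,
#'                       base_spec = slide_spec(width_px = 480, height_px = 480,
#'                                              n_mature_ganglia = 3,
#'                                              n_immature_ganglia = 0))
#' dplyr::count(co, label)
generate_cohort <- function(n_cases, hscr_fraction, inadequate_fraction = 0,
                            seed = 1L, base_spec = slide_spec()) {
  stopifnot(is_count(n_cases), hscr_fraction >= 0, hscr_fraction <= 1,
            inadequate_fraction >= 0, inadequate_fraction <= 1)
  if (hscr_fraction + inadequate_fraction > 1 + 1e-9) {
    abort("hscr_fraction + inadequate_fraction must be at most 1")
  }
  if (n_cases == 0) {
    return(structure(tibble::tibble(case_id = character(0), label = character(0),
                                    bundle = list()),
                     class = c("cohort", class(tibble::tibble()))))
  }
  n_inad <- as.integer(round(n_cases * inadequate_fraction))
  n_hscr <- as.integer(round(n_cases * hscr_fraction))
  if (n_inad + n_hscr > n_cases) n_hscr <- n_cases - n_inad
  n_non <- n_cases - n_inad - n_hscr
  labels <- withr::with_seed(seed, sample(c(rep("HSCR", n_hscr),
                                            rep("non-HSCR", n_non),
                                            rep("inadequate", n_inad))))
  bundles <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    case_seed <- as.integer((abs(seed) + 7919 * i) %% .Machine$integer.max)
    sp <- base_spec
    sp$seed <- case_seed
    if (labels[i] == "HSCR") {
      sp$n_mature_ganglia <- 0L
      sp$n_immature_ganglia <- 0L
    } else if (labels[i] == "inadequate") {
      ## superficial rectal biopsy: epithelium + mucosa only
      sp$n_mature_ganglia <- 0L
      sp$n_immature_ganglia <- 0L
      sp$layer_band_fractions <- c(epithelium = 0.15, mucosa = 0.55,
                                   submucosa = 0, muscularis = 0, serosa = 0)
      sp$vessel_density <- 0
    }
    bundles[[i]] <- generate_slide(sp)
  }
  out <- tibble::tibble(case_id = sprintf("case_%03d", seq_len(n_cases)),
                        label = labels, bundle = bundles)
  class(out) <- c("cohort", class(out))
  out
}

#' @export
print.cohort <- function(x, ...) {
  if (!"bundle" %in% names(x)) return(NextMethod())   # summarised derivative
  cat(sprintf("<cohort> %d cases: %s\n", nrow(x),
              paste(sprintf("%s %d", names(table(x$label)), table(x$label)),
                    collapse = ", ")))
  invisible(x)
}
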