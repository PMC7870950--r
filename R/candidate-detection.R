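## Candidate detection: nucleus-scale blob detection on the hematoxylin
## channel, hand-crafted morphology features per blob, a fixed monotone
## logistic score, then the hierarchical veto.  Fully deterministic: no
## learned weights, no randomness.

#' Detection parameters
#'
#' Tunables of [detect_candidates()].  `blur_sigma` / `seed_window` /
#' `seed_threshold` control the hematoxylin blob seeding (a compact
#' nucleolus- or nucleus-scale blob survives the blur; thin Schwann-like
#' streaks and texture noise do not); `patch_px` is the candidate box
#' (default 100 px, the size of a mature ganglion soma); `nms_radius_px`
#' keeps one candidate per soma.
#'
#' @param blur_sigma Gaussian blur sigma (px) before local-maximum seeding.
#' @param seed_window side of the square local-maximum window (px, odd).
#' @param seed_threshold minimum blurred hematoxylin OD at a seed.
#' @param patch_px candidate patch box side (px).
#' @param nms_radius_px non-maximum-suppression radius (px).
#' @param weights,intercept parameters of the logistic scoring map; the
#'   weights of `nucleus_area`, `nucleolus_prominence` and
#'   `cytoplasm_abundance` must be nonnegative so the score is monotone
#'   nondecreasing in each.
#' @return a list of class `detection_params`.
#' @export
detection_params <- function(blur_sigma = 3, seed_window = 15L,
                             seed_threshold = 0.6, patch_px = 100L,
                             nms_radius_px = 50,
                             weights = c(nucleus_area = 3.0,
                                         nucleolus_prominence = 1.2,
                                         cytoplasm_abundance = 2.2,
                                         stain_ratio = 1.5),
                             intercept = -4) {
  stopifnot(blur_sigma > 0, seed_window >= 3, seed_threshold > 0,
            patch_px >= 10, nms_radius_px >= 0)
  need <- c("nucleus_area", "nucleolus_prominence", "cytoplasm_abundance",
            "stain_ratio")
  stopifnot(all(need %in% names(weights)))
  if (any(weights[need[1:3]] < 0)) {
    abort("weights of the three morphology features must be nonnegative (monotone score)")
  }
  structure(list(blur_sigma = blur_sigma, seed_window = as.integer(seed_window),
                 seed_threshold = seed_threshold, patch_px = as.integer(patch_px),
                 nms_radius_px = nms_radius_px, weights = weights[need],
                 intercept = intercept),
            class = "detection_params")
}

#' Score a candidate from its morphology features
#'
#' Fixed logistic map over a weighted feature sum.  Monotone nondecreasing
#' in `nucleus_area` (fraction of pale vesicular-nucleus pixels around the
#' seed), `nucleolus_prominence` (central hematoxylin excess over its
#' surround) and `cytoplasm_abundance` (mean eosin in the soma annulus).
#'
#' @param features named numeric vector (or data frame of such rows) with
#'   entries `nucleus_area`, `nucleolus_prominence`, `cytoplasm_abundance`,
#'   `stain_ratio`; all finite.
#' @param params a [detection_params()].
#' @return numeric score(s) in `[0, 1]`.
#' @export
#' @examples
#' score_candidate(c(nucleus_area = 0, nucleolus_prominence = 0,
#'                   cytoplasm_abundance = 0, stain_ratio = 0))
score_candidate <- function(features, params = detection_params()) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features)) features <- matrix(features, nrow = 1,
                                               dimnames = list(NULL, names(features)))
  need <- names(params$weights)
  stopifnot(all(need %in% colnames(features)))
  f <- features[, need, drop = FALSE]
  if (any(!is.finite(f))) abort("features must be finite (no NaN/NA/Inf)")
  z <- params$intercept + as.numeric(f %*% params$weights)
  stats::plogis(z)
}

## Ring/disk pixel offsets within the patch, precomputed once per call.
ring_offsets <- function(r_out, r_in = -1) {
  r <- ceiling(r_out)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  d <- sqrt(off$dx^2 + off$dy^2)
  off[d <= r_out & d > r_in, ]
}

## Mean of img values at (x + dx, y + dy), clipped at borders.
ring_mean <- function(img, x, y, off, predicate = NULL) {
  cols <- round(x) + off$dx + 1; rows <- round(y) + off$dy + 1
  keep <- cols >= 1 & cols <= ncol(img) & rows >= 1 & rows <= nrow(img)
  v <- img[cbind(rows[keep], cols[keep])]
  if (is.null(predicate)) mean(v) else mean(predicate(v))
}

extract_candidate_features <- function(st, x, y, scale = 1) {
  H <- st$hematoxylin; E <- st$eosin
  core4   <- ring_offsets(4 * scale)
  core10  <- ring_offsets(10 * scale)
  ring_nuc <- ring_offsets(24 * scale, 6 * scale)
  ring_prom <- ring_offsets(18 * scale, 8 * scale)
  ring_cyt <- ring_offsets(45 * scale, 12 * scale)
  purrr::map2_dfr(x, y, function(xi, yi) {
    ## pale vesicular nucleus: low H and low E around the seed
    cols <- round(xi) + ring_nuc$dx + 1; rows <- round(yi) + ring_nuc$dy + 1
    keep <- cols >= 1 & cols <= ncol(H) & rows >= 1 & rows <= nrow(H)
    idx <- cbind(rows[keep], cols[keep])
    pale <- mean(H[idx] < 0.25 & E[idx] < 0.30)
    prom <- ring_mean(H, xi, yi, core4) - ring_mean(H, xi, yi, ring_prom)
    cyt <- ring_mean(E, xi, yi, ring_cyt)
    colsc <- round(xi) + core10$dx + 1; rowsc <- round(yi) + core10$dy + 1
    keepc <- colsc >= 1 & colsc <= ncol(H) & rowsc >= 1 & rowsc <= nrow(H)
    idxc <- cbind(rowsc[keepc], colsc[keepc])
    ratio <- mean(H[idxc] / (H[idxc] + E[idxc] + 0.05))
    tibble::tibble(nucleus_area = pale, nucleolus_prominence = max(prom, 0),
                   cytoplasm_abundance = cyt, stain_ratio = ratio)
  })
}

## Stable non-maximum suppression: keep the higher-scoring of any two
## candidates whose centroids are closer than `radius`.
nms_candidates <- function(cand, radius) {
  if (nrow(cand) <= 1 || radius <= 0) return(cand)
  ord <- order(-cand$base_score, cand$y, cand$x)
  cand <- cand[ord, ]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d <- sqrt((cand$x[j] - cand$x[i])^2 + (cand$y[j] - cand$y[i])^2)
      keep[j[d < radius]] <- FALSE
    }
  }
  cand[keep, ]
}

#' Detect ganglion-cell candidates in a slide image
#'
#' Pipeline: H&E unmixing, Gaussian blur of the hematoxylin channel, local
#' maxima above `seed_threshold` as seeds, morphology features per seed,
#' logistic base score, non-maximum suppression, then the hierarchical
#' layer veto.  Returns candidates sorted by `base_score` descending
#' (ties: smaller y, then smaller x).  Deterministic.
#'
#' @param image RGB array in `[0, 1]`.
#' @param layers a [new_layer_map()] for the same image (typically from
#'   [segment_layers()]).
#' @param params a [detection_params()].
#' @return a tibble with columns `x`, `y` (0-based centroid), `box_w`,
#'   `box_h`, the four features, `base_score`, `contextual_score`
#'   (initialized to `base_score`) and `layer`.
#' @export
detect_candidates <- function(image, layers, params = detection_params()) {
  stopifnot(inherits(layers, "layer_map"),
            all(dim(image)[1:2] == dim(layers$labels)))
  st <- separate_stains(image)
  scale <- params$patch_px / 100
  hs <- EBImage::gblur(st$hematoxylin, sigma = params$blur_sigma)
  mx <- EBImage::dilate(hs, EBImage::makeBrush(params$seed_window, shape = "box"))
  seeds <- which(hs >= mx - 1e-12 & hs > params$seed_threshold, arr.ind = TRUE)
  if (nrow(seeds) == 0) {
    return(empty_candidates())
  }
  x <- seeds[, 2] - 1; y <- seeds[, 1] - 1
  feats <- extract_candidate_features(st, x, y, scale = scale)
  d <- dim(image)
  half <- params$patch_px / 2
  ## patch boxes shrink at borders instead of discarding the candidate
  cand <- tibble::tibble(
    x = as.numeric(x), y = as.numeric(y),
    box_w = pmin(half, x) + pmin(half, d[2] - 1 - x),
    box_h = pmin(half, y) + pmin(half, d[1] - 1 - y)
  )
  cand <- dplyr::bind_cols(cand, feats)
  cand$base_score <- score_candidate(feats, params)
  cand$contextual_score <- cand$base_score
  cand <- nms_candidates(cand, params$nms_radius_px)
  cand <- hierarchical_filter(cand, layers)
  cand <- cand[order(-cand$base_score, cand$y, cand$x), ]
  tibble::as_tibble(cand)
}

empty_candidates <- function() {
  tibble::tibble(x = numeric(0), y = numeric(0), box_w = numeric(0),
                 box_h = numeric(0), nucleus_area = numeric(0),
                 nucleolus_prominence = numeric(0),
                 cytoplasm_abundance = numeric(0), stain_ratio = numeric(0),
                 base_score = numeric(0), contextual_score = numeric(0),
                 layer = character(0))
}
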