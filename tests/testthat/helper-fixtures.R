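# Shared fixtures (built in code, cached per test run) and independent
# oracles used to cross-check the implementation.

fixture_cache <- new.env(parent = emptyenv())

# A compact slide that still fits full-size ganglia: 480 px with 30/30
# permissible bands (144 px each, enough for the 112 px mature margin).
small_spec <- function(seed = 101, ...) {
  args <- list(width_px = 480L, height_px = 480L,
               layer_band_fractions = c(epithelium = 0.08, mucosa = 0.18,
                                        submucosa = 0.30, muscularis = 0.30,
                                        serosa = 0.10),
               n_mature_ganglia = 3L, n_immature_ganglia = 1L, n_mimics = 3L,
               cluster_size_mean = 3, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(slide_spec, args)
}

fixture_bundle <- function(seed = 101) {
  key <- paste0("bundle_", seed)
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- generate_slide(small_spec(seed))
  }
  fixture_cache[[key]]
}

fixture_detection <- function(seed = 101) {
  key <- paste0("det_", seed)
  if (is.null(fixture_cache[[key]])) {
    b <- fixture_bundle(seed)
    layers <- segment_layers(b$image)
    cand <- detect_candidates(b$image, layers)
    fixture_cache[[key]] <- list(bundle = b, layers = layers, candidates = cand)
  }
  fixture_cache[[key]]
}

# --- independent oracles ----------------------------------------------------

# Connected components of the distance-<=radius graph by breadth-first
# transitive closure (quadratic; independent of hclust).
oracle_clusters <- function(x, y, radius) {
  n <- length(x)
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      d <- sqrt((x - x[j])^2 + (y - y[j])^2)
      nb <- which(d <= radius & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Ray-casting point-in-polygon, written independently of mgcv::in.out.
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# Brute-force cell-level metric recount on explicit decoys.
oracle_cell_metrics <- function(det_x, det_y, truth_polys, decoys, radius) {
  detected <- 0L
  for (p in truth_polys) {
    hit <- FALSE
    for (k in seq_along(det_x)) {
      if (oracle_point_in_polygon(det_x[k], det_y[k], p)) { hit <- TRUE; break }
    }
    detected <- detected + hit
  }
  fa <- 0L
  for (i in seq_len(nrow(decoys))) {
    near <- FALSE
    for (k in seq_along(det_x)) {
      if (sqrt((det_x[k] - decoys[i, 1])^2 + (det_y[k] - decoys[i, 2])^2) <= radius) {
        near <- TRUE; break
      }
    }
    fa <- fa + near
  }
  list(detected = detected, false_alarm = fa)
}

# 48-case, 4-observer consultation flag matrix reproducing the printed
# per-observer counts (18, 10, 29, 18) and the cross-observer distribution
# (9 all-four, 5 exactly-three, 9 exactly-two, 6 exactly-one).
printed_flag_matrix <- function() {
  m <- matrix(FALSE, nrow = 48, ncol = 4,
              dimnames = list(NULL, paste0("p", 2:5)))
  r <- 0L
  add <- function(rows, cols) {
    for (q in seq_len(rows)) {
      r <<- r + 1L
      m[r, cols] <<- TRUE
    }
  }
  add(9, 1:4)                      # all four observers
  add(4, c(1, 3, 4)); add(1, c(1, 2, 3))   # exactly three (5 cases)
  add(5, c(3, 4)); add(4, c(1, 3))         # exactly two (9 cases)
  add(6, 3)                                # exactly one (6 cases)
  m
}

flags_tibble <- function(m, case_ids = sprintf("case_%02d", seq_len(nrow(m)))) {
  if (is.null(colnames(m))) colnames(m) <- paste0("obs", seq_len(ncol(m)))
  tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(m), case_id = case_ids),
    -dplyr::all_of("case_id"),
    names_to = "observer", values_to = "needs_consultation")
}

# Rectangular negative regions: permissible bands inset by `inset`,
# suitable as ganglion-free decoy regions together with truth rejection.
permissible_rectangles <- function(layers, inset = 10) {
  lab <- layers$labels
  out <- list()
  for (code in c(3L, 4L)) {
    rows <- which(apply(lab == code, 1, any))
    if (length(rows) == 0) next
    y0 <- min(rows) - 1 + inset; y1 <- max(rows) - 1 - inset
    x0 <- inset; x1 <- ncol(lab) - 1 - inset
    if (y1 > y0) {
      out[[length(out) + 1]] <- cbind(x = c(x0, x1, x1, x0),
                                      y = c(y0, y0, y1, y1))
    }
  }
  out
}
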