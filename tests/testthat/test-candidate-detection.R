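# Blob detection, morphology features and the monotone logistic score.

test_that("scores stay in [0, 1] and vanish for featureless input", {
  expect_lt(score_candidate(c(nucleus_area = 0, nucleolus_prominence = 0,
                              cytoplasm_abundance = 0, stain_ratio = 0)), 0.1)
  withr::with_seed(8, {
    f <- matrix(runif(4e4, 0, 3), ncol = 4,
                dimnames = list(NULL, c("nucleus_area", "nucleolus_prominence",
                                        "cytoplasm_abundance", "stain_ratio")))
    s <- score_candidate(f)
    expect_true(all(s >= 0 & s <= 1))
  })
})

test_that("the score is monotone in each morphology feature", {
  base <- c(nucleus_area = 0.3, nucleolus_prominence = 0.5,
            cytoplasm_abundance = 0.4, stain_ratio = 0.5)
  for (feat in c("nucleus_area", "nucleolus_prominence", "cytoplasm_abundance")) {
    grid <- seq(0, 2, by = 0.1)
    s <- vapply(grid, function(v) {
      f <- base; f[feat] <- v
      score_candidate(f)
    }, numeric(1))
    expect_true(all(diff(s) >= -1e-12), info = feat)
  }
})

test_that("non-finite features are rejected", {
  f <- c(nucleus_area = NaN, nucleolus_prominence = 0,
         cytoplasm_abundance = 0, stain_ratio = 0)
  expect_error(score_candidate(f), "finite")
})

test_that("planted mature ganglia are recovered", {
  sp <- slide_spec(width_px = 1024L, height_px = 1024L,
                   n_mature_ganglia = 10L, n_immature_ganglia = 0L, seed = 77)
  b <- generate_slide(sp)
  layers <- segment_layers(b$image)
  cand <- detect_candidates(b$image, layers)
  g <- b$annotations[b$annotations$label == "mature_ganglion", ]
  hits <- vapply(g$polygon, function(p) {
    any(ganglia:::points_in_polygon(cbind(cand$x, cand$y), p))
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("a slide with mimics only yields nothing after the veto", {
  b <- generate_slide(small_spec(seed = 55, n_mature_ganglia = 0L,
                                 n_immature_ganglia = 0L, n_mimics = 6L,
                                 vessel_density = 0))
  layers <- segment_layers(b$image)
  cand <- detect_candidates(b$image, layers)
  expect_equal(nrow(cand), 0L)
})

test_that("candidates come back sorted, deterministic, with valid boxes", {
  det <- fixture_detection()
  cand <- det$candidates
  expect_gt(nrow(cand), 0)
  expect_true(all(diff(cand$base_score) <= 1e-12))
  expect_true(all(cand$base_score >= 0 & cand$base_score <= 1))
  expect_true(all(cand$contextual_score == cand$base_score))
  # patch box contains the centroid even at borders
  expect_true(all(cand$box_w > 0 & cand$box_h > 0))
  cand2 <- detect_candidates(det$bundle$image, det$layers)
  expect_equal(cand2, cand)
})

test_that("non-maximum suppression keeps one candidate per soma", {
  det <- fixture_detection()
  cand <- det$candidates
  if (nrow(cand) > 1) {
    d <- as.matrix(dist(cbind(cand$x, cand$y)))
    diag(d) <- Inf
    expect_gte(min(d), 50)
  }
  g <- det$bundle$annotations
  g <- g[g$label == "mature_ganglion", ]
  per_cell <- vapply(g$polygon, function(p) {
    sum(ganglia:::points_in_polygon(cbind(cand$x, cand$y), p))
  }, numeric(1))
  expect_true(all(per_cell <= 1))
})

test_that("candidate tables round-trip through CSV", {
  det <- fixture_detection()
  cand <- det$candidates
  cand$case_id <- "case_001"; cand$slide_id <- "slide_1"
  path <- withr::local_tempfile(fileext = ".csv")
  write_candidates(cand, path)
  back <- read_candidates(path)
  expect_equal(back$x, cand$x)
  expect_equal(back$base_score, cand$base_score, tolerance = 1e-12)
  expect_equal(back$layer, cand$layer)
})
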