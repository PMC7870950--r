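# Neighbourhood re-scoring: clustering, context bonuses, fixed-point
# convergence.

test_that("single-linkage clustering matches forced cases", {
  cand <- tibble::tibble(x = c(0, 10, 5), y = c(0, 0, 8))
  expect_equal(length(unique(cluster_candidates(cand, 50))), 1L)
  cand2 <- tibble::tibble(x = c(0, 500), y = c(0, 0))
  expect_equal(length(unique(cluster_candidates(cand2, 50))), 2L)
  expect_equal(cluster_candidates(tibble::tibble(x = 1, y = 1), 10), 1L)
  expect_equal(cluster_candidates(tibble::tibble(x = numeric(0), y = numeric(0)), 10),
               integer(0))
  expect_error(cluster_candidates(cand, 0))
})

test_that("clustering equals the brute-force transitive closure", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      n <- 100
      cand <- tibble::tibble(x = runif(n, 0, 600), y = runif(n, 0, 600))
      radius <- runif(1, 20, 120)
      got <- cluster_candidates(cand, radius)
      want <- oracle_clusters(cand$x, cand$y, radius)
      # same partition up to relabelling
      expect_equal(length(unique(got)), length(unique(want)))
      expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1))
    }
  })
})

# A plain submucosa-only image: no vessels, no companions, so context
# bonuses are exactly zero and scores must be preserved.
plain_submucosa_image <- function(px = 300) {
  H <- matrix(0.15, px, px); E <- matrix(0.35, px, px)
  img <- ganglia:::rgb_from_concentrations(H, E)
  layers <- new_layer_map(matrix(3L, px, px))
  list(image = img, layers = layers)
}

manual_candidate <- function(x, y, score = 0.5) {
  tibble::tibble(x = x, y = y, box_w = 100, box_h = 100,
                 nucleus_area = 0.5, nucleolus_prominence = 1,
                 cytoplasm_abundance = 0.5, stain_ratio = 0.5,
                 base_score = score, contextual_score = score,
                 layer = "submucosa")
}

test_that("an isolated candidate with no context keeps its base score", {
  bg <- plain_submucosa_image()
  cand <- manual_candidate(150, 150, 0.4)
  out <- contextual_rescore(cand, bg$image, bg$layers)
  expect_equal(out$contextual_score, 0.4, tolerance = 1e-12)
  expect_equal(out$cluster_size, 1)
})

test_that("a clustered candidate never scores below its isolated twin", {
  bg <- plain_submucosa_image(600)
  focal <- manual_candidate(300, 300, 0.5)
  alone <- contextual_rescore(focal, bg$image, bg$layers)
  neighbours <- manual_candidate(c(250, 350, 300, 260), c(300, 300, 250, 350), 0.5)
  grouped <- contextual_rescore(dplyr::bind_rows(focal, neighbours),
                                bg$image, bg$layers)
  focal_row <- grouped[grouped$x == 300 & grouped$y == 300, ]
  expect_gte(focal_row$contextual_score, alone$contextual_score)
  expect_gt(focal_row$contextual_score, focal_row$base_score)
})

test_that("adding a neighbour never decreases another candidate's score", {
  bg <- plain_submucosa_image(600)
  withr::with_seed(5, {
    for (rep in 1:4) {
      n <- sample(2:6, 1)
      xs <- runif(n, 100, 500); ys <- runif(n, 100, 500)
      sc <- runif(n, 0.2, 0.9)
      cand <- manual_candidate(xs, ys, sc)
      before <- contextual_rescore(cand, bg$image, bg$layers)
      extra <- manual_candidate(runif(1, 100, 500), runif(1, 100, 500), 0.8)
      after <- contextual_rescore(dplyr::bind_rows(cand, extra),
                                  bg$image, bg$layers)
      for (i in seq_len(n)) {
        b_i <- before$contextual_score[before$x == xs[i]]
        a_i <- after$contextual_score[after$x == xs[i]]
        if (length(b_i) == 1 && length(a_i) == 1) expect_gte(a_i, b_i - 1e-12)
      }
    }
  })
})

test_that("rescoring converges to a fixed point within max_iters", {
  det <- fixture_detection()
  out <- contextual_rescore(det$candidates, det$bundle$image, det$layers,
                            max_iters = 10)
  again <- contextual_rescore(out, det$bundle$image, det$layers, max_iters = 10)
  expect_equal(nrow(again), nrow(out))
  expect_equal(again$contextual_score, out$contextual_score, tolerance = 1e-12)
  expect_true(all(out$contextual_score >= 0 & out$contextual_score <= 1))
  expect_true(all(out$contextual_score >= context_params()$floor_score))
})

test_that("low-scoring context-free candidates are pruned", {
  bg <- plain_submucosa_image()
  weak <- manual_candidate(150, 150, 0.01)   # below the 0.05 floor
  out <- contextual_rescore(weak, bg$image, bg$layers)
  expect_equal(nrow(out), 0L)
})

test_that("max_iters must be a positive integer", {
  bg <- plain_submucosa_image()
  cand <- manual_candidate(150, 150)
  expect_error(contextual_rescore(cand, bg$image, bg$layers, max_iters = 0),
               "positive integer")
})
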