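# Ranked image sets, case-level AI score, pathologist score book.

rand_candidates <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    x = runif(n, 0, 2000), y = runif(n, 0, 2000),
    box_w = 100, box_h = 100,
    base_score = runif(n), contextual_score = runif(n)
  ))
}

test_that("60 candidates triage into 12 full sets of 3 (36 patches)", {
  sets <- build_image_sets(rand_candidates(60))
  expect_equal(nrow(sets), 12L)
  expect_equal(sum(sets$n_patches), 36L)
  expect_true(all(sets$n_patches == 3L))
  expect_true(all(diff(sets$set_score) <= 1e-12))   # nonincreasing with rank
})

test_that("7 candidates give sets of sizes 3, 3, 1", {
  sets <- build_image_sets(rand_candidates(7))
  expect_equal(sets$n_patches, c(3L, 3L, 1L))
  expect_equal(nrow(build_image_sets(rand_candidates(0))), 0L)
})

test_that("the selected 36 are exactly the top-36 contextual scores", {
  cand <- rand_candidates(80, seed = 4)
  cand$contextual_score[1:10] <- cand$contextual_score[11:20]   # force ties
  sets <- build_image_sets(cand)
  chosen <- sort(unlist(lapply(sets$members, function(m) m$ai_score)),
                 decreasing = TRUE)
  oracle <- sort(cand$contextual_score, decreasing = TRUE)[1:36]
  expect_equal(chosen, oracle)
  # set score is the best member
  for (i in seq_len(nrow(sets))) {
    expect_equal(sets$set_score[i], max(sets$members[[i]]$ai_score))
  }
})

test_that("case AI score averages the three best sets", {
  expect_equal(case_ai_score(c(0.9, 0.8, 0.7, 0.2)), 0.8)
  expect_equal(case_ai_score(c(0.5)), 0.5)
  expect_equal(case_ai_score(numeric(0)), 0)
  sets <- build_image_sets(rand_candidates(20, seed = 9))
  expect_equal(case_ai_score(sets),
               mean(sort(sets$set_score, decreasing = TRUE)[1:3]))
})

test_that("pathologist scores validate and are immutable", {
  sets <- build_image_sets(rand_candidates(9))
  rec <- case_record("case_007", sets)
  rec <- record_pathologist_scores(rec, "p2", c(5, 1, 1))
  expect_equal(rec$pathologist_scores$p2, c(5L, 1L, 1L))
  expect_error(record_pathologist_scores(rec, "p2", c(4, 1, 1)), "immutable")
  expect_error(record_pathologist_scores(rec, "p3", c(6, 1, 1)), "1..5")
  expect_error(record_pathologist_scores(rec, "p3", c(5, 1)), "3 sets")
  td <- tidy(rec)
  expect_equal(td$score_p2, c(5L, 1L, 1L))
  expect_equal(glance(rec)$n_sets, 3L)
})

test_that("patches include the box plus margin and clip at borders", {
  img <- array(runif(120 * 120 * 3), dim = c(120, 120, 3))
  p <- extract_patch(img, 60, 60, box_px = 40, margin_px = 10)
  expect_equal(dim(p)[1:2], c(61, 61))
  corner <- extract_patch(img, 0, 0, box_px = 40, margin_px = 10)
  expect_lte(dim(corner)[1], 32)
  expect_gt(dim(corner)[1], 0)
})

test_that("patch area fraction matches direct arithmetic", {
  det <- fixture_detection()
  rc <- contextual_rescore(det$candidates, det$bundle$image, det$layers)
  sets <- build_image_sets(rc)
  pf <- patch_area_fraction(sets, det$layers)
  manual_patch <- sum(unlist(lapply(sets$members, function(m) m$box_w * m$box_h)))
  manual_tissue <- sum(det$layers$labels != 0L)
  expect_equal(pf$patch_area_px, manual_patch)
  expect_equal(pf$tissue_area_px, manual_tissue)
  expect_equal(pf$fraction, manual_patch / manual_tissue)
  expect_lt(pf$fraction, 1)
})

test_that("exported image sets match their manifest", {
  det <- fixture_detection()
  rc <- contextual_rescore(det$candidates, det$bundle$image, det$layers)
  rec <- case_record("case_001", build_image_sets(rc))
  dir <- withr::local_tempdir()
  path <- export_image_sets(rec, det$bundle$image, dir, config_hash = "abc")
  man <- jsonlite::read_json(path)
  expect_equal(man$case_id, "case_001")
  expect_equal(length(man$sets), nrow(rec$sets))
  pngs <- list.files(file.path(dir, "case_001"), pattern = "\\.png$")
  expect_equal(length(pngs), sum(rec$sets$n_patches))
})
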