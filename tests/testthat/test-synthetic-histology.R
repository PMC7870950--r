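# Synthetic slide and cohort generator: determinism, placement soundness,
# morphology-independent invariants.

test_that("a spec without ganglia yields no ganglion polygons", {
  b <- generate_slide(small_spec(seed = 1, n_mature_ganglia = 0L,
                                 n_immature_ganglia = 0L))
  expect_false(any(b$annotations$label %in% c("mature_ganglion",
                                              "immature_ganglion")))
})

test_that("the same spec and seed reproduce the bundle exactly", {
  b1 <- generate_slide(small_spec(seed = 42))
  b2 <- generate_slide(small_spec(seed = 42))
  expect_identical(b1$image, b2$image)
  expect_identical(b1$layers$labels, b2$layers$labels)
  expect_equal(b1$annotations$polygon, b2$annotations$polygon)
  b3 <- generate_slide(small_spec(seed = 43))
  expect_false(identical(b1$image, b3$image))
})

test_that("20 requested mature ganglia are all placed in permissible layers", {
  sp <- slide_spec(width_px = 1024L, height_px = 1024L,
                   n_mature_ganglia = 20L, n_immature_ganglia = 0L,
                   cluster_size_mean = 3, seed = 7)
  b <- generate_slide(sp)
  g <- b$annotations[b$annotations$label == "mature_ganglion", ]
  expect_equal(nrow(g), 20L)
  cen <- t(vapply(g$polygon, ganglia:::polygon_centroid, numeric(2)))
  expect_true(all(is_permissible_location(cen, b$layers)))
})

test_that("ganglion polygons lie entirely within permissible bands; mimics never do", {
  for (seed in c(3, 9, 27)) {
    b <- fixture_bundle(seed * 100 + 1)
    ann <- b$annotations
    for (i in seq_len(nrow(ann))) {
      p <- ann$polygon[[i]]
      expect_gt(ganglia:::polygon_area(p), 0)
      if (ann$label[i] %in% c("mature_ganglion", "immature_ganglion")) {
        expect_true(all(is_permissible_location(p, b$layers)),
                    info = sprintf("seed %d polygon %d", seed, i))
      }
      if (ann$label[i] == "mimic") {
        cen <- ganglia:::polygon_centroid(p)
        expect_false(is_permissible_location(cen, b$layers),
                     info = sprintf("seed %d mimic %d", seed, i))
      }
    }
  }
})

test_that("bands too thin for a ganglion raise an explicit error", {
  sp <- small_spec(seed = 1,
                   layer_band_fractions = c(epithelium = 0.1, mucosa = 0.5,
                                            submucosa = 0.05, muscularis = 0.05,
                                            serosa = 0.1))
  expect_error(generate_slide(sp), "tall enough")
})

test_that("invalid specs are rejected up front", {
  expect_error(slide_spec(layer_band_fractions = c(epithelium = 0.5, mucosa = 0.5,
                                                   submucosa = 0.3, muscularis = 0.1,
                                                   serosa = 0)),
               "sum to at most 1")
  expect_error(slide_spec(n_mature_ganglia = -1))
  expect_error(slide_spec(noise_level = -0.1))
})

test_that("cohort labels drive ganglion content and layer structure", {
  base <- small_spec(seed = 0)
  co <- generate_cohort(10, hscr_fraction = 0.5, seed = 11, base_spec = base)
  n_gang <- vapply(co$bundle, function(b) {
    sum(b$annotations$label %in% c("mature_ganglion", "immature_ganglion"))
  }, numeric(1))
  expect_equal(sum(n_gang == 0), 5L)
  expect_true(all(n_gang[co$label == "non-HSCR"] >= 1))
  expect_setequal(co$label[n_gang == 0], "HSCR")
})

test_that("inadequate cases contain no submucosa, muscularis or ganglia", {
  co <- generate_cohort(4, hscr_fraction = 0.25, inadequate_fraction = 0.5,
                        seed = 2, base_spec = small_spec(seed = 0))
  inad <- co$bundle[co$label == "inadequate"]
  expect_gte(length(inad), 1)
  for (b in inad) {
    expect_equal(sum(b$layers$labels %in% c(3L, 4L)), 0)
    expect_false(any(b$annotations$label %in% c("mature_ganglion",
                                                "immature_ganglion")))
  }
})

test_that("cohort generation is deterministic and the empty cohort is valid", {
  co1 <- generate_cohort(8, 0.4, 0.1, seed = 9, base_spec = small_spec(seed = 0))
  co2 <- generate_cohort(8, 0.4, 0.1, seed = 9, base_spec = small_spec(seed = 0))
  expect_identical(co1$label, co2$label)
  expect_identical(co1$bundle[[3]]$image, co2$bundle[[3]]$image)
  expect_equal(nrow(generate_cohort(0, 0.5, seed = 1)), 0L)
  expect_error(generate_cohort(4, 0.8, 0.4, seed = 1), "at most 1")
})
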