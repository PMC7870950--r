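# Cell-level metrics and cohort consultation statistics.

square_at <- function(cx, cy, half = 5) {
  cbind(x = c(cx - half, cx + half, cx + half, cx - half),
        y = c(cy - half, cy - half, cy + half, cy + half))
}

test_that("sensitivity is plain detected-over-total arithmetic", {
  centers <- expand.grid(x = seq(50, 950, by = 100), y = seq(50, 950, by = 100))
  polys <- lapply(seq_len(100), function(i) square_at(centers$x[i], centers$y[i]))
  truth <- annotation_set(rep("mature_ganglion", 100), polys)
  det <- tibble::tibble(x = centers$x[1:96], y = centers$y[1:96])
  m <- cell_level_metrics(det, truth, decoys = matrix(numeric(0), ncol = 2))
  expect_equal(m$sensitivity_pct, 96)
  expect_equal(m$n_detected, 96L)
})

test_that("no detections means perfect specificity and zero sensitivity", {
  truth <- annotation_set("mature_ganglion", list(square_at(10, 10)))
  decoys <- cbind(runif(50, 100, 500), runif(50, 100, 500))
  m <- cell_level_metrics(tibble::tibble(x = numeric(0), y = numeric(0)),
                          truth, decoys = decoys)
  expect_equal(m$specificity_pct, 100)
  expect_equal(m$sensitivity_pct, 0)
})

test_that("zero truth polygons give NA sensitivity, not 0", {
  truth <- annotation_set()
  m <- cell_level_metrics(tibble::tibble(x = 1, y = 1), truth,
                          decoys = cbind(100, 100))
  expect_true(is.na(m$sensitivity_pct))
  expect_false(is.na(m$specificity_pct))
})

test_that("metrics equal the brute-force recount on random fixtures", {
  withr::with_seed(33, {
    for (rep in 1:5) {
      n_t <- sample(3:12, 1)
      polys <- lapply(seq_len(n_t), function(i) {
        square_at(runif(1, 50, 550), runif(1, 50, 550), half = runif(1, 5, 30))
      })
      truth <- annotation_set(rep("immature_ganglion", n_t), polys)
      det <- tibble::tibble(x = runif(20, 0, 600), y = runif(20, 0, 600))
      decoys <- cbind(runif(40, 0, 600), runif(40, 0, 600))
      m <- cell_level_metrics(det, truth, decoys = decoys, decoy_radius_px = 30)
      o <- oracle_cell_metrics(det$x, det$y, polys, decoys, 30)
      expect_equal(m$n_detected, o$detected)
      expect_equal(m$n_false_alarm, o$false_alarm)
      expect_equal(m$sensitivity_pct, 100 * o$detected / n_t)
      expect_equal(m$specificity_pct, 100 * (40 - o$false_alarm) / 40)
    }
  })
})

test_that("decoys sampled from negative regions avoid truth polygons", {
  truth <- annotation_set("mature_ganglion", list(square_at(100, 100, 40)))
  region <- list(cbind(x = c(0, 300, 300, 0), y = c(0, 0, 300, 300)))
  m <- cell_level_metrics(tibble::tibble(x = numeric(0), y = numeric(0)),
                          truth, negative_regions = region, n_decoys = 120,
                          seed = 4)
  expect_equal(m$n_decoys, 120L)
  dec <- ganglia:::sample_decoys(region, 120, truth$polygon, 4)
  expect_false(any(ganglia:::points_in_polygon(dec, truth$polygon[[1]])))
})

test_that("consultation statistics reproduce the printed cohort numbers", {
  flags <- flags_tibble(printed_flag_matrix())
  rep48 <- consultation_statistics(flags)
  expect_equal(rep48$per_observer$n_consult[order(rep48$per_observer$observer)],
               c(18, 10, 29, 18))
  cross <- rep48$cross_observer
  expect_equal(cross$pct[cross$k == 4], 18.75)
  expect_equal(cross$pct[cross$k == 3], 10.42)
  expect_equal(cross$pct[cross$k == 2], 18.75)
  expect_equal(cross$pct[cross$k == 1], 12.5)
  expect_equal(cross$n_cases[1], 48)

  # per-observer rates over the full 50-case cohort (two conclusive-only
  # exclusions return as unflagged cases): the printed 20-58% range
  m50 <- rbind(printed_flag_matrix(), matrix(FALSE, 2, 4))
  rep50 <- consultation_statistics(flags_tibble(m50))
  rates <- sort(rep50$per_observer$rate_pct)
  expect_equal(min(rates), 20)
  expect_equal(max(rates), 58)
  expect_equal(glance(rep50)$max_rate_pct, 58)
})

test_that("consultation statistics equal a brute-force recount", {
  withr::with_seed(44, {
    for (rep in 1:4) {
      n_case <- sample(10:40, 1); n_obs <- sample(2:5, 1)
      m <- matrix(runif(n_case * n_obs) < 0.3, n_case, n_obs,
                  dimnames = list(NULL, paste0("o", seq_len(n_obs))))
      rep_got <- consultation_statistics(flags_tibble(m))
      expect_equal(rep_got$per_observer$n_consult[order(rep_got$per_observer$observer)],
                   unname(colSums(m)))
      ks <- rowSums(m)
      for (k in 0:n_obs) {
        expect_equal(rep_got$cross_observer$n_cases_exactly_k[rep_got$cross_observer$k == k],
                     sum(ks == k))
      }
      expect_equal(rep_got$cross_observer$pct,
                   round(100 * rep_got$cross_observer$n_cases_exactly_k / n_case, 2))
    }
  })
})

test_that("observers with different case sets are rejected; zero flags give zero rates", {
  bad <- tibble::tibble(case_id = c("a", "b", "a"),
                        observer = c("o1", "o1", "o2"),
                        needs_consultation = FALSE)
  expect_error(consultation_statistics(bad), "different case sets")
  none <- flags_tibble(matrix(FALSE, 10, 3))
  rep0 <- consultation_statistics(none)
  expect_true(all(rep0$per_observer$rate_pct == 0))
  expect_equal(rep0$cross_observer$pct[rep0$cross_observer$k == 0], 100)
})

test_that("cohort reports serialize to JSON and CSV", {
  rep48 <- consultation_statistics(flags_tibble(printed_flag_matrix()))
  pj <- withr::local_tempfile(fileext = ".json")
  pc <- withr::local_tempfile(fileext = ".csv")
  write_cohort_report(rep48, pj, pc)
  back <- jsonlite::read_json(pj)
  expect_equal(back$n_cases, 48L)
  expect_equal(nrow(utils::read.csv(pc)), 4L)
})
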