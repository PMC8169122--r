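# FUCCI track generator: fate realisation, determinism, event structure.

allocs <- fig_fate_allocations()

test_that("count-based allocations are realised exactly in truth labels", {
  co <- make_fucci_cohort(allocs$cis_G1, default_params, seed = 2)
  truth <- table(vapply(co, `[[`, character(1), "truth_fate"))
  expect_identical(as.integer(truth[c("SINGLE_DIV", "G2_EXIT", "SG2_ARREST")]),
                   c(7L, 40L, 3L))
  expect_error(make_fucci_cohort(allocs$cis_G1, default_params, n = 49),
               "sum to")
})

test_that("an all-proliferative cohort always divides at least twice", {
  co <- make_fucci_cohort(fate_allocation("untreated", PROLIF = 20),
                          default_params, noise_sd = 0, seed = 3)
  expect_true(all(vapply(co, `[[`, numeric(1), "n_divisions_truth") >= 2))
})

test_that("cohorts are byte-identical across reruns with the same seed", {
  small <- fate_allocation("G1/S", PROLIF = 5, SINGLE_DIV = 5, G2_EXIT = 5)
  a <- make_fucci_cohort(small, default_params, seed = 7)
  b <- make_fucci_cohort(small, default_params, seed = 7)
  expect_identical(a, b)
  c2 <- make_fucci_cohort(small, default_params, seed = 8)
  expect_false(identical(a, c2))
})

test_that("track events are well formed", {
  co <- make_fucci_cohort(allocs$cis_G1S_palbo, default_params, seed = 5)
  for (tr in co) {
    ev <- tr$events
    expect_false(is.unsorted(ev$time_min))
    anas <- ev$time_min[ev$event == "ANAPHASE"]
    nebd <- ev$time_min[ev$event == "NEBD"]
    # every anaphase has a NEBD within 3 h before it
    for (a in anas) {
      expect_true(any(nebd < a & a - nebd <= 180))
    }
    expect_identical(tr$n_divisions_truth, length(anas))
    # nothing after death; frames span at most 72 h
    if (any(ev$event == "DEATH")) {
      expect_identical(which.max(ev$time_min),
                       which(ev$event == "DEATH"))
    }
    expect_lte(max(tr$frames$time_min), 72 * 60)
  }
})

test_that("fate trajectories realise their defining features", {
  co <- make_fucci_cohort(allocs$cis_G1, default_params,
                          noise_sd = 0, seed = 9)
  truth <- vapply(co, `[[`, character(1), "truth_fate")
  g2exit <- co[truth == "G2_EXIT"][[1]]
  # a G2-exit shows a long green run ending in red without anaphase
  ph <- g2exit$frames$truth_phase
  r <- rle(ph)
  green_h <- max(r$lengths[r$values == "S/G2/M"]) * 0.5
  expect_gte(green_h, 20)
  expect_identical(r$values[length(r$values)], "G1")
  expect_identical(g2exit$n_divisions_truth, 0L)
  expect_true("G2_EXIT" %in% g2exit$events$event)
  # arrested tracks enlarge over the movie
  area <- g2exit$frames$area_um2
  expect_gt(area[length(area)] / area[1], 1.5)
})

test_that("noiseless tracks reproduce truth phases; noisy agreement >= 99%", {
  co0 <- make_fucci_cohort(fate_allocation("untreated", PROLIF = 10),
                           default_params, noise_sd = 0, seed = 4)
  for (tr in co0) {
    expect_identical(call_phase_track(tr), tr$frames$truth_phase)
  }
  co <- make_fucci_cohort(allocs$cis_G1S_thy, default_params, seed = 4)
  agree <- vapply(co, function(tr) {
    mean(call_phase_track(tr) == tr$frames$truth_phase)
  }, numeric(1))
  expect_gte(mean(agree), 0.99)
})

test_that("track CSVs round-trip through disk", {
  co <- make_fucci_cohort(fate_allocation("lateS", SINGLE_DIV = 4, DAM = 2),
                          default_params, seed = 12)
  dir <- tempfile("tracks")
  write_tracks(co, dir)
  back <- read_tracks(dir)
  expect_identical(length(back), 6L)
  expect_equal(back[[3]]$frames$red, co[[3]]$frames$red)
  expect_identical(back[[3]]$truth_fate, co[[3]]$truth_fate)
  expect_equal(back[[3]]$events$time_min, co[[3]]$events$time_min)
  unlink(dir, recursive = TRUE)
})

test_that("probability allocations sample fates and invalid labels error", {
  pa <- fate_allocation("G1/S", PROLIF = 0.5, G2_EXIT = 0.5)
  co <- make_fucci_cohort(pa, default_params, n = 30, seed = 6)
  expect_true(all(vapply(co, `[[`, character(1), "truth_fate") %in%
                    c("PROLIF", "G2_EXIT")))
  expect_error(fate_allocation("G1", NOT_A_FATE = 1), "unknown fate")
  expect_error(fate_allocation("G1", PROLIF = -1), "non-negative")
  expect_error(fate_allocation("somewhere", PROLIF = 1))
})
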