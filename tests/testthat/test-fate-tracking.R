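# Phase calling, division events, fate classification and aggregation.

allocs <- fig_fate_allocations()

test_that("phase calling follows the colour semantics", {
  n <- 20
  tr <- data.frame(red = rep(100, n), green = rep(0, n))
  expect_true(all(call_phase_track(tr) == "G1"))
  tr2 <- data.frame(red = c(rep(100, 8), rep(0, 12)),
                    green = c(rep(0, 4), rep(100, 16)))
  got <- call_phase_track(tr2)
  expect_identical(got, c(rep("G1", 4), rep("G1/S", 4), rep("S/G2/M", 12)))
  # runs shorter than min_run are merged into the flanking phase
  tr3 <- data.frame(red = c(rep(100, 6), 0, rep(100, 6)),
                    green = c(rep(0, 6), 100, rep(0, 6)))
  expect_true(all(call_phase_track(tr3, min_run = 2) == "G1"))
  expect_error(call_phase_track(data.frame(red = 1:5)), "green")
  expect_error(call_phase_track(tr, red_threshold = 0), "red_threshold")
})

test_that("DEAD is absorbing in phase calls", {
  tr <- data.frame(red = c(100, 100, 0, 0), green = c(0, 0, 0, 0),
                   alive = c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(call_phase_track(tr), c("G1", "G1", "DEAD", "DEAD"))
})

test_that("annotated division events are paired and validated", {
  tr <- list(
    frames = data.frame(time_min = seq(0, 720, 30), red = 100, green = 0),
    events = data.frame(event = c("NEBD", "ANAPHASE", "NEBD", "ANAPHASE"),
                        time_min = c(600, 630, 1860, 1890))
  )
  pairs <- detect_division_events(tr)
  expect_identical(nrow(pairs), 2L)
  expect_equal(mitotic_length(pairs), c(30, 30))
  expect_equal(interphase_length(pairs), 1860 - 630)
  # anaphase without a NEBD in window is dropped with a warning
  bad <- list(frames = tr$frames,
              events = data.frame(event = "ANAPHASE", time_min = 500))
  expect_warning(p2 <- detect_division_events(bad), "no NEBD")
  expect_identical(nrow(p2), 0L)
  # no events at all
  none <- list(frames = tr$frames,
               events = data.frame(event = character(0),
                                   time_min = numeric(0)))
  expect_identical(nrow(detect_division_events(none)), 0L)
})

test_that("area-drop proxy recovers division times within one frame", {
  co <- make_fucci_cohort(fate_allocation("untreated", PROLIF = 8),
                          default_params, noise_sd = 0, seed = 21)
  for (tr in co) {
    truth <- tr$events$time_min[tr$events$event == "ANAPHASE"]
    prox <- detect_division_events(tr, use_annotations = FALSE)
    expect_identical(nrow(prox), length(truth))
    expect_true(all(abs(prox$anaphase_min - truth) <= 30))
  }
})

test_that("cohort mitotic lengths recover the generator parameter", {
  p45 <- cell_cycle_params(mitotic_length_minutes = 45)
  co <- make_fucci_cohort(fate_allocation("untreated", PROLIF = 40),
                          p45, seed = 31)
  ml <- unlist(lapply(co, function(tr) {
    mitotic_length(detect_division_events(tr))
  }))
  expect_lt(abs(mean(ml) - 45), 2)
})

test_that("fate decision order handles each archetype", {
  mk <- function(red, green, events = NULL, alive = NULL) {
    n <- length(red)
    fr <- data.frame(time_min = seq(0, by = 30, length.out = n),
                     red = red, green = green)
    if (!is.null(alive)) fr$alive <- alive
    structure(list(frames = fr, events = events), class = "fucci_track")
  }
  n <- 145
  # three anaphases -> PROLIF
  ev3 <- data.frame(event = rep(c("NEBD", "ANAPHASE"), 3),
                    time_min = c(570, 600, 1570, 1600, 2570, 2600))
  tr <- mk(rep(100, n), rep(0, n), ev3)
  expect_identical(classify_fate(tr)$fate, "PROLIF")
  expect_identical(classify_fate(tr)$n_divisions, 3L)
  # green >= 20 h then red, no anaphase -> G2_EXIT
  g_run <- rep(c(0, 100, 0), c(10, 45, 90))
  r_run <- rep(c(100, 0, 100), c(10, 45, 90))
  expect_identical(classify_fate(mk(r_run, g_run))$fate, "G2_EXIT")
  # green run shorter than the criterion, red tail -> not G2_EXIT
  g2 <- rep(c(0, 100, 0), c(10, 30, 105))
  r2 <- rep(c(100, 0, 100), c(10, 30, 105))
  expect_false(classify_fate(mk(r2, g2))$fate == "G2_EXIT")
  # death without division -> DBM; with one division -> DAM
  evd <- data.frame(event = "DEATH", time_min = 1200)
  alive <- rep(c(TRUE, FALSE), c(41, n - 41))
  expect_identical(classify_fate(mk(rep(100, n), rep(0, n), evd,
                                    alive))$fate, "DBM")
  evd2 <- data.frame(event = c("NEBD", "ANAPHASE", "DEATH"),
                     time_min = c(570, 600, 1200))
  expect_identical(classify_fate(mk(rep(100, n), rep(0, n), evd2,
                                    alive))$fate, "DAM")
  # one division, never green again -> G1_AAM; green re-entry -> SINGLE_DIV
  ev1 <- data.frame(event = c("NEBD", "ANAPHASE"), time_min = c(570, 600))
  expect_identical(classify_fate(mk(rep(100, n), rep(0, n), ev1))$fate,
                   "G1_AAM")
  g_re <- c(rep(0, 60), rep(100, 85))
  r_re <- c(rep(100, 60), rep(0, 85))
  expect_identical(classify_fate(mk(r_re, g_re, ev1))$fate, "SINGLE_DIV")
  # red throughout, nothing else -> G1_ABM; green tail -> SG2_ARREST
  expect_identical(classify_fate(mk(rep(100, n), rep(0, n)))$fate, "G1_ABM")
  g_t <- c(rep(0, 20), rep(100, 125))
  r_t <- c(rep(100, 20), rep(0, 125))
  expect_identical(classify_fate(mk(r_t, g_t))$fate, "SG2_ARREST")
  # all-GAP -> UNCLASSIFIABLE
  expect_identical(classify_fate(mk(rep(0, n), rep(0, n)))$fate,
                   "UNCLASSIFIABLE")
})

test_that("lowering the G2-exit criterion never loses G2_EXIT calls", {
  co <- make_fucci_cohort(allocs$cis_G1, default_params, seed = 13)
  count_g2e <- function(h) {
    sum(vapply(co, function(tr) {
      classify_fate(tr, g2_exit_min_green_hours = h)$fate
    }, character(1)) == "G2_EXIT")
  }
  hs <- c(30, 25, 20, 15, 10)
  counts <- vapply(hs, count_g2e, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("exposure-phase labelling maps protocols and offsets", {
  expect_identical(label_exposure_phase("palbo_release", 0), "G1")
  expect_identical(label_exposure_phase("palbo_release", 6), "G1/S")
  expect_identical(label_exposure_phase("thy_release", -2), "G1/S")
  expect_identical(label_exposure_phase("thy_release", 4), "lateS")
  expect_error(label_exposure_phase("palbo_release", 20), "range")
  expect_error(label_exposure_phase("unknown_protocol", 0))
})

test_that("cohort aggregation fractions are consistent with division counts", {
  cohorts <- list(palbo = allocs$cis_G1S_palbo, thy = allocs$cis_G1S_thy,
                  lateS = allocs$cis_lateS)
  for (nm in names(cohorts)) {
    co <- make_fucci_cohort(cohorts[[nm]], default_params, seed = 17)
    calls <- lapply(co, classify_fate)
    agg <- aggregate_cohort(calls, nm)
    ft <- agg$fate_table
    expect_equal(sum(ft$fraction), 1)
    # PROLIF fraction == fraction of tracks with >= 2 divisions (identity)
    ndiv <- vapply(calls, `[[`, numeric(1), "n_divisions")
    expect_equal(ft$fraction[ft$fate == "PROLIF"], mean(ndiv >= 2))
    dv <- agg$divisions
    expect_identical(sum(dv$count), 50L)
  }
  expect_error(aggregate_cohort(list()), "at least one")
})

test_that("phase fractions sum to one and recover an all-G1 snapshot", {
  n <- 10
  co <- lapply(seq_len(n), function(i) {
    structure(list(
      track_id = i,
      frames = data.frame(time_min = seq(0, 120, 30), red = 100, green = 0),
      events = NULL
    ), class = "fucci_track")
  })
  pf <- phase_fractions(structure(co, class = c("fucci_cohort", "list")))
  expect_true(all(pf$red == 1 & pf$yellow == 0 & pf$green == 0))
  expect_error(phase_fractions(structure(list(),
                                         class = c("fucci_cohort", "list"))),
               "empty")
})
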