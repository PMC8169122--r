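## Single-cell FUCCI trajectory generator.
##
## Each track realises one fate from the eight-label ontology as a piecewise
## colour schedule (red / yellow / green / gap), an event list (NEBD,
## ANAPHASE, DEATH, G2_EXIT) and a nuclear-area trajectory, sampled at the
## configured cadence over a 72 h horizon. Intensities are in arbitrary
## units with full reporter signal at 100; the frame-level ground-truth phase
## is derived from the noiseless intensities with the same threshold rule the
## phase caller uses, so a noiseless track is recovered exactly.

FUCCI_FULL <- 100          # full reporter intensity (arbitrary units)
TRACK_HORIZON_H <- 72

# Sample one lognormal duration.
sdur <- function(mean, cv) rlnorm_mcv(1L, mean, cv)

# Time (h) from exposure to S entry, and cell age at exposure, per phase.
exposure_position <- function(phase, p) {
  switch(phase,
    "G1" = list(to_s = sdur(p$g1_release_to_s_hours, p$duration_cv),
                age = p$g1_hours - p$g1_release_to_s_hours),
    "G1/S" = list(to_s = 0, age = p$g1_hours),
    "earlyS" = list(to_s = -p$g1s_overlap_hours / 2,
                    age = p$g1_hours + p$g1s_overlap_hours / 2),
    "lateS" = list(to_s = -(p$s_hours - 2),
                   age = p$g1_hours + p$s_hours - 2),
    "G2/M" = list(to_s = -p$s_hours, age = p$g1_hours + p$s_hours),
    "untreated" = {
      T <- p$g1_hours + p$s_hours + p$g2_hours + p$m_hours
      age <- -T * log2(1 - runif(1) / 2) # steady-state age density
      list(to_s = p$g1_hours - age, age = age)
    },
    stop("unknown exposure phase: ", phase, call. = FALSE)
  )
}

# Build the colour segments and events of one full mitotic cycle starting at
# `t0` with `to_s` hours until S entry (negative: already inside S or G2).
# Returns list(segments, events, anaphase_time).
build_cycle <- function(t0, to_s, p) {
  ml_h <- p$mitotic_length_minutes / 60
  g1_end <- t0 + max(to_s, 0)
  ov <- p$g1s_overlap_hours
  s_entry <- t0 + to_s # may precede t0
  yellow_end <- s_entry + ov
  s_end <- s_entry + sdur(p$s_hours, p$duration_cv)
  nebd <- s_end + sdur(p$g2_hours, p$duration_cv)
  # cells exposed late in the cycle still need a forward-time mitosis
  nebd <- max(nebd, t0 + 0.25)
  ana <- nebd + ml_h
  seg <- data.frame(
    t_start = c(t0, max(t0, s_entry), max(t0, yellow_end)),
    t_end = c(max(t0, s_entry), max(t0, yellow_end), ana),
    colour = c("red", "yellow", "green"),
    stringsAsFactors = FALSE
  )
  seg <- seg[seg$t_end > seg$t_start, , drop = FALSE]
  list(
    segments = seg,
    events = data.frame(event = c("NEBD", "ANAPHASE"), time_h = c(nebd, ana),
                        stringsAsFactors = FALSE),
    anaphase = ana,
    yellow_window = c(max(t0, s_entry), max(t0, yellow_end))
  )
}

# Assemble the full schedule for one track. Returns a list with segments
# (t_start, t_end, colour), events (event, time_h), death (or Inf),
# divisions (anaphase times), arrest_start (or Inf), birth_age.
build_fate_schedule <- function(fate, phase, p, horizon = TRACK_HORIZON_H) {
  pos <- exposure_position(phase, p)
  ov <- p$g1s_overlap_hours
  gap_h <- p$frame_interval_minutes / 60 # one colourless frame after anaphase

  n_cycles_to <- function(n, max_last_ana) {
    # sample chained cycles until `n` anaphases land before `max_last_ana`
    for (try in 1:500) {
      segs <- list(); evs <- list(); anas <- numeric(0)
      t0 <- 0; to_s <- pos$to_s
      while (length(anas) < n) {
        cy <- build_cycle(t0, to_s, p)
        segs[[length(segs) + 1L]] <- cy$segments
        evs[[length(evs) + 1L]] <- cy$events
        anas <- c(anas, cy$anaphase)
        t0 <- cy$anaphase + gap_h
        to_s <- sdur(p$g1_hours, p$duration_cv)
      }
      if (anas[n] <= max_last_ana) {
        return(list(segments = do.call(rbind, segs),
                    events = do.call(rbind, evs), anaphases = anas))
      }
      pos <- exposure_position(phase, p) # resample starting position too
    }
    stop("could not realise ", n, " divisions within the horizon; ",
         "cell-cycle durations are too long for fate '", fate, "'",
         call. = FALSE)
  }

  add_gap <- function(segments, anaphases) {
    # insert a one-frame colourless gap after each anaphase
    gaps <- data.frame(t_start = anaphases, t_end = anaphases + gap_h,
                       colour = "gap", stringsAsFactors = FALSE)
    rbind(segments[, c("t_start", "t_end", "colour")], gaps)
  }

  arrest_green_tail <- function(t_from) {
    # prolonged S/G2 arrest: green from t_from to horizon
    data.frame(t_start = t_from, t_end = horizon, colour = "green",
               stringsAsFactors = FALSE)
  }

  out <- switch(fate,
    PROLIF = {
      # keep cycling past the horizon; at least two completed divisions
      base <- n_cycles_to(2, horizon - 1e-9)
      segs <- base$segments; evs <- base$events; anas <- base$anaphases
      t0 <- anas[length(anas)] + gap_h
      while (t0 < horizon) {
        cy <- build_cycle(t0, sdur(p$g1_hours, p$duration_cv), p)
        if (cy$anaphase > horizon) {
          segs <- rbind(segs[, 1:3],
                        within(cy$segments, t_end <- pmin(t_end, horizon)))
          evs <- rbind(evs, cy$events[cy$events$time_h <= horizon, ])
          break
        }
        segs <- rbind(segs[, 1:3], cy$segments)
        evs <- rbind(evs, cy$events)
        anas <- c(anas, cy$anaphase)
        t0 <- cy$anaphase + gap_h
      }
      list(segments = add_gap(segs, anas), events = evs, divisions = anas,
           death = Inf, arrest_start = Inf)
    },
    SINGLE_DIV = {
      base <- n_cycles_to(1, horizon - 16)
      ana <- base$anaphases[1]
      g1d <- sdur(p$g1_hours, p$duration_cv)
      s_re <- min(ana + gap_h + g1d, horizon - 4) # daughter re-enters S
      segs <- rbind(
        base$segments[, 1:3],
        data.frame(t_start = ana + gap_h, t_end = s_re, colour = "red"),
        data.frame(t_start = s_re, t_end = s_re + ov, colour = "yellow"),
        arrest_green_tail(s_re + ov)
      )
      list(segments = add_gap(segs, ana), events = base$events,
           divisions = ana, death = Inf, arrest_start = s_re + ov)
    },
    G2_EXIT = {
      green_dur <- max(sdur(p$s_hours, p$duration_cv) +
                         sdur(p$g2_exit_arrest_hours, p$duration_cv),
                       0.75 * (p$s_hours + p$g2_exit_arrest_hours))
      s_entry <- max(pos$to_s, 0)
      y_end <- max(s_entry + ov, 0)
      t_exit <- min(y_end + green_dur, horizon - 3)
      segs <- rbind(
        data.frame(t_start = 0, t_end = s_entry, colour = "red"),
        data.frame(t_start = s_entry, t_end = y_end, colour = "yellow"),
        data.frame(t_start = y_end, t_end = t_exit, colour = "green"),
        data.frame(t_start = t_exit, t_end = horizon, colour = "red")
      )
      segs <- segs[segs$t_end > segs$t_start, , drop = FALSE]
      list(segments = segs,
           events = data.frame(event = "G2_EXIT", time_h = t_exit),
           divisions = numeric(0), death = Inf,
           arrest_start = y_end + sdur(p$s_hours, p$duration_cv))
    },
    SG2_ARREST = {
      s_entry <- max(pos$to_s, 0)
      y_end <- max(s_entry + ov, 0)
      segs <- rbind(
        data.frame(t_start = 0, t_end = s_entry, colour = "red"),
        data.frame(t_start = s_entry, t_end = y_end, colour = "yellow"),
        arrest_green_tail(y_end)
      )
      segs <- segs[segs$t_end > segs$t_start, , drop = FALSE]
      list(segments = segs, events = NULL, divisions = numeric(0),
           death = Inf, arrest_start = y_end + sdur(p$s_hours, p$duration_cv))
    },
    G1_ABM = {
      list(segments = data.frame(t_start = 0, t_end = horizon,
                                 colour = "red"),
           events = NULL, divisions = numeric(0), death = Inf,
           arrest_start = sdur(p$g1_hours, p$duration_cv) / 2)
    },
    G1_AAM = {
      base <- n_cycles_to(1, horizon - 14)
      ana <- base$anaphases[1]
      segs <- rbind(
        base$segments[, 1:3],
        data.frame(t_start = ana + gap_h, t_end = horizon, colour = "red")
      )
      list(segments = add_gap(segs, ana), events = base$events,
           divisions = ana, death = Inf,
           arrest_start = ana + sdur(p$g1_hours, p$duration_cv))
    },
    DBM = {
      s_entry <- max(pos$to_s, 0)
      y_end <- max(s_entry + ov, 0)
      death <- min(y_end + runif(1, 3, 14), horizon - 1)
      segs <- rbind(
        data.frame(t_start = 0, t_end = s_entry, colour = "red"),
        data.frame(t_start = s_entry, t_end = y_end, colour = "yellow"),
        data.frame(t_start = y_end, t_end = death, colour = "green")
      )
      segs <- segs[segs$t_end > segs$t_start, , drop = FALSE]
      list(segments = segs,
           events = data.frame(event = "DEATH", time_h = death),
           divisions = numeric(0), death = death, arrest_start = Inf)
    },
    DAM = {
      base <- n_cycles_to(1, horizon - 10)
      ana <- base$anaphases[1]
      death <- min(ana + gap_h + runif(1, 2, 8), horizon - 0.5)
      segs <- rbind(
        base$segments[, 1:3],
        data.frame(t_start = ana + gap_h, t_end = death, colour = "red")
      )
      evs <- rbind(base$events,
                   data.frame(event = "DEATH", time_h = death))
      list(segments = add_gap(segs, ana), events = evs, divisions = ana,
           death = death, arrest_start = Inf)
    },
    stop("unknown fate label: ", fate, call. = FALSE)
  )
  out$birth_age <- pos$age
  out
}

# Noiseless reporter intensities at time t (hours) for a schedule.
schedule_intensities <- function(times_h, schedule, p) {
  red <- numeric(length(times_h)); green <- numeric(length(times_h))
  segs <- schedule$segments
  ov <- p$g1s_overlap_hours
  for (i in seq_len(nrow(segs))) {
    inseg <- times_h >= segs$t_start[i] & times_h < segs$t_end[i]
    if (!any(inseg)) next
    switch(segs$colour[i],
      red = { red[inseg] <- FUCCI_FULL },
      yellow = {
        frac <- (times_h[inseg] - segs$t_start[i]) / ov
        red[inseg] <- FUCCI_FULL * pmax(0, 1 - frac)
        green[inseg] <- FUCCI_FULL * pmin(1, frac + 0.25)
      },
      green = { green[inseg] <- FUCCI_FULL },
      gap = { } # colourless
    )
  }
  last <- segs[nrow(segs), ]
  at_end <- times_h >= max(segs$t_end)
  if (any(at_end) && is.finite(schedule$death) == FALSE) {
    if (last$colour == "red") red[at_end] <- FUCCI_FULL
    if (last$colour == "green") green[at_end] <- FUCCI_FULL
  }
  dead <- times_h >= schedule$death
  red[dead] <- 0; green[dead] <- 0
  list(red = red, green = green, dead = dead)
}

# Nuclear-area trajectory (um^2) for a schedule.
schedule_areas <- function(times_h, schedule, p) {
  T <- p$g1_hours + p$s_hours + p$g2_hours + p$m_hours
  A0 <- p$baseline_area_um2
  divs <- sort(schedule$divisions)
  births <- c(-schedule$birth_age, divs)
  area <- numeric(length(times_h))
  for (i in seq_along(times_h)) {
    t <- times_h[i]
    tb <- max(births[births <= t], -schedule$birth_age)
    area[i] <- A0 * (1 + (t - tb) / T)
  }
  if (is.finite(schedule$arrest_start)) {
    ta <- schedule$arrest_start
    tb <- max(births[births <= ta], -schedule$birth_age)
    a_at <- A0 * (1 + (ta - tb) / T)
    arr <- times_h >= ta
    # enlargement saturates at the sixfold ceiling of the observed range
    area[arr] <- a_at * pmin(p$enlargement_rate^((times_h[arr] - ta) / 24), 6)
  }
  if (is.finite(schedule$death)) {
    dead <- times_h >= schedule$death
    if (any(dead) && any(!dead)) area[dead] <- area[which(!dead)[sum(!dead)]]
  }
  area
}

#' Generate a cohort of synthetic FUCCI tracks with known fates
#'
#' Realises a phase-dependent fate allocation as single-cell FUCCI intensity
#' tracks sampled every `frame_interval_minutes` over 72 h. With a
#' count-based allocation the fates are assigned exactly (no sampling) and
#' shuffled deterministically by the seed; a probability allocation is
#' sampled multinomially. Each track carries its frames, its event
#' annotations (NEBD, ANAPHASE, DEATH, G2_EXIT), the ground-truth fate and
#' exposure phase, and the true division count.
#'
#' @param allocation a [fate_allocation()].
#' @param params a [cell_cycle_params()].
#' @param n cohort size; for count-based allocations the counts must sum to
#'   `n` (default: the count sum). Required for probability allocations.
#' @param noise_sd additive Gaussian intensity noise (full reporter signal is
#'   100; default 5).
#' @param seed integer seed; identical seeds give byte-identical cohorts.
#' @return A list of `fucci_track` objects (class `fucci_cohort`). Each
#'   track has `track_id`, `frames` (time_min, red, green, area_um2, alive,
#'   truth_phase), `events` (event, time_min), `truth_fate`,
#'   `truth_exposure_phase`, `n_divisions_truth`.
#' @export
make_fucci_cohort <- function(allocation, params = cell_cycle_params(),
                              n = NULL, noise_sd = 5, seed = 1L) {
  stopifnot(inherits(allocation, "fate_allocation"),
            inherits(params, "cell_cycle_params"))
  vals <- allocation$values
  if (is.null(n)) {
    if (allocation$mode != "counts") {
      stop("'n' is required for probability allocations", call. = FALSE)
    }
    n <- sum(vals)
  }
  check_scalar(n, "n", 1)
  check_scalar(noise_sd, "noise_sd", 0)
  if (allocation$mode == "counts") {
    if (sum(vals) != n) {
      stop(sprintf(
        "fate counts sum to %d but the cohort size is %d", sum(vals), n
      ), call. = FALSE)
    }
    fates <- rep(names(vals), times = vals)
  } else {
    fates <- with_seed(derive_seed(seed, "fate_sampling"),
                       sample(names(vals), n, replace = TRUE, prob = vals))
  }
  fates <- with_seed(derive_seed(seed, "fate_shuffle"), sample(fates))
  dt_min <- params$frame_interval_minutes
  times_min <- seq(0, TRACK_HORIZON_H * 60, by = dt_min)
  times_h <- times_min / 60
  cohort <- vector("list", length(fates))
  for (i in seq_along(fates)) {
    cohort[[i]] <- with_seed(derive_seed(seed, paste0("track_", i)), {
      sch <- build_fate_schedule(fates[i], allocation$exposure_phase, params)
      ints <- schedule_intensities(times_h, sch, params)
      area <- schedule_areas(times_h, sch, params)
      # truth labels use the same threshold-and-hysteresis rule as the
      # phase caller, so a noiseless track is recovered exactly
      truth_phase <- merge_short_runs(
        phase_rule(ints$red, ints$green,
                   red_threshold = 20, green_threshold = 20), 2L)
      truth_phase[ints$dead] <- "DEAD"
      red <- ints$red; green <- ints$green
      if (noise_sd > 0) {
        red <- pmax(0, red + rnorm(length(red), 0, noise_sd))
        green <- pmax(0, green + rnorm(length(green), 0, noise_sd))
        area <- pmax(1, area * (1 + rnorm(length(area), 0, 0.02)))
        red[ints$dead] <- 0; green[ints$dead] <- 0
      }
      events <- sch$events
      events <- if (is.null(events) || nrow(events) == 0L) {
        data.frame(event = character(0), time_min = numeric(0))
      } else {
        data.frame(event = events$event, time_min = round(events$time_h * 60, 3))
      }
      structure(
        list(
          track_id = i,
          frames = data.frame(
            time_min = times_min, red = red, green = green,
            area_um2 = area, alive = !ints$dead, truth_phase = truth_phase
          ),
          events = events[order(events$time_min), , drop = FALSE],
          truth_fate = fates[i],
          truth_exposure_phase = allocation$exposure_phase,
          n_divisions_truth = length(sch$divisions)
        ),
        class = "fucci_track"
      )
    })
  }
  structure(cohort, class = c("fucci_cohort", "list"))
}

#' Write or read a FUCCI cohort as plain CSV files
#'
#' `write_tracks()` emits three CSVs into `dir`: `frames.csv` (one row per
#' track and frame), `events.csv` and `truth.csv`, plus a small manifest.
#' `read_tracks()` reconstructs the cohort.
#'
#' @param cohort a `fucci_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir` (write) or a `fucci_cohort` (read).
#' @export
write_tracks <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frames <- do.call(rbind, lapply(cohort, function(tr) {
    cbind(track_id = tr$track_id, tr$frames)
  }))
  events <- do.call(rbind, lapply(cohort, function(tr) {
    if (nrow(tr$events) == 0L) return(NULL)
    cbind(track_id = tr$track_id, tr$events)
  }))
  if (is.null(events)) {
    events <- data.frame(track_id = integer(0), event = character(0),
                         time_min = numeric(0))
  }
  truth <- do.call(rbind, lapply(cohort, function(tr) {
    data.frame(track_id = tr$track_id, truth_fate = tr$truth_fate,
               truth_exposure_phase = tr$truth_exposure_phase,
               n_divisions_truth = tr$n_divisions_truth)
  }))
  write.csv(frames, file.path(dir, "frames.csv"), row.names = FALSE)
  write.csv(events, file.path(dir, "events.csv"), row.names = FALSE)
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  writeLines(sprintf("tracks: %d", length(cohort)),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(dir) {
  frames <- read.csv(file.path(dir, "frames.csv"))
  events <- read.csv(file.path(dir, "events.csv"))
  truth <- read.csv(file.path(dir, "truth.csv"))
  cohort <- lapply(truth$track_id, function(id) {
    structure(
      list(
        track_id = id,
        frames = frames[frames$track_id == id,
                        setdiff(names(frames), "track_id"), drop = FALSE],
        events = events[events$track_id == id,
                        setdiff(names(events), "track_id"), drop = FALSE],
        truth_fate = truth$truth_fate[truth$track_id == id],
        truth_exposure_phase = truth$truth_exposure_phase[truth$track_id == id],
        n_divisions_truth = truth$n_divisions_truth[truth$track_id == id]
      ),
      class = "fucci_track"
    )
  })
  structure(cohort, class = c("fucci_cohort", "list"))
}
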