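## FUCCI phase calling, division/death event detection and the single-cell
## fate ontology.

PHASE_LABELS <- c("G1", "G1/S", "S/G2/M", "GAP", "DEAD")

# Threshold rule mapping reporter intensities to phase labels.
phase_rule <- function(red, green, red_threshold, green_threshold) {
  lab <- rep("GAP", length(red))
  lab[red > red_threshold & green <= green_threshold] <- "G1"
  lab[red > red_threshold & green > green_threshold] <- "G1/S"
  lab[red <= red_threshold & green > green_threshold] <- "S/G2/M"
  lab
}

# Merge runs shorter than min_run into the preceding run (or following run at
# the start of the sequence). GAP and DEAD runs are preserved: a colourless
# post-mitotic frame is a real reporter state, not noise.
merge_short_runs <- function(labels, min_run) {
  if (min_run <= 1L || length(labels) < 2L) return(labels)
  repeat {
    r <- rle(labels)
    short <- which(r$lengths < min_run & !r$values %in% c("GAP", "DEAD"))
    short <- short[vapply(short, function(i) {
      (i > 1 && !r$values[i - 1] %in% c("GAP", "DEAD")) ||
        (i < length(r$values) && !r$values[i + 1] %in% c("GAP", "DEAD"))
    }, logical(1))]
    if (length(short) == 0L) break
    i <- short[1]
    repl <- if (i > 1 && !r$values[i - 1] %in% c("GAP", "DEAD")) {
      r$values[i - 1]
    } else {
      r$values[i + 1]
    }
    r$values[i] <- repl
    labels <- inverse.rle(r)
    # merged neighbours collapse on the next rle() pass
  }
  labels
}

#' Call FUCCI cell-cycle phase along a track
#'
#' Frames with only the red reporter above threshold are G1; both reporters
#' above, G1/S; only green, S/G2/M; neither, GAP (the colourless
#' post-mitotic window). Frames after death are DEAD (absorbing). Runs of
#' coloured labels shorter than `min_run` frames are merged into the
#' flanking phase (hysteresis against threshold chatter); GAP runs are kept
#' as-is since the one-frame post-anaphase gap is real.
#'
#' @param track a `fucci_track` or a data.frame with columns `red`, `green`
#'   and optionally `alive`.
#' @param red_threshold,green_threshold intensity thresholds (> 0; full
#'   reporter signal in synthetic tracks is 100, default thresholds 20).
#' @param min_run minimum run length, in frames, of a coloured phase call.
#' @return Character vector of per-frame labels in
#'   `{G1, G1/S, S/G2/M, GAP, DEAD}`.
#' @export
call_phase_track <- function(track, red_threshold = 20, green_threshold = 20,
                             min_run = 2L) {
  frames <- if (inherits(track, "fucci_track")) track$frames else track
  if (!all(c("red", "green") %in% names(frames))) {
    stop("track frames must carry 'red' and 'green' intensity columns",
         call. = FALSE)
  }
  check_scalar(red_threshold, "red_threshold", 0, strict = TRUE)
  check_scalar(green_threshold, "green_threshold", 0, strict = TRUE)
  if (nrow(frames) < 2L) stop("track must have at least 2 frames",
                              call. = FALSE)
  lab <- phase_rule(frames$red, frames$green, red_threshold, green_threshold)
  lab <- merge_short_runs(lab, as.integer(min_run))
  if (!is.null(frames$alive)) {
    dead_from <- match(FALSE, frames$alive)
    if (!is.na(dead_from)) lab[dead_from:length(lab)] <- "DEAD"
  }
  lab
}

#' Detect division events (NEBD/anaphase pairs) on a track
#'
#' Event annotations take precedence: NEBD and ANAPHASE annotations are
#' paired in time order, requiring anaphase to follow NEBD by 15 min to 3 h;
#' an anaphase with no preceding NEBD in that window is flagged and dropped.
#' Without annotations a morphology proxy is used: a nuclear-area drop of at
#' least 40% within one frame coincident with a green-to-reset transition.
#'
#' @param track a `fucci_track` (or list with `frames` and optional `events`).
#' @param use_annotations logical; set FALSE to force the proxy.
#' @param area_drop minimum fractional single-frame area drop for the proxy.
#' @return data.frame with columns `nebd_min`, `anaphase_min`, one row per
#'   division, plus attribute `"dropped"` (count of inconsistent anaphases).
#' @export
detect_division_events <- function(track, use_annotations = TRUE,
                                   area_drop = 0.4) {
  ev <- track$events
  empty <- data.frame(nebd_min = numeric(0), anaphase_min = numeric(0))
  if (use_annotations && !is.null(ev) && nrow(ev) > 0 &&
      any(ev$event %in% c("NEBD", "ANAPHASE"))) {
    nebd <- sort(ev$time_min[ev$event == "NEBD"])
    ana <- sort(ev$time_min[ev$event == "ANAPHASE"])
    pairs <- empty
    dropped <- 0L
    for (a in ana) {
      cand <- nebd[nebd < a & a - nebd <= 180 & a - nebd >= 15]
      if (length(cand) == 0L) {
        dropped <- dropped + 1L
        warning("anaphase at ", a, " min has no NEBD within 15 min-3 h; dropped",
                call. = FALSE)
        next
      }
      nb <- max(cand)
      pairs <- rbind(pairs, data.frame(nebd_min = nb, anaphase_min = a))
      nebd <- nebd[nebd != nb]
    }
    attr(pairs, "dropped") <- dropped
    return(pairs)
  }
  frames <- track$frames
  if (is.null(frames$area_um2)) return(empty)
  n <- nrow(frames)
  if (n < 2L) return(empty)
  rel_drop <- 1 - frames$area_um2[-1] / frames$area_um2[-n]
  green_reset <- frames$green[-n] > 20 & frames$green[-1] <= 20
  hit <- which(rel_drop >= area_drop & green_reset)
  if (length(hit) == 0L) return(empty)
  ana_min <- frames$time_min[hit + 1L]
  dt <- if (n >= 2) frames$time_min[2] - frames$time_min[1] else 30
  pairs <- data.frame(nebd_min = ana_min - dt, anaphase_min = ana_min)
  attr(pairs, "dropped") <- 0L
  pairs
}

#' Mitotic and interphase lengths from division events
#'
#' Mitotic length is NEBD to anaphase; interphase length is anaphase to the
#' next NEBD of the followed daughter line.
#'
#' @param pair one row of [detect_division_events()] output (or a list/df
#'   with `nebd_min`, `anaphase_min`).
#' @return Length in minutes (strictly positive).
#' @export
mitotic_length <- function(pair) {
  len <- pair$anaphase_min - pair$nebd_min
  if (any(len <= 0)) stop("anaphase must follow NEBD", call. = FALSE)
  len
}

#' @rdname mitotic_length
#' @param pairs the full division table of a track, time-ordered.
#' @return For `interphase_length()`: vector of anaphase-to-next-NEBD
#'   lengths (minutes), length `nrow(pairs) - 1`.
#' @export
interphase_length <- function(pairs) {
  if (nrow(pairs) < 2L) return(numeric(0))
  if (is.unsorted(pairs$anaphase_min)) {
    stop("division pairs must be time-ordered", call. = FALSE)
  }
  len <- pairs$nebd_min[-1] - pairs$anaphase_min[-nrow(pairs)]
  if (any(len <= 0)) stop("out-of-order events: interphase must be positive",
                          call. = FALSE)
  len
}

#' Classify the fate of a single track
#'
#' Applies the eight-label fate ontology with a fixed decision order, using
#' only events within the horizon (closed interval): death first (before or
#' after mitosis), then two-or-more divisions (proliferative), then single
#' division, then G2-exit (a green run of at least `g2_exit_min_green_hours`
#' ending in red without anaphase), then G1 arrest (before/after mitosis),
#' then S/G2 arrest. A track with one division is a single division only if
#' it re-enters S/G2 (green) afterwards; a red-only tail after the division
#' is G1 arrest after mitosis. All-GAP tracks are flagged UNCLASSIFIABLE.
#'
#' @param track a `fucci_track`.
#' @param horizon_hours fate horizon (default 72; events exactly at the
#'   horizon are included).
#' @param g2_exit_min_green_hours minimum green-run length for a G2-exit
#'   call (default 20).
#' @param red_threshold,green_threshold,min_run passed to
#'   [call_phase_track()].
#' @return A list of class `fate_call`: `fate` (label or "UNCLASSIFIABLE"),
#'   `n_divisions`, `division_times_min`, `mitotic_lengths_min`,
#'   `first_g1_length_after_division_min` (NA if absent).
#' @export
classify_fate <- function(track, horizon_hours = 72,
                          g2_exit_min_green_hours = 20,
                          red_threshold = 20, green_threshold = 20,
                          min_run = 2L) {
  frames <- track$frames
  horizon_min <- horizon_hours * 60
  keep <- frames$time_min <= horizon_min
  frames <- frames[keep, , drop = FALSE]
  phases <- call_phase_track(frames, red_threshold, green_threshold, min_run)
  pairs <- detect_division_events(
    list(frames = frames,
         events = if (!is.null(track$events)) {
           track$events[track$events$time_min <= horizon_min, , drop = FALSE]
         })
  )
  nd <- nrow(pairs)
  died <- FALSE
  if (!is.null(track$events) && nrow(track$events) > 0) {
    died <- any(track$events$event == "DEATH" &
                  track$events$time_min <= horizon_min)
  }
  if (!died && !is.null(frames$alive)) died <- any(!frames$alive)

  call <- function(fate) {
    structure(
      list(
        fate = fate,
        n_divisions = nd,
        division_times_min = pairs$anaphase_min,
        mitotic_lengths_min = if (nd > 0) mitotic_length(pairs) else numeric(0),
        first_g1_length_after_division_min = first_g1_after_division(
          frames, phases, pairs
        )
      ),
      class = "fate_call"
    )
  }

  if (all(phases %in% c("GAP", "DEAD"))) {
    fc <- call("UNCLASSIFIABLE")
    attr(fc, "note") <- "no coloured frames within the horizon"
    return(fc)
  }
  if (died) return(call(if (nd == 0) "DBM" else "DAM"))
  if (nd >= 2) return(call("PROLIF"))
  dt_min <- if (nrow(frames) >= 2) frames$time_min[2] - frames$time_min[1] else 30
  if (nd == 1) {
    after <- phases[frames$time_min > pairs$anaphase_min[1]]
    green_after <- sum(after == "S/G2/M")
    return(call(if (green_after >= min_run) "SINGLE_DIV" else "G1_AAM"))
  }
  # no divisions: inspect green runs
  r <- rle(phases)
  run_h <- r$lengths * dt_min / 60
  ends <- cumsum(r$lengths)
  green_i <- which(r$values == "S/G2/M" & run_h >= g2_exit_min_green_hours)
  for (i in green_i) {
    later <- r$values[seq_along(r$values) > i]
    if (any(later == "G1")) return(call("G2_EXIT"))
  }
  last_col <- r$values[max(which(!r$values %in% c("GAP", "DEAD")))]
  if (last_col %in% c("S/G2/M", "G1/S")) return(call("SG2_ARREST"))
  call("G1_ABM")
}

first_g1_after_division <- function(frames, phases, pairs) {
  if (nrow(pairs) == 0L) return(NA_real_)
  t0 <- pairs$anaphase_min[1]
  after <- which(frames$time_min > t0)
  g1 <- after[phases[after] == "G1"]
  if (length(g1) == 0L) return(NA_real_)
  # contiguous leading G1 block of the daughter
  non_g1 <- after[phases[after] != "G1" & frames$time_min[after] > frames$time_min[g1[1]]]
  end_t <- if (length(non_g1)) frames$time_min[non_g1[1]] else
    frames$time_min[after[length(after)]]
  end_t - frames$time_min[g1[1]]
}

#' Map a synchronisation protocol and pulse offset to an exposure phase
#'
#' Release from a CDK4/6 inhibitor (`palbo_release`) puts cells at the start
#' of G1 progression: a pulse at release targets G1, at ~6 h targets G1/S.
#' Release from a thymidine block (`thy_release`) puts cells at the G1/S
#' boundary: a pulse up to 2 h before release targets G1/S, ~4 h after
#' release targets late S. Breakpoints are configurable.
#'
#' @param protocol `"palbo_release"` or `"thy_release"`.
#' @param offset_hours pulse time relative to release, within `[-4, 12]`.
#' @param breakpoints optional named list of two numeric vectors
#'   (`palbo_release`, `thy_release`) of cut points.
#' @return One of [EXPOSURE_PHASES].
#' @export
label_exposure_phase <- function(protocol = c("palbo_release", "thy_release"),
                                 offset_hours, breakpoints = NULL) {
  protocol <- match.arg(protocol)
  check_scalar(offset_hours, "offset_hours")
  if (offset_hours < -4 || offset_hours > 12) {
    stop("offset_hours outside the calibrated range [-4, 12]", call. = FALSE)
  }
  if (is.null(breakpoints)) {
    breakpoints <- list(
      palbo_release = c(3, 9),  # G1 | G1/S | earlyS
      thy_release = c(0, 2, 8)  # G1/S | earlyS | lateS | G2/M
    )
  }
  bp <- breakpoints[[protocol]]
  if (protocol == "palbo_release") {
    c("G1", "G1/S", "earlyS")[findInterval(offset_hours, bp) + 1L]
  } else {
    c("G1/S", "earlyS", "lateS", "G2/M")[findInterval(offset_hours, bp,
                                                      left.open = TRUE) + 1L]
  }
}

#' Aggregate fate calls into a cohort fate table
#'
#' @param calls list of `fate_call` objects (UNCLASSIFIABLE calls are
#'   excluded from fractions, with a message).
#' @param condition character vector of condition labels (recycled).
#' @return A list with `fate_table` (condition, fate, count, fraction; the
#'   fractions within a condition sum to 1 over classified tracks) and
#'   `divisions` (condition, divisions in 0/1/2/3+, count).
#' @export
aggregate_cohort <- function(calls, condition = "cohort") {
  if (length(calls) == 0L) stop("at least one classified track is required",
                                call. = FALSE)
  condition <- rep_len(condition, length(calls))
  fate <- vapply(calls, `[[`, character(1), "fate")
  ndiv <- vapply(calls, `[[`, numeric(1), "n_divisions")
  keep <- fate != "UNCLASSIFIABLE"
  if (any(!keep)) {
    message(sum(!keep), " unclassifiable track(s) excluded from fate fractions")
  }
  fate_table <- do.call(rbind, lapply(unique(condition), function(cond) {
    f <- fate[keep & condition == cond]
    counts <- table(factor(f, levels = FATE_LABELS))
    data.frame(condition = cond, fate = names(counts),
               count = as.integer(counts),
               fraction = as.numeric(counts) / max(sum(counts), 1L))
  }))
  div_bin <- cut(ndiv, breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
                 labels = c("0", "1", "2", "3+"))
  divisions <- as.data.frame(table(condition = condition, divisions = div_bin),
                             responseName = "count")
  list(fate_table = fate_table, divisions = divisions)
}

#' Red/yellow/green phase fractions
#'
#' For a cohort, computes per-frame fractions of cells in the red (G1),
#' yellow (G1/S) and green (S/G2/M) classes among live cells; the colourless
#' post-mitotic GAP is counted with red (G1-like) so the three fractions sum
#' to 1. For a [simulate_population()] result the fraction columns are
#' returned directly.
#'
#' @param x a `fucci_cohort` or the data.frame returned by
#'   [simulate_population()].
#' @param ... thresholds passed to [call_phase_track()].
#' @return data.frame with `time_min`, `red`, `yellow`, `green`.
#' @export
phase_fractions <- function(x, ...) {
  if (is.data.frame(x) && all(c("frac_red", "frac_yellow", "frac_green")
                              %in% names(x))) {
    return(data.frame(time_min = x$time_h * 60, red = x$frac_red,
                      yellow = x$frac_yellow, green = x$frac_green))
  }
  if (length(x) == 0L) stop("empty snapshot", call. = FALSE)
  phases <- lapply(x, call_phase_track, ...)
  times <- x[[1]]$frames$time_min
  mat <- do.call(rbind, phases)
  colMeans2 <- function(lbl) {
    apply(mat, 2, function(col) {
      live <- col != "DEAD"
      if (!any(live)) return(NA_real_)
      sum(col[live] %in% lbl) / sum(live)
    })
  }
  data.frame(
    time_min = times,
    red = colMeans2(c("G1", "GAP")),
    yellow = colMeans2("G1/S"),
    green = colMeans2("S/G2/M")
  )
}
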