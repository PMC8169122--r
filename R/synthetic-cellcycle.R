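## Cell-cycle parameterisation and phase-dependent fate allocations.

#' Fate ontology labels
#'
#' The eight single-cell fates recognised by the package: proliferative
#' (two or more divisions), single division, G2-exit (withdrawal from a
#' prolonged S/G2 arrest into a G1-like state without mitosis), G1 arrest
#' before mitosis, G1 arrest after mitosis, death before mitosis, death
#' after mitosis, and sustained S/G2 arrest.
#' @export
FATE_LABELS <- c("PROLIF", "SINGLE_DIV", "G2_EXIT", "G1_ABM", "G1_AAM",
                 "DBM", "DAM", "SG2_ARREST")

#' Exposure-phase labels
#' @export
EXPOSURE_PHASES <- c("G1", "G1/S", "earlyS", "lateS", "G2/M", "untreated")

#' Cell-cycle parameters for the synthetic generators
#'
#' Mean phase durations default to G1 22 h, S 7 h, G2 3 h, M 1 h (33 h
#' cycle). Under the exponential steady-state age distribution this puts the
#' red (G1) occupancy at `2 * (1 - 2^(-22/33))` which is approximately 0.74,
#' inside the 0.70-0.80 band reported for untreated populations; the
#' occupancy implied by the defaults is checked at construction.
#'
#' @param g1_hours,s_hours,g2_hours,m_hours mean phase durations (hours).
#' @param g1s_overlap_hours duration of the red+green (yellow) overlap window
#'   at the start of S while the G1 reporter decays (default 2 h).
#' @param mitotic_length_minutes NEBD-to-anaphase duration (default 30 min).
#' @param duration_cv lognormal coefficient of variation of sampled phase
#'   durations (default 0.15).
#' @param g2_exit_arrest_hours mean duration of the S/G2 arrest preceding a
#'   G2-exit (default 24 h; must exceed the classifier's 20 h green-run
#'   criterion).
#' @param enlargement_rate nuclear-area fold change per 24 h for arrested
#'   cells (default 1.6, i.e. about fourfold over 72 h, inside the reported
#'   two- to sixfold range).
#' @param p53_functional logical; with functional p53, green-arrested cells
#'   undergo G2-exit into a red G1-like state, otherwise they linger in S/G2
#'   or attempt aberrant divisions.
#' @param frame_interval_minutes sampling cadence of tracks and population
#'   snapshots (default 30 min).
#' @param baseline_area_um2 nuclear area of a newborn cell (default 150).
#' @param g1_release_to_s_hours time from a G1 (CDK4/6-release) exposure to
#'   S entry (default 6 h, the release-to-G1/S interval of the
#'   synchronisation protocol).
#' @param treated_slowdown multiplicative cycle lengthening for cells that
#'   keep proliferating after a genotoxic pulse (default 1.8).
#' @return An object of class `cell_cycle_params`.
#' @export
cell_cycle_params <- function(g1_hours = 22, s_hours = 7, g2_hours = 3,
                              m_hours = 1, g1s_overlap_hours = 2,
                              mitotic_length_minutes = 30,
                              duration_cv = 0.15,
                              g2_exit_arrest_hours = 24,
                              enlargement_rate = 1.6,
                              p53_functional = TRUE,
                              frame_interval_minutes = 30,
                              baseline_area_um2 = 150,
                              g1_release_to_s_hours = 6,
                              treated_slowdown = 1.8) {
  for (nm in c("g1_hours", "s_hours", "g2_hours", "m_hours",
               "mitotic_length_minutes", "frame_interval_minutes",
               "g2_exit_arrest_hours", "baseline_area_um2",
               "g1_release_to_s_hours", "treated_slowdown")) {
    check_scalar(get(nm), nm, 0, strict = TRUE)
  }
  check_scalar(duration_cv, "duration_cv", 0)
  check_scalar(enlargement_rate, "enlargement_rate", 1)
  if (g1s_overlap_hours <= 0 || g1s_overlap_hours >= s_hours) {
    stop("'g1s_overlap_hours' must lie strictly between 0 and 's_hours'",
         call. = FALSE)
  }
  p <- structure(
    list(
      g1_hours = g1_hours, s_hours = s_hours, g2_hours = g2_hours,
      m_hours = m_hours, g1s_overlap_hours = g1s_overlap_hours,
      mitotic_length_minutes = mitotic_length_minutes,
      duration_cv = duration_cv,
      g2_exit_arrest_hours = g2_exit_arrest_hours,
      enlargement_rate = enlargement_rate,
      p53_functional = isTRUE(p53_functional),
      frame_interval_minutes = frame_interval_minutes,
      baseline_area_um2 = baseline_area_um2,
      g1_release_to_s_hours = g1_release_to_s_hours,
      treated_slowdown = treated_slowdown
    ),
    class = "cell_cycle_params"
  )
  occ <- steady_state_red_fraction(p)
  if (occ < 0.70 || occ > 0.80) {
    warning(sprintf(
      "steady-state G1 occupancy implied by these durations is %.2f, outside [0.70, 0.80]",
      occ
    ), call. = FALSE)
  }
  p
}

#' Steady-state red (G1) fraction implied by cell-cycle parameters
#'
#' Under balanced exponential growth the cell-age density is
#' `f(a) = (2 ln 2 / T) 2^(-a/T)`, so the fraction of cells younger than the
#' G1/S transition (red-only cells) is `2 (1 - 2^(-g1/T))`.
#'
#' @param params a [cell_cycle_params()].
#' @return Scalar fraction in (0, 1).
#' @export
steady_state_red_fraction <- function(params) {
  T <- params$g1_hours + params$s_hours + params$g2_hours + params$m_hours
  2 * (1 - 2^(-params$g1_hours / T))
}

#' Phase-dependent fate allocation
#'
#' Maps each of the eight fates to either exact counts (summing to the cohort
#' size; fates are then assigned exactly, not sampled) or probabilities
#' (summing to 1).
#'
#' @param exposure_phase one of [EXPOSURE_PHASES].
#' @param ... named fate counts or probabilities; names must be a subset of
#'   [FATE_LABELS].
#' @return An object of class `fate_allocation` with fields `exposure_phase`,
#'   `values` (named numeric over all eight fates), `mode`
#'   (`"counts"` or `"probs"`).
#' @export
fate_allocation <- function(exposure_phase, ...) {
  exposure_phase <- match.arg(exposure_phase, EXPOSURE_PHASES)
  vals <- c(...)
  if (length(vals) == 0 || is.null(names(vals)) || any(names(vals) == "")) {
    stop("fate allocation requires named fate counts or probabilities",
         call. = FALSE)
  }
  bad <- setdiff(names(vals), FATE_LABELS)
  if (length(bad)) {
    stop("unknown fate label(s): ", paste(bad, collapse = ", "),
         "; allowed labels are ", paste(FATE_LABELS, collapse = ", "),
         call. = FALSE)
  }
  if (any(vals < 0)) stop("fate counts/probabilities must be non-negative",
                          call. = FALSE)
  full <- setNames(numeric(length(FATE_LABELS)), FATE_LABELS)
  full[names(vals)] <- vals
  tot <- sum(full)
  mode <- if (abs(tot - 1) <= 1e-9) "probs" else "counts"
  if (mode == "counts" && any(abs(full - round(full)) > 1e-9)) {
    stop("fate values must sum to 1 (probabilities) or be integer counts",
         call. = FALSE)
  }
  structure(
    list(exposure_phase = exposure_phase,
         values = if (mode == "counts") round(full) else full,
         mode = mode),
    class = "fate_allocation"
  )
}

#' Cohort fate allocations for the synchronisation-and-pulse experiments
#'
#' Count-based allocations (n = 50 each) for the four synchronised exposure
#' conditions plus an untreated control. The headline counts are fixed: 7/50
#' single divisions and no proliferative cells for G1 exposure; 13/50 and
#' 16/50 proliferative for CDK4/6-inhibitor- and thymidine-synchronised G1/S
#' exposure; 4/50 proliferative (two divisions) for late-S exposure. The
#' remainder of each cohort is split following the narrated outcomes
#' (predominantly G2-exit for G1 exposure; predominantly a single division
#' followed by S/G2 arrest for late S); the splits are package defaults and
#' can be replaced with any [fate_allocation()].
#'
#' @return Named list of `fate_allocation` objects:
#'   `cis_G1`, `cis_G1S_palbo`, `cis_G1S_thy`, `cis_lateS`, `control`.
#' @export
fig_fate_allocations <- function() {
  list(
    cis_G1 = fate_allocation("G1",
      SINGLE_DIV = 7, G2_EXIT = 40, SG2_ARREST = 3),
    cis_G1S_palbo = fate_allocation("G1/S",
      PROLIF = 13, SINGLE_DIV = 18, G2_EXIT = 12, G1_AAM = 2,
      DAM = 3, DBM = 2),
    cis_G1S_thy = fate_allocation("G1/S",
      PROLIF = 16, SINGLE_DIV = 17, G2_EXIT = 11, G1_AAM = 1,
      DAM = 3, DBM = 2),
    cis_lateS = fate_allocation("lateS",
      PROLIF = 4, SINGLE_DIV = 36, G2_EXIT = 6, DAM = 3, DBM = 1),
    control = fate_allocation("untreated", PROLIF = 50)
  )
}

#' Default per-phase fate probabilities for a pulse treatment
#'
#' Used by [simulate_population()] with `treatment = "pulse"`. The
#' proliferative probabilities follow the synchronised-cohort fractions
#' (0 for G1, 0.26 and 0.32 for G1/S and early S, 0.08 for late S); the
#' remainder reflects the dominant narrated outcome per phase. With
#' non-functional p53, arrest probabilities shift toward continued (aberrant)
#' division and post-mitotic death.
#'
#' @param p53_functional logical.
#' @return Named list mapping exposure phase to a probability
#'   [fate_allocation()].
#' @export
default_phase_fate_map <- function(p53_functional = TRUE) {
  if (p53_functional) {
    list(
      "G1" = fate_allocation("G1",
        G2_EXIT = 0.80, SINGLE_DIV = 0.14, SG2_ARREST = 0.04, DBM = 0.02),
      "G1/S" = fate_allocation("G1/S",
        PROLIF = 0.26, SINGLE_DIV = 0.30, G2_EXIT = 0.30, G1_AAM = 0.04,
        DAM = 0.06, DBM = 0.04),
      "earlyS" = fate_allocation("earlyS",
        PROLIF = 0.32, SINGLE_DIV = 0.30, G2_EXIT = 0.24, G1_AAM = 0.02,
        DAM = 0.06, DBM = 0.06),
      "lateS" = fate_allocation("lateS",
        PROLIF = 0.08, SINGLE_DIV = 0.64, G2_EXIT = 0.16, DAM = 0.08,
        DBM = 0.04),
      "G2/M" = fate_allocation("G2/M",
        SINGLE_DIV = 0.50, G1_AAM = 0.26, PROLIF = 0.04, DAM = 0.14,
        DBM = 0.06)
    )
  } else {
    list(
      "G1" = fate_allocation("G1",
        PROLIF = 0.10, SINGLE_DIV = 0.30, G2_EXIT = 0.20, SG2_ARREST = 0.30,
        DBM = 0.10),
      "G1/S" = fate_allocation("G1/S",
        PROLIF = 0.35, SINGLE_DIV = 0.30, SG2_ARREST = 0.15, DAM = 0.15,
        DBM = 0.05),
      "earlyS" = fate_allocation("earlyS",
        PROLIF = 0.40, SINGLE_DIV = 0.25, SG2_ARREST = 0.15, DAM = 0.15,
        DBM = 0.05),
      "lateS" = fate_allocation("lateS",
        PROLIF = 0.20, SINGLE_DIV = 0.40, SG2_ARREST = 0.15, DAM = 0.20,
        DBM = 0.05),
      "G2/M" = fate_allocation("G2/M",
        PROLIF = 0.15, SINGLE_DIV = 0.40, G1_AAM = 0.15, DAM = 0.25,
        DBM = 0.05)
    )
  }
}
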