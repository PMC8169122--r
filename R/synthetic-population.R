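## Phase-structured population simulator.
##
## Untreated populations cycle exponentially; a pulse treatment at time zero
## allocates every cell a fate according to its cell-cycle phase at exposure
## (the phase-fate map), after which arrested lineages follow analytic
## piecewise colour timelines while proliferative lineages keep cycling with
## a damage-related slowdown. Colour classes follow FUCCI semantics: red =
## G1, yellow = G1/S overlap, green = S/G2/M; the one-frame post-mitotic
## colourless gap is counted with red for fraction reporting.

# Sample steady-state cell ages (hours since birth) for a growing population.
sample_steady_ages <- function(n, total_h) {
  -total_h * log2(1 - runif(n) / 2)
}

new_cycler <- function(n, p, slowdown = 1) {
  cv <- p$duration_cv
  list(
    g1 = rlnorm_mcv(n, p$g1_hours * slowdown, cv),
    s = rlnorm_mcv(n, p$s_hours * slowdown, cv),
    g2m = rlnorm_mcv(n, (p$g2_hours + p$m_hours) * slowdown, cv)
  )
}

cycler_counts <- function(st, ov) {
  if (length(st$tpos) == 0L) return(c(red = 0, yellow = 0, green = 0))
  red <- st$tpos < st$g1
  yellow <- !red & st$tpos < st$g1 + ov
  c(red = sum(red), yellow = sum(yellow), green = sum(!red & !yellow))
}

step_cyclers <- function(st, dt, p, slowdown = 1) {
  if (length(st$tpos) == 0L) return(st)
  st$tpos <- st$tpos + dt
  total <- st$g1 + st$s + st$g2m
  idx <- which(st$tpos >= total)
  if (length(idx)) {
    over <- st$tpos[idx] - total[idx]
    nd <- new_cycler(2L * length(idx), p, slowdown)
    half <- seq_along(idx)
    st$g1[idx] <- nd$g1[half]; st$s[idx] <- nd$s[half]
    st$g2m[idx] <- nd$g2m[half]
    st$tpos[idx] <- over
    st$g1 <- c(st$g1, nd$g1[-half]); st$s <- c(st$s, nd$s[-half])
    st$g2m <- c(st$g2m, nd$g2m[-half])
    st$tpos <- c(st$tpos, over)
  }
  st
}

# Piecewise colour timeline of one arrested/dying cell: breakpoint times
# (ascending, h) and colour codes for the intervals between them.
# codes: 1 red, 2 yellow, 3 green, 0 gone (dead).
arrested_timeline <- function(fate, to_s, p) {
  ov <- p$g1s_overlap_hours
  cv <- p$duration_cv
  s_rem <- if (to_s >= 0) sdur(p$s_hours, cv) else max(sdur(p$s_hours, cv) + to_s, 0.5)
  arrest <- sdur(p$g2_exit_arrest_hours, cv)
  y0 <- max(to_s, 0); g0 <- max(to_s + ov, 0)
  pre <- list(times = c(y0, g0), cols = c(1, 2)) # red then yellow lead-in
  tl <- switch(fate,
    G2_EXIT = {
      t_exit <- g0 + s_rem + arrest
      list(times = c(pre$times, t_exit), cols = c(pre$cols, 3, 1), w = NULL)
    },
    SG2_ARREST = {
      if (p$p53_functional) {
        t_exit <- g0 + s_rem + 2 * arrest # delayed exit to a G1-like state
        list(times = c(pre$times, t_exit), cols = c(pre$cols, 3, 1), w = NULL)
      } else {
        list(times = pre$times, cols = c(pre$cols, 3), w = NULL)
      }
    },
    G1_ABM = list(times = numeric(0), cols = 1, w = NULL),
    G1_AAM = {
      t_div <- g0 + s_rem + sdur(p$g2_hours + p$m_hours, cv)
      list(times = c(pre$times, t_div), cols = c(pre$cols, 3, 1),
           w = c(t_div, 2))
    },
    SINGLE_DIV = {
      t_div <- g0 + s_rem + sdur(p$g2_hours + p$m_hours, cv)
      t_s2 <- t_div + sdur(p$g1_hours, cv)
      t_g2 <- t_s2 + ov
      if (p$p53_functional) {
        t_exit <- t_g2 + sdur(p$s_hours, cv) + arrest
        list(times = c(pre$times, t_div, t_s2, t_g2, t_exit),
             cols = c(pre$cols, 3, 1, 2, 3, 1), w = c(t_div, 2))
      } else {
        list(times = c(pre$times, t_div, t_s2, t_g2),
             cols = c(pre$cols, 3, 1, 2, 3), w = c(t_div, 2))
      }
    },
    DBM = {
      t_death <- g0 + runif(1, 3, 14)
      list(times = c(pre$times, t_death), cols = c(pre$cols, 3, 0),
           w = c(t_death, 0))
    },
    DAM = {
      t_div <- g0 + s_rem + sdur(p$g2_hours + p$m_hours, cv)
      t_death <- t_div + runif(1, 2, 8)
      list(times = c(pre$times, t_div, t_death),
           cols = c(pre$cols, 3, 1, 0),
           w = rbind(c(t_div, 2), c(t_death, 0)))
    },
    stop("fate '", fate, "' cannot arise in the arrested branch",
         call. = FALSE)
  )
  # drop zero-length leading intervals (cells already past yellow at pulse)
  keep <- c(diff(c(0, tl$times)) > 1e-12, TRUE)
  tl$cols <- tl$cols[keep]
  tl$times <- tl$times[keep[-length(keep)]]
  tl
}

#' Simulate FUCCI colour dynamics of a cell population
#'
#' Runs a phase-structured population forward at the configured frame
#' cadence. With `treatment = "none"` all cells cycle and divide; with
#' `treatment = "pulse"` every cell is allocated a fate at time zero
#' according to its cell-cycle phase at exposure, proliferative cells keep
#' cycling (slowed by `params$treated_slowdown`), and arrested, dying and
#' G2-exiting cells follow their fate timelines. Dead cells leave the
#' population.
#'
#' @param params a [cell_cycle_params()].
#' @param treatment `"none"` or `"pulse"`.
#' @param phase_fate_map named list mapping exposure phases to probability
#'   [fate_allocation()]s; default [default_phase_fate_map()] for the
#'   parameter set's p53 status. Required (non-empty) for `"pulse"`.
#' @param n0 starting population size (>= 100 for stable fractions).
#' @param duration_days simulated time (<= 21).
#' @param seed integer seed.
#' @return data.frame time series: `time_h`, `n_red`, `n_yellow`, `n_green`,
#'   `n_total` (live cells), `frac_red`, `frac_yellow`, `frac_green`
#'   (summing to 1), `mean_area_cycling`, `mean_area_arrested` (um^2; NA
#'   when the compartment is empty).
#' @export
simulate_population <- function(params = cell_cycle_params(),
                                treatment = c("none", "pulse"),
                                phase_fate_map = NULL,
                                n0 = 2000, duration_days = 7, seed = 1L) {
  stopifnot(inherits(params, "cell_cycle_params"))
  treatment <- match.arg(treatment)
  check_scalar(n0, "n0", 100)
  check_scalar(duration_days, "duration_days", 0, strict = TRUE)
  if (duration_days > 21) stop("'duration_days' must be at most 21",
                               call. = FALSE)
  if (treatment == "pulse") {
    if (is.null(phase_fate_map)) {
      phase_fate_map <- default_phase_fate_map(params$p53_functional)
    }
    if (length(phase_fate_map) == 0L) {
      stop("'phase_fate_map' must be non-empty for a pulse treatment",
           call. = FALSE)
    }
  }
  p <- params
  ov <- p$g1s_overlap_hours
  dt <- p$frame_interval_minutes / 60
  times <- seq(0, duration_days * 24, by = dt)
  total_h <- p$g1_hours + p$s_hours + p$g2_hours + p$m_hours
  A0 <- p$baseline_area_um2

  with_seed(derive_seed(seed, "population"), {
    dur <- new_cycler(n0, p)
    age <- sample_steady_ages(n0, total_h)
    tot0 <- dur$g1 + dur$s + dur$g2m
    tpos <- age %% tot0

    if (treatment == "none") {
      cyc <- list(tpos = tpos, g1 = dur$g1, s = dur$s, g2m = dur$g2m)
      arr_counts <- function(i) c(red = 0, yellow = 0, green = 0)
      arr_area <- function(i) NA_real_
      slowdown <- 1
    } else {
      s_mid <- (p$s_hours - ov) / 2
      phase <- ifelse(tpos < dur$g1, "G1",
               ifelse(tpos < dur$g1 + ov, "G1/S",
               ifelse(tpos < dur$g1 + ov + s_mid, "earlyS",
               ifelse(tpos < dur$g1 + dur$s, "lateS", "G2/M"))))
      fate <- character(n0)
      for (ph in unique(phase)) {
        alloc <- phase_fate_map[[ph]]
        if (is.null(alloc)) {
          stop("phase_fate_map has no allocation for exposure phase ", ph,
               call. = FALSE)
        }
        idx <- which(phase == ph)
        fate[idx] <- sample(names(alloc$values), length(idx), replace = TRUE,
                            prob = alloc$values)
      }
      is_prolif <- fate == "PROLIF"
      slowdown <- p$treated_slowdown
      cyc <- list(tpos = tpos[is_prolif] * slowdown,
                  g1 = dur$g1[is_prolif] * slowdown,
                  s = dur$s[is_prolif] * slowdown,
                  g2m = dur$g2m[is_prolif] * slowdown)
      a_idx <- which(!is_prolif)
      na <- length(a_idx)
      col_mat <- matrix(1L, na, length(times))
      w_mat <- matrix(1, na, length(times))
      arrest_t <- numeric(na)
      for (j in seq_len(na)) {
        i <- a_idx[j]
        to_s <- if (phase[i] == "G1") dur$g1[i] - tpos[i] else
          -(tpos[i] - dur$g1[i])
        tl <- arrested_timeline(fate[i], to_s, p)
        col_mat[j, ] <- tl$cols[findInterval(times, tl$times) + 1L]
        if (!is.null(tl$w)) {
          w <- if (is.matrix(tl$w)) tl$w else matrix(tl$w, nrow = 1)
          for (k in seq_len(nrow(w))) {
            w_mat[j, times >= w[k, 1]] <- w[k, 2]
          }
        }
        arrest_t[j] <- if (fate[i] %in% c("DBM", "DAM")) Inf else
          max(to_s, 0) + ov + p$s_hours
      }
      w_mat[col_mat == 0L] <- 0
      base_area <- A0 * (1 + tpos[a_idx] / pmax(tot0[a_idx], 1e-9))
      arr_counts <- function(i) {
        c(red = sum(w_mat[col_mat[, i] == 1L, i]),
          yellow = sum(w_mat[col_mat[, i] == 2L, i]),
          green = sum(w_mat[col_mat[, i] == 3L, i]))
      }
      arr_area <- function(i) {
        live <- w_mat[, i] > 0
        if (!any(live)) return(NA_real_)
        t <- times[i]
        a <- base_area
        gr <- live & t > arrest_t
        a[gr] <- base_area[gr] *
          pmin(p$enlargement_rate^((t - arrest_t[gr]) / 24), 6)
        mean(a[live])
      }
    }

    out <- data.frame(time_h = times, n_red = NA_real_, n_yellow = NA_real_,
                      n_green = NA_real_, n_total = NA_real_,
                      frac_red = NA_real_, frac_yellow = NA_real_,
                      frac_green = NA_real_, mean_area_cycling = NA_real_,
                      mean_area_arrested = NA_real_)
    for (i in seq_along(times)) {
      if (i > 1) cyc <- step_cyclers(cyc, dt, p, slowdown)
      cc <- cycler_counts(cyc, ov * slowdown)
      ac <- arr_counts(i)
      n <- cc + ac
      tot <- sum(n)
      out$n_red[i] <- n["red"]; out$n_yellow[i] <- n["yellow"]
      out$n_green[i] <- n["green"]; out$n_total[i] <- tot
      if (tot > 0) {
        out$frac_red[i] <- n["red"] / tot
        out$frac_yellow[i] <- n["yellow"] / tot
        out$frac_green[i] <- n["green"] / tot
      }
      out$mean_area_cycling[i] <- if (length(cyc$tpos)) {
        mean(A0 * (1 + cyc$tpos / (cyc$g1 + cyc$s + cyc$g2m)))
      } else NA_real_
      out$mean_area_arrested[i] <- arr_area(i)
    }
    out
  })
}
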