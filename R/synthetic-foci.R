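## DNA-damage focus kinetics generator.
##
## Emulates 53BP1 focus count/size dynamics across generations after a
## genotoxic pulse: an undamaged replication shows a small number of
## replication-associated foci (< 20) and a few large G1 nuclear bodies in
## daughters; cells exposed in G1 accumulate a ~100-focus burst on S entry
## and arrest; cells exposed in early S burst during the first replication
## and resolve the damage over subsequent generations, with G1 bodies
## growing from daughter to grand-daughter.

#' Focus kinetics parameters
#'
#' @param appearance_rate focus appearance rate during damaged replication
#'   (foci/hour; shapes the rise of the S-phase burst).
#' @param resolution_rate focus resolution rate after the burst (foci/hour).
#' @param size_growth focus area growth for persistent foci (um^2/hour).
#' @param g1_body_mean_area_um2 mean area of G1 53BP1 nuclear bodies
#'   (default 2.5; bodies are capped at 5 um^2).
#' @param s_burst_count expected focus count during damaged replication
#'   (default 100).
#' @param baseline_count undamaged replication focus scale (default 12,
#'   below the <20 regime).
#' @return object of class `foci_kinetics`.
#' @export
foci_kinetics <- function(appearance_rate = 25, resolution_rate = 4,
                          size_growth = 0.02, g1_body_mean_area_um2 = 2.5,
                          s_burst_count = 100, baseline_count = 12) {
  for (nm in c("appearance_rate", "resolution_rate", "size_growth",
               "g1_body_mean_area_um2", "s_burst_count", "baseline_count")) {
    check_scalar(get(nm), nm, 0)
  }
  structure(
    list(appearance_rate = appearance_rate,
         resolution_rate = resolution_rate, size_growth = size_growth,
         g1_body_mean_area_um2 = g1_body_mean_area_um2,
         s_burst_count = s_burst_count, baseline_count = baseline_count),
    class = "foci_kinetics"
  )
}

# Bounded count noise: mean `m`, hard upper bound `cap`.
rcount_capped <- function(n, m, cap) {
  if (m <= 0) return(rep(0L, n))
  if (m >= cap) return(rep(as.integer(cap), n))
  rbinom(n, size = as.integer(cap), prob = m / cap)
}

#' Generate a 53BP1 focus count/size time series across generations
#'
#' Builds the per-frame ground-truth focus record of one followed lineage
#' line over 72 h, given the cell-cycle phase at the time of the pulse.
#' `exposure_phase = "untreated"` gives the control kinetics: fewer than 20
#' replication-associated foci and a few large (up to 5 um^2) G1 nuclear
#' bodies. A G1-exposed cell bursts to `s_burst_count` foci on S entry and
#' arrests without dividing; an early-S-exposed lineage bursts during the
#' first replication and resolves across generations while its G1 bodies
#' grow from daughter to grand-daughter.
#'
#' @param exposure_phase one of [EXPOSURE_PHASES].
#' @param kinetics a [foci_kinetics()].
#' @param generations number of generations to follow (>= 1).
#' @param params a [cell_cycle_params()] providing phase durations and the
#'   frame cadence.
#' @param seed integer seed.
#' @return data.frame with one row per frame: `time_min`, `generation`,
#'   `phase` (G1/S/G2/ARREST), `channel`, `count`, `mean_area_um2`,
#'   `max_area_um2`.
#' @export
make_foci_series <- function(exposure_phase = "untreated",
                             kinetics = foci_kinetics(), generations = 2L,
                             params = cell_cycle_params(), seed = 1L) {
  exposure_phase <- match.arg(exposure_phase, EXPOSURE_PHASES)
  stopifnot(inherits(kinetics, "foci_kinetics"))
  check_scalar(generations, "generations", 1)
  kk <- kinetics
  p <- params
  dt_min <- p$frame_interval_minutes
  times_min <- seq(0, TRACK_HORIZON_H * 60, by = dt_min)
  times_h <- times_min / 60
  damaged <- exposure_phase != "untreated"

  with_seed(derive_seed(seed, paste0("foci_", exposure_phase)), {
    cv <- p$duration_cv
    # time from pulse to the first S entry (negative: already inside S)
    e1 <- switch(exposure_phase,
      "untreated" = sdur(p$g1_hours / 2, cv),
      "G1" = sdur(p$g1_release_to_s_hours, cv),
      "G1/S" = 0, "earlyS" = -1, "lateS" = -5, "G2/M" = -p$s_hours
    )
    arrests <- damaged && exposure_phase == "G1" # S/G2 arrest, no division
    first_div <- if (arrests) Inf else
      max(e1, 0) + max(p$s_hours + e1 - max(e1, 0), 0.5) +
        sdur(p$g2_hours + p$m_hours, cv)
    divs <- numeric(0)
    if (is.finite(first_div)) {
      divs <- first_div
      while (length(divs) < generations - 1 &&
             divs[length(divs)] < TRACK_HORIZON_H) {
        divs <- c(divs, divs[length(divs)] +
                    sdur(p$g1_hours, cv) + sdur(p$s_hours, cv) +
                    sdur(p$g2_hours + p$m_hours, cv))
      }
    }
    gen <- findInterval(times_h, divs) + 1L
    gen_start <- c(0, divs)
    g1_len <- c(max(e1, 0), rlnorm_mcv(length(divs), p$g1_hours, cv))
    s_end1 <- max(e1, 0) + max(p$s_hours + min(e1, 0), 0.5)

    phase <- character(length(times_h))
    for (i in seq_along(times_h)) {
      g <- gen[i]
      tg <- times_h[i] - gen_start[g]
      phase[i] <- if (g == 1L) {
        if (times_h[i] < max(e1, 0)) "G1"
        else if (times_h[i] < s_end1) "S"
        else if (arrests) "ARREST" else "G2"
      } else {
        if (tg < g1_len[g]) "G1"
        else if (tg < g1_len[g] + p$s_hours) "S"
        else "G2"
      }
    }

    ngen <- max(gen)
    burst_scale <- if (arrests) rep(1, ngen) else
      pmax(0.3^(seq_len(ngen) - 1), 0.05)
    g1_area <- if (!damaged) rep(kk$g1_body_mean_area_um2, ngen) else
      pmin(kk$g1_body_mean_area_um2 *
             c(0.4, 0.9, 1.3, 1.5)[pmin(seq_len(ngen), 4)], 5)

    count <- integer(length(times_h))
    mean_area <- numeric(length(times_h))
    on <- kk$appearance_rate > 0
    for (i in seq_along(times_h)) {
      if (!on) break
      g <- gen[i]
      ph <- phase[i]
      if (ph == "G1") {
        count[i] <- rcount_capped(1, if (damaged) 4 else 3, 9)
        mean_area[i] <- min(rlnorm_mcv(1, g1_area[g], 0.2), 5)
      } else if (!damaged) {
        count[i] <- rcount_capped(1, kk$baseline_count *
                                    (if (ph == "S") 1 else 0.4), 19)
        mean_area[i] <- rlnorm_mcv(1, 0.4, 0.2)
      } else {
        burst <- kk$s_burst_count * burst_scale[g]
        s_start <- if (g == 1L) max(e1, 0) else gen_start[g] + g1_len[g]
        m <- if (ph == "S") {
          burst * pmin(1, kk$appearance_rate *
                         pmax(times_h[i] - s_start, dt_min / 60) / burst)
        } else if (ph == "ARREST") {
          pmax(burst - kk$resolution_rate * (times_h[i] - s_end1),
               0.3 * burst)
        } else { # G2: damage partially resolved at the end of S
          0.3 * burst
        }
        count[i] <- rpois(1, max(m, 0))
        mean_area[i] <- rlnorm_mcv(
          1, 0.5 + kk$size_growth * pmax(times_h[i], 0), 0.15)
      }
      if (count[i] == 0) mean_area[i] <- 0
    }
    data.frame(
      time_min = times_min, generation = gen, phase = phase,
      channel = "53BP1", count = count, mean_area_um2 = mean_area,
      # G1 nuclear bodies stay within the 5 um^2 ceiling
      max_area_um2 = ifelse(phase == "G1",
                            pmin(mean_area * 1.8, 5),
                            mean_area * ifelse(count > 0, 1.8, 0))
    )
  })
}

#' Render a nucleus with Gaussian foci
#'
#' Draws a bright nuclear disc on a dark background and superimposes
#' Gaussian spots at the given positions, producing a 16-bit single-channel
#' frame plus the ground-truth mask and focus table. Used to exercise the
#' focus-detection stage against known truth.
#'
#' @param foci data.frame with `x_rel`, `y_rel` (position relative to the
#'   nucleus centre, in units of nucleus radius) and `area_um2`.
#' @param nucleus_radius_um nucleus radius (default 8).
#' @param pixel_size_um microns per pixel (default 0.2).
#' @param image_px image side length (default auto to fit the nucleus).
#' @param nucleus_level,focus_peak,noise_sd intensity parameters.
#' @param seed noise seed.
#' @return list with `image` (matrix), `mask` (logical matrix),
#'   `truth` (the foci table with pixel coordinates attached).
#' @export
render_foci_frame <- function(foci, nucleus_radius_um = 8,
                              pixel_size_um = 0.2, image_px = NULL,
                              nucleus_level = 3000, focus_peak = 20000,
                              noise_sd = 100, seed = 1L) {
  r_px <- nucleus_radius_um / pixel_size_um
  if (is.null(image_px)) image_px <- ceiling(2.6 * r_px)
  n <- as.integer(image_px)
  cx <- (n + 1) / 2
  xx <- matrix(rep(seq_len(n), n), n, n)
  yy <- t(xx)
  mask <- (xx - cx)^2 + (yy - cx)^2 <= r_px^2
  img <- matrix(0, n, n)
  img[mask] <- nucleus_level
  if (nrow(foci)) {
    foci$x_px <- cx + foci$x_rel * r_px
    foci$y_px <- cx + foci$y_rel * r_px
    for (i in seq_len(nrow(foci))) {
      # the divisor calibrates the above-threshold footprint of the spot to
      # its nominal area under the default detection settings
      sigma_px <- sqrt(foci$area_um2[i] / pi) / pixel_size_um / 2.75
      span <- ceiling(4 * sigma_px)
      rr <- pmax(1, round(foci$x_px[i]) - span):
        pmin(n, round(foci$x_px[i]) + span)
      cc <- pmax(1, round(foci$y_px[i]) - span):
        pmin(n, round(foci$y_px[i]) + span)
      d2 <- outer(rr - foci$x_px[i], cc - foci$y_px[i],
                  function(a, b) a^2 + b^2)
      img[rr, cc] <- img[rr, cc] + focus_peak * exp(-d2 / (2 * sigma_px^2))
    }
  }
  if (noise_sd > 0) {
    img <- with_seed(derive_seed(seed, "foci_noise"),
                     img + rnorm(length(img), 0, noise_sd))
  }
  list(image = clip16(img), mask = mask, truth = foci)
}

#' Generate a PCNA focus pattern for an S-phase sub-stage
#'
#' Early S: many small foci dispersed through the nucleus interior; mid S:
#' foci concentrated in a perinucleolar/ring annulus; late S: few large
#' peripheral clusters; non-S: almost no foci.
#'
#' @param stage `"nonS"`, `"earlyS"`, `"midS"` or `"lateS"`.
#' @param seed integer seed.
#' @return data.frame with `x_rel`, `y_rel`, `area_um2` and attribute
#'   `"stage"`.
#' @export
make_pcna_pattern <- function(stage = c("earlyS", "midS", "lateS", "nonS"),
                              seed = 1L) {
  stage <- match.arg(stage)
  with_seed(derive_seed(seed, paste0("pcna_", stage)), {
    out <- switch(stage,
      nonS = {
        n <- rpois(1, 1)
        data.frame(x_rel = runif(n, -0.3, 0.3), y_rel = runif(n, -0.3, 0.3),
                   area_um2 = rlnorm_mcv(n, 0.3, 0.3))
      },
      earlyS = {
        n <- 60 + rpois(1, 40)
        rad <- sqrt(runif(n)) * 0.8
        th <- runif(n, 0, 2 * pi)
        data.frame(x_rel = rad * cos(th), y_rel = rad * sin(th),
                   area_um2 = rlnorm_mcv(n, 0.15, 0.3))
      },
      midS = {
        n <- 30 + rpois(1, 10)
        rad <- runif(n, 0.55, 0.75)
        th <- (seq_len(n) + runif(n, -0.25, 0.25)) * 2 * pi / n # spaced ring
        data.frame(x_rel = rad * cos(th), y_rel = rad * sin(th),
                   area_um2 = rlnorm_mcv(n, 0.25, 0.3))
      },
      lateS = {
        n <- 6 + rpois(1, 4)
        rad <- runif(n, 0.78, 0.92)
        th <- (seq_len(n) + runif(n, -0.3, 0.3)) * 2 * pi / n # spaced ring
        data.frame(x_rel = rad * cos(th), y_rel = rad * sin(th),
                   area_um2 = rlnorm_mcv(n, 1.6, 0.25))
      }
    )
    attr(out, "stage") <- stage
    out
  })
}
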