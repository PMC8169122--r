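## Nuclear/cell area measurement and control-calibrated stable/enlarged
## gating, the imaging analogue of a size sort gated on untreated controls.

#' Measure object areas from a label mask
#'
#' @param labels integer label matrix (0 = background).
#' @param pixel_size_um microns per pixel (> 0).
#' @param condition condition label recorded per record.
#' @return data.frame of size records: `cell_id`, `condition`,
#'   `nuclear_area_um2`, `gate` (UNSET); empty for an empty labelling.
#' @export
measure_areas <- function(labels, pixel_size_um = 0.65,
                          condition = "sample") {
  check_scalar(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  n <- max(labels)
  if (n == 0L) {
    return(data.frame(cell_id = integer(0), condition = character(0),
                      nuclear_area_um2 = numeric(0), gate = character(0)))
  }
  sizes <- tabulate(labels[labels > 0], nbins = n)
  keep <- which(sizes > 0)
  data.frame(
    cell_id = keep,
    condition = condition,
    nuclear_area_um2 = sizes[keep] * pixel_size_um^2,
    gate = "UNSET"
  )
}

#' Gate treated cells into stable vs enlarged classes
#'
#' The gate is calibrated on untreated control cells only: the threshold is
#' the `control_quantile` quantile of the control nuclear areas, and a
#' treated cell is ENLARGED iff its area strictly exceeds the threshold.
#' Adding or removing treated cells never moves the gate.
#'
#' @param treated,control size-record data.frames (column
#'   `nuclear_area_um2`); at least 50 control records are required.
#' @param control_quantile calibration quantile (default 0.975).
#' @return list with `records` (treated records with `gate` filled in),
#'   `threshold_um2`, `enlarged_fraction`, and
#'   `enlarged_fold_change` (mean enlarged area over mean control area).
#' @export
gate_stable_enlarged <- function(treated, control, control_quantile = 0.975) {
  if (nrow(control) < 50L) {
    stop("at least 50 control records are required to calibrate the gate",
         call. = FALSE)
  }
  check_scalar(control_quantile, "control_quantile", 0)
  thr <- quantile(control$nuclear_area_um2, control_quantile, names = FALSE)
  treated$gate <- ifelse(treated$nuclear_area_um2 > thr, "ENLARGED", "STABLE")
  enlarged <- treated$nuclear_area_um2[treated$gate == "ENLARGED"]
  list(
    records = treated,
    threshold_um2 = thr,
    enlarged_fraction = mean(treated$gate == "ENLARGED"),
    enlarged_fold_change = if (length(enlarged)) {
      mean(enlarged) / mean(control$nuclear_area_um2)
    } else NA_real_
  )
}

#' Fold change in mean area with a bootstrap interval
#'
#' @param treated,control numeric area vectors or size-record data.frames.
#' @param n_boot bootstrap replicates (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed bootstrap seed (fixed for reproducibility).
#' @return list with `ratio` (mean treated / mean control), `ci` (two
#'   quantiles of the bootstrap ratio distribution), `n_treated`,
#'   `n_control`. A zero-variance degenerate comparison collapses the
#'   interval to a point with a warning.
#' @export
fold_change <- function(treated, control, n_boot = 1000L, conf = 0.95,
                        seed = 1L) {
  pull <- function(x) {
    if (is.data.frame(x)) x$nuclear_area_um2 else as.numeric(x)
  }
  tr <- pull(treated); ct <- pull(control)
  if (length(tr) == 0L || length(ct) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ratio <- mean(tr) / mean(ct)
  if (sd(ct) == 0 && sd(tr) == 0) {
    warning("zero-variance groups: interval collapses to a point",
            call. = FALSE)
    return(list(ratio = ratio, ci = c(ratio, ratio),
                n_treated = length(tr), n_control = length(ct)))
  }
  boots <- with_seed(derive_seed(seed, "fold_change_boot"), {
    vapply(seq_len(n_boot), function(i) {
      mean(sample(tr, replace = TRUE)) / mean(sample(ct, replace = TRUE))
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  list(ratio = ratio,
       ci = unname(quantile(boots, c(alpha, 1 - alpha))),
       n_treated = length(tr), n_control = length(ct))
}
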