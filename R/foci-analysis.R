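## 53BP1/PCNA focus detection and quantification: projection, nucleus
## segmentation, robust per-nucleus thresholding, focus-count classes,
## PCNA-based S-phase sub-staging and per-generation time-series summaries.

#' Maximum-intensity projection of a z-stack
#'
#' @param zstack 3D array (row, col, slice) or a list of matrices; a single
#'   matrix (or one-slice stack) is returned unchanged.
#' @return 2D matrix of per-pixel maxima across slices.
#' @export
max_project <- function(zstack) {
  if (is.list(zstack)) {
    if (length(zstack) == 0L) stop("empty stack", call. = FALSE)
    zstack <- simplify2array(zstack)
  }
  if (is.matrix(zstack)) return(zstack)
  if (!is.array(zstack) || length(dim(zstack)) != 3L || dim(zstack)[3] < 1L) {
    stop("zstack must be a matrix or a (row, col, slice) array with >= 1 slice",
         call. = FALSE)
  }
  apply(zstack, c(1, 2), max)
}

#' Segment nuclei as bright regions on a dark background
#'
#' Otsu threshold (or a supplied absolute threshold) followed by
#' connected-component labelling; components below the minimum area are
#' removed and labels are compacted.
#'
#' @param image 2D matrix.
#' @param pixel_size_um microns per pixel (default 0.2).
#' @param min_area_um2 minimum nucleus area (default 20).
#' @param threshold optional absolute intensity threshold; default Otsu on
#'   the 16-bit range.
#' @return Integer label matrix (0 = background); warns when nothing is
#'   found.
#' @export
segment_nuclei <- function(image, pixel_size_um = 0.2, min_area_um2 = 20,
                           threshold = NULL) {
  check_scalar(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  if (is.null(threshold)) {
    threshold <- EBImage::otsu(image / MAX16, range = c(0, 1)) * MAX16
  }
  fg <- image > threshold
  if (!any(fg)) {
    warning("no foreground found; empty labelling", call. = FALSE)
    return(matrix(0L, nrow(image), ncol(image)))
  }
  lab <- EBImage::bwlabel(fg)
  min_px <- min_area_um2 / pixel_size_um^2
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  out <- matrix(0L, nrow(image), ncol(image))
  for (j in seq_along(keep)) out[lab == keep[j]] <- j
  out
}

#' Detect foci within a nucleus mask
#'
#' Thresholds at the per-nucleus robust level `median + k_mad * MAD` of the
#' in-mask intensities, labels connected components above threshold, and
#' keeps those of area at least `min_area_um2`. The median+MAD rule is
#' affine-equivariant, so rescaling the image intensities by a positive
#' constant leaves the detected foci unchanged.
#'
#' @param image 2D matrix (a projection).
#' @param nucleus_mask logical matrix (or 0/1), non-empty.
#' @param k_mad threshold multiplier (default 3).
#' @param min_area_um2 minimum focus area (default 0.08, about 2 px at
#'   0.2 um/px).
#' @param pixel_size_um microns per pixel (> 0).
#' @return list of class `foci_record`: `count`, `foci` (data.frame `x`,
#'   `y` 0-based centroids, `area_um2`, `mean_intensity`), `threshold`.
#' @export
detect_foci <- function(image, nucleus_mask, k_mad = 3, min_area_um2 = 0.08,
                        pixel_size_um = 0.2) {
  check_scalar(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  mask <- nucleus_mask > 0
  if (!any(mask)) stop("nucleus mask is empty", call. = FALSE)
  vals <- image[mask]
  thr <- median(vals) + k_mad * mad(vals)
  fg <- image > thr & mask
  lab <- EBImage::bwlabel(fg)
  n <- max(lab)
  foci <- data.frame(x = numeric(0), y = numeric(0), area_um2 = numeric(0),
                     mean_intensity = numeric(0))
  if (n > 0) {
    px_area <- pixel_size_um^2
    idx <- which(lab > 0)
    lv <- lab[idx]
    sizes <- tabulate(lv, nbins = n)
    xs <- tapply(row(lab)[idx], lv, mean) - 1
    ys <- tapply(col(lab)[idx], lv, mean) - 1
    mi <- tapply(image[idx], lv, mean)
    foci <- data.frame(x = as.numeric(xs), y = as.numeric(ys),
                       area_um2 = sizes * px_area,
                       mean_intensity = as.numeric(mi))
    foci <- foci[foci$area_um2 >= min_area_um2, , drop = FALSE]
    rownames(foci) <- NULL
  }
  structure(list(count = nrow(foci), foci = foci, threshold = thr),
            class = "foci_record")
}

#' Fractions of cells in focus-count classes
#'
#' Bins per-cell focus counts into fewer than `cutoffs[1]` (strict),
#' `cutoffs[1]` to `cutoffs[2]` (inclusive), and more than `cutoffs[2]`
#' (strict).
#'
#' @param counts integer vector of per-cell focus counts (>= 1 cell).
#' @param cutoffs two class boundaries (default `c(5, 15)`).
#' @return Named numeric vector `low`, `mid`, `high` summing to 1.
#' @export
foci_classes <- function(counts, cutoffs = c(5, 15)) {
  if (length(counts) == 0L) stop("at least one cell is required",
                                 call. = FALSE)
  stopifnot(length(cutoffs) == 2L, cutoffs[1] < cutoffs[2])
  low <- mean(counts < cutoffs[1])
  high <- mean(counts > cutoffs[2])
  c(low = low, mid = 1 - low - high, high = high)
}

#' Sub-stage S phase from the PCNA focus pattern
#'
#' Operational rules on the detected PCNA foci: fewer than `min_s_foci`
#' foci is non-S; few large foci at the nuclear periphery is late S; many
#' foci concentrated in a perinucleolar annulus (low spread of radial
#' positions) is mid S; many small foci dispersed through the interior is
#' early S. Radial positions are measured from the nucleus centroid in
#' units of the equivalent nucleus radius.
#'
#' @param record a `foci_record` from [detect_foci()] on the PCNA channel.
#' @param nucleus_mask logical matrix of the nucleus (required).
#' @param min_s_foci minimum focus count of a replicating cell (default 4).
#' @param late_max_count,late_min_area late-S rule: at most this many foci
#'   (default 25) with mean area above this (default 0.8 um^2).
#' @param mid_radial_sd_max maximum radial-position spread for the
#'   perinucleolar ring (default 0.13).
#' @return One of `"nonS"`, `"earlyS"`, `"midS"`, `"lateS"`.
#' @export
classify_s_stage <- function(record, nucleus_mask, min_s_foci = 4,
                             late_max_count = 25, late_min_area = 0.8,
                             mid_radial_sd_max = 0.13) {
  if (missing(nucleus_mask) || is.null(nucleus_mask)) {
    stop("nucleus mask is required", call. = FALSE)
  }
  mask <- nucleus_mask > 0
  if (record$count < min_s_foci) return("nonS")
  cx <- mean(row(mask)[mask]) - 1
  cy <- mean(col(mask)[mask]) - 1
  req <- sqrt(sum(mask) / pi) # equivalent nucleus radius, px
  radial <- sqrt((record$foci$x - cx)^2 + (record$foci$y - cy)^2) / req
  if (record$count <= late_max_count &&
      mean(record$foci$area_um2) >= late_min_area &&
      median(radial) > 0.6) {
    return("lateS")
  }
  if (sd(radial) <= mid_radial_sd_max && median(radial) > 0.4) {
    return("midS")
  }
  "earlyS"
}

#' Per-generation summaries of a focus time series
#'
#' Summarises a lineage focus record (e.g. from [make_foci_series()] or
#' compiled from per-frame [detect_foci()] output) per generation: the peak
#' focus count, the mean and maximum focus area during G1, and whether the
#' peak count decreases from the previous generation.
#'
#' @param records data.frame with time-ordered rows and columns `time_min`,
#'   `generation`, `phase`, `count`, `mean_area_um2` (and optionally
#'   `max_area_um2`).
#' @return data.frame per generation: `generation`, `peak_count`,
#'   `g1_mean_area_um2`, `g1_max_area_um2`, `count_decreasing`.
#' @export
foci_timeseries <- function(records) {
  need <- c("time_min", "generation", "phase", "count", "mean_area_um2")
  if (!all(need %in% names(records))) {
    stop("records must carry columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.unsorted(records$time_min)) {
    stop("records must be time-ordered", call. = FALSE)
  }
  gens <- sort(unique(records$generation))
  out <- do.call(rbind, lapply(gens, function(g) {
    sub <- records[records$generation == g, , drop = FALSE]
    g1 <- sub[sub$phase == "G1" & sub$count > 0, , drop = FALSE]
    data.frame(
      generation = g,
      peak_count = max(sub$count),
      g1_mean_area_um2 = if (nrow(g1)) mean(g1$mean_area_um2) else NA_real_,
      g1_max_area_um2 = if (nrow(g1)) {
        max(if (!is.null(g1$max_area_um2)) g1$max_area_um2 else
          g1$mean_area_um2)
      } else NA_real_
    )
  }))
  out$count_decreasing <- c(NA, diff(out$peak_count) < 0)
  out
}
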