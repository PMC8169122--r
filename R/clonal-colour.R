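## RGB clonal-colour analysis: preprocessing, per-cell RGB extraction,
## extreme-value filtering, 512-colour quantisation, top-64 reduction,
## >0.1% clone calling and diversity summaries.

#' Rolling-ball (sliding-paraboloid) background subtraction
#'
#' Estimates a smooth background as the greyscale opening of each channel
#' with a paraboloid-of-revolution structuring element of the given pixel
#' radius (the paraboloid depth equals the channel's dynamic range at the
#' rim, so features narrower than the radius are excluded from the
#' background while gradients at scale >= radius are kept). The additive
#' separability of the paraboloid makes the opening exact as two passes of
#' one-dimensional erosions/dilations. A flat-disc morphological opening is
#' available as `method = "opening"` and agrees with the paraboloid within a
#' few percent on smooth scenes.
#'
#' @param image 2D matrix or 3-channel (row, col, channel) array.
#' @param ball_radius structuring-element radius in pixels (default 250).
#' @param per_channel process channels independently (default TRUE; with
#'   FALSE the channel mean is used to estimate one shared background).
#' @param method `"paraboloid"` (default) or `"opening"`.
#' @return Image of the same shape with the background removed; values are
#'   non-negative.
#' @export
subtract_background <- function(image, ball_radius = 250, per_channel = TRUE,
                                method = c("paraboloid", "opening")) {
  method <- match.arg(method)
  check_scalar(ball_radius, "ball_radius", 1)
  arr <- as_channel_array(image)
  if (ball_radius > nrow(arr) && ball_radius > ncol(arr)) {
    stop("ball_radius exceeds both image dimensions", call. = FALSE)
  }
  bg_of <- function(ch) estimate_background(ch, ball_radius, method)
  out <- arr
  if (per_channel) {
    for (k in seq_len(dim(arr)[3])) {
      out[, , k] <- pmax(arr[, , k] - bg_of(arr[, , k]), 0)
    }
  } else {
    shared <- bg_of(apply(arr, c(1, 2), mean))
    for (k in seq_len(dim(arr)[3])) out[, , k] <- pmax(arr[, , k] - shared, 0)
  }
  if (is.matrix(image)) out[, , 1] else out
}

# Background of one channel by greyscale opening.
estimate_background <- function(ch, radius, method) {
  if (method == "opening") {
    side <- min(2 * as.integer(radius) + 1L, min(dim(ch)) - 1L)
    if (side %% 2L == 0L) side <- side - 1L
    kern <- EBImage::makeBrush(max(side, 3L), shape = "disc")
    # EBImage greyscale morphology expects intensities in [0, 1]
    lo <- min(ch); hi <- max(ch)
    if (hi <= lo) return(ch)
    return(EBImage::opening((ch - lo) / (hi - lo), kern) * (hi - lo) + lo)
  }
  depth <- max(ch) - min(ch)
  if (depth <= 0) return(ch) # constant image: background is the image
  r <- as.integer(min(radius, max(dim(ch)) - 1L))
  prof <- depth * ((0:r) / radius)^2 # paraboloid height profile
  ero <- parab_pass(parab_pass(ch, prof, op = "erode"), prof, op = "erode",
                    along = "col")
  parab_pass(parab_pass(ero, prof, op = "dilate"), prof, op = "dilate",
             along = "col")
}

# One-dimensional greyscale erosion/dilation with an additive quadratic
# structuring element, applied along rows or columns of a matrix.
parab_pass <- function(m, prof, op = c("erode", "dilate"),
                       along = c("row", "col")) {
  op <- match.arg(op); along <- match.arg(along)
  out <- m
  r <- length(prof) - 1L
  for (d in seq(-r, r)) {
    h <- prof[abs(d) + 1L]
    sh <- if (along == "row") shift_na(m, d, 0L) else shift_na(m, 0L, d)
    if (op == "erode") {
      cand <- sh + h
      out <- pmin(out, cand, na.rm = TRUE)
    } else {
      cand <- sh - h
      out <- pmax(out, cand, na.rm = TRUE)
    }
  }
  out
}

#' Disc mean filter
#'
#' Replaces each pixel by the arithmetic mean over the disc neighbourhood of
#' the given radius (circular kernel). At the image border the mean is taken
#' over the in-bounds part of the disc, so constant images are unchanged
#' everywhere.
#'
#' @param image 2D matrix or 3-channel array.
#' @param radius disc radius in pixels (default 5).
#' @return Smoothed image of the same shape.
#' @export
smooth_mean <- function(image, radius = 5) {
  check_scalar(radius, "radius", 1)
  arr <- as_channel_array(image)
  offs <- disc_offsets(radius)
  smooth_one <- function(ch) {
    acc <- matrix(0, nrow(ch), ncol(ch))
    cnt <- matrix(0, nrow(ch), ncol(ch))
    for (i in seq_len(nrow(offs))) {
      sh <- shift_na(ch, offs$dx[i], offs$dy[i])
      ok <- !is.na(sh)
      acc[ok] <- acc[ok] + sh[ok]
      cnt <- cnt + ok
    }
    acc / cnt
  }
  out <- arr
  for (k in seq_len(dim(arr)[3])) out[, , k] <- smooth_one(arr[, , k])
  if (is.matrix(image)) out[, , 1] else out
}

#' Detect cells as prominent regional maxima
#'
#' Runs on the channel sum of a preprocessed (background-subtracted,
#' smoothed) image. Maxima are found with an h-maxima transform: the image
#' minus `noise_tolerance` is reconstructed under the image by iterative
#' geodesic dilation, and the regional maxima of the reconstruction — one
#' per maximum with prominence exceeding the tolerance — are returned as
#' plateau centroids.
#'
#' @param image 2D matrix or 3-channel array (channels are summed).
#' @param noise_tolerance minimum prominence of a maximum (> 0; grey
#'   levels; default 10).
#' @return data.frame with `x`, `y` (0-based row/col pixel coordinates of
#'   plateau centroids).
#' @export
detect_cells <- function(image, noise_tolerance = 10) {
  check_scalar(noise_tolerance, "noise_tolerance", 0, strict = TRUE)
  arr <- as_channel_array(image)
  img <- apply(arr, c(1, 2), sum)
  if (max(img) <= noise_tolerance) {
    return(data.frame(x = numeric(0), y = numeric(0)))
  }
  rec <- reconstruct_grey(img - noise_tolerance, img)
  # h-dome: img - rec reaches the tolerance exactly on the summit plateau of
  # every maximum whose prominence exceeds it
  dome <- img - rec
  keep <- dome >= noise_tolerance * (1 - 1e-9) & img > noise_tolerance
  lab <- EBImage::bwlabel(keep)
  n <- max(lab)
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  xs <- tapply(row(lab)[lab > 0], lab[lab > 0], mean)
  ys <- tapply(col(lab)[lab > 0], lab[lab > 0], mean)
  data.frame(x = as.numeric(xs) - 1, y = as.numeric(ys) - 1)
}

# Morphological greyscale reconstruction of `marker` under `mask` by
# iterated 3x3 geodesic dilation. Intensities are normalised into [0, 1]
# for EBImage's greyscale dilation and rescaled on return.
reconstruct_grey <- function(marker, mask, max_iter = 4096L) {
  lo <- min(marker, mask); hi <- max(mask)
  if (hi <= lo) return(mask)
  marker <- (marker - lo) / (hi - lo)
  mask_n <- (mask - lo) / (hi - lo)
  box <- EBImage::makeBrush(3, "box")
  r <- pmin(marker, mask_n)
  tol <- 1e-9
  for (i in seq_len(max_iter)) {
    nxt <- pmin(EBImage::dilate(r, box), mask_n)
    if (max(abs(nxt - r)) < tol) break
    r <- nxt
  }
  r * (hi - lo) + lo
}

#' Sample per-cell RGB means from the raw image
#'
#' Applies a circular ROI of the given radius at each detected point to the
#' unprocessed image and records the mean red, green and blue intensities.
#' ROIs at the border are clipped to the image, and the mean is taken over
#' the in-bounds part of the disc.
#'
#' @param raw_image 3-channel (row, col, channel) array, channel order R,G,B.
#' @param points data.frame with `x`, `y` (0-based row/col coordinates) as
#'   returned by [detect_cells()]; an empty frame gives an empty table.
#' @param roi_radius ROI radius in pixels (default 5).
#' @param image_id identifier recorded per record.
#' @return data.frame of RGB cell records: `cell_id`, `image_id`, `x`, `y`,
#'   `mean_r`, `mean_g`, `mean_b`.
#' @export
sample_roi_rgb <- function(raw_image, points, roi_radius = 5,
                           image_id = "image") {
  arr <- as_channel_array(raw_image)
  if (dim(arr)[3] != 3L) stop("raw_image must have three channels (R,G,B)",
                              call. = FALSE)
  if (nrow(points) == 0L) {
    return(data.frame(cell_id = integer(0), image_id = character(0),
                      x = numeric(0), y = numeric(0), mean_r = numeric(0),
                      mean_g = numeric(0), mean_b = numeric(0)))
  }
  if (any(points$x < 0 | points$x > nrow(arr) - 1 |
          points$y < 0 | points$y > ncol(arr) - 1)) {
    stop("points must lie inside the image", call. = FALSE)
  }
  offs <- disc_offsets(roi_radius)
  means <- matrix(NA_real_, nrow(points), 3)
  for (i in seq_len(nrow(points))) {
    rr <- round(points$x[i]) + 1L + offs$dx
    cc <- round(points$y[i]) + 1L + offs$dy
    ok <- rr >= 1 & rr <= nrow(arr) & cc >= 1 & cc <= ncol(arr)
    idx <- cbind(rr[ok], cc[ok])
    for (k in 1:3) means[i, k] <- mean(arr[, , k][idx])
  }
  data.frame(cell_id = seq_len(nrow(points)), image_id = image_id,
             x = points$x, y = points$y,
             mean_r = means[, 1], mean_g = means[, 2], mean_b = means[, 3])
}

#' Remove cells with extreme channel values
#'
#' A record is removed iff any of its three channel means lies outside the
#' per-channel `[low_quantile, high_quantile]` band (or outside absolute
#' `bounds` when given). The removal reason is logged per cell.
#'
#' @param records RGB cell records (needs `mean_r`, `mean_g`, `mean_b`).
#' @param low_quantile,high_quantile per-channel quantile band (defaults
#'   0.01 and 0.99).
#' @param bounds optional numeric `c(low, high)` absolute intensity bounds
#'   applied to all channels instead of quantiles.
#' @return The retained records, with the rejection log (data.frame
#'   `cell_id`, `reason`) as attribute `"rejections"`.
#' @export
filter_rgb_extremes <- function(records, low_quantile = 0.01,
                                high_quantile = 0.99, bounds = NULL) {
  if (nrow(records) == 0L) stop("no records to filter", call. = FALSE)
  chans <- c("mean_r", "mean_g", "mean_b")
  if (is.null(bounds) && nrow(records) < 10L) {
    stop("at least 10 records are required for quantile estimation",
         call. = FALSE)
  }
  reasons <- rep("", nrow(records))
  for (ch in chans) {
    v <- records[[ch]]
    lim <- if (is.null(bounds)) {
      quantile(v, c(low_quantile, high_quantile), names = FALSE)
    } else bounds
    lo <- v < lim[1]; hi <- v > lim[2]
    reasons[lo] <- paste0(reasons[lo], ch, " too low;")
    reasons[hi] <- paste0(reasons[hi], ch, " too high;")
  }
  drop <- reasons != ""
  if (all(drop)) {
    stop("all records rejected; review the filtering thresholds",
         call. = FALSE)
  }
  out <- records[!drop, , drop = FALSE]
  attr(out, "rejections") <- data.frame(
    cell_id = records$cell_id[drop], reason = reasons[drop]
  )
  out
}

# Per-channel bin indices (0-based) of RGB values over the fixed 16-bit range.
colour_bin <- function(v, bins = 8L) {
  pmin(floor(as.numeric(v) / (MAX16 + 1) * bins), bins - 1L)
}

#' Quantise cell colours into fixed RGB classes
#'
#' Each channel is divided into `bins_per_channel` equal bins over the full
#' 16-bit range `[0, 65535]`, giving `bins_per_channel^3` colour classes
#' (512 with the default 8). The class index is
#' `bins^2 * bin_r + bins * bin_g + bin_b`.
#'
#' @param records RGB cell records.
#' @param bins_per_channel bins per channel (>= 2; default 8).
#' @return `records` with added columns `colour_class` (integer in
#'   `[0, bins^3 - 1]`) and per-channel `bin_r`, `bin_g`, `bin_b`.
#' @export
quantise_colours <- function(records, bins_per_channel = 8L) {
  check_scalar(bins_per_channel, "bins_per_channel", 2)
  b <- as.integer(bins_per_channel)
  vals <- records[, c("mean_r", "mean_g", "mean_b")]
  if (any(vals < 0 | vals > MAX16)) {
    stop("intensities must lie within [0, 65535]", call. = FALSE)
  }
  records$bin_r <- colour_bin(records$mean_r, b)
  records$bin_g <- colour_bin(records$mean_g, b)
  records$bin_b <- colour_bin(records$mean_b, b)
  records$colour_class <- as.integer(
    b^2 * records$bin_r + b * records$bin_g + records$bin_b
  )
  records
}

#' Reduce assignments to the k most represented colours
#'
#' The `k` most frequent colour classes receive reduced ids `0..k-1` in
#' descending frequency (ties broken by ascending colour-class index); all
#' other cells are UNASSIGNED (`NA`). Coverage is the assigned fraction of
#' all cells. With fewer than `k` distinct classes, all classes are kept
#' (coverage 1) with a warning.
#'
#' @param assignments output of [quantise_colours()].
#' @param k size of the reduced colour set (default 64).
#' @return `assignments` with a `reduced_class` column; the coverage
#'   fraction is attached as attribute `"coverage"` and the class ranking as
#'   attribute `"class_ranking"`.
#' @export
top_k_reduction <- function(assignments, k = 64L) {
  check_scalar(k, "k", 1)
  counts <- table(assignments$colour_class)
  classes <- as.integer(names(counts))
  ord <- order(-as.integer(counts), classes)
  ranked <- classes[ord]
  if (length(ranked) < k) {
    warning(sprintf(
      "only %d distinct colour classes present (k = %d); keeping all",
      length(ranked), as.integer(k)
    ), call. = FALSE)
  }
  kept <- head(ranked, k)
  assignments$reduced_class <-
    match(assignments$colour_class, kept) - 1L # NA = UNASSIGNED
  coverage <- mean(!is.na(assignments$reduced_class))
  attr(assignments, "coverage") <- coverage
  attr(assignments, "class_ranking") <- ranked
  assignments
}

#' Call positive clonal colours
#'
#' Computes clone abundances over the reduced colour set. Fractions use all
#' cells (including UNASSIGNED) as denominator; a clone is positive iff its
#' fraction strictly exceeds `min_fraction` (default 0.001, i.e. >0.1% of
#' the population).
#'
#' @param assignments output of [top_k_reduction()].
#' @param min_fraction positivity threshold on the population fraction.
#' @return A `clone_table` data.frame sorted by count descending (ties by
#'   ascending colour class): `reduced_class`, `colour_class`, `count`,
#'   `fraction`, `is_positive_clone`; attributes `"n_cells"`,
#'   `"coverage"`, `"n_positive"`.
#' @export
call_clones <- function(assignments, min_fraction = 0.001) {
  check_scalar(min_fraction, "min_fraction", 0)
  n_cells <- nrow(assignments)
  if (n_cells == 0L) {
    tab <- data.frame(reduced_class = integer(0), colour_class = integer(0),
                      count = integer(0), fraction = numeric(0),
                      is_positive_clone = logical(0))
    class(tab) <- c("clone_table", "data.frame")
    attr(tab, "n_cells") <- 0L
    attr(tab, "coverage") <- NA_real_
    attr(tab, "n_positive") <- 0L
    return(tab)
  }
  if (!"reduced_class" %in% names(assignments)) {
    stop("assignments must carry 'reduced_class'; run top_k_reduction() first",
         call. = FALSE)
  }
  assigned <- assignments[!is.na(assignments$reduced_class), , drop = FALSE]
  if (nrow(assigned) == 0L) {
    tab <- data.frame(reduced_class = integer(0), colour_class = integer(0),
                      count = integer(0), fraction = numeric(0),
                      is_positive_clone = logical(0))
    class(tab) <- c("clone_table", "data.frame")
    attr(tab, "n_cells") <- n_cells
    attr(tab, "coverage") <- 0
    attr(tab, "n_positive") <- 0L
    return(tab)
  }
  agg <- aggregate(cell_count ~ reduced_class + colour_class,
                   data = data.frame(assigned[c("reduced_class",
                                                "colour_class")],
                                     cell_count = 1L),
                   FUN = sum)
  agg <- agg[order(-agg$cell_count, agg$colour_class), , drop = FALSE]
  tab <- data.frame(
    reduced_class = agg$reduced_class,
    colour_class = agg$colour_class,
    count = as.integer(agg$cell_count),
    fraction = agg$cell_count / n_cells
  )
  tab$is_positive_clone <- tab$fraction > min_fraction
  rownames(tab) <- NULL
  class(tab) <- c("clone_table", "data.frame")
  attr(tab, "n_cells") <- n_cells
  attr(tab, "coverage") <- sum(tab$count) / n_cells
  attr(tab, "n_positive") <- sum(tab$is_positive_clone)
  tab
}

#' Clonal diversity summaries
#'
#' Richness is the number of positive clones; the Shannon index and Pielou
#' evenness are computed over positive-clone fractions renormalised to sum
#' to one; the cells-per-clone summary covers positive clones.
#'
#' @param clone_table output of [call_clones()].
#' @return list with `richness`, `shannon`, `evenness` (NA for a single
#'   clone), `cells_per_clone` (named min/median/mean/max), `flag`
#'   (character; "empty" when no positive clones).
#' @export
clone_diversity <- function(clone_table) {
  pos <- clone_table[clone_table$is_positive_clone, , drop = FALSE]
  if (nrow(pos) == 0L) {
    return(list(richness = 0L, shannon = NA_real_, evenness = NA_real_,
                cells_per_clone = c(min = NA, median = NA, mean = NA,
                                    max = NA),
                flag = "empty"))
  }
  p <- pos$fraction / sum(pos$fraction)
  shannon <- -sum(p * log(p))
  list(
    richness = nrow(pos),
    shannon = shannon,
    evenness = if (nrow(pos) > 1) shannon / log(nrow(pos)) else NA_real_,
    cells_per_clone = c(min = min(pos$count), median = median(pos$count),
                        mean = mean(pos$count), max = max(pos$count)),
    flag = "ok"
  )
}

#' Full clonal-colour pipeline on one image
#'
#' Background subtraction, smoothing, maxima detection on the channel sum,
#' ROI sampling of the raw image, extreme-value filtering, quantisation,
#' top-k reduction and clone calling.
#'
#' @param image 3-channel raw image (R,G,B).
#' @param ball_radius,smooth_radius,noise_tolerance,roi_radius,k,min_fraction
#'   stage parameters (see the stage functions).
#' @param filter_extremes apply [filter_rgb_extremes()] (default TRUE).
#' @return list with `records` (assignments) and `clones` (clone table).
#' @export
analyze_clone_image <- function(image, ball_radius = 250, smooth_radius = 5,
                                noise_tolerance = 10, roi_radius = 5,
                                k = 64L, min_fraction = 0.001,
                                filter_extremes = TRUE) {
  arr <- as_channel_array(image)
  pre <- subtract_background(arr, ball_radius)
  pre <- smooth_mean(pre, smooth_radius)
  pts <- detect_cells(pre, noise_tolerance)
  rec <- sample_roi_rgb(arr, pts, roi_radius)
  if (filter_extremes && nrow(rec) >= 10L) {
    rec <- filter_rgb_extremes(rec)
  }
  rec <- quantise_colours(rec)
  rec <- top_k_reduction(rec, k)
  list(records = rec, clones = call_clones(rec, min_fraction))
}
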