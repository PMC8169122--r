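# Clonal colour analysis: preprocessing, quantisation, clone calling.

test_that("background subtraction contracts hold on degenerate images", {
  expect_lt(max(abs(subtract_background(matrix(1000, 48, 48), 20))), 1)
  expect_identical(subtract_background(matrix(0, 48, 48), 20),
                   matrix(0, 48, 48))
  expect_error(subtract_background(matrix(0, 16, 16), 300), "dimensions")
})

test_that("rolling ball preserves a bright disc on a gradient", {
  n <- 128
  img <- outer(seq_len(n), seq_len(n), function(i, j) 2000 + 10 * i + 5 * j)
  offs <- expand.grid(dx = -4:4, dy = -4:4)
  offs <- offs[offs$dx^2 + offs$dy^2 <= 16, ]
  img[cbind(64 + offs$dx, 64 + offs$dy)] <-
    img[cbind(64 + offs$dx, 64 + offs$dy)] + 8000
  para <- subtract_background(img, 30, method = "paraboloid")
  open <- subtract_background(img, 30, method = "opening")
  expect_lt(abs(max(para) - 8000) / 8000, 0.05)
  expect_lt(abs(max(open) - 8000) / 8000, 0.05)
  # the two estimators agree on the reference instance
  expect_lt(abs(max(para) - max(open)) / 8000, 0.05)
  # background residual is flat away from the disc
  interior <- abs(row(img) - 64) < 25 & abs(col(img) - 64) < 25
  ondisc <- (row(img) - 64)^2 + (col(img) - 64)^2 <= 36
  expect_lt(max(para[interior & !ondisc]), 100)
})

test_that("disc mean filter matches direct convolution", {
  expect_equal(smooth_mean(matrix(7, 20, 20), 5), matrix(7, 20, 20))
  sp <- matrix(0, 31, 31)
  sp[16, 16] <- 970
  disc_n <- sum(outer(-5:5, -5:5, function(a, b) a^2 + b^2 <= 25))
  sm <- smooth_mean(sp, 5)
  expect_equal(sm[16, 16], 970 / disc_n)
  # impulse of amplitude a deflects any pixel by at most a/|disc|
  expect_lte(max(sm), 970 / disc_n + 1e-9)
})

test_that("maxima detection finds isolated spots and nothing in blanks", {
  n <- 96
  img <- matrix(0, n, n)
  d2 <- function(cx, cy) outer(seq_len(n) - cx, seq_len(n) - cy,
                               function(a, b) a^2 + b^2)
  img <- img + 5000 * exp(-d2(30, 30) / 18) + 5000 * exp(-d2(70, 60) / 18)
  pts <- detect_cells(img, noise_tolerance = 100)
  expect_identical(nrow(pts), 2L)
  got <- pts[order(pts$x), ]
  expect_lt(max(abs(got$x - c(29, 69))), 2)
  expect_lt(max(abs(got$y - c(29, 59))), 2)
  expect_identical(nrow(detect_cells(matrix(0, 32, 32), 10)), 0L)
  expect_error(detect_cells(img, 0), "noise_tolerance")
})

test_that("detected points match rendered ground-truth centroids", {
  pop <- grid_population(n_founders = 4, n_cells = 12)
  ri <- render_clone_image(pop, c(160, 160), cell_radius_px = 5,
                           noise_sd = 30, background = 50, seed = 4)
  pre <- smooth_mean(subtract_background(ri$image, 40), 5)
  pts <- detect_cells(pre, noise_tolerance = 400)
  expect_identical(nrow(pts), nrow(pop))
  # every truth centroid has a detection within 2 px
  for (i in seq_len(nrow(ri$truth))) {
    dmin <- min(sqrt((pts$x - ri$truth$x_px[i])^2 +
                       (pts$y - ri$truth$y_px[i])^2))
    expect_lt(dmin, 2)
  }
})

test_that("ROI sampling means match explicit pixel enumeration", {
  arr <- array(0, dim = c(11, 11, 3))
  arr[, , 1] <- matrix(seq_len(121), 11, 11)
  arr[, , 2] <- 500
  pts <- data.frame(x = 5, y = 5) # centre, 0-based
  rec <- sample_roi_rgb(arr, pts, roi_radius = 3)
  offs <- expand.grid(dx = -3:3, dy = -3:3)
  offs <- offs[offs$dx^2 + offs$dy^2 <= 9, ]
  expect_equal(rec$mean_r, mean(arr[, , 1][cbind(6 + offs$dx, 6 + offs$dy)]))
  expect_equal(rec$mean_g, 500)
  # corner point: clipped partial disc
  rec2 <- sample_roi_rgb(arr, data.frame(x = 0, y = 0), roi_radius = 3)
  keep <- offs[1 + offs$dx >= 1 & 1 + offs$dy >= 1, ]
  expect_equal(rec2$mean_r,
               mean(arr[, , 1][cbind(1 + keep$dx, 1 + keep$dy)]))
  # empty point list is not an error
  expect_identical(nrow(sample_roi_rgb(arr, pts[0, ])), 0L)
})

test_that("extreme-value filtering removes exactly the outliers", {
  base <- data.frame(cell_id = 1:40, mean_r = 30000, mean_g = 30000,
                     mean_b = 30000)
  expect_identical(nrow(filter_rgb_extremes(base)), 40L) # identical records
  rec <- base
  rec$mean_r[1:3] <- 65000 # 3 high outliers in one channel
  out <- filter_rgb_extremes(rec, bounds = c(1000, 60000))
  expect_identical(nrow(out), 37L)
  expect_identical(attr(out, "rejections")$cell_id, 1:3)
  expect_match(attr(out, "rejections")$reason[1], "mean_r too high")
  expect_error(filter_rgb_extremes(base[0, ]), "no records")
  expect_error(filter_rgb_extremes(base[1:5, ]), "at least 10")
  expect_error(filter_rgb_extremes(rec, bounds = c(0, 100)), "all records")
})

test_that("quantisation spans exactly bins^3 classes with the index formula", {
  sweep <- bin_centre_sweep(8L)
  q <- quantise_colours(sweep)
  expect_identical(length(unique(q$colour_class)), 512L)
  expect_identical(range(q$colour_class), c(0L, 511L))
  ext <- data.frame(cell_id = 1:2, mean_r = c(0, 65535),
                    mean_g = c(0, 65535), mean_b = c(0, 65535))
  expect_identical(quantise_colours(ext)$colour_class, c(0L, 511L))
})

test_that("quantisation matches brute-force per-channel binning", {
  set.seed(14)
  rec <- data.frame(cell_id = 1:300,
                    mean_r = runif(300, 0, 65535),
                    mean_g = runif(300, 0, 65535),
                    mean_b = runif(300, 0, 65535))
  q <- quantise_colours(rec)
  brute <- function(v) pmin(v %/% 8192, 7)
  expect_identical(q$colour_class,
                   as.integer(64 * brute(rec$mean_r) + 8 * brute(rec$mean_g) +
                                brute(rec$mean_b)))
})

test_that("top-k reduction ranks by frequency and reports coverage", {
  # constructed frequencies: top-2 mass = 0.93 of 100 cells
  classes <- rep(c(10L, 3L, 200L, 77L), times = c(55, 38, 4, 3))
  rec <- data.frame(cell_id = seq_along(classes), colour_class = classes)
  red <- top_k_reduction(rec, k = 2)
  expect_equal(attr(red, "coverage"), 0.93)
  expect_identical(red$reduced_class[red$colour_class == 10L][1], 0L)
  expect_identical(red$reduced_class[red$colour_class == 3L][1], 1L)
  expect_true(all(is.na(red$reduced_class[red$colour_class %in% c(200L, 77L)])))
  # tie at rank k broken by smaller class index
  tie <- data.frame(cell_id = 1:6, colour_class = rep(c(9L, 4L, 30L), each = 2))
  red2 <- top_k_reduction(tie, k = 2)
  expect_identical(sort(unique(red2$colour_class[!is.na(red2$reduced_class)])),
                   c(4L, 9L))
  # single colour: full coverage, one group
  one <- suppressWarnings(
    top_k_reduction(data.frame(cell_id = 1:5, colour_class = 7L), k = 3))
  expect_equal(attr(one, "coverage"), 1)
  expect_warning(top_k_reduction(data.frame(cell_id = 1, colour_class = 1L),
                                 k = 64), "distinct")
})

test_that("clone calling applies the strict >0.1% threshold", {
  # 3 clones strictly above 0.1% of 10000, one exactly at, one below
  counts <- c(a = 5000, b = 4000, c = 979, d = 10, e = 11)
  classes <- rep(1:5, times = counts)
  rec <- data.frame(cell_id = seq_along(classes), colour_class = classes)
  red <- suppressWarnings(top_k_reduction(rec, k = 64))
  expect_warning(tab <- call_clones(red), NA)
  expect_identical(attr(tab, "n_positive"), 4L) # 11/10000 > 0.001, 10 not
  expect_false(tab$is_positive_clone[tab$count == 10])
  expect_identical(tab$count, sort(tab$count, decreasing = TRUE))
  # single colour population
  one <- call_clones(suppressWarnings(top_k_reduction(
    data.frame(cell_id = 1:50, colour_class = 3L), k = 64)))
  expect_identical(attr(one, "n_positive"), 1L)
  expect_equal(one$fraction, 1)
  # empty input
  empty <- call_clones(data.frame(cell_id = integer(0),
                                  colour_class = integer(0),
                                  reduced_class = integer(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("diversity summaries match closed forms", {
  eq <- data.frame(cell_id = 1:640, colour_class = rep(1:64, each = 10))
  tab <- call_clones(top_k_reduction(eq, 64), min_fraction = 0.001)
  div <- clone_diversity(tab)
  expect_identical(div$richness, 64L)
  expect_equal(div$shannon, log(64))
  expect_equal(div$evenness, 1)
  two <- data.frame(cell_id = 1:100, colour_class = rep(1:2, times = c(90, 10)))
  div2 <- clone_diversity(call_clones(suppressWarnings(top_k_reduction(two, 64))))
  expect_equal(div2$shannon, -(0.9 * log(0.9) + 0.1 * log(0.1)))
  one <- data.frame(cell_id = 1:10, colour_class = 1L)
  div1 <- clone_diversity(call_clones(suppressWarnings(top_k_reduction(one, 64))))
  expect_identical(div1$richness, 1L)
  expect_equal(div1$shannon, 0)
})

test_that("monotonicity: threshold up, positives never up; k up, coverage never down", {
  set.seed(8)
  classes <- sample.int(40, 3000, replace = TRUE,
                        prob = rexp(40))
  rec <- data.frame(cell_id = seq_along(classes), colour_class = classes)
  red <- suppressWarnings(top_k_reduction(rec, 64))
  thresholds <- c(0.0005, 0.001, 0.005, 0.02, 0.1)
  pos <- vapply(thresholds,
                function(th) attr(call_clones(red, th), "n_positive"),
                integer(1))
  expect_true(all(diff(pos) <= 0))
  cov <- vapply(c(1, 2, 5, 10, 40, 64),
                function(k) attr(suppressWarnings(top_k_reduction(rec, k)),
                                 "coverage"),
                numeric(1))
  expect_true(all(diff(cov) >= 0))
})
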