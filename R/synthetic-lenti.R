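## Lentiviral RGB colour-mixing generator.
##
## Emulates co-transduction with three lentiviral vectors (red, green, blue):
## each founder cell receives a Poisson number of integrations per vector and
## a lognormal per-integration expression level, yielding a heritable colour
## code. Daughters inherit the founder colour exactly; measurement noise only
## enters when populations are rendered to images and re-sampled.

#' Lentiviral RGB colour-mixing model
#'
#' Defines how founder cells acquire their heritable RGB colour code:
#' per-channel vector copy numbers are Poisson with the given means, each
#' integration expresses at a lognormal level (coefficient of variation
#' `expression_cv`), and `expression_scale` converts copy-number-times-
#' expression into 16-bit intensity. Founders that would be colourless
#' (zero integrations across all three channels) are resampled, and by
#' default founder colour codes are also resampled until they are
#' distinguishable under the default 8x8x8 colour quantisation, emulating
#' the detection ceiling of the assay (at most `bins^3` distinguishable
#' codes, of which 64 groups are analysed).
#'
#' @param n_founders number of founder cells (default 64, the size of the
#'   reduced colour set used for analysis).
#' @param mean_integrations_per_channel expected vector copies for R, G, B.
#' @param expression_scale 16-bit intensity contributed by one integration at
#'   unit expression.
#' @param expression_cv lognormal coefficient of variation of per-integration
#'   expression.
#' @param background_level constant background intensity added at rendering.
#' @param founder_weights relative clone abundances (recycled/normalised);
#'   default equal.
#' @param distinct_classes logical; resample founder colours until all fall in
#'   distinct quantisation classes (default TRUE).
#' @param seed integer seed for founder colour sampling.
#' @return An object of class `lenti_mix_model`.
#' @export
lenti_mix_model <- function(n_founders = 64,
                            mean_integrations_per_channel = c(1.5, 1.5, 1.5),
                            expression_scale = 9000,
                            expression_cv = 0.25,
                            background_level = 400,
                            founder_weights = NULL,
                            distinct_classes = TRUE,
                            seed = 1L) {
  check_scalar(n_founders, "n_founders", 1, strict = FALSE)
  if (!is.numeric(mean_integrations_per_channel) ||
      length(mean_integrations_per_channel) != 3L ||
      any(mean_integrations_per_channel < 0)) {
    stop("'mean_integrations_per_channel' must be three non-negative numbers",
         call. = FALSE)
  }
  if (sum(mean_integrations_per_channel) <= 0) {
    stop(paste0(
      "'mean_integrations_per_channel' must have positive total: with all ",
      "three means at 0 every founder would be colourless"
    ), call. = FALSE)
  }
  check_scalar(expression_scale, "expression_scale", 0, strict = TRUE)
  check_scalar(expression_cv, "expression_cv", 0)
  check_scalar(background_level, "background_level", 0)
  if (is.null(founder_weights)) founder_weights <- rep(1, n_founders)
  if (any(founder_weights < 0) || sum(founder_weights) <= 0) {
    stop("'founder_weights' must be non-negative with positive sum",
         call. = FALSE)
  }
  founder_weights <- rep_len(founder_weights, n_founders)
  structure(
    list(
      n_founders = as.integer(n_founders),
      mean_integrations_per_channel = mean_integrations_per_channel,
      expression_scale = expression_scale,
      expression_cv = expression_cv,
      background_level = background_level,
      founder_weights = founder_weights / sum(founder_weights),
      distinct_classes = isTRUE(distinct_classes),
      seed = as.integer(seed)
    ),
    class = "lenti_mix_model"
  )
}

# Sample founder colour codes (true 16-bit RGB per founder).
sample_founder_colours <- function(model) {
  n <- model$n_founders
  mus <- model$mean_integrations_per_channel
  draw_one <- function() {
    repeat {
      k <- rpois(3L, mus)
      if (sum(k) > 0) break
    }
    expr <- vapply(k, function(ki) {
      if (ki == 0) 0 else sum(rlnorm_mcv(ki, 1, model$expression_cv))
    }, numeric(1))
    clip16(expr * model$expression_scale)
  }
  cols <- matrix(0, n, 3, dimnames = list(NULL, c("r", "g", "b")))
  seen <- character(0)
  for (i in seq_len(n)) {
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      rgb <- draw_one()
      if (!model$distinct_classes) break
      key <- paste(colour_bin(rgb), collapse = "/")
      if (!key %in% seen) {
        seen <- c(seen, key)
        break
      }
      if (attempt > 5000L) {
        stop(paste0(
          "could not draw ", n, " founders with distinct colour classes; ",
          "reduce 'n_founders' or set distinct_classes = FALSE"
        ), call. = FALSE)
      }
    }
    cols[i, ] <- rgb
  }
  cols
}

#' Generate a clonally marked cell population
#'
#' Draws `n_cells` cells from the founder clones of a colour-mixing model.
#' Founder colours are sampled once from the model and inherited exactly by
#' every cell of that clone (measurement noise enters only at image
#' rendering). Cell positions are uniform in the unit square and can be
#' re-scaled by [render_clone_image()].
#'
#' @param model a [lenti_mix_model()].
#' @param n_cells number of cells to draw (>= 1).
#' @return A data.frame with one row per cell: `cell_id`, `founder_id`,
#'   `r`, `g`, `b` (true 16-bit intensities), `x`, `y` (unit square).
#'   The founder colour table is attached as attribute `"founders"`.
#' @export
make_lenti_population <- function(model, n_cells) {
  if (!inherits(model, "lenti_mix_model")) {
    stop("'model' must be created with lenti_mix_model()", call. = FALSE)
  }
  check_scalar(n_cells, "n_cells", 1)
  with_seed(derive_seed(model$seed, "lenti_population"), {
    founders <- sample_founder_colours(model)
    founder_id <- sample.int(model$n_founders, n_cells, replace = TRUE,
                             prob = model$founder_weights)
    data.frame(
      cell_id = seq_len(n_cells),
      founder_id = founder_id,
      r = founders[founder_id, "r"],
      g = founders[founder_id, "g"],
      b = founders[founder_id, "b"],
      x = runif(n_cells),
      y = runif(n_cells)
    ) -> pop
    attr(pop, "founders") <- founders
    pop
  })
}

#' Render a clonal population to a 3-channel 16-bit image
#'
#' Cells are drawn as flat discs of their founder colour on a smooth
#' background, with optional additive Gaussian read noise. Channel order is
#' fixed as (R, G, B). Unit-square cell coordinates are scaled to the image
#' with a margin of one cell radius; a warning (not an error) is raised when
#' disc overlap exceeds the packing limit.
#'
#' @param population output of [make_lenti_population()].
#' @param image_shape integer (rows, cols) of the image.
#' @param cell_radius_px disc radius in pixels.
#' @param noise_sd additive Gaussian noise standard deviation (16-bit units).
#' @param background constant background level added to all channels
#'   (default: the model background carried by the caller, 0 if unknown).
#' @param max_overlap_frac warn when more than this fraction of disc pixels
#'   are shared between cells (default 0.05).
#' @param seed seed for the noise stream.
#' @return A list with `image` (rows x cols x 3 array of integers in
#'   `[0, 65535]`) and `truth` (data.frame `cell_id`, `founder_id`, `x_px`,
#'   `y_px` of disc centres, 0-based pixel coordinates).
#' @export
render_clone_image <- function(population, image_shape = c(256L, 256L),
                               cell_radius_px = 4, noise_sd = 0,
                               background = 0, max_overlap_frac = 0.05,
                               seed = 1L) {
  stopifnot(length(image_shape) == 2L)
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  check_scalar(cell_radius_px, "cell_radius_px", 1)
  check_scalar(noise_sd, "noise_sd", 0)
  img <- array(background, dim = c(nr, nc, 3L))
  if (nrow(population) == 0L) {
    truth <- data.frame(cell_id = integer(0), founder_id = integer(0),
                        x_px = numeric(0), y_px = numeric(0))
    img <- clip16(round(img))
    return(list(image = img, truth = truth))
  }
  r <- as.integer(cell_radius_px)
  margin <- r + 1
  row_px <- round(margin + population$y * (nr - 2 * margin)) # y -> rows
  col_px <- round(margin + population$x * (nc - 2 * margin))
  offs <- disc_offsets(r)
  cover <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(population))) {
    rr <- row_px[i] + offs$dx
    cc <- col_px[i] + offs$dy
    keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    idx <- cbind(rr[keep], cc[keep])
    cover[idx] <- cover[idx] + 1L
    for (ch in 1:3) {
      chan <- img[, , ch]
      chan[idx] <- population[[c("r", "g", "b")[ch]]][i] + background
      img[, , ch] <- chan
    }
  }
  occupied <- sum(cover > 0L)
  if (occupied > 0 && sum(cover > 1L) / occupied > max_overlap_frac) {
    warning(sprintf(
      "cell discs overlap on %.1f%% of occupied pixels (packing limit %.1f%%)",
      100 * sum(cover > 1L) / occupied, 100 * max_overlap_frac
    ), call. = FALSE)
  }
  if (noise_sd > 0) {
    img <- with_seed(derive_seed(seed, "render_noise"),
                     img + rnorm(length(img), 0, noise_sd))
  }
  img <- clip16(round(img))
  list(
    image = img,
    truth = data.frame(
      cell_id = population$cell_id,
      founder_id = population$founder_id,
      x_px = row_px - 1, # 0-based, row-major
      y_px = col_px - 1
    )
  )
}

#' Write / read a 3-channel 16-bit clone image as TIFF
#'
#' Channel order (R, G, B) is preserved; intensities are stored as 16-bit.
#' A sidecar YAML-like text file records the pixel size.
#'
#' @param image rows x cols x 3 array in `[0, 65535]`.
#' @param path output TIFF path.
#' @param pixel_size_um microns per pixel recorded in the sidecar
#'   (default 0.65 for clone images).
#' @return `path`, invisibly.
#' @export
write_clone_tiff <- function(image, path, pixel_size_um = 0.65) {
  img <- as_channel_array(image) / MAX16
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  writeLines(
    c("channels: R,G,B", sprintf("pixel_size_um: %g", pixel_size_um)),
    paste0(path, ".meta")
  )
  invisible(path)
}

#' @rdname write_clone_tiff
#' @export
read_clone_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  as_channel_array(img * MAX16)
}
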