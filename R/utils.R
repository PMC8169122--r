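#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rpois rlnorm runif rbinom quantile median mad
#'   setNames rmultinom aggregate sd
#' @importFrom utils head write.csv read.csv
NULL

MAX16 <- 65535

## ---- seed plumbing -------------------------------------------------------

#' Derive a child seed from a master seed and a stream label
#'
#' All generators in the package draw their randomness from one explicit
#' master seed; independent streams (e.g. founder colours vs cell placement)
#' use child seeds derived deterministically from the master seed and a short
#' label, so adding a new stream never perturbs existing ones.
#'
#' @param seed integer master seed.
#' @param label character stream label.
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a scoped RNG seeded with `seed`; global RNG state is
# untouched (withr restores it).
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

## ---- validation helpers --------------------------------------------------

check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    stop(sprintf(
      "'%s' must be %s %s (got %s)", name,
      if (strict) "greater than" else "at least", lower, format(x)
    ), call. = FALSE)
  }
  invisible(x)
}

clip16 <- function(x) pmin(pmax(x, 0), MAX16)

## ---- lognormal with mean/cv parameterisation -----------------------------

# Draw n lognormal values with the given arithmetic mean and coefficient of
# variation; cv = 0 degenerates to the constant mean.
rlnorm_mcv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

## ---- image helpers -------------------------------------------------------

# Offsets (dx, dy) of a disc of the given pixel radius, centre included.
disc_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= r^2 + 1e-9, , drop = FALSE]
}

# Shift a matrix by (dx, dy), exposing NA outside the original support.
shift_na <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  sr <- max(1, 1 - dx):min(nr, nr - dx)
  sc <- max(1, 1 - dy):min(nc, nc - dy)
  if (length(sr) && length(sc)) out[sr, sc] <- m[sr + dx, sc + dy]
  out
}

as_channel_array <- function(image) {
  if (is.matrix(image)) {
    array(image, dim = c(dim(image), 1L))
  } else if (is.array(image) && length(dim(image)) == 3L) {
    image
  } else {
    stop("image must be a 2D matrix or a 3D (row, col, channel) array",
         call. = FALSE)
  }
}
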