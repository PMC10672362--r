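#' Synthetic tissue phantom (ground-truth reflectivity magnitude)
#'
#' Generates a nonnegative reflectivity-magnitude map to drive the speckle
#' simulator. Three styles are available:
#' \describe{
#'   \item{\code{layered}}{horizontally undulating strata of differing mean
#'     reflectivity, with multiplicative log-normal sub-resolution scatterer
#'     texture -- the geometry most OCT B-scans of biological tissue exhibit;}
#'   \item{\code{blobs}}{smooth random Gaussian inclusions on a dim
#'     background;}
#'   \item{\code{constant}}{a uniform map at \code{level} (useful for
#'     fully developed speckle statistics checks).}
#' }
#' Output is deterministic given \code{(rows, cols, seed, style)} and does not
#' disturb the caller's RNG state.
#'
#' @param rows,cols Phantom size in pixels (each >= 32).
#' @param seed Integer seed.
#' @param style One of \code{"layered"}, \code{"blobs"}, \code{"constant"}.
#' @param level Amplitude for \code{style = "constant"} (default 1).
#' @param n_layers Number of strata for \code{style = "layered"}; default
#'   drawn in 4..7.
#' @param texture_sd Log-sd of the multiplicative scatterer jitter
#'   (default 0.5; 0 disables texture).
#' @param pitch_z,pitch_x Physical pixel pitches recorded on the phantom,
#'   micrometres per pixel.
#' @return An object of class \code{oct_phantom}: list with \code{amplitude}
#'   matrix, \code{pitches}, \code{seed}, \code{style}.
#' @export
#' @examples
#' ph <- generate_phantom(64, 64, seed = 1)
#' range(ph$amplitude)
generate_phantom <- function(rows, cols, seed = 0L,
                             style = c("layered", "blobs", "constant"),
                             level = 1, n_layers = NULL, texture_sd = 0.5,
                             pitch_z = 1, pitch_x = 1) {
  style <- match.arg(style)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 32L || cols < 32L) stop("phantom must be at least 32 x 32")
  amp <- with_local_seed(seed, {
    switch(style,
      constant = matrix(level, rows, cols),
      layered = layered_amplitude(rows, cols, n_layers, texture_sd),
      blobs = blob_amplitude(rows, cols, texture_sd))
  })
  if (any(amp < 0) || any(!is.finite(amp))) {
    stop("internal error: phantom amplitude must be finite and nonnegative")
  }
  structure(list(amplitude = amp,
                 pitches = c(axial = pitch_z, lateral = pitch_x),
                 seed = as.integer(seed), style = style),
            class = "oct_phantom")
}

# Undulating strata: boundaries are slow sinusoid mixtures; each layer gets a
# mean reflectivity well separated from its neighbour, then multiplicative
# log-normal texture models unresolved scatterers.
layered_amplitude <- function(rows, cols, n_layers, texture_sd) {
  if (is.null(n_layers)) n_layers <- sample(4:7, 1)
  n_layers <- as.integer(n_layers)
  if (n_layers < 2L) stop("layered phantom needs at least 2 layers")
  # mean depths of the n_layers - 1 internal boundaries
  base <- sort(stats::runif(n_layers - 1L, 0.12, 0.88)) * rows
  # enforce a minimal gap so layers stay visible
  min_gap <- max(4, rows / (4 * n_layers))
  for (k in seq_along(base)[-1]) {
    base[k] <- max(base[k], base[k - 1] + min_gap)
  }
  j <- seq_len(cols)
  bound <- sapply(seq_along(base), function(k) {
    a1 <- stats::runif(1, 0.5, 2.5); a2 <- stats::runif(1, 0.2, 1)
    p1 <- stats::runif(1, cols / 2, 2 * cols); p2 <- stats::runif(1, cols / 6, cols / 2)
    ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
    base[k] + a1 * sin(2 * pi * j / p1 + ph1) + a2 * sin(2 * pi * j / p2 + ph2)
  })  # cols x (n_layers-1)
  # alternate bright/dark means with a guaranteed contrast step
  means <- numeric(n_layers)
  means[1] <- stats::runif(1, 0.2, 0.9)
  for (k in 2:n_layers) {
    repeat {
      m <- stats::runif(1, 0.15, 1)
      if (abs(m - means[k - 1]) >= 0.25) break
    }
    means[k] <- m
  }
  i <- seq_len(rows)
  layer_of <- matrix(1L, rows, cols)
  for (k in seq_len(ncol(bound))) {
    layer_of <- layer_of + outer(i, bound[, k], FUN = ">")
  }
  amp <- matrix(means[layer_of], rows, cols)
  if (texture_sd > 0) {
    jit <- exp(stats::rnorm(rows * cols, -texture_sd^2 / 2, texture_sd))
    amp <- amp * matrix(jit, rows, cols)
  }
  amp
}

blob_amplitude <- function(rows, cols, texture_sd) {
  n_blobs <- sample(4:9, 1)
  i <- seq_len(rows); j <- seq_len(cols)
  amp <- matrix(0.15, rows, cols)
  for (b in seq_len(n_blobs)) {
    ci <- stats::runif(1, 1, rows); cj <- stats::runif(1, 1, cols)
    si <- stats::runif(1, rows / 16, rows / 5)
    sj <- stats::runif(1, cols / 16, cols / 5)
    a <- stats::runif(1, 0.3, 0.9)
    amp <- amp + a * outer(exp(-(i - ci)^2 / (2 * si^2)),
                           exp(-(j - cj)^2 / (2 * sj^2)))
  }
  if (texture_sd > 0) {
    jit <- exp(stats::rnorm(rows * cols, -texture_sd^2 / 2, texture_sd))
    amp <- amp * matrix(jit, rows, cols)
  }
  amp
}
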