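#' Peak signal-to-noise ratio
#'
#' \code{10 * log10(data_range^2 / MSE)}. The default \code{data_range} is
#' the reference image's recorded dynamic-range span (for a [log_image()]),
#' so that comparisons of different estimates against one reference share one
#' scale -- equivalent to computing the metric on the \code{[0, 1]}
#' dynamic-range-mapped representation with a unit data range. For plain
#' matrices the default falls back to the joint value range. With an
#' explicit \code{data_range} the metric is symmetric in its arguments.
#' Identical images return the cap sentinel (99 dB) rather than infinity.
#'
#' @param reference,test [log_image()]s or numeric matrices of equal shape.
#' @param data_range Value range spanned by the signal; default: the
#'   reference's dynamic-range span, else the joint value range.
#' @param cap Value reported for a zero-MSE pair (default 99).
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, data_range = NULL, cap = 99) {
  a <- image_values(reference); b <- image_values(test)
  if (!identical(dim(a), dim(b))) stop("images must have the same shape")
  mse <- mean((a - b)^2)
  if (mse == 0) return(cap)
  if (is.null(data_range)) data_range <- default_data_range(reference, a, b)
  if (data_range <= 0) stop("data_range must be > 0")
  min(cap, 10 * log10(data_range^2 / mse))
}

#' Structural similarity index
#'
#' Standard SSIM with a Gaussian weighting window (sigma 1.5, 11 x 11),
#' stabilizers \code{K1 = 0.01}, \code{K2 = 0.03}, computed on the shared
#' joint-range normalization (unit data range) and averaged over the map.
#' Local means/variances use reflected boundaries.
#'
#' @inheritParams psnr
#' @param window_size Odd Gaussian window side (default 11).
#' @param sigma Window standard deviation in pixels (default 1.5).
#' @param K1,K2 Stabilizing constants.
#' @return Mean SSIM in \code{[-1, 1]}.
#' @export
ssim <- function(reference, test, data_range = NULL,
                 window_size = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  a <- image_values(reference); b <- image_values(test)
  if (!identical(dim(a), dim(b))) stop("images must have the same shape")
  if (min(dim(a)) < 7L) stop("ssim needs images of at least 7 x 7")
  if (identical(a, b)) return(1)
  if (is.null(data_range)) data_range <- default_data_range(reference, a, b)
  if (data_range <= 0) stop("data_range must be > 0")
  # shared affine to [0, 1]
  lo <- min(a, b)
  a <- (a - lo) / data_range; b <- (b - lo) / data_range
  w <- gaussian_kernel(window_size, sigma)
  mu_a <- conv2_reflect(a, w); mu_b <- conv2_reflect(b, w)
  va <- conv2_reflect(a * a, w) - mu_a^2
  vb <- conv2_reflect(b * b, w) - mu_b^2
  vab <- conv2_reflect(a * b, w) - mu_a * mu_b
  C1 <- K1^2; C2 <- K2^2
  s <- ((2 * mu_a * mu_b + C1) * (2 * vab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

image_values <- function(x) {
  if (inherits(x, "log_image")) x$values else as.matrix(x)
}

default_data_range <- function(reference, a, b) {
  if (inherits(reference, "log_image")) diff(reference$dynamic_range)
  else diff(range(a, b))
}

#' Tiled PSNR/SSIM evaluation report
#'
#' Tiles both images with non-overlapping \code{tile x tile} squares from the
#' top-left corner (remainder strips narrower than a tile are excluded),
#' computes PSNR and SSIM per tile, and reports per-tile values and means.
#' Images smaller than one tile are evaluated as a single whole-image tile
#' with a warning.
#'
#' @inheritParams psnr
#' @param tile Tile side in pixels (default 256).
#' @return An object of class \code{metrics_report}: list with
#'   \code{psnr_db}, \code{ssim} (each \code{list(per_tile, mean)}),
#'   \code{tile}, \code{n_tiles}.
#' @export
evaluate_tiles <- function(reference, test, tile = 256L) {
  a <- image_values(reference); b <- image_values(test)
  if (!identical(dim(a), dim(b))) stop("images must have the same shape")
  tile <- as.integer(tile)
  nr <- nrow(a); nc <- ncol(a)
  if (nr < tile || nc < tile) {
    warning("image smaller than one tile; evaluating as a single tile")
    tiles <- list(list(rows = seq_len(nr), cols = seq_len(nc)))
  } else {
    ti <- seq_len(nr %/% tile); tj <- seq_len(nc %/% tile)
    tiles <- list()
    for (i in ti) for (j in tj) {
      tiles[[length(tiles) + 1L]] <- list(
        rows = (i - 1L) * tile + seq_len(tile),
        cols = (j - 1L) * tile + seq_len(tile))
    }
  }
  dr <- if (inherits(reference, "log_image")) diff(reference$dynamic_range) else NULL
  p <- vapply(tiles, function(t) psnr(a[t$rows, t$cols], b[t$rows, t$cols],
                                      data_range = dr), numeric(1))
  s <- vapply(tiles, function(t) ssim(a[t$rows, t$cols], b[t$rows, t$cols],
                                      data_range = dr), numeric(1))
  structure(list(psnr_db = list(per_tile = p, mean = mean(p)),
                 ssim = list(per_tile = s, mean = mean(s)),
                 tile = tile, n_tiles = length(tiles)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d tile(s) of %d px: PSNR %.2f dB, SSIM %.4f\n",
              x$n_tiles, x$tile, x$psnr_db$mean, x$ssim$mean))
  invisible(x)
}
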