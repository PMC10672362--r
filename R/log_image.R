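#' Log-scaled (dB) tomogram container
#'
#' A B-scan tomogram stored as \code{10*log10(intensity)} values, with rows
#' along the axial (depth) axis and columns along the lateral (scan) axis,
#' carrying the physical pixel pitches and the dynamic range used for display
#' and normalization.
#'
#' @param values Numeric matrix of dB values (rows axial, columns lateral).
#' @param pitch_z,pitch_x Axial/lateral pixel pitch, micrometres per pixel.
#' @param dynamic_range Length-2 numeric \code{c(floor_dB, ceil_dB)}; values
#'   are clipped to this range on construction. Default: the finite value
#'   range of \code{values}.
#' @return An object of class \code{log_image}.
#' @export
log_image <- function(values, pitch_z = 1, pitch_x = 1, dynamic_range = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(dynamic_range)) {
    fin <- values[is.finite(values)]
    if (!length(fin)) stop("log_image needs at least one finite value")
    dynamic_range <- range(fin)
    if (diff(dynamic_range) == 0) dynamic_range[2] <- dynamic_range[1] + 1
  }
  dynamic_range <- as.numeric(dynamic_range)
  if (length(dynamic_range) != 2L || dynamic_range[1] >= dynamic_range[2]) {
    stop("dynamic_range must be c(floor_dB, ceil_dB) with floor < ceil")
  }
  values[values < dynamic_range[1]] <- dynamic_range[1]
  values[!is.finite(values)] <- dynamic_range[1]
  structure(list(values = values,
                 pitch_z = as.numeric(pitch_z), pitch_x = as.numeric(pitch_x),
                 dynamic_range = dynamic_range),
            class = "log_image")
}

#' @export
print.log_image <- function(x, ...) {
  cat(sprintf("<log_image> %d x %d px, pitch (z, x) = (%g, %g) um/px, range [%.1f, %.1f] dB\n",
              nrow(x$values), ncol(x$values), x$pitch_z, x$pitch_x,
              x$dynamic_range[1], x$dynamic_range[2]))
  invisible(x)
}

#' @export
dim.log_image <- function(x) dim(x$values)

#' Convert a log_image to linear intensity (and back)
#'
#' @param image A [log_image()].
#' @return \code{linear_intensity}: matrix of \code{10^(dB/10)} values.
#' @export
linear_intensity <- function(image) {
  stopifnot(inherits(image, "log_image"))
  10^(image$values / 10)
}

#' @param intensity Nonnegative intensity matrix.
#' @param floor_intensity Intensities below this are clipped before taking the
#'   log (guards \code{log10(0)}).
#' @param ... Passed to [log_image()].
#' @rdname linear_intensity
#' @export
intensity_to_log <- function(intensity, floor_intensity = 1e-12, ...) {
  intensity <- pmax(as.matrix(intensity), floor_intensity)
  log_image(10 * log10(intensity), ...)
}

# Affine dB -> [0,1] normalization used throughout training and inference.
# The affine comes from robust quantiles rather than the raw min/max: the dB
# maximum of a speckled image is an interference extreme that fluctuates by
# several dB between realizations, which would misalign the training and
# inference affines. Returns list(values, scale) with the affine (lo, hi).
normalize_db <- function(values, lo = NULL, hi = NULL, q = 0.005) {
  if (inherits(values, "log_image")) values <- values$values
  if (is.null(lo)) lo <- stats::quantile(values, q, names = FALSE)
  if (is.null(hi)) hi <- stats::quantile(values, 1 - q, names = FALSE)
  if (hi <= lo) hi <- lo + 1
  list(values = (values - lo) / (hi - lo), scale = c(lo = lo, hi = hi))
}

denormalize_db <- function(values, scale) {
  values * (scale[["hi"]] - scale[["lo"]]) + scale[["lo"]]
}
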