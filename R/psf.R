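#' One-dimensional PSF profile
#'
#' A peak-normalized, symmetric amplitude profile sampled on an integer pixel
#' grid, together with the axis it belongs to and the physical pixel pitch.
#' Constructed by [lateral_psf()] and [axial_psf()]; users rarely call this
#' directly.
#'
#' @param samples Numeric vector of nonnegative amplitudes, odd length, peak
#'   at the central sample.
#' @param axis \code{"axial"} or \code{"lateral"}.
#' @param pixel_pitch Micrometres per pixel.
#' @return An object of class \code{psf_1d}.
#' @export
psf_1d <- function(samples, axis = c("axial", "lateral"), pixel_pitch) {
  axis <- match.arg(axis)
  samples <- as.numeric(samples)
  if (length(samples) %% 2L != 1L) stop("psf_1d requires an odd sample count")
  if (any(!is.finite(samples)) || any(samples < 0)) {
    stop("psf_1d samples must be finite and nonnegative")
  }
  peak <- max(samples)
  if (peak <= 0) stop("psf_1d needs a positive peak")
  samples <- samples / peak
  ctr <- (length(samples) + 1L) %/% 2L
  if (abs(samples[ctr] - 1) > 1e-9) {
    stop("psf_1d peak must sit at the central sample")
  }
  structure(list(samples = samples, axis = axis,
                 pixel_pitch = as.numeric(pixel_pitch),
                 half_support = ctr - 1L),
            class = "psf_1d")
}

#' Lateral (Gaussian-beam) PSF profile
#'
#' The lateral PSF of a scanned OCT beam is Gaussian in amplitude,
#' proportional to \code{exp(-2 x^2 / omega_x^2)} where \code{omega_x} is the
#' beam waist. Samples are taken at the system's lateral pixel pitch.
#'
#' @param spec An [oct_system_spec()].
#' @param half_support Number of pixels on each side of the peak. Default
#'   (\code{NULL}) extends until the amplitude falls below 1\% of the peak.
#' @param oversample Sampling refinement factor: samples are taken at
#'   \code{delta_x / oversample} spacing (used by the speckle simulator's
#'   sub-resolution scatterer grid; default 1 = the acquisition grid).
#' @return A [psf_1d()] on the lateral axis.
#' @export
#' @examples
#' p <- lateral_psf(oct_system_preset("chicken"))
#' p$samples[p$half_support + 1]  # peak = 1
lateral_psf <- function(spec, half_support = NULL, oversample = 1L) {
  stopifnot(inherits(spec, "oct_system_spec"))
  oversample <- as.integer(oversample)
  if (oversample < 1L) stop("oversample must be >= 1")
  pitch <- spec$delta_x / oversample
  if (is.null(half_support)) {
    # exp(-2 (k d)^2 / w^2) < 0.01  <=>  k d > w sqrt(log(100)/2)
    half_support <- ceiling(spec$omega_x * sqrt(log(100) / 2) / pitch)
  }
  half_support <- as.integer(half_support)
  if (half_support < 1L) stop("half_support must be >= 1")
  k <- seq.int(-half_support, half_support)
  x <- k * pitch
  psf_1d(exp(-2 * x^2 / spec$omega_x^2), axis = "lateral",
         pixel_pitch = pitch)
}

#' Axial (Hanning-window FFT) PSF profile
#'
#' In swept-source / spectral-domain OCT the axial response is the magnitude
#' of the discrete Fourier transform of the spectral apodization window: here
#' a Hanning window over the \code{n_spectral} measured points, zero padded to
#' \code{n_fft} points. The profile is centred on its peak, peak-normalized,
#' and truncated to the contiguous symmetric support outside which the
#' amplitude stays below \code{threshold} times the peak.
#'
#' @param spec An [oct_system_spec()] (uses \code{n_spectral}, \code{n_fft},
#'   \code{delta_z}).
#' @param threshold Truncation threshold as a fraction of the peak
#'   (default 0.01). With typical zero-padding factors this yields a visible
#'   support of roughly 7-9 pixels.
#' @param oversample Sampling refinement factor: the FFT is zero padded to
#'   \code{oversample * n_fft} points so the profile is sampled at
#'   \code{delta_z / oversample} spacing (default 1).
#' @return A [psf_1d()] on the axial axis.
#' @export
axial_psf <- function(spec, threshold = 0.01, oversample = 1L) {
  stopifnot(inherits(spec, "oct_system_spec"))
  oversample <- as.integer(oversample)
  if (oversample < 1L) stop("oversample must be >= 1")
  if (spec$n_spectral > spec$n_fft) stop("n_spectral must not exceed n_fft")
  w <- hanning_window(spec$n_spectral)
  padded <- c(w, rep(0, oversample * spec$n_fft - spec$n_spectral))
  mag <- Mod(stats::fft(padded))
  mag <- mag / max(mag)
  # peak is at DC; re-centre so index 0 becomes the middle of a symmetric window
  nfft <- oversample * spec$n_fft
  half_max <- nfft %/% 2L
  idx <- c(seq.int(nfft - half_max + 1L, nfft), seq_len(half_max + 1L))
  centred <- mag[idx]                      # length 2*half_max + 1, peak in middle
  ctr <- half_max + 1L
  above <- which(centred >= threshold)
  hs <- max(abs(above - ctr))
  hs <- max(1L, as.integer(hs))
  keep <- centred[(ctr - hs):(ctr + hs)]
  psf_1d(keep, axis = "axial", pixel_pitch = spec$delta_z / oversample)
}

# Symmetric (periodic-free) Hanning window of length n: sin^2 taper that
# vanishes at both end samples.
hanning_window <- function(n) {
  n <- as.integer(n)
  if (n < 2L) stop("hanning window needs n >= 2")
  k <- seq_len(n) - 1L
  0.5 - 0.5 * cos(2 * pi * k / (n - 1L))
}

#' Separable 2D PSF kernel
#'
#' The OCT PSF is separable into an axial and a lateral profile; the 2D kernel
#' is their outer product (axial index along rows, lateral along columns),
#' normalized to unit peak.
#'
#' @param axial,lateral [psf_1d()] profiles.
#' @return An object of class \code{psf_2d}: list with the \code{kernel}
#'   matrix and \code{pitches = c(axial, lateral)} in micrometres per pixel.
#' @export
separable_psf <- function(axial, lateral) {
  stopifnot(inherits(axial, "psf_1d"), inherits(lateral, "psf_1d"))
  if (axial$axis != "axial" || lateral$axis != "lateral") {
    stop("separable_psf expects (axial, lateral) profiles in that order")
  }
  kernel <- outer(axial$samples, lateral$samples)
  structure(list(kernel = kernel,
                 pitches = c(axial = axial$pixel_pitch,
                             lateral = lateral$pixel_pitch),
                 oversample = 1L),
            class = "psf_2d")
}

#' Build the full separable PSF of a system
#'
#' Convenience wrapper: [axial_psf()] and [lateral_psf()] combined through
#' [separable_psf()]. The default \code{oversample = 2} samples the kernel on
#' a grid twice as fine as the acquisition pitch; the speckle simulator then
#' places independent scatterers on that sub-resolution grid (speckle arises
#' from scatterers spaced below the resolution cell) and reads the tomogram
#' out at the acquisition pitch. \code{oversample = 1} gives the plain
#' acquisition-grid kernel.
#'
#' @inheritParams lateral_psf
#' @return A \code{psf_2d}; its \code{oversample} field records the grid
#'   refinement.
#' @export
system_psf <- function(spec, oversample = 2L) {
  psf <- separable_psf(axial_psf(spec, oversample = oversample),
                       lateral_psf(spec, oversample = oversample))
  psf$oversample <- as.integer(oversample)
  psf
}
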