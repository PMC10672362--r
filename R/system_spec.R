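#' OCT acquisition system specification
#'
#' Bundles the physical parameters of an OCT acquisition system from which the
#' discrete point spread function (PSF) and the per-axis sampling-resolution
#' ratios derive: the axial/lateral sampling spaces (distance between adjacent
#' pixels, in micrometres), the effective PSF widths (axial effective width of
#' the Hanning-window spectral response; lateral Gaussian beam waist), and the
#' spectral sampling (number of measured spectral points and total FFT length
#' after zero padding).
#'
#' @param name Label for the system (used in plans and reports).
#' @param delta_z Axial sampling space, micrometres per pixel.
#' @param delta_x Lateral sampling space, micrometres per pixel.
#' @param omega_z Axial PSF effective width, micrometres.
#' @param omega_x Lateral Gaussian waist, micrometres.
#' @param n_spectral Effective number of measured spectral points.
#' @param n_fft Total number of FFT points after zero padding
#'   (\code{n_spectral <= n_fft}).
#' @param axial_range Optional axial imaging range, micrometres.
#' @param n_axial_pixels Optional number of pixels per A-line. When both
#'   \code{axial_range} and \code{n_axial_pixels} are given they must be
#'   consistent with \code{delta_z = axial_range / n_axial_pixels}.
#'
#' @return An object of class \code{oct_system_spec}.
#' @seealso [sampling_resolution_ratio()], [lateral_psf()], [axial_psf()],
#'   [plan_resampling()], [read_system_spec()]
#' @export
#' @examples
#' spec <- oct_system_spec("chicken", delta_z = 6, delta_x = 3.06,
#'                         omega_z = 18, omega_x = 8.28,
#'                         n_spectral = 1600, n_fft = 2048)
#' sampling_resolution_ratio(spec$omega_x, spec$delta_x)
oct_system_spec <- function(name, delta_z, delta_x, omega_z, omega_x,
                            n_spectral, n_fft,
                            axial_range = NULL, n_axial_pixels = NULL) {
  lens <- c(delta_z = delta_z, delta_x = delta_x,
            omega_z = omega_z, omega_x = omega_x)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("all sampling spaces and PSF widths must be positive and finite")
  }
  n_spectral <- as.integer(n_spectral)
  n_fft <- as.integer(n_fft)
  if (n_spectral < 2L || n_fft < 2L) stop("n_spectral and n_fft must be >= 2")
  if (n_spectral > n_fft) {
    stop("n_spectral must not exceed n_fft (zero padding only adds points)")
  }
  if (!is.null(axial_range) && !is.null(n_axial_pixels)) {
    implied <- axial_range / n_axial_pixels
    if (abs(implied - delta_z) > 1e-6 * delta_z) {
      stop(sprintf(
        "inconsistent axial geometry: axial_range/n_axial_pixels = %.6g but delta_z = %.6g",
        implied, delta_z))
    }
  }
  structure(list(
    name = as.character(name),
    delta_z = as.numeric(delta_z), delta_x = as.numeric(delta_x),
    omega_z = as.numeric(omega_z), omega_x = as.numeric(omega_x),
    n_spectral = n_spectral, n_fft = n_fft,
    axial_range = if (is.null(axial_range)) NULL else as.numeric(axial_range),
    n_axial_pixels = if (is.null(n_axial_pixels)) NULL else as.integer(n_axial_pixels)
  ), class = "oct_system_spec")
}

#' @export
print.oct_system_spec <- function(x, ...) {
  cat(sprintf("<oct_system_spec> %s\n", x$name))
  cat(sprintf("  axial : delta_z = %g um/px, omega_z = %g um  (pz = %d)\n",
              x$delta_z, x$omega_z, sampling_resolution_ratio(x$omega_z, x$delta_z)))
  cat(sprintf("  lateral: delta_x = %g um/px, omega_x = %g um  (px = %d)\n",
              x$delta_x, x$omega_x, sampling_resolution_ratio(x$omega_x, x$delta_x)))
  cat(sprintf("  spectral: %d measured points, %d FFT points\n",
              x$n_spectral, x$n_fft))
  invisible(x)
}

#' Sampling-resolution ratio of one image axis
#'
#' The sampling-resolution ratio is the PSF effective width divided by the
#' sampling space, rounded to the nearest integer: the number of pixels that
#' the effective PSF footprint (equivalently, one speckle grain) covers along
#' that axis. Rounding is half-away-from-zero and the result is floored at 1
#' pixel (a PSF can never cover less than the pixel it falls on).
#'
#' @param omega PSF effective width, micrometres (> 0).
#' @param delta Sampling space, micrometres per pixel (> 0).
#' @return Integer number of pixels, >= 1.
#' @export
#' @examples
#' sampling_resolution_ratio(8.28, 3.06)  # 3
#' sampling_resolution_ratio(18, 9)       # 2
#' sampling_resolution_ratio(8.28, 8)     # 1
sampling_resolution_ratio <- function(omega, delta) {
  if (!is.finite(omega) || !is.finite(delta) || omega <= 0 || delta <= 0) {
    stop("omega and delta must be positive finite scalars")
  }
  # round() in R rounds half to even; the ratio convention wants half away
  # from zero, so round via floor(x + 0.5) on the (positive) ratio
  r <- as.integer(floor(omega / delta + 0.5))
  max(1L, r)
}

#' Per-axis sampling-resolution ratios of a system
#'
#' @param spec An [oct_system_spec()].
#' @return A list with integer fields \code{px} (lateral) and \code{pz} (axial).
#' @export
system_resolution_ratios <- function(spec) {
  stopifnot(inherits(spec, "oct_system_spec"))
  list(px = sampling_resolution_ratio(spec$omega_x, spec$delta_x),
       pz = sampling_resolution_ratio(spec$omega_z, spec$delta_z))
}

#' Read / write an OCT system spec as YAML
#'
#' The YAML schema uses explicit unit-suffixed keys: \code{delta_z_um},
#' \code{delta_x_um}, \code{omega_z_um}, \code{omega_x_um}, \code{n_spectral},
#' \code{n_fft}, and optional \code{axial_range_um}, \code{n_axial_pixels},
#' \code{name}. Six ready-made system files ship with the package under
#' \code{system.file("extdata", "systems", package = "octshot")}.
#'
#' @param path Path to a YAML file.
#' @return An [oct_system_spec()].
#' @export
read_system_spec <- function(path) {
  if (!file.exists(path)) stop("system spec file not found: ", path)
  y <- yaml::read_yaml(path)
  need <- c("delta_z_um", "delta_x_um", "omega_z_um", "omega_x_um",
            "n_spectral", "n_fft")
  missing <- setdiff(need, names(y))
  if (length(missing)) {
    stop("system spec YAML missing keys: ", paste(missing, collapse = ", "))
  }
  oct_system_spec(
    name = if (is.null(y$name)) tools::file_path_sans_ext(basename(path)) else y$name,
    delta_z = y$delta_z_um, delta_x = y$delta_x_um,
    omega_z = y$omega_z_um, omega_x = y$omega_x_um,
    n_spectral = y$n_spectral, n_fft = y$n_fft,
    axial_range = y$axial_range_um, n_axial_pixels = y$n_axial_pixels)
}

#' @param spec An [oct_system_spec()] to serialize.
#' @rdname read_system_spec
#' @export
write_system_spec <- function(spec, path) {
  stopifnot(inherits(spec, "oct_system_spec"))
  y <- list(name = spec$name,
            delta_z_um = spec$delta_z, delta_x_um = spec$delta_x,
            omega_z_um = spec$omega_z, omega_x_um = spec$omega_x,
            n_spectral = spec$n_spectral, n_fft = spec$n_fft)
  if (!is.null(spec$axial_range)) y$axial_range_um <- spec$axial_range
  if (!is.null(spec$n_axial_pixels)) y$n_axial_pixels <- spec$n_axial_pixels
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Packaged acquisition-system presets
#'
#' Returns one of the six acquisition systems shipped with the package
#' (chicken muscle / blueberry bench system, chicken skin, cucumber, retinal
#' imager, and two intravascular catheter systems), read from the packaged
#' YAML files.
#'
#' @param name One of \code{"chicken"}, \code{"chicken_skin"},
#'   \code{"cucumber"}, \code{"retina"}, \code{"cardiovascular1"},
#'   \code{"cardiovascular2"}.
#' @return An [oct_system_spec()].
#' @export
#' @examples
#' system_resolution_ratios(oct_system_preset("chicken"))
oct_system_preset <- function(name = c("chicken", "chicken_skin", "cucumber",
                                       "retina", "cardiovascular1",
                                       "cardiovascular2")) {
  name <- match.arg(name)
  path <- system.file("extdata", "systems", paste0(name, ".yaml"),
                      package = "octshot", mustWork = TRUE)
  read_system_spec(path)
}
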