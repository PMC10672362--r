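#' Simulate a speckled tomogram from a phantom
#'
#' Coherent imaging forward model: each phantom pixel is given an i.i.d.
#' uniform phase on \code{[0, 2pi)}, the complex reflectivity field is
#' convolved with the system PSF (same-size, reflected boundary), and the
#' log-intensity tomogram \code{10*log10(|f * alpha|^2 + eps)} is returned.
#' Where the PSF footprint covers many scatterers of comparable amplitude
#' this produces fully developed speckle with exponential intensity
#' statistics; near sparse or dim structure the speckle is only partially
#' developed, with no separate mechanism needed.
#'
#' @param phantom An [generate_phantom()] result.
#' @param psf A \code{psf_2d} from [separable_psf()] / [system_psf()].
#' @param seed Integer seed for the phase realization.
#' @param db_floor Intensity floor added before the log (default 1e-12,
#'   relative to unit mean intensity).
#' @param display_range_db Width of the recorded dynamic range below the
#'   image peak (default 45 dB); values below the floor are clipped.
#' @return A [log_image()] with the phantom's pixel pitches.
#' @seealso [ground_truth_tomogram()], [make_pair()]
#' @export
simulate_speckled_tomogram <- function(phantom, psf, seed = 0L,
                                       db_floor = 1e-12,
                                       display_range_db = 45) {
  stopifnot(inherits(phantom, "oct_phantom"), inherits(psf, "psf_2d"))
  s <- psf$oversample %||% 1L
  amp <- fine_amplitude(phantom$amplitude, s)
  if (nrow(psf$kernel) > nrow(amp) || ncol(psf$kernel) > ncol(amp)) {
    stop("PSF support exceeds phantom dimensions")
  }
  if (all(amp == 0)) warning("all-zero phantom: tomogram sits at the dB floor")
  field <- with_local_seed(seed, {
    phase <- matrix(stats::runif(length(amp), 0, 2 * pi), nrow(amp))
    amp * exp(1i * phase)
  })
  blurred <- conv2_reflect(field, psf$kernel)
  intensity <- coarse_grid(Mod(blurred)^2, s)
  to_log_with_range(intensity, db_floor, display_range_db,
                    pitch_z = phantom$pitches[["axial"]],
                    pitch_x = phantom$pitches[["lateral"]])
}

# Scatterers live on a grid `s` times finer than the acquisition grid: each
# pixel splits into s^2 independent scatterers of amplitude a/s, preserving
# the pixel's mean backscattered intensity a^2.
fine_amplitude <- function(amp, s) {
  if (s == 1L) return(amp)
  amp[rep(seq_len(nrow(amp)), each = s), rep(seq_len(ncol(amp)), each = s)] / s
}

coarse_grid <- function(x, s) {
  if (s == 1L) return(x)
  x[seq.int(1L, nrow(x), by = s), seq.int(1L, ncol(x), by = s)]
}

#' Speckle-free ground-truth tomogram
#'
#' The incoherent-mean limit of infinitely many speckle realizations:
#' \code{10*log10(|f|^2 * |alpha|^2 + eps)}, i.e. the squared phantom
#' amplitude convolved with the squared PSF. Deterministic (no phases drawn).
#'
#' @inheritParams simulate_speckled_tomogram
#' @return A [log_image()].
#' @export
ground_truth_tomogram <- function(phantom, psf, db_floor = 1e-12,
                                  display_range_db = 45) {
  stopifnot(inherits(phantom, "oct_phantom"), inherits(psf, "psf_2d"))
  s <- psf$oversample %||% 1L
  amp <- fine_amplitude(phantom$amplitude, s)
  intensity <- coarse_grid(conv2_reflect(amp^2, psf$kernel^2), s)
  intensity[intensity < 0] <- 0       # FFT round-off guard
  to_log_with_range(intensity, db_floor, display_range_db,
                    pitch_z = phantom$pitches[["axial"]],
                    pitch_x = phantom$pitches[["lateral"]])
}

to_log_with_range <- function(intensity, db_floor, display_range_db,
                              pitch_z, pitch_x) {
  db <- 10 * log10(intensity + db_floor)
  ceil <- max(db)
  log_image(db, pitch_z = pitch_z, pitch_x = pitch_x,
            dynamic_range = c(ceil - display_range_db, ceil))
}

#' Draw fully developed speckle intensities
#'
#' Fully developed speckle intensity follows an exponential density
#' \code{p(y | x) = (1/x) exp(-y/x)} with mean \code{x} (the ground-truth
#' pixel intensity); the fluctuations are of the same order as the signal.
#'
#' @param mean_intensity Ground-truth mean intensity, > 0.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Numeric vector of \code{n} nonnegative intensities.
#' @export
sample_speckle_intensity <- function(mean_intensity, n, seed = 0L) {
  if (!is.finite(mean_intensity) || mean_intensity <= 0) {
    stop("mean_intensity must be positive")
  }
  with_local_seed(seed, stats::rexp(n, rate = 1 / mean_intensity))
}

#' Incoherent (angular) compounding of speckle realizations
#'
#' Averages independent speckle realizations in the linear intensity domain
#' and returns the dB image of the mean -- the software analogue of hardware
#' angular compounding. Variance of the compound decays as 1/M.
#'
#' @param realizations List of [log_image()]s with identical shapes.
#' @return A [log_image()] with the metadata of the first realization.
#' @export
angular_compound <- function(realizations) {
  if (!length(realizations)) stop("need at least one realization")
  stopifnot(all(vapply(realizations, inherits, TRUE, "log_image")))
  dims <- lapply(realizations, dim)
  if (length(unique(dims)) != 1L) stop("realizations must share one shape")
  acc <- Reduce(`+`, lapply(realizations, linear_intensity))
  first <- realizations[[1]]
  log_image(10 * log10(acc / length(realizations)),
            pitch_z = first$pitch_z, pitch_x = first$pitch_x,
            dynamic_range = first$dynamic_range)
}

#' One-shot training fixture: a paired speckled / clean tomogram
#'
#' Builds the separable PSF of an acquisition system, draws one phantom, and
#' returns the speckled tomogram together with its speckle-free ground truth
#' from the same phantom -- the single supervised pair every few-shot
#' despeckler in this package trains on.
#'
#' @param spec An [oct_system_spec()].
#' @param rows,cols Image size in pixels.
#' @param seed Integer seed (phantom and phase realization derive from it).
#' @param style Phantom style, see [generate_phantom()].
#' @param ... Further arguments to [generate_phantom()].
#' @return List with \code{noisy}, \code{clean} ([log_image()]s sharing the
#'   system's pixel pitches), and the \code{phantom}.
#' @export
#' @examples
#' pair <- make_pair(oct_system_preset("chicken"), 64, 96, seed = 1)
#' dim(pair$noisy)
make_pair <- function(spec, rows, cols, seed = 0L, style = "layered", ...) {
  stopifnot(inherits(spec, "oct_system_spec"))
  psf <- system_psf(spec)
  phantom <- generate_phantom(rows, cols, seed = seed, style = style,
                              pitch_z = spec$delta_z, pitch_x = spec$delta_x,
                              ...)
  noisy <- simulate_speckled_tomogram(phantom, psf, seed = seed + 1L)
  clean <- ground_truth_tomogram(phantom, psf)
  list(noisy = noisy, clean = clean, phantom = phantom)
}
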