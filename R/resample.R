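#' Rational resampling plan between acquisition systems
#'
#' A trained despeckler carries the resolution signature (speckle grain size
#' in pixels) of the system it was trained on. When the target system's
#' sampling-resolution ratio differs, the image being fed to the model can be
#' resampled so that its integer ratio matches the counterpart system's.
#' \code{plan_resampling} computes, per axis, the rational factor that
#' achieves this, choosing the best rational approximation with denominator
#' at most \code{max_denominator}.
#'
#' The factor is expressed as a decimation factor: applying the plan
#' multiplies the sampling space by \code{factor} (so \code{factor > 1}
#' shortens the image, \code{factor < 1} lengthens it). The plan records which
#' image (source or target) it applies to; the adaptation can be applied to
#' either side interchangeably depending on the desired output resolution.
#'
#' @param source,target [oct_system_spec()]s.
#' @param applied_to Which image the plan will be applied to:
#'   \code{"target"} (default; adapt test images to the trained model) or
#'   \code{"source"} (adapt the training image before fitting).
#' @param max_denominator Largest denominator allowed in the rational factor
#'   (default 3).
#' @return A list of two \code{resampling_plan} objects (axial, lateral).
#'   Each has fields \code{axis}, \code{factor_num}, \code{factor_den},
#'   \code{direction} (\code{"decimate"}, \code{"interpolate"} or
#'   \code{"identity"}), \code{applied_to}, and \code{target_ratio} (the
#'   integer ratio the resampled image will have).
#' @seealso [apply_resampling()], [predict_output_regime()]
#' @export
#' @examples
#' plans <- plan_resampling(oct_system_preset("chicken"),
#'                          oct_system_preset("cucumber"),
#'                          applied_to = "source")
#' plans$lateral$factor_num / plans$lateral$factor_den  # 8/3
plan_resampling <- function(source, target,
                            applied_to = c("target", "source"),
                            max_denominator = 3L) {
  stopifnot(inherits(source, "oct_system_spec"),
            inherits(target, "oct_system_spec"))
  applied_to <- match.arg(applied_to)
  max_denominator <- as.integer(max_denominator)
  if (max_denominator < 1L) stop("max_denominator must be >= 1")

  resampled <- if (applied_to == "source") source else target
  counterpart <- if (applied_to == "source") target else source

  one_axis <- function(axis) {
    if (axis == "axial") {
      omega <- resampled$omega_z; delta <- resampled$delta_z
      p_des <- sampling_resolution_ratio(counterpart$omega_z, counterpart$delta_z)
    } else {
      omega <- resampled$omega_x; delta <- resampled$delta_x
      p_des <- sampling_resolution_ratio(counterpart$omega_x, counterpart$delta_x)
    }
    p_own <- sampling_resolution_ratio(omega, delta)
    if (p_own == p_des) {
      return(new_resampling_plan(axis, 1L, 1L, "identity", applied_to, p_des))
    }
    f <- (omega / delta) / p_des          # decimation factor on the sampling space
    rat <- best_rational_for_ratio(f, max_denominator, omega, delta, p_des)
    if (rat$num == rat$den) {
      return(new_resampling_plan(axis, 1L, 1L, "identity", applied_to, p_des))
    }
    direction <- if (p_des < p_own) "decimate" else "interpolate"
    new_resampling_plan(axis, rat$num, rat$den, direction, applied_to, p_des)
  }

  list(axial = one_axis("axial"), lateral = one_axis("lateral"))
}

#' Construct a resampling plan by hand
#'
#' Mostly useful for undoing an adaptation (e.g. decimating a model output
#' back to the native target grid); [plan_resampling()] is the usual entry
#' point.
#'
#' @param axis \code{"axial"} or \code{"lateral"}.
#' @param factor_num,factor_den Rational decimation factor (applying the plan
#'   multiplies the sampling space by \code{factor_num / factor_den}).
#' @param applied_to \code{"source"} or \code{"target"}.
#' @return A \code{resampling_plan}.
#' @export
resampling_plan <- function(axis = c("axial", "lateral"), factor_num,
                            factor_den, applied_to = c("target", "source")) {
  axis <- match.arg(axis); applied_to <- match.arg(applied_to)
  num <- as.integer(factor_num); den <- as.integer(factor_den)
  if (num < 1L || den < 1L) stop("factor must be a positive rational")
  direction <- if (num == den) "identity" else if (num > den) "decimate" else "interpolate"
  new_resampling_plan(axis, num, den, direction, applied_to, NA_integer_)
}

new_resampling_plan <- function(axis, num, den, direction, applied_to,
                                target_ratio) {
  structure(list(axis = axis, factor_num = as.integer(num),
                 factor_den = as.integer(den), direction = direction,
                 applied_to = applied_to,
                 target_ratio = as.integer(target_ratio)),
            class = "resampling_plan")
}

#' @export
print.resampling_plan <- function(x, ...) {
  cat(sprintf("<resampling_plan> %s axis of %s image: %s", x$axis,
              x$applied_to, x$direction))
  if (x$direction != "identity") {
    cat(sprintf(" by %d/%d (ratio -> %d px)", x$factor_num, x$factor_den,
                x$target_ratio))
  }
  cat("\n")
  invisible(x)
}

# Best rational approximation num/den of f > 0 with den <= max_den
# (exhaustive over denominators; ties go to the smaller denominator).
best_rational <- function(f, max_den) {
  if (!is.finite(f) || f <= 0) stop("rational factor must be positive")
  best <- NULL
  for (d in seq_len(max_den)) {
    n <- max(1L, as.integer(floor(f * d + 0.5)))
    err <- abs(f - n / d)
    if (is.null(best) || err < best$err - 1e-15) {
      best <- list(num = n, den = d, err = err)
    }
  }
  g <- gcd_int(best$num, best$den)
  list(num = best$num %/% g, den = best$den %/% g)
}

# Rational factor for a resampling plan: the contract is that the resampled
# image's integer sampling-resolution ratio equals p_des. Prefer the best
# approximation with denominator <= max_den among those that honour the
# contract; when none does (coarse rationals can overshoot the rounding
# band), grow the denominator until one does.
best_rational_for_ratio <- function(f, max_den, omega, delta, p_des) {
  hits_band <- function(n, d) {
    sampling_resolution_ratio(omega, delta * n / d) == p_des
  }
  best <- NULL
  for (d in seq_len(max_den)) {
    n <- max(1L, as.integer(floor(f * d + 0.5)))
    if (!hits_band(n, d)) next
    err <- abs(f - n / d)
    if (is.null(best) || err < best$err - 1e-15) {
      best <- list(num = n, den = d, err = err)
    }
  }
  if (is.null(best)) {
    for (d in seq.int(max_den + 1L, 512L)) {
      n <- max(1L, as.integer(floor(f * d + 0.5)))
      if (hits_band(n, d)) { best <- list(num = n, den = d); break }
    }
    if (is.null(best)) stop("no rational factor reaches the requested ratio")
  }
  g <- gcd_int(best$num, best$den)
  list(num = best$num %/% g, den = best$den %/% g)
}

gcd_int <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' Apply a rational resampling plan to an image
#'
#' Polyphase rational resampling along the plan's axis with a windowed-sinc
#' anti-alias / interpolation filter. For a decimation factor \code{num/den}
#' the output length is \code{round(n * den / num)} (half away from zero);
#' the pixel pitch metadata is multiplied by the factor.
#'
#' @param image A [log_image()].
#' @param plan A \code{resampling_plan} from [plan_resampling()], or a list of
#'   them (applied in sequence).
#' @param patch_dim Optional patch side length; a warning is raised when the
#'   resampled axis drops below twice this value (too short to train on).
#' @return The resampled [log_image()].
#' @export
apply_resampling <- function(image, plan, patch_dim = NULL) {
  stopifnot(inherits(image, "log_image"))
  if (!inherits(plan, "resampling_plan") && is.list(plan)) {
    for (p in plan) image <- apply_resampling(image, p, patch_dim)
    return(image)
  }
  stopifnot(inherits(plan, "resampling_plan"))
  if (plan$direction == "identity" ||
      (plan$factor_num == plan$factor_den)) {
    return(image)
  }
  up <- plan$factor_den; down <- plan$factor_num
  v <- image$values
  if (plan$axis == "axial") {
    out <- apply(v, 2, resample_1d, up = up, down = down)
    img <- log_image(out, pitch_z = image$pitch_z * down / up,
                     pitch_x = image$pitch_x,
                     dynamic_range = image$dynamic_range)
  } else {
    out <- t(apply(v, 1, resample_1d, up = up, down = down))
    img <- log_image(out, pitch_z = image$pitch_z,
                     pitch_x = image$pitch_x * down / up,
                     dynamic_range = image$dynamic_range)
  }
  if (!is.null(patch_dim)) {
    n_axis <- if (plan$axis == "axial") nrow(img$values) else ncol(img$values)
    if (n_axis < 2L * patch_dim) {
      warning(sprintf("resampled %s extent (%d px) is below twice the patch dimension (%d)",
                      plan$axis, n_axis, patch_dim))
    }
  }
  img
}

# Rational polyphase resampling of a vector by up/down with a Hamming-windowed
# sinc low-pass (cutoff at the narrower of the two Nyquist bands). Output
# length is round_half_up(n * up / down). Edges are reflect-padded so the
# first output sample aligns with the first input sample.
resample_1d <- function(x, up, down, taps_per_branch = 10L) {
  n <- length(x)
  if (up == down) return(x)
  g <- gcd_int(up, down); up <- up %/% g; down <- down %/% g
  mx <- max(up, down)
  half <- taps_per_branch * mx
  t_idx <- seq.int(-half, half)
  fc <- 1 / (2 * mx)                       # cycles/sample in upsampled domain
  h <- 2 * fc * sinc(2 * fc * t_idx) * hamming_window(length(t_idx))
  h <- h / sum(h) * up                     # unit DC gain after upsampling
  c0 <- half                               # 0-based filter centre

  out_len <- as.integer(floor(n * up / down + 0.5))
  pad <- as.integer(ceiling((c0 + down + 1) / up)) + 1L
  xp <- c(rev(x[seq_len(min(pad, n))]), x, rev(x[seq.int(n - min(pad, n) + 1L, n)]))
  if (pad > n) {  # degenerate very short inputs: recycle reflection
    xp <- c(rep(x[1], pad), x, rep(x[n], pad))
  }
  m <- length(xp)
  xup <- numeric(m * up)
  xup[(seq_len(m) - 1L) * up + 1L] <- xp
  yfull <- conv_full(xup, h)
  # output sample k (0-based) sits at upsampled position pad*up + k*down,
  # shifted by the filter centre c0
  pos <- pad * up + (seq_len(out_len) - 1L) * down + c0 + 1L
  yfull[pos]
}

sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

hamming_window <- function(n) {
  k <- seq_len(n) - 1L
  0.54 - 0.46 * cos(2 * pi * k / (n - 1L))
}

# Full linear convolution via FFT (real in, real out).
conv_full <- function(x, h) {
  nout <- length(x) + length(h) - 1L
  nfft <- stats::nextn(nout, 2)
  Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) *
                stats::fft(c(h, numeric(nfft - length(h)))), inverse = TRUE))[seq_len(nout)] / nfft
}

#' Predicted output regime under a domain shift
#'
#' A despeckler's output resolution follows the source system it was trained
#' on. Per axis: when the source ratio is below the target's, the model may
#' hallucinate detail (artificially enhanced resolution); when it is above,
#' the output is blurred along that axis; equal ratios are matched.
#'
#' @param source,target Either [oct_system_spec()]s or lists with integer
#'   fields \code{px}, \code{pz} (as from [system_resolution_ratios()]).
#' @return List with \code{axial} and \code{lateral} entries, each one of
#'   \code{"matched"}, \code{"detail_enhanced_risk"}, \code{"blurred"}.
#' @export
predict_output_regime <- function(source, target) {
  sr <- as_ratios(source); tr <- as_ratios(target)
  one <- function(s, t) {
    if (s < t) "detail_enhanced_risk" else if (s > t) "blurred" else "matched"
  }
  list(axial = one(sr$pz, tr$pz), lateral = one(sr$px, tr$px))
}

as_ratios <- function(x) {
  if (inherits(x, "oct_system_spec")) return(system_resolution_ratios(x))
  if (is.list(x) && all(c("px", "pz") %in% names(x))) {
    if (x$px < 1 || x$pz < 1) stop("sampling-resolution ratios must be >= 1")
    return(list(px = as.integer(x$px), pz = as.integer(x$pz)))
  }
  stop("expected an oct_system_spec or a list with px and pz")
}
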