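# Internal helpers shared across modules.

# Evaluate expr with a locally set RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# 2D "same"-size convolution with symmetric (reflect) boundary handling,
# computed by FFT. Accepts real or complex x; kernel must have odd sides.
conv2_reflect <- function(x, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr %% 2L != 1L || kc %% 2L != 1L) stop("kernel sides must be odd")
  pr <- kr %/% 2L; pc <- kc %/% 2L
  xp <- pad_reflect(x, pr, pc)
  full <- conv2_full(xp, kernel)
  full[(2L * pr + 1L):(2L * pr + nrow(x)),
       (2L * pc + 1L):(2L * pc + ncol(x)), drop = FALSE]
}

pad_reflect <- function(x, pr, pc) {
  nr <- nrow(x); nc <- ncol(x)
  if (pr >= nr || pc >= nc) stop("image smaller than kernel support")
  ri <- c(rev(seq_len(pr)), seq_len(nr), nr + 1L - seq_len(pr))
  ci <- c(rev(seq_len(pc)), seq_len(nc), nc + 1L - seq_len(pc))
  x[ri, ci, drop = FALSE]
}

# Full 2D linear convolution via FFT; returns (nr+kr-1) x (nc+kc-1).
conv2_full <- function(x, k) {
  nr <- nrow(x) + nrow(k) - 1L
  nc <- ncol(x) + ncol(k) - 1L
  fr <- stats::nextn(nr, 2); fc <- stats::nextn(nc, 2)
  X <- matrix(0 + 0i, fr, fc); K <- matrix(0 + 0i, fr, fc)
  X[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  K[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  out <- stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE) / (fr * fc)
  out <- out[seq_len(nr), seq_len(nc), drop = FALSE]
  if (is.complex(x) || is.complex(k)) out else Re(out)
}

# Normalized 2D Gaussian kernel (sums to 1) on an odd size x size grid.
gaussian_kernel <- function(size = 7L, sigma = 1) {
  size <- as.integer(size)
  if (size %% 2L != 1L) stop("Gaussian kernel size must be odd")
  k <- seq.int(-(size %/% 2L), size %/% 2L)
  g <- exp(-k^2 / (2 * sigma^2))
  kern <- outer(g, g)
  kern / sum(kern)
}
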