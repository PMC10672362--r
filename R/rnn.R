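#' Parameters of the recurrent patch encoder-decoder
#'
#' One recurrent cell \code{z_t = ReLU(W_zy' y_t + W_zz' z_{t-1} + b)} (state
#' width \code{nn}, zero initial state) wrapped with a linear fully connected
#' head \code{x_t = head_W' z_t + head_b} that emits \code{P} values per depth
#' step. The patch rows are fed as the step sequence: \code{y_t} is the
#' \code{Nx}-vector of laterally neighbouring pixels at depth \code{t}.
#'
#' Weights are initialized uniformly on \code{[-1/sqrt(fan_in), 1/sqrt(fan_in)]}
#' with a threaded seed, biases at zero.
#'
#' @param Nx Input vector length per step (patch width).
#' @param nn Hidden state width (default 1000).
#' @param P Output dimension per step (1 or \code{Nx}).
#' @param seed Integer seed for initialization.
#' @return An object of class \code{rnn_params}: list of \code{W_zy}
#'   (\code{Nx x nn}), \code{W_zz} (\code{nn x nn}), \code{b} (\code{nn}),
#'   \code{head_W} (\code{nn x P}), \code{head_b} (\code{P}).
#' @export
rnn_params <- function(Nx, nn = 1000L, P = 1L, seed = 0L) {
  Nx <- as.integer(Nx); nn <- as.integer(nn); P <- as.integer(P)
  if (min(Nx, nn, P) < 1L) stop("Nx, nn and P must be >= 1")
  with_local_seed(seed, {
    structure(list(
      W_zy = matrix(stats::runif(Nx * nn, -1, 1) / sqrt(Nx), Nx, nn),
      W_zz = matrix(stats::runif(nn * nn, -1, 1) / sqrt(nn), nn, nn),
      b = numeric(nn),
      head_W = matrix(stats::runif(nn * P, -1, 1) / sqrt(nn), nn, P),
      head_b = numeric(P),
      nn = nn, Nx = Nx, P = P
    ), class = "rnn_params")
  })
}

#' Run the recurrent cell over one analysis patch
#'
#' The patch's \code{Lt} rows are consumed as the input sequence (top row
#' first); the state starts at zero. Returns every per-step head output;
#' patch-to-pixel prediction keeps only the last one (see [predict_pixel()]).
#'
#' @param sequence \code{Lt x Nx} numeric matrix (one analysis patch).
#' @param params An [rnn_params()].
#' @return \code{Lt x P} matrix of head outputs.
#' @export
rnn_forward <- function(sequence, params) {
  sequence <- as.matrix(sequence)
  if (ncol(sequence) != params$Nx) {
    stop(sprintf("sequence step length %d does not match Nx = %d",
                 ncol(sequence), params$Nx))
  }
  inputs <- array(0, c(1L, nrow(sequence), ncol(sequence)))
  inputs[1L, , ] <- sequence
  out <- rnn_forward_batch(inputs, params)$outputs
  matrix(out[1L, , ], nrow(sequence), params$P)
}

# Batched forward pass: inputs is m x Lt x Nx. Returns per-step outputs
# (m x Lt x P) and, when cache = TRUE, the hidden states needed by BPTT.
rnn_forward_batch <- function(inputs, params, cache = FALSE) {
  dims <- dim(inputs)
  m <- dims[1]; Lt <- dims[2]
  nn <- params$nn; P <- params$P
  outputs <- array(0, c(m, Lt, P))
  Z_prev <- matrix(0, m, nn)
  states <- if (cache) vector("list", Lt) else NULL
  for (t in seq_len(Lt)) {
    Yt <- matrix(inputs[, t, ], m, params$Nx)
    pre <- Yt %*% params$W_zy + Z_prev %*% params$W_zz +
      matrix(params$b, m, nn, byrow = TRUE)
    Z <- pre * (pre > 0)
    outputs[, t, ] <- Z %*% params$head_W +
      matrix(params$head_b, m, P, byrow = TRUE)
    if (cache) states[[t]] <- Z
    Z_prev <- Z
  }
  list(outputs = outputs, states = states)
}

# Backpropagation through time. d_outputs is m x Lt x P (dLoss/dOutput).
# Returns gradients with the same shapes as the parameters.
rnn_backward_batch <- function(inputs, params, states, d_outputs) {
  dims <- dim(inputs)
  m <- dims[1]; Lt <- dims[2]
  nn <- params$nn
  gW_zy <- matrix(0, params$Nx, nn); gW_zz <- matrix(0, nn, nn)
  gb <- numeric(nn)
  gHW <- matrix(0, nn, params$P); gHb <- numeric(params$P)
  dZ_next <- matrix(0, m, nn)
  for (t in rev(seq_len(Lt))) {
    Z <- states[[t]]
    dOut <- matrix(d_outputs[, t, ], m, params$P)
    gHW <- gHW + crossprod(Z, dOut)
    gHb <- gHb + colSums(dOut)
    dZ <- dOut %*% t(params$head_W) + dZ_next
    dPre <- dZ * (Z > 0)                 # ReLU: Z > 0 iff pre > 0
    Yt <- matrix(inputs[, t, ], m, params$Nx)
    gW_zy <- gW_zy + crossprod(Yt, dPre)
    if (t > 1L) {
      gW_zz <- gW_zz + crossprod(states[[t - 1L]], dPre)
    }
    gb <- gb + colSums(dPre)
    dZ_next <- dPre %*% t(params$W_zz)
  }
  list(W_zy = gW_zy, W_zz = gW_zz, b = gb, head_W = gHW, head_b = gHb)
}

#' Patch-to-pixel and patch-to-patch prediction
#'
#' \code{predict_pixel} runs the recurrence over the patch and returns only
#' the last head output (the first \code{Lt - 1} outputs are ignored): the
#' despeckled estimate of the anchor pixel. Requires \code{P = 1}.
#' \code{predict_patch} stacks all per-step outputs into an \code{Lt x Nx}
#' prediction aligned with the input patch. Requires \code{P = Nx}.
#'
#' @param patch \code{Lt x Nx} matrix.
#' @param params An [rnn_params()].
#' @return Scalar (\code{predict_pixel}) or \code{Lt x Nx} matrix
#'   (\code{predict_patch}).
#' @export
predict_pixel <- function(patch, params) {
  if (params$P != 1L) stop("predict_pixel requires a P = 1 model")
  out <- rnn_forward(patch, params)
  out[nrow(out), 1L]
}

#' @rdname predict_pixel
#' @export
predict_patch <- function(patch, params) {
  if (params$P != params$Nx) stop("predict_patch requires a P = Nx model")
  rnn_forward(patch, params)
}

#' Low-pass preprocessing for the deblurring variant
#'
#' The deblurring recurrent despeckler (DRNN) extracts its analysis patches
#' from a low-pass filtered copy of the noisy image and learns to restore the
#' clean image from the blurred one. The filter is a normalized 2D Gaussian
#' (default 7 x 7, sigma 1), applied with reflected boundaries; it is used
#' identically at training and inference.
#'
#' @param image A [log_image()] or numeric matrix.
#' @param size Odd kernel side length (default 7).
#' @param sigma Gaussian standard deviation in pixels (default 1).
#' @return Same type as \code{image}, blurred.
#' @export
deblur_preprocess <- function(image, size = 7L, sigma = 1) {
  kern <- gaussian_kernel(size, sigma)
  if (inherits(image, "log_image")) {
    out <- conv2_reflect(image$values, kern)
    log_image(out, pitch_z = image$pitch_z, pitch_x = image$pitch_x,
              dynamic_range = image$dynamic_range)
  } else {
    conv2_reflect(as.matrix(image), kern)
  }
}

#' Two-layer patch discriminator
#'
#' The adversarial refinement stage uses a deliberately tiny discriminator:
#' the flattened \code{Lt x Nx} patch goes through one hidden fully connected
#' ReLU layer and one scalar sigmoid output -- a realness score in (0, 1).
#'
#' @param input_dim Flattened patch length (\code{Lt * Nx}).
#' @param hidden Hidden width (default 128).
#' @param seed Integer seed.
#' @return An object of class \code{discriminator_params}.
#' @export
discriminator_params <- function(input_dim, hidden = 128L, seed = 0L) {
  input_dim <- as.integer(input_dim); hidden <- as.integer(hidden)
  with_local_seed(seed, {
    structure(list(
      W1 = matrix(stats::runif(input_dim * hidden, -1, 1) / sqrt(input_dim),
                  input_dim, hidden),
      b1 = numeric(hidden),
      W2 = matrix(stats::runif(hidden, -1, 1) / sqrt(hidden), hidden, 1L),
      b2 = numeric(1L),
      input_dim = input_dim, hidden = hidden
    ), class = "discriminator_params")
  })
}

#' @param patch \code{Lt x Nx} matrix (or a batch as an \code{m x (Lt*Nx)}
#'   matrix of flattened patches).
#' @param params A \code{discriminator_params}.
#' @rdname discriminator_params
#' @return \code{discriminator_forward}: realness score(s) in (0, 1).
#' @export
discriminator_forward <- function(patch, params) {
  X <- flatten_patches(patch, params$input_dim)
  drop(disc_forward_batch(X, params)$p)
}

flatten_patches <- function(patch, input_dim) {
  if (is.matrix(patch) && ncol(patch) == input_dim && nrow(patch) >= 1 &&
      length(patch) != input_dim) {
    return(patch)                         # already m x D
  }
  v <- as.numeric(patch)
  if (length(v) != input_dim) {
    stop(sprintf("patch has %d values; discriminator expects %d",
                 length(v), input_dim))
  }
  matrix(v, 1L, input_dim)
}

disc_forward_batch <- function(X, params) {
  pre1 <- X %*% params$W1 + matrix(params$b1, nrow(X), params$hidden, byrow = TRUE)
  H <- pre1 * (pre1 > 0)
  logit <- drop(H %*% params$W2) + params$b2
  list(p = 1 / (1 + exp(-logit)), logit = logit, H = H, X = X)
}

# Backward pass from dLoss/dlogit; returns parameter grads and dLoss/dX.
disc_backward_batch <- function(cache, params, d_logit) {
  m <- nrow(cache$X)
  d_logit <- matrix(d_logit, m, 1L)
  gW2 <- crossprod(cache$H, d_logit)
  gb2 <- sum(d_logit)
  dH <- d_logit %*% t(params$W2)
  dPre1 <- dH * (cache$H > 0)
  gW1 <- crossprod(cache$X, dPre1)
  gb1 <- colSums(dPre1)
  dX <- dPre1 %*% t(params$W1)
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2), dX = dX)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars in a parameter set or a fitted
#' despeckler. The default recurrent predictor (\code{Nx = 15},
#' \code{nn = 1000}, \code{P = 15}) has 1,031,015 parameters; the default
#' U-Net about eight times as many.
#'
#' @param model An [rnn_params()], [discriminator_params()],
#'   [unet_params()], or \code{despeckler_model}.
#' @return Integer scalar.
#' @export
count_parameters <- function(model) {
  UseMethod("count_parameters")
}

#' @export
count_parameters.rnn_params <- function(model) {
  length(model$W_zy) + length(model$W_zz) + length(model$b) +
    length(model$head_W) + length(model$head_b)
}

#' @export
count_parameters.discriminator_params <- function(model) {
  length(model$W1) + length(model$b1) + length(model$W2) + length(model$b2)
}

#' @export
count_parameters.despeckler_model <- function(model) {
  count_parameters(model$params)
}
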