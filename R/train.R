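#' Training configuration for the few-shot despecklers
#'
#' Defaults follow the few-shot regime this package targets: Adam with
#' \code{beta1 = 0.5}, \code{beta2 = 0.9} and initial learning rate
#' \code{1e-4}; a short content (MSE) stage of 8 epochs (useful range about
#' 5-12); an optional adversarial stage of 20 epochs (range about 10-30)
#' balancing the losses with \code{lambda_adv}; early stopping when the
#' training MSE plateaus, since overtraining a single image overfits and
#' blurs.
#'
#' @param lr Initial learning rate (> 0).
#' @param beta1,beta2 Adam moment decay rates.
#' @param epochs_content Epochs for the MSE stage.
#' @param epochs_adv Epochs for the adversarial stage.
#' @param lambda_adv Weight of the adversarial term in the generator loss
#'   (total loss = MSE + lambda_adv * adversarial).
#' @param batch_size Analysis patches (or crops) per optimizer step.
#' @param seed Integer seed threading all training randomness.
#' @param early_stop_tol Relative MSE improvement under which training stops.
#' @param early_stop_window Epochs over which the improvement is measured.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(lr = 1e-4, beta1 = 0.5, beta2 = 0.9,
                         epochs_content = 8L, epochs_adv = 20L,
                         lambda_adv = 1e-3, batch_size = 256L, seed = 0L,
                         early_stop_tol = 0.01, early_stop_window = 2L) {
  if (lr <= 0) stop("lr must be > 0")
  if (epochs_content < 1L || epochs_adv < 1L) stop("epochs must be >= 1")
  if (lambda_adv < 0) stop("lambda_adv must be >= 0")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 epochs_content = as.integer(epochs_content),
                 epochs_adv = as.integer(epochs_adv),
                 lambda_adv = lambda_adv,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 early_stop_tol = early_stop_tol,
                 early_stop_window = as.integer(early_stop_window)),
            class = "train_config")
}

# ---- Adam over nested parameter lists -------------------------------------

adam_state <- function() list(m = NULL, v = NULL, t = 0L)

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(g)) {
      if (is.null(m)) m <- vector("list", length(g))
      if (is.null(v)) v <- vector("list", length(g))
      names(m) <- names(g); names(v) <- names(g)
      for (n in names(g)) {
        res <- walk(p[[n]], g[[n]], m[[n]], v[[n]])
        p[[n]] <- res$p; m[[n]] <- res$m; v[[n]] <- res$v
      }
      return(list(p = p, m = m, v = v))
    }
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- cfg$beta1 * m + (1 - cfg$beta1) * g
    v <- cfg$beta2 * v + (1 - cfg$beta2) * g^2
    mh <- m / (1 - cfg$beta1^t)
    vh <- v / (1 - cfg$beta2^t)
    p <- p - cfg$lr * mh / (sqrt(vh) + 1e-8)
    list(p = p, m = m, v = v)
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}

# ---- content stage --------------------------------------------------------

#' Content (MSE) training stage
#'
#' Minimizes the mean squared error between the model's patch predictions and
#' the clean targets with Adam, over shuffled mini-batches, with early
#' stopping on a loss plateau. For the recurrent predictors the loss covers
#' every per-step output (at inference patch-to-pixel keeps only the last
#' step). For the U-Net, \code{data} is a crop set from [make_crop_dataset()].
#'
#' @param model A \code{despeckler_model} (see [few_shot_fit()], which wraps
#'   this; calling it directly is useful for custom loops).
#' @param data A \code{patch_dataset} (recurrent methods) or crop dataset
#'   (U-Net).
#' @param cfg A [train_config()].
#' @return The model with updated parameters and a \code{trace} of per-epoch
#'   losses.
#' @export
train_content <- function(model, data, cfg = train_config()) {
  stopifnot(inherits(model, "despeckler_model"))
  if (model$method == "unet") {
    return(train_unet_content(model, data, cfg))
  }
  stopifnot(inherits(data, "patch_dataset"))
  if (data$m < 1L) stop("empty dataset")
  params <- model$params
  targ <- target_array(data)
  st <- adam_state()
  trace <- numeric(0)
  for (epoch in seq_len(cfg$epochs_content)) {
    ord <- with_local_seed(cfg$seed * 1000L + epoch, sample.int(data$m))
    ep_loss <- 0; n_seen <- 0
    for (start in seq(1L, data$m, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, data$m)]
      res <- rnn_mse_grad(params, data$inputs[idx, , , drop = FALSE],
                          targ[idx, , , drop = FALSE])
      if (!is.finite(res$loss)) {
        stop(sprintf("training diverged (loss = %g) at epoch %d", res$loss, epoch))
      }
      upd <- adam_step(params, res$grads, st, cfg)
      params <- upd$params; st <- upd$state
      ep_loss <- ep_loss + res$loss * length(idx)
      n_seen <- n_seen + length(idx)
    }
    trace <- c(trace, ep_loss / n_seen)
    if (early_stop_hit(trace, cfg)) break
  }
  model$params <- params
  model$trace <- c(model$trace, list(content = trace))
  model
}

target_array <- function(data) {
  if (length(dim(data$targets)) == 2L) {
    array(data$targets, c(data$m, data$cfg$Lt, 1L))
  } else {
    data$targets
  }
}

# MSE loss and parameter gradients for one batch of analysis patches.
rnn_mse_grad <- function(params, inputs, targets) {
  fw <- rnn_forward_batch(inputs, params, cache = TRUE)
  diff <- fw$outputs - targets
  loss <- mean(diff^2)
  d_out <- 2 * diff / length(diff)
  grads <- rnn_backward_batch(inputs, params, fw$states, d_out)
  list(loss = loss, grads = grads, outputs = fw$outputs, states = fw$states)
}

early_stop_hit <- function(trace, cfg) {
  w <- cfg$early_stop_window
  if (length(trace) <= w) return(FALSE)
  prev <- trace[length(trace) - w]
  (prev - trace[length(trace)]) / max(prev, 1e-12) < cfg$early_stop_tol
}

train_unet_content <- function(model, data, cfg) {
  params <- model$params
  n <- dim(data$crops_x)[1]
  if (n < 1L) stop("empty crop dataset")
  st <- adam_state()
  trace <- numeric(0)
  for (epoch in seq_len(cfg$epochs_content)) {
    ord <- with_local_seed(cfg$seed * 1000L + epoch, sample.int(n))
    ep_loss <- 0
    for (k in ord) {
      x <- data$crops_x[k, , ]
      y <- data$crops_y[k, , ]
      fw <- unet_forward_cached(x, params)
      diff <- fw$Y - y
      loss <- mean(diff^2)
      if (!is.finite(loss)) stop("training diverged (U-Net loss not finite)")
      grads <- unet_backward(2 * diff / length(diff), fw, params)
      upd <- adam_step(params, grads, st, cfg)
      params <- upd$params; st <- upd$state
      ep_loss <- ep_loss + loss
    }
    trace <- c(trace, ep_loss / n)
    if (early_stop_hit(trace, cfg)) break
  }
  model$params <- params
  model$trace <- c(model$trace, list(content = trace))
  model
}

# ---- adversarial stage ----------------------------------------------------

#' Adversarial refinement stage
#'
#' Starting from a content-trained patch-to-patch generator, alternates
#' discriminator and generator updates: the discriminator learns to separate
#' clean patches (real) from generator outputs (fake) with binary
#' cross-entropy; the generator minimizes MSE plus \code{lambda_adv} times
#' the non-saturating adversarial loss \code{-log D(G(y))}.
#'
#' @param model A content-trained \code{despeckler_model} with \code{P = Nx}.
#' @param discriminator A [discriminator_params()] (default: fresh one sized
#'   to the patch).
#' @param data The \code{patch_dataset} used for the content stage.
#' @param cfg A [train_config()].
#' @return The model, with refreshed generator parameters, the trained
#'   \code{discriminator} attached, and adversarial-stage traces.
#' @export
train_adversarial <- function(model, data, cfg = train_config(),
                              discriminator = NULL) {
  stopifnot(inherits(model, "despeckler_model"),
            inherits(data, "patch_dataset"))
  pc <- data$cfg
  if (pc$P != pc$Nx) stop("adversarial stage needs a patch-to-patch (P = Nx) dataset")
  D_dim <- pc$Lt * pc$Nx
  if (is.null(discriminator)) {
    discriminator <- discriminator_params(D_dim, seed = cfg$seed + 77L)
  }
  gen <- model$params
  targ <- target_array(data)
  st_g <- adam_state(); st_d <- adam_state()
  g_trace <- numeric(0); d_trace <- numeric(0)
  sat_run <- 0L; warned <- FALSE
  for (epoch in seq_len(cfg$epochs_adv)) {
    ord <- with_local_seed(cfg$seed * 2000L + epoch, sample.int(data$m))
    ep_g <- 0; ep_d <- 0; nb <- 0L
    for (start in seq(1L, data$m, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, data$m)]
      mB <- length(idx)
      xin <- data$inputs[idx, , , drop = FALSE]
      xtg <- targ[idx, , , drop = FALSE]

      # --- discriminator step: real = clean patches, fake = G(y) ---
      fake <- rnn_forward_batch(xin, gen)$outputs       # m x Lt x Nx
      Xreal <- matrix(xtg, mB, D_dim)
      Xfake <- matrix(fake, mB, D_dim)
      fr <- disc_forward_batch(Xreal, discriminator)
      ff <- disc_forward_batch(Xfake, discriminator)
      eps <- 1e-12
      d_loss <- -mean(log(fr$p + eps)) - mean(log(1 - ff$p + eps))
      # dBCE/dlogit: real label 1 -> p - 1 ; fake label 0 -> p
      br <- disc_backward_batch(fr, discriminator, (fr$p - 1) / mB)
      bf <- disc_backward_batch(ff, discriminator, ff$p / mB)
      d_grads <- Map(`+`, br$grads, bf$grads)
      upd <- adam_step(discriminator[c("W1", "b1", "W2", "b2")], d_grads, st_d, cfg)
      discriminator[c("W1", "b1", "W2", "b2")] <- upd$params
      st_d <- upd$state

      # --- generator step: MSE + lambda * (-log D(G(y))) ---
      fw <- rnn_forward_batch(xin, gen, cache = TRUE)
      diff <- fw$outputs - xtg
      mse <- mean(diff^2)
      d_out <- 2 * diff / length(diff)
      g_loss <- mse
      if (cfg$lambda_adv > 0) {
        Xg <- matrix(fw$outputs, mB, D_dim)
        fg <- disc_forward_batch(Xg, discriminator)
        adv <- -mean(log(fg$p + eps))
        bg <- disc_backward_batch(fg, discriminator, (fg$p - 1) / mB)
        d_out <- d_out + cfg$lambda_adv * array(bg$dX, dim(d_out))
        g_loss <- mse + cfg$lambda_adv * adv
      }
      if (!is.finite(g_loss)) stop("adversarial training diverged")
      grads <- rnn_backward_batch(xin, gen, fw$states, d_out)
      updg <- adam_step(gen, grads, st_g, cfg)
      gen <- updg$params; st_g <- updg$state

      ep_g <- ep_g + g_loss; ep_d <- ep_d + d_loss; nb <- nb + 1L
      sat_run <- if (d_loss < 1e-3) sat_run + 1L else 0L
      if (sat_run > 5L && !warned) {
        warning("discriminator loss saturated near zero; consider lowering its learning rate")
        warned <- TRUE
      }
    }
    g_trace <- c(g_trace, ep_g / nb)
    d_trace <- c(d_trace, ep_d / nb)
  }
  model$params <- gen
  model$discriminator <- discriminator
  model$trace <- c(model$trace,
                   list(adversarial = g_trace, discriminator = d_trace))
  model
}

# ---- inference ------------------------------------------------------------

#' Despeckle a full tomogram with a trained model
#'
#' The test image is normalized to \code{[0, 1]} by its own value range
#' (robust to brightness offsets across systems), the deblurring filter is
#' applied first for DRNN models, the analysis patch slides across every
#' pixel (patch-to-pixel fills each pixel from its own patch; patch-to-patch
#' models average overlapping patch predictions), and the result is mapped
#' back to dB. U-Net models see the whole image, reflect-padded to a
#' multiple of \code{2^depth}.
#'
#' @param image A [log_image()].
#' @param model A trained \code{despeckler_model}.
#' @param stride Anchor stride for patch-to-patch averaging (default 1 =
#'   maximal overlap; larger is faster, coarser).
#' @param batch_size Patches per forward batch.
#' @return A despeckled [log_image()] of the same shape.
#' @export
despeckle_image <- function(image, model, stride = 1L, batch_size = 4096L) {
  stopifnot(inherits(image, "log_image"), inherits(model, "despeckler_model"))
  pc <- model$patch_cfg
  nr <- nrow(image$values); nc <- ncol(image$values)
  if (model$method != "unet" && (nr < pc$Lt || nc < pc$Nx)) {
    stop("image smaller than the analysis patch")
  }
  work <- image
  if (!is.null(model$deblur_filter)) {
    work <- deblur_preprocess(work, model$deblur_filter$size,
                              model$deblur_filter$sigma)
  }
  norm <- normalize_db(work$values)
  V <- norm$values

  if (model$method == "unet") {
    mult <- 2^model$params$depth
    pr <- (mult - nr %% mult) %% mult
    pc2 <- (mult - nc %% mult) %% mult
    Vp <- V
    if (pr > 0) Vp <- rbind(Vp, Vp[nr - seq_len(pr) + 1L, , drop = FALSE])
    if (pc2 > 0) Vp <- cbind(Vp, Vp[, ncol(Vp) - seq_len(pc2) + 1L, drop = FALSE])
    out <- unet_forward(Vp, model$params)[seq_len(nr), seq_len(nc)]
  } else if (pc$P == 1L) {
    anchors <- as.matrix(expand.grid(i = seq_len(nr), j = seq_len(nc)))
    out <- matrix(0, nr, nc)
    for (start in seq(1L, nrow(anchors), by = batch_size)) {
      sel <- start:min(start + batch_size - 1L, nrow(anchors))
      patches <- patches_from_matrix(V, pc, anchors[sel, , drop = FALSE])
      pred <- rnn_forward_batch(patches, model$params)$outputs
      out[anchors[sel, 1L] + (anchors[sel, 2L] - 1L) * nr] <- pred[, pc$Lt, 1L]
    }
  } else {
    rows <- unique(c(seq.int(1L, nr, by = stride), nr))
    cols <- unique(c(seq.int(1L, nc, by = stride), nc))
    anchors <- as.matrix(expand.grid(i = rows, j = cols))
    preds <- array(0, c(nrow(anchors), pc$Lt, pc$Nx))
    for (start in seq(1L, nrow(anchors), by = batch_size)) {
      sel <- start:min(start + batch_size - 1L, nrow(anchors))
      patches <- patches_from_matrix(V, pc, anchors[sel, , drop = FALSE])
      preds[sel, , ] <- rnn_forward_batch(patches, model$params)$outputs
    }
    rec <- overlap_average_reconstruct(preds, anchors, c(nr, nc), pc)
    out <- rec$values
    if (anyNA(out)) {
      warning("stride left uncovered pixels; filling from the input")
      out[is.na(out)] <- V[is.na(out)]
    }
  }
  log_image(denormalize_db(out, norm$scale),
            pitch_z = image$pitch_z, pitch_x = image$pitch_x,
            dynamic_range = image$dynamic_range)
}

patches_from_matrix <- function(V, cfg, anchors) {
  nr <- nrow(V); nc <- ncol(V)
  m <- nrow(anchors)
  ai <- anchors[, 1L]; aj <- anchors[, 2L]
  out <- array(0, c(m, cfg$Lt, cfg$Nx))
  for (t in seq_len(cfg$Lt)) {
    ri <- pmin(pmax(ai - cfg$Lt + t, 1L), nr)
    for (u in seq_len(cfg$Nx)) {
      cu <- pmin(pmax(aj - cfg$nL + u - 1L, 1L), nc)
      out[, t, u] <- V[ri + (cu - 1L) * nr]
    }
  }
  out
}

# ---- one-shot fitting -----------------------------------------------------

#' Fit a despeckler from a single image pair
#'
#' The few-shot entry point: given one speckled tomogram and its
#' speckle-suppressed ground truth (or a sub-region of them), builds the
#' training set, initializes the chosen predictor and runs its training
#' stage(s), returning a sealed model that [despeckle_image()] accepts.
#'
#' Methods: \code{"rnn"} (patch-to-pixel recurrent predictor), \code{"drnn"}
#' (same, trained on the low-pass-filtered input: despeckling as deblurring),
#' \code{"rnn_gan"} (patch-to-patch recurrent generator with overlapping
#' patch averaging, refined adversarially), \code{"unet"} (one-shot U-Net
#' trained on random crops of the pair).
#'
#' @param noisy,clean [log_image()]s of identical shape.
#' @param method One of \code{"rnn"}, \code{"drnn"}, \code{"rnn_gan"},
#'   \code{"unet"}.
#' @param region Training region as in [build_dataset()] (e.g.
#'   \code{list(cols = 1:100)} for the first 100 columns); recurrent methods
#'   only.
#' @param cfg A [train_config()].
#' @param patch_cfg An [analysis_patch_config()]; default 15 x 15 with the
#'   output dimension the method requires.
#' @param nn Hidden width of the recurrent cell (default 1000).
#' @param unet_depth,unet_base U-Net levels and base channels (defaults 4, 32).
#' @param crop_size,n_crops U-Net random-crop side (default 64; sides must be
#'   divisible by \code{2^unet_depth}) and number of crops (default 1000).
#' @param source_spec Optional [oct_system_spec()] recorded on the model for
#'   later domain planning.
#' @return A \code{despeckler_model}.
#' @export
few_shot_fit <- function(noisy, clean,
                         method = c("rnn", "drnn", "rnn_gan", "unet"),
                         region = NULL, cfg = train_config(),
                         patch_cfg = NULL, nn = 1000L,
                         unet_depth = 4L, unet_base = 32L,
                         crop_size = 64L, n_crops = 1000L,
                         source_spec = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(noisy, "log_image"), inherits(clean, "log_image"))

  if (method == "unet") {
    data <- make_crop_dataset(noisy, clean, crop_size = crop_size,
                              n_crops = n_crops, depth = unet_depth,
                              seed = cfg$seed)
    model <- new_despeckler_model(
      method, unet_params(unet_depth, unet_base, seed = cfg$seed),
      analysis_patch_config(Lt = crop_size, Nx = crop_size, nL = 0L,
                            nR = crop_size - 1L, P = crop_size),
      data$normalization, source_spec)
    return(train_content(model, data, cfg))
  }

  P_wanted <- if (method == "rnn_gan") NULL else 1L
  if (is.null(patch_cfg)) {
    patch_cfg <- if (method == "rnn_gan") {
      analysis_patch_config(P = 15L)
    } else {
      analysis_patch_config(P = 1L)
    }
  }
  if (method == "rnn_gan" && patch_cfg$P != patch_cfg$Nx) {
    patch_cfg <- analysis_patch_config(patch_cfg$Lt, patch_cfg$Nx,
                                       patch_cfg$nL, patch_cfg$nR,
                                       P = patch_cfg$Nx)
  }
  if (method != "rnn_gan" && patch_cfg$P != 1L) {
    stop("rnn and drnn are patch-to-pixel methods (P = 1)")
  }
  input_img <- noisy
  deblur_filter <- NULL
  if (method == "drnn") {
    deblur_filter <- list(size = 7L, sigma = 1)
    input_img <- deblur_preprocess(noisy, deblur_filter$size,
                                   deblur_filter$sigma)
  }
  check_region_size(input_img, region, patch_cfg)
  data <- build_dataset(input_img, clean, patch_cfg, region)
  params <- rnn_params(patch_cfg$Nx, nn = nn, P = patch_cfg$P, seed = cfg$seed)
  model <- new_despeckler_model(method, params, patch_cfg,
                                data$normalization, source_spec,
                                deblur_filter = deblur_filter)
  model <- train_content(model, data, cfg)
  if (method == "rnn_gan") {
    model <- train_adversarial(model, data, cfg)
  }
  model
}

check_region_size <- function(image, region, pc) {
  nr <- if (!is.null(region$rows)) length(region$rows) else nrow(image$values)
  nc <- if (!is.null(region$cols)) length(region$cols) else ncol(image$values)
  if (nr < 1L || nc < 1L) stop("empty training region")
  if (nrow(image$values) < pc$Lt || ncol(image$values) < pc$Nx) {
    stop("training image smaller than one analysis patch")
  }
}

new_despeckler_model <- function(method, params, patch_cfg, normalization,
                                 source_spec = NULL, deblur_filter = NULL) {
  structure(list(method = method, params = params, patch_cfg = patch_cfg,
                 normalization = normalization, source_spec = source_spec,
                 deblur_filter = deblur_filter, discriminator = NULL,
                 trace = list()),
            class = "despeckler_model")
}

#' @export
print.despeckler_model <- function(x, ...) {
  cat(sprintf("<despeckler_model> method = %s, %s parameters\n", x$method,
              format(count_parameters(x$params), big.mark = ",")))
  if (!is.null(x$source_spec)) {
    rr <- system_resolution_ratios(x$source_spec)
    cat(sprintf("  source system: %s (px = %d, pz = %d)\n",
                x$source_spec$name, rr$px, rr$pz))
  }
  invisible(x)
}

#' Random-crop dataset for the one-shot U-Net
#'
#' Draws \code{n_crops} random square crops (seeded) from the pair, both
#' normalized by the noisy image's value range.
#'
#' @inheritParams few_shot_fit
#' @param depth U-Net depth the crops must be divisible for.
#' @param seed Integer seed.
#' @return List with arrays \code{crops_x}, \code{crops_y}
#'   (\code{n x crop x crop}), the \code{normalization} affine, and the crop
#'   \code{anchors}.
#' @export
make_crop_dataset <- function(noisy, clean, crop_size = 64L, n_crops = 1000L,
                              depth = 4L, seed = 0L) {
  stopifnot(inherits(noisy, "log_image"), inherits(clean, "log_image"))
  crop_size <- as.integer(crop_size)
  if (crop_size %% 2^depth != 0L) {
    stop(sprintf("crop_size must be divisible by 2^depth = %d", 2^depth))
  }
  nr <- nrow(noisy$values); nc <- ncol(noisy$values)
  if (nr < crop_size || nc < crop_size) stop("image smaller than one crop")
  norm <- normalize_db(noisy$values)
  Yn <- norm$values
  Xn <- (clean$values - norm$scale[["lo"]]) /
    (norm$scale[["hi"]] - norm$scale[["lo"]])
  anchors <- with_local_seed(seed, cbind(
    sample.int(nr - crop_size + 1L, n_crops, replace = TRUE),
    sample.int(nc - crop_size + 1L, n_crops, replace = TRUE)))
  crops_x <- array(0, c(n_crops, crop_size, crop_size))
  crops_y <- array(0, c(n_crops, crop_size, crop_size))
  for (k in seq_len(n_crops)) {
    ri <- anchors[k, 1L] + seq_len(crop_size) - 1L
    ci <- anchors[k, 2L] + seq_len(crop_size) - 1L
    crops_x[k, , ] <- Yn[ri, ci]
    crops_y[k, , ] <- Xn[ri, ci]
  }
  list(crops_x = crops_x, crops_y = crops_y, normalization = norm$scale,
       anchors = anchors)
}

#' Save / load a trained despeckler
#'
#' Serializes the model (method tag, network parameters, patch geometry,
#' normalization affine, source system, optional deblur filter and
#' discriminator) as an RDS container plus a human-readable JSON manifest.
#'
#' @param model A \code{despeckler_model}.
#' @param path Output path (conventionally \code{.rds}).
#' @return \code{path} invisibly; \code{load_model} returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "despeckler_model"))
  saveRDS(model, path)
  manifest <- list(
    method = model$method,
    n_parameters = count_parameters(model$params),
    patch = list(Lt = model$patch_cfg$Lt, Nx = model$patch_cfg$Nx,
                 P = model$patch_cfg$P),
    normalization = as.list(model$normalization),
    source_system = if (is.null(model$source_spec)) NULL else model$source_spec$name,
    deblur = !is.null(model$deblur_filter))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "despeckler_model")) stop("not a despeckler_model file")
  m
}
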