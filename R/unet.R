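#' Parameters of the one-shot patch U-Net
#'
#' A standard encoder-decoder U-Net with skip connections: per resolution
#' level two 3x3 same-padded ReLU convolutions, 2x2 max pooling on the way
#' down, 2x2 stride-2 transposed convolutions on the way up, channel
#' concatenation with the encoder skip, and a final 1x1 convolution to one
#' channel. The default (4 levels, 32 base channels) has about 7.8 million
#' trainable parameters, in the 8 x 10^6 regime -- roughly eight times the
#' default recurrent predictor. Inputs must have sides divisible by
#' \code{2^depth}; [despeckle_image()] reflect-pads and crops automatically.
#'
#' @param depth Number of resolution levels (default 4).
#' @param base_channels Channels at the first level (default 32; doubled per
#'   level).
#' @param in_channels Input channels (default 1).
#' @param seed Integer seed for initialization.
#' @return An object of class \code{unet_params}.
#' @export
unet_params <- function(depth = 4L, base_channels = 32L, in_channels = 1L,
                        seed = 0L) {
  depth <- as.integer(depth); base <- as.integer(base_channels)
  if (depth < 1L || base < 1L) stop("depth and base_channels must be >= 1")
  with_local_seed(seed, {
    # He-scaled uniform init: keeps activation variance roughly constant
    # through the ReLU cascade, so the initial output is on the input scale
    conv_init <- function(cin, cout) {
      fan <- 9L * cin
      lim <- sqrt(6 / fan)
      list(W = matrix(stats::runif(fan * cout, -lim, lim), fan, cout),
           b = numeric(cout))
    }
    convT_init <- function(cin, cout) {
      lim <- sqrt(6 / cin)
      list(W = array(stats::runif(cin * cout * 4L, -lim, lim),
                     c(cin, cout, 4L)),
           b = numeric(cout))
    }
    ch <- base * 2^(seq_len(depth) - 1L)
    enc <- vector("list", depth)
    cin <- as.integer(in_channels)
    for (l in seq_len(depth)) {
      enc[[l]] <- list(conv1 = conv_init(cin, ch[l]),
                       conv2 = conv_init(ch[l], ch[l]))
      cin <- ch[l]
    }
    ch_b <- base * 2^depth
    bott <- list(conv1 = conv_init(ch[depth], ch_b),
                 conv2 = conv_init(ch_b, ch_b))
    up <- vector("list", depth); dec <- vector("list", depth)
    cprev <- ch_b
    for (l in rev(seq_len(depth))) {
      up[[l]] <- convT_init(cprev, ch[l])
      dec[[l]] <- list(conv1 = conv_init(2L * ch[l], ch[l]),
                       conv2 = conv_init(ch[l], ch[l]))
      cprev <- ch[l]
    }
    lim_f <- sqrt(6 / ch[1])
    final <- list(W = matrix(stats::runif(ch[1], -lim_f, lim_f), ch[1], 1L),
                  b = numeric(1L))
    structure(list(depth = depth, base_channels = base,
                   in_channels = as.integer(in_channels),
                   enc = enc, bott = bott, up = up, dec = dec, final = final),
              class = "unet_params")
  })
}

#' @export
count_parameters.unet_params <- function(model) {
  total <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk)
    else if (is.numeric(x)) total <<- total + length(x)
    invisible(NULL)
  }
  walk(list(model$enc, model$bott, model$up, model$dec, model$final))
  as.integer(total)
}

# ---- primitive layers (feature maps are H x W x C arrays) -----------------

as_feature_map <- function(x) {
  if (length(dim(x)) == 2L) array(x, c(dim(x), 1L)) else x
}

im2col3 <- function(X) {
  d <- dim(X); H <- d[1]; W <- d[2]; C <- d[3]
  Xp <- array(0, c(H + 2L, W + 2L, C))
  Xp[2:(H + 1L), 2:(W + 1L), ] <- X
  cols <- matrix(0, H * W, 9L * C)
  o <- 0L
  for (dj in -1:1) for (di in -1:1) {
    o <- o + 1L
    blk <- Xp[(1:H) + di + 1L, (1:W) + dj + 1L, , drop = FALSE]
    cols[, ((o - 1L) * C + 1L):(o * C)] <- matrix(blk, H * W, C)
  }
  cols
}

col2im3 <- function(dcols, H, W, C) {
  dXp <- array(0, c(H + 2L, W + 2L, C))
  o <- 0L
  for (dj in -1:1) for (di in -1:1) {
    o <- o + 1L
    blk <- array(dcols[, ((o - 1L) * C + 1L):(o * C)], c(H, W, C))
    dXp[(1:H) + di + 1L, (1:W) + dj + 1L, ] <-
      dXp[(1:H) + di + 1L, (1:W) + dj + 1L, , drop = FALSE] + blk
  }
  dXp[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
}

conv3_forward <- function(X, layer, relu = TRUE) {
  d <- dim(X); H <- d[1]; W <- d[2]; C <- d[3]
  cols <- im2col3(X)
  out <- cols %*% layer$W
  out <- sweep(out, 2L, layer$b, `+`)
  if (relu) out <- out * (out > 0)
  list(Y = array(out, c(H, W, ncol(layer$W))), cols = cols, relu = relu)
}

conv3_backward <- function(dY, cache, layer, H, W, Cin) {
  cout <- ncol(layer$W)
  dmat <- matrix(dY, H * W, cout)
  if (cache$relu) dmat <- dmat * (matrix(cache$Y, H * W, cout) > 0)
  gW <- crossprod(cache$cols, dmat)
  gb <- colSums(dmat)
  dcols <- dmat %*% t(layer$W)
  dX <- col2im3(dcols, H, W, Cin)
  list(grads = list(W = gW, b = gb), dX = dX)
}

maxpool2_forward <- function(X) {
  d <- dim(X); H <- d[1]; W <- d[2]
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  s <- list(X[io, jo, , drop = FALSE], X[io, jo + 1L, , drop = FALSE],
            X[io + 1L, jo, , drop = FALSE], X[io + 1L, jo + 1L, , drop = FALSE])
  Y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  which_max <- array(4L, dim(Y))       # first maximal branch wins
  for (k in 3:1) which_max[s[[k]] == Y] <- k
  list(Y = Y, which_max = which_max)
}

maxpool2_backward <- function(dY, cache, H, W) {
  d <- dim(dY); C <- d[3]
  dX <- array(0, c(H, W, C))
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  for (k in 1:4) {
    mask <- cache$which_max == k
    di <- (k - 1L) %/% 2L   # 0 for k=1,2 ; 1 for k=3,4
    dj <- (k - 1L) %% 2L    # 0 for k=1,3 ; 1 for k=2,4
    tmp <- array(0, dim(dY))
    tmp[mask] <- dY[mask]
    dX[io + di, jo + dj, ] <- tmp
  }
  dX
}

convT2_forward <- function(X, layer) {
  d <- dim(X); H <- d[1]; W <- d[2]; Cin <- d[3]
  cout <- dim(layer$W)[2]
  Xm <- matrix(X, H * W, Cin)
  Y <- array(0, c(2L * H, 2L * W, cout))
  io <- seq(1L, 2L * H, 2L); jo <- seq(1L, 2L * W, 2L)
  phase <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  for (k in 1:4) {
    out <- sweep(Xm %*% layer$W[, , k], 2L, layer$b, `+`)
    Y[io + phase[[k]][1], jo + phase[[k]][2], ] <- array(out, c(H, W, cout))
  }
  list(Y = Y, Xm = Xm)
}

convT2_backward <- function(dY, cache, layer, H, W, Cin) {
  cout <- dim(layer$W)[2]
  io <- seq(1L, 2L * H, 2L); jo <- seq(1L, 2L * W, 2L)
  phase <- list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  gW <- array(0, dim(layer$W)); gb <- numeric(cout)
  dXm <- matrix(0, H * W, Cin)
  for (k in 1:4) {
    dk <- matrix(dY[io + phase[[k]][1], jo + phase[[k]][2], , drop = FALSE],
                 H * W, cout)
    gW[, , k] <- crossprod(cache$Xm, dk)
    gb <- gb + colSums(dk)
    dXm <- dXm + dk %*% t(layer$W[, , k])
  }
  list(grads = list(W = gW, b = gb), dX = array(dXm, c(H, W, Cin)))
}

conv_block_forward <- function(X, block) {
  c1 <- conv3_forward(X, block$conv1)
  c2 <- conv3_forward(c1$Y, block$conv2)
  list(Y = c2$Y, c1 = c1, c2 = c2, Cin = dim(X)[3], H = dim(X)[1], W = dim(X)[2])
}

conv_block_backward <- function(dY, cache, block) {
  ch <- ncol(block$conv1$W)
  b2 <- conv3_backward(dY, cache$c2, block$conv2, cache$H, cache$W, ch)
  b1 <- conv3_backward(b2$dX, cache$c1, block$conv1, cache$H, cache$W, cache$Cin)
  list(grads = list(conv1 = b1$grads, conv2 = b2$grads), dX = b1$dX)
}

#' Forward pass of the U-Net
#'
#' @param image_patch 2D matrix (or \code{H x W x 1} array) with both sides
#'   divisible by \code{2^depth}.
#' @param params A [unet_params()].
#' @return Denoised matrix of the same height and width.
#' @export
unet_forward <- function(image_patch, params) {
  unet_forward_cached(image_patch, params)$Y
}

unet_forward_cached <- function(image_patch, params) {
  X <- as_feature_map(as_matrix_or_array(image_patch))
  d <- dim(X)
  if (d[1] %% 2^params$depth != 0L || d[2] %% 2^params$depth != 0L) {
    stop(sprintf("input sides must be multiples of %d", 2^params$depth))
  }
  skips <- vector("list", params$depth)
  pools <- vector("list", params$depth)
  cur <- X
  for (l in seq_len(params$depth)) {
    skips[[l]] <- conv_block_forward(cur, params$enc[[l]])
    pools[[l]] <- maxpool2_forward(skips[[l]]$Y)
    cur <- pools[[l]]$Y
  }
  bott <- conv_block_forward(cur, params$bott)
  cur <- bott$Y
  ups <- vector("list", params$depth)
  decs <- vector("list", params$depth)
  for (l in rev(seq_len(params$depth))) {
    ups[[l]] <- convT2_forward(cur, params$up[[l]])
    cat_in <- abind3(ups[[l]]$Y, skips[[l]]$Y)
    decs[[l]] <- conv_block_forward(cat_in, params$dec[[l]])
    cur <- decs[[l]]$Y
  }
  H <- dim(cur)[1]; W <- dim(cur)[2]; C <- dim(cur)[3]
  fin_mat <- matrix(cur, H * W, C) %*% params$final$W + params$final$b
  list(Y = matrix(fin_mat, H, W), X = X, skips = skips, pools = pools,
       bott = bott, ups = ups, decs = decs, last = cur)
}

unet_backward <- function(dY, cache, params) {
  H <- nrow(dY); W <- ncol(dY)
  Clast <- nrow(params$final$W)
  last_mat <- matrix(cache$last, H * W, Clast)
  dmat <- matrix(dY, H * W, 1L)
  gfinal <- list(W = crossprod(last_mat, dmat), b = sum(dmat))
  dcur <- array(dmat %*% t(params$final$W), c(H, W, Clast))
  gdec <- vector("list", params$depth)
  gup <- vector("list", params$depth)
  dskip_store <- vector("list", params$depth)
  # decoder runs shallow-to-deep in backward order (forward built deep-to-shallow)
  for (l in seq_len(params$depth)) {
    db <- conv_block_backward(dcur, cache$decs[[l]], params$dec[[l]])
    gdec[[l]] <- db$grads
    ch <- dim(cache$ups[[l]]$Y)[3]         # channels of the upsampled half
    dup <- db$dX[, , seq_len(ch), drop = FALSE]
    dskip_store[[l]] <- db$dX[, , ch + seq_len(dim(db$dX)[3] - ch), drop = FALSE]
    hu <- dim(cache$ups[[l]]$Y)[1] %/% 2L
    wu <- dim(cache$ups[[l]]$Y)[2] %/% 2L
    cin_up <- dim(params$up[[l]]$W)[1]
    ub <- convT2_backward(dup, cache$ups[[l]], params$up[[l]], hu, wu, cin_up)
    gup[[l]] <- ub$grads
    dcur <- ub$dX                          # into the next-deeper decoder / bottleneck
  }
  gbott <- conv_block_backward(dcur, cache$bott, params$bott)
  dpool <- gbott$dX
  genc <- vector("list", params$depth)
  for (l in rev(seq_len(params$depth))) {
    Hs <- dim(cache$skips[[l]]$Y)[1]; Ws <- dim(cache$skips[[l]]$Y)[2]
    dskip_total <- maxpool2_backward(dpool, cache$pools[[l]], Hs, Ws) +
      dskip_store[[l]]
    eb <- conv_block_backward(dskip_total, cache$skips[[l]], params$enc[[l]])
    genc[[l]] <- eb$grads
    dpool <- eb$dX
  }
  list(enc = genc, bott = gbott$grads, up = gup, dec = gdec, final = gfinal)
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

as_matrix_or_array <- function(x) {
  if (inherits(x, "log_image")) x$values else x
}
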