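# Shared fixtures and independent brute-force oracles for the test suite.

tiny_spec <- function() {
  oct_system_spec("tiny", delta_z = 6, delta_x = 3.06, omega_z = 18,
                  omega_x = 8.28, n_spectral = 1600, n_fft = 2048)
}

table1_specs <- function() {
  lapply(c("chicken", "chicken_skin", "cucumber", "retina",
           "cardiovascular1", "cardiovascular2"), oct_system_preset)
}

# scalar-loop reference for the recurrent cell (independent of the batched
# matrix implementation under test)
naive_rnn_forward <- function(sequence, params) {
  Lt <- nrow(sequence)
  z <- numeric(params$nn)
  out <- matrix(0, Lt, params$P)
  for (t in seq_len(Lt)) {
    pre <- numeric(params$nn)
    for (h in seq_len(params$nn)) {
      acc <- params$b[h]
      for (k in seq_len(params$Nx)) acc <- acc + params$W_zy[k, h] * sequence[t, k]
      for (k in seq_len(params$nn)) acc <- acc + params$W_zz[k, h] * z[k]
      pre[h] <- max(0, acc)
    }
    z <- pre
    for (p in seq_len(params$P)) {
      acc <- params$head_b[p]
      for (h in seq_len(params$nn)) acc <- acc + params$head_W[h, p] * z[h]
      out[t, p] <- acc
    }
  }
  out
}

# direct double-loop patch extraction with replicate padding
naive_extract_patch <- function(values, i, j, cfg) {
  out <- matrix(0, cfg$Lt, cfg$Nx)
  for (t in seq_len(cfg$Lt)) {
    for (u in seq_len(cfg$Nx)) {
      r <- min(max(i - cfg$Lt + t, 1L), nrow(values))
      c <- min(max(j - cfg$nL + u - 1L, 1L), ncol(values))
      out[t, u] <- values[r, c]
    }
  }
  out
}

# per-pixel accumulation oracle for overlap averaging
naive_overlap_average <- function(preds, anchors, shape, cfg) {
  acc <- matrix(0, shape[1], shape[2])
  cnt <- matrix(0, shape[1], shape[2])
  for (k in seq_len(nrow(anchors))) {
    for (t in seq_len(cfg$Lt)) {
      for (u in seq_len(cfg$Nx)) {
        r <- anchors[k, 1] - cfg$Lt + t
        c <- anchors[k, 2] - cfg$nL + u - 1L
        if (r >= 1 && r <= shape[1] && c >= 1 && c <= shape[2]) {
          acc[r, c] <- acc[r, c] + preds[k, t, u]
          cnt[r, c] <- cnt[r, c] + 1
        }
      }
    }
  }
  list(values = acc / ifelse(cnt > 0, cnt, NA), coverage = cnt)
}

# direct per-pixel SSIM oracle (independent of the convolution-based path)
naive_ssim <- function(a, b, data_range, window_size = 11L, sigma = 1.5,
                       K1 = 0.01, K2 = 0.03) {
  lo <- min(a, b)
  a <- (a - lo) / data_range; b <- (b - lo) / data_range
  h <- window_size %/% 2L
  k <- seq(-h, h)
  g1 <- exp(-k^2 / (2 * sigma^2)); w <- outer(g1, g1); w <- w / sum(w)
  nr <- nrow(a); nc <- ncol(a)
  refl <- function(idx, n) { idx[idx < 1] <- 1 - idx[idx < 1]; idx[idx > n] <- 2 * n + 1 - idx[idx > n]; idx }
  s <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    ri <- refl(i + k, nr)
    for (j in seq_len(nc)) {
      cj <- refl(j + k, nc)
      wa <- a[ri, cj]; wb <- b[ri, cj]
      mua <- sum(w * wa); mub <- sum(w * wb)
      va <- sum(w * wa^2) - mua^2; vb <- sum(w * wb^2) - mub^2
      vab <- sum(w * wa * wb) - mua * mub
      C1 <- K1^2; C2 <- K2^2
      s[i, j] <- ((2 * mua * mub + C1) * (2 * vab + C2)) /
        ((mua^2 + mub^2 + C1) * (va + vb + C2))
    }
  }
  mean(s)
}

# compact training pair shared by the lightweight training tests
small_training_pair <- function(seed = 0) {
  make_pair(tiny_spec(), 64, 96, seed = seed)
}
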