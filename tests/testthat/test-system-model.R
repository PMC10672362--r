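test_that("sampling-resolution ratio reproduces the published system table", {
  # (omega_x, delta_x) -> px for all six shipped systems
  expected_px <- c(chicken = 3L, chicken_skin = 2L, cucumber = 1L,
                   retina = 2L, cardiovascular1 = 2L, cardiovascular2 = 1L)
  for (nm in names(expected_px)) {
    sp <- oct_system_preset(nm)
    r <- system_resolution_ratios(sp)
    expect_identical(r$px, expected_px[[nm]])
    expect_identical(r$pz, 3L)
  }
  expect_identical(sampling_resolution_ratio(8.28, 3.06), 3L)
  expect_identical(sampling_resolution_ratio(18, 9), 2L)
  expect_identical(sampling_resolution_ratio(8.28, 8), 1L)
  expect_identical(sampling_resolution_ratio(5, 5), 1L)
  # floor at one pixel, errors on nonpositive input
  expect_identical(sampling_resolution_ratio(1, 10), 1L)
  expect_error(sampling_resolution_ratio(-1, 2), "positive")
  expect_error(sampling_resolution_ratio(2, 0), "positive")
})

test_that("spec construction validates geometry and round-trips YAML", {
  expect_error(oct_system_spec("x", -1, 1, 1, 1, 10, 20), "positive")
  expect_error(oct_system_spec("x", 1, 1, 1, 1, 30, 20), "exceed")
  expect_error(oct_system_spec("x", 5, 1, 1, 1, 10, 20,
                               axial_range = 100, n_axial_pixels = 10),
               "inconsistent")
  ok <- oct_system_spec("x", 10, 1, 30, 2, 10, 20,
                        axial_range = 100, n_axial_pixels = 10)
  expect_s3_class(ok, "oct_system_spec")
  f <- tempfile(fileext = ".yaml")
  write_system_spec(tiny_spec(), f)
  back <- read_system_spec(f)
  expect_equal(back$delta_x, 3.06)
  expect_equal(back$n_fft, 2048L)
})

test_that("lateral PSF matches the Gaussian beam profile", {
  sp <- tiny_spec()
  p <- lateral_psf(sp)
  ctr <- p$half_support + 1L
  expect_equal(p$samples[ctr], 1)
  expect_equal(p$samples[ctr + 1L], exp(-2 * 3.06^2 / 8.28^2), tolerance = 1e-12)
  expect_equal(p$samples, rev(p$samples))
  # value at physical offset omega_x / sqrt(2) equals exp(-1)
  sp2 <- oct_system_spec("t", 1, 8.28 / sqrt(2), 3, 8.28, 64, 128)
  p2 <- lateral_psf(sp2, half_support = 2)
  expect_equal(p2$samples[p2$half_support + 2L], exp(-1), tolerance = 1e-12)
})

test_that("axial PSF is the zero-padded Hanning spectrum with bounded support", {
  sp <- tiny_spec()
  p <- axial_psf(sp)
  expect_equal(p$samples, rev(p$samples))          # symmetric
  expect_equal(max(p$samples), 1)
  expect_true(length(p$samples) >= 5 && length(p$samples) <= 11)
  expect_error(axial_psf(oct_system_spec("b", 1, 1, 1, 1, 64, 64)), NA)

  # FWHM against a dense 16x-oversampled spectrum oracle
  fwhm_from <- function(x, pitch) {
    x <- c(x, 0)                 # truncated supports end below threshold
    ctr <- which.max(x)
    right <- which(x[ctr:length(x)] < 0.5)[1]
    i2 <- ctr + right - 1L
    frac <- (x[i2 - 1L] - 0.5) / (x[i2 - 1L] - x[i2])
    2 * ((i2 - 1L - ctr) + frac) * pitch
  }
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(1600) - 1) / 1599)
  dense <- Mod(stats::fft(c(w, rep(0, 16 * 2048 - 1600))))
  dense <- dense / max(dense)
  half <- (16 * 2048) %/% 2
  dense_c <- dense[c((16 * 2048 - half + 1):(16 * 2048), 1:(half + 1))]
  oracle_fwhm <- fwhm_from(dense_c, 1 / 16)        # in acquisition pixels
  got_fwhm <- fwhm_from(p$samples, 1)
  expect_equal(got_fwhm, oracle_fwhm, tolerance = 0.05)

  # more zero padding (smaller NH at fixed NFFT) widens the main lobe
  f_full <- fwhm_from(axial_psf(oct_system_spec("a", 1, 1, 3, 3, 2048, 2048))$samples, 1)
  f_padded <- fwhm_from(axial_psf(oct_system_spec("a", 1, 1, 3, 3, 1600, 2048))$samples, 1)
  f_more <- fwhm_from(axial_psf(oct_system_spec("a", 1, 1, 3, 3, 1024, 2048))$samples, 1)
  expect_lt(f_full, f_padded)
  expect_lt(f_padded, f_more)
})

test_that("separable PSF is the rank-1 outer product", {
  ax <- psf_1d(c(0, 1, 0), "axial", 1)
  la <- psf_1d(exp(-(-3:3)^2 / 4), "lateral", 1)
  k <- separable_psf(ax, la)
  expect_equal(k$kernel[2, ], la$samples)          # delta axial replicates rows
  expect_equal(k$kernel[1, ], rep(0, 7))
  both <- separable_psf(psf_1d(c(0, 1, 0), "axial", 1),
                        psf_1d(c(0, 1, 0), "lateral", 1))
  expect_equal(sum(both$kernel != 0), 1L)          # single-pixel kernel
  k7 <- separable_psf(axial_psf(tiny_spec()), lateral_psf(tiny_spec(), 3))
  sv <- svd(k7$kernel)$d
  expect_lt(sv[2] / sv[1], 1e-12)                  # numerically rank 1
})

test_that("resampling plans reproduce the published adaptation factors", {
  chicken <- oct_system_preset("chicken")
  retina <- oct_system_preset("retina")
  cucumber <- oct_system_preset("cucumber")
  skin <- oct_system_preset("chicken_skin")

  p <- plan_resampling(chicken, skin, applied_to = "source")$lateral
  expect_identical(c(p$factor_num, p$factor_den), c(4L, 3L))   # px 3 -> 2
  expect_identical(p$direction, "decimate")

  p <- plan_resampling(chicken, cucumber, applied_to = "source")$lateral
  expect_identical(c(p$factor_num, p$factor_den), c(8L, 3L))   # px 3 -> 1
  expect_identical(p$direction, "decimate")

  p <- plan_resampling(retina, cucumber, applied_to = "source")$lateral
  expect_identical(c(p$factor_num, p$factor_den), c(2L, 1L))   # px 2 -> 1
  expect_identical(p$direction, "decimate")

  ident <- plan_resampling(chicken, chicken)
  expect_identical(ident$axial$direction, "identity")
  expect_identical(ident$lateral$direction, "identity")
})

test_that("applying a plan lands on the counterpart ratio for every system pair", {
  specs <- table1_specs()
  for (a in specs) for (b in specs) {
    if (identical(a$name, b$name)) next
    plans <- plan_resampling(a, b, applied_to = "source")
    img <- log_image(matrix(rnorm(40 * 60), 40, 60),
                     pitch_z = a$delta_z, pitch_x = a$delta_x)
    out <- apply_resampling(img, plans)
    expect_identical(
      sampling_resolution_ratio(a$omega_x, out$pitch_x),
      sampling_resolution_ratio(b$omega_x, b$delta_x),
      info = paste(a$name, "->", b$name))
    expect_identical(
      sampling_resolution_ratio(a$omega_z, out$pitch_z),
      sampling_resolution_ratio(b$omega_z, b$delta_z),
      info = paste(a$name, "->", b$name))
    # adapting onward to the original system restores the original ratio
    a_mod <- oct_system_spec(a$name, out$pitch_z, out$pitch_x, a$omega_z,
                             a$omega_x, a$n_spectral, a$n_fft)
    back <- apply_resampling(out, plan_resampling(a_mod, a, applied_to = "source"))
    expect_identical(sampling_resolution_ratio(a$omega_x, back$pitch_x),
                     sampling_resolution_ratio(a$omega_x, a$delta_x))
  }
})

test_that("rational resampling honours the length convention and is invertible", {
  img <- log_image(matrix(rnorm(30 * 300), 30, 300), pitch_x = 3.06)
  plan <- resampling_plan("lateral", 8, 3)
  out <- apply_resampling(img, plan)
  expect_identical(ncol(out$values), 113L)         # round(300 * 3 / 8)
  expect_equal(out$pitch_x, 3.06 * 8 / 3)

  # identity plan is bit-exact
  idp <- resampling_plan("lateral", 1, 1)
  expect_identical(apply_resampling(img, idp)$values, img$values)

  # Nyquist round trip on a band-limited signal
  x <- outer(rep(1, 20), sin(seq(0, 6 * pi, length.out = 200)))
  im2 <- log_image(x, dynamic_range = c(-2, 2))
  down <- apply_resampling(im2, resampling_plan("lateral", 2, 1))
  up <- apply_resampling(down, resampling_plan("lateral", 1, 2))
  expect_equal(up$values[, 20:180], x[, 20:180], tolerance = 0.02)

  # axial resampling acts on rows
  img3 <- log_image(matrix(rnorm(100 * 20), 100, 20), pitch_z = 2)
  out3 <- apply_resampling(img3, resampling_plan("axial", 2, 1))
  expect_identical(nrow(out3$values), 50L)
  expect_equal(out3$pitch_z, 4)

  expect_warning(
    apply_resampling(log_image(matrix(rnorm(30 * 40), 30, 40)),
                     resampling_plan("lateral", 8, 3), patch_dim = 15),
    "below twice")
})

test_that("output regime prediction follows the source/target ratio ordering", {
  expect_identical(
    predict_output_regime(list(px = 2, pz = 3), list(px = 3, pz = 3))$lateral,
    "detail_enhanced_risk")
  expect_identical(
    predict_output_regime(list(px = 2, pz = 3), list(px = 1, pz = 3))$lateral,
    "blurred")
  r <- predict_output_regime(oct_system_preset("chicken"),
                             oct_system_preset("chicken"))
  expect_identical(r$lateral, "matched")
  expect_identical(r$axial, "matched")
  expect_error(predict_output_regime(list(px = 0, pz = 1), list(px = 1, pz = 1)),
               ">= 1")
})
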