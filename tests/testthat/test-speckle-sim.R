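test_that("phantom generation is deterministic and style-faithful", {
  a <- generate_phantom(64, 64, seed = 5)
  b <- generate_phantom(64, 64, seed = 5)
  expect_identical(a$amplitude, b$amplitude)
  d <- generate_phantom(64, 64, seed = 6)
  expect_false(identical(a$amplitude, d$amplitude))

  cst <- generate_phantom(40, 40, seed = 1, style = "constant", level = 0.7)
  expect_true(all(cst$amplitude == 0.7))

  expect_error(generate_phantom(10, 64), "32")
  expect_error(generate_phantom(64, 64, style = "nope"))

  # layered phantoms show >= 3 strata in the row-mean profile
  lay <- generate_phantom(128, 128, seed = 2, style = "layered",
                          n_layers = 4, texture_sd = 0)
  prof <- rowMeans(lay$amplitude)
  sm <- stats::filter(prof, rep(1 / 5, 5), sides = 2)
  jumps <- abs(diff(sm[!is.na(sm)]))
  # change-point scan: count well-separated boundary crossings
  cand <- which(jumps > 0.03)
  n_bound <- if (length(cand)) 1L + sum(diff(cand) > 5) else 0L
  expect_gte(n_bound + 1L, 3L)
})

test_that("fully developed speckle has exponential single-pixel statistics", {
  sp <- tiny_spec()
  psf <- system_psf(sp)
  ph <- generate_phantom(256, 256, seed = 3, style = "constant")
  Y <- simulate_speckled_tomogram(ph, psf, seed = 11)
  I <- linear_intensity(Y)[30:226, 30:226]
  # contrast (std over mean) of exponential intensities is 1
  expect_equal(sd(I) / mean(I), 1, tolerance = 0.05)
  set.seed(11)
  samp <- sample(I, 1e4)
  D <- suppressWarnings(
    stats::ks.test(samp, "pexp", rate = 1 / mean(samp)))$statistic
  expect_lt(D, 1.628 / sqrt(1e4))                 # 1% critical value
  # exceedance probability P(y > x) = exp(-1)
  p_exc <- mean(samp > mean(samp))
  expect_equal(p_exc, exp(-1), tolerance = 3 * sqrt(exp(-1) * (1 - exp(-1)) / 1e4) / exp(-1))
})

test_that("exponential speckle holds for every shipped system PSF", {
  ph <- generate_phantom(192, 192, seed = 3, style = "constant")
  for (sp in table1_specs()) {
    Y <- simulate_speckled_tomogram(ph, system_psf(sp), seed = 13)
    I <- linear_intensity(Y)[25:168, 25:168]
    set.seed(13)
    samp <- sample(I, 8e3)
    D <- suppressWarnings(
      stats::ks.test(samp, "pexp", rate = 1 / mean(samp)))$statistic
    expect_lt(D, 1.628 / sqrt(8e3))
    expect_equal(sd(I) / mean(I), 1, tolerance = 0.06)
  }
})

test_that("simulator is seed-reproducible and grounded in the imaging model", {
  sp <- tiny_spec()
  psf <- system_psf(sp)
  ph <- generate_phantom(64, 64, seed = 9, pitch_z = sp$delta_z,
                         pitch_x = sp$delta_x)
  y1 <- simulate_speckled_tomogram(ph, psf, seed = 4)
  y2 <- simulate_speckled_tomogram(ph, psf, seed = 4)
  expect_identical(y1$values, y2$values)
  y3 <- simulate_speckled_tomogram(ph, psf, seed = 5)
  expect_false(identical(y1$values, y3$values))
  expect_equal(y1$pitch_x, 3.06)

  # delta phantom through a plain acquisition-grid kernel reproduces |alpha|^2
  amp <- matrix(0, 64, 64); amp[32, 32] <- 1
  dph <- generate_phantom(64, 64, seed = 1, style = "constant", level = 0)
  dph$amplitude <- amp
  kern <- separable_psf(axial_psf(sp), lateral_psf(sp, 3))
  ygt <- ground_truth_tomogram(dph, kern, display_range_db = 120)
  Ilin <- 10^(ygt$values / 10)
  hsz <- (nrow(kern$kernel) - 1L) / 2; hsx <- (ncol(kern$kernel) - 1L) / 2
  got <- Ilin[(32 - hsz):(32 + hsz), (32 - hsx):(32 + hsx)]
  expect_equal(got, kern$kernel^2, tolerance = 1e-6)
  expect_equal(which(Ilin == max(Ilin)), which(amp == 1))   # peak at the pixel
  # speckled realization also peaks around the reflector
  ys <- simulate_speckled_tomogram(dph, kern, seed = 2)
  pk <- which(ys$values == max(ys$values), arr.ind = TRUE)
  expect_lt(max(abs(pk - 32)), max(hsz, hsx) + 1)

  expect_warning(simulate_speckled_tomogram(
    generate_phantom(64, 64, seed = 1, style = "constant", level = 0), kern,
    seed = 1), "all-zero")
})

test_that("incoherent compounding converges to the ground-truth tomogram", {
  sp <- tiny_spec()
  psf <- system_psf(sp)
  ph <- generate_phantom(64, 64, seed = 21, style = "constant")

  one <- simulate_speckled_tomogram(ph, psf, seed = 1)
  same <- angular_compound(list(one))
  expect_equal(same$values, one$values, tolerance = 1e-9)
  expect_error(angular_compound(list()), "at least one")
  expect_error(angular_compound(list(one, log_image(matrix(0, 3, 3)))), "shape")

  # compound variance scales as 1/M
  ph96 <- generate_phantom(96, 96, seed = 22, style = "constant")
  seed_base <- 0L
  vs <- sapply(c(1, 4, 16), function(M) {
    comp <- angular_compound(lapply(seq_len(M), function(k) {
      seed_base <<- seed_base + 1L
      simulate_speckled_tomogram(ph96, psf, seed = 100 + seed_base)
    }))
    var(as.vector(linear_intensity(comp)[17:80, 17:80]))
  })
  expect_equal(vs[1] / vs[2], 4, tolerance = 0.5)
  expect_equal(vs[2] / vs[3], 4, tolerance = 0.5)

  # Monte-Carlo mean approaches the incoherent ground truth (3-sigma coverage)
  M <- 120
  mc <- Reduce(`+`, lapply(seq_len(M), function(k)
    linear_intensity(simulate_speckled_tomogram(ph, psf, seed = 500 + k)))) / M
  gt <- linear_intensity(ground_truth_tomogram(ph, psf))
  rel <- abs(mc - gt)[13:52, 13:52] / gt[13:52, 13:52]
  expect_gte(mean(rel <= 3 / sqrt(M)), 0.99)
  expect_lt(mean(rel), 1.5 / sqrt(M))
})

test_that("energy bookkeeping: speckled and clean images share mean intensity", {
  sp <- tiny_spec()
  psf <- system_psf(sp)
  ph <- generate_phantom(128, 128, seed = 8, style = "layered")
  Y <- linear_intensity(simulate_speckled_tomogram(ph, psf, seed = 3))
  X <- linear_intensity(ground_truth_tomogram(ph, psf))
  expect_equal(mean(Y[17:112, 17:112]), mean(X[17:112, 17:112]),
               tolerance = 0.05)
})

test_that("speckle intensity sampler has exponential moments and tail", {
  x <- 2.5
  s <- sample_speckle_intensity(x, 1e5, seed = 3)
  expect_equal(mean(s), x, tolerance = 3 / sqrt(1e5) * 1.2)
  expect_equal(var(s), x^2, tolerance = x^2 * 0.05)
  p <- mean(s > x)
  expect_equal(p, exp(-1), tolerance = 3 * sqrt(exp(-1) * (1 - exp(-1)) / 1e5) / exp(-1))
  expect_error(sample_speckle_intensity(0, 10), "positive")
  s2 <- sample_speckle_intensity(x, 100, seed = 3)
  expect_identical(s2, sample_speckle_intensity(x, 100, seed = 3))
})

test_that("make_pair yields a registered speckled/clean fixture", {
  sp <- tiny_spec()
  pr <- make_pair(sp, 64, 96, seed = 7)
  expect_identical(dim(pr$noisy$values), c(64L, 96L))
  expect_identical(dim(pr$clean$values), c(64L, 96L))
  expect_equal(pr$noisy$pitch_x, sp$delta_x)
  expect_equal(pr$clean$pitch_z, sp$delta_z)
  p <- psnr(pr$clean, pr$noisy)
  expect_true(is.finite(p) && p < 30)             # speckle dominates
  pr2 <- make_pair(sp, 64, 96, seed = 8)
  expect_false(identical(pr$noisy$values, pr2$noisy$values))
  expect_identical(pr$clean$values,
                   make_pair(sp, 64, 96, seed = 7)$clean$values)
})
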