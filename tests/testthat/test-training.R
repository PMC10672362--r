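# Lightweight training checks (small fixtures, small hidden widths).

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 1, batch_size = 64L, epochs_content = 3L, epochs_adv = 2L),
    list(...))
  do.call(train_config, args)
}

test_that("content training reduces the loss deterministically", {
  pr <- small_training_pair()
  cfg <- small_cfg()
  m1 <- few_shot_fit(pr$noisy, pr$clean, "rnn", region = list(cols = 1:30),
                     cfg = cfg, nn = 50)
  tr <- m1$trace$content
  expect_lt(tr[length(tr)], tr[1])
  m2 <- few_shot_fit(pr$noisy, pr$clean, "rnn", region = list(cols = 1:30),
                     cfg = cfg, nn = 50)
  expect_identical(m1$trace$content, m2$trace$content)   # seed determinism
  expect_identical(m1$params, m2$params)
})

test_that("the recurrent model can memorize a tiny training pair", {
  # capacity check: a 16x16 region, long schedule, near-zero training MSE
  pr <- small_training_pair()
  cfg <- train_config(seed = 2, batch_size = 4, epochs_content = 200,
                      early_stop_tol = 0)
  m <- few_shot_fit(pr$noisy, pr$clean, "rnn",
                    region = list(rows = 1:16, cols = 1:16),
                    cfg = cfg, nn = 150)
  expect_lt(tail(m$trace$content, 1), 1e-3)
})

test_that("deblurring variant stores its filter; plain variant does not", {
  pr <- small_training_pair()
  cfg <- small_cfg(epochs_content = 1)
  md <- few_shot_fit(pr$noisy, pr$clean, "drnn", region = list(cols = 1:20),
                     cfg = cfg, nn = 20)
  expect_false(is.null(md$deblur_filter))
  expect_identical(md$deblur_filter$size, 7L)
  mr <- few_shot_fit(pr$noisy, pr$clean, "rnn", region = list(cols = 1:20),
                     cfg = cfg, nn = 20)
  expect_null(mr$deblur_filter)
})

test_that("zero adversarial weight reproduces a pure content step", {
  pr <- small_training_pair()
  cfg <- train_config(seed = 3, batch_size = 10000, epochs_content = 1,
                      epochs_adv = 1, lambda_adv = 0, early_stop_tol = 0)
  pc <- analysis_patch_config(Lt = 5, Nx = 5, P = 5)
  ds <- build_dataset(pr$noisy, pr$clean, pc, list(rows = 1:12, cols = 1:12))
  base <- octshot:::new_despeckler_model("rnn_gan", rnn_params(5, 30, 5, seed = 3),
                                         pc, ds$normalization)
  content <- train_content(base, ds, cfg)
  adv <- train_adversarial(base, ds, cfg)
  expect_equal(adv$params, content$params, tolerance = 1e-12)
})

test_that("adversarial refinement keeps fidelity and a live discriminator", {
  pr <- small_training_pair()
  cfg <- train_config(seed = 4, batch_size = 128, epochs_content = 3,
                      epochs_adv = 3)
  m <- few_shot_fit(pr$noisy, pr$clean, "rnn_gan", region = list(cols = 1:30),
                    cfg = cfg, nn = 50)
  expect_false(is.null(m$discriminator))
  # discriminator has learned something but is not saturated
  d_loss <- tail(m$trace$discriminator, 1)
  expect_gt(d_loss, 1e-3)
  ds <- build_dataset(pr$noisy, pr$clean, m$patch_cfg, list(cols = 31:40))
  D_dim <- m$patch_cfg$Lt * m$patch_cfg$Nx
  targ <- octshot:::target_array(ds)
  fake <- octshot:::rnn_forward_batch(ds$inputs, m$params)$outputs
  dreal <- mean(discriminator_forward(matrix(targ, ds$m, D_dim), m$discriminator))
  dfake <- mean(discriminator_forward(matrix(fake, ds$m, D_dim), m$discriminator))
  expect_gt(dreal, dfake)                           # better than chance

  # fidelity regression: PSNR on the training image within 1 dB of content stage
  mc <- few_shot_fit(pr$noisy, pr$clean, "rnn_gan",
                     region = list(cols = 1:30),
                     cfg = train_config(seed = 4, batch_size = 128,
                                        epochs_content = 3, epochs_adv = 1,
                                        lambda_adv = 0),
                     nn = 50)
  p_adv <- psnr(pr$clean, despeckle_image(pr$noisy, m, stride = 2))
  p_content <- psnr(pr$clean, despeckle_image(pr$noisy, mc, stride = 2))
  expect_gt(p_adv, p_content - 1)
})

test_that("full-image inference honours shape and identity contracts", {
  pr <- small_training_pair()
  # hand-built identity model: one hidden unit relays the anchor pixel
  pc <- analysis_patch_config(Lt = 1, Nx = 1, P = 1)
  p <- rnn_params(1, nn = 1, P = 1, seed = 0)
  p$W_zy[] <- 1; p$W_zz[] <- 0; p$b[] <- 0; p$head_W[] <- 1; p$head_b[] <- 0
  idm <- octshot:::new_despeckler_model("rnn", p, pc,
                                        c(lo = 0, hi = 1))
  # image whose darkest value fills >1% of pixels, so the robust affine
  # maps every pixel into [0, 1] and the ReLU relay is exact
  v <- matrix(seq(0, 20, length.out = 48 * 48), 48, 48)
  v[1:6, ] <- 0
  img <- log_image(v, dynamic_range = c(0, 20))
  out <- despeckle_image(img, idm)
  expect_equal(out$values, img$values, tolerance = 1e-10)

  cfgS <- small_cfg(epochs_content = 1)
  for (method in c("rnn", "drnn")) {
    m <- few_shot_fit(pr$noisy, pr$clean, method, region = list(cols = 1:15),
                      cfg = cfgS, nn = 10)
    o <- despeckle_image(pr$noisy, m)
    expect_identical(dim(o$values), dim(pr$noisy$values))
  }
  mg <- few_shot_fit(pr$noisy, pr$clean, "rnn_gan", region = list(cols = 1:15),
                     cfg = cfgS, nn = 10)
  og <- despeckle_image(pr$noisy, mg, stride = 3)
  expect_identical(dim(og$values), dim(pr$noisy$values))
  mu <- few_shot_fit(pr$noisy, pr$clean, "unet",
                     cfg = small_cfg(epochs_content = 1, lr = 1e-3),
                     unet_depth = 2, unet_base = 2, crop_size = 16,
                     n_crops = 8)
  ou <- despeckle_image(pr$noisy, mu)                # 64x96 padded to /4
  expect_identical(dim(ou$values), dim(pr$noisy$values))
  expect_error(despeckle_image(log_image(matrix(0, 4, 4)), mg), "smaller")
})

test_that("U-Net crop datasets are seeded and sized as configured", {
  pr <- make_pair(tiny_spec(), 256, 256, seed = 1)
  d1 <- make_crop_dataset(pr$noisy, pr$clean, crop_size = 64, depth = 4, seed = 5)
  expect_identical(dim(d1$crops_x), c(1000L, 64L, 64L))  # >= 1000 crops by default
  d2 <- make_crop_dataset(pr$noisy, pr$clean, crop_size = 64, depth = 4, seed = 5)
  expect_identical(d1$anchors, d2$anchors)
  expect_error(make_crop_dataset(pr$noisy, pr$clean, crop_size = 60, depth = 4),
               "divisible")
})

test_that("models survive a save/load round trip with manifest", {
  pr <- small_training_pair()
  m <- few_shot_fit(pr$noisy, pr$clean, "rnn", region = list(cols = 1:15),
                    cfg = small_cfg(epochs_content = 1), nn = 10,
                    source_spec = tiny_spec())
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  expect_true(file.exists(paste0(f, ".json")))
  manifest <- jsonlite::read_json(paste0(f, ".json"))
  expect_identical(manifest$method, "rnn")
  expect_identical(manifest$source_system, "tiny")
  back <- load_model(f)
  expect_identical(back$params, m$params)
  o1 <- despeckle_image(pr$noisy, m)
  o2 <- despeckle_image(pr$noisy, back)
  expect_identical(o1$values, o2$values)
})

test_that("divergent training aborts with a diagnostic", {
  pr <- small_training_pair()
  pc <- analysis_patch_config(Lt = 3, Nx = 3, P = 1)
  ds <- build_dataset(pr$noisy, pr$clean, pc, list(rows = 1:8, cols = 1:8))
  bad <- octshot:::new_despeckler_model("rnn", rnn_params(3, 10, 1, seed = 1),
                                        pc, ds$normalization)
  bad$params$W_zz[] <- 1e154                         # overflow on step one
  expect_error(train_content(bad, ds, small_cfg()), "diverged")
})
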