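test_that("warm-up + cosine schedule ramps 0 -> base_lr then decays to ~0", {
  cfg <- train_config("vit", max_epochs = 30, warmup_epochs = 2)
  total <- 300 # 10 steps per epoch
  warm <- 2 / 30 * total
  expect_identical(lr_at(0, total, cfg), 0)
  expect_equal(lr_at(warm, total, cfg), 1e-3)
  expect_lte(lr_at(total, total, cfg), 1e-9)
  # continuity at the boundary
  expect_equal(lr_at(warm - 1e-6 * total, total, cfg), lr_at(warm, total, cfg),
               tolerance = 1e-3)
  # non-increasing after warm-up
  lrs <- lr_at(seq(warm, total, length.out = 200), total, cfg)
  expect_true(all(diff(lrs) <= 1e-12))
  expect_error(lr_at(-1, total, cfg), "out of range")
  expect_error(lr_at(total + 1, total, cfg), "out of range")
})

test_that("the CNN default schedule is constant at 1e-3", {
  cfg <- train_config("cnn")
  expect_identical(cfg$max_epochs, 10L)
  expect_equal(lr_at(c(0, 50, 100), 100, cfg), rep(1e-3, 3))
})

test_that("training configs validate their rates", {
  expect_error(train_config("cnn", base_lr = 0), "positive")
  expect_error(train_config("vit", warmup_epochs = 30, max_epochs = 30),
               "warmup")
})

test_that("the CNN fits a linearly separable image set to >= 99% within 10 epochs", {
  toy <- toy_image_set(24, seed = 5)
  cfg <- train_config("cnn", batch_size = 16L, seed = 5)
  m <- build_cnn(seed = 5)
  m <- train_model(m, toy$x, toy$y, toy$x, toy$y, cfg)
  final <- m$history$train_acc[nrow(m$history)]
  expect_gte(final, 0.99)
})

test_that("training is deterministic given the seed", {
  toy <- toy_image_set(8, seed = 2)
  cfg <- train_config("cnn", batch_size = 8L, max_epochs = 2L, seed = 9)
  h1 <- train_model(build_cnn(seed = 9), toy$x, toy$y, toy$x, toy$y, cfg)$history
  h2 <- train_model(build_cnn(seed = 9), toy$x, toy$y, toy$x, toy$y, cfg)$history
  expect_identical(h1, h2)
})

test_that("early stopping fires after patience epochs without improvement", {
  # constant images + balanced constant labels give a flat validation loss
  x <- array(0, c(125, 50, 3, 8))
  y <- rep(1:2, 4)
  cfg <- train_config("vit", max_epochs = 30L, warmup_epochs = 2L,
                      batch_size = 8L, early_stopping_patience = 5L, seed = 1)
  m <- build_vit(seed = 1)
  m <- train_model(m, x, y, x, y, cfg)
  expect_lte(nrow(m$history), 2L + 5L + 1L)
  expect_gte(nrow(m$history), 5L)
})

test_that("checkpointed weights score no worse than final-epoch weights on validation", {
  toy <- toy_image_set(10, seed = 3)
  val <- toy_image_set(6, seed = 4)
  cfg <- train_config("cnn", batch_size = 8L, max_epochs = 6L, seed = 3)
  m <- build_cnn(seed = 3)
  m <- train_model(m, toy$x, toy$y, val$x, val$y, cfg)
  best <- attr(m$history, "best_epoch")
  restored <- whaledet:::evaluate_loss(m, val$x, val$y)
  expect_lte(restored$loss, m$history$val_loss[nrow(m$history)] + 1e-8)
  expect_equal(m$history$val_loss[best], min(m$history$val_loss))
  expect_equal(restored$loss, m$history$val_loss[best], tolerance = 1e-8)
})

test_that("loss decreases over the first epochs on the separable set (3-seed median)", {
  drops <- vapply(1:3, function(sd) {
    toy <- toy_image_set(12, seed = sd)
    cfg <- train_config("cnn", batch_size = 12L, max_epochs = 3L, seed = sd)
    m <- train_model(build_cnn(seed = sd), toy$x, toy$y, toy$x, toy$y, cfg)
    m$history$train_loss[1] - m$history$train_loss[3]
  }, 0)
  expect_gt(median(drops), 0)
})

test_that("empty datasets and label mismatches are rejected", {
  x <- array(0, c(125, 50, 3, 4))
  expect_error(train_model(build_cnn(seed = 1), x, 1:2, x, 1:4), "mismatch")
  expect_error(train_model(build_cnn(seed = 1), x[, , , 0, drop = FALSE],
                           integer(0), x, 1:4), "empty")
})

test_that("predict warns on images that skipped per-image standardization", {
  m <- build_cnn(seed = 1)
  img <- render_rgb(mel_spectrogram(tone_segment(500))) # standardized = FALSE
  expect_warning(predict(m, img), "standardize")
})
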