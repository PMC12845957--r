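test_that("patch extraction of a 125x50x3 image yields 90 vectors of length 192", {
  img <- array(runif(125 * 50 * 3), c(125, 50, 3))
  p <- extract_patches(img)
  expect_identical(dim(p), c(90L, 192L))
})

test_that("an 8x8x3 image is a single patch equal to its own flattening", {
  img <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  p <- extract_patches(img)
  expect_identical(dim(p), c(1L, 192L))
  expect_identical(p[1, ], as.numeric(img))
})

test_that("a 16x10x3 image gives a 2x1 patch grid matching brute-force slices", {
  img <- array(rnorm(16 * 10 * 3), c(16, 10, 3))
  p <- extract_patches(img)
  expect_identical(nrow(p), 2L)
  expect_identical(p[1, ], as.numeric(img[1:8, 1:8, ]))
  expect_identical(p[2, ], as.numeric(img[9:16, 1:8, ]))
})

test_that("patch tiles are disjoint and cover exactly the 120x48 sub-grid", {
  # mark each pixel with a unique value; collected patch values must be unique
  # and exactly the values of the covered sub-grid
  img <- array(seq_len(125 * 50 * 3), c(125, 50, 3))
  p <- extract_patches(img)
  vals <- sort(as.vector(p))
  covered <- sort(as.vector(img[1:120, 1:48, ]))
  expect_identical(vals, as.numeric(covered))
})

test_that("the first convolution of the built CNN has 16*(6*6*3+1) = 1744 parameters", {
  m <- build_cnn(seed = 1)
  conv1 <- whaledet:::leaf_layers(m$layers)[[1]]
  expect_identical(sum(vapply(conv1$params, length, 0L)), 1744L)
  expect_identical(dim(conv1$params$W), c(6L, 6L, 3L, 16L))
})

test_that("model summaries list the configured blocks in order", {
  s <- model_summary(build_cnn(seed = 1))
  expect_match(s[2], "Conv2D 6x6, 3->16, tanh")
  expect_match(s[6], "Conv2D 4x4, 16->32, relu")
  expect_match(s[10], "Conv2D 3x3, 32->64, relu")
  dropout_lines <- grep("Dropout", s, value = TRUE)
  expect_identical(dropout_lines,
                   c("Dropout 0.50                                                 params: 0",
                     "Dropout 0.40                                                 params: 0",
                     "Dropout 0.30                                                 params: 0",
                     "Dropout 0.20                                                 params: 0"))
})

test_that("CNN forward pass emits two probabilities per image summing to 1", {
  m <- build_cnn(seed = 3)
  imgs <- array(rnorm(125 * 50 * 3 * 4), c(125, 50, 3, 4))
  p <- predict(m, imgs)
  expect_identical(dim(p), c(4L, 2L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
})

test_that("two builds from the same config and seed have identical initial weights", {
  for (builder in list(build_cnn, build_vit)) {
    a <- whaledet:::leaf_layers(builder(seed = 11)$layers)
    b <- whaledet:::leaf_layers(builder(seed = 11)$layers)
    for (i in seq_along(a)) expect_identical(a[[i]]$params, b[[i]]$params)
  }
})

test_that("the ViT config fixes 90 tokens of dimension 192 before embedding", {
  cfg <- vit_config()
  expect_identical(cfg$n_patches, 90L)
  expect_identical((125L %/% 8L) * (50L %/% 8L), 90L)
  m <- build_vit(cfg, seed = 2)
  pe <- m$layers[[1]]
  expect_identical(pe$n_tokens, 90L)
  expect_identical(nrow(pe$params$We), 192L)
})

test_that("ViT forward pass emits valid probabilities", {
  m <- build_vit(seed = 5)
  imgs <- array(rnorm(125 * 50 * 3 * 3), c(125, 50, 3, 3))
  p <- predict(m, imgs)
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
})

test_that("with zeroed positional embeddings, patch permutation leaves pooled logits unchanged", {
  m <- build_vit(seed = 8)
  m$layers[[1]]$params$pos[] <- 0
  img <- array(rnorm(125 * 50 * 3), c(125, 50, 3))
  x1 <- array(img, c(125, 50, 3, 1))
  logits1 <- whaledet:::forward_model(m, x1, training = FALSE)
  # permute patch rows of the image: swap the top 8-row band with the second
  perm <- img
  perm[1:8, , ] <- img[9:16, , ]
  perm[9:16, , ] <- img[1:8, , ]
  logits2 <- whaledet:::forward_model(m, array(perm, c(125, 50, 3, 1)),
                                      training = FALSE)
  expect_equal(logits1, logits2, tolerance = 1e-5)
})

test_that("batch predictions match single-image predictions", {
  m <- build_cnn(seed = 4)
  imgs <- array(rnorm(125 * 50 * 3 * 3), c(125, 50, 3, 3))
  pb <- predict(m, imgs)
  for (i in 1:3) {
    ps <- predict(m, imgs[, , , i])
    expect_equal(unname(pb[i, ]), unname(ps[1, ]), tolerance = 1e-5)
  }
})

test_that("duplicated images in a batch give identical probability rows", {
  m <- build_cnn(seed = 4)
  one <- array(rnorm(125 * 50 * 3), c(125, 50, 3, 1))
  both <- array(c(one, one), c(125, 50, 3, 2))
  p <- predict(m, both)
  expect_equal(p[1, ], p[2, ], tolerance = 1e-12)
})

test_that("shape errors surface as configuration errors", {
  expect_error(extract_patches(array(0, c(5, 5, 3))), "smaller than one patch")
  expect_error(extract_patches(matrix(0, 10, 10)), "channels")
  expect_error(extract_patches(array(0, c(16, 16, 3)), patch = 8, stride = 4),
               "stride")
})

test_that("the external-backbone adapter wraps any probability function", {
  fake <- backbone_adapter(function(x) {
    n <- dim(x)[4]
    matrix(rep(c(0.9, 0.1), each = n), n, 2)
  }, name = "stub")
  p <- predict(fake, array(0, c(125, 50, 3, 2)))
  expect_identical(colnames(p), whale_classes())
  expect_equal(p[, "humpback"], c(0.9, 0.9))
})
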