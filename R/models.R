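# The two classifier architectures, built from declarative configs:
# a compact 4-block CNN and a 90-patch vision transformer.

#' CNN architecture configuration
#'
#' Four convolutional blocks followed by a dense head. Block structure
#' (filters, kernel, activation): (16, 6x6, tanh), (32, 4x4, relu),
#' (64, 3x3, relu), (64, 3x3, linear). Blocks 1-3 are
#' Conv -> MaxPool 2x2 -> BatchNorm -> Dropout (0.5 / 0.4 / 0.3); block 4 is
#' Conv -> Flatten -> Dropout 0.2. Head: Dense 64 relu -> Dense 2 softmax.
#' Convolutions use "same" padding, stride 1.
#'
#' @param input_shape image dimensions (height, width, channels).
#' @param block4_activation activation of the fourth convolution, which the
#'   architecture leaves unspecified; `"linear"` by default.
#' @return list of class `cnn_config`.
#' @export
cnn_config <- function(input_shape = c(125L, 50L, 3L),
                       block4_activation = "linear") {
  structure(list(
    input_shape = as.integer(input_shape),
    blocks = list(
      list(filters = 16L, kernel = c(6L, 6L), activation = "tanh",
           pool = TRUE, batchnorm = TRUE, dropout = 0.5),
      list(filters = 32L, kernel = c(4L, 4L), activation = "relu",
           pool = TRUE, batchnorm = TRUE, dropout = 0.4),
      list(filters = 64L, kernel = c(3L, 3L), activation = "relu",
           pool = TRUE, batchnorm = TRUE, dropout = 0.3),
      list(filters = 64L, kernel = c(3L, 3L), activation = block4_activation,
           pool = FALSE, batchnorm = FALSE, dropout = 0.2, flatten = TRUE)
    ),
    head_units = 64L,
    n_classes = 2L
  ), class = "cnn_config")
}

#' ViT architecture configuration
#'
#' Non-overlapping 8x8 patches with stride 8 (VALID padding: the 5 remainder
#' rows and 2 remainder columns of the 125x50 grid are dropped), giving
#' floor(125/8) x floor(50/8) = 15 x 6 = 90 patches of 8*8*3 = 192 values.
#' Each patch is linearly embedded to 64 dimensions, given a learned
#' positional embedding, and passed through 4 pre-norm encoder blocks
#' (4 attention heads of key dimension 64, dropout 0.1; MLP [128, 64] with
#' GELU, dropout 0.1). Head: global average pooling over tokens, MLP
#' [2048, 1024] with GELU and dropout 0.3, then a 2-class softmax.
#'
#' @param input_shape image dimensions (height, width, channels).
#' @return list of class `vit_config`.
#' @export
vit_config <- function(input_shape = c(125L, 50L, 3L)) {
  patch <- 8L
  n_patches <- (input_shape[1L] %/% patch) * (input_shape[2L] %/% patch)
  structure(list(
    input_shape = as.integer(input_shape),
    patch = patch,
    n_patches = n_patches,
    embed_dim = 64L,
    n_layers = 4L,
    n_heads = 4L,
    key_dim = 64L,
    attn_dropout = 0.1,
    mlp_units = c(128L, 64L),
    mlp_dropout = 0.1,
    head_units = c(2048L, 1024L),
    head_dropout = 0.3,
    n_classes = 2L
  ), class = "vit_config")
}

#' Extract flattened image patches
#'
#' Cuts a (height x width x channels) image into non-overlapping
#' `patch` x `patch` tiles with stride `patch`, dropping remainder rows and
#' columns, in raster order (patch rows first, then columns). Each tile is
#' flattened column-major (row index fastest, then column, then channel).
#'
#' @param img numeric array, height x width x channels.
#' @param patch patch side length in pixels.
#' @param stride stride between patches; must equal `patch`
#'   (non-overlapping tiling).
#' @return matrix with one flattened patch per row
#'   (`floor(h/patch) * floor(w/patch)` rows, `patch^2 * channels` columns).
#' @export
extract_patches <- function(img, patch = 8L, stride = patch) {
  img <- unclass(img)
  if (length(dim(img)) != 3L) stop("img must be a height x width x channels array")
  if (stride != patch) stop("only non-overlapping tiling (stride == patch) is supported")
  gh <- dim(img)[1L] %/% patch
  gw <- dim(img)[2L] %/% patch
  if (gh < 1L || gw < 1L) stop("image smaller than one patch")
  out <- matrix(0, gh * gw, patch * patch * dim(img)[3L])
  k <- 0L
  for (r in seq_len(gh)) {
    for (cc in seq_len(gw)) {
      k <- k + 1L
      tile <- img[((r - 1L) * patch + 1L):(r * patch),
                  ((cc - 1L) * patch + 1L):(cc * patch), , drop = FALSE]
      out[k, ] <- as.numeric(tile)
    }
  }
  out
}

#' Build the 4-block CNN classifier
#'
#' @param config a [cnn_config()].
#' @param seed integer seed for weight initialization; two builds from the
#'   same config and seed have identical initial weights.
#' @return list of class `whale_model`.
#' @export
build_cnn <- function(config = cnn_config(), seed = 1L) {
  h <- config$input_shape[1L]
  w <- config$input_shape[2L]
  cin <- config$input_shape[3L]
  layers <- with_seed(seed, {
    out <- list()
    for (blk in config$blocks) {
      cl <- layer_conv2d(blk$kernel[1L], blk$kernel[2L], cin,
                         blk$filters, blk$activation)
      if (length(out) == 0L) cl$input_layer <- TRUE
      out <- c(out, list(cl))
      cin <- blk$filters
      if (blk$pool) {
        out <- c(out, list(layer_maxpool2()))
        h <- h %/% 2L
        w <- w %/% 2L
        if (h < 1L || w < 1L) stop("input shape too small for the pooling stack")
      }
      if (blk$batchnorm) out <- c(out, list(layer_batchnorm(blk$filters)))
      if (isTRUE(blk$flatten)) out <- c(out, list(layer_flatten()))
      out <- c(out, list(layer_dropout(blk$dropout)))
    }
    flat_dim <- h * w * cin
    out <- c(out, list(
      layer_dense(flat_dim, config$head_units, "relu"),
      layer_dense(config$head_units, config$n_classes, "linear")
    ))
    out
  })
  structure(list(layers = layers, arch = "cnn", config = config, seed = seed,
                 classes = whale_classes(), input_layout = "HWNC"),
            class = "whale_model")
}

#' Build the vision transformer classifier
#'
#' @param config a [vit_config()].
#' @param seed integer seed for weight initialization.
#' @return list of class `whale_model`.
#' @export
build_vit <- function(config = vit_config(), seed = 1L) {
  if (config$embed_dim < 1L || config$n_heads < 1L) {
    stop("invalid transformer configuration")
  }
  layers <- with_seed(seed, {
    pe <- layer_patch_embed(config$patch, config$embed_dim, config$input_shape)
    if (pe$n_tokens != config$n_patches) {
      stop(sprintf("patch grid yields %d tokens but config declares %d",
                   pe$n_tokens, config$n_patches))
    }
    blocks <- lapply(seq_len(config$n_layers), function(i) {
      layer_vit_block(config$embed_dim, config$n_heads, config$key_dim,
                      config$mlp_units, config$n_patches,
                      config$attn_dropout, config$mlp_dropout)
    })
    head <- list(
      layer_gap_tokens(config$n_patches),
      layer_dense(config$embed_dim, config$head_units[1L], "gelu"),
      layer_dropout(config$head_dropout),
      layer_dense(config$head_units[1L], config$head_units[2L], "gelu"),
      layer_dropout(config$head_dropout),
      layer_dense(config$head_units[2L], config$n_classes, "linear")
    )
    c(list(pe), blocks, head)
  })
  structure(list(layers = layers, arch = "vit", config = config, seed = seed,
                 classes = whale_classes(), input_layout = "HWCN"),
            class = "whale_model")
}

# Forward pass. `x` is a batch array (H, W, C, N) of standardized images;
# returns logits (N x n_classes).
forward_model <- function(model, x, training = FALSE) {
  if (model$input_layout == "HWNC") x <- aperm(x, c(1L, 2L, 4L, 3L))
  for (L in model$layers) x <- L$fwd(x, training)
  x
}

backward_model <- function(model, dlogits) {
  dy <- dlogits
  for (L in rev(model$layers)) dy <- L$bwd(dy)
  invisible(dy)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Count trainable parameters of a model
#' @param model a `whale_model`.
#' @export
n_parameters <- function(model) {
  sum(vapply(leaf_layers(model$layers),
             function(L) sum(vapply(L$params, length, 0L)), 0))
}

#' Plain-text architecture summary
#' @param model a `whale_model`.
#' @return character vector, one line per layer.
#' @export
model_summary <- function(model) {
  lines <- vapply(model$layers, function(L) {
    n <- sum(vapply(leaf_layers(list(L)), function(l) sum(vapply(l$params, length, 0L)), 0))
    sprintf("%-60s params: %d", L$describe(), n)
  }, "")
  c(sprintf("whale_model (%s), %d parameters", model$arch, n_parameters(model)),
    lines)
}

#' @export
print.whale_model <- function(x, ...) {
  cat(model_summary(x), sep = "\n")
  invisible(x)
}

#' Adapter hook for an externally supplied pretrained backbone
#'
#' Accepts any function mapping a batch of 125 x 50 x 3 images to 2-class
#' probabilities (for example a transfer-learning backbone exported from
#' another framework) and wraps it with this package's prediction interface.
#' No pretrained weights ship with the package.
#'
#' @param predict_fn function(images_array) -> N x 2 probability matrix.
#' @param name label for reports.
#' @return list of class `whale_external_model`.
#' @export
backbone_adapter <- function(predict_fn, name = "external_backbone") {
  stopifnot(is.function(predict_fn))
  structure(list(predict_fn = predict_fn, name = name,
                 classes = whale_classes()),
            class = "whale_external_model")
}
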