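# Native neural-network layers with hand-derived backpropagation.
#
# Convolutional activations use layout (H, W, N, C) — channel last so that
# matrix(x, ncol = C) exposes one column per channel, which makes the
# convolution (shift-and-multiply over kernel offsets, one BLAS gemm per
# offset over the whole batch) and spatial batch norm cheap in R. Token
# activations (transformer) are matrices of shape (N * T) x D, image-major:
# row (n-1)*T + t is token t of image n.
#
# Each layer is an environment with $params / $grads (named lists of arrays),
# $decay (which params receive weight decay), $fwd(x, training) and $bwd(dy).

act_fn <- function(name) {
  switch(name,
    linear = list(f = function(z) z, df = function(z, a) 1),
    relu = list(f = function(z) {
      z[z < 0] <- 0
      z
    }, df = function(z, a) (z > 0) * 1),
    tanh = list(f = base::tanh, df = function(z, a) 1 - a^2),
    gelu = list(f = function(z) z * stats::pnorm(z),
                df = function(z, a) stats::pnorm(z) + z * stats::dnorm(z)),
    stop(sprintf("unknown activation: %s", name))
  )
}

glorot_uniform <- function(fan_in, fan_out, n) {
  limit <- sqrt(6 / (fan_in + fan_out))
  runif(n, -limit, limit)
}

new_layer <- function(type) {
  L <- new.env(parent = emptyenv())
  L$type <- type
  L$params <- list()
  L$grads <- list()
  L$decay <- character()
  L
}

layer_conv2d <- function(kh, kw, cin, cout, activation = "linear") {
  force(kh); force(kw); force(cin); force(cout); force(activation)
  L <- new_layer("conv2d")
  fan_in <- kh * kw * cin
  fan_out <- kh * kw * cout
  L$params <- list(
    W = array(glorot_uniform(fan_in, fan_out, kh * kw * cin * cout),
              dim = c(kh, kw, cin, cout)),
    b = numeric(cout)
  )
  L$decay <- "W"
  act <- act_fn(activation)
  L$describe <- function() {
    sprintf("Conv2D %dx%d, %d->%d, %s, same", kh, kw, cin, cout, activation)
  }
  L$fwd <- function(x, training) {
    z <- conv2d_fwd_cpp(x, dim(x), L$params$W, dim(L$params$W), L$params$b)
    a <- act$f(z)
    L$cache <- list(x = x, z = z, a = a)
    a
  }
  L$bwd <- function(dy) {
    cc <- L$cache
    dz <- dy * act$df(cc$z, cc$a)
    r <- conv2d_bwd_cpp(cc$x, dim(cc$x), L$params$W, dim(L$params$W), dz,
                        !isTRUE(L$input_layer)) # input images need no gradient
    L$grads <- list(W = r$dw, b = r$db)
    r$dx
  }
  L
}

layer_maxpool2 <- function() {
  L <- new_layer("maxpool2")
  L$describe <- function() "MaxPool 2x2 stride 2"
  L$fwd <- function(x, training) {
    d <- dim(x)
    H2 <- d[1L] %/% 2L
    W2 <- d[2L] %/% 2L
    ri <- seq_len(H2) * 2L - 1L
    ci <- seq_len(W2) * 2L - 1L
    s <- list(
      x[ri, ci, , , drop = FALSE], x[ri + 1L, ci, , , drop = FALSE],
      x[ri, ci + 1L, , , drop = FALSE], x[ri + 1L, ci + 1L, , , drop = FALSE]
    )
    m <- pmax(s[[1L]], s[[2L]], s[[3L]], s[[4L]])
    L$cache <- list(s = s, m = m, in_dim = d, ri = ri, ci = ci)
    m
  }
  L$bwd <- function(dy) {
    cc <- L$cache
    dx <- array(0, cc$in_dim)
    taken <- array(FALSE, dim(cc$m))
    offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
    for (k in 1:4) {
      mask <- (cc$s[[k]] == cc$m) & !taken # ties go to the first max found
      taken <- taken | mask
      dx[cc$ri + offs[[k]][1L], cc$ci + offs[[k]][2L], , ] <- dy * mask
    }
    dx
  }
  L
}

layer_batchnorm <- function(channels, momentum = 0.99, eps = 1e-3) {
  force(channels); force(momentum); force(eps)
  L <- new_layer("batchnorm")
  L$params <- list(gamma = rep(1, channels), beta = numeric(channels))
  # Inference statistics come from an explicit recalibration pass over the
  # training data with dropout inactive ("precise BN"): this architecture
  # places dropout between blocks, so training-time batch statistics are
  # systematically wider than eval-time ones and a plain moving average of
  # them miscalibrates inference. The debiased moving average remains as a
  # fallback for models that were never recalibrated.
  L$running_mean <- numeric(channels)
  L$running_var <- numeric(channels)
  L$steps <- 0L
  L$frozen <- NULL   # list(mean, var) from the last recalibration pass
  L$collect <- FALSE # when TRUE, eval-mode forwards accumulate statistics
  L$describe <- function() sprintf("BatchNorm (%d ch)", channels)
  L$fwd <- function(x, training) {
    d <- dim(x)
    xm <- matrix(x, ncol = channels)
    if (training) {
      mu <- colMeans(xm)
      v <- pmax(colMeans(xm * xm) - mu^2, 0)
      L$running_mean <- momentum * L$running_mean + (1 - momentum) * mu
      L$running_var <- momentum * L$running_var + (1 - momentum) * v
      L$steps <- L$steps + 1L
    } else if (L$collect) {
      mu <- colMeans(xm)
      v <- pmax(colMeans(xm * xm) - mu^2, 0)
      L$acc_sum <- L$acc_sum + colSums(xm)
      L$acc_sumsq <- L$acc_sumsq + colSums(xm * xm)
      L$acc_n <- L$acc_n + nrow(xm)
    } else if (!is.null(L$frozen)) {
      mu <- L$frozen$mean
      v <- L$frozen$var
    } else if (L$steps == 0L) {
      mu <- numeric(channels)
      v <- rep(1, channels)
    } else {
      debias <- 1 - momentum^L$steps
      mu <- L$running_mean / debias
      v <- pmax(L$running_var / debias, 0)
    }
    inv_std <- 1 / sqrt(v + eps)
    xhat <- sweep(sweep(xm, 2L, mu), 2L, inv_std, "*")
    y <- sweep(sweep(xhat, 2L, L$params$gamma, "*"), 2L, L$params$beta, "+")
    L$cache <- list(xhat = xhat, inv_std = inv_std, d = d, training = training)
    array(y, d)
  }
  L$bwd <- function(dy) {
    cc <- L$cache
    dym <- matrix(dy, ncol = channels)
    L$grads <- list(gamma = colSums(dym * cc$xhat), beta = colSums(dym))
    dxhat <- sweep(dym, 2L, L$params$gamma, "*")
    if (cc$training) {
      M <- nrow(dym)
      t1 <- sweep(dxhat, 2L, colMeans(dxhat))
      t2 <- sweep(cc$xhat, 2L, colMeans(dxhat * cc$xhat), "*")
      dxm <- sweep(t1 - t2, 2L, cc$inv_std, "*")
    } else {
      dxm <- sweep(dxhat, 2L, cc$inv_std, "*")
    }
    array(dxm, cc$d)
  }
  L
}

layer_dropout <- function(rate) {
  force(rate)
  L <- new_layer("dropout")
  L$describe <- function() sprintf("Dropout %.2f", rate)
  L$fwd <- function(x, training) {
    if (!training || rate <= 0) {
      L$cache <- NULL
      return(x)
    }
    mask <- (runif(length(x)) >= rate) / (1 - rate)
    L$cache <- mask
    x * mask
  }
  L$bwd <- function(dy) {
    if (is.null(L$cache)) dy else dy * L$cache
  }
  L
}

# (H, W, N, C) -> (N, H*W*C)
layer_flatten <- function() {
  L <- new_layer("flatten")
  L$describe <- function() "Flatten"
  L$fwd <- function(x, training) {
    d <- dim(x)
    L$cache <- d
    xp <- aperm(x, c(1L, 2L, 4L, 3L)) # (H, W, C, N)
    t(matrix(xp, d[1L] * d[2L] * d[4L], d[3L]))
  }
  L$bwd <- function(dy) {
    d <- L$cache
    xp <- array(t(dy), c(d[1L], d[2L], d[4L], d[3L]))
    aperm(xp, c(1L, 2L, 4L, 3L))
  }
  L
}

layer_dense <- function(din, dout, activation = "linear") {
  force(din); force(dout); force(activation)
  L <- new_layer("dense")
  L$params <- list(
    W = matrix(glorot_uniform(din, dout, din * dout), din, dout),
    b = numeric(dout)
  )
  L$decay <- "W"
  act <- act_fn(activation)
  L$describe <- function() sprintf("Dense %d->%d, %s", din, dout, activation)
  L$fwd <- function(x, training) {
    z <- x %*% L$params$W + rep(L$params$b, each = nrow(x))
    a <- act$f(z)
    L$cache <- list(x = x, z = z, a = a)
    a
  }
  L$bwd <- function(dy) {
    cc <- L$cache
    dz <- dy * act$df(cc$z, cc$a)
    L$grads <- list(W = crossprod(cc$x, dz), b = colSums(dz))
    dz %*% t(L$params$W)
  }
  L
}

layer_layernorm <- function(d_model, eps = 1e-6) {
  force(d_model); force(eps)
  L <- new_layer("layernorm")
  L$params <- list(gamma = rep(1, d_model), beta = numeric(d_model))
  L$describe <- function() sprintf("LayerNorm (%d)", d_model)
  L$fwd <- function(x, training) {
    mu <- rowMeans(x)
    v <- rowMeans(x * x) - mu^2
    inv_std <- 1 / sqrt(pmax(v, 0) + eps)
    xhat <- (x - mu) * inv_std
    y <- sweep(xhat, 2L, L$params$gamma, "*")
    y <- sweep(y, 2L, L$params$beta, "+")
    L$cache <- list(xhat = xhat, inv_std = inv_std)
    y
  }
  L$bwd <- function(dy) {
    cc <- L$cache
    L$grads <- list(gamma = colSums(dy * cc$xhat), beta = colSums(dy))
    dxhat <- sweep(dy, 2L, L$params$gamma, "*")
    (dxhat - rowMeans(dxhat) - cc$xhat * rowMeans(dxhat * cc$xhat)) * cc$inv_std
  }
  L
}

# Multi-head self-attention over (N*T) x D token matrices.
layer_mha <- function(d_model, n_heads, key_dim, dropout = 0, n_tokens) {
  force(d_model); force(n_heads); force(key_dim); force(dropout); force(n_tokens)
  L <- new_layer("mha")
  dk <- key_dim
  inner <- n_heads * dk
  mk <- function(din, dout) matrix(glorot_uniform(din, dout, din * dout), din, dout)
  L$params <- list(
    Wq = mk(d_model, inner), bq = numeric(inner),
    Wk = mk(d_model, inner), bk = numeric(inner),
    Wv = mk(d_model, inner), bv = numeric(inner),
    Wo = mk(inner, d_model), bo = numeric(d_model)
  )
  L$decay <- c("Wq", "Wk", "Wv", "Wo")
  L$describe <- function() {
    sprintf("MultiHeadAttention heads=%d key_dim=%d", n_heads, dk)
  }
  L$fwd <- function(x, training) {
    R <- nrow(x)
    N <- R %/% n_tokens
    Q <- x %*% L$params$Wq + rep(L$params$bq, each = R)
    K <- x %*% L$params$Wk + rep(L$params$bk, each = R)
    V <- x %*% L$params$Wv + rep(L$params$bv, each = R)
    O <- matrix(0, R, inner)
    A_all <- array(0, c(n_tokens, n_tokens, n_heads, N))
    mask_all <- if (training && dropout > 0) array(0, c(n_tokens, n_tokens, n_heads, N)) else NULL
    scale <- 1 / sqrt(dk)
    for (n in seq_len(N)) {
      rows <- ((n - 1L) * n_tokens + 1L):(n * n_tokens)
      for (h in seq_len(n_heads)) {
        cols <- ((h - 1L) * dk + 1L):(h * dk)
        S <- (Q[rows, cols] %*% t(K[rows, cols])) * scale
        S <- S - apply(S, 1L, max)
        A <- exp(S)
        A <- A / rowSums(A)
        A_all[, , h, n] <- A
        if (!is.null(mask_all)) {
          m <- (runif(length(A)) >= dropout) / (1 - dropout)
          mask_all[, , h, n] <- m
          A <- A * m
        }
        O[rows, cols] <- A %*% V[rows, cols]
      }
    }
    out <- O %*% L$params$Wo + rep(L$params$bo, each = R)
    L$cache <- list(x = x, Q = Q, K = K, V = V, O = O, A = A_all,
                    mask = mask_all, N = N)
    out
  }
  L$bwd <- function(dy) {
    cc <- L$cache
    R <- nrow(dy)
    N <- cc$N
    dWo <- crossprod(cc$O, dy)
    dbo <- colSums(dy)
    dO <- dy %*% t(L$params$Wo)
    dQ <- matrix(0, R, inner)
    dK <- matrix(0, R, inner)
    dV <- matrix(0, R, inner)
    scale <- 1 / sqrt(dk)
    for (n in seq_len(N)) {
      rows <- ((n - 1L) * n_tokens + 1L):(n * n_tokens)
      for (h in seq_len(n_heads)) {
        cols <- ((h - 1L) * dk + 1L):(h * dk)
        A <- cc$A[, , h, n]
        Ad <- if (is.null(cc$mask)) A else A * cc$mask[, , h, n]
        dOnh <- dO[rows, cols]
        dAd <- dOnh %*% t(cc$V[rows, cols])
        dV[rows, cols] <- crossprod(Ad, dOnh)
        dA <- if (is.null(cc$mask)) dAd else dAd * cc$mask[, , h, n]
        dS <- A * (dA - rowSums(A * dA)) * scale
        dQ[rows, cols] <- dS %*% cc$K[rows, cols]
        dK[rows, cols] <- crossprod(dS, cc$Q[rows, cols])
      }
    }
    L$grads <- list(
      Wq = crossprod(cc$x, dQ), bq = colSums(dQ),
      Wk = crossprod(cc$x, dK), bk = colSums(dK),
      Wv = crossprod(cc$x, dV), bv = colSums(dV),
      Wo = dWo, bo = dbo
    )
    dQ %*% t(L$params$Wq) + dK %*% t(L$params$Wk) + dV %*% t(L$params$Wv)
  }
  L
}

# Patch extraction + linear embedding + learned positional embedding.
# Input (H, W, C, N); output (N*T) x embed_dim, image-major token rows.
layer_patch_embed <- function(patch, embed_dim, img_dim = c(125L, 50L, 3L)) {
  force(patch); force(embed_dim); force(img_dim)
  L <- new_layer("patch_embed")
  gh <- img_dim[1L] %/% patch
  gw <- img_dim[2L] %/% patch
  n_tokens <- gh * gw
  token_len <- patch * patch * img_dim[3L]
  L$params <- list(
    We = matrix(glorot_uniform(token_len, embed_dim, token_len * embed_dim),
                token_len, embed_dim),
    be = numeric(embed_dim),
    pos = matrix(stats::rnorm(n_tokens * embed_dim, sd = 0.02),
                 n_tokens, embed_dim)
  )
  L$decay <- "We"
  L$n_tokens <- n_tokens
  L$describe <- function() {
    sprintf("PatchEmbed %dx%d stride %d -> %d tokens x %d", patch, patch,
            patch, n_tokens, embed_dim)
  }
  L$fwd <- function(x, training) {
    N <- dim(x)[4L]
    P <- matrix(0, N * n_tokens, token_len)
    t_idx <- 0L
    for (r in seq_len(gh)) { # raster order: patch rows, then columns
      for (cc in seq_len(gw)) {
        t_idx <- t_idx + 1L
        rows <- ((r - 1L) * patch + 1L):(r * patch)
        cols <- ((cc - 1L) * patch + 1L):(cc * patch)
        xs <- x[rows, cols, , , drop = FALSE] # (patch, patch, C, N)
        P[(seq_len(N) - 1L) * n_tokens + t_idx, ] <- t(matrix(xs, token_len, N))
      }
    }
    tok <- rep(seq_len(n_tokens), N)
    Z <- P %*% L$params$We + rep(L$params$be, each = N * n_tokens) +
      L$params$pos[tok, ]
    L$cache <- list(P = P, tok = tok)
    Z
  }
  L$bwd <- function(dy) {
    cc <- L$cache
    L$grads <- list(
      We = crossprod(cc$P, dy),
      be = colSums(dy),
      pos = rowsum(dy, cc$tok)
    )
    NULL # input images receive no gradient
  }
  L
}

# Mean over tokens: (N*T) x D -> N x D
layer_gap_tokens <- function(n_tokens) {
  force(n_tokens)
  L <- new_layer("gap")
  L$describe <- function() "GlobalAveragePool over tokens"
  L$fwd <- function(x, training) {
    N <- nrow(x) %/% n_tokens
    L$cache <- N
    rowsum(x, rep(seq_len(N), each = n_tokens)) / n_tokens
  }
  L$bwd <- function(dy) {
    N <- L$cache
    dy[rep(seq_len(N), each = n_tokens), , drop = FALSE] / n_tokens
  }
  L
}

# Pre-norm transformer encoder block: x + MHA(LN(x)), then h + MLP(LN(h)).
layer_vit_block <- function(d_model, n_heads, key_dim, mlp_units, n_tokens,
                            attn_dropout = 0.1, mlp_dropout = 0.1) {
  force(d_model); force(n_heads); force(key_dim); force(mlp_units)
  force(n_tokens); force(attn_dropout); force(mlp_dropout)
  L <- new_layer("vit_block")
  L$sub <- list(
    ln1 = layer_layernorm(d_model),
    mha = layer_mha(d_model, n_heads, key_dim, attn_dropout, n_tokens),
    ln2 = layer_layernorm(d_model),
    fc1 = layer_dense(d_model, mlp_units[1L], "gelu"),
    do1 = layer_dropout(mlp_dropout),
    fc2 = layer_dense(mlp_units[1L], mlp_units[2L], "gelu"),
    do2 = layer_dropout(mlp_dropout)
  )
  L$describe <- function() {
    sprintf("TransformerBlock d=%d heads=%d mlp=[%s]", d_model, n_heads,
            paste(mlp_units, collapse = ","))
  }
  L$fwd <- function(x, training) {
    s <- L$sub
    h <- x + s$mha$fwd(s$ln1$fwd(x, training), training)
    m <- s$do2$fwd(s$fc2$fwd(s$do1$fwd(s$fc1$fwd(s$ln2$fwd(h, training),
                                                 training), training),
                             training), training)
    h + m
  }
  L$bwd <- function(dy) {
    s <- L$sub
    dm <- s$ln2$bwd(s$fc1$bwd(s$do1$bwd(s$fc2$bwd(s$do2$bwd(dy)))))
    dh <- dy + dm
    dh + s$ln1$bwd(s$mha$bwd(dh))
  }
  L
}

# flat list of all parameter-bearing layers, descending into composites
leaf_layers <- function(layers) {
  out <- list()
  for (L in layers) {
    if (!is.null(L$sub)) out <- c(out, leaf_layers(L$sub)) else out <- c(out, L)
  }
  out
}
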