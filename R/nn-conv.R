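# 2-D convolution stack for the location network.
#
# Spatial activations travel as a "ctensor": list(m, H, W, N) where m is a
# (H*W*N) x C matrix whose rows are ordered h-fastest, then w, then sample n.
# Convolution is im2col + one matrix multiply; the gather/scatter index
# template is cached per (geometry, batch size).

ctensor <- function(m, H, W, N) list(m = m, H = H, W = W, N = N)

# Pack an array of images dim (H, W, C, N) into a ctensor.
images_to_ctensor <- function(arr) {
  d <- dim(arr)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  # target row order: h, then w, then n; columns are channels
  m <- matrix(aperm(arr, c(1, 2, 4, 3)), nrow = H * W * N, ncol = C)
  ctensor(m, H, W, N)
}

conv_geom <- function(H, W, C_in, k, stride, pad, N) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  H_out <- (Hp - k) %/% stride + 1L
  W_out <- (Wp - k) %/% stride + 1L
  # rows of the unpadded input inside the padded row space (one sample)
  h <- rep(seq_len(H), times = W)
  w <- rep(seq_len(W), each = H)
  pad_rows1 <- (h + pad) + Hp * (w + pad - 1L)
  pad_rows <- as.vector(outer(pad_rows1, (seq_len(N) - 1L) * Hp * Wp, "+"))
  # gather template: rows = (ho, wo, n), cols = (dh, dw, c)
  ho <- rep(seq_len(H_out), times = W_out)
  wo <- rep(seq_len(W_out), each = H_out)
  base1 <- ((ho - 1L) * stride + 1L) + Hp * ((wo - 1L) * stride)   # (dh=1, dw=1)
  base <- as.vector(outer(base1, (seq_len(N) - 1L) * Hp * Wp, "+"))  # length H_out*W_out*N
  dh <- rep(seq_len(k) - 1L, times = k)
  dw <- rep(seq_len(k) - 1L, each = k)
  off_spatial <- dh + Hp * dw                                       # length k*k
  npadrow <- Hp * Wp * N
  offs <- as.vector(outer(off_spatial, (seq_len(C_in) - 1L) * npadrow, "+"))
  idx <- outer(base, offs, "+")                                     # (H_out*W_out*N) x (k*k*C_in)
  list(Hp = Hp, Wp = Wp, H_out = H_out, W_out = W_out,
       pad_rows = pad_rows, idx = idx, npadrow = npadrow)
}

layer_conv <- function(C_in, C_out, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  self <- new_nn_layer("conv")
  fan_in <- k * k * C_in
  self$params <- list(
    W = matrix(stats::rnorm(fan_in * C_out, sd = sqrt(2 / fan_in)), fan_in, C_out),
    b = numeric(C_out)
  )
  self$grads <- list(W = matrix(0, fan_in, C_out), b = numeric(C_out))
  self$C_in <- C_in; self$C_out <- C_out; self$k <- k
  self$stride <- as.integer(stride); self$pad <- as.integer(pad)
  self$geom_cache <- list()

  get_geom <- function(H, W, N) {
    key <- paste(H, W, N, sep = "_")
    g <- self$geom_cache[[key]]
    if (is.null(g)) {
      g <- conv_geom(H, W, self$C_in, self$k, self$stride, self$pad, N)
      self$geom_cache[[key]] <- g
    }
    g
  }

  self$forward <- function(x, train = TRUE) {
    g <- get_geom(x$H, x$W, x$N)
    if (self$pad > 0L) {
      mp <- matrix(0, g$npadrow, self$C_in)
      mp[g$pad_rows, ] <- x$m
    } else {
      mp <- x$m
    }
    # g$idx spans channels via column offsets into the padded matrix vector
    xcol <- matrix(mp[g$idx], nrow = nrow(g$idx))
    self$xcol <- xcol
    self$in_geom <- list(H = x$H, W = x$W, N = x$N, g = g)
    out <- add_rowvec(xcol %*% self$params$W, self$params$b)
    ctensor(out, g$H_out, g$W_out, x$N)
  }

  self$backward <- function(dy) {
    g <- self$in_geom$g
    dym <- dy$m
    self$grads$W <- self$grads$W + crossprod(self$xcol, dym)
    self$grads$b <- self$grads$b + colSums(dym)
    dxcol <- dym %*% t(self$params$W)
    dmp <- numeric(g$npadrow * self$C_in)
    # within one template column the output->input map is injective
    for (j in seq_len(ncol(g$idx))) {
      ii <- g$idx[, j]
      dmp[ii] <- dmp[ii] + dxcol[, j]
    }
    dmp <- matrix(dmp, g$npadrow, self$C_in)
    dxm <- if (self$pad > 0L) dmp[g$pad_rows, , drop = FALSE] else dmp
    ctensor(dxm, self$in_geom$H, self$in_geom$W, self$in_geom$N)
  }
  self
}

# Batch normalization over (batch x spatial) per channel, with running stats.
layer_bn2d <- function(C, momentum = 0.1, eps = 1e-5) {
  self <- new_nn_layer("bn2d")
  self$params <- list(gamma = rep(1, C), beta = numeric(C))
  self$grads <- list(gamma = numeric(C), beta = numeric(C))
  self$state <- list(run_mean = numeric(C), run_var = rep(1, C))
  self$momentum <- momentum; self$eps <- eps
  self$forward <- function(x, train = TRUE) {
    m <- x$m
    if (train) {
      mu <- colMeans(m)
      xc <- add_rowvec(m, -mu)
      v <- colMeans(xc * xc)
      if (isTRUE(self$refreshing)) {
        # exact post-training recalibration: plain average of batch moments
        k <- (self$refresh_n %||% 0L) + 1L
        self$state$run_mean <- self$state$run_mean + (mu - self$state$run_mean) / k
        self$state$run_var <- self$state$run_var + (v - self$state$run_var) / k
        self$refresh_n <- k
      } else {
        self$state$run_mean <- (1 - self$momentum) * self$state$run_mean + self$momentum * mu
        self$state$run_var <- (1 - self$momentum) * self$state$run_var + self$momentum * v
      }
    } else {
      mu <- self$state$run_mean
      v <- self$state$run_var
      xc <- add_rowvec(m, -mu)
    }
    istd <- 1 / sqrt(v + self$eps)
    xhat <- xc * matrix(istd, nrow(m), length(istd), byrow = TRUE)
    self$xhat <- xhat; self$istd <- istd; self$train_mode <- train
    out <- add_rowvec(xhat * matrix(self$params$gamma, nrow(m), length(istd), byrow = TRUE),
                      self$params$beta)
    ctensor(out, x$H, x$W, x$N)
  }
  self$backward <- function(dy) {
    dym <- dy$m
    n <- nrow(dym)
    C <- length(self$params$gamma)
    self$grads$gamma <- self$grads$gamma + colSums(dym * self$xhat)
    self$grads$beta <- self$grads$beta + colSums(dym)
    dxhat <- dym * matrix(self$params$gamma, n, C, byrow = TRUE)
    if (self$train_mode) {
      dxm <- (dxhat - matrix(colMeans(dxhat), n, C, byrow = TRUE) -
                self$xhat * matrix(colMeans(dxhat * self$xhat), n, C, byrow = TRUE)) *
        matrix(self$istd, n, C, byrow = TRUE)
    } else {
      dxm <- dxhat * matrix(self$istd, n, C, byrow = TRUE)
    }
    ctensor(dxm, dy$H, dy$W, dy$N)
  }
  self
}

# Identity stand-in for a norm layer (normalization-free variant).
layer_identity_ct <- function() {
  self <- new_nn_layer("identity_ct")
  self$forward <- function(x, train = TRUE) x
  self$backward <- function(dy) dy
  self
}

make_norm <- function(kind, C) {
  if (kind == "batch") layer_bn2d(C) else layer_identity_ct()
}

layer_relu_ct <- function() {
  self <- new_nn_layer("relu_ct")
  self$forward <- function(x, train = TRUE) {
    self$mask <- x$m > 0
    ctensor(x$m * self$mask, x$H, x$W, x$N)
  }
  self$backward <- function(dy) ctensor(dy$m * self$mask, dy$H, dy$W, dy$N)
  self
}

# Global average pool: ctensor -> (N x C) matrix.
layer_gap <- function() {
  self <- new_nn_layer("gap")
  self$forward <- function(x, train = TRUE) {
    self$HW <- x$H * x$W; self$H <- x$H; self$W <- x$W; self$N <- x$N
    grp <- rep(seq_len(x$N), each = self$HW)
    out <- rowsum(x$m, grp) / self$HW
    rownames(out) <- NULL
    out
  }
  self$backward <- function(dy) {
    dxm <- dy[rep(seq_len(self$N), each = self$HW), , drop = FALSE] / self$HW
    ctensor(dxm, self$H, self$W, self$N)
  }
  self
}

# Batch-norm statistics drift behind fast weight updates during short
# training runs; recompute them exactly under the final weights by
# averaging batch moments over one extra pass (precise BN).
bn_recalibrate <- function(model, forward_pass) {
  bns <- Filter(function(l) l$kind == "bn2d", nn_collect_layers(model))
  for (l in bns) {
    l$refreshing <- TRUE
    l$refresh_n <- 0L
    l$state$run_mean <- l$state$run_mean * 0
    l$state$run_var <- l$state$run_var * 0
  }
  forward_pass()
  for (l in bns) l$refreshing <- FALSE
  invisible(model)
}

# Basic residual block (two 3x3 convs; 1x1 projection shortcut when needed).
resnet_block <- function(C_in, C_out, stride, norm = "batch") {
  self <- new_nn_layer("resblock")
  self$conv1 <- layer_conv(C_in, C_out, 3L, stride, 1L)
  self$bn1 <- make_norm(norm, C_out)
  self$relu1 <- layer_relu_ct()
  self$conv2 <- layer_conv(C_out, C_out, 3L, 1L, 1L)
  self$bn2 <- make_norm(norm, C_out)
  # without batch norm, damp the residual branch at init so each block
  # starts close to the identity (stabilizes the first optimizer steps)
  if (norm != "batch") self$conv2$params$W <- self$conv2$params$W * 0.5
  self$proj <- !(stride == 1L && C_in == C_out)
  self$children <- list(self$conv1, self$bn1, self$conv2, self$bn2)
  if (self$proj) {
    self$convd <- layer_conv(C_in, C_out, 1L, stride, 0L)
    self$bnd <- make_norm(norm, C_out)
    self$children <- c(self$children, list(self$convd, self$bnd))
  }
  self$forward <- function(x, train = TRUE) {
    a <- self$bn1$forward(self$conv1$forward(x, train), train)
    a <- self$relu1$forward(a, train)
    a <- self$bn2$forward(self$conv2$forward(a, train), train)
    s <- if (self$proj) self$bnd$forward(self$convd$forward(x, train), train) else x
    pre <- a$m + s$m
    self$mask <- pre > 0
    ctensor(pre * self$mask, a$H, a$W, a$N)
  }
  self$backward <- function(dy) {
    dpre <- ctensor(dy$m * self$mask, dy$H, dy$W, dy$N)
    da <- self$conv2$backward(self$bn2$backward(dpre))
    da <- self$conv1$backward(self$bn1$backward(self$relu1$backward(da)))
    ds <- if (self$proj) self$convd$backward(self$bnd$backward(dpre)) else dpre
    ctensor(da$m + ds$m, da$H, da$W, da$N)
  }
  self
}

# ResNet-style backbone with a 32x32-friendly stem (3x3 stride-1 first
# convolution, no initial max-pool), followed by global average pooling.
resnet_backbone <- function(C_in, widths = c(64L, 128L, 256L, 512L),
                            blocks = c(2L, 2L, 2L, 2L), norm = "batch") {
  stopifnot(length(widths) == length(blocks))
  self <- new_nn_layer("resnet")
  self$stem_conv <- layer_conv(C_in, widths[1], 3L, 1L, 1L)
  self$stem_bn <- make_norm(norm, widths[1])
  self$stem_relu <- layer_relu_ct()
  self$blocks <- list()
  c_prev <- widths[1]
  for (s in seq_along(widths)) {
    for (b in seq_len(blocks[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      self$blocks[[length(self$blocks) + 1L]] <- resnet_block(c_prev, widths[s], stride, norm)
      c_prev <- widths[s]
    }
  }
  self$gap <- layer_gap()
  self$out_dim <- c_prev
  self$children <- c(list(self$stem_conv, self$stem_bn), self$blocks)
  self$forward <- function(x, train = TRUE) {
    a <- self$stem_relu$forward(self$stem_bn$forward(self$stem_conv$forward(x, train), train), train)
    for (bl in self$blocks) a <- bl$forward(a, train)
    self$gap$forward(a, train)
  }
  self$backward <- function(dy) {
    da <- self$gap$backward(dy)
    for (bl in rev(self$blocks)) da <- bl$backward(da)
    self$stem_conv$backward(self$stem_bn$backward(self$stem_relu$backward(da)))
  }
  self
}
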