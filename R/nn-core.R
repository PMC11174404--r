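# Minimal neural-network engine: layers are environments holding parameters,
# gradients, a forward() that caches what backward() needs, and a backward()
# that accumulates parameter gradients and returns the input gradient.
# Reference semantics (environments) let an optimizer update weights in place.

`%||%` <- function(a, b) if (is.null(a)) b else a

new_nn_layer <- function(kind) {
  self <- new.env(parent = emptyenv())
  self$kind <- kind
  self$params <- list()
  self$grads <- list()
  self$children <- list()
  class(self) <- "nn_layer"
  self
}

#' @keywords internal
nn_collect_layers <- function(m) {
  if (length(m$children) > 0L) {
    out <- list()
    for (ch in m$children) out <- c(out, nn_collect_layers(ch))
    out
  } else {
    list(m)
  }
}

nn_zero_grads <- function(m) {
  for (l in nn_collect_layers(m)) {
    l$grads <- lapply(l$params, function(p) {
      if (is.matrix(p) || is.array(p)) array(0, dim = dim(p)) else numeric(length(p))
    })
  }
  invisible(m)
}

# Flat numeric views of all parameters, used for freeze checks and checkpoints.
nn_param_vector <- function(m) {
  unlist(lapply(nn_collect_layers(m), function(l) lapply(l$params, as.numeric)),
         use.names = FALSE)
}

nn_get_state <- function(m) {
  lapply(nn_collect_layers(m), function(l) list(params = l$params, extra = l$state %||% NULL))
}

nn_set_state <- function(m, state) {
  layers <- nn_collect_layers(m)
  stopifnot(length(layers) == length(state))
  for (i in seq_along(layers)) {
    layers[[i]]$params <- state[[i]]$params
    if (!is.null(state[[i]]$extra)) layers[[i]]$state <- state[[i]]$extra
  }
  invisible(m)
}

add_rowvec <- function(M, b) M + rep(b, each = nrow(M))

layer_dense <- function(d_in, d_out, init_sd = sqrt(2 / d_in)) {
  self <- new_nn_layer("dense")
  self$params <- list(
    W = matrix(stats::rnorm(d_in * d_out, sd = init_sd), d_in, d_out),
    b = numeric(d_out)
  )
  self$grads <- list(W = matrix(0, d_in, d_out), b = numeric(d_out))
  self$forward <- function(x, train = TRUE) {
    self$x <- x
    add_rowvec(x %*% self$params$W, self$params$b)
  }
  self$backward <- function(dy) {
    self$grads$W <- self$grads$W + crossprod(self$x, dy)
    self$grads$b <- self$grads$b + colSums(dy)
    dy %*% t(self$params$W)
  }
  self
}

layer_relu <- function() {
  self <- new_nn_layer("relu")
  self$forward <- function(x, train = TRUE) {
    self$mask <- x > 0
    x * self$mask
  }
  self$backward <- function(dy) dy * self$mask
  self
}

# Row-wise layer normalization over the feature dimension.
layer_layernorm <- function(d, eps = 1e-5) {
  self <- new_nn_layer("layernorm")
  self$params <- list(gamma = rep(1, d), beta = numeric(d))
  self$grads <- list(gamma = numeric(d), beta = numeric(d))
  self$eps <- eps
  self$forward <- function(x, train = TRUE) {
    mu <- rowMeans(x)
    xc <- x - mu
    v <- rowMeans(xc * xc)
    istd <- 1 / sqrt(v + self$eps)
    xhat <- xc * istd
    self$xhat <- xhat
    self$istd <- istd
    add_rowvec(xhat * matrix(self$params$gamma, nrow(x), d, byrow = TRUE), self$params$beta)
  }
  self$backward <- function(dy) {
    d <- length(self$params$gamma)
    g <- matrix(self$params$gamma, nrow(dy), d, byrow = TRUE)
    self$grads$gamma <- self$grads$gamma + colSums(dy * self$xhat)
    self$grads$beta <- self$grads$beta + colSums(dy)
    dxhat <- dy * g
    (dxhat - rowMeans(dxhat) - self$xhat * rowMeans(dxhat * self$xhat)) * self$istd
  }
  self
}

softmax_rows <- function(z) {
  z <- z - z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z)
  e / rowSums(e)
}

# Combined softmax + cross-entropy; y is an integer class vector (1-based).
# Returns list(loss, dlogits) with dlogits averaged over the batch.
softmax_xent <- function(logits, y) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / n, probs = p)
}

# ---- Adam -------------------------------------------------------------------

adam_new <- function(module, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  layers <- nn_collect_layers(module)
  st <- lapply(layers, function(l) {
    list(m = lapply(l$params, function(p) p * 0), v = lapply(l$params, function(p) p * 0))
  })
  env <- new.env(parent = emptyenv())
  env$layers <- layers
  env$st <- st
  env$lr <- lr; env$beta1 <- beta1; env$beta2 <- beta2; env$eps <- eps
  env$t <- 0L
  env
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (i in seq_along(opt$layers)) {
    l <- opt$layers[[i]]
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      opt$st[[i]]$m[[nm]] <- b1 * opt$st[[i]]$m[[nm]] + (1 - b1) * g
      opt$st[[i]]$v[[nm]] <- b2 * opt$st[[i]]$v[[nm]] + (1 - b2) * g * g
      mhat <- opt$st[[i]]$m[[nm]] / bc1
      vhat <- opt$st[[i]]$v[[nm]] / bc2
      l$params[[nm]] <- l$params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    }
  }
  invisible(opt)
}
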