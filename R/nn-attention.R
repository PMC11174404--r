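# Multi-head self-attention and pre-norm transformer encoder layers.
#
# A batch of sequences is one (n_seq * S) x D matrix, sequence-major: rows
# 1..S belong to sequence 1, rows S+1..2S to sequence 2, and so on. S is the
# token count (16 for 1024-sample segments split into 16 x 64).

# Fixed sinusoidal position table, S x D.
sinusoidal_encoding <- function(S, D) {
  pos <- seq_len(S) - 1L
  i <- seq_len(D) - 1L
  angle <- outer(pos, 1 / 10000^((i %/% 2L) * 2 / D))
  pe <- matrix(0, S, D)
  even <- (i %% 2L) == 0L
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, !even] <- cos(angle[, !even, drop = FALSE])
  pe
}

layer_mha <- function(D, heads) {
  stopifnot(D %% heads == 0L)
  self <- new_nn_layer("mha")
  d <- D %/% heads
  init <- function() matrix(stats::rnorm(D * D, sd = sqrt(1 / D)), D, D)
  self$params <- list(Wq = init(), Wk = init(), Wv = init(), Wo = init(),
                      bq = numeric(D), bk = numeric(D), bv = numeric(D), bo = numeric(D))
  self$grads <- lapply(self$params, function(p) p * 0)
  self$D <- D; self$heads <- heads; self$d <- d

  # (n*S) x D head block -> S x d x n array of contiguous per-sequence slices
  to3d <- function(M, cols, S, n) aperm(array(M[, cols], c(S, n, d)), c(1, 3, 2))
  from3d <- function(Ar, S, n) matrix(aperm(Ar, c(1, 3, 2)), S * n, d)

  self$forward <- function(x, S, train = TRUE) {
    n <- nrow(x) %/% S
    p <- self$params
    Q <- add_rowvec(x %*% p$Wq, p$bq)
    K <- add_rowvec(x %*% p$Wk, p$bk)
    V <- add_rowvec(x %*% p$Wv, p$bv)
    O <- matrix(0, nrow(x), self$D)
    A <- array(0, c(S, S, self$heads, n))
    sc <- 1 / sqrt(d)
    for (h in seq_len(self$heads)) {
      cols <- ((h - 1L) * d + 1L):(h * d)
      Qa <- to3d(Q, cols, S, n); Ka <- to3d(K, cols, S, n); Va <- to3d(V, cols, S, n)
      Oa <- array(0, c(S, d, n))
      for (i in seq_len(n)) {
        Ai <- softmax_rows(tcrossprod(Qa[, , i], Ka[, , i]) * sc)
        A[, , h, i] <- Ai
        Oa[, , i] <- Ai %*% Va[, , i]
      }
      O[, cols] <- from3d(Oa, S, n)
    }
    self$x <- x; self$Q <- Q; self$K <- K; self$V <- V; self$A <- A; self$O <- O
    self$S <- S; self$n <- n
    add_rowvec(O %*% p$Wo, p$bo)
  }

  self$backward <- function(dy) {
    p <- self$params
    S <- self$S; n <- self$n
    self$grads$Wo <- self$grads$Wo + crossprod(self$O, dy)
    self$grads$bo <- self$grads$bo + colSums(dy)
    dO <- dy %*% t(p$Wo)
    dQ <- matrix(0, nrow(dy), self$D)
    dK <- matrix(0, nrow(dy), self$D)
    dV <- matrix(0, nrow(dy), self$D)
    sc <- 1 / sqrt(d)
    for (h in seq_len(self$heads)) {
      cols <- ((h - 1L) * d + 1L):(h * d)
      Qa <- to3d(self$Q, cols, S, n); Ka <- to3d(self$K, cols, S, n)
      Va <- to3d(self$V, cols, S, n); dOa <- to3d(dO, cols, S, n)
      dQa <- array(0, c(S, d, n)); dKa <- dQa; dVa <- dQa
      for (i in seq_len(n)) {
        Ai <- self$A[, , h, i]
        dOi <- dOa[, , i]
        dAi <- tcrossprod(dOi, Va[, , i])
        dVa[, , i] <- crossprod(Ai, dOi)
        ds <- Ai * (dAi - rowSums(dAi * Ai))
        dQa[, , i] <- ds %*% Ka[, , i] * sc
        dKa[, , i] <- crossprod(ds, Qa[, , i]) * sc
      }
      dQ[, cols] <- from3d(dQa, S, n)
      dK[, cols] <- from3d(dKa, S, n)
      dV[, cols] <- from3d(dVa, S, n)
    }
    self$grads$Wq <- self$grads$Wq + crossprod(self$x, dQ)
    self$grads$Wk <- self$grads$Wk + crossprod(self$x, dK)
    self$grads$Wv <- self$grads$Wv + crossprod(self$x, dV)
    self$grads$bq <- self$grads$bq + colSums(dQ)
    self$grads$bk <- self$grads$bk + colSums(dK)
    self$grads$bv <- self$grads$bv + colSums(dV)
    dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  }
  self
}

# One pre-norm encoder layer: x + MHA(LN(x)), then x + FFN(LN(x)).
encoder_layer <- function(D, heads, d_ff) {
  self <- new_nn_layer("encoder_layer")
  self$ln1 <- layer_layernorm(D)
  self$mha <- layer_mha(D, heads)
  self$ln2 <- layer_layernorm(D)
  self$ff1 <- layer_dense(D, d_ff)
  self$ffrelu <- layer_relu()
  self$ff2 <- layer_dense(d_ff, D)
  self$children <- list(self$ln1, self$mha, self$ln2, self$ff1, self$ff2)
  self$forward <- function(x, S, train = TRUE) {
    y <- x + self$mha$forward(self$ln1$forward(x, train), S, train)
    y + self$ff2$forward(self$ffrelu$forward(self$ff1$forward(self$ln2$forward(y, train), train), train), train)
  }
  self$backward <- function(dz) {
    dy <- dz + self$ln2$backward(self$ff1$backward(self$ffrelu$backward(self$ff2$backward(dz))))
    dy + self$ln1$backward(self$mha$backward(dy))
  }
  self
}

# Encoder stack with optional sinusoidal position encoding and a final
# layer norm; returns the (n*S) x D token representations.
encoder_stack <- function(D, heads, n_layers, d_ff, S,
                          positional_encoding = c("sinusoidal", "none")) {
  positional_encoding <- match.arg(positional_encoding)
  self <- new_nn_layer("encoder_stack")
  self$S <- S
  # tokens are raw sensor samples (no learned embedding), so the position
  # table is damped: a full-amplitude table would dominate the signal
  self$pe <- if (positional_encoding == "sinusoidal") 0.1 * sinusoidal_encoding(S, D) else NULL
  self$layers <- lapply(seq_len(n_layers), function(i) encoder_layer(D, heads, d_ff))
  self$ln_final <- layer_layernorm(D)
  self$children <- c(self$layers, list(self$ln_final))
  self$forward <- function(x, train = TRUE) {
    n <- nrow(x) %/% self$S
    if (!is.null(self$pe)) x <- x + self$pe[rep(seq_len(self$S), n), , drop = FALSE]
    for (l in self$layers) x <- l$forward(x, self$S, train)
    self$ln_final$forward(x, train)
  }
  self$backward <- function(dy) {
    dx <- self$ln_final$backward(dy)
    for (l in rev(self$layers)) dx <- l$backward(dx)
    dx
  }
  self
}

# Flatten sequence-major token matrix (n*S) x D into n x (S*D), tokens in
# chronological order (token 1's D dims first).
seq_flatten <- function(m, S) {
  n <- nrow(m) %/% S
  D <- ncol(m)
  a <- array(m, dim = c(S, n, D))
  out <- aperm(a, c(2, 3, 1))    # n x D x S
  dim(out) <- c(n, D * S)
  out
}

seq_unflatten <- function(m, S, D) {
  n <- nrow(m)
  a <- array(m, dim = c(n, D, S))
  out <- aperm(a, c(3, 1, 2))    # S x n x D
  dim(out) <- c(S * n, D)
  out
}
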