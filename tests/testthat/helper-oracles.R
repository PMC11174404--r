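# Hand-rolled pre-norm encoder layer: an independent re-computation of the
# same arithmetic from the layer's weights, using only base matrix ops.
encoder_oracle <- function(stack, x, S) {
  ln <- function(v, g, b) {
    mu <- mean(v); sd2 <- mean((v - mu)^2)
    (v - mu) / sqrt(sd2 + 1e-5) * g + b
  }
  ln_mat <- function(M, l) t(apply(M, 1, ln, g = l$params$gamma, b = l$params$beta))
  n <- nrow(x) / S
  out <- x
  if (!is.null(stack$pe)) out <- out + stack$pe[rep(seq_len(S), n), ]
  for (lay in stack$layers) {
    p <- lay$mha$params
    h <- lay$mha$heads
    d <- ncol(x) / h
    xn <- ln_mat(out, lay$ln1)
    att <- matrix(0, nrow(out), ncol(out))
    for (i in seq_len(n)) {
      rows <- ((i - 1) * S + 1):(i * S)
      Q <- xn[rows, , drop = FALSE] %*% p$Wq + rep(p$bq, each = S)
      K <- xn[rows, , drop = FALSE] %*% p$Wk + rep(p$bk, each = S)
      V <- xn[rows, , drop = FALSE] %*% p$Wv + rep(p$bv, each = S)
      O <- matrix(0, S, ncol(x))
      for (hh in seq_len(h)) {
        cols <- ((hh - 1) * d + 1):(hh * d)
        sc <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(d)
        A <- exp(sc) / rowSums(exp(sc))
        O[, cols] <- A %*% V[, cols, drop = FALSE]
      }
      att[rows, ] <- O %*% p$Wo + rep(p$bo, each = S)
    }
    out <- out + att
    yn <- ln_mat(out, lay$ln2)
    f1 <- pmax(yn %*% lay$ff1$params$W + rep(lay$ff1$params$b, each = nrow(yn)), 0)
    out <- out + f1 %*% lay$ff2$params$W + rep(lay$ff2$params$b, each = nrow(yn))
  }
  ln_mat(out, stack$ln_final)
}
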