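#' Motion feature network configuration
#'
#' The MFN feeds each IMU axis (Ax, Ay, Az, Gx, Gy, Gz) of a 1024-sample
#' segment through a transformer encoder: the series is split into 16
#' tokens of 64 samples in chronological order, passed through a stack of
#' encoder layers (default 6 layers, 8 heads), and the 16 x 64 encoder
#' output is flattened and mapped by one fully connected layer to a 128-d
#' feature vector per axis.
#'
#' @param tokens,token_dim tokenization shape; `tokens * token_dim` must
#'   equal the segment length (16 x 64 = 1024).
#' @param layers,heads encoder depth and attention heads; `token_dim` must
#'   be divisible by `heads`.
#' @param feedforward_dim inner dimension of the position-wise FFN (256,
#'   the standard 4x ratio).
#' @param feature_dim output feature dimension per axis (128).
#' @param positional_encoding `"sinusoidal"` (default; temporal order
#'   matters for motion) or `"none"`.
#' @param weight_sharing `"shared"` (one encoder serves all six axes),
#'   `"per-sensor"` (one for accelerometer, one for gyroscope) or
#'   `"per-axis"` (six encoders).
#' @return A named list of settings.
#' @export
mfn_config <- function(tokens = 16L, token_dim = 64L, layers = 6L, heads = 8L,
                       feedforward_dim = 256L, feature_dim = 128L,
                       positional_encoding = c("sinusoidal", "none"),
                       weight_sharing = c("shared", "per-sensor", "per-axis")) {
  tokens <- as.integer(tokens); token_dim <- as.integer(token_dim)
  if (token_dim %% as.integer(heads) != 0L)
    stop("token_dim must be divisible by heads")
  list(tokens = tokens, token_dim = token_dim, layers = as.integer(layers),
       heads = as.integer(heads), feedforward_dim = as.integer(feedforward_dim),
       feature_dim = as.integer(feature_dim),
       positional_encoding = match.arg(positional_encoding),
       weight_sharing = match.arg(weight_sharing))
}

#' Tokenize a 1024-sample axis into a 16 x 64 matrix
#'
#' Token `i` (0-based) holds samples `64*i .. 64*(i+1)-1`; no overlap, no
#' padding, so concatenating the rows in order reproduces the input.
#'
#' @param series numeric vector of length `tokens * token_dim` (1024).
#' @param tokens,token_dim tokenization shape.
#' @return `tokens` x `token_dim` matrix.
#' @export
tokenize_axis <- function(series, tokens = 16L, token_dim = 64L) {
  if (length(series) != tokens * token_dim)
    stop(sprintf("series length %d != %d x %d", length(series), tokens, token_dim))
  matrix(series, nrow = tokens, ncol = token_dim, byrow = TRUE)
}

axis_names <- function() c("Ax", "Ay", "Az", "Gx", "Gy", "Gz")

# Which encoder index serves each of the six axes, per sharing policy.
encoder_assignment <- function(weight_sharing) {
  switch(weight_sharing,
         shared = rep(1L, 6L),
         `per-sensor` = c(1L, 1L, 1L, 2L, 2L, 2L),
         `per-axis` = 1:6)
}

#' Build the motion feature network
#'
#' @param config an [mfn_config()].
#' @return An `mfn_model` object.
#' @export
build_mfn <- function(config = mfn_config()) {
  self <- new_nn_layer("mfn")
  assign_ <- encoder_assignment(config$weight_sharing)
  n_enc <- max(assign_)
  self$encoders <- lapply(seq_len(n_enc), function(i)
    encoder_stack(config$token_dim, config$heads, config$layers,
                  config$feedforward_dim, config$tokens, config$positional_encoding))
  self$proj <- lapply(seq_len(n_enc), function(i)
    layer_dense(config$tokens * config$token_dim, config$feature_dim,
                init_sd = sqrt(1 / (config$tokens * config$token_dim))))
  self$assign <- assign_
  self$config <- config
  self$children <- c(self$encoders, self$proj)

  # x: list of six (n*S) x D token matrices in axis order.
  self$forward <- function(x, train = TRUE) {
    feats <- vector("list", 6L)
    self$enc_groups <- vector("list", n_enc)
    for (e in seq_len(n_enc)) {
      ax <- which(self$assign == e)
      xin <- do.call(rbind, x[ax])
      h <- self$encoders[[e]]$forward(xin, train)
      flat <- seq_flatten(h, config$tokens)
      z <- self$proj[[e]]$forward(flat, train)
      nper <- nrow(z) / length(ax)
      for (k in seq_along(ax)) {
        feats[[ax[k]]] <- z[((k - 1) * nper + 1):(k * nper), , drop = FALSE]
      }
      self$enc_groups[[e]] <- list(ax = ax, nper = nper)
    }
    names(feats) <- axis_names()
    feats
  }

  # dfeats: list of six n x feature_dim gradient matrices. Input gradients
  # are not needed (tokens are raw data), so backward returns NULL.
  self$backward <- function(dfeats) {
    for (e in seq_len(n_enc)) {
      gi <- self$enc_groups[[e]]
      dz <- do.call(rbind, dfeats[gi$ax])
      dflat <- self$proj[[e]]$backward(dz)
      dh <- seq_unflatten(dflat, config$tokens, config$token_dim)
      self$encoders[[e]]$backward(dh)
    }
    invisible(NULL)
  }
  class(self) <- c("mfn_model", class(self))
  self
}

# Stack segments into the per-axis token matrices build_mfn() consumes:
# a list of six (n_segments * tokens) x token_dim matrices.
segments_to_tokens <- function(segments, tokens = 16L, token_dim = 64L) {
  pull <- list(
    function(s) s$A[1, ], function(s) s$A[2, ], function(s) s$A[3, ],
    function(s) s$G[1, ], function(s) s$G[2, ], function(s) s$G[3, ]
  )
  out <- lapply(pull, function(f) {
    do.call(rbind, lapply(segments, function(s) tokenize_axis(f(s), tokens, token_dim)))
  })
  names(out) <- axis_names()
  out
}

#' Extract the six per-axis motion features of segments
#'
#' @param model a [build_mfn()] model.
#' @param segments list of segments (normalized `A`, `G` channels of
#'   length 1024), or a list of six token matrices.
#' @return Named list of six n x feature_dim matrices
#'   (`Zax, Zay, Zaz, Zgx, Zgy, Zgz`).
#' @export
extract_motion_features <- function(model, segments) {
  x <- if (is.matrix(segments[[1]]) && length(segments) == 6L) segments
       else segments_to_tokens(segments, model$config$tokens, model$config$token_dim)
  feats <- model$forward(x, train = FALSE)
  names(feats) <- c("Zax", "Zay", "Zaz", "Zgx", "Zgy", "Zgz")
  feats
}
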