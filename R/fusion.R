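#' Concatenate per-axis motion features into per-sensor vectors
#'
#' `Za = [Zax || Zay || Zaz]`, `Zg = [Zgx || Zgy || Zgz]` (fixed x, y, z
#' order), giving 384-d accelerometer and gyroscope feature vectors from
#' six 128-d axis features.
#'
#' @param motion named list of six n x d matrices from
#'   [extract_motion_features()].
#' @return `list(Za, Zg)` of n x 3d matrices.
#' @export
concat_axis_features <- function(motion) {
  list(Za = cbind(motion$Zax, motion$Zay, motion$Zaz),
       Zg = cbind(motion$Zgx, motion$Zgy, motion$Zgz))
}

#' Low-rank multimodal fusion factors
#'
#' The multilinear fusion `Zm = W (Za (x) Zg (x) Zl) + b` is computed
#' without materializing the outer-product tensor by writing the weight
#' tensor as a sum of `r` rank-one factors: `Zm = b + sum_i (wa_i Za') *
#' (wg_i Zg') * (wl_i Zl')` (elementwise products), where each modality
#' vector is augmented with a trailing constant 1 (so unimodal and
#' bimodal terms survive the product; switchable).
#'
#' @param dims integer vector of modality input dimensions (2 or 3
#'   modalities), e.g. `c(384, 384, 128)`.
#' @param output_dim fused feature dimension (512).
#' @param rank number of rank-one factors `r` (4).
#' @param augment_ones append a trailing 1 to each modality before
#'   projection (default `TRUE`).
#' @param init_sd factor initialization sd.
#' @return A `fusion_factors` list with per-modality factor arrays
#'   `(dim + augment) x output_dim x rank` and a bias of length
#'   `output_dim` (initialized to zero).
#' @export
fusion_factors <- function(dims, output_dim = 512L, rank = 4L,
                           augment_ones = TRUE, init_sd = 0.05) {
  if (rank < 1L) stop("rank must be >= 1")
  d_in <- dims + as.integer(augment_ones)
  W <- lapply(d_in, function(d)
    array(stats::rnorm(d * output_dim * rank, sd = init_sd), c(d, output_dim, rank)))
  structure(list(W = W, b = numeric(output_dim), dims = as.integer(dims),
                 output_dim = as.integer(output_dim), rank = as.integer(rank),
                 augment_ones = augment_ones),
            class = "fusion_factors")
}

augment1 <- function(x) cbind(x, 1)

#' Fuse modality features by low-rank multimodal fusion
#'
#' `Zm = b + sum_{i=1..r} (wa_i Za') * (wg_i Zg') * (wl_i Zl')` where `*`
#' is the elementwise product and `'` marks the trailing-1 augmentation.
#' Cost is linear in the rank and in each modality dimension; no
#' intermediate of size `da * dg * dl` is ever allocated.
#'
#' @param factors a [fusion_factors()].
#' @param ... one matrix (n x dim) per modality, in the order of
#'   `factors$dims` (e.g. `Za, Zg, Zl`).
#' @return n x output_dim fused feature matrix `Zm`.
#' @export
lmf_fuse <- function(factors, ...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !is.matrix(xs[[1]])) xs <- xs[[1]]
  if (length(xs) != length(factors$dims))
    stop(sprintf("expected %d modalities, got %d", length(factors$dims), length(xs)))
  xs <- lapply(xs, function(x) if (is.matrix(x)) x else matrix(x, nrow = 1))
  for (m in seq_along(xs)) {
    if (ncol(xs[[m]]) != factors$dims[m])
      stop(sprintf("modality %d has dimension %d, factors expect %d",
                   m, ncol(xs[[m]]), factors$dims[m]))
  }
  if (factors$augment_ones) xs <- lapply(xs, augment1)
  n <- nrow(xs[[1]])
  out <- matrix(factors$b, n, factors$output_dim, byrow = TRUE)
  for (i in seq_len(factors$rank)) {
    prod_i <- xs[[1]] %*% factors$W[[1]][, , i]
    for (m in seq_along(xs)[-1]) prod_i <- prod_i * (xs[[m]] %*% factors$W[[m]][, , i])
    out <- out + prod_i
  }
  out
}

#' Brute-force full-tensor fusion oracle
#'
#' Materializes the weight tensor `W = sum_i wa_i (x) wg_i (x) wl_i`
#' explicitly, forms the outer-product tensor `Z = Za' (x) Zg' (x) Zl'`,
#' contracts them, and adds the bias. Exponential in the number of
#' modalities, so it refuses dimension products above `1e6`; it exists to
#' pin down the semantics that [lmf_fuse()] computes cheaply.
#'
#' @inheritParams lmf_fuse
#' @return n x output_dim matrix, equal to [lmf_fuse()] up to float error.
#' @export
full_tensor_oracle <- function(factors, ...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !is.matrix(xs[[1]])) xs <- xs[[1]]
  xs <- lapply(xs, function(x) if (is.matrix(x)) x else matrix(x, nrow = 1))
  if (factors$augment_ones) xs <- lapply(xs, augment1)
  d_in <- vapply(xs, ncol, 0L)
  if (prod(as.numeric(d_in)) * factors$output_dim > 1e6)
    stop("dimension product too large for the full-tensor oracle")
  # W[j1, ..., jM, o] = sum_i prod_m w_m[j_m, o, i], flattened to
  # (d1*...*dM) x output_dim with j1 fastest (matching outer()).
  Wm <- matrix(0, prod(d_in), factors$output_dim)
  for (i in seq_len(factors$rank)) {
    for (o in seq_len(factors$output_dim)) {
      cols <- lapply(seq_along(xs), function(m) factors$W[[m]][, o, i])
      Wm[, o] <- Wm[, o] + as.vector(Reduce(outer, cols))
    }
  }
  n <- nrow(xs[[1]])
  out <- matrix(0, n, factors$output_dim)
  for (s in seq_len(n)) {
    Z <- Reduce(outer, lapply(xs, function(x) x[s, ]))   # outer-product tensor
    out[s, ] <- as.vector(crossprod(Wm, as.vector(Z))) + factors$b
  }
  out
}

# Trainable LMF layer wrapping fusion_factors with backprop.
layer_lmf <- function(dims, output_dim, rank, augment_ones = TRUE, init_sd = 0.05) {
  self <- new_nn_layer("lmf")
  f <- fusion_factors(dims, output_dim, rank, augment_ones, init_sd)
  self$params <- c(stats::setNames(f$W, paste0("W", seq_along(f$W))), list(b = f$b))
  self$grads <- lapply(self$params, function(p) p * 0)
  self$dims <- f$dims; self$output_dim <- f$output_dim
  self$rank <- f$rank; self$augment_ones <- augment_ones
  self$nmod <- length(dims)

  self$factors <- function() {
    structure(list(W = unname(self$params[seq_len(self$nmod)]), b = self$params$b,
                   dims = self$dims, output_dim = self$output_dim,
                   rank = self$rank, augment_ones = self$augment_ones),
              class = "fusion_factors")
  }
  self$forward <- function(xs, train = TRUE) {
    if (self$augment_ones) xs <- lapply(xs, augment1)
    self$xs <- xs
    n <- nrow(xs[[1]])
    self$P <- vector("list", self$rank)
    out <- matrix(self$params$b, n, self$output_dim, byrow = TRUE)
    for (i in seq_len(self$rank)) {
      Pi <- lapply(seq_len(self$nmod), function(m) xs[[m]] %*% self$params[[m]][, , i])
      self$P[[i]] <- Pi
      out <- out + Reduce(`*`, Pi)
    }
    out
  }
  self$backward <- function(dy) {
    dxs <- lapply(self$xs, function(x) x * 0)
    for (i in seq_len(self$rank)) {
      Pi <- self$P[[i]]
      for (m in seq_len(self$nmod)) {
        others <- Reduce(`*`, Pi[-m], matrix(1, nrow(dy), ncol(dy)))
        dPm <- dy * others
        self$grads[[m]][, , i] <- self$grads[[m]][, , i] + crossprod(self$xs[[m]], dPm)
        dxs[[m]] <- dxs[[m]] + dPm %*% t(self$params[[m]][, , i])
      }
    }
    self$grads$b <- self$grads$b + colSums(dy)
    if (self$augment_ones) dxs <- lapply(dxs, function(d) d[, -ncol(d), drop = FALSE])
    dxs
  }
  self
}

#' Build the activity classification head
#'
#' The recognizer head: one fully connected layer from the fused feature
#' to the six activity classes, followed by softmax.
#'
#' @param input_dim fused feature dimension (512).
#' @param num_classes number of activities (6).
#' @return A dense layer module.
#' @export
build_activity_head <- function(input_dim = 512L, num_classes = 6L) {
  layer_dense(input_dim, num_classes, init_sd = sqrt(1 / input_dim))
}

#' Classify activities from fused features
#'
#' @param head a [build_activity_head()] layer.
#' @param Zm n x input_dim fused feature matrix.
#' @return `list(activity, probs)`: predicted labels and n x 6 softmax
#'   probabilities (rows sum to 1).
#' @export
classify_activity <- function(head, Zm) {
  if (!is.matrix(Zm)) Zm <- matrix(Zm, nrow = 1)
  logits <- head$forward(Zm, train = FALSE)
  p <- softmax_rows(logits)
  list(activity = activities()[max.col(p, ties.method = "first")], probs = p)
}
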