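#' Location feature network configuration
#'
#' The LFN is a ResNet18-topology convolutional network over 32 x 32
#' location images whose classification layer is replaced by two fully
#' connected heads: 512 -> 128 (the location feature) and 128 -> 6 (room
#' softmax). The stem is adapted to 32 x 32 inputs: a 3 x 3 stride-1 first
#' convolution and no initial max-pool (a 224 x 224 stem would collapse
#' such small maps). `widths`/`blocks` default to the ResNet18 plan
#' (64/128/256/512, two basic blocks per stage) and can be scaled down for
#' small experiments.
#'
#' @param use_light include the ambient-light plane (4-channel input);
#'   `FALSE` gives the 3-channel geomagnetic-only variant.
#' @param num_rooms number of room classes (6).
#' @param feature_dim location feature dimension (128).
#' @param widths,blocks per-stage channel widths and block counts.
#' @param norm `"batch"` (batch normalization, the ResNet18 canon) or
#'   `"none"` (normalization-free residual blocks). Absolute channel
#'   levels carry the room signature in location images, and small-batch
#'   batch-norm lets the network lean on batch-relative levels that do
#'   not transfer to single-sample inference; the normalization-free
#'   variant makes training and inference the same function.
#' @param init `"scratch"` (default) or `"imagenet-adapted"`; the latter
#'   adapts user-supplied 3-channel pretrained stem filters to 4 channels
#'   (4th filter = mean of the RGB filters) and requires `pretrained_stem`.
#' @param pretrained_stem optional 3 x 3 x 3 x width array of stem filters
#'   for `init = "imagenet-adapted"`.
#' @return A named list of settings.
#' @export
lfn_config <- function(use_light = TRUE, num_rooms = 6L, feature_dim = 128L,
                       widths = c(64L, 128L, 256L, 512L), blocks = c(2L, 2L, 2L, 2L),
                       norm = c("batch", "none"),
                       init = c("scratch", "imagenet-adapted"),
                       pretrained_stem = NULL) {
  list(use_light = use_light, num_rooms = as.integer(num_rooms),
       feature_dim = as.integer(feature_dim),
       widths = as.integer(widths), blocks = as.integer(blocks),
       norm = match.arg(norm),
       init = match.arg(init), pretrained_stem = pretrained_stem)
}

# Adapt a 3-channel stem filter bank (k*k*3 x C_out, or array) to 4 input
# channels: the extra channel's filters are the mean of the RGB filters.
adapt_stem_to_4ch <- function(W3, k = 3L) {
  C_out <- ncol(W3)
  W3a <- array(W3, c(k * k, 3L, C_out))
  W4 <- array(0, c(k * k, 4L, C_out))
  W4[, 1:3, ] <- W3a
  W4[, 4L, ] <- apply(W3a, c(1, 3), mean)
  matrix(W4, k * k * 4L, C_out)
}

#' Build the location feature network
#'
#' @param config an [lfn_config()].
#' @return An `lfn_model` object (backbone + 128-d feature head + room head).
#' @export
build_lfn <- function(config = lfn_config()) {
  C_in <- if (config$use_light) 4L else 3L
  backbone <- resnet_backbone(C_in, config$widths, config$blocks,
                              norm = config$norm %||% "batch")
  fc1 <- layer_dense(backbone$out_dim, config$feature_dim)
  relu1 <- layer_relu()
  fc2 <- layer_dense(config$feature_dim, config$num_rooms)
  if (config$init == "imagenet-adapted") {
    if (is.null(config$pretrained_stem))
      stop("init='imagenet-adapted' needs `pretrained_stem` (3-channel stem filters); ",
           "no pretrained weights ship with the package")
    W <- config$pretrained_stem
    if (is.array(W) && length(dim(W)) == 4L) W <- matrix(W, dim(W)[1] * dim(W)[2] * dim(W)[3], dim(W)[4])
    if (config$use_light) W <- adapt_stem_to_4ch(W)
    if (!all(dim(W) == dim(backbone$stem_conv$params$W)))
      stop("pretrained stem filters do not match the stem geometry")
    backbone$stem_conv$params$W <- W
  }
  self <- new_nn_layer("lfn")
  self$backbone <- backbone
  self$fc1 <- fc1; self$relu1 <- relu1; self$fc2 <- fc2
  self$config <- config
  self$children <- list(backbone, fc1, fc2)
  self$forward <- function(x, train = TRUE) {
    feat <- self$relu1$forward(self$fc1$forward(self$backbone$forward(x, train), train), train)
    list(feature = feat, logits = self$fc2$forward(feat, train))
  }
  self$backward_logits <- function(dlogits) {
    dfeat <- self$fc2$backward(dlogits)
    self$backbone$backward(self$fc1$backward(self$relu1$backward(dfeat)))
  }
  class(self) <- c("lfn_model", class(self))
  self
}

# Stack a list of segments into the image ctensor the LFN consumes.
segments_to_images <- function(segments, use_light = TRUE) {
  C <- if (use_light) 4L else 3L
  N <- length(segments)
  arr <- array(0, c(32L, 32L, C, N))
  for (i in seq_len(N)) {
    img <- segments[[i]]$image
    if (is.null(img)) stop("segment has no location image; run preprocess_sessions()")
    arr[, , , i] <- img[, , seq_len(C)] / 255 - 0.5
  }
  images_to_ctensor(arr)
}

# Training-time heading augmentation: rotate the horizontal magnetometer
# pair by a random angle per segment and re-form the image, so the network
# must learn heading-invariant room features instead of memorizing the
# headings present in the training sessions.
augmented_images <- function(segments, use_light = TRUE) {
  C <- if (use_light) 4L else 3L
  N <- length(segments)
  arr <- array(0, c(32L, 32L, C, N))
  for (i in seq_len(N)) {
    g <- segments[[i]]
    if (is.null(g$image_bounds)) return(segments_to_images(segments, use_light))
    th <- stats::runif(1, 0, 2 * pi)
    B <- g$B_raw
    g$B_raw <- rbind(cos(th) * B[1, ] - sin(th) * B[2, ],
                     sin(th) * B[1, ] + cos(th) * B[2, ],
                     B[3, ])
    img <- form_location_image(g, g$image_bounds)
    arr[, , , i] <- img[, , seq_len(C)] / 255 - 0.5
  }
  images_to_ctensor(arr)
}

#' Train the LFN room classifier
#'
#' Adam + cross-entropy over room labels. Defaults follow the reference
#' recipe: batch size 32, learning rate 0.01, 300 epochs — scale `epochs`
#' down for small experiments.
#'
#' @param model a [build_lfn()] model.
#' @param train_segments list of segments carrying `image` and `room`.
#' @param batch_size,epochs,lr training hyperparameters.
#' @param lr_final learning rate at the last epoch (linear decay from
#'   `lr`; default constant).
#' @param augment_yaw rotate the horizontal magnetometer pair of each
#'   training sample by a fresh random heading each epoch (the phone's
#'   heading is uncontrolled, so room identity must not depend on it).
#' @param seed integer controlling shuffling and augmentation (and nothing
#'   else; build the model under its own seed).
#' @param verbose print epoch losses.
#' @return `list(model, history)` where `history$loss` has one mean loss
#'   per epoch.
#' @export
train_lfn <- function(model, train_segments, batch_size = 32L, epochs = 300L,
                      lr = 0.01, lr_final = lr, augment_yaw = TRUE, seed = 0L,
                      verbose = FALSE) {
  if (length(train_segments) == 0L) stop("empty training set")
  y <- match(vapply(train_segments, `[[`, "", "room"), rooms())
  opt <- adam_new(model, lr = lr)
  losses <- numeric(0)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      if (epochs > 1L) opt$lr <- lr + (lr_final - lr) * (ep - 1) / (epochs - 1)
      ord <- sample.int(length(train_segments))
      ep_loss <- 0; nb <- 0L
      for (b0 in seq(1L, length(ord), by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
        x <- if (augment_yaw) augmented_images(train_segments[idx], model$config$use_light)
             else segments_to_images(train_segments[idx], model$config$use_light)
        nn_zero_grads(model)
        out <- model$forward(x, train = TRUE)
        ce <- softmax_xent(out$logits, y[idx])
        model$backward_logits(ce$dlogits)
        adam_step(opt)
        ep_loss <- ep_loss + ce$loss; nb <- nb + 1L
      }
      losses <- c(losses, ep_loss / nb)
      if (verbose) message(sprintf("lfn epoch %d loss %.4f", ep, ep_loss / nb))
    }
    bn_recalibrate(model, function() {
      for (b0 in seq(1L, length(train_segments), by = batch_size)) {
        idx <- b0:min(b0 + batch_size - 1L, length(train_segments))
        x <- segments_to_images(train_segments[idx], model$config$use_light)
        model$forward(x, train = TRUE)
      }
    })
  })
  list(model = model, history = list(loss = losses))
}

#' Classify the room of location images
#'
#' @param model a trained [build_lfn()] model.
#' @param segments list of segments (with `image`), or a single 32x32xC array.
#' @return `list(room, probs)`: predicted labels and an n x 6 probability
#'   matrix (rows sum to 1).
#' @export
classify_room <- function(model, segments) {
  if (is.array(segments)) {
    arr <- array(segments, c(32L, 32L, dim(segments)[3], 1L))
    x <- images_to_ctensor(arr / 255 - 0.5)
  } else {
    x <- segments_to_images(segments, model$config$use_light)
  }
  out <- model$forward(x, train = FALSE)
  p <- softmax_rows(out$logits)
  list(room = rooms()[max.col(p, ties.method = "first")], probs = p)
}

#' Extract 128-d location features
#'
#' Drops the room-classification head and returns the penultimate
#' fully-connected activation for each segment.
#'
#' @param model a trained [build_lfn()] model.
#' @param segments list of segments (with `image`), or a single array.
#' @return n x feature_dim matrix.
#' @export
extract_location_feature <- function(model, segments) {
  if (is.array(segments)) {
    arr <- array(segments, c(32L, 32L, dim(segments)[3], 1L))
    x <- images_to_ctensor(arr / 255 - 0.5)
  } else {
    x <- segments_to_images(segments, model$config$use_light)
  }
  model$forward(x, train = FALSE)$feature
}

#' Save / load model checkpoints
#'
#' Single-file serialized weights plus configuration for any model built by
#' this package ([build_lfn()], [build_mfn()], composite recognizers).
#'
#' @param model model object.
#' @param path file path.
#' @return `load_checkpoint` returns the rebuilt model.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(kind = model$kind, config = model$config, state = nn_get_state(model))
  if (identical(model$kind, "lm_iar") && !is.null(model$lfn)) {
    obj$lfn <- list(config = model$lfn$config, state = nn_get_state(model$lfn))
  }
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param builder optional function(config) rebuilding the architecture;
#'   inferred from `kind` for models this package builds.
#' @export
load_checkpoint <- function(path, builder = NULL) {
  obj <- readRDS(path)
  if (is.null(builder)) {
    builder <- switch(obj$kind,
      lfn = build_lfn,
      mfn = build_mfn,
      lm_iar = function(cfg) build_composite_from_config(cfg),
      stop("unknown checkpoint kind: ", obj$kind))
  }
  model <- builder(obj$config)
  nn_set_state(model, obj$state)
  if (identical(obj$kind, "lm_iar") && !is.null(obj$lfn)) {
    lfn <- build_lfn(obj$lfn$config)
    nn_set_state(lfn, obj$lfn$state)
    model$lfn <- lfn
  }
  model
}
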