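#' Dataset splitting specification
#'
#' @param train_fraction fraction of units in the training side (0.8).
#' @param unit `"sequence"` (default: all segments of one recording fall on
#'   the same side, preventing leakage between overlapping windows),
#'   `"segment"`, or `"subject"` (train on some users, test on others).
#' @param seed integer controlling the draw.
#' @return A named list of settings.
#' @export
split_spec <- function(train_fraction = 0.8, unit = c("sequence", "segment", "subject"),
                       seed = 0L) {
  if (train_fraction <= 0 || train_fraction >= 1) stop("train_fraction must be in (0,1)")
  list(train_fraction = train_fraction, unit = match.arg(unit), seed = as.integer(seed))
}

#' Split segments into train and test sets
#'
#' Deterministic under the spec's seed. The draw is stratified by class
#' (activity label, or room for unlabeled location sessions): 80/20 is
#' applied within every class so no class can vanish from either side.
#' Warns if one still does (e.g. a class with a single sequence).
#'
#' @param segments list of labeled segments.
#' @param spec a [split_spec()].
#' @return `list(train, test)` of segment lists.
#' @export
split_dataset <- function(segments, spec = split_spec()) {
  if (length(segments) == 0L) stop("no segments to split")
  key <- switch(spec$unit,
    segment = as.character(seq_along(segments)),
    sequence = vapply(segments, `[[`, "", "session_id"),
    subject = vapply(segments, function(s) s$subject_id %||% NA_character_, "")
  )
  cls <- vapply(segments, function(s) {
    if (!is.null(s$activity) && !is.na(s$activity)) s$activity else s$room
  }, "")
  unit_cls <- tapply(cls, key, function(v) v[1])
  units <- names(unit_cls)
  train_units <- with_seed(spec$seed, {
    unlist(lapply(split(units, unit_cls[units]), function(u) {
      n_tr <- max(1L, min(length(u) - 1L, round(spec$train_fraction * length(u))))
      if (length(u) == 1L) u else sample(u, n_tr)
    }), use.names = FALSE)
  })
  is_train <- key %in% train_units
  out <- list(train = segments[is_train], test = segments[!is_train])
  labs <- vapply(segments, function(s) s$activity %||% NA_character_, "")
  for (cl in stats::na.omit(unique(labs))) {
    if (!cl %in% labs[is_train] || !cl %in% labs[!is_train])
      warning("class '", cl, "' is absent from one side of the split")
  }
  out
}

build_composite_from_config <- function(cfg) {
  with_seed(cfg$init_seed %||% 0L, {
    mfn <- build_mfn(do.call(mfn_config, cfg$mfn))
    d3 <- 3L * mfn$config$feature_dim
    dims <- if (cfg$variant == "M-IAR") c(d3, d3) else c(d3, d3, cfg$lfn_feature_dim)
    lmf <- layer_lmf(dims, cfg$fusion$output_dim, cfg$fusion$rank, cfg$fusion$augment_ones)
    head <- build_activity_head(cfg$fusion$output_dim, 6L)
    composite_model(cfg$variant, NULL, mfn, lmf, head, cfg)
  })
}

composite_model <- function(variant, lfn, mfn, lmf, head, cfg) {
  self <- new_nn_layer("lm_iar")
  self$variant <- variant
  self$lfn <- lfn
  self$mfn <- mfn
  self$lmf <- lmf
  self$head <- head
  self$config <- cfg
  # the frozen LFN is deliberately NOT a child: stage-2 optimization and
  # gradient flow never touch it
  self$children <- list(mfn, lmf, head)
  class(self) <- c("lm_iar_model", class(self))
  self
}

composite_forward <- function(model, tokens, Zl, train = TRUE) {
  feats <- model$mfn$forward(tokens, train)
  names(feats) <- c("Zax", "Zay", "Zaz", "Zgx", "Zgy", "Zgz")
  cc <- concat_axis_features(feats)
  xs <- if (model$variant == "M-IAR") list(cc$Za, cc$Zg) else list(cc$Za, cc$Zg, Zl)
  Zm <- model$lmf$forward(xs, train)
  model$head$forward(Zm, train)
}

composite_backward <- function(model, dlogits) {
  dZm <- model$head$backward(dlogits)
  dxs <- model$lmf$backward(dZm)
  d <- model$mfn$config$feature_dim
  sp <- function(m) list(m[, 1:d, drop = FALSE], m[, (d + 1):(2 * d), drop = FALSE],
                         m[, (2 * d + 1):(3 * d), drop = FALSE])
  dfeats <- c(sp(dxs[[1]]), sp(dxs[[2]]))
  model$mfn$backward(dfeats)   # location branch is frozen: dxs[[3]] is dropped
  invisible(NULL)
}

# Location features for all segments under a frozen LFN, in chunks.
precompute_location_features <- function(lfn, segments, chunk = 64L) {
  out <- matrix(0, length(segments), lfn$config$feature_dim)
  for (b0 in seq(1L, length(segments), by = chunk)) {
    idx <- b0:min(b0 + chunk - 1L, length(segments))
    out[idx, ] <- extract_location_feature(lfn, segments[idx])
  }
  out
}

#' Train the indoor activity recognizer (stage 2)
#'
#' Builds the motion encoder, fusion layer and activity head, and trains
#' them jointly with Adam and cross-entropy on activity labels. For the
#' location-aware variants a pretrained LFN is required; its weights are
#' frozen (it is excluded from the optimizer and no gradient flows into
#' it), and its 128-d features are precomputed once. `"M-IAR"` drops the
#' location branch entirely and fuses only the accelerometer and gyroscope
#' features with a two-modality LMF.
#'
#' @param train_segments preprocessed segments with activity labels.
#' @param variant `"LM-IAR"`, `"LM-IAR-nl"`, or `"M-IAR"`.
#' @param lfn pretrained [build_lfn()] model (required unless `"M-IAR"`);
#'   for `"LM-IAR-nl"` it must have been built with `use_light = FALSE`.
#' @param mfn_opts arguments for [mfn_config()].
#' @param fusion_opts list with `rank` (4), `output_dim` (512),
#'   `augment_ones` (TRUE).
#' @param epochs,batch_size,lr stage-2 hyperparameters (Adam, lr 0.001).
#' @param seed controls initialization and shuffling.
#' @param verbose print epoch losses.
#' @return `list(model, history)`; `model` is an `lm_iar_model`.
#' @export
train_lm_iar <- function(train_segments, variant = c("LM-IAR", "LM-IAR-nl", "M-IAR"),
                         lfn = NULL, mfn_opts = list(), fusion_opts = list(),
                         epochs = 30L, batch_size = 32L, lr = 0.001,
                         seed = 0L, verbose = FALSE) {
  variant <- match.arg(variant)
  if (length(train_segments) == 0L) stop("empty training set")
  if (variant != "M-IAR" && is.null(lfn))
    stop("variant ", variant, " requires a pretrained LFN model/checkpoint")
  if (variant == "LM-IAR-nl" && !is.null(lfn) && lfn$config$use_light)
    warning("LM-IAR-nl expects an LFN trained without the light channel")
  fusion_opts <- utils::modifyList(list(rank = 4L, output_dim = 512L, augment_ones = TRUE),
                                   fusion_opts)
  mcfg <- do.call(mfn_config, mfn_opts)
  y <- match(vapply(train_segments, `[[`, "", "activity"), activities())
  if (anyNA(y)) stop("all training segments need activity labels")
  tokens_all <- segments_to_tokens(train_segments, mcfg$tokens, mcfg$token_dim)
  Zl_all <- if (variant == "M-IAR") NULL else precompute_location_features(lfn, train_segments)
  S <- mcfg$tokens
  model <- NULL
  losses <- numeric(0)
  with_seed(seed, {
    mfn <- build_mfn(mcfg)
    d3 <- 3L * mcfg$feature_dim
    dims <- if (variant == "M-IAR") c(d3, d3) else c(d3, d3, lfn$config$feature_dim)
    lmf <- layer_lmf(dims, fusion_opts$output_dim, fusion_opts$rank, fusion_opts$augment_ones)
    head <- build_activity_head(fusion_opts$output_dim, 6L)
    cfg <- list(variant = variant, mfn = mfn_opts, fusion = fusion_opts,
                lfn_feature_dim = if (is.null(lfn)) NULL else lfn$config$feature_dim,
                init_seed = seed)
    model <- composite_model(variant, lfn, mfn, lmf, head, cfg)
    opt <- adam_new(model, lr = lr)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(train_segments))
      ep_loss <- 0; nb <- 0L
      for (b0 in seq(1L, length(ord), by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
        rows <- as.vector(t(outer((idx - 1L) * S, seq_len(S), "+")))
        tk <- lapply(tokens_all, function(m) m[rows, , drop = FALSE])
        Zl <- if (is.null(Zl_all)) NULL else Zl_all[idx, , drop = FALSE]
        nn_zero_grads(model)
        logits <- composite_forward(model, tk, Zl, train = TRUE)
        ce <- softmax_xent(logits, y[idx])
        composite_backward(model, ce$dlogits)
        adam_step(opt)
        ep_loss <- ep_loss + ce$loss; nb <- nb + 1L
      }
      losses <- c(losses, ep_loss / nb)
      if (verbose) message(sprintf("%s epoch %d loss %.4f", variant, ep, ep_loss / nb))
    }
  })
  list(model = model, history = list(loss = losses))
}

#' Predict activities for segments
#'
#' @param model an `lm_iar_model` from [train_lm_iar()].
#' @param segments preprocessed segments.
#' @return `list(activity, probs)`.
#' @export
predict_activity <- function(model, segments) {
  mcfg <- model$mfn$config
  S <- mcfg$tokens
  n <- length(segments)
  probs <- matrix(0, n, 6L)
  chunk <- 64L
  for (b0 in seq(1L, n, by = chunk)) {
    idx <- b0:min(b0 + chunk - 1L, n)
    tk <- segments_to_tokens(segments[idx], S, mcfg$token_dim)
    Zl <- if (model$variant == "M-IAR") NULL
          else precompute_location_features(model$lfn, segments[idx])
    logits <- composite_forward(model, tk, Zl, train = FALSE)
    probs[idx, ] <- softmax_rows(logits)
  }
  list(activity = activities()[max.col(probs, ties.method = "first")], probs = probs)
}

#' Evaluate a trained recognizer
#'
#' Top-1 accuracy (fraction of test segments whose argmax prediction
#' equals the label) and the 6 x 6 confusion matrix (rows = true class,
#' columns = predicted).
#'
#' @param model an `lm_iar_model`.
#' @param test_segments labeled segments.
#' @return `list(top1, confusion, n_test, class_names)`.
#' @export
evaluate_model <- function(model, test_segments) {
  if (length(test_segments) == 0L) stop("empty test set")
  truth <- vapply(test_segments, `[[`, "", "activity")
  pred <- predict_activity(model, test_segments)$activity
  cls <- activities()
  confusion <- table(factor(truth, levels = cls), factor(pred, levels = cls))
  confusion <- matrix(as.integer(confusion), 6L, 6L, dimnames = list(cls, cls))
  list(top1 = mean(pred == truth), confusion = confusion,
       n_test = length(test_segments), class_names = cls)
}

#' Run the ablation harness
#'
#' Trains and evaluates the three model variants (`LM-IAR`, `LM-IAR-nl`,
#' `M-IAR`) under identical splits and seeds: per seed, the activity
#' segments are split by sequence, an LFN is pretrained on room labels
#' (with and without the light channel) using the training side plus any
#' location-survey segments, stage 2 is trained per variant, and each is
#' evaluated on the held-out side.
#'
#' @param segments preprocessed activity-labeled segments.
#' @param seeds integer vector; one full run per seed.
#' @param survey_segments optional location-only segments added to LFN
#'   pretraining.
#' @param lfn_opts arguments for [lfn_config()] (minus `use_light`).
#' @param lfn_train list with `epochs`, `batch_size`, `lr` for stage 1.
#' @param mfn_opts,fusion_opts,stage2 architecture and stage-2 training
#'   settings passed to [train_lm_iar()].
#' @param variants subset of the three model variants to train.
#' @param verbose print progress.
#' @return A data.frame `variant x seed -> top1`; per-run evaluation
#'   reports (with confusion matrices) in `attr(, "reports")`.
#' @export
run_ablation <- function(segments, seeds = 0:2, survey_segments = list(),
                         lfn_opts = list(), lfn_train = list(),
                         mfn_opts = list(), fusion_opts = list(),
                         stage2 = list(),
                         variants = c("LM-IAR", "LM-IAR-nl", "M-IAR"),
                         verbose = FALSE) {
  lfn_train <- utils::modifyList(
    list(epochs = 8L, batch_size = 32L, lr = 0.002, lr_final = 4e-4), lfn_train)
  stage2 <- utils::modifyList(list(epochs = 10L, batch_size = 32L, lr = 0.002), stage2)
  variants <- match.arg(variants, several.ok = TRUE)
  rows <- list()
  reports <- list()
  for (seed in seeds) {
    sp <- split_dataset(segments, split_spec(0.8, "sequence", seed))
    lfn_pool <- c(sp$train, survey_segments)
    lfns <- list()
    need_light <- "LM-IAR" %in% variants
    need_nolight <- "LM-IAR-nl" %in% variants
    for (ul in c(TRUE, FALSE)[c(need_light, need_nolight)]) {
      cfg <- do.call(lfn_config, utils::modifyList(lfn_opts, list(use_light = ul)))
      m <- with_seed(seed + 1000L, build_lfn(cfg))
      fit <- train_lfn(m, lfn_pool, batch_size = lfn_train$batch_size,
                       epochs = lfn_train$epochs, lr = lfn_train$lr,
                       lr_final = lfn_train$lr_final, seed = seed)
      lfns[[if (ul) "light" else "nolight"]] <- fit$model
    }
    for (v in variants) {
      lfn_v <- switch(v, `LM-IAR` = lfns$light, `LM-IAR-nl` = lfns$nolight, `M-IAR` = NULL)
      fit <- train_lm_iar(sp$train, v, lfn = lfn_v, mfn_opts = mfn_opts,
                          fusion_opts = fusion_opts, epochs = stage2$epochs,
                          batch_size = stage2$batch_size, lr = stage2$lr,
                          seed = seed, verbose = verbose)
      rep <- evaluate_model(fit$model, sp$test)
      rows[[length(rows) + 1L]] <- data.frame(variant = v, seed = seed, top1 = rep$top1)
      reports[[paste(v, seed, sep = "_")]] <- rep
      if (verbose) message(sprintf("seed %d %s top1 %.3f", seed, v, rep$top1))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}
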