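test_that("axis features concatenate in fixed x,y,z order", {
  set.seed(31)
  motion <- setNames(lapply(1:6, function(i) matrix(rnorm(2 * 128), 2, 128)),
                     c("Zax", "Zay", "Zaz", "Zgx", "Zgy", "Zgz"))
  cc <- concat_axis_features(motion)
  expect_equal(ncol(cc$Za), 384L)
  expect_equal(ncol(cc$Zg), 384L)
  expect_equal(cc$Za[, 1:128], motion$Zax)
  expect_equal(cc$Za[, 129:256], motion$Zay)
  expect_equal(cc$Zg[, 257:384], motion$Zgz)
  one_hot <- matrix(0, 1, 128); one_hot[1, 5] <- 1
  cc2 <- concat_axis_features(list(Zax = one_hot, Zay = one_hot * 0, Zaz = one_hot * 0,
                                   Zgx = one_hot * 0, Zgy = one_hot * 0, Zgz = one_hot * 0))
  expect_equal(which(cc2$Za != 0), 5L)
  expect_true(all(cc2$Zg == 0))
})

test_that("all-ones closed form: rank-1 fusion of ones gives the dim product", {
  f <- fusion_factors(c(2, 2, 2), output_dim = 3, rank = 1, augment_ones = FALSE)
  for (m in 1:3) f$W[[m]][] <- 1
  f$b[] <- 0
  out <- lmf_fuse(f, rep(1, 2), rep(1, 2), rep(1, 2))
  expect_equal(as.vector(out), rep(8, 3))            # 2*2*2 per component
})

test_that("rank-1 oracle matches a fully hand-expanded 2x2x2 contraction", {
  set.seed(32)
  f <- fusion_factors(c(2, 2, 2), output_dim = 1, rank = 1, augment_ones = FALSE)
  za <- rnorm(2); zg <- rnorm(2); zl <- rnorm(2)
  # Zm = sum_{p,q,s} wa[p] wg[q] wl[s] za[p] zg[q] zl[s] + b
  #    = (wa.za)(wg.zg)(wl.zl) + b
  by_hand <- sum(f$W[[1]][, 1, 1] * za) * sum(f$W[[2]][, 1, 1] * zg) *
    sum(f$W[[3]][, 1, 1] * zl) + f$b
  expect_equal(as.vector(full_tensor_oracle(f, za, zg, zl)), by_hand,
               tolerance = 1e-12)
  expect_equal(as.vector(lmf_fuse(f, za, zg, zl)), by_hand, tolerance = 1e-12)
})

test_that("lmf_fuse equals the full-tensor oracle on random configurations", {
  set.seed(33)
  worst <- 0
  for (i in 1:120) {
    dims <- sample(2:5, 3, replace = TRUE)
    out_d <- sample(1:4, 1)
    r <- sample(1:4, 1)
    aug <- i %% 2 == 0
    f <- fusion_factors(dims, out_d, r, augment_ones = aug, init_sd = 0.5)
    f$b <- rnorm(out_d)
    n <- sample(1:3, 1)
    xs <- lapply(dims, function(d) matrix(rnorm(n * d), n, d))
    a <- do.call(lmf_fuse, c(list(f), xs))
    b <- do.call(full_tensor_oracle, c(list(f), xs))
    worst <- max(worst, max(abs(a - b)) / max(abs(b)))
  }
  expect_lt(worst, 1e-4)
  # two-modality fusion agrees as well (the M-IAR path)
  f2 <- fusion_factors(c(3, 4), output_dim = 2, rank = 3, init_sd = 0.5)
  xs2 <- list(matrix(rnorm(6), 2, 3), matrix(rnorm(8), 2, 4))
  expect_equal(do.call(lmf_fuse, c(list(f2), xs2)),
               do.call(full_tensor_oracle, c(list(f2), xs2)), tolerance = 1e-8)
})

test_that("annihilation and multilinearity without augmentation", {
  set.seed(34)
  f <- fusion_factors(c(3, 3, 2), output_dim = 4, rank = 2, augment_ones = FALSE)
  f$b <- rnorm(4)
  za <- matrix(rnorm(3), 1); zg <- matrix(rnorm(3), 1); zl <- matrix(rnorm(2), 1)
  # one all-zero modality collapses the product to the bias
  expect_equal(as.vector(lmf_fuse(f, za * 0, zg, zl)), f$b)
  # scaling one modality scales Zm - b linearly
  base <- lmf_fuse(f, za, zg, zl)
  scaled <- lmf_fuse(f, 3 * za, zg, zl)
  expect_equal(sweep(scaled, 2, f$b), 3 * sweep(base, 2, f$b), tolerance = 1e-10)
})

test_that("oracle refuses dimension products that would materialize a huge tensor", {
  f <- fusion_factors(c(200, 200, 200), output_dim = 4, rank = 1)
  expect_error(full_tensor_oracle(f, rnorm(200), rnorm(200), rnorm(200)),
               "too large")
})

test_that("dimension mismatches are reported", {
  f <- fusion_factors(c(3, 3, 2), output_dim = 2, rank = 2)
  expect_error(lmf_fuse(f, rnorm(3), rnorm(3)), "modalities")
  expect_error(lmf_fuse(f, rnorm(3), rnorm(4), rnorm(2)), "dimension")
})

test_that("the trainable LMF layer computes lmf_fuse and exact gradients", {
  set.seed(35)
  lm <- lmiar:::layer_lmf(c(3, 3, 2), 4, 2)
  xs <- list(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3), matrix(rnorm(4), 2, 2))
  out <- lm$forward(xs)
  expect_equal(out, do.call(lmf_fuse, c(list(lm$factors()), xs)), tolerance = 1e-12)
  dy <- matrix(rnorm(8), 2, 4)
  dxs <- lm$backward(dy)
  for (m in 1:3) {
    fm <- function(x) { x2 <- xs; x2[[m]] <- x; sum(lm$forward(x2) * dy) }
    expect_lt(max(abs(dxs[[m]] - num_grad(fm, xs[[m]]))), 1e-7)
  }
  # no intermediate of size da*dg*dl is ever allocated: the layer stores
  # only per-rank projections of output_dim width
  expect_equal(dim(lm$P[[1]][[1]]), c(2L, 4L))
})

test_that("activity head is a calibrated softmax classifier", {
  set.seed(36)
  head <- build_activity_head(16, 6)
  Zm <- matrix(rnorm(3 * 16), 3, 16)
  out <- classify_activity(head, Zm)
  expect_equal(rowSums(out$probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(out$activity %in% activities()))
  # zero weights -> uniform probabilities
  head$params$W[] <- 0; head$params$b[] <- 0
  expect_equal(as.vector(classify_activity(head, Zm)$probs), rep(1 / 6, 18))
  # argmax invariant to adding a constant to all logits
  head2 <- build_activity_head(16, 6)
  p1 <- classify_activity(head2, Zm)$activity
  head2$params$b <- head2$params$b + 5
  expect_equal(classify_activity(head2, Zm)$activity, p1)
})
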