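test_that("trim_edges removes the configured margin and checks bounds", {
  s <- toy_session(n = 2000L)                       # 20 s at 100 Hz
  tr <- trim_edges(s, 3)
  expect_equal(length(tr$t), 1400L)                 # 3 s off each side
  expect_equal(tr$B[, 1], s$B[, 301])
  expect_identical(trim_edges(s, 0), s)
  expect_error(trim_edges(toy_session(n = 600L), 3), "too short")
})

test_that("recursive filter implements the first-order recursion", {
  expect_equal(filter_config(5)$alpha, 1 / 3)        # alpha = 2/(N+1)
  expect_error(filter_config(0), "N")

  # constant input is a fixed point (unit DC gain)
  expect_equal(recursive_filter(rep(7, 50)), rep(7, 50))
  # one-step recursion by hand: N=3 -> alpha=1/2; A1 = 0.5*0 + 0.5*1
  expect_equal(recursive_filter(1, filter_config(3), A0 = 0), 0.5)

  # matches an explicit R-level loop on random input
  set.seed(4)
  x <- rnorm(200)
  cfg <- filter_config(5)
  a <- x[1]
  ref <- numeric(200)
  for (k in seq_along(x)) {
    a <- (1 - cfg$alpha) * a + cfg$alpha * x[k]
    ref[k] <- a
  }
  out <- recursive_filter(x, cfg)
  expect_equal(out, ref, tolerance = 1e-12)
  # causal convex combination: output within the input/init range
  expect_true(all(out >= min(x, x[1]) - 1e-12 & out <= max(x, x[1]) + 1e-12))
})

test_that("min-max normalization maps to [0,1] with a zero degenerate case", {
  expect_equal(minmax_normalize(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(7, 7, 7)), c(0, 0, 0))
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(50, sd = runif(1, 0.1, 10))
    y <- minmax_normalize(x)
    expect_equal(min(y), 0)
    expect_equal(max(y), 1)
  }
})

test_that("segment count matches the enumeration oracle", {
  # oracle: count window starts explicitly
  oracle <- function(n, len, step) {
    cnt <- 0L
    s <- 0L
    while (s + len <= n) { cnt <- cnt + 1L; s <- s + step }
    cnt
  }
  for (len in c(8L, 1024L)) {
    for (step in c(1L, 200L)) {
      for (n in c(0:20, 1000:1030, 1423:1425, 5000)) {
        expect_identical(length(lmiar:::segment_starts(n, len, step)), oracle(n, len, step))
      }
    }
  }
  # closed form at the documented sizes
  expect_identical(lmiar:::segment_starts(1424L, 1024L, 200L), c(0L, 200L, 400L))
  expect_identical(length(lmiar:::segment_starts(1024L, 1024L, 200L)), 1L)
  expect_identical(length(lmiar:::segment_starts(1023L, 1024L, 200L)), 0L)
  expect_error(lmiar:::segment_starts(100L, 0L, 1L), "length")
})

test_that("segment_session windows carry labels and normalized channels", {
  s <- trim_edges(toy_session(n = 2000L), 3)        # n = 1400
  segs <- segment_session(s)
  expect_length(segs, 2L)                           # floor((1400-1024)/200)+1
  expect_equal(segs[[2]]$start_index, 200L)
  expect_equal(segs[[1]]$room, "kitchen")
  for (g in segs) {
    expect_true(all(g$A >= 0 & g$A <= 1))
    expect_true(all(g$B >= 0 & g$B <= 1))
    expect_true(all(g$L >= 0 & g$L <= 1))
    expect_equal(dim(g$B_raw), c(3L, 1024L))
  }
  # per-segment scope achieves exact 0/1 per window; session scope only overall
  seg2 <- segment_session(s, normalize_scope = "segment")
  expect_equal(min(seg2[[2]]$A[1, ]), 0)
  expect_equal(max(seg2[[2]]$A[1, ]), 1)
})

test_that("form_location_image lays samples out row-major and rescales", {
  s <- trim_edges(toy_session(n = 2000L), 3)
  g <- segment_session(s)[[1]]
  ramp <- seq(0, 1023)
  g$B_raw <- rbind(ramp, ramp, ramp)
  g$L_raw <- ramp
  img <- form_location_image(g)                     # per-segment min-max
  expect_equal(dim(img), c(32L, 32L, 4L))
  expect_equal(img[1, 1, 1], 0)
  expect_equal(img[32, 32, 1], 255)
  expect_equal(img[1, 2, 4], 255 / 1023)            # sample t=1 -> row 0, col 1
  expect_equal(img[2, 1, 4], 255 * 32 / 1023)       # sample t=32 -> row 1, col 0

  # constant channel -> all-zero plane under the per-segment contract
  g$L_raw <- rep(3, 1024)
  expect_equal(form_location_image(g)[, , 4], matrix(0, 32, 32))

  # fixed physical bounds preserve the absolute level instead
  img_fixed <- form_location_image(g, bounds = list(mag = c(-80, 80), light = c(0, 600)))
  expect_equal(img_fixed[, , 4], matrix(255 * 3 / 600, 32, 32))

  g$length <- 512L
  expect_error(form_location_image(g), "1024")
})

test_that("location images are invertible up to affine rescale", {
  s <- trim_edges(toy_session(n = 2000L), 3)
  g <- segment_session(s)[[1]]
  img <- form_location_image(g)
  # undo the row-major layout, then the per-channel affine map
  recovered <- as.vector(t(img[, , 1]))
  orig <- g$B_raw[1, ]
  expect_equal(recovered / 255 * diff(range(orig)) + min(orig), orig,
               tolerance = 1e-9)
})

test_that("preprocess_sessions attaches images and respects the filter", {
  segs <- preprocess_sessions(list(toy_session(n = 2000L)), preprocess_config())
  expect_length(segs, 2L)
  expect_equal(dim(segs[[1]]$image), c(32L, 32L, 4L))
  expect_true(all(segs[[1]]$image >= 0 & segs[[1]]$image <= 255))
  # filtering happened: the stored raw channel is smoother than the input
  s_raw <- trim_edges(toy_session(n = 2000L), 3)
  expect_lt(sd(diff(segs[[1]]$B_raw[1, ])), sd(diff(s_raw$B[1, 1:1024])) + 1e-9)
})
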