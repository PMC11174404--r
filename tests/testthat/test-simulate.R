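test_that("generated datasets are seed-deterministic and labeled correctly", {
  sim <- sim_config(seed = 3L, sessions_per_activity = 2L, duration_range = c(26, 28))
  acts <- activity_specs()
  a <- generate_dataset(apartment_spec(), acts, sim)
  b <- generate_dataset(apartment_spec(), acts, sim)
  expect_identical(a, b)
  expect_length(a, 12L)
  for (s in a) {
    expect_s3_class(s, "recording_session")
    if (s$activity == "cooking") expect_equal(s$room, "kitchen")
    if (s$activity == "eating") expect_equal(s$room, "diningroom")
    if (s$activity == "sleeping") expect_true(s$room %in% c("bedroom1", "bedroom2"))
    expect_true(all(s$L >= 0))
  }
  # a different seed changes the data
  c_ <- generate_dataset(apartment_spec(), acts, sim_config(seed = 4L,
        sessions_per_activity = 2L, duration_range = c(26, 28)))
  expect_false(identical(a, c_))
})

test_that("field magnitude is rotation-invariant and near the room base", {
  apt <- apartment_spec()
  sim <- sim_config(seed = 5L, sessions_per_activity = 1L,
                    duration_range = c(26, 28), orientation_model = "random")
  surveys <- generate_dataset(apt, location_survey_specs(), sim)
  for (s in surveys) {
    base_norm <- sqrt(sum(apt$rooms[[s$room]]$base^2))
    norms <- sqrt(colSums(s$B^2))
    # rotation preserves the norm; spread comes only from gradient + noise
    expect_lt(abs(median(norms) - base_norm), 6)
    expect_true(all(abs(norms - base_norm) < 20))
  }
  # base magnitudes sit in the plausible indoor band
  for (r in rooms()) {
    nb <- sqrt(sum(apt$rooms[[r]]$base^2))
    expect_gte(nb, 20); expect_lte(nb, 70)
  }
  expect_error(apartment_spec(separation = 10), "band")
})

test_that("trajectories are confined, smooth, and phase-aware", {
  rect <- c(1, 2, 4, 5)
  pos <- sample_trajectory(rect, duration = 20, seed = 8L)
  expect_equal(nrow(pos), 2000L)
  expect_true(all(pos[, 1] >= rect[1] & pos[, 1] <= rect[3]))
  expect_true(all(pos[, 2] >= rect[2] & pos[, 2] <= rect[4]))
  # speed cap
  speed <- sqrt(rowSums(diff(pos)^2)) * 100
  expect_lte(max(speed), 1.5 + 1e-9)
  # stationary stretches freeze the position
  moving <- rep(c(TRUE, FALSE), each = 1000)
  pos2 <- sample_trajectory(rect, 20, seed = 8L, moving = moving)
  expect_equal(pos2[1001, ], pos2[2000, ])
  expect_error(sample_trajectory(c(0, 0, 0, 1), 5, seed = 1L), "degenerate")
  expect_error(sample_trajectory(rect, -1, seed = 1L), "duration")
})

test_that("walk phases carry gait-frequency power, stationary ones only noise", {
  sim <- sim_config(seed = 9L, sessions_per_activity = 2L, duration_range = c(30, 32))
  acts <- activity_specs()["eating"]
  sessions <- generate_dataset(apartment_spec(), acts, sim)
  s <- sessions[[1]]
  # the walk phase occupies the first ~4-6 s; take 4 s and spectrum-peak it
  walk <- s$A[, 101:500]
  walk_energy <- walk - rowMeans(walk)
  spec <- Mod(stats::mvfft(t(walk_energy)))[1:200, ]
  freq <- (seq_len(200) - 1) / 4                     # 4 s window -> 0.25 Hz bins
  peak_freq <- freq[which.max(rowSums(spec[2:200, , drop = FALSE]) ) + 1]
  expect_lt(abs(peak_freq - 2), 0.5)                 # near the 2 Hz gait default
  # late stationary-on-table stretch: variance at the noise floor
  tail_idx <- (ncol(s$A) - 400):ncol(s$A)
  expect_lt(max(apply(s$A[, tail_idx], 1, sd)), 5 * 0.02 * 1.2 + 0.05)
})

test_that("confusable scenarios install the intended ambiguities", {
  mc <- make_confusable_scenario("motion-confusable")
  expect_identical(mc$activities$desk_work$script, mc$activities$eating$script)
  expect_identical(mc$activities$desk_work$gait_freq, mc$activities$eating$gait_freq)
  expect_false(identical(mc$activities$desk_work$rooms, mc$activities$eating$rooms))

  lo <- make_confusable_scenario("light-only")
  expect_identical(lo$apartment$rooms$livingroom$base, lo$apartment$rooms$diningroom$base)
  expect_identical(lo$apartment$rooms$livingroom$grad, lo$apartment$rooms$diningroom$grad)
  expect_false(isTRUE(all.equal(lo$apartment$rooms$livingroom$day_lux,
                                lo$apartment$rooms$diningroom$day_lux)))
  # scenario construction is deterministic
  expect_identical(make_confusable_scenario("light-only"), lo)
})

test_that("per-phase orientation re-draws keep the field magnitude invariant", {
  sim <- sim_config(seed = 13L, sessions_per_activity = 1L,
                    duration_range = c(26, 28), orientation = "phase")
  apt <- apartment_spec()
  s <- generate_dataset(apt, activity_specs()["eating"], sim)[[1]]
  base_norm <- sqrt(sum(apt$rooms[[s$room]]$base^2))
  expect_lt(abs(median(sqrt(colSums(s$B^2))) - base_norm), 6)
})

test_that("training under varied orientations generalizes better than fixed", {
  accs <- sapply(0:1, function(s) {
    mk <- function(model, seed) {
      sim <- sim_config(seed = seed, sessions_per_activity = 4L,
                        duration_range = c(26, 30), orientation_model = model)
      preprocess_sessions(generate_dataset(apartment_spec(),
                                           location_survey_specs(), sim),
                          preprocess_config())
    }
    train_var <- mk("handheld", s)
    train_fix <- mk("fixed", s + 500L)
    test_new <- mk("handheld", s + 1000L)       # unseen orientations
    fit1 <- function(segs) {
      m <- lmiar:::with_seed(300L + s, build_lfn(lfn_config(
        widths = c(8L, 16L, 32L, 32L), blocks = rep(1L, 4), norm = "none")))
      train_lfn(m, segs, epochs = 4L, lr = 0.002, lr_final = 4e-4,
                augment_yaw = FALSE, seed = s)$model
    }
    truth <- vapply(test_new, `[[`, "", "room")
    c(varied = mean(classify_room(fit1(train_var), test_new)$room == truth),
      fixed = mean(classify_room(fit1(train_fix), test_new)$room == truth))
  })
  expect_gte(mean(accs["varied", ] - accs["fixed", ]), 0)
})

test_that("separation knob scales inter-room contrast without moving the mean", {
  a0 <- apartment_spec(separation = 0)
  bases0 <- sapply(a0$rooms, `[[`, "base")
  expect_equal(max(apply(bases0, 1, sd)), 0)
  a1 <- apartment_spec(separation = 1)
  bases1 <- sapply(a1$rooms, `[[`, "base")
  a2 <- apartment_spec(separation = 1.2)
  bases2 <- sapply(a2$rooms, `[[`, "base")
  expect_true(all(apply(bases2, 1, sd) >= apply(bases1, 1, sd)))
})
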