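# Synthetic apartment / activity simulator.
#
# Generates labeled recording_sessions with the statistical structure the
# recognizer assumes: room-dependent quasi-static geomagnetic signatures
# (affine field per room + noise), room- and daytime-dependent light levels,
# activity-dependent motion phases (walk / sit / lie / stationary), and an
# uncontrolled phone orientation (one random 3-D rotation per session).

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

rot_axis <- function(axis, theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, 3, byrow = TRUE),
         y = matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, 3, byrow = TRUE),
         z = matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE))
}

# A hand-held phone is roughly screen-up: heading (yaw) is uniform, tilt
# (pitch/roll) is a small random perturbation.
handheld_rotation <- function(tilt_sd = 5 * pi / 180) {
  rot_axis("z", stats::runif(1, 0, 2 * pi)) %*%
    rot_axis("x", stats::rnorm(1, 0, tilt_sd)) %*%
    rot_axis("y", stats::rnorm(1, 0, tilt_sd))
}

draw_orientation <- function(policy) {
  switch(policy,
         handheld = handheld_rotation(),
         random = random_rotation(),
         fixed = diag(3))
}

# Rotate a 3 x n channel matrix by a per-sample heading (z-axis) angle.
apply_yaw <- function(m, yaw) {
  c_ <- cos(yaw); s_ <- sin(yaw)
  rbind(c_ * m[1, ] - s_ * m[2, ],
        s_ * m[1, ] + c_ * m[2, ],
        m[3, ])
}

# Heading over time: a walker faces the direction of travel, so yaw drifts
# during walk phases (random-turn process) and holds still otherwise.
yaw_track <- function(moving, turn_sd = 0.04) {
  yaw0 <- stats::runif(1, 0, 2 * pi)
  dyaw <- ifelse(moving, stats::rnorm(length(moving), 0, turn_sd), 0)
  yaw0 + cumsum(dyaw)
}

#' Synthetic apartment specification
#'
#' Six disjoint room rectangles (meters), each with a geomagnetic base
#' vector (microtesla), a smooth linear spatial gradient (microtesla/m), a
#' magnetic noise sd, and day/night illuminance levels (lux). The base
#' vectors are a shared earth-field component plus per-room deviations;
#' `separation` scales those deviations, which makes inter-room geomagnetic
#' separability a single tunable knob (0 = all rooms magnetically
#' identical). `light_contrast` scales the spread of room light levels the
#' same way.
#'
#' @param separation non-negative scale on inter-room base-vector spread.
#' @param light_contrast non-negative scale on inter-room light spread.
#' @param mag_noise_sd magnetometer noise sd in microtesla.
#' @return An `apartment_spec` list with one entry per room.
#' @export
apartment_spec <- function(separation = 1, light_contrast = 1, mag_noise_sd = 0.5) {
  # Deviations are spread in the orientation-invariant coordinates a
  # phone with uncontrolled heading can still resolve: the vertical
  # component Bz and the horizontal magnitude |Bxy| (indoor steel and
  # appliances distort both by tens of microtesla between rooms).
  centre <- c(25, 10, -40)
  devs <- list(
    bedroom1 = c(-10, -8, 15), bedroom2 = c(-13, -10, 0),
    livingroom = c(-5, 10, -15), restroom = c(5, 20, 7),
    kitchen = c(20, -10, -8), diningroom = c(-17, -18, -22)
  )
  rects <- list(
    bedroom1 = c(0, 0, 4, 3), bedroom2 = c(4.5, 0, 8, 3),
    livingroom = c(0, 3.5, 5, 8), restroom = c(8.5, 0, 10, 2),
    kitchen = c(5.5, 6.5, 8, 8), diningroom = c(5.5, 3.5, 8, 6)
  )
  grads <- list(
    bedroom1 = matrix(c(1.2, -0.5, 0.8, 0.4, -1.0, 0.6), 3, 2),
    bedroom2 = matrix(c(-0.8, 1.1, 0.3, -0.6, 0.9, -1.2), 3, 2),
    livingroom = matrix(c(0.5, 0.7, -1.1, 1.0, -0.4, 0.2), 3, 2),
    restroom = matrix(c(1.5, -1.2, 0.4, 0.8, 0.5, -0.9), 3, 2),
    kitchen = matrix(c(-1.0, 0.6, 1.3, -0.3, -0.8, 0.7), 3, 2),
    diningroom = matrix(c(0.9, -0.7, -0.5, 1.2, 0.3, -1.0), 3, 2)
  )
  lux <- list(
    bedroom1 = c(150, 5), bedroom2 = c(180, 8), livingroom = c(420, 60),
    restroom = c(90, 30), kitchen = c(300, 40), diningroom = c(220, 25)
  )
  day_centre <- mean(vapply(lux, `[`, 0, 1))
  night_centre <- mean(vapply(lux, `[`, 0, 2))
  spec <- lapply(rooms(), function(r) {
    base <- centre + separation * devs[[r]]
    nb <- sqrt(sum(base^2))
    if (nb < 20 || nb > 70)
      stop(sprintf("room %s base field magnitude %.1f uT outside the 20-70 uT band", r, nb))
    day <- max(1, day_centre + light_contrast * (lux[[r]][1] - day_centre))
    night <- max(0.5, night_centre + light_contrast * (lux[[r]][2] - night_centre))
    # light sensor noise scales with the measured level (plus a floor)
    list(rect = rects[[r]], base = base, grad = grads[[r]],
         noise_sd = mag_noise_sd, day_lux = day, night_lux = night,
         lux_sd_frac = 0.05, lux_sd_floor = 2)
  })
  names(spec) <- rooms()
  structure(list(rooms = spec), class = "apartment_spec")
}

default_phase_params <- function() {
  list(
    walk = list(acc_amp = 2.5, sway_amp = 0.8, gyro_amp = 0.6,
                acc_noise = 0.4, gyro_noise = 0.05),
    sit_down = list(pulse_acc = 3.0, pulse_gyro = 1.5, acc_noise = 0.3, gyro_noise = 0.05),
    stand = list(acc_noise = 0.15, gyro_noise = 0.05),
    lie_down = list(pulse_acc = 2.2, pulse_gyro = 2.2, acc_noise = 0.3, gyro_noise = 0.05),
    sit_still = list(acc_noise = 0.08, gyro_noise = 0.02),
    stationary_on_table = list(acc_noise = 0.02, gyro_noise = 0.005),
    # phone resting on the mattress next to a sleeper: breathing-coupled
    # micro-oscillation (~0.25 Hz)
    lie_still_bed = list(breath_amp = 0.06, breath_freq = 0.25,
                         acc_noise = 0.02, gyro_noise = 0.008)
  )
}

new_activity_spec <- function(name, rooms, script, gait_freq = 2, effort = 1) {
  structure(list(name = name, rooms = rooms, script = script,
                 gait_freq = gait_freq, effort = effort,
                 phase_params = default_phase_params()),
            class = "activity_spec")
}

ph <- function(phase, lo, hi = lo) list(phase = phase, dur = c(lo, hi))

#' Default activity specifications
#'
#' One motion script per compound activity: ordered phases (walk, posture
#' transition, stationary...) with duration ranges in seconds; the final
#' phase stretches to fill the session. Room assignments follow the typical
#' apartment mapping (cooking in the kitchen, sleeping in a bedroom, ...).
#'
#' @return Named list of `activity_spec` objects.
#' @export
activity_specs <- function() {
  m <- activity_room_map()
  list(
    eating = new_activity_spec("eating", m$eating, list(
      ph("walk", 4, 6), ph("sit_down", 1.5, 2), ph("stationary_on_table", 10, 10)),
      gait_freq = 2.0),
    sleeping = new_activity_spec("sleeping", m$sleeping, list(
      ph("walk", 3, 5), ph("lie_down", 2, 2.5), ph("lie_still_bed", 10, 10)),
      gait_freq = 1.7),
    using_bathroom = new_activity_spec("using_bathroom", m$using_bathroom, list(
      ph("walk", 6, 9), ph("stand", 3, 5), ph("walk", 2, 3), ph("stationary_on_table", 6, 6)),
      gait_freq = 2.1),
    doing_laundry = new_activity_spec("doing_laundry", m$doing_laundry, list(
      ph("walk", 3, 4), ph("stand", 2, 3), ph("walk", 2, 3), ph("stand", 2, 3),
      ph("walk", 2, 3), ph("stand", 6, 6)),
      gait_freq = 2.3, effort = 1.5),
    cooking = new_activity_spec("cooking", m$cooking, list(
      ph("walk", 2, 3), ph("stand", 4, 6), ph("walk", 2, 3), ph("stand", 8, 8)),
      gait_freq = 2.0, effort = 1.3),
    desk_work = new_activity_spec("desk_work", m$desk_work, list(
      ph("walk", 5, 7), ph("sit_down", 1.5, 2), ph("stationary_on_table", 10, 10)),
      gait_freq = 2.0)
  )
}

#' Location-survey (walking) specifications
#'
#' One walk-only script per room with no activity label, emulating the
#' extra geomagnetic/light survey recordings collected by walking around
#' each room in daylight and at night to train the location network.
#'
#' @return Named list of `activity_spec` objects (activity label absent).
#' @export
location_survey_specs <- function() {
  out <- lapply(rooms(), function(r) {
    sp <- new_activity_spec(NA_character_, r, list(ph("walk", 60, 60)))
    sp$survey_room <- r
    sp
  })
  names(out) <- rooms()
  out
}

#' Simulation configuration
#'
#' @param seed integer; fully determines the generated dataset.
#' @param sessions_per_activity sessions generated per activity spec.
#' @param duration_range session length range in seconds.
#' @param day_fraction fraction of sessions recorded in daylight.
#' @param n_subjects number of simulated users; each gets a fixed
#'   amplitude multiplier and gait-timing multiplier.
#' @param orientation `"session"` (one random phone rotation per session)
#'   or `"phase"` (re-rotated at each motion-phase boundary, modeling
#'   hold-then-put-down transitions).
#' @param orientation_model how a rotation is drawn: `"handheld"`
#'   (default; uniform heading with ~10 degree tilt jitter, the posture of
#'   a phone held or laid roughly screen-up), `"random"` (uniform over all
#'   3-D rotations) or `"fixed"` (identity; a strapped-down sensor).
#' @param gravity include the rotated gravity component in simulated
#'   accelerometer output (phones report raw accelerometer incl. gravity).
#' @param sampling_rate Hz.
#' @return A named list of settings.
#' @export
sim_config <- function(seed = 0L, sessions_per_activity = 20L,
                       duration_range = c(50, 60), day_fraction = 0.5,
                       n_subjects = 3L, orientation = c("session", "phase"),
                       orientation_model = c("handheld", "random", "fixed"),
                       gravity = TRUE, sampling_rate = 100) {
  list(seed = as.integer(seed), sessions_per_activity = as.integer(sessions_per_activity),
       duration_range = duration_range, day_fraction = day_fraction,
       n_subjects = as.integer(n_subjects), orientation = match.arg(orientation),
       orientation_model = match.arg(orientation_model),
       gravity = gravity, sampling_rate = sampling_rate)
}

#' Smooth confined random-walk trajectory
#'
#' Positions inside a room rectangle at the sampling rate: an
#' Ornstein-Uhlenbeck-style velocity random walk, speed-capped during
#' moving stretches and frozen during stationary ones, reflected at walls.
#'
#' @param room_rectangle `c(x0, y0, x1, y1)` in meters.
#' @param duration seconds.
#' @param seed optional integer seed.
#' @param sampling_rate Hz.
#' @param moving optional logical vector (length `duration * sampling_rate`)
#'   marking samples where the subject is walking; default all moving.
#' @param max_speed cap in m/s.
#' @return An n x 2 matrix of positions.
#' @export
sample_trajectory <- function(room_rectangle, duration, seed = NULL,
                              sampling_rate = 100, moving = NULL, max_speed = 1.5) {
  r <- room_rectangle
  if (r[3] <= r[1] || r[4] <= r[2]) stop("degenerate room rectangle")
  if (duration <= 0) stop("duration must be positive")
  run <- function() {
    n <- round(duration * sampling_rate)
    if (is.null(moving)) moving <- rep(TRUE, n)
    dt <- 1 / sampling_rate
    pos <- matrix(0, n, 2)
    p <- c(stats::runif(1, r[1], r[3]), stats::runif(1, r[2], r[4]))
    v <- stats::rnorm(2, 0, 0.3)
    for (k in seq_len(n)) {
      if (moving[k]) {
        v <- 0.98 * v + stats::rnorm(2, 0, 0.08)
        sp <- sqrt(sum(v^2))
        if (sp > max_speed) v <- v * max_speed / sp
        p <- p + v * dt
        # reflect at walls
        if (p[1] < r[1]) { p[1] <- 2 * r[1] - p[1]; v[1] <- -v[1] }
        if (p[1] > r[3]) { p[1] <- 2 * r[3] - p[1]; v[1] <- -v[1] }
        if (p[2] < r[2]) { p[2] <- 2 * r[2] - p[2]; v[2] <- -v[2] }
        if (p[2] > r[4]) { p[2] <- 2 * r[4] - p[2]; v[2] <- -v[2] }
        p[1] <- min(max(p[1], r[1]), r[3])
        p[2] <- min(max(p[2], r[2]), r[4])
      }
      pos[k, ] <- p
    }
    pos
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Realize a motion script into per-sample phase labels for n samples.
realize_script <- function(script, n, sampling_rate) {
  labs <- character(0)
  for (i in seq_along(script)) {
    dur <- stats::runif(1, script[[i]]$dur[1], script[[i]]$dur[2])
    labs <- c(labs, rep(script[[i]]$phase, round(dur * sampling_rate)))
  }
  if (length(labs) >= n) labs[seq_len(n)]
  else c(labs, rep(script[[length(script)]]$phase, n - length(labs)))
}

# World-frame accelerometer/gyroscope template for one session.
motion_template <- function(phase_labels, spec, amp_mult, freq_mult, sampling_rate,
                            gravity = TRUE) {
  n <- length(phase_labels)
  tt <- (seq_len(n) - 1) / sampling_rate
  acc <- matrix(0, 3, n)
  gyr <- matrix(0, 3, n)
  f <- spec$gait_freq * freq_mult
  eff <- spec$effort * amp_mult
  pp <- spec$phase_params
  runs <- rle(phase_labels)
  pos0 <- cumsum(c(1, runs$lengths))
  for (j in seq_along(runs$values)) {
    idx <- pos0[j]:(pos0[j] + runs$lengths[j] - 1L)
    phase <- runs$values[j]
    p <- pp[[phase]]
    ni <- length(idx)
    if (phase == "walk") {
      acc[3, idx] <- acc[3, idx] + eff * p$acc_amp * sin(2 * pi * f * tt[idx])
      acc[1, idx] <- acc[1, idx] + eff * p$sway_amp * sin(2 * pi * f / 2 * tt[idx])
      gyr[2, idx] <- gyr[2, idx] + eff * p$gyro_amp * sin(2 * pi * f * tt[idx] + 1)
    } else if (phase %in% c("sit_down", "lie_down")) {
      pulse <- sin(pi * seq(0, 1, length.out = ni))
      acc[3, idx] <- acc[3, idx] - eff * p$pulse_acc * pulse
      ax <- if (phase == "lie_down") 1L else 2L
      gyr[ax, idx] <- gyr[ax, idx] + eff * p$pulse_gyro * pulse
    } else if (phase == "lie_still_bed") {
      br <- p$breath_amp * sin(2 * pi * p$breath_freq * tt[idx])
      acc[3, idx] <- acc[3, idx] + br
      gyr[1, idx] <- gyr[1, idx] + 0.3 * p$breath_amp * sin(2 * pi * p$breath_freq * tt[idx] + 0.7)
    } else if (phase == "stand") {
      # standing with task effort (arm motion): low-frequency stirring
      acc[1, idx] <- acc[1, idx] + 0.4 * eff * sin(2 * pi * 0.8 * tt[idx])
      gyr[3, idx] <- gyr[3, idx] + 0.15 * eff * sin(2 * pi * 0.8 * tt[idx])
    }
    acc[, idx] <- acc[, idx] + matrix(stats::rnorm(3 * ni, 0, p$acc_noise * amp_mult), 3, ni)
    gyr[, idx] <- gyr[, idx] + matrix(stats::rnorm(3 * ni, 0, p$gyro_noise * amp_mult), 3, ni)
  }
  if (gravity) acc[3, ] <- acc[3, ] + 9.81
  list(acc = acc, gyr = gyr)
}

#' Generate a labeled synthetic dataset
#'
#' For each activity spec and repetition: a room is drawn from the
#' activity's allowed rooms, a trajectory is sampled inside it, the
#' geomagnetic channel is `R (base + grad (pos - room centre)) + noise`
#' with `R` the session's random phone-orientation rotation, light is the
#' room's day or night level plus noise, and the IMU channels come from the
#' activity's motion script rotated by `R`. The seed fully determines the
#' output.
#'
#' @param apartment an [apartment_spec()].
#' @param activities list of `activity_spec` objects ([activity_specs()] or
#'   [location_survey_specs()]).
#' @param config a [sim_config()].
#' @return List of [recording_session()] objects.
#' @export
generate_dataset <- function(apartment, activities, config = sim_config()) {
  with_seed(config$seed, {
    rate <- config$sampling_rate
    subj_amp <- 1 + 0.15 * (seq_len(config$n_subjects) - (config$n_subjects + 1) / 2)
    subj_frq <- 1 + 0.08 * (seq_len(config$n_subjects) - (config$n_subjects + 1) / 2)
    sessions <- list()
    for (spec in activities) {
      for (i in seq_len(config$sessions_per_activity)) {
        room <- if (length(spec$rooms) == 1L) spec$rooms else sample(spec$rooms, 1L)
        rm_def <- apartment$rooms[[room]]
        if (is.null(rm_def)) stop("activity references unknown room: ", room)
        subj <- ((i - 1L) %% config$n_subjects) + 1L
        duration <- stats::runif(1, config$duration_range[1], config$duration_range[2])
        n <- round(duration * rate)
        phases <- realize_script(spec$script, n, rate)
        moving <- phases == "walk"
        pos <- sample_trajectory(rm_def$rect, duration, seed = NULL,
                                 sampling_rate = rate, moving = moving)
        centre <- c((rm_def$rect[1] + rm_def$rect[3]) / 2, (rm_def$rect[2] + rm_def$rect[4]) / 2)
        Bw <- rm_def$base + rm_def$grad %*% t(sweep(pos, 2, centre))
        day <- stats::runif(1) < config$day_fraction
        lux <- if (day) rm_def$day_lux else rm_def$night_lux
        mo <- motion_template(phases, spec, subj_amp[subj], subj_frq[subj], rate,
                              gravity = config$gravity)
        if (config$orientation_model == "handheld") {
          # heading follows the walking direction; tilt is a small fixed
          # perturbation (per session, or re-drawn when the phone is set
          # down at each phase boundary)
          yaw <- yaw_track(moving)
          tilt_sd <- 5 * pi / 180
          new_tilt <- function() rot_axis("x", stats::rnorm(1, 0, tilt_sd)) %*%
            rot_axis("y", stats::rnorm(1, 0, tilt_sd))
          if (config$orientation == "phase") {
            runs <- rle(phases)
            pos0 <- cumsum(c(1, runs$lengths))
            B <- matrix(0, 3, n); A <- matrix(0, 3, n); G <- matrix(0, 3, n)
            for (j in seq_along(runs$values)) {
              idx <- pos0[j]:(pos0[j] + runs$lengths[j] - 1L)
              R <- new_tilt()
              off <- if (j == 1L) 0 else stats::runif(1, 0, 2 * pi)
              B[, idx] <- R %*% apply_yaw(Bw[, idx, drop = FALSE], yaw[idx] + off)
              A[, idx] <- R %*% apply_yaw(mo$acc[, idx, drop = FALSE], yaw[idx] + off)
              G[, idx] <- R %*% apply_yaw(mo$gyr[, idx, drop = FALSE], yaw[idx] + off)
            }
          } else {
            R <- new_tilt()
            B <- R %*% apply_yaw(Bw, yaw)
            A <- R %*% apply_yaw(mo$acc, yaw)
            G <- R %*% apply_yaw(mo$gyr, yaw)
          }
        } else if (config$orientation == "session") {
          R <- draw_orientation(config$orientation_model)
          B <- R %*% Bw
          A <- R %*% mo$acc
          G <- R %*% mo$gyr
        } else {
          runs <- rle(phases)
          pos0 <- cumsum(c(1, runs$lengths))
          B <- matrix(0, 3, n); A <- matrix(0, 3, n); G <- matrix(0, 3, n)
          for (j in seq_along(runs$values)) {
            idx <- pos0[j]:(pos0[j] + runs$lengths[j] - 1L)
            R <- draw_orientation(config$orientation_model)
            B[, idx] <- R %*% Bw[, idx, drop = FALSE]
            A[, idx] <- R %*% mo$acc[, idx, drop = FALSE]
            G[, idx] <- R %*% mo$gyr[, idx, drop = FALSE]
          }
        }
        B <- B + matrix(stats::rnorm(3 * n, 0, rm_def$noise_sd), 3, n)
        L <- pmax(0, lux + stats::rnorm(n, 0, rm_def$lux_sd_frac * lux + rm_def$lux_sd_floor))
        act <- spec$name
        sid <- sprintf("%s_%s_%03d", ifelse(is.na(act), paste0("survey_", room), act), room, i)
        sessions[[length(sessions) + 1L]] <- recording_session(
          session_id = sid, t = (seq_len(n) - 1) / rate,
          B = B, A = A, G = G, L = L, room = room, activity = act,
          subject_id = sprintf("subj%d", subj), sampling_rate = rate
        )
      }
    }
    sessions
  })
}

#' Construct confusability scenarios
#'
#' `"motion-confusable"`: eating and desk_work share one identical motion
#' script (and desk_work moves to a single distinct room), so they are
#' separable only through location. `"light-only"`: living room and dining
#' room share identical geomagnetic statistics and differ only in light
#' level, so separating the activities that live in them requires the
#' ambient-light channel. `"default"` returns the standard apartment and
#' activity set.
#'
#' @param kind one of `"default"`, `"motion-confusable"`, `"light-only"`.
#' @return `list(apartment =, activities =)`.
#' @export
make_confusable_scenario <- function(kind = c("default", "motion-confusable", "light-only")) {
  kind <- match.arg(kind)
  apt <- apartment_spec()
  acts <- activity_specs()
  if (kind == "motion-confusable") {
    acts$desk_work$script <- acts$eating$script
    acts$desk_work$gait_freq <- acts$eating$gait_freq
    acts$desk_work$effort <- acts$eating$effort
    acts$desk_work$rooms <- "livingroom"
  } else if (kind == "light-only") {
    apt$rooms$livingroom$base <- apt$rooms$diningroom$base
    apt$rooms$livingroom$grad <- apt$rooms$diningroom$grad
    apt$rooms$livingroom$noise_sd <- apt$rooms$diningroom$noise_sd
    acts$desk_work$script <- acts$eating$script
    acts$desk_work$gait_freq <- acts$eating$gait_freq
    acts$desk_work$effort <- acts$eating$effort
    acts$desk_work$rooms <- "livingroom"
  }
  list(apartment = apt, activities = acts)
}
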