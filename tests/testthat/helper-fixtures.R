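# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# A deterministic hand-built session: simple analytic channels, no simulator.
toy_session <- function(n = 2000L, rate = 100, room = "kitchen",
                        activity = "cooking") {
  t <- (seq_len(n) - 1) / rate
  recording_session(
    session_id = "toy1", t = t,
    B = rbind(30 + sin(t), 5 + cos(t), -40 + 0.5 * sin(2 * t)),
    A = rbind(0.1 * sin(t), 0.1 * cos(t), 9.81 + 0.2 * sin(4 * t)),
    G = rbind(0.05 * sin(3 * t), 0.05 * cos(3 * t), 0.02 * sin(t)),
    L = 300 + 10 * sin(t),
    room = room, activity = activity, subject_id = "subjA",
    sampling_rate = rate
  )
}

# Small simulated survey dataset (rooms only), shared across test files.
survey_segments <- function() {
  cached("survey_segments", function() {
    sim <- sim_config(seed = 7L, sessions_per_activity = 2L,
                      duration_range = c(26, 30))
    sessions <- generate_dataset(apartment_spec(), location_survey_specs(), sim)
    preprocess_sessions(sessions, preprocess_config())
  })
}

# Small simulated activity dataset, shared across test files.
activity_segments <- function() {
  cached("activity_segments", function() {
    sc <- make_confusable_scenario("motion-confusable")
    sim <- sim_config(seed = 11L, sessions_per_activity = 3L,
                      duration_range = c(26, 30))
    sessions <- generate_dataset(sc$apartment, sc$activities, sim)
    preprocess_sessions(sessions, preprocess_config())
  })
}

# Central-difference gradient of a scalar function of an array.
num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

tiny_mfn_opts <- list(layers = 1L, heads = 2L, feature_dim = 16L,
                      feedforward_dim = 32L)
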