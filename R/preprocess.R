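#' Weighted recursive average filter configuration
#'
#' The denoising filter is a first-order recursion
#' `A_k = (1 - alpha) * A_{k-1} + alpha * D_k` whose weight is tied to a
#' nominal averaging-window length `N` by `alpha = 2 / (N + 1)` (so `N = 5`
#' gives `alpha = 1/3`). Larger `N` means heavier smoothing.
#'
#' @param N positive integer window length (default 5).
#' @return A list with `N` and the derived weight `alpha`.
#' @export
filter_config <- function(N = 5L) {
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("filter window length N must be >= 1")
  list(N = N, alpha = 2 / (N + 1))
}

#' Trim session edges
#'
#' Removes the first and last `trim_seconds` of every channel; the edges of
#' a hand-held recording contain start/stop handling interference.
#'
#' @param session a [recording_session()].
#' @param trim_seconds seconds to drop from each end (default 3).
#' @return The trimmed [recording_session()].
#' @export
trim_edges <- function(session, trim_seconds = 3) {
  stopifnot(inherits(session, "recording_session"))
  if (trim_seconds == 0) return(session)
  n <- length(session$t)
  k <- round(trim_seconds * session$sampling_rate)
  if (n <= 2 * k) stop("session too short to trim")
  keep <- (k + 1L):(n - k)
  session$t <- session$t[keep]
  session$B <- session$B[, keep, drop = FALSE]
  session$A <- session$A[, keep, drop = FALSE]
  session$G <- session$G[, keep, drop = FALSE]
  session$L <- session$L[keep]
  session
}

#' Weighted recursive average filter
#'
#' Applies `A_k = (1 - alpha) * A_{k-1} + alpha * D_k` left to right. The
#' initial state `A_0` defaults to the first sample, which avoids a start-up
#' transient; a constant input is a fixed point (unit DC gain).
#'
#' @param series numeric vector.
#' @param config a [filter_config()].
#' @param A0 initial state (default: first sample).
#' @return Filtered series, same length as the input.
#' @export
recursive_filter <- function(series, config = filter_config(), A0 = series[1]) {
  if (length(series) < 1L) stop("series must be non-empty")
  alpha <- config$alpha
  # A_k = (1-a) A_{k-1} + a D_k  ==  filter() recursion with one init value
  out <- stats::filter(alpha * series, filter = 1 - alpha,
                       method = "recursive", init = A0)
  as.numeric(out)
}

#' Min-max normalization to [0, 1]
#'
#' `X_i = (x_i - x_min) / (x_max - x_min)`. A constant series (zero range)
#' maps to all zeros instead of erroring: stationary-phone stretches are
#' common and must not crash the pipeline.
#'
#' @param series numeric vector.
#' @return Normalized series in `[0, 1]`.
#' @export
minmax_normalize <- function(series) {
  if (length(series) < 1L) stop("series must be non-empty")
  lo <- min(series); hi <- max(series)
  if (hi == lo) return(rep(0, length(series)))
  (series - lo) / (hi - lo)
}

# 0-based window start offsets for sliding segmentation.
segment_starts <- function(n, length = 1024L, step = 200L) {
  if (length < 1L || step < 1L) stop("segment length and step must be >= 1")
  if (n < length) return(integer(0))
  seq.int(0L, n - length, by = step)
}

#' Default preprocessing configuration
#'
#' @param trim_seconds edge trim in seconds (3).
#' @param filter_N recursive-filter window length (5).
#' @param segment_length window length in samples (1024).
#' @param segment_step window stride in samples (200).
#' @param normalize_scope `"session"` (default) or `"segment"`: whether
#'   the `[0,1]` min-max of each channel uses whole-session or per-window
#'   extrema. Session scope preserves the relative amplitude of quiet
#'   stretches (a phone resting on a table) against active ones (walking),
#'   which per-window scaling would blow up to full scale.
#' @param mag_bounds,light_bounds fixed physical bounds used when scaling
#'   geomagnetic and light channels into location images; see
#'   [form_location_image()].
#' @param light_log scale the light plane logarithmically (`log1p`);
#'   illuminance spans decades between day and night, so a log scale
#'   preserves contrast at low light where a linear one crushes it.
#' @return A named list of settings.
#' @export
preprocess_config <- function(trim_seconds = 3, filter_N = 5L,
                              segment_length = 1024L, segment_step = 200L,
                              normalize_scope = c("session", "segment"),
                              mag_bounds = c(-80, 80), light_bounds = c(0, 600),
                              light_log = TRUE) {
  list(trim_seconds = trim_seconds, filter_N = as.integer(filter_N),
       segment_length = as.integer(segment_length),
       segment_step = as.integer(segment_step),
       normalize_scope = match.arg(normalize_scope),
       mag_bounds = mag_bounds, light_bounds = light_bounds,
       light_log = light_log)
}

#' Slide fixed-length windows over a session
#'
#' Windows of `length` samples start at offsets `0, step, 2*step, ...`; a
#' window is emitted iff it fits entirely, so a session of `n` samples
#' yields `floor((n - length)/step) + 1` segments when `n >= length`, else
#' none. Each segment keeps the filtered channel values (`B_raw`, `L_raw`)
#' alongside per-channel min-max normalized copies (`B`, `A`, `G`, `L` in
#' `[0,1]`); with `normalize_scope = "session"` the extrema come from the
#' whole session instead of the window.
#'
#' @param session a (trimmed, filtered) [recording_session()].
#' @param length window length in samples (default 1024).
#' @param step window stride in samples (default 200).
#' @param normalize_scope see [preprocess_config()].
#' @return A list of `segment` objects.
#' @export
segment_session <- function(session, length = 1024L, step = 200L,
                            normalize_scope = c("session", "segment")) {
  stopifnot(inherits(session, "recording_session"))
  normalize_scope <- match.arg(normalize_scope)
  n <- base::length(session$t)
  starts <- segment_starts(n, length, step)
  norm_rows <- function(m) t(apply(m, 1L, minmax_normalize))
  if (normalize_scope == "session") {
    Bn <- norm_rows(session$B); An <- norm_rows(session$A)
    Gn <- norm_rows(session$G); Ln <- minmax_normalize(session$L)
  }
  lapply(starts, function(s0) {
    idx <- (s0 + 1L):(s0 + length)
    seg <- list(
      session_id = session$session_id,
      start_index = s0,
      length = length,
      room = session$room,
      activity = session$activity,
      subject_id = session$subject_id,
      B_raw = session$B[, idx, drop = FALSE],
      L_raw = session$L[idx]
    )
    if (normalize_scope == "segment") {
      seg$B <- norm_rows(seg$B_raw)
      seg$A <- norm_rows(session$A[, idx, drop = FALSE])
      seg$G <- norm_rows(session$G[, idx, drop = FALSE])
      seg$L <- minmax_normalize(seg$L_raw)
    } else {
      seg$B <- Bn[, idx, drop = FALSE]
      seg$A <- An[, idx, drop = FALSE]
      seg$G <- Gn[, idx, drop = FALSE]
      seg$L <- Ln[idx]
    }
    class(seg) <- "sensor_segment"
    seg
  })
}

#' Form a location image from a segment
#'
#' The 1024 samples of each location channel (Bx, By, Bz, L) are laid out
#' chronologically row-major on a 32 x 32 grid (sample `t`, 0-based, lands
#' at row `t %/% 32`, column `t %% 32`) and scaled to `[0, 255]`.
#'
#' With `bounds = NULL` the scaling is the per-channel min-max of the
#' segment itself (a constant channel maps to an all-zero plane). Passing
#' fixed physical bounds instead (the pipeline default: magnetometer range
#' for Bx/By/Bz, illuminance range for L) preserves *absolute* field and
#' light levels across segments — the quantity a geomagnetic room
#' fingerprint actually lives in, which a per-window min-max would cancel.
#' Values outside fixed bounds are clipped.
#'
#' @param segment a segment from [segment_session()] (length exactly 1024).
#' @param bounds `NULL` for per-segment min-max, or a list with `mag` and
#'   `light` 2-vectors of fixed bounds and optionally `light_log = TRUE`
#'   (log-scale the light plane).
#' @return A 32 x 32 x 4 array, channel order (Bx, By, Bz, L), values in
#'   `[0, 255]`.
#' @export
form_location_image <- function(segment, bounds = NULL) {
  if (segment$length != 1024L) stop("location images require segments of length 1024")
  Lchan <- segment$L_raw
  lims <- NULL
  if (!is.null(bounds)) {
    lb <- bounds$light
    if (isTRUE(bounds$light_log)) {
      Lchan <- log1p(pmax(Lchan, 0))
      lb <- log1p(pmax(lb, 0))
    }
    lims <- list(bounds$mag, bounds$mag, bounds$mag, lb)
  }
  chans <- list(segment$B_raw[1, ], segment$B_raw[2, ], segment$B_raw[3, ], Lchan)
  img <- array(0, c(32L, 32L, 4L))
  for (ci in 1:4) {
    v <- chans[[ci]]
    if (is.null(lims)) {
      v <- minmax_normalize(v) * 255
    } else {
      lo <- lims[[ci]][1]; hi <- lims[[ci]][2]
      v <- (pmin(pmax(v, lo), hi) - lo) / (hi - lo) * 255
    }
    # sample t (0-based) -> row t %/% 32 + 1, col t %% 32 + 1 (row-major)
    img[, , ci] <- matrix(v, 32L, 32L, byrow = TRUE)
  }
  img
}

#' Run the full preprocessing pipeline on sessions
#'
#' Per session: trim edges, apply the recursive average filter to every
#' channel independently, slide 1024-sample windows, normalize, and attach
#' a location image to every segment.
#'
#' @param sessions a list of [recording_session()] objects.
#' @param config a [preprocess_config()].
#' @return A flat list of segments, each carrying an `image` field.
#' @export
preprocess_sessions <- function(sessions, config = preprocess_config()) {
  fc <- filter_config(config$filter_N)
  bounds <- list(mag = config$mag_bounds, light = config$light_bounds,
                 light_log = isTRUE(config$light_log))
  out <- list()
  for (s in sessions) {
    s <- trim_edges(s, config$trim_seconds)
    for (i in 1:3) {
      s$B[i, ] <- recursive_filter(s$B[i, ], fc)
      s$A[i, ] <- recursive_filter(s$A[i, ], fc)
      s$G[i, ] <- recursive_filter(s$G[i, ], fc)
    }
    s$L <- recursive_filter(s$L, fc)
    segs <- segment_session(s, config$segment_length, config$segment_step,
                            config$normalize_scope)
    if (config$segment_length == 1024L) {
      segs <- lapply(segs, function(g) {
        g$image <- form_location_image(g, bounds)
        g$image_bounds <- bounds
        g
      })
    }
    out <- c(out, segs)
  }
  out
}
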