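#' Labeled multi-sensor smartphone recordings
#'
#' A `recording_session` bundles the four synchronized sensor streams a
#' smartphone logs during one indoor-activity session: 3-axis geomagnetic
#' intensity `B` (microtesla), 3-axis acceleration `A` (m/s^2), 3-axis
#' angular velocity `G` (rad/s) and 1-axis ambient light `L` (lux), sampled
#' on a common 100 Hz clock, plus a room label and (optionally) an activity
#' label and subject id.
#'
#' @param session_id character scalar identifying the session.
#' @param t numeric vector of sample times in seconds, strictly increasing.
#' @param B,A,G numeric 3 x n matrices (rows x, y, z).
#' @param L numeric vector of length n, non-negative.
#' @param room one of [rooms()].
#' @param activity one of [activities()] or `NA` for location-only sessions.
#' @param subject_id character scalar or `NA`.
#' @param sampling_rate sampling frequency in Hz (default 100).
#' @return An object of class `recording_session`.
#' @export
recording_session <- function(session_id, t, B, A, G, L, room,
                              activity = NA_character_, subject_id = NA_character_,
                              sampling_rate = 100) {
  B <- unname(as.matrix(B)); A <- unname(as.matrix(A)); G <- unname(as.matrix(G))
  L <- as.numeric(L); t <- as.numeric(t)
  n <- length(t)
  if (n < 1L) stop("session must contain at least one sample")
  if (any(diff(t) <= 0)) stop("time axis must be strictly increasing")
  for (nm in c("B", "A", "G")) {
    m <- get(nm)
    if (nrow(m) != 3L || ncol(m) != n)
      stop(sprintf("channel %s must be 3 x %d", nm, n))
  }
  if (length(L) != n) stop("channel L must have length n")
  if (any(L < 0)) stop("illuminance must be non-negative")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  room <- match.arg(room, rooms())
  if (!is.na(activity)) {
    activity <- match.arg(activity, activities())
    allowed <- activity_room_map()[[activity]]
    if (!(room %in% allowed))
      warning(sprintf("activity '%s' recorded in atypical room '%s' (typical: %s)",
                      activity, room, paste(allowed, collapse = ", ")))
  }
  structure(list(session_id = session_id, sampling_rate = sampling_rate,
                 t = t, B = B, A = A, G = G, L = L,
                 room = room, activity = activity, subject_id = subject_id),
            class = "recording_session")
}

#' Room and activity vocabularies
#'
#' Six rooms of the apartment model and the six compound activities,
#' together with the typical activity-to-room mapping (cooking happens in
#' the kitchen, sleeping in a bedroom, and so on). The mapping is advisory:
#' constructing a session with an atypical pairing warns but succeeds.
#'
#' @return Character vectors, or for `activity_room_map()` a named list of
#'   allowed rooms per activity.
#' @export
rooms <- function() {
  c("bedroom1", "bedroom2", "livingroom", "restroom", "kitchen", "diningroom")
}

#' @rdname rooms
#' @export
activities <- function() {
  c("eating", "sleeping", "using_bathroom", "doing_laundry", "cooking", "desk_work")
}

#' @rdname rooms
#' @export
activity_room_map <- function() {
  list(
    eating = "diningroom",
    sleeping = c("bedroom1", "bedroom2"),
    using_bathroom = "restroom",
    doing_laundry = "restroom",
    cooking = "kitchen",
    desk_work = c("livingroom", "bedroom2")
  )
}

#' @export
print.recording_session <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf("<recording_session> %s: n=%d (%.1f s @ %g Hz), room=%s, activity=%s\n",
              x$session_id, n, n / x$sampling_rate, x$sampling_rate,
              x$room, ifelse(is.na(x$activity), "<none>", x$activity)))
  invisible(x)
}

sensor_files <- c(Magnetometer = "Magnetometer.csv", Accelerometer = "Accelerometer.csv",
                  Gyroscope = "Gyroscope.csv", Light = "Light.csv")

#' Write a recording session as per-sensor CSV files
#'
#' Emits `Magnetometer.csv`, `Accelerometer.csv`, `Gyroscope.csv` (columns
#' `seconds_elapsed,x,y,z`), `Light.csv` (columns
#' `seconds_elapsed,illuminance`) and a `labels.json` sidecar with
#' `session_id`, `room`, `activity` and `subject_id`. [read_session()]
#' inverts this layout.
#'
#' @param session a [recording_session()].
#' @param directory_path directory to create/write into.
#' @return Invisibly, the vector of files written.
#' @export
write_session <- function(session, directory_path) {
  stopifnot(inherits(session, "recording_session"))
  dir.create(directory_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory_path)) stop("cannot create directory: ", directory_path)
  w3 <- function(file, m) {
    df <- data.frame(seconds_elapsed = session$t, x = m[1, ], y = m[2, ], z = m[3, ])
    utils::write.csv(df, file.path(directory_path, file), row.names = FALSE)
  }
  w3(sensor_files[["Magnetometer"]], session$B)
  w3(sensor_files[["Accelerometer"]], session$A)
  w3(sensor_files[["Gyroscope"]], session$G)
  utils::write.csv(data.frame(seconds_elapsed = session$t, illuminance = session$L),
                   file.path(directory_path, sensor_files[["Light"]]), row.names = FALSE)
  labels <- list(session_id = session$session_id, room = session$room,
                 activity = if (is.na(session$activity)) NULL else session$activity,
                 subject_id = if (is.na(session$subject_id)) NULL else session$subject_id,
                 sampling_rate = session$sampling_rate)
  jsonlite::write_json(labels, file.path(directory_path, "labels.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(file.path(directory_path, c(sensor_files, "labels.json")))
}

#' Read a recording session from a per-sensor CSV directory
#'
#' Reads the four sensor CSVs plus the `labels.json` sidecar written by
#' [write_session()]. All channels are assumed to share one clock; if
#' channel lengths differ by exactly one sample they are truncated to the
#' shortest, larger mismatches are an error.
#'
#' @param directory_path directory containing the session files.
#' @param labels optional named list overriding the sidecar labels
#'   (`session_id`, `room`, `activity`, `subject_id`).
#' @return A [recording_session()].
#' @export
read_session <- function(directory_path, labels = NULL) {
  for (f in sensor_files) {
    if (!file.exists(file.path(directory_path, f)))
      stop("missing ", f, " in ", directory_path)
  }
  rd <- function(f) utils::read.csv(file.path(directory_path, f))
  mag <- rd(sensor_files[["Magnetometer"]])
  acc <- rd(sensor_files[["Accelerometer"]])
  gyr <- rd(sensor_files[["Gyroscope"]])
  lgt <- rd(sensor_files[["Light"]])
  for (df in list(mag, acc, gyr, lgt)) {
    if (any(diff(df$seconds_elapsed) <= 0)) stop("non-monotone timestamps")
  }
  ns <- c(nrow(mag), nrow(acc), nrow(gyr), nrow(lgt))
  if (diff(range(ns)) > 1L)
    stop(sprintf("channel length mismatch after alignment exceeds 1 sample (%s)",
                 paste(ns, collapse = "/")))
  n <- min(ns)
  if (n < 1L) stop("empty sensor files")
  side <- file.path(directory_path, "labels.json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  if (!is.null(labels)) meta[names(labels)] <- labels
  if (is.null(meta$room)) stop("no room label found (labels.json missing or incomplete)")
  recording_session(
    session_id = meta$session_id %||% basename(directory_path),
    t = mag$seconds_elapsed[seq_len(n)],
    B = t(as.matrix(mag[seq_len(n), c("x", "y", "z")])),
    A = t(as.matrix(acc[seq_len(n), c("x", "y", "z")])),
    G = t(as.matrix(gyr[seq_len(n), c("x", "y", "z")])),
    L = lgt$illuminance[seq_len(n)],
    room = meta$room,
    activity = if (is.null(meta$activity)) NA_character_ else meta$activity,
    subject_id = if (is.null(meta$subject_id)) NA_character_ else meta$subject_id,
    sampling_rate = meta$sampling_rate %||% 100
  )
}
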