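## Population profiles and activity scripts for the synthetic IMU generator.

#' Base activity vocabulary
#'
#' The six study classes are represented by eleven base labels: the three
#' static postures, their small-movement variants (activities of daily living
#' performed while sitting/standing/lying), level walking, and the four
#' incline activities.  Transitions are rendered with composite labels of the
#' form `"<from>_to_<to>"` and are not part of this vocabulary.
#'
#' @return Character vector of valid base activity labels.
#' @export
base_activities <- function() {
  c("sit", "stand", "lie",
    "small_move_sit", "small_move_stand", "small_move_lie",
    "walk", "stairs_up", "stairs_down", "ramp_up", "ramp_down")
}

#' Default device tilt (pitch) per activity
#'
#' Pitch of the device frame relative to gravity, in degrees, for a phone worn
#' on the right-front hip.  The device frame has x,y in the face plane and z
#' pointing outward; upright stance places gravity approximately on +y
#' (9.81 m/s^2).  Sitting rotates the pelvis back so a substantial gravity
#' component appears on z; lying is close to 90 degrees.
#'
#' @return Named numeric vector of tilt angles (degrees) per base activity.
#' @export
default_pelvis_tilt <- function() {
  c(sit = 28, stand = 4, lie = 86,
    small_move_sit = 28, small_move_stand = 4, small_move_lie = 86,
    walk = 8, stairs_up = 16, stairs_down = 11,
    ramp_up = 12, ramp_down = 9)
}

#' Construct a population gait/posture profile
#'
#' A profile parameterises the synthetic signal generator: gait cadence and
#' step amplitude, left/right step-amplitude asymmetry (non-zero for
#' hemiparetic gait), per-activity device tilt, the skew imposed on vertical
#' linear acceleration during stair navigation, micro-rotation rate during
#' small movements, additive sensor noise, and the sampling-rate model
#' (nominally 50 Hz with a 3.84 Hz standard deviation, matching consumer
#' smartphone sampling jitter).
#'
#' @param profile_id One of `"able_bodied"`, `"elderly"`, `"stroke"`.
#' @param step_frequency Step cadence during walking, Hz (steps per second).
#' @param step_accel_amplitude Peak vertical linear acceleration per step, m/s^2.
#' @param gait_asymmetry Left/right step-amplitude ratio deviation in `[0, 1]`;
#'   alternate steps have amplitude scaled by `1 + a` and `1 - a`.
#' @param pelvis_tilt_by_activity Named numeric vector, degrees of device
#'   pitch per activity (see [default_pelvis_tilt()]).
#' @param stair_vertical_skew Dimensionless skew coefficient for the vertical
#'   linear-acceleration waveform on stairs; applied with positive sign for
#'   ascent and negative for descent.
#' @param small_move_rotation_rate Peak gyroscope rate during small
#'   movements, deg/s.
#' @param sensor_noise_sd Additive Gaussian noise on linear acceleration, m/s^2.
#' @param sample_rate_mean Mean sampling rate, Hz.
#' @param sample_rate_sd Standard deviation of the sampling rate, Hz.
#' @return An object of class `har_profile`.
#' @seealso [profile_defaults()] for the three study profiles.
#' @export
har_profile <- function(profile_id = c("able_bodied", "elderly", "stroke"),
                        step_frequency = 1.9,
                        step_accel_amplitude = 2.5,
                        gait_asymmetry = 0,
                        pelvis_tilt_by_activity = default_pelvis_tilt(),
                        stair_vertical_skew = 0.6,
                        small_move_rotation_rate = 20,
                        sensor_noise_sd = 0.15,
                        sample_rate_mean = 50,
                        sample_rate_sd = 3.84) {
  profile_id <- match.arg(profile_id)
  stopifnot(sample_rate_mean > 0, sensor_noise_sd >= 0,
            gait_asymmetry >= 0, gait_asymmetry <= 1,
            step_frequency > 0, step_accel_amplitude > 0)
  missing_tilt <- setdiff(base_activities(), names(pelvis_tilt_by_activity))
  if (length(missing_tilt) > 0) {
    stop("pelvis_tilt_by_activity missing activities: ",
         paste(missing_tilt, collapse = ", "))
  }
  structure(list(
    profile_id = profile_id,
    step_frequency = step_frequency,
    step_accel_amplitude = step_accel_amplitude,
    gait_asymmetry = gait_asymmetry,
    pelvis_tilt_by_activity = pelvis_tilt_by_activity,
    stair_vertical_skew = stair_vertical_skew,
    small_move_rotation_rate = small_move_rotation_rate,
    sensor_noise_sd = sensor_noise_sd,
    sample_rate_mean = sample_rate_mean,
    sample_rate_sd = sample_rate_sd
  ), class = "har_profile")
}

#' Default profiles for the three study populations
#'
#' Simulation defaults, not estimates of any real cohort: able-bodied gait has
#' symmetric steps at ~1.9 Hz; elderly gait is slower with reduced step
#' amplitude; hemiparetic stroke gait is slower still with a pronounced
#' left/right amplitude asymmetry (0.4).
#'
#' @param profile_id One of `"able_bodied"`, `"elderly"`, `"stroke"`.
#' @param ... Overrides passed on to [har_profile()].
#' @return A `har_profile`.
#' @export
profile_defaults <- function(profile_id = c("able_bodied", "elderly", "stroke"),
                             ...) {
  profile_id <- match.arg(profile_id)
  args <- switch(profile_id,
    able_bodied = list(step_frequency = 1.9, step_accel_amplitude = 2.5,
                       gait_asymmetry = 0, stair_vertical_skew = 0.6,
                       small_move_rotation_rate = 20, sensor_noise_sd = 0.15),
    elderly = list(step_frequency = 1.6, step_accel_amplitude = 1.7,
                   gait_asymmetry = 0.05, stair_vertical_skew = 0.5,
                   small_move_rotation_rate = 15, sensor_noise_sd = 0.15),
    stroke = list(step_frequency = 1.4, step_accel_amplitude = 1.5,
                  gait_asymmetry = 0.4, stair_vertical_skew = 0.5,
                  small_move_rotation_rate = 12, sensor_noise_sd = 0.18)
  )
  args$profile_id <- profile_id
  do.call(har_profile, utils::modifyList(args, list(...)))
}

#' Construct an activity script
#'
#' An ordered sequence of (activity, duration) segments describing a
#' continuous test circuit.  Consecutive segments with different postures
#' define implicit transition intervals at their boundaries.
#'
#' @param labels Character vector of base activity labels.
#' @param durations Numeric vector of segment durations in seconds (> 0).
#' @return A `har_script` data frame with columns `label`, `duration`,
#'   `start`, `end`.
#' @export
har_script <- function(labels, durations) {
  if (length(labels) == 0) stop("script must contain at least one segment")
  if (length(labels) != length(durations)) {
    stop("labels and durations must have equal length")
  }
  if (any(durations <= 0)) stop("segment durations must be positive")
  unknown <- setdiff(labels, base_activities())
  if (length(unknown) > 0) {
    stop("unknown activity label(s): ", paste(unknown, collapse = ", "))
  }
  end <- cumsum(durations)
  structure(data.frame(label = labels, duration = durations,
                       start = c(0, head(end, -1)), end = end,
                       stringsAsFactors = FALSE),
            class = c("har_script", "data.frame"))
}

#' Default test-circuit script
#'
#' A condensed daily-living circuit covering all six study classes: static
#' postures, small movements within them, level walking, stairs and ramps.
#' Segment durations are long enough that stable-state windows survive the
#' +/- 2 s transition buffer applied downstream.
#'
#' @return A `har_script`.
#' @export
default_script <- function() {
  har_script(
    labels = c("stand", "sit", "small_move_sit", "sit", "stand", "walk",
               "stairs_up", "walk", "stairs_down", "ramp_up", "ramp_down",
               "walk", "stand", "small_move_stand", "lie", "small_move_lie",
               "lie"),
    durations = c(10, 10, 9, 6, 8, 14, 9, 7, 9, 8, 8, 10, 8, 9, 9, 9, 7)
  )
}

#' Read an activity script from CSV
#'
#' @param path CSV file with columns `label,duration` (header row mandatory).
#' @return A `har_script`.
#' @export
read_script_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  har_script(df$label, df$duration)
}
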