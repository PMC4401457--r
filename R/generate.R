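## Synthetic IMU recording generator.
##
## Signal model: per-activity deterministic templates (tilted gravity +
## periodic / skewed linear acceleration + gyroscope bursts) plus additive
## Gaussian noise.  Transitions between postures are 1.5 s smooth (cosine)
## interpolations of the gravity orientation with an added movement burst,
## labelled with composite "<from>_to_<to>" labels.

G_STANDARD <- 9.81

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues form; used both by the generator (device mounting tilt) and by
#' tests as a closed-form oracle.
#'
#' @param axis Length-3 numeric axis (need not be unit length).
#' @param angle_deg Rotation angle in degrees (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  k <- axis / sqrt(sum(axis^2))
  phi <- angle_deg * pi / 180
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), nrow = 3)  # column-major: K %*% v = k x v
  diag(3) * cos(phi) + sin(phi) * K + (1 - cos(phi)) * tcrossprod(k)
}

## Jittered timestamps: mean spacing 1/rate_mean; i.i.d. Gaussian perturbation
## of the spacing (delta-method sd = rate_sd / rate_mean^2), truncated so
## timestamps stay strictly increasing.
.jittered_timestamps <- function(total, rate_mean, rate_sd) {
  dt0 <- 1 / rate_mean
  n_guess <- ceiling(total * rate_mean * 1.3) + 10
  sd_dt <- rate_sd / rate_mean^2
  dts <- dt0 + stats::rnorm(n_guess, 0, sd_dt)
  dts <- pmax(dts, 0.2 * dt0)
  t <- cumsum(c(0, dts))
  t[t < total]
}

## Per-sample tilt timeline (deg) with cosine interpolation of width 2*half
## around posture changes, plus composite transition labels.
.tilt_and_labels <- function(t, script, tilts, half = 0.75) {
  seg_idx <- findInterval(t, script$start, rightmost.closed = FALSE)
  seg_idx[seg_idx < 1] <- 1
  seg_idx[seg_idx > nrow(script)] <- nrow(script)
  label <- script$label[seg_idx]
  tilt <- unname(tilts[label])
  if (nrow(script) > 1) {
    for (b in seq_len(nrow(script) - 1)) {
      from <- script$label[b]; to <- script$label[b + 1]
      if (from == to) next
      tb <- script$end[b]
      in_band <- t >= tb - half & t < tb + half
      if (!any(in_band)) next
      label[in_band] <- paste(from, "to", to, sep = "_")
      t1 <- unname(tilts[from]); t2 <- unname(tilts[to])
      if (t1 != t2) {
        u <- (t[in_band] - (tb - half)) / (2 * half)
        tilt[in_band] <- t1 + (t2 - t1) * (1 - cos(pi * u)) / 2
      }
    }
  }
  list(tilt = tilt, label = label, segment = seg_idx)
}

## Activity-specific linear acceleration (n x 3) and gyro (n x 3) templates in
## the canonical body frame, given local segment time tau.
.activity_motion <- function(activity, tau, profile) {
  n <- length(tau)
  lin <- matrix(0, n, 3)
  gyr <- matrix(0, n, 3)
  f <- profile$step_frequency
  A <- profile$step_accel_amplitude
  gam <- profile$gait_asymmetry
  gait_like <- activity %in% c("walk", "stairs_up", "stairs_down",
                               "ramp_up", "ramp_down")
  if (gait_like) {
    amp_scale <- switch(activity, walk = 1, stairs_up = 0.9,
                        stairs_down = 0.9, ramp_up = 0.85, ramp_down = 0.85)
    step <- floor(f * tau)
    amp <- A * amp_scale * ifelse(step %% 2 == 0, 1 + gam, 1 - gam)
    ph <- 2 * pi * f * tau
    y_wave <- sin(ph)
    if (activity %in% c("stairs_up", "stairs_down")) {
      s <- profile$stair_vertical_skew *
        if (activity == "stairs_up") 1 else -1
      y_wave <- y_wave + s * (sin(ph)^2 - 0.5)
    }
    lin[, 2] <- amp * y_wave
    lin[, 3] <- 0.4 * A * amp_scale * sin(ph + pi / 2)
    lin[, 1] <- 0.2 * A * amp_scale * sin(pi * f * tau)
    gyr[, 3] <- 0.3 * sin(pi * f * tau)
    gyr[, 1] <- 0.1 * sin(ph)
  } else if (grepl("^small_move_", activity)) {
    rate <- profile$small_move_rotation_rate * pi / 180
    lin[, 1] <- 0.30 * sin(2 * pi * 0.8 * tau)
    lin[, 3] <- 0.25 * sin(2 * pi * 0.6 * tau + 1)
    gyr[, 2] <- rate * sin(2 * pi * 0.5 * tau)^2
    gyr[, 1] <- 0.3 * rate * sin(2 * pi * 0.7 * tau)
  }
  list(lin = lin, gyr = gyr)
}

#' Generate a labelled synthetic IMU recording
#'
#' Renders an activity script as a time-aligned multi-channel sensor stream:
#' per-sample timestamp (jittered ~50 Hz), raw acceleration, gravity, linear
#' acceleration (raw minus gravity, exactly), gyroscope, and a ground-truth
#' label.  Walking segments carry quasi-periodic vertical linear acceleration
#' at the profile's step frequency with left/right amplitude asymmetry; stair
#' segments add a skewed vertical waveform whose skew sign follows the
#' direction; static postures differ in the gravity components through the
#' profile's per-activity device tilt; small-movement segments add
#' micro-rotations.  The decomposition `accel_raw = gravity + accel_linear`
#' holds exactly and `||gravity|| = 9.81` at every sample.
#'
#' @param script A [har_script()].
#' @param profile A [har_profile()].
#' @param seed Integer seed; the output is deterministic given
#'   `(script, profile, seed, mount)`.
#' @param participant_id Identifier stored with the recording.
#' @param mount Optional 3x3 rotation applied to all vector channels,
#'   modelling device mounting orientation on the body (default identity).
#' @return A `har_recording`: list with `participant_id`, `t`, `accel_raw`,
#'   `gravity`, `accel_linear`, `gyro` (n x 3 matrices), `label` (character),
#'   and an `annotations` attribute (the script segments).
#' @export
generate_recording <- function(script, profile, seed = 1,
                               participant_id = "p01", mount = diag(3)) {
  stopifnot(inherits(script, "har_script"), inherits(profile, "har_profile"))
  set.seed(seed)
  total <- sum(script$duration)
  t <- .jittered_timestamps(total, profile$sample_rate_mean,
                            profile$sample_rate_sd)
  n <- length(t)
  tl <- .tilt_and_labels(t, script, profile$pelvis_tilt_by_activity)
  theta <- tl$tilt * pi / 180
  gravity <- cbind(0, G_STANDARD * cos(theta), G_STANDARD * sin(theta))

  lin <- matrix(0, n, 3)
  gyr <- matrix(0, n, 3)
  for (s in seq_len(nrow(script))) {
    in_seg <- tl$segment == s
    if (!any(in_seg)) next
    tau <- t[in_seg] - script$start[s]
    mo <- .activity_motion(script$label[s], tau, profile)
    lin[in_seg, ] <- mo$lin
    gyr[in_seg, ] <- mo$gyr
  }

  ## gyro x records the pitch rate during posture interpolation
  if (n > 2) {
    dtheta <- numeric(n)
    dtheta[2:(n - 1)] <- (theta[3:n] - theta[1:(n - 2)]) /
      (t[3:n] - t[1:(n - 2)])
    dtheta[1] <- (theta[2] - theta[1]) / (t[2] - t[1])
    dtheta[n] <- (theta[n] - theta[n - 1]) / (t[n] - t[n - 1])
    gyr[, 1] <- gyr[, 1] + dtheta
  }

  ## movement burst during transitions
  if (nrow(script) > 1) {
    for (b in seq_len(nrow(script) - 1)) {
      if (script$label[b] == script$label[b + 1]) next
      tb <- script$end[b]
      env <- exp(-((t - tb)^2) / (2 * 0.35^2))
      osc <- sin(2 * pi * 2 * (t - tb))
      lin[, 2] <- lin[, 2] + 0.8 * env * osc
      lin[, 3] <- lin[, 3] + 0.5 * env * osc
    }
  }

  if (profile$sensor_noise_sd > 0) {
    lin <- lin + matrix(stats::rnorm(3 * n, 0, profile$sensor_noise_sd), n, 3)
    gyr <- gyr + matrix(stats::rnorm(3 * n, 0, 0.15 * profile$sensor_noise_sd),
                        n, 3)
  }

  if (!isTRUE(all.equal(mount, diag(3)))) {
    gravity <- tcrossprod(gravity, mount)
    lin <- tcrossprod(lin, mount)
    gyr <- tcrossprod(gyr, mount)
  }

  rec <- structure(list(
    participant_id = participant_id,
    t = t,
    accel_raw = gravity + lin,
    gravity = gravity,
    accel_linear = lin,
    gyro = gyr,
    label = tl$label
  ), class = "har_recording")
  attr(rec, "annotations") <- data.frame(label = script$label,
                                         start_s = script$start,
                                         end_s = script$end,
                                         stringsAsFactors = FALSE)
  attr(rec, "profile_id") <- profile$profile_id
  rec
}

#' Generate a standing calibration sample
#'
#' A 10 s standing-still recording whose device orientation is rotated from
#' canonical upright (gravity on +y) by `tilt_perturbation` degrees about
#' `axis`.  Sensor noise is reduced to 5% of the profile level during the
#' second from 4 s to 5 s, giving the recording a contiguous quietest second
#' for the orientation-correction search.
#'
#' @param profile A [har_profile()].
#' @param tilt_perturbation Rotation angle in degrees.
#' @param seed Integer seed.
#' @param axis Rotation axis (default z).
#' @param participant_id Identifier stored with the recording.
#' @return A `har_recording` of duration 10 s, all samples labelled "stand".
#' @export
generate_calibration_sample <- function(profile, tilt_perturbation = 0,
                                        seed = 1, axis = c(0, 0, 1),
                                        participant_id = "p01") {
  stopifnot(inherits(profile, "har_profile"))
  set.seed(seed)
  t <- .jittered_timestamps(10, profile$sample_rate_mean,
                            profile$sample_rate_sd)
  n <- length(t)
  M <- rotation_about(axis, tilt_perturbation)
  g <- as.numeric(M %*% c(0, G_STANDARD, 0))
  gravity <- matrix(rep(g, each = n), n, 3)
  noise_sd <- rep(profile$sensor_noise_sd, n)
  noise_sd[t >= 4 & t < 5] <- 0.05 * profile$sensor_noise_sd
  lin <- matrix(stats::rnorm(3 * n, 0, rep(noise_sd, 3)), n, 3)
  gyr <- matrix(stats::rnorm(3 * n, 0, 0.1 * profile$sensor_noise_sd + 1e-12),
                n, 3)
  if (profile$sensor_noise_sd == 0) { lin[] <- 0; gyr[] <- 0 }
  rec <- structure(list(
    participant_id = participant_id,
    t = t,
    accel_raw = gravity + lin,
    gravity = gravity,
    accel_linear = lin,
    gyro = gyr,
    label = rep("stand", n)
  ), class = "har_recording")
  attr(rec, "annotations") <- data.frame(label = "stand", start_s = 0,
                                         end_s = 10, stringsAsFactors = FALSE)
  attr(rec, "profile_id") <- profile$profile_id
  rec
}

#' Generate a synthetic cohort
#'
#' One circuit recording plus one standing calibration sample per simulated
#' participant.  Per-participant seeds and device mounting tilts (Gaussian,
#' sd 8 degrees, about a random axis in the device x-z plane) are derived
#' deterministically from the master seed.
#'
#' @param n_per_profile Named integer vector, e.g.
#'   `c(able_bodied = 3, stroke = 2)`; names must be profile ids.
#' @param script A [har_script()] shared by all participants.
#' @param seed Master integer seed.
#' @param profiles Optional named list of `har_profile` objects overriding
#'   [profile_defaults()] per population.
#' @return A `har_cohort`: list of participants, each a list with
#'   `participant_id`, `profile_id`, `recording`, `calibration`.
#' @export
generate_cohort <- function(n_per_profile, script = default_script(),
                            seed = 1, profiles = NULL) {
  stopifnot(all(n_per_profile >= 0))
  out <- list()
  for (pid in names(n_per_profile)) {
    np <- n_per_profile[[pid]]
    if (np == 0) next
    prof <- if (!is.null(profiles) && !is.null(profiles[[pid]]))
      profiles[[pid]] else profile_defaults(pid)
    for (k in seq_len(np)) {
      part_id <- sprintf("%s_%02d", pid, k)
      sub_seed <- (seed + 7919 * (length(out) + 1)) %% .Machine$integer.max
      set.seed(sub_seed)
      ang <- stats::rnorm(1, 0, 8)
      ax_mix <- stats::runif(1, 0, 2 * pi)
      axis <- c(cos(ax_mix), 0, sin(ax_mix))
      M <- rotation_about(axis, ang)
      rec <- generate_recording(script, prof, seed = sub_seed + 1,
                                participant_id = part_id, mount = M)
      cal <- generate_calibration_sample(prof, tilt_perturbation = ang,
                                         seed = sub_seed + 2, axis = axis,
                                         participant_id = part_id)
      out[[part_id]] <- list(participant_id = part_id, profile_id = pid,
                             recording = rec, calibration = cal)
    }
  }
  structure(out, class = "har_cohort")
}

#' Write / read a recording as CSV
#'
#' Columns `t, ax, ay, az, gx, gy, gz, lx, ly, lz, wx, wy, wz, label`
#' (SI units; header row mandatory).
#'
#' @param recording A `har_recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  df <- data.frame(t = recording$t,
                   ax = recording$accel_raw[, 1], ay = recording$accel_raw[, 2],
                   az = recording$accel_raw[, 3],
                   gx = recording$gravity[, 1], gy = recording$gravity[, 2],
                   gz = recording$gravity[, 3],
                   lx = recording$accel_linear[, 1],
                   ly = recording$accel_linear[, 2],
                   lz = recording$accel_linear[, 3],
                   wx = recording$gyro[, 1], wy = recording$gyro[, 2],
                   wz = recording$gyro[, 3],
                   label = recording$label)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param participant_id Identifier attached to the recording on read.
#' @export
read_recording_csv <- function(path, participant_id = "p01") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(
    participant_id = participant_id,
    t = df$t,
    accel_raw = as.matrix(df[, c("ax", "ay", "az")]),
    gravity = as.matrix(df[, c("gx", "gy", "gz")]),
    accel_linear = as.matrix(df[, c("lx", "ly", "lz")]),
    gyro = as.matrix(df[, c("wx", "wy", "wz")]),
    label = df$label
  ), class = "har_recording")
}

#' Write annotation segments as CSV (`label, start_s, end_s`)
#'
#' @param recording A `har_recording` carrying an `annotations` attribute.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(recording, path) {
  ann <- attr(recording, "annotations")
  if (is.null(ann)) stop("recording has no annotations attribute")
  utils::write.csv(ann, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.har_recording <- function(x, ...) {
  cat(sprintf("<har_recording> %s: %d samples, %.1f s, %d labels\n",
              x$participant_id, length(x$t), max(x$t),
              length(unique(x$label))))
  invisible(x)
}
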