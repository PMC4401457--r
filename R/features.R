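## The 76 time-domain features computed per one-second window.
##
## Channels per window: raw acceleration A, gravity G, linear acceleration
## L = A - G, gyroscope W (all n x 3, device frame), and rotated linear
## acceleration RL = L %*% t(R) with R the orientation correction.
## Moment features use population (biased) estimators; kurtosis is
## non-excess (Gaussian -> 3).  Covariance/variance/SD features use the
## sample (n-1) estimators of stats::cov / stats::sd.  Zero-variance inputs
## return 0 for skewness, kurtosis and correlations (documented convention).
##
## Covariance-element ordering for the three 6-element blocks is diagonal
## first, then off-diagonals: (1,1), (2,2), (3,3), (1,2), (1,3), (2,3) —
## e.g. the gravity block 25..30 is xx, yy, zz, xy, xz, yz.

N_FEATURES <- 76L

.cov6 <- function(M) {
  C <- stats::cov(M)
  c(C[1, 1], C[2, 2], C[3, 3], C[1, 2], C[1, 3], C[2, 3])
}

.skew_pop <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 < 1e-24) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

.kurt_pop <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 < 1e-24) return(0)
  mean((x - mean(x))^4) / m2^2
}

#' Harmonic mean of the absolute values of a series
#'
#' `n / sum(1 / |s|)`; a series containing a zero (or an empty/all-zero
#' series) returns 0 by convention, since the harmonic mean is dominated by
#' its smallest element.
#'
#' @param series Numeric vector.
#' @return Scalar harmonic mean.
#' @export
harmonic_mean <- function(series) {
  if (length(series) == 0) stop("series must be non-empty")
  a <- abs(series)
  if (any(a < 1e-300)) return(0)
  length(a) / sum(1 / a)
}

.safe_cor <- function(a, b) {
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(0)
  stats::cor(a, b)
}

## sign-change count per second; zeros are skipped when assigning signs
.cross_rate <- function(x, dur) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0)
  sum(diff(s) != 0) / dur
}

#' The feature registry
#'
#' Index, name, source channel and family for each of the 76 features.  The
#' registry is the canonical naming used by all reports.
#'
#' @return Data frame with columns `index`, `name`, `channel`, `family`.
#' @export
feature_registry <- function() {
  reg <- list(
    list(1, "sum_range_linear_accel", "linear", "range"),
    list(2, "sum_sd_linear_accel", "linear", "dispersion"),
    list(3, "sma_sum_range_linear_accel", "linear", "moving_average"),
    list(4, "gravity_difference_to_y", "gravity", "orientation"),
    list(5, "range_gravity_x", "gravity", "range"),
    list(6, "range_gravity_y", "gravity", "range"),
    list(7, "range_gravity_z", "gravity", "range"),
    list(8, "mean_gravity_x", "gravity", "orientation"),
    list(9, "mean_gravity_y", "gravity", "orientation"),
    list(10, "mean_gravity_z", "gravity", "orientation"),
    list(11, "range_linear_accel_x", "linear", "range"),
    list(12, "range_linear_accel_y", "linear", "range"),
    list(13, "range_linear_accel_z", "linear", "range"),
    list(14, "mean_linear_accel_x", "linear", "central"),
    list(15, "mean_linear_accel_y", "linear", "central"),
    list(16, "mean_linear_accel_z", "linear", "central"),
    list(17, "kurtosis_gravity_x", "gravity", "shape"),
    list(18, "kurtosis_gravity_y", "gravity", "shape"),
    list(19, "kurtosis_gravity_z", "gravity", "shape"),
    list(20, "sum_kurtosis_gravity", "gravity", "shape"),
    list(21, "sum_sd_linear_accel_dup", "linear", "dispersion"),
    list(22, "sum_var_gravity", "gravity", "dispersion"),
    list(23, "sma_sum_var_gravity", "gravity", "moving_average"),
    list(24, "max_slope_sma_sum_var_gravity", "gravity", "moving_average"),
    list(25, "cov_gravity_xx", "gravity", "covariance"),
    list(26, "cov_gravity_yy", "gravity", "covariance"),
    list(27, "cov_gravity_zz", "gravity", "covariance"),
    list(28, "cov_gravity_xy", "gravity", "covariance"),
    list(29, "cov_gravity_xz", "gravity", "covariance"),
    list(30, "cov_gravity_yz", "gravity", "covariance"),
    list(31, "cov_linear_xx", "linear", "covariance"),
    list(32, "cov_linear_yy", "linear", "covariance"),
    list(33, "cov_linear_zz", "linear", "covariance"),
    list(34, "cov_linear_xy", "linear", "covariance"),
    list(35, "cov_linear_xz", "linear", "covariance"),
    list(36, "cov_linear_yz", "linear", "covariance"),
    list(37, "cov_rotated_xx", "rotated_linear", "covariance"),
    list(38, "cov_rotated_yy", "rotated_linear", "covariance"),
    list(39, "cov_rotated_zz", "rotated_linear", "covariance"),
    list(40, "cov_rotated_xy", "rotated_linear", "covariance"),
    list(41, "cov_rotated_xz", "rotated_linear", "covariance"),
    list(42, "cov_rotated_yz", "rotated_linear", "covariance"),
    list(43, "velocity_rotated_xz", "rotated_linear", "velocity"),
    list(44, "velocity_rotated_y", "rotated_linear", "velocity"),
    list(45, "mean_norm_linear", "linear", "magnitude"),
    list(46, "mean_norm_rotated_linear", "rotated_linear", "magnitude"),
    list(47, "mean_norm_raw", "raw", "magnitude"),
    list(48, "skew_rotated_x", "rotated_linear", "shape"),
    list(49, "skew_rotated_y", "rotated_linear", "shape"),
    list(50, "skew_rotated_z", "rotated_linear", "shape"),
    list(51, "ma_skew_rotated_x", "rotated_linear", "moving_average"),
    list(52, "ma_skew_rotated_y", "rotated_linear", "moving_average"),
    list(53, "ma_skew_rotated_z", "rotated_linear", "moving_average"),
    list(54, "sum_ma_skew_rotated_xy", "rotated_linear", "moving_average"),
    list(55, "range_rotated_x", "rotated_linear", "range"),
    list(56, "ma_distance_rotated", "rotated_linear", "moving_average"),
    list(57, "mean_abs_linear_x", "linear", "central"),
    list(58, "mean_abs_linear_y", "linear", "central"),
    list(59, "mean_abs_linear_z", "linear", "central"),
    list(60, "harmonic_mean_linear_x", "linear", "central"),
    list(61, "harmonic_mean_linear_y", "linear", "central"),
    list(62, "harmonic_mean_linear_z", "linear", "central"),
    list(63, "cumsum_linear_x", "linear", "central"),
    list(64, "cumsum_linear_y", "linear", "central"),
    list(65, "cumsum_linear_z", "linear", "central"),
    list(66, "cor_gravity_heading_accel", "rotated_linear", "correlation"),
    list(67, "mean_velocity_gravity_dir", "rotated_linear", "velocity"),
    list(68, "mean_velocity_heading_dir", "rotated_linear", "velocity"),
    list(69, "mean_gyro_x", "gyro", "central"),
    list(70, "mean_gyro_y", "gyro", "central"),
    list(71, "mean_gyro_z", "gyro", "central"),
    list(72, "iqr_linear_x", "linear", "dispersion"),
    list(73, "iqr_linear_y", "linear", "dispersion"),
    list(74, "iqr_linear_z", "linear", "dispersion"),
    list(75, "zero_cross_rate_linear_y", "linear", "crossing"),
    list(76, "mean_cross_rate_linear_y", "linear", "crossing")
  )
  data.frame(index = vapply(reg, function(r) as.integer(r[[1]]), integer(1)),
             name = vapply(reg, `[[`, character(1), 2),
             channel = vapply(reg, `[[`, character(1), 3),
             family = vapply(reg, `[[`, character(1), 4),
             stringsAsFactors = FALSE)
}

#' Export the feature registry as JSON
#'
#' @param path Output path.
#' @param W Moving-average span recorded in the params of the
#'   moving-average features.
#' @return `path`, invisibly.
#' @export
write_feature_registry_json <- function(path, W = 3) {
  reg <- feature_registry()
  reg$params <- ifelse(reg$family == "moving_average",
                       sprintf("W=%d", W), "")
  jsonlite::write_json(reg, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Create an empty moving-average context
#'
#' Holds the per-recording history needed by the moving-average features:
#' the last `W` values of the sum-of-range (feature 1), sum-of-gravity-
#' variance (feature 22), its running SMA series (for the max-slope feature),
#' the per-axis skewness triplets, and the per-window mean distance of
#' rotated linear acceleration from its window mean.  At the start of a
#' recording, averages are taken over the windows available so far.
#'
#' @param W Moving-average span in windows (= seconds); default 3.
#' @return A `har_context`.
#' @export
har_context <- function(W = 3) {
  stopifnot(W >= 1)
  structure(list(W = W, f1 = numeric(0), f22 = numeric(0),
                 sma22 = numeric(0), skew = matrix(numeric(0), 0, 3),
                 dist = numeric(0)),
            class = "har_context")
}

.push_tail <- function(x, v, W) {
  x <- c(x, v)
  if (length(x) > W) x <- x[(length(x) - W + 1):length(x)]
  x
}

#' Maximum slope of the simple-moving-average series
#'
#' Maximum successive difference of the SMA-of-summed-gravity-variance
#' series held in the context (including the current window's value); with
#' fewer than 2 points of SMA history the cold-start value is 0.
#'
#' @param sma_history Numeric vector of SMA values, oldest first.
#' @return Scalar maximum successive difference.
#' @export
max_slope_sma <- function(sma_history) {
  if (length(sma_history) < 2) return(0)
  max(diff(sma_history))
}

#' Correlation between acceleration along gravity and heading
#'
#' In the orientation-corrected frame the vertical axis is +y; the heading
#' is the unit vector of the window-mean horizontal (x, z) rotated linear
#' acceleration.  Returns the Pearson correlation between the vertical
#' component and the component along heading.  If the mean horizontal
#' acceleration norm is below `1e-6` (heading undefined) or either component
#' has zero variance, returns 0 by convention.
#'
#' @param RL n x 3 rotated linear acceleration.
#' @return Correlation in `[-1, 1]`.
#' @export
grav_heading_correlation <- function(RL) {
  h <- c(mean(RL[, 1]), mean(RL[, 3]))
  hn <- sqrt(sum(h^2))
  if (hn < 1e-6) return(0)
  h <- h / hn
  a_head <- RL[, 1] * h[1] + RL[, 3] * h[2]
  .safe_cor(RL[, 2], a_head)
}

#' Compute the 76-feature vector for one window
#'
#' @param window A `har_window` from [segment_windows()].
#' @param recording The `har_recording` the window indexes into.
#' @param context A `har_context` carrying moving-average history; pass the
#'   updated context returned by the previous call on the same recording.
#' @param correction A `har_rotation` from
#'   [estimate_orientation_correction()] (or a bare 3x3 matrix).
#' @return List with `values` (named numeric vector of length 76) and
#'   `context` (updated history).
#' @export
compute_feature_vector <- function(window, recording, context, correction) {
  idx <- window$sample_idx
  if (length(idx) < 2) stop("degenerate window: fewer than 2 samples")
  t <- recording$t[idx]
  A <- recording$accel_raw[idx, , drop = FALSE]
  G <- recording$gravity[idx, , drop = FALSE]
  L <- recording$accel_linear[idx, , drop = FALSE]
  Wg <- recording$gyro[idx, , drop = FALSE]
  RL <- apply_rotation(L, correction)
  dur <- window$duration
  v <- numeric(N_FEATURES)

  rng <- function(x) max(x) - min(x)
  l_range <- apply(L, 2, rng)
  g_range <- apply(G, 2, rng)
  l_sd <- apply(L, 2, stats::sd)
  g_kurt <- apply(G, 2, .kurt_pop)
  g_cov <- .cov6(G)
  l_cov <- .cov6(L)
  rl_cov <- .cov6(RL)
  rl_skew <- apply(RL, 2, .skew_pop)

  v[1] <- sum(l_range)
  v[2] <- sum(l_sd)
  v[4] <- mean(G[, 2]) - mean(G[, 3]) - mean(G[, 1])
  v[5:7] <- g_range
  v[8:10] <- colMeans(G)
  v[11:13] <- l_range
  v[14:16] <- colMeans(L)
  v[17:19] <- g_kurt
  v[20] <- sum(g_kurt)
  v[21] <- v[2]
  v[22] <- sum(g_cov[1:3])
  v[25:30] <- g_cov
  v[31:36] <- l_cov
  v[37:42] <- rl_cov

  vx <- pracma::trapz(t, RL[, 1])
  vz <- pracma::trapz(t, RL[, 3])
  v[43] <- sqrt(vx^2 + vz^2)
  v[44] <- pracma::trapz(t, RL[, 2])
  v[45] <- mean(sqrt(rowSums(L^2)))
  v[46] <- mean(sqrt(rowSums(RL^2)))
  v[47] <- mean(sqrt(rowSums(A^2)))
  v[48:50] <- rl_skew
  v[55] <- rng(RL[, 1])
  v[57:59] <- colMeans(abs(L))
  v[60:62] <- apply(L, 2, harmonic_mean)
  v[63:65] <- colSums(L)
  v[66] <- grav_heading_correlation(RL)
  v[67] <- mean(pracma::cumtrapz(t, RL[, 2]))
  h <- c(mean(RL[, 1]), mean(RL[, 3]))
  hn <- sqrt(sum(h^2))
  v[68] <- if (hn < 1e-6) 0 else {
    h <- h / hn
    mean(pracma::cumtrapz(t, RL[, 1] * h[1] + RL[, 3] * h[2]))
  }
  v[69:71] <- colMeans(Wg)
  v[72:74] <- apply(L, 2, stats::IQR)
  v[75] <- .cross_rate(L[, 2], dur)
  v[76] <- .cross_rate(L[, 2] - mean(L[, 2]), dur)

  ## moving-average features: update history, average over available windows
  Wspan <- context$W
  context$f1 <- .push_tail(context$f1, v[1], Wspan)
  context$f22 <- .push_tail(context$f22, v[22], Wspan)
  v[3] <- mean(context$f1)
  v[23] <- mean(context$f22)
  context$sma22 <- .push_tail(context$sma22, v[23], Wspan)
  v[24] <- max_slope_sma(context$sma22)
  context$skew <- rbind(context$skew, rl_skew)
  if (nrow(context$skew) > Wspan) {
    context$skew <- context$skew[(nrow(context$skew) - Wspan + 1):
                                   nrow(context$skew), , drop = FALSE]
  }
  v[51:53] <- colMeans(context$skew)
  v[54] <- v[51] + v[52]
  d_now <- mean(sqrt(rowSums(sweep(RL, 2, colMeans(RL))^2)))
  context$dist <- .push_tail(context$dist, d_now, Wspan)
  v[56] <- mean(context$dist)

  names(v) <- feature_registry()$name
  list(values = v, context = context)
}

#' Compute the feature matrix for a list of windows
#'
#' Iterates [compute_feature_vector()] over the windows of one recording in
#' order, threading the moving-average context (which is reset at the start
#' of the recording).
#'
#' @param recording A `har_recording`.
#' @param windows Windows from [segment_windows()] (optionally after
#'   [apply_transition_buffer()]); must be in chronological order.
#' @param correction A `har_rotation` (or 3x3 matrix).
#' @param W Moving-average span in windows; default 3.
#' @return Numeric matrix, `length(windows)` x 76, with registry column names.
#' @export
compute_features <- function(recording, windows, correction, W = 3) {
  ctx <- har_context(W)
  out <- matrix(NA_real_, length(windows), N_FEATURES,
                dimnames = list(NULL, feature_registry()$name))
  for (k in seq_along(windows)) {
    fv <- compute_feature_vector(windows[[k]], recording, ctx, correction)
    out[k, ] <- fv$values
    ctx <- fv$context
  }
  out
}
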