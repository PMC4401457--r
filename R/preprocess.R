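## Orientation correction, 1 s windowing, transition buffering, and the
## seven level-specific labelled datasets.

#' Estimate the orientation correction from a standing calibration sample
#'
#' Searches the calibration recording with a sliding 1 s window (0.1 s
#' stride) for the second with the smallest sum over axes of the raw
#' acceleration standard deviation (ties broken by the earliest window), and
#' builds the shortest-arc (quaternion) rotation aligning the mean measured
#' gravity direction in that window with the canonical upright axis +y, so
#' that `R %*% mean(gravity)` is approximately `(0, 9.81, 0)`.  Heading (the
#' rotation about the vertical) is left unconstrained and fixed implicitly by
#' the minimal-rotation choice.
#'
#' @param calibration A `har_recording` of standing-still data, >= 2 s.
#' @return A `har_rotation`: list with `R` (3x3 orthonormal, det +1) and
#'   `source_window` `(start_s, end_s)` of the calibration second used.
#' @export
estimate_orientation_correction <- function(calibration) {
  stopifnot(inherits(calibration, "har_recording"))
  t <- calibration$t
  dur <- t[length(t)] - t[1]
  if (dur < 1) stop("calibration must contain at least 1 s of data")
  starts <- seq(t[1], t[1] + dur - 1, by = 0.1)
  sd_sum <- vapply(starts, function(s) {
    in_w <- t >= s & t < s + 1
    if (sum(in_w) < 2) return(Inf)
    sum(apply(calibration$accel_raw[in_w, , drop = FALSE], 2, stats::sd))
  }, numeric(1))
  best <- which.min(sd_sum)  # earliest window on ties
  s0 <- starts[best]
  in_w <- t >= s0 & t < s0 + 1
  g_mean <- colMeans(calibration$accel_raw[in_w, , drop = FALSE])
  if (sqrt(sum(g_mean^2)) < 1) {
    stop("invalid calibration: near-zero mean acceleration")
  }
  R <- .shortest_arc_rotation(g_mean, c(0, 1, 0))
  structure(list(R = R, source_window = c(start_s = s0, end_s = s0 + 1)),
            class = "har_rotation")
}

## Shortest-arc rotation taking direction u onto direction v, built from the
## quaternion q = (cos(a/2), sin(a/2) * axis) with axis = u x v / |u x v|.
.shortest_arc_rotation <- function(u, v) {
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  ax <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s_ <- sqrt(sum(ax^2))
  if (s_ < 1e-12) {
    if (c_ > 0) return(diag(3))
    ## antipodal: rotate pi about any axis orthogonal to u
    ortho <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ortho - sum(ortho * u) * u
    ax <- ax / sqrt(sum(ax^2))
    return(2 * tcrossprod(ax) - diag(3))
  }
  ax <- ax / s_
  half <- sqrt((1 + c_) / 2)        # cos(a/2)
  qv <- ax * sqrt((1 - c_) / 2)     # sin(a/2) * axis
  w <- half
  x <- qv[1]; y <- qv[2]; z <- qv[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3)
}

#' Apply a rotation correction to a 3-vector series
#'
#' @param stream n x 3 numeric matrix.
#' @param correction A `har_rotation` (or bare 3x3 matrix).
#' @return n x 3 matrix of per-sample rotated vectors (norms preserved).
#' @export
apply_rotation <- function(stream, correction) {
  R <- if (inherits(correction, "har_rotation")) correction$R else correction
  stream %*% t(R)
}

#' Segment a recording into consecutive one-second windows
#'
#' Windows are half-open intervals `[k, k+1)` seconds from the first
#' timestamp, non-overlapping; the trailing partial second is discarded.
#' Each window's label is the majority per-sample label, ties broken by the
#' earliest label occurring in the window.
#'
#' @param recording A `har_recording` of duration >= 1 s.
#' @return A list of `har_window` objects: `participant_id`, `index`
#'   (1-based), `t_start`, `duration` (1), `sample_idx` (row indices into the
#'   recording), `label`.
#' @export
segment_windows <- function(recording) {
  t <- recording$t
  if (length(t) == 0) return(list())
  t0 <- t[1]
  n_win <- floor(t[length(t)] - t0)
  if (n_win < 1) return(list())
  out <- vector("list", n_win)
  for (k in seq_len(n_win)) {
    lo <- t0 + (k - 1)
    idx <- which(t >= lo & t < lo + 1)
    labs <- recording$label[idx]
    counts <- table(factor(labs, levels = unique(labs)))  # unique() keeps
    lab <- names(counts)[which.max(counts)]               # earliest on ties
    out[[k]] <- structure(list(participant_id = recording$participant_id,
                               index = k, t_start = lo, duration = 1,
                               sample_idx = idx, label = lab),
                          class = "har_window")
  }
  out
}

#' Relabel windows inside the transition buffer
#'
#' For every change of state in the annotations (boundary between two
#' consecutive segments with different labels), a 2 s buffer on either side
#' is taken; every window intersecting `[change - 2, change + 2]` is
#' relabelled with the composite transition label `"<from>_to_<to>"`.  Such
#' windows are excluded from the level 1-6 datasets and form the level 7
#' occurrences.  Windows whose majority label was already a composite
#' transition label are marked as transitions as well.
#'
#' @param windows List of `har_window` from [segment_windows()].
#' @param annotations Data frame `label, start_s, end_s` of stable segments.
#' @param buffer_s Buffer half-width in seconds (default 2).
#' @return The window list with updated `label` and a logical
#'   `is_transition` field on every window.
#' @export
apply_transition_buffer <- function(windows, annotations, buffer_s = 2) {
  if (length(windows) == 0) return(windows)
  changes <- list()
  if (nrow(annotations) > 1) {
    for (b in seq_len(nrow(annotations) - 1)) {
      from <- annotations$label[b]; to <- annotations$label[b + 1]
      if (from == to) next
      changes[[length(changes) + 1]] <-
        list(at = annotations$end_s[b],
             label = paste(from, "to", to, sep = "_"))
    }
  }
  for (k in seq_along(windows)) {
    w <- windows[[k]]
    w$is_transition <- grepl("_to_", w$label)
    for (ch in changes) {
      ## any overlap of [t_start, t_start+1) with [at - buffer, at + buffer]
      if (w$t_start < ch$at + buffer_s && w$t_start + w$duration > ch$at - buffer_s) {
        w$label <- ch$label
        w$is_transition <- TRUE
      }
    }
    windows[[k]] <- w
  }
  windows
}

## Class mapping per level.  Returns the class for a window label at a level,
## or NA_character_ if the label is not part of that level's class set.
.level_class <- function(label, level) {
  is_trans <- grepl("_to_", label)
  small <- grepl("^small_move_", label)
  base <- sub("^small_move_", "", label)
  mobile <- label %in% c("walk", "stairs_up", "stairs_down",
                         "ramp_up", "ramp_down")
  switch(as.character(level),
    "1" = if (is_trans) NA_character_
          else if (mobile) "mobile" else "immobile",
    "2" = if (!is_trans && !small && label %in% c("sit", "stand")) label
          else NA_character_,
    "3" = if (!is_trans && base %in% c("sit", "stand", "lie")) base
          else NA_character_,
    "4" = if (is_trans) NA_character_
          else if (label %in% c("walk", "ramp_up", "ramp_down"))
            "large_movements"
          else if (label %in% c("stairs_up", "stairs_down")) "stairs"
          else NA_character_,
    "5" = if (is_trans) NA_character_
          else if (label == "walk") "large_movements"
          else if (label %in% c("stairs_up", "stairs_down",
                                "ramp_up", "ramp_down")) label
          else NA_character_,
    "6" = if (is_trans) NA_character_
          else if (small) "small_moves"
          else if (label %in% c("sit", "stand", "lie")) "none"
          else NA_character_,
    "7" = if (is_trans) label else NA_character_,
    stop("level must be an integer in 1..7")
  )
}

#' Build the labelled dataset for one detail level
#'
#' The seven levels map the same windows onto class sets of increasing
#' granularity: level 1 mobile/immobile; level 2 sit/stand (small-movement
#' variants excluded); level 3 sit/stand/lie (small movements included under
#' their base posture); level 4 large movements vs stairs (ramps folded into
#' large movements); level 5 ramp up/ramp down/large movements/stairs
#' up/stairs down; level 6 small movements yes/no within immobile states;
#' level 7 transition classes only.  Windows whose label is outside the
#' level's class set are dropped.
#'
#' @param windows List of `har_window` (after [apply_transition_buffer()]).
#' @param features Numeric matrix of per-window feature vectors, rows aligned
#'   with `windows`.
#' @param level Integer 1-7.
#' @return A `har_level_dataset`: list with `level`, `X` (occurrences x 76),
#'   `y` (character classes), `groups` (participant ids), `window_index`.
#' @export
build_level_dataset <- function(windows, features, level) {
  stopifnot(length(level) == 1, level %in% 1:7)
  if (length(windows) == 0) {
    return(structure(list(level = level,
                          X = matrix(numeric(0), 0, ncol(feature_registry())),
                          y = character(0), groups = character(0),
                          window_index = integer(0)),
                     class = "har_level_dataset"))
  }
  stopifnot(nrow(features) == length(windows))
  cls <- vapply(windows, function(w) .level_class(w$label, level),
                character(1))
  keep <- !is.na(cls)
  structure(list(
    level = level,
    X = features[keep, , drop = FALSE],
    y = cls[keep],
    groups = vapply(windows[keep], `[[`, character(1), "participant_id"),
    window_index = vapply(windows[keep], `[[`, integer(1), "index")
  ), class = "har_level_dataset")
}

#' @export
print.har_level_dataset <- function(x, ...) {
  cat(sprintf("<har_level_dataset> level %d: %d occurrences, classes: %s\n",
              x$level, length(x$y),
              paste(names(table(x$y)), table(x$y), sep = "=", collapse = ", ")))
  invisible(x)
}
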