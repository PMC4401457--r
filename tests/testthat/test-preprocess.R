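test_that("orientation correction is identity for an upright calibration", {
  prof <- profile_defaults("able_bodied", sensor_noise_sd = 0)
  cal <- generate_calibration_sample(prof, 0, seed = 1)
  corr <- estimate_orientation_correction(cal)
  expect_equal(corr$R, diag(3), tolerance = 1e-9)
})

test_that("orientation correction recovers arbitrary tilts in closed form", {
  prof <- profile_defaults("able_bodied", sensor_noise_sd = 0)
  for (ang in c(-40, 15, 30, 75)) {
    cal <- generate_calibration_sample(prof, ang, seed = 1, axis = c(0, 0, 1))
    corr <- estimate_orientation_correction(cal)
    ## R^T R = I, det = +1
    expect_lt(max(abs(crossprod(corr$R) - diag(3))), 1e-9)
    expect_equal(det(corr$R), 1, tolerance = 1e-9)
    ## shortest-arc rotation about z is the closed-form inverse tilt
    expect_equal(corr$R, rotation_about(c(0, 0, 1), -ang), tolerance = 1e-6)
    g <- as.numeric(corr$R %*% colMeans(cal$gravity))
    expect_equal(g, c(0, 9.81, 0), tolerance = 1e-6)
  }
})

test_that("quietest-second search picks the low-noise calibration second", {
  prof <- profile_defaults("elderly")  # noisy, except the built-in quiet second
  cal <- generate_calibration_sample(prof, 20, seed = 6)
  corr <- estimate_orientation_correction(cal)
  expect_gte(corr$source_window[["start_s"]], 3.5)
  expect_lte(corr$source_window[["end_s"]], 5.5)
})

test_that("degenerate calibrations are rejected", {
  prof <- profile_defaults("able_bodied", sensor_noise_sd = 0)
  cal <- generate_calibration_sample(prof, 0, seed = 1)
  short <- cal
  keep <- short$t < 0.5
  for (f in c("t", "label")) short[[f]] <- short[[f]][keep]
  for (f in c("accel_raw", "gravity", "accel_linear", "gyro")) {
    short[[f]] <- short[[f]][keep, , drop = FALSE]
  }
  expect_error(estimate_orientation_correction(short), "at least 1 s")
  zero <- cal
  zero$accel_raw <- zero$accel_raw * 0
  expect_error(estimate_orientation_correction(zero), "near-zero")
})

test_that("apply_rotation is an isometry and matches single-vector oracles", {
  series <- matrix(rnorm(300), 100, 3)
  expect_identical(apply_rotation(series, diag(3)), series)
  R90 <- rotation_about(c(0, 0, 1), 90)
  corr <- structure(list(R = R90), class = "har_rotation")
  out <- apply_rotation(matrix(c(1, 0, 0), 1, 3), corr)
  expect_equal(as.numeric(out), c(0, 1, 0), tolerance = 1e-12)
  rot <- apply_rotation(series, corr)
  expect_lt(max(abs(sqrt(rowSums(rot^2)) - sqrt(rowSums(series^2)))), 1e-9)
})

test_that("windowing follows the one-second rule and drops the partial tail", {
  prof <- profile_defaults("able_bodied", sample_rate_sd = 0,
                           sensor_noise_sd = 0)
  w10 <- segment_windows(generate_recording(har_script("stand", 10.02),
                                            prof, seed = 1))
  expect_length(w10, 10)
  w107 <- segment_windows(generate_recording(har_script("stand", 10.7),
                                             prof, seed = 1))
  expect_length(w107, 10)
  expect_lt(w107[[10]]$t_start + 1, 10.7)
})

test_that("jittered windows contain exactly the samples in their interval", {
  rec <- generate_recording(har_script("walk", 12),
                            profile_defaults("stroke"), seed = 13)
  w <- segment_windows(rec)
  counts <- integer(0)
  for (win in w) {
    expected <- which(rec$t >= win$t_start & rec$t < win$t_start + 1)
    expect_identical(win$sample_idx, expected)
    counts <- c(counts, length(expected))
  }
  expect_gt(stats::sd(counts), 0)    # jitter varies the per-window count
  expect_equal(mean(counts), 50, tolerance = 2)
})

test_that("window labels are the majority with earliest-label tie-break", {
  ## 0.4 s sit + 0.6 s stand in one window -> majority stand
  t <- seq(0, 1, by = 0.02)
  lin <- matrix(0, length(t), 3)
  rec <- make_test_recording(t, lin)
  rec$label <- ifelse(t < 0.4, "sit", "stand")
  w <- segment_windows(rec)
  expect_equal(w[[1]]$label, "stand")
  ## exact 50/50 tie -> earliest label in the window
  rec$label <- ifelse(t < 0.5, "sit", "stand")
  expect_equal(segment_windows(rec)[[1]]$label, "sit")
})

test_that("transition buffer relabels exactly the +/- 2 s neighbourhood", {
  prof <- profile_defaults("able_bodied", sample_rate_sd = 0,
                           sensor_noise_sd = 0)
  sc <- har_script(c("sit", "stand"), c(10, 10))
  rec <- generate_recording(sc, prof, seed = 1)
  w <- apply_transition_buffer(segment_windows(rec),
                               attr(rec, "annotations"))
  labs <- vapply(w, `[[`, character(1), "label")
  trans <- vapply(w, `[[`, logical(1), "is_transition")
  ## change at t = 10: windows covering [8, 12] are transitions; these are
  ## the 1-based windows 9..12 (window k spans [k-1, k))
  expect_true(all(trans[9:12]))
  expect_true(all(labs[9:12] == "sit_to_stand"))
  expect_false(any(trans[c(1:8, 13:length(w))]))
  ## no state change -> unchanged
  rec1 <- generate_recording(har_script("walk", 8), prof, seed = 1)
  w1 <- segment_windows(rec1)
  expect_equal(vapply(apply_transition_buffer(w1, attr(rec1, "annotations")),
                      `[[`, character(1), "label"),
               vapply(w1, `[[`, character(1), "label"))
})

test_that("close state changes merge into one buffered region", {
  prof <- profile_defaults("able_bodied", sample_rate_sd = 0,
                           sensor_noise_sd = 0)
  sc <- har_script(c("sit", "stand", "walk"), c(10, 3, 10))
  rec <- generate_recording(sc, prof, seed = 1)
  w <- apply_transition_buffer(segment_windows(rec),
                               attr(rec, "annotations"))
  trans <- vapply(w, `[[`, logical(1), "is_transition")
  ## changes at 10 and 13: buffers [8,12] and [11,15] overlap; the 3 s
  ## stand segment is fully absorbed into the transition region [8, 15],
  ## i.e. windows 9..15 (window k spans [k-1, k))
  expect_true(all(trans[9:15]))
  expect_false(any(trans[c(1:8, 16:length(w))]))
  labs <- vapply(w, `[[`, character(1), "label")
  expect_false(any(labs[trans] %in% base_activities()))
})

test_that("level class mapping follows the seven level definitions", {
  expect_equal(harselect:::.level_class("stairs_up", 1), "mobile")
  expect_equal(harselect:::.level_class("stairs_up", 4), "stairs")
  expect_equal(harselect:::.level_class("stairs_up", 5), "stairs_up")
  expect_true(is.na(harselect:::.level_class("stairs_up", 2)))
  expect_true(is.na(harselect:::.level_class("small_move_stand", 2)))
  expect_equal(harselect:::.level_class("small_move_stand", 3), "stand")
  expect_equal(harselect:::.level_class("small_move_stand", 6), "small_moves")
  expect_equal(harselect:::.level_class("small_move_stand", 1), "immobile")
  expect_equal(harselect:::.level_class("ramp_up", 4), "large_movements")
  expect_equal(harselect:::.level_class("ramp_up", 5), "ramp_up")
  expect_equal(harselect:::.level_class("walk", 5), "large_movements")
  expect_equal(harselect:::.level_class("sit_to_stand", 7), "sit_to_stand")
  expect_true(is.na(harselect:::.level_class("sit_to_stand", 1)))
  expect_true(is.na(harselect:::.level_class("walk", 6)))
})

test_that("level datasets respect membership, nesting and conservation", {
  coh <- generate_cohort(c(able_bodied = 1), default_script(), seed = 17)
  pre <- preprocess_participant(coh[[1]])
  w <- pre$windows; f <- pre$features
  ds <- lapply(1:7, function(l) build_level_dataset(w, f, l))
  trans_idx <- which(vapply(w, `[[`, logical(1), "is_transition"))
  for (l in 1:6) {
    expect_length(intersect(ds[[l]]$window_index, trans_idx), 0)
  }
  ## L2 occurrences are a subset of L3 occurrences (by window identity)
  expect_true(all(ds[[2]]$window_index %in% ds[[3]]$window_index))
  ## every non-transition window appears in L1; window count conservation
  expect_setequal(ds[[1]]$window_index, setdiff(seq_along(w), trans_idx))
  expect_setequal(ds[[7]]$window_index, trans_idx)
  expect_equal(length(ds[[1]]$y) + length(ds[[7]]$y), length(w))
  ## empty window list -> empty dataset at every level
  empty <- build_level_dataset(list(), matrix(numeric(0), 0, 76), 3)
  expect_equal(length(empty$y), 0)
})
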