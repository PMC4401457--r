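test_that("script construction validates its inputs", {
  expect_error(har_script(character(0), numeric(0)), "at least one")
  expect_error(har_script("walk", 0), "positive")
  expect_error(har_script(c("walk", "fly"), c(5, 5)), "unknown activity")
  sc <- har_script(c("stand", "walk"), c(5, 10))
  expect_equal(sc$start, c(0, 5))
  expect_equal(sc$end, c(5, 15))
})

test_that("motionless stance with zero noise yields pure gravity", {
  prof <- profile_defaults("able_bodied", sensor_noise_sd = 0)
  rec <- generate_recording(har_script("stand", 10), prof, seed = 1)
  expect_true(all(rec$accel_linear == 0))
  expect_true(all(rec$gyro == 0))
  expect_true(all(apply(rec$gravity, 2, function(g) max(g) - min(g)) == 0))
  expect_true(all(rec$label == "stand"))
})

test_that("decomposition identity and gravity norm hold for every sample", {
  for (pid in c("able_bodied", "elderly", "stroke")) {
    rec <- generate_recording(default_script(), profile_defaults(pid),
                              seed = 11)
    expect_lt(max(abs(rec$accel_raw - rec$gravity - rec$accel_linear)), 1e-9)
    gn <- sqrt(rowSums(rec$gravity^2))
    expect_true(all(abs(gn - 9.81) <= 0.01 * 9.81))
  }
})

test_that("label timeline partitions the recording with no gaps", {
  rec <- generate_recording(default_script(), profile_defaults("elderly"),
                            seed = 2)
  expect_equal(length(rec$label), length(rec$t))
  expect_false(any(is.na(rec$label)))
  ## every label is a base activity or a composite transition
  ok <- rec$label %in% base_activities() | grepl("_to_", rec$label)
  expect_true(all(ok))
})

test_that("timestamps are strictly increasing with the nominal mean rate", {
  prof <- profile_defaults("able_bodied")
  rec <- generate_recording(har_script("walk", 60), prof, seed = 3)
  dt <- diff(rec$t)
  expect_true(all(dt > 0))
  expect_equal(mean(1 / dt), 50, tolerance = 0.08)
  expect_gt(stats::sd(dt), 0)  # jitter present
})

test_that("same seed reproduces a byte-identical CSV export", {
  prof <- profile_defaults("stroke")
  sc <- har_script(c("stand", "walk"), c(5, 10))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_recording_csv(generate_recording(sc, prof, seed = 42), f1)
  write_recording_csv(generate_recording(sc, prof, seed = 42), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(
    readLines(f1),
    {
      f3 <- tempfile(fileext = ".csv")
      write_recording_csv(generate_recording(sc, prof, seed = 43), f3)
      readLines(f3)
    }))
})

test_that("a script can be read from the packaged CSV format", {
  path <- system.file("extdata", "example_script.csv", package = "harselect")
  sc <- read_script_csv(path)
  expect_s3_class(sc, "har_script")
  expect_equal(sc$label[1], "stand")
  expect_equal(sum(sc$duration), 63)
})

test_that("recording and annotation CSVs round-trip", {
  rec <- generate_recording(har_script(c("sit", "walk"), c(4, 4)),
                            profile_defaults("elderly"), seed = 12)
  f <- tempfile(fileext = ".csv")
  write_recording_csv(rec, f)
  back <- read_recording_csv(f, participant_id = rec$participant_id)
  expect_equal(back$accel_raw, rec$accel_raw, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$label, rec$label)
  fa <- tempfile(fileext = ".csv")
  write_annotations_csv(rec, fa)
  ann <- utils::read.csv(fa)
  expect_equal(ann$label, c("sit", "walk"))
  expect_equal(ann$end_s, c(4, 8))
})

test_that("walking at 2 Hz puts the first autocorrelation peak at 0.5 s", {
  prof <- profile_defaults("able_bodied", step_frequency = 2,
                           gait_asymmetry = 0, sensor_noise_sd = 0.05,
                           sample_rate_sd = 0)
  rec <- generate_recording(har_script("walk", 20), prof, seed = 9)
  y <- rec$accel_linear[, 2]
  ac <- stats::acf(y, lag.max = 60, plot = FALSE)$acf[-1]
  dt <- mean(diff(rec$t))
  ## first local maximum after the initial decay
  peaks <- which(diff(sign(diff(ac))) == -2) + 1
  first_peak_lag <- peaks[1] * dt
  expect_equal(first_peak_lag, 0.5, tolerance = 0.05)
})

test_that("stair vertical skew is non-zero with direction-dependent sign", {
  prof <- profile_defaults("able_bodied", sensor_noise_sd = 0.05)
  up <- generate_recording(har_script("stairs_up", 15), prof, seed = 5)
  dn <- generate_recording(har_script("stairs_down", 15), prof, seed = 5)
  skew <- function(x) mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5
  expect_gt(skew(up$accel_linear[, 2]), 0.1)
  expect_lt(skew(dn$accel_linear[, 2]), -0.1)
})

test_that("postures differ in gravity components per the tilt map", {
  prof <- profile_defaults("able_bodied", sensor_noise_sd = 0)
  sit <- generate_recording(har_script("sit", 5), prof, seed = 1)
  stand <- generate_recording(har_script("stand", 5), prof, seed = 1)
  lie <- generate_recording(har_script("lie", 5), prof, seed = 1)
  z_sit <- mean(sit$gravity[, 3]); z_stand <- mean(stand$gravity[, 3])
  expect_gt(z_sit - z_stand, 1)       # designed sit/stand separability
  expect_gt(mean(lie$gravity[, 3]), 9)  # lying: gravity mostly on z
})

test_that("gait asymmetry produces distinct alternating step amplitudes", {
  step_ratio <- function(asym) {
    prof <- profile_defaults("able_bodied", gait_asymmetry = asym,
                             step_frequency = 2, sensor_noise_sd = 0,
                             sample_rate_sd = 0)
    rec <- generate_recording(har_script("walk", 20), prof, seed = 8)
    step <- floor(2 * rec$t)
    amp <- tapply(abs(rec$accel_linear[, 2]), step, max)
    amp <- amp[-c(1, length(amp))]
    even <- amp[seq(1, length(amp), by = 2)]
    odd <- amp[seq(2, length(amp), by = 2)]
    max(mean(even), mean(odd)) / min(mean(even), mean(odd))
  }
  expect_equal(step_ratio(0), 1, tolerance = 0.05)
  expect_gt(step_ratio(0.4), 1.5)
})

test_that("calibration sample is upright for zero tilt and rotated otherwise", {
  prof <- profile_defaults("able_bodied", sensor_noise_sd = 0)
  cal0 <- generate_calibration_sample(prof, 0, seed = 1)
  expect_true(all(abs(cal0$gravity[, 1]) < 1e-12))
  expect_true(all(abs(cal0$gravity[, 2] - 9.81) < 1e-12))
  cal30 <- generate_calibration_sample(prof, 30, seed = 1, axis = c(0, 0, 1))
  expected <- rotation_about(c(0, 0, 1), 30) %*% c(0, 9.81, 0)
  expect_equal(unname(cal30$gravity[1, ]), as.numeric(expected),
               tolerance = 1e-12)
  expect_equal(sqrt(sum(cal30$gravity[1, ]^2)), 9.81, tolerance = 1e-9)
  ## determinism
  c1 <- generate_calibration_sample(profile_defaults("elderly"), 12, seed = 7)
  c2 <- generate_calibration_sample(profile_defaults("elderly"), 12, seed = 7)
  expect_identical(c1, c2)
})

test_that("cohort generation is deterministic with unique participant ids", {
  sc <- har_script(c("stand", "sit"), c(6, 6))
  coh1 <- generate_cohort(c(able_bodied = 2, stroke = 1), sc, seed = 3)
  coh2 <- generate_cohort(c(able_bodied = 2, stroke = 1), sc, seed = 3)
  expect_identical(coh1, coh2)
  ids <- vapply(coh1, `[[`, character(1), "participant_id")
  expect_equal(anyDuplicated(ids), 0L)
  expect_length(coh1, 3)
  expect_length(generate_cohort(c(able_bodied = 0), sc, seed = 1), 0)
})

test_that("stroke cohort shows larger left/right amplitude ratio than able-bodied", {
  sc <- har_script("walk", 20)
  ratio_of <- function(pid, asym) {
    prof <- profile_defaults(pid, gait_asymmetry = asym, sensor_noise_sd = 0,
                             sample_rate_sd = 0)
    coh <- generate_cohort(stats::setNames(3, pid), sc, seed = 21,
                           profiles = stats::setNames(list(prof), pid))
    mean(vapply(coh, function(p) {
      rec <- p$recording
      ## mounting rotation preserves per-step peak |linear accel| norms
      a <- sqrt(rowSums(rec$accel_linear^2))
      step <- floor(prof$step_frequency * rec$t)
      amp <- tapply(a, step, max)
      amp <- amp[-c(1, length(amp))]
      even <- mean(amp[seq(1, length(amp), by = 2)])
      odd <- mean(amp[seq(2, length(amp), by = 2)])
      max(even, odd) / min(even, odd)
    }, numeric(1)))
  }
  expect_gt(ratio_of("stroke", 0.4), ratio_of("able_bodied", 0) + 0.3)
})
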