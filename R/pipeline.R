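## End-to-end plumbing: cohort -> windows -> features -> level datasets,
## and the planted-signal matrix generator used for selector validation.

#' Preprocess one participant
#'
#' Estimates the orientation correction from the participant's calibration
#' sample, segments the circuit recording into 1 s windows, applies the
#' +/- 2 s transition buffer, and computes the 76-feature matrix.
#'
#' @param participant One element of a `har_cohort` (list with `recording`
#'   and `calibration`).
#' @param W Moving-average span in windows.
#' @return List with `windows`, `features` (matrix), `correction`.
#' @export
preprocess_participant <- function(participant, W = 3) {
  correction <- estimate_orientation_correction(participant$calibration)
  windows <- segment_windows(participant$recording)
  windows <- apply_transition_buffer(
    windows, attr(participant$recording, "annotations"))
  features <- compute_features(participant$recording, windows, correction, W)
  list(windows = windows, features = features, correction = correction)
}

#' Build level datasets for a cohort
#'
#' Preprocesses every participant and assembles the seven level-specific
#' datasets, pooled across the whole cohort and split by population.
#'
#' @param cohort A `har_cohort` from [generate_cohort()].
#' @param levels Integer vector of levels to build (default 1:7).
#' @param W Moving-average span in windows.
#' @return List with `pooled` (level -> `har_level_dataset`),
#'   `by_population` (population -> level -> dataset), `windows` and
#'   `features` (per participant).
#' @export
cohort_level_datasets <- function(cohort, levels = 1:7, W = 3) {
  pre <- lapply(cohort, preprocess_participant, W = W)
  all_windows <- do.call(c, lapply(pre, `[[`, "windows"))
  all_features <- do.call(rbind, lapply(pre, `[[`, "features"))
  pooled <- lapply(levels, function(l)
    build_level_dataset(all_windows, all_features, l))
  names(pooled) <- as.character(levels)
  pops <- unique(vapply(cohort, `[[`, character(1), "profile_id"))
  by_pop <- lapply(pops, function(pop) {
    in_pop <- vapply(cohort, function(p) p$profile_id == pop, logical(1))
    w <- do.call(c, lapply(pre[in_pop], `[[`, "windows"))
    f <- do.call(rbind, lapply(pre[in_pop], `[[`, "features"))
    ds <- lapply(levels, function(l) build_level_dataset(w, f, l))
    names(ds) <- as.character(levels)
    ds
  })
  names(by_pop) <- pops
  list(pooled = pooled, by_population = by_pop,
       windows = lapply(pre, `[[`, "windows"),
       features = lapply(pre, `[[`, "features"))
}

#' Write a level dataset as a feature-matrix CSV
#'
#' One row per occurrence with columns
#' `participant_id, window_index, level, class, f1..f76`.
#'
#' @param dataset A `har_level_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_level_dataset_csv <- function(dataset, path) {
  X <- dataset$X
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  df <- cbind(data.frame(participant_id = dataset$groups,
                         window_index = dataset$window_index,
                         level = dataset$level, class = dataset$y,
                         stringsAsFactors = FALSE),
              as.data.frame(X))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Generate a feature matrix with planted informative features
#'
#' Validation fixture for the selectors: `p` standard-normal noise features
#' of which `m` carry class signal, at randomly drawn column positions.
#' The class structure is a balanced `2^m` factorial: each class is an
#' m-bit code and each planted feature receives a mean shift of `effect`
#' standard deviations on one distinct bit.  Every planted feature is
#' therefore individually class-informative while the planted features are
#' mutually non-redundant — the regime all three filter methods are meant
#' to recover in full.  The default effect size of 2 matches the strong,
#' posture-driven contrasts the IMU generator is designed to produce (e.g.
#' sit-vs-stand gravity components).
#'
#' @param n Occurrences (default 160, balanced over the `2^m` classes).
#' @param p Total features (default 12).
#' @param m Informative features (default 3).
#' @param effect Per-bit class mean shift in SD units (default 2).
#' @param seed Integer seed.
#' @return List with `X`, `y` (character class codes), `planted` (sorted
#'   informative column indices).
#' @export
make_planted_matrix <- function(n = 160, p = 12, m = 3, effect = 2,
                                seed = 1) {
  stopifnot(m <= p, m >= 1)
  set.seed(seed)
  n_classes <- 2^m
  y <- rep(seq_len(n_classes) - 1, length.out = n)
  X <- matrix(stats::rnorm(n * p), n, p)
  planted <- sort(sample.int(p, m))
  for (b in seq_len(m)) {
    bit <- (y %/% 2^(b - 1)) %% 2
    X[, planted[b]] <- X[, planted[b]] + effect * bit
  }
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = as.character(y), planted = planted)
}
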