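## Independent oracles used by the tests.  Each is a literal, loop-based
## transcription of the published definition, kept deliberately separate
## from the package implementation it checks.

## Relief-F, literal weight-update rule with exhaustive neighbour search on
## min-max normalized features; multi-class misses weighted by class prior
## renormalized over contrasting classes.
oracle_relief <- function(X, y) {
  X <- as.matrix(X); y <- as.character(y)
  n <- nrow(X); p <- ncol(X)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  Xn <- X
  for (i in seq_len(p)) {
    Xn[, i] <- if (hi[i] > lo[i]) (X[, i] - lo[i]) / (hi[i] - lo[i]) else 0
  }
  prior <- table(y) / n
  w <- numeric(p)
  for (j in seq_len(n)) {
    d <- rep(Inf, n)
    for (o in seq_len(n)) {
      if (o != j) d[o] <- sqrt(sum((Xn[j, ] - Xn[o, ])^2))
    }
    hits <- which(y == y[j] & seq_len(n) != j)
    nh <- hits[which.min(d[hits])]
    for (i in seq_len(p)) {
      miss_i <- 0
      for (cl in setdiff(unique(y), y[j])) {
        oc <- which(y == cl)
        nm <- oc[which.min(d[oc])]
        miss_i <- miss_i +
          (prior[[cl]] / (1 - prior[[y[j]]])) * (Xn[j, i] - Xn[nm, i])^2
      }
      w[i] <- w[i] + miss_i - (Xn[j, i] - Xn[nh, i])^2
    }
  }
  w
}

## Plug-in entropy / SU on discrete vectors.
oracle_su <- function(a, b) {
  ent <- function(v) {
    p <- as.numeric(table(v)) / length(v)
    -sum(p * log(p))
  }
  ha <- ent(a); hb <- ent(b)
  if (ha == 0 || hb == 0) return(0)
  hj <- ent(paste(a, b, sep = "\r"))
  2 * (ha + hb - hj) / (ha + hb)
}

## CFS merit evaluated by exhaustive enumeration over all non-empty subsets
## (SU correlations on pre-discretized codes); returns the best subset,
## ties broken by smaller size then lexicographic order.
oracle_cfs_exhaustive <- function(codes, y) {
  p <- ncol(codes)
  rcf <- sapply(seq_len(p), function(j) oracle_su(codes[, j], y))
  rff <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i < j) rff[i, j] <- rff[j, i] <- oracle_su(codes[, i], codes[, j])
  }
  best <- NULL; best_m <- -Inf
  for (mask in 1:(2^p - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    k <- length(S)
    rff_bar <- if (k > 1) mean(rff[S, S][upper.tri(rff[S, S])]) else 0
    m <- k * mean(rcf[S]) / sqrt(k + k * (k - 1) * rff_bar)
    if (m > best_m + 1e-12) { best_m <- m; best <- S }
  }
  list(indices = best, merit = best_m)
}

## FCBF, literal transcription of the published pseudocode: S_list ordered
## by decreasing SU with the class (> delta); walk the list, for each
## predominant feature remove all later features whose pairwise SU is >=
## their class SU.
oracle_fcbf <- function(codes, y, delta = 0) {
  p <- ncol(codes)
  su_c <- sapply(seq_len(p), function(j) oracle_su(codes[, j], y))
  s_list <- which(su_c > delta)
  s_list <- s_list[order(-su_c[s_list], s_list)]
  fp_pos <- 1
  while (fp_pos <= length(s_list)) {
    fp <- s_list[fp_pos]
    fq_pos <- fp_pos + 1
    while (fq_pos <= length(s_list)) {
      fq <- s_list[fq_pos]
      if (oracle_su(codes[, fp], codes[, fq]) >= su_c[fq]) {
        s_list <- s_list[-fq_pos]
      } else {
        fq_pos <- fq_pos + 1
      }
    }
    fp_pos <- fp_pos + 1
  }
  s_list
}

## Exact two-sided sign-test p by full enumeration of the 2^n equally
## likely sign patterns: probability of an outcome at least as extreme
## (in |n_pos - n/2|) as observed.
oracle_sign_p <- function(n_pos, n) {
  if (n == 0) return(1)
  obs <- abs(n_pos - n / 2)
  count <- 0
  for (mask in 0:(2^n - 1)) {
    k <- sum(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (abs(k - n / 2) >= obs - 1e-12) count <- count + 1
  }
  count / 2^n
}

## Small deterministic recording for feature tests: constant gravity
## (upright), arbitrary injected linear acceleration and gyro series.
make_test_recording <- function(t, lin, gyro = NULL, gravity = NULL,
                                label = "stand", id = "t01") {
  n <- length(t)
  if (is.null(gravity)) gravity <- cbind(0, rep(9.81, n), 0)
  if (is.null(gyro)) gyro <- matrix(0, n, 3)
  structure(list(participant_id = id, t = t,
                 accel_raw = gravity + lin, gravity = gravity,
                 accel_linear = lin, gyro = gyro,
                 label = rep(label, length.out = n)),
            class = "har_recording")
}

## One-window wrapper: features of the first full second of a recording.
single_window_features <- function(rec, W = 1, R = diag(3)) {
  w <- segment_windows(rec)
  corr <- structure(list(R = R, source_window = c(0, 1)),
                    class = "har_rotation")
  compute_features(rec, w, corr, W = W)
}
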