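## Filter feature selection: Relief-F, CFS (merit + forward best-first
## search) and FCBF (symmetrical-uncertainty predominant correlation).

#' Relief-F feature weighting
#'
#' Ranks features by relevance: for every occurrence the nearest hit (same
#' class) and nearest miss (each contrasting class) are found by Euclidean
#' distance on min-max normalized features, and each feature's weight
#' accumulates the squared miss difference minus the squared hit difference.
#' With more than two classes, per-class miss contributions are combined
#' weighted by the class prior renormalized over contrasting classes.  All
#' occurrences are used (no subsampling); ties in neighbour distance are
#' broken by the lowest row index; weight updates use the normalized feature
#' values, so weights are comparable across features.
#'
#' @param X Occurrences x features numeric matrix.
#' @param y Class labels (factor or character), >= 2 classes with >= 2
#'   occurrences each.
#' @param n_neighbors Number of nearest hits/misses averaged per occurrence
#'   (default 1, the printed update rule).
#' @return A `har_weights`: list with `w` (named weight per feature),
#'   `ranking` (feature indices, best first) and `method = "relief_f"`.
#' @export
relief_f <- function(X, y, n_neighbors = 1) {
  X <- as.matrix(X)
  y <- as.character(y)
  n <- nrow(X); p <- ncol(X)
  classes <- unique(y)
  if (length(classes) < 2) stop("relief_f requires at least 2 classes")
  if (any(table(y) < 2)) stop("relief_f requires >= 2 occurrences per class")

  ## min-max normalization; constant columns map to 0
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  span <- hi - lo
  span[span == 0] <- 1
  Xn <- sweep(sweep(X, 2, lo), 2, span, "/")
  Xn[, hi == lo] <- 0

  D <- as.matrix(stats::dist(Xn))
  diag(D) <- Inf
  prior <- table(y) / n
  w <- numeric(p)
  for (j in seq_len(n)) {
    same <- which(y == y[j])
    same <- same[same != j]
    k_h <- min(n_neighbors, length(same))
    hit_idx <- same[order(D[j, same])][seq_len(k_h)]
    hit_term <- colMeans((Xn[hit_idx, , drop = FALSE] -
                            matrix(Xn[j, ], k_h, p, byrow = TRUE))^2)
    miss_term <- numeric(p)
    others <- setdiff(classes, y[j])
    denom <- 1 - prior[[y[j]]]
    for (cl in others) {
      oc <- which(y == cl)
      k_m <- min(n_neighbors, length(oc))
      miss_idx <- oc[order(D[j, oc])][seq_len(k_m)]
      mt <- colMeans((Xn[miss_idx, , drop = FALSE] -
                        matrix(Xn[j, ], k_m, p, byrow = TRUE))^2)
      miss_term <- miss_term + (prior[[cl]] / denom) * mt
    }
    w <- w + miss_term - hit_term
  }
  names(w) <- colnames(X)
  structure(list(w = w, ranking = order(-w, seq_len(p)),
                 method = "relief_f"),
            class = "har_weights")
}

#' Top-k feature subset from a weight vector
#'
#' @param weights A `har_weights` (or bare numeric vector).
#' @param k Number of features to keep (default 10, the subset size used to
#'   compare populations).
#' @return A `har_subset`: `indices` ordered by rank (ties broken by lower
#'   feature index), `method = "relief_top10"`, `score` (weight of the k-th
#'   feature).
#' @export
top_k <- function(weights, k = 10) {
  w <- if (inherits(weights, "har_weights")) weights$w else weights
  stopifnot(k >= 1)
  if (k > length(w)) stop("k exceeds the number of features")
  ord <- order(-w, seq_along(w))
  idx <- ord[seq_len(k)]
  structure(list(indices = idx, method = "relief_top10",
                 score = unname(w[idx[k]])),
            class = "har_subset")
}

#' Symmetrical uncertainty between two discrete series
#'
#' `SU = 2 I(a; b) / (H(a) + H(b))`, a normalized mutual information in
#' `[0, 1]`, computed with plug-in entropies.  If either series has zero
#' entropy (constant), SU is 0 by convention.
#'
#' @param a,b Discrete vectors of equal length.
#' @return SU in `[0, 1]`.
#' @export
symmetrical_uncertainty <- function(a, b) {
  if (length(a) != length(b)) stop("series must have equal length")
  .entropy <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pa <- table(a) / length(a)
  pb <- table(b) / length(b)
  ha <- .entropy(as.numeric(pa))
  hb <- .entropy(as.numeric(pb))
  if (ha == 0 || hb == 0) return(0)
  pj <- table(a, b) / length(a)
  hj <- .entropy(as.numeric(pj))
  mi <- ha + hb - hj
  2 * mi / (ha + hb)
}

#' Equal-frequency discretization
#'
#' Codes each feature into `n_bins` quantile bins computed from the ranks,
#' so that any strictly monotone per-feature transform yields identical
#' codes.  Constant features receive a single code.
#'
#' @param X Occurrences x features numeric matrix.
#' @param n_bins Number of bins (>= 2), default 10.
#' @return A `har_discretized`: list with `codes` (integer matrix, values in
#'   `0..n_bins-1`) and `edges` (list of per-feature quantile edges, for
#'   reference).
#' @export
discretize_equal_frequency <- function(X, n_bins = 10) {
  stopifnot(n_bins >= 2)
  X <- as.matrix(X)
  n <- nrow(X)
  codes <- apply(X, 2, function(x) {
    r <- rank(x, ties.method = "min")
    as.integer(floor((r - 1) * n_bins / n))
  })
  codes <- matrix(as.integer(codes), n, ncol(X),
                  dimnames = dimnames(X))
  edges <- lapply(seq_len(ncol(X)), function(j)
    unname(stats::quantile(X[, j], probs = seq(0, 1, length.out = n_bins + 1))))
  structure(list(codes = codes, edges = edges), class = "har_discretized")
}

## Pairwise SU cache over the columns of a discrete code matrix + class.
.su_cache <- function(codes, y) {
  p <- ncol(codes)
  su_c <- vapply(seq_len(p), function(j)
    symmetrical_uncertainty(codes[, j], y), numeric(1))
  ff <- matrix(NA_real_, p, p)
  list(
    class_su = su_c,
    pair = function(i, j) {
      if (is.na(ff[i, j])) {
        v <- symmetrical_uncertainty(codes[, i], codes[, j])
        ff[i, j] <<- v; ff[j, i] <<- v
      }
      ff[i, j]
    }
  )
}

#' CFS subset merit
#'
#' `merit(S) = k * mean(r_cf) / sqrt(k + k (k-1) * mean(r_ff))` for a subset
#' of `k` features, where `r_cf` are the feature-class correlations and
#' `r_ff` the pairwise feature-feature correlations; for `k = 1` the merit
#' reduces to the feature's class correlation.
#'
#' @param rcf Feature-class correlations of the subset members.
#' @param rff_mean Mean pairwise feature-feature correlation (ignored for
#'   `k = 1`).
#' @return Scalar merit.
#' @export
cfs_merit <- function(rcf, rff_mean = 0) {
  k <- length(rcf)
  k * mean(rcf) / sqrt(k + k * (k - 1) * rff_mean)
}

#' Correlation-based feature selection (CFS)
#'
#' Forward best-first search over feature subsets scored by [cfs_merit()],
#' with feature-class and feature-feature correlations measured by
#' symmetrical uncertainty on equal-frequency-discretized features (or by
#' absolute Pearson correlation on the raw values).  The open list is
#' ordered by merit; each expansion adds one feature to the expanded subset;
#' the search stops after five consecutive fully expanded non-improving
#' subsets (or when the open list is exhausted).
#'
#' @param X Occurrences x features numeric matrix.
#' @param y Class labels (>= 2 classes).
#' @param n_bins Bins for discretization (default 10).
#' @param correlation `"su"` (default) or `"pearson"` for the pairwise
#'   estimator.
#' @param max_stale Stopping criterion: consecutive fully expanded
#'   non-improving subsets (default 5).
#' @return A `har_subset` with `indices` (ascending), `method = "cfs"` and
#'   `score` (the merit of the selected subset).
#' @export
cfs <- function(X, y, n_bins = 10, correlation = c("su", "pearson"),
                max_stale = 5) {
  correlation <- match.arg(correlation)
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2) stop("cfs requires at least 2 classes")
  p <- ncol(X)

  if (correlation == "su") {
    codes <- discretize_equal_frequency(X, n_bins)$codes
    cache <- .su_cache(codes, y)
    rcf <- cache$class_su
    rff <- cache$pair
  } else {
    yi <- as.integer(factor(y))
    rcf <- vapply(seq_len(p), function(j) {
      if (stats::sd(X[, j]) < 1e-12) 0 else abs(stats::cor(X[, j], yi))
    }, numeric(1))
    pc <- matrix(NA_real_, p, p)
    rff <- function(i, j) {
      if (is.na(pc[i, j])) {
        v <- if (stats::sd(X[, i]) < 1e-12 || stats::sd(X[, j]) < 1e-12) 0
             else abs(stats::cor(X[, i], X[, j]))
        pc[i, j] <<- v; pc[j, i] <<- v
      }
      pc[i, j]
    }
  }

  merit_of <- function(S) {
    k <- length(S)
    if (k == 0) return(-Inf)
    if (k == 1) return(cfs_merit(rcf[S]))
    pairs <- utils::combn(S, 2)
    rff_mean <- mean(vapply(seq_len(ncol(pairs)), function(q)
      rff(pairs[1, q], pairs[2, q]), numeric(1)))
    cfs_merit(rcf[S], rff_mean)
  }

  key_of <- function(S) paste0("s", paste(sort(S), collapse = ","))
  open_sets <- list(integer(0))
  open_merits <- -Inf
  visited <- new.env(hash = TRUE)
  assign(key_of(integer(0)), TRUE, envir = visited)
  best_set <- integer(0); best_merit <- -Inf
  stale <- 0

  while (length(open_sets) > 0 && stale < max_stale) {
    pick <- which.max(open_merits)
    S <- open_sets[[pick]]
    open_sets[[pick]] <- NULL
    open_merits <- open_merits[-pick]
    improved <- FALSE
    for (f in setdiff(seq_len(p), S)) {
      child <- c(S, f)
      key <- key_of(child)
      if (exists(key, envir = visited, inherits = FALSE)) next
      assign(key, TRUE, envir = visited)
      m <- merit_of(child)
      open_sets[[length(open_sets) + 1]] <- child
      open_merits <- c(open_merits, m)
      if (m > best_merit + 1e-12) {
        best_merit <- m
        best_set <- child
        improved <- TRUE
      }
    }
    stale <- if (improved) 0 else stale + 1
  }
  structure(list(indices = sort(best_set), method = "cfs",
                 score = best_merit),
            class = "har_subset")
}

#' Fast correlation-based filter (FCBF)
#'
#' Ranks features by symmetrical uncertainty with the class, keeps those
#' above `delta`, then traverses the ranking in decreasing order removing
#' every remaining feature whose correlation with an already-kept
#' predominant feature is at least its correlation with the class
#' (`SU(f, f') >= SU(f', class)`).  Ties in the ranking are broken by lower
#' feature index.
#'
#' @param X Occurrences x features numeric matrix.
#' @param y Class labels (>= 2 classes).
#' @param delta SU-with-class threshold (default 0: keep features with
#'   strictly positive class correlation).
#' @param n_bins Bins for discretization (default 10).
#' @return A `har_subset` with `indices` in rank order,
#'   `method = "fcbf"` and `score` (SU of the top-ranked kept feature;
#'   `NA` if none kept).
#' @export
fcbf <- function(X, y, delta = 0, n_bins = 10) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2) stop("fcbf requires at least 2 classes")
  codes <- discretize_equal_frequency(X, n_bins)$codes
  cache <- .su_cache(codes, y)
  su_c <- cache$class_su
  cand <- which(su_c > delta)
  if (length(cand) == 0) {
    return(structure(list(indices = integer(0), method = "fcbf",
                          score = NA_real_), class = "har_subset"))
  }
  ord <- cand[order(-su_c[cand], cand)]
  keep <- logical(length(ord))
  alive <- rep(TRUE, length(ord))
  for (i in seq_along(ord)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    fp <- ord[i]
    for (j in seq_along(ord)) {
      if (j <= i || !alive[j]) next
      fq <- ord[j]
      if (cache$pair(fp, fq) >= su_c[fq]) alive[j] <- FALSE
    }
  }
  kept <- ord[keep & alive]
  structure(list(indices = kept, method = "fcbf",
                 score = su_c[kept[1]]),
            class = "har_subset")
}

#' Run the three selectors for every level and population
#'
#' @param datasets Nested list: `datasets[[population]][[level]]` is a
#'   `har_level_dataset` (levels indexed as character or integer).
#' @param k Subset size for the Relief-F ranking (default 10).
#' @param n_bins Discretization bins for SU-based methods.
#' @param n_neighbors Relief-F neighbours.
#' @return Data frame with one row per population x level x method:
#'   `population`, `level`, `method`, `n_selected`, `indices`
#'   (comma-separated string), `score`.
#' @export
run_selection_grid <- function(datasets, k = 10, n_bins = 10,
                               n_neighbors = 1) {
  rows <- list()
  for (pop in names(datasets)) {
    for (lev in names(datasets[[pop]])) {
      ds <- datasets[[pop]][[lev]]
      if (length(unique(ds$y)) < 2 || any(table(ds$y) < 2)) next
      subs <- list(
        relief_top10 = top_k(relief_f(ds$X, ds$y, n_neighbors), k),
        cfs = cfs(ds$X, ds$y, n_bins),
        fcbf = fcbf(ds$X, ds$y, n_bins = n_bins)
      )
      for (m in names(subs)) {
        rows[[length(rows) + 1]] <- data.frame(
          population = pop, level = as.integer(ds$level), method = m,
          n_selected = length(subs[[m]]$indices),
          indices = paste(subs[[m]]$indices, collapse = ","),
          score = subs[[m]]$score,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Cross-population common-feature table
#'
#' For one selection method, intersects the selected feature indices across
#' every pair of populations and across all populations, per level —
#' the cross-population comparison report shape.
#'
#' @param grid Output of [run_selection_grid()].
#' @param method One of `"relief_top10"`, `"cfs"`, `"fcbf"`.
#' @return Data frame `comparison`, `level`, `common` (comma-separated
#'   indices, `"n/a"` when empty).
#' @export
common_features <- function(grid, method) {
  g <- grid[grid$method == method, ]
  pops <- unique(g$population)
  combos <- c(if (length(pops) >= 2) utils::combn(pops, 2, simplify = FALSE),
              if (length(pops) > 2) list(pops))
  rows <- list()
  for (cb in combos) {
    for (lev in sort(unique(g$level))) {
      sets <- lapply(cb, function(p) {
        s <- g$indices[g$population == p & g$level == lev]
        if (length(s) == 0) return(NULL)
        as.integer(strsplit(s, ",")[[1]])
      })
      if (any(vapply(sets, is.null, logical(1)))) next
      common <- Reduce(intersect, sets)
      rows[[length(rows) + 1]] <- data.frame(
        comparison = paste(cb, collapse = " & "), level = lev,
        common = if (length(common) == 0) "n/a"
                 else paste(sort(common), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
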