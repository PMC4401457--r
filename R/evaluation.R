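## Subset evaluation: three generic classifiers, participant-wise
## leave-one-out cross-validation, paired sign tests, Benjamini-Hochberg.

## Gaussian naive Bayes, closed form.  Variance floor 1e-9 * largest feature
## variance guards single-valued features within a class.
.nb_fit <- function(X, y) {
  classes <- sort(unique(y))
  eps <- 1e-9 * max(apply(X, 2, stats::var), 1e-12)
  stats_by_class <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    list(mu = colMeans(Xi),
         va = pmax(apply(Xi, 2, stats::var), eps),
         logprior = log(nrow(Xi) / nrow(X)))
  })
  names(stats_by_class) <- classes
  list(classes = classes, stats = stats_by_class)
}

.nb_predict <- function(fit, X) {
  scores <- vapply(fit$classes, function(cl) {
    st <- fit$stats[[cl]]
    ll <- -0.5 * sweep(sweep(X, 2, st$mu)^2, 2, st$va, "/") -
      0.5 * matrix(log(2 * pi * st$va), nrow(X), ncol(X), byrow = TRUE)
    rowSums(ll) + st$logprior
  }, numeric(nrow(X)))
  if (nrow(X) == 1) scores <- matrix(scores, nrow = 1)
  fit$classes[max.col(scores, ties.method = "first")]
}

#' Fit a classifier on training data and predict a test set
#'
#' The three evaluation classifiers: Gaussian naive Bayes (closed-form,
#' implemented here), a linear support vector machine (e1071, cost 1, no
#' internal scaling) and a C4.5-style decision tree (rpart, information
#' split).  Variance in the variance-less case is floored; all fits are
#' deterministic given the data.
#'
#' @param classifier One of `"naive_bayes"`, `"linear_svm"`,
#'   `"decision_tree"`.
#' @param X_train,y_train Training matrix and labels (>= 2 classes).
#' @param X_test Test matrix with the same columns as `X_train`.
#' @return Character vector of predicted class labels.
#' @export
fit_predict <- function(classifier = c("naive_bayes", "linear_svm",
                                       "decision_tree"),
                        X_train, y_train, X_test) {
  classifier <- match.arg(classifier)
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  if (nrow(X_train) == 0) stop("empty training set")
  if (length(unique(y_train)) < 2) {
    stop("training set must contain at least 2 classes")
  }
  if (ncol(X_test) != ncol(X_train)) {
    stop("test feature columns do not match training columns")
  }
  y_train <- as.character(y_train)
  switch(classifier,
    naive_bayes = .nb_predict(.nb_fit(X_train, y_train), X_test),
    linear_svm = {
      fit <- e1071::svm(x = X_train, y = factor(y_train), kernel = "linear",
                        cost = 1, scale = FALSE)
      as.character(stats::predict(fit, X_test))
    },
    decision_tree = {
      df <- as.data.frame(X_train)
      names(df) <- paste0("f", seq_len(ncol(X_train)))
      df$.y <- factor(y_train)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          parms = list(split = "information"))
      nd <- as.data.frame(X_test)
      names(nd) <- paste0("f", seq_len(ncol(X_test)))
      as.character(stats::predict(fit, nd, type = "class"))
    })
}

#' Participant-wise leave-one-out cross-validation
#'
#' One fold per participant: all windows of the left-out participant form
#' the test set, the remaining participants the training set, so no
#' subject-identity leakage occurs.  Features are standardized per fold
#' using training-fold means and standard deviations only.  Per-fold
#' accuracy is the window-level correct fraction, in percent.
#'
#' @param dataset A `har_level_dataset`.
#' @param classifier Classifier tag, see [fit_predict()].
#' @param subset A `har_subset`, integer vector of feature indices, or
#'   `NULL` for all features.
#' @return A `har_cv`: `folds` data frame (`participant`, `n`, `accuracy`
#'   in percent), `confusion` (aggregate truth x prediction table),
#'   `classifier`, `feature_set` tag.
#' @export
loocv_by_participant <- function(dataset, classifier = "naive_bayes",
                                 subset = NULL) {
  idx <- if (is.null(subset)) seq_len(ncol(dataset$X))
         else if (inherits(subset, "har_subset")) subset$indices
         else as.integer(subset)
  if (length(idx) == 0 || any(idx < 1 | idx > ncol(dataset$X))) {
    stop("invalid feature subset")
  }
  participants <- unique(dataset$groups)
  if (length(participants) < 2) {
    stop("loocv requires at least 2 participants")
  }
  X <- dataset$X[, idx, drop = FALSE]
  y <- dataset$y
  all_classes <- sort(unique(y))
  conf <- matrix(0L, length(all_classes), length(all_classes),
                 dimnames = list(truth = all_classes, pred = all_classes))
  folds <- list()
  for (p in participants) {
    test <- dataset$groups == p
    if (!any(test)) {
      warning("participant ", p, " has no occurrences at this level; skipped")
      next
    }
    if (length(unique(y[!test])) < 2) {
      warning("training fold for ", p, " has a single class; skipped")
      next
    }
    mu <- colMeans(X[!test, , drop = FALSE])
    sg <- apply(X[!test, , drop = FALSE], 2, stats::sd)
    sg[sg < 1e-12] <- 1
    Ztr <- sweep(sweep(X[!test, , drop = FALSE], 2, mu), 2, sg, "/")
    Zte <- sweep(sweep(X[test, , drop = FALSE], 2, mu), 2, sg, "/")
    pred <- fit_predict(classifier, Ztr, y[!test], Zte)
    truth <- y[test]
    acc <- 100 * mean(pred == truth)
    folds[[length(folds) + 1]] <-
      data.frame(participant = p, n = sum(test), accuracy = acc,
                 stringsAsFactors = FALSE)
    for (cl in unique(truth)) {
      for (pc in unique(pred[truth == cl])) {
        if (pc %in% all_classes) {
          conf[cl, pc] <- conf[cl, pc] + sum(truth == cl & pred == pc)
        }
      }
    }
  }
  structure(list(folds = do.call(rbind, folds), confusion = conf,
                 classifier = classifier,
                 feature_set = if (is.null(subset)) "all" else
                   if (inherits(subset, "har_subset")) subset$method
                   else "custom"),
            class = "har_cv")
}

#' Exact paired sign test
#'
#' Two-sided exact binomial test on the signs of the paired differences;
#' ties (absolute difference below `tie_tol`) are dropped.  With all pairs
#' tied, p = 1 and `all_ties` is flagged.
#'
#' @param acc_a,acc_b Paired per-fold accuracies (equal length, percent).
#' @param tie_tol Tie tolerance on the differences (default 1e-12).
#' @return A `har_signtest`: `n_pos`, `n_neg`, `n_ties`, `p` (two-sided
#'   exact), `all_ties`.
#' @export
paired_sign_test <- function(acc_a, acc_b, tie_tol = 1e-12) {
  if (length(acc_a) != length(acc_b)) stop("paired vectors of equal length required")
  if (length(acc_a) < 1) stop("at least one pair required")
  d <- acc_a - acc_b
  ties <- abs(d) < tie_tol
  n_pos <- sum(d > 0 & !ties)
  n_neg <- sum(d < 0 & !ties)
  n <- n_pos + n_neg
  if (n == 0) {
    p <- 1
  } else {
    p <- min(1, 2 * stats::pbinom(min(n_pos, n_neg), n, 0.5))
  }
  structure(list(n_pos = n_pos, n_neg = n_neg, n_ties = sum(ties),
                 p = p, all_ties = n == 0),
            class = "har_signtest")
}

#' Benjamini-Hochberg step-up correction
#'
#' Standard step-up procedure (via [stats::p.adjust()]): the rejection set
#' is the largest `k` with `p_(k) <= k q / m`.
#'
#' @param pvals Vector of p-values in `(0, 1]`.
#' @param q False-discovery-rate level (default 0.05).
#' @return List with `adjusted` (BH-adjusted p-values) and `reject`
#'   (logical).
#' @export
benjamini_hochberg <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) {
    return(list(adjusted = numeric(0), reject = logical(0)))
  }
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}

#' Evaluate feature subsets against the full feature set
#'
#' For each level dataset and classifier, runs participant-wise LOOCV with
#' all features and with each provided subset, then compares each subset's
#' per-fold accuracies against the all-features accuracies with the exact
#' paired sign test; BH correction is applied across all comparisons in the
#' result table.
#'
#' In this fixed-subset mode the subsets were selected on the full dataset
#' before cross-validation (the design the study tables imply).  For a
#' leak-free variant re-select inside each training fold with
#' `reselect = TRUE`, which re-runs the selection method per fold and
#' evaluates the fold-specific subset.
#'
#' @param datasets Named list of `har_level_dataset` (names are levels).
#' @param subsets_by_level Named list (level -> named list of `har_subset`).
#' @param classifiers Character vector of classifier tags.
#' @param q BH level (default 0.05).
#' @param reselect Re-run selection inside each training fold (slower);
#'   default `FALSE`.
#' @return A `har_evaluation`: data frame `results` with one row per level x
#'   classifier x feature set (mean accuracy, sign-test p vs all features,
#'   BH-adjusted p, significance flag), plus `cv` (list of `har_cv`).
#' @export
evaluate_subsets <- function(datasets, subsets_by_level,
                             classifiers = c("naive_bayes"),
                             q = 0.05, reselect = FALSE) {
  rows <- list(); cvs <- list(); comps <- list()
  for (lev in names(datasets)) {
    ds <- datasets[[lev]]
    if (length(unique(ds$y)) < 2) next
    for (clf in classifiers) {
      cv_all <- loocv_by_participant(ds, clf, NULL)
      key_all <- paste(lev, clf, "all", sep = ".")
      cvs[[key_all]] <- cv_all
      rows[[length(rows) + 1]] <- data.frame(
        level = as.integer(ds$level), classifier = clf, feature_set = "all",
        n_features = ncol(ds$X),
        mean_accuracy = mean(cv_all$folds$accuracy),
        p = NA_real_, stringsAsFactors = FALSE)
      for (m in names(subsets_by_level[[lev]])) {
        sub <- subsets_by_level[[lev]][[m]]
        if (length(sub$indices) == 0) next
        cv_sub <- if (reselect) {
          .loocv_reselect(ds, clf, m)
        } else {
          loocv_by_participant(ds, clf, sub)
        }
        key <- paste(lev, clf, m, sep = ".")
        cvs[[key]] <- cv_sub
        shared <- intersect(cv_all$folds$participant,
                            cv_sub$folds$participant)
        st <- paired_sign_test(
          cv_sub$folds$accuracy[match(shared, cv_sub$folds$participant)],
          cv_all$folds$accuracy[match(shared, cv_all$folds$participant)])
        rows[[length(rows) + 1]] <- data.frame(
          level = as.integer(ds$level), classifier = clf, feature_set = m,
          n_features = length(sub$indices),
          mean_accuracy = mean(cv_sub$folds$accuracy),
          p = st$p, stringsAsFactors = FALSE)
        comps[[length(comps) + 1]] <- length(rows)
      }
    }
  }
  results <- do.call(rbind, rows)
  results$p_adjusted <- NA_real_
  results$significant <- NA
  comp_idx <- which(!is.na(results$p))
  if (length(comp_idx) > 0) {
    bh <- benjamini_hochberg(results$p[comp_idx], q)
    results$p_adjusted[comp_idx] <- bh$adjusted
    results$significant[comp_idx] <- bh$reject
  }
  structure(list(results = results, cv = cvs, q = q),
            class = "har_evaluation")
}

## Per-fold re-selection mode: run the named selector on each training fold.
.loocv_reselect <- function(dataset, classifier, method) {
  participants <- unique(dataset$groups)
  folds <- list()
  all_classes <- sort(unique(dataset$y))
  conf <- matrix(0L, length(all_classes), length(all_classes),
                 dimnames = list(truth = all_classes, pred = all_classes))
  for (p in participants) {
    test <- dataset$groups == p
    ytr <- dataset$y[!test]
    if (length(unique(ytr)) < 2 || any(table(ytr) < 2)) next
    Xtr <- dataset$X[!test, , drop = FALSE]
    sub <- switch(method,
      relief_top10 = top_k(relief_f(Xtr, ytr), 10),
      cfs = cfs(Xtr, ytr),
      fcbf = fcbf(Xtr, ytr))
    if (length(sub$indices) == 0) next
    idx <- sub$indices
    mu <- colMeans(Xtr[, idx, drop = FALSE])
    sg <- apply(Xtr[, idx, drop = FALSE], 2, stats::sd)
    sg[sg < 1e-12] <- 1
    Ztr <- sweep(sweep(Xtr[, idx, drop = FALSE], 2, mu), 2, sg, "/")
    Zte <- sweep(sweep(dataset$X[test, idx, drop = FALSE], 2, mu), 2, sg, "/")
    pred <- fit_predict(classifier, Ztr, ytr, Zte)
    truth <- dataset$y[test]
    folds[[length(folds) + 1]] <-
      data.frame(participant = p, n = sum(test),
                 accuracy = 100 * mean(pred == truth),
                 stringsAsFactors = FALSE)
    for (cl in unique(truth)) {
      for (pc in unique(pred[truth == cl])) {
        if (pc %in% all_classes) {
          conf[cl, pc] <- conf[cl, pc] + sum(truth == cl & pred == pc)
        }
      }
    }
  }
  structure(list(folds = do.call(rbind, folds), confusion = conf,
                 classifier = classifier,
                 feature_set = paste0(method, "_refit")),
            class = "har_cv")
}

#' Write the evaluation report files
#'
#' Emits (i) an accuracy table (level x classifier x feature set with
#' significance flags), (ii) one confusion table per cross-validation run,
#' and (iii) optionally a cross-population common-feature table — all as
#' CSV.  With empty results, headers-only files are written.
#'
#' @param evaluation A `har_evaluation` (or `NULL` for headers only).
#' @param dir Output directory (created if needed).
#' @param common Optional output of [common_features()].
#' @return Character vector of file paths written, invisibly.
#' @export
report_tables <- function(evaluation, dir, common = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  acc_path <- file.path(dir, "accuracy.csv")
  if (is.null(evaluation) || is.null(evaluation$results)) {
    writeLines(paste("level", "classifier", "feature_set", "n_features",
                     "mean_accuracy", "p", "p_adjusted", "significant",
                     sep = ","), acc_path)
  } else {
    utils::write.csv(evaluation$results, acc_path, row.names = FALSE)
    for (key in names(evaluation$cv)) {
      cm_path <- file.path(dir, paste0("confusion_", key, ".csv"))
      utils::write.csv(as.data.frame.matrix(evaluation$cv[[key]]$confusion),
                       cm_path, row.names = TRUE)
      paths <- c(paths, cm_path)
    }
  }
  paths <- c(acc_path, paths)
  if (!is.null(common)) {
    cf_path <- file.path(dir, "common_features.csv")
    utils::write.csv(common, cf_path, row.names = FALSE)
    paths <- c(paths, cf_path)
  }
  invisible(paths)
}
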