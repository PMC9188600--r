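# Relief-F feature ranking and Gaussian-kernel SVM classification under
# leave-one-out cross-validation, with confusion-matrix metrics
# (PD = positive class).

META_COLS <- c("subject_id", "group", "phoneme", "repetition")

feature_cols <- function(table) setdiff(names(table), META_COLS)

assert_feature_table <- function(table) {
  if (!is.data.frame(table) || !all(c("group") %in% names(table))) {
    pm_stop("expected a feature table data.frame with a `group` column",
            "phonemark_invalid_argument")
  }
  feats <- feature_cols(table)
  if (length(feats) == 0L) {
    pm_stop("feature table has no feature columns",
            "phonemark_invalid_argument")
  }
  if (anyNA(table[feats])) {
    pm_stop("feature table contains missing values",
            "phonemark_invalid_argument")
  }
  invisible(table)
}

#' Relief-F feature ranking
#'
#' Binary Relief-F: features are min-max scaled to \[0, 1\]; for every
#' sample its `k` nearest hits (same class) and `k` nearest misses (other
#' class) under Euclidean distance are found, and each feature's weight is
#' decreased by the mean hit difference and increased by the mean miss
#' difference, averaged over samples. Large positive weight = the feature
#' separates the classes locally. Ties in the ranking are broken
#' alphabetically by feature name so the order is deterministic.
#'
#' @param table a feature table (data.frame with `group` plus feature
#'   columns; see [extract_features()]).
#' @param k number of nearest hits/misses (default 10); every class must
#'   have at least `k + 1` samples.
#' @return data.frame with columns `feature`, `weight`, sorted by
#'   descending weight.
#' @export
relief_f <- function(table, k = 10) {
  assert_feature_table(table)
  feats <- sort(feature_cols(table))
  x <- as.matrix(table[feats])
  y <- as.character(table$group)
  counts <- table(y)
  if (any(counts < k + 1)) {
    pm_stop(sprintf("every class needs at least k + 1 = %d samples", k + 1),
            "phonemark_insufficient_class")
  }
  rng <- apply(x, 2, function(col) diff(range(col)))
  xs <- sweep(x, 2, apply(x, 2, min))
  nz <- rng > 0
  xs[, nz] <- sweep(xs[, nz, drop = FALSE], 2, rng[nz], "/")
  xs[, !nz] <- 0
  m <- nrow(xs)
  w <- numeric(length(feats))
  d2 <- as.matrix(stats::dist(xs))^2
  for (i in seq_len(m)) {
    same <- which(y == y[i]); same <- setdiff(same, i)
    diff_cls <- which(y != y[i])
    hits <- same[order(d2[i, same])][seq_len(k)]
    misses <- diff_cls[order(d2[i, diff_cls])][seq_len(k)]
    dh <- colMeans(abs(xs[hits, , drop = FALSE] -
                         rep(xs[i, ], each = k)))
    dm <- colMeans(abs(xs[misses, , drop = FALSE] -
                         rep(xs[i, ], each = k)))
    w <- w + (dm - dh) / m
  }
  out <- data.frame(feature = feats, weight = w, stringsAsFactors = FALSE)
  out[order(-out$weight, out$feature), , drop = FALSE]
}

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity and specificity (in percent) from TP/TN/FP/FN
#' counts, with PD as the positive class. A metric whose denominator is
#' zero is returned as `NA` with a warning.
#'
#' @param tp,tn,fp,fn non-negative counts, total > 0.
#' @return named numeric vector `c(accuracy, sensitivity, specificity)` in
#'   percent.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || sum(counts) == 0) {
    pm_stop("counts must be non-negative with a positive total",
            "phonemark_invalid_argument")
  }
  sens <- if (tp + fn == 0) {
    warning("sensitivity undefined: no positive cases"); NA_real_
  } else 100 * tp / (tp + fn)
  spec <- if (tn + fp == 0) {
    warning("specificity undefined: no negative cases"); NA_real_
  } else 100 * tn / (tn + fp)
  c(accuracy = 100 * (tp + tn) / sum(counts),
    sensitivity = sens, specificity = spec)
}

#' Leave-one-out Gaussian-SVM classification
#'
#' For each row, an SVM with Gaussian (radial) kernel is trained on all
#' other rows and predicts the held-out one. Features are z-scored with the
#' training fold's statistics only, so no information about the held-out
#' sample leaks into the scaler. Deterministic given the table order.
#'
#' @param table a feature table with a two-level `group` column
#'   (`"PD"` = positive).
#' @param gamma Gaussian kernel width; default `1 / n_features` on the
#'   z-scored features.
#' @param cost soft-margin regularization constant (default 1).
#' @param features optional character vector restricting the feature columns
#'   used.
#' @return an object of class `classification_report`: counts `tp`, `tn`,
#'   `fp`, `fn`, percentage `metrics`, `selected_features`, and a
#'   `predictions` data.frame (one row per fold).
#' @export
loocv_svm <- function(table, gamma = NULL, cost = 1, features = NULL) {
  assert_feature_table(table)
  feats <- if (is.null(features)) feature_cols(table) else features
  if (!all(feats %in% names(table))) {
    pm_stop("unknown feature name(s)", "phonemark_invalid_argument")
  }
  y <- factor(as.character(table$group))
  if (nlevels(y) != 2L || any(table(y) < 2L)) {
    pm_stop("need two classes with at least 2 samples each",
            "phonemark_invalid_argument")
  }
  x <- as.matrix(table[feats])
  n <- nrow(x)
  if (is.null(gamma)) gamma <- 1 / length(feats)
  pred <- character(n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    mu <- colMeans(xtr)
    sg <- apply(xtr, 2, sd)
    sg[sg == 0] <- 1
    ztr <- sweep(sweep(xtr, 2, mu), 2, sg, "/")
    zte <- (x[i, ] - mu) / sg
    fit <- e1071::svm(ztr, y[-i], kernel = "radial", gamma = gamma,
                      cost = cost, scale = FALSE)
    pred[i] <- as.character(predict(fit, matrix(zte, nrow = 1)))
  }
  truth <- as.character(y)
  tp <- sum(pred == "PD" & truth == "PD")
  tn <- sum(pred != "PD" & truth != "PD")
  fp <- sum(pred == "PD" & truth != "PD")
  fn <- sum(pred != "PD" & truth == "PD")
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 metrics = confusion_metrics(tp, tn, fp, fn),
                 selected_features = feats,
                 gamma = gamma, cost = cost,
                 predictions = data.frame(row = seq_len(n), truth = truth,
                                          predicted = pred,
                                          stringsAsFactors = FALSE)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Leave-one-out Gaussian-SVM classification\n")
  cat(sprintf("  samples: %d  (TP %d, TN %d, FP %d, FN %d)\n",
              x$tp + x$tn + x$fp + x$fn, x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("  accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%\n",
              x$metrics["accuracy"], x$metrics["sensitivity"],
              x$metrics["specificity"]))
  invisible(x)
}

#' @export
summary.classification_report <- function(object, ...) {
  print(object)
  cat(sprintf("  gamma %.4g, cost %.4g, %d features:\n",
              object$gamma, object$cost, length(object$selected_features)))
  cat("   ", paste(object$selected_features, collapse = ", "), "\n")
  invisible(object)
}

#' Concatenate per-phoneme feature tables
#'
#' Builds one row per (subject, repetition) whose features are the
#' phoneme-prefixed features of every input table, mirroring multi-vowel
#' classifier inputs such as "/a/ + /e/ + /i/ + /o/ + /u/". Rows missing in
#' any phoneme are dropped with a message.
#'
#' @param tables named list of feature tables, names = phoneme labels; or
#'   unnamed, in which case each table's `phoneme` column must be constant.
#' @param features optional character vector restricting which feature
#'   columns are carried over from each table.
#' @return a feature table with `phoneme` set to the concatenation label.
#' @export
combine_phonemes <- function(tables, features = NULL) {
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- vapply(tables, function(t) as.character(t$phoneme[1]),
                            character(1))
  }
  pieces <- lapply(names(tables), function(ph) {
    t <- tables[[ph]]
    assert_feature_table(t)
    feats <- if (is.null(features)) feature_cols(t) else features
    piece <- t[c("subject_id", "group", "repetition", feats)]
    names(piece)[-(1:3)] <- paste0(ph, ".", feats)
    piece
  })
  subj_sets <- lapply(pieces, function(p) unique(p$subject_id))
  if (length(Reduce(intersect, subj_sets)) == 0L) {
    pm_stop("phoneme tables share no subjects", "phonemark_invalid_argument")
  }
  out <- Reduce(function(a, b) {
    merge(a, b, by = c("subject_id", "group", "repetition"))
  }, pieces)
  n_max <- max(vapply(pieces, nrow, integer(1)))
  if (nrow(out) < n_max) {
    message(sprintf("combine_phonemes: dropped %d row(s) missing a phoneme",
                    n_max - nrow(out)))
  }
  out$phoneme <- paste(names(tables), collapse = "+")
  out[c(META_COLS, setdiff(names(out), META_COLS))]
}
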