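#' Split specification
#'
#' @param test_fraction Fraction of each class held out for testing
#'   (default 0.2, i.e. an 80/20 split).
#' @param k_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed for all sampling.
#' @return An object of class \code{split_spec}.
#' @export
split_spec <- function(test_fraction = 0.2, k_folds = 5, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1, k_folds >= 2)
  structure(list(test_fraction = test_fraction, k_folds = as.integer(k_folds),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified train/test split
#'
#' Samples, per class and without replacement,
#' \code{ceiling(class size x test_fraction)} items into the test partition;
#' the training partition is the complement. Ceiling rounding makes an
#' 80/20 split of 694 + 13,472 items yield test counts of 139 + 2,695 and
#' train counts of 555 + 10,777.
#'
#' @param labels Vector of class labels (any atomic type).
#' @param spec A \code{\link{split_spec}}.
#' @return List with integer index vectors \code{train} and \code{test}
#'   (sorted), plus \code{per_class_test_counts}.
#' @export
stratified_split <- function(labels, spec = split_spec()) {
  stopifnot(length(labels) >= 2)
  set.seed(spec$seed)
  classes <- sort(unique(labels))
  test <- integer(0)
  counts <- stats::setNames(integer(length(classes)), as.character(classes))
  for (cl in classes) {
    idx <- which(labels == cl)
    n_test <- as.integer(ceiling(length(idx) * spec$test_fraction))
    if (n_test >= length(idx))
      stop("class ", cl, " would have an empty training partition")
    counts[as.character(cl)] <- n_test
    test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test,
       per_class_test_counts = counts)
}

#' Down-sample the majority class to balance a binary training set
#'
#' Keeps every minority-class item and a without-replacement subsample of
#' the majority class of the same size, so the returned subset has exactly
#' twice the minority count.
#'
#' @param labels Binary label vector for the training items.
#' @param seed Integer seed.
#' @param indices Optional index vector the labels refer to (defaults to
#'   \code{seq_along(labels)}).
#' @return Sorted integer vector of retained indices.
#' @export
downsample_majority <- function(labels, seed = 1L, indices = seq_along(labels)) {
  stopifnot(length(labels) == length(indices))
  tab <- table(labels)
  if (length(tab) != 2) stop("labels must contain exactly two classes")
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  if (tab[minority] == tab[majority]) return(sort(indices))
  set.seed(seed)
  keep_min <- indices[labels == minority]
  maj_pool <- indices[labels == majority]
  keep_maj <- sample(maj_pool, tab[[minority]])
  sort(c(keep_min, keep_maj))
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a threshold (equal scores grouped into a
#' single step) to build the ROC curve, and integrates it by the trapezoid
#' rule. With ties handled this way the AUC equals the Mann-Whitney pair
#' statistic \eqn{(\#\{s_{pos} > s_{neg}\} + \frac{1}{2}\#ties)/(n_+ n_-)}.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels Binary labels (1/TRUE/"CTC" = positive).
#' @return List with \code{roc_points} (data frame of \code{fpr},
#'   \code{tpr}, from (0,0) to (1,1), both non-decreasing) and \code{auc}.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  np <- sum(y == 1); nn <- sum(y == 0)
  if (np == 0 || nn == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  grp_last <- c(ss[-1] != ss[-length(ss)], TRUE)  # last element of each tie group
  tp <- cumsum(ys)[grp_last]
  fp <- cumsum(1 - ys)[grp_last]
  tpr <- c(0, tp / np)
  fpr <- c(0, fp / nn)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Confusion-matrix statistics
#'
#' @param predicted Binary predicted labels.
#' @param truth Binary true labels.
#' @param scores Optional scores; when given, ROC points and AUC are
#'   included.
#' @return An \code{eval_report}: list with \code{tp}, \code{fp}, \code{tn},
#'   \code{fn}, \code{sensitivity} (= tp/(tp+fn)), \code{specificity}
#'   (= tn/(tn+fp)), and optionally \code{roc_points}, \code{auc}.
#' @export
confusion_stats <- function(predicted, truth, scores = NULL) {
  p <- as_binary_labels(predicted)
  y <- as_binary_labels(truth)
  if (length(p) != length(y)) stop("prediction and truth lengths differ")
  tp <- sum(p == 1 & y == 1); fp <- sum(p == 1 & y == 0)
  tn <- sum(p == 0 & y == 0); fn <- sum(p == 0 & y == 1)
  rep <- list(tp = tp, fp = fp, tn = tn, fn = fn,
              sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
              specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  if (!is.null(scores) && length(unique(y)) == 2) {
    r <- roc_auc(scores, y)
    rep$roc_points <- r$roc_points
    rep$auc <- r$auc
  }
  structure(rep, class = "eval_report")
}

stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("class ", cl, " has fewer members (", length(idx),
           ") than folds (", k, ")")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Partitions the training items into k stratified folds; for each fold the
#' model is fit on the remaining folds (optionally down-sampling the
#' majority class within the fold training set) and scored on the held-out
#' fold. Per-fold confusion/ROC reports use the 0.5 cut-off. The pooled
#' report concatenates the out-of-fold predictions; the mean of fold AUCs is
#' also returned.
#'
#' @param indices Integer indices of the training items (into the caller's
#'   data).
#' @param labels Binary labels aligned with \code{indices}.
#' @param k Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @param train_fn \code{function(train_indices, train_labels)} returning a
#'   fitted object.
#' @param predict_fn \code{function(fitted, test_indices)} returning scores
#'   in \code{[0, 1]}.
#' @param balance \code{"none"} or \code{"per-fold"} (down-sample the
#'   majority class inside each fold's training set).
#' @return List with \code{per_fold} (list of \code{eval_report}),
#'   \code{pooled} (\code{eval_report} over concatenated out-of-fold
#'   predictions), \code{mean_fold_auc}, \code{fold} (fold id per item), and
#'   \code{oof_scores}.
#' @export
kfold_cv <- function(indices, labels, k, seed, train_fn, predict_fn,
                     balance = c("none", "per-fold")) {
  balance <- match.arg(balance)
  stopifnot(length(indices) == length(labels), k >= 2)
  y <- as_binary_labels(labels)
  fold <- stratified_folds(y, k, seed)
  oof <- rep(NA_real_, length(indices))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    tr_idx <- indices[tr]; tr_y <- y[tr]
    if (balance == "per-fold") {
      keep <- downsample_majority(tr_y, seed = seed + f, indices = seq_along(tr_y))
      tr_idx <- tr_idx[keep]; tr_y <- tr_y[keep]
    }
    fitted <- train_fn(tr_idx, tr_y)
    sc <- predict_fn(fitted, indices[te])
    oof[te] <- sc
    per_fold[[f]] <- confusion_stats(as.numeric(sc >= 0.5), y[te], scores = sc)
  }
  pooled <- confusion_stats(as.numeric(oof >= 0.5), y, scores = oof)
  aucs <- vapply(per_fold, function(r) r$auc %||% NA_real_, 0)
  list(per_fold = per_fold, pooled = pooled,
       mean_fold_auc = mean(aucs, na.rm = TRUE),
       fold = fold, oof_scores = oof)
}
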