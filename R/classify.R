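#' Confusion-derived classification metrics
#'
#' Accuracy, sensitivity and specificity as percentages; sensitivity is
#' computed on the positive class.
#' @param tp,fn,tn,fp confusion counts (nonnegative; positive and negative
#'   totals must be > 0).
#' @return tibble with `accuracy`, `sensitivity`, `specificity` (percent)
#'   and the counts.
#' @export
classification_metrics <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  if (tp + fn == 0 || tn + fp == 0) abort("zero class denominator")
  tibble::tibble(
    tp = tp, fn = fn, tn = tn, fp = fp,
    accuracy = 100 * (tp + tn) / (tp + fn + tn + fp),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp))
}

#' Leave-one-out SVM classification
#'
#' For every subject, an SVM is trained on the remaining n - 1 (feature
#' z-scoring fit on the training fold only, then applied to the held-out
#' subject) and the held-out label is predicted; the per-fold predictions
#' are aggregated into a confusion table. Default kernel is RBF with
#' `cost = 1` and `gamma = 1/n_features`.
#'
#' @param features numeric matrix or data frame (subjects x features).
#' @param labels factor or character vector of two classes.
#' @param positive label of the positive class (default: first level).
#' @param kernel,cost,gamma passed to [e1071::svm()]; `gamma = NULL` uses
#'   `1/ncol(features)`.
#' @return object of class `nh_classification`: tibble row with the
#'   metrics, plus attributes `predictions` (per-fold) and `features`.
#' @export
loocv_svm <- function(features, labels, positive = NULL, kernel = "radial",
                      cost = 1, gamma = NULL) {
  X <- as.matrix(features)
  stopifnot(nrow(X) >= 4, !anyNA(X))
  labels <- factor(labels)
  if (nlevels(labels) != 2) abort("exactly two classes required")
  positive <- positive %||% levels(labels)[1]
  stopifnot(positive %in% levels(labels))
  if (any(table(labels) < 2)) abort("each class needs >= 2 subjects")
  gamma <- gamma %||% (1 / ncol(X))
  n <- nrow(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    tr_x <- X[-i, , drop = FALSE]
    tr_y <- droplevels(labels[-i])
    if (nlevels(tr_y) < 2) abort("a training fold is missing a class")
    mu <- colMeans(tr_x)
    sg <- apply(tr_x, 2, sd)
    sg[sg == 0] <- 1
    tr_z <- scale(tr_x, mu, sg)
    te_z <- matrix((X[i, ] - mu) / sg, nrow = 1)
    fit <- e1071::svm(tr_z, tr_y, kernel = kernel, cost = cost,
                      gamma = gamma, scale = FALSE)
    pred[i] <- as.character(predict(fit, te_z))
  }
  is_pos <- labels == positive
  pred_pos <- pred == positive
  out <- classification_metrics(tp = sum(is_pos & pred_pos),
                                fn = sum(is_pos & !pred_pos),
                                tn = sum(!is_pos & !pred_pos),
                                fp = sum(!is_pos & pred_pos))
  out$positive_class <- positive
  attr(out, "predictions") <- tibble::tibble(
    truth = as.character(labels), predicted = pred)
  attr(out, "features") <- colnames(X) %||% as.character(seq_len(ncol(X)))
  class(out) <- c("nh_classification", class(out))
  out
}

#' Evaluate every feature combination by leave-one-out SVM
#'
#' Runs [loocv_svm()] for every nonempty feature subset up to `max_size`
#' and marks the best combination by accuracy, ties broken by fewer
#' features then lexicographic feature id.
#'
#' @param features numeric matrix or data frame (subjects x named features).
#' @param labels two-class labels.
#' @param max_size largest subset size (default: all features).
#' @param ... passed to [loocv_svm()].
#' @return tibble of class `nh_combination_search`: `combination` (feature
#'   ids joined by "+"), `n_features`, metrics columns, `best` flag.
#' @export
enumerate_combinations <- function(features, labels, max_size = NULL, ...) {
  X <- as.matrix(features)
  nf <- ncol(X)
  stopifnot(nf >= 1)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(nf))
  max_size <- min(max_size %||% nf, nf)
  subsets <- unlist(lapply(seq_len(max_size), function(k)
    utils::combn(nf, k, simplify = FALSE)), recursive = FALSE)
  res <- purrr::map_dfr(subsets, function(s) {
    r <- loocv_svm(X[, s, drop = FALSE], labels, ...)
    tibble::tibble(combination = paste(colnames(X)[s], collapse = "+"),
                   n_features = length(s),
                   accuracy = r$accuracy, sensitivity = r$sensitivity,
                   specificity = r$specificity,
                   tp = r$tp, fn = r$fn, tn = r$tn, fp = r$fp)
  })
  ord <- order(-res$accuracy, res$n_features, res$combination)
  res$best <- FALSE
  res$best[ord[1]] <- TRUE
  class(res) <- c("nh_combination_search", class(res))
  res
}
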