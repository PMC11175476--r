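# Model evaluation: confusion counts, the six classification metrics,
# stratified ten-fold cross-validation and independent-test evaluation.

# split a feature table into x (numeric matrix), label vector and 0/1
# response (CPP = 1)
.split_xy <- function(table) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  bad <- setdiff(unique(as.character(table$label)), c("CPP", "nonCPP"))
  if (length(bad) > 0) {
    rlang::abort(sprintf("Labels must be CPP/nonCPP; found: %s",
                         paste(bad, collapse = ", ")))
  }
  feats <- names(table)[vapply(table, is.numeric, logical(1))]
  list(x = as.matrix(table[, feats, drop = FALSE]),
       label = as.character(table$label),
       y01 = as.numeric(table$label == "CPP"),
       id = if ("id" %in% names(table)) table$id else seq_len(nrow(table)),
       features = feats)
}

#' Stratified fold assignment
#'
#' Assigns each record to one of `k` validation folds, stratified by label
#' so every fold carries the class balance of the whole set. Deterministic
#' given the seed.
#'
#' @param labels Class label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  folds <- integer(length(labels))
  .with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  folds
}

#' Confusion counts of a binary prediction
#'
#' @param y_true,y_pred Label vectors over `{CPP, nonCPP}` (equal length).
#' @param positive_class The class counted as positive; default `"CPP"`.
#' @return One-row tibble with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred, positive_class = "CPP") {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1)
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  bad <- setdiff(unique(c(y_true, y_pred)), c("CPP", "nonCPP"))
  if (length(bad) > 0) {
    rlang::abort(sprintf("Labels outside {CPP, nonCPP}: %s",
                         paste(bad, collapse = ", ")))
  }
  pos_t <- y_true == positive_class
  pos_p <- y_pred == positive_class
  tibble::tibble(
    TP = sum(pos_t & pos_p), FP = sum(!pos_t & pos_p),
    TN = sum(!pos_t & !pos_p), FN = sum(pos_t & !pos_p))
}

# rank (Mann-Whitney) AUC with ties counted half
.rank_auc <- function(scores, y_pos) {
  n1 <- sum(y_pos); n0 <- sum(!y_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' The six classification metrics
#'
#' Accuracy, Matthews correlation coefficient, sensitivity, specificity,
#' F1 score (`2 TP / (2 TP + FP + FN)`) from confusion counts, and AUC by
#' the rank (Mann-Whitney) estimator with ties counted half when
#' per-record scores are supplied. MCC is reported as 0 (with a warning)
#' when any confusion-matrix margin is zero.
#'
#' @param counts One-row tibble from [confusion_counts()].
#' @param scores Optional per-record scores (probability of the positive
#'   class) for the AUC.
#' @param y_true Labels matching `scores` (required with `scores`).
#' @param positive_class Positive label for the AUC; default `"CPP"`.
#' @return One-row tibble `ACC`, `MCC`, `SN`, `SP`, `F1`, `AUC`.
#' @export
classification_metrics <- function(counts, scores = NULL, y_true = NULL,
                                   positive_class = "CPP") {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  n <- tp + fp + tn + fn
  if (n == 0) rlang::abort("No evaluated records.")
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) {
    rlang::warn("A confusion-matrix margin is zero; MCC reported as 0.")
    mcc <- 0
  } else {
    mcc <- (tp * tn - fn * fp) / sqrt(denom2)
  }
  auc <- NA_real_
  if (!is.null(scores)) {
    stopifnot(!is.null(y_true), length(scores) == length(y_true))
    auc <- .rank_auc(scores, as.character(y_true) == positive_class)
  }
  tibble::tibble(
    ACC = (tp + tn) / n,
    MCC = mcc,
    SN = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    SP = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    F1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    AUC = auc)
}

#' Stratified ten-fold cross-validation of the soft-voting ensemble
#'
#' For each fold: fit the scaler, the convolutional network and the
#' boosted-tree member on the training part, evaluate on the held-out
#' part, and record confusion counts and the six metrics. Aggregates are
#' reported both as fold-metric means (the default summary) and as metrics
#' of the pooled confusion counts.
#'
#' @param table Feature tibble (`id`, `label`, descriptor columns), at
#'   least 10 records per class.
#' @param spec A [convboost_spec()].
#' @param seed Master seed; folds, member training and dropout derive from it.
#' @param k Number of folds (default 10).
#' @return An object of class `cv_result` with `folds` (per-fold tibble),
#'   `summary` (fold-mean metrics), `pooled` (metrics of summed counts),
#'   `assignments`, and `predictions` (per-record out-of-fold tibble).
#' @export
ten_fold_cv <- function(table, spec = convboost_spec(), seed = 1L, k = 10L) {
  xy <- .split_xy(table)
  tab <- table(xy$label)
  if (any(tab < k)) {
    rlang::abort(sprintf(
      "Every class needs at least %d records; got %s.", k,
      paste(names(tab), tab, collapse = ", ")))
  }
  assignments <- stratified_folds(xy$label, k = k,
                                  seed = .derive_seed(seed, "cv-folds"))
  fold_rows <- vector("list", k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- assignments != f
    model <- fit_convboost(table[tr, , drop = FALSE], spec,
                           seed = .derive_seed(seed, paste0("cv-fit", f)))
    pr <- predict(model, table[!tr, , drop = FALSE])
    truth <- xy$label[!tr]
    cc <- confusion_counts(truth, pr$label)
    met <- classification_metrics(cc, scores = pr$p_ensemble, y_true = truth)
    fold_rows[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f), cc, met)
    preds[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f, truth = truth), pr)
  }
  folds <- dplyr::bind_rows(fold_rows)
  preds <- dplyr::bind_rows(preds)
  pooled_counts <- tibble::tibble(
    TP = sum(folds$TP), FP = sum(folds$FP),
    TN = sum(folds$TN), FN = sum(folds$FN))
  pooled <- classification_metrics(pooled_counts, scores = preds$p_ensemble,
                                   y_true = preds$truth)
  summary <- dplyr::summarise(folds, dplyr::across(
    c("ACC", "MCC", "SN", "SP", "F1", "AUC"), mean))
  structure(list(folds = folds, summary = summary, pooled = pooled,
                 assignments = assignments, predictions = preds,
                 spec = spec, seed = seed, k = k),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold cross-validation\n", x$k))
  cat(sprintf("  fold-mean: ACC %.3f  MCC %.3f  SN %.3f  SP %.3f  F1 %.3f  AUC %.3f\n",
              x$summary$ACC, x$summary$MCC, x$summary$SN, x$summary$SP,
              x$summary$F1, x$summary$AUC))
  invisible(x)
}

#' @rdname ten_fold_cv
#' @param x A `cv_result`.
#' @param ... Unused.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @rdname ten_fold_cv
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) x$summary

#' Independent-test evaluation
#'
#' Fits the ensemble once on the full training table and evaluates it once
#' on a disjoint test table (record ids must not overlap).
#'
#' @param train_table,test_table Feature tibbles with matching descriptor
#'   columns and disjoint `id`s.
#' @param spec A [convboost_spec()].
#' @param seed Master seed.
#' @return A list with `metrics` (one-row tibble), `counts`, `predictions`
#'   and the fitted `model`.
#' @export
independent_test <- function(train_table, test_table,
                             spec = convboost_spec(), seed = 1L) {
  if ("id" %in% names(train_table) && "id" %in% names(test_table)) {
    overlap <- intersect(train_table$id, test_table$id)
    if (length(overlap) > 0) {
      rlang::abort(sprintf("Train/test ids overlap: %s%s",
                           paste(utils::head(overlap, 5), collapse = ", "),
                           if (length(overlap) > 5) ", ..." else ""))
    }
  }
  model <- fit_convboost(train_table, spec,
                         seed = .derive_seed(seed, "indep-fit"))
  pr <- predict(model, test_table)
  truth <- as.character(test_table$label)
  cc <- confusion_counts(truth, pr$label)
  met <- classification_metrics(cc, scores = pr$p_ensemble, y_true = truth)
  list(metrics = met, counts = cc, predictions = pr, model = model)
}

#' Plot per-fold cross-validation metrics
#'
#' One point per fold and metric with the fold-mean marked, in the style
#' of a cross-validation box plot.
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds,
    cols = c("ACC", "MCC", "SN", "SP", "F1", "AUC"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 21,
                          fill = "white", size = 2.5) +
    ggplot2::labs(x = NULL, y = "score",
                  title = sprintf("%d-fold cross-validation", object$k)) +
    ggplot2::theme_minimal()
}
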