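test_that("confusion counts match a manual tally and swap symmetry", {
  y <- rep(c("CPP", "nonCPP"), each = 10)
  pred <- y
  pred[c(2, 5, 14)] <- ifelse(y[c(2, 5, 14)] == "CPP", "nonCPP", "CPP")
  cc <- confusion_counts(y, pred)
  expect_equal(cc, tibble::tibble(TP = 8L, FP = 1L, TN = 9L, FN = 2L))
  sw <- confusion_counts(y, pred, positive_class = "nonCPP")
  expect_equal(unname(unlist(sw[c("TP", "TN", "FP", "FN")])),
               unname(unlist(cc[c("TN", "TP", "FN", "FP")])))
  perfect <- confusion_counts(y, y)
  expect_equal(perfect$FP + perfect$FN, 0L)
  expect_error(confusion_counts(c("CPP"), c("maybe")), "outside")
})

test_that("metric formulas reproduce the hand-evaluated 9/1/8/2 case", {
  cc <- tibble::tibble(TP = 9L, FN = 1L, TN = 8L, FP = 2L)
  m <- classification_metrics(cc)
  expect_equal(m$ACC, 0.85)
  expect_equal(m$SN, 0.9)
  expect_equal(m$SP, 0.8)
  # MCC = (9*8 - 1*2) / sqrt(11 * 10 * 10 * 9), evaluated before the build
  expect_equal(m$MCC, 0.7035265, tolerance = 1e-7)
  expect_equal(m$F1, 18 / 21)
})

test_that("a perfect classifier scores one everywhere", {
  m <- classification_metrics(tibble::tibble(TP = 5L, FP = 0L, TN = 5L, FN = 0L))
  expect_equal(unlist(m[c("ACC", "MCC", "SN", "SP", "F1")]),
               c(ACC = 1, MCC = 1, SN = 1, SP = 1, F1 = 1))
})

test_that("metrics agree with an exhaustive small-confusion-matrix oracle", {
  for (tp in 0:6) for (fp in 0:(6 - tp)) for (tn in 0:4) {
    for (fn in 0:2) {
      if (tp + fp + tn + fn == 0 || tp + fp + tn + fn > 12) next
      cc <- tibble::tibble(TP = tp, FP = fp, TN = tn, FN = fn)
      m <- suppressWarnings(classification_metrics(cc))
      n <- tp + fp + tn + fn
      expect_equal(m$ACC, (tp + tn) / n)
      den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      mcc_oracle <- if (den == 0) 0 else (tp * tn - fn * fp) / sqrt(den)
      expect_equal(m$MCC, mcc_oracle)
      expect_true(is.na(m$MCC) || (m$MCC >= -1 && m$MCC <= 1))
      if (tp + fn > 0) expect_equal(m$SN, tp / (tp + fn))
      if (2 * tp + fp + fn > 0) expect_equal(m$F1, 2 * tp / (2 * tp + fp + fn))
      # balanced data: accuracy is the mean of sensitivity and specificity
      if (tp + fn == tn + fp && tp + fn > 0) {
        expect_equal(m$ACC, (m$SN + m$SP) / 2)
      }
    }
  }
})

test_that("AUC hits the rank-statistic limits and tie convention", {
  y <- c("CPP", "CPP", "nonCPP", "nonCPP")
  cc <- confusion_counts(y, y)
  expect_equal(classification_metrics(cc, scores = c(.9, .8, .2, .1),
                                      y_true = y)$AUC, 1)
  expect_equal(classification_metrics(cc, scores = rep(0.5, 4),
                                      y_true = y)$AUC, 0.5)
  # ties counted half: scores (.9,.5 | .5,.1) -> AUC 0.875
  expect_equal(classification_metrics(cc, scores = c(.9, .5, .5, .1),
                                      y_true = y)$AUC, 0.875)
  # invariance under strictly monotone transforms
  sc <- c(.91, .42, .55, .13)
  a1 <- classification_metrics(cc, scores = sc, y_true = y)$AUC
  a2 <- classification_metrics(cc, scores = log(sc / (1 - sc)), y_true = y)$AUC
  expect_equal(a1, a2)
})

test_that("stratified folds partition the data with the class balance", {
  labels <- rep(c("CPP", "nonCPP"), each = 300)
  f <- stratified_folds(labels, k = 10, seed = 3)
  expect_equal(sort(unique(f)), 1:10)
  counts <- table(f, labels)
  expect_true(all(counts == 30))                  # 60 per fold, 30 per class
  expect_identical(f, stratified_folds(labels, k = 10, seed = 3))
  expect_false(identical(f, stratified_folds(labels, k = 10, seed = 4)))
})

test_that("ten_fold_cv enforces the per-class minimum", {
  tab <- toy_feature_table(n_per_class = 5L)
  expect_error(ten_fold_cv(tab, convboost_spec("FC-STR")), "at least 10")
})

test_that("independent_test rejects overlapping ids and matches
           training-set evaluation on identical data", {
  tab <- toy_feature_table(n_per_class = 15L, shift = 4, seed = 23)
  expect_error(independent_test(tab, tab), "overlap")
  test_tab <- tab
  test_tab$id <- paste0("t_", tab$id)
  spec <- convboost_spec("FC-STR", epochs = 4L)
  res <- independent_test(tab, test_tab, spec, seed = 31)
  expect_named(res$metrics, c("ACC", "MCC", "SN", "SP", "F1", "AUC"))
  # test set duplicates the training set: metrics equal the training-set
  # evaluation of the same fitted model
  tr_pred <- predict(res$model, tab)
  tr_cc <- confusion_counts(tab$label, tr_pred$label)
  tr_m <- classification_metrics(tr_cc, scores = tr_pred$p_ensemble,
                                 y_true = tab$label)
  expect_equal(res$metrics, tr_m)
})

test_that("cv_result exposes tidy/glance/pooled views", {
  tab <- toy_feature_table(n_per_class = 12L, shift = 4, seed = 29)
  spec <- convboost_spec("FC-STR", epochs = 2L)
  cv <- ten_fold_cv(tab, spec, seed = 7, k = 3L)
  expect_s3_class(tidy(cv), "tbl_df")
  expect_equal(nrow(tidy(cv)), 3)
  expect_named(glance(cv), c("ACC", "MCC", "SN", "SP", "F1", "AUC"))
  expect_equal(sum(tidy(cv)$TP + tidy(cv)$FP + tidy(cv)$TN + tidy(cv)$FN),
               nrow(tab))
  # every record validated exactly once
  expect_equal(sort(cv$predictions$id), sort(tab$id))
  expect_s3_class(autoplot(cv), "ggplot")
})
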