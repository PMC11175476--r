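# The soft-voting ensemble: convolutional network + gradient-boosted
# trees, each producing a CPP probability that is averaged.

#' Specification of the soft-voting ensemble
#'
#' @param fc_name Feature composition the model is trained on (fixes the
#'   descriptor order fed to the convolutional member and the default
#'   epoch count: 25/20/25/20 for FC-SEQ / FC-STR / FC-SEQ-STR /
#'   FC-Kendall).
#' @param variant Composition variant, `"+NOHo"` (default) or `"baseline"`.
#' @param epochs Convolutional training epochs; `NULL` uses the
#'   composition default.
#' @param cnn A [cnn_spec()].
#' @param xgb_params Fixed XGBoost hyperparameters (named list); defaults
#'   to the package's documented configuration. Ignored when `tune = TRUE`.
#' @param tune Tune XGBoost by Bayesian optimisation at fit time.
#' @param tune_iter,tune_cv_folds Budget of the tuner when `tune = TRUE`.
#' @return A list of class `convboost_spec`.
#' @export
convboost_spec <- function(fc_name = "FC-STR", variant = "+NOHo",
                           epochs = NULL, cnn = cnn_spec(),
                           xgb_params = NULL, tune = FALSE,
                           tune_iter = 32L, tune_cv_folds = 3L) {
  epochs <- epochs %||% default_epochs(fc_name)
  structure(list(fc_name = fc_name, variant = variant,
                 epochs = as.integer(epochs), cnn = cnn,
                 xgb_params = xgb_params %||% .xgb_default_params(),
                 tune = tune, tune_iter = tune_iter,
                 tune_cv_folds = tune_cv_folds),
            class = "convboost_spec")
}

#' Fit the soft-voting ensemble on a feature table
#'
#' Standardises every descriptor (z-score fit on this table only), trains
#' the convolutional network for the configured epochs, trains (or
#' Bayes-tunes) the XGBoost member, and stores the scaler and feature
#' order so prediction can reproduce the exact input layout.
#'
#' @param table Feature tibble (`id`, `label`, descriptor columns).
#' @param spec A [convboost_spec()].
#' @param seed Master seed; member seeds derive from it.
#' @return An object of class `convboost_model`.
#' @export
fit_convboost <- function(table, spec = convboost_spec(), seed = 1L) {
  xy <- .split_xy(table)
  if (!all(is.finite(xy$x))) rlang::abort("Non-finite feature values.")
  ctr <- colMeans(xy$x)
  scl <- apply(xy$x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- scale(xy$x, center = ctr, scale = scl)
  net <- build_cnn(ncol(xs), spec$cnn, seed = .derive_seed(seed, "cnn-init"))
  net <- train_cnn(net, xs, xy$label, epochs = spec$epochs,
                   seed = .derive_seed(seed, "cnn-train"))
  if (spec$tune) {
    tuned <- tune_xgboost(table, n_iter = spec$tune_iter,
                          cv_folds = spec$tune_cv_folds,
                          seed = .derive_seed(seed, "xgb-tune"))
    booster <- tuned$booster
    xgb_params <- tuned$best_params
  } else {
    booster <- .xgb_fit(xy$x, xy$y01, spec$xgb_params,
                        seed = .derive_seed(seed, "xgb-fit"))
    xgb_params <- spec$xgb_params
    tuned <- NULL
  }
  structure(list(
    cnn = net, booster = booster, xgb_params = xgb_params, tuning = tuned,
    center = ctr, scale = scl, features = xy$features,
    meta = list(fc_name = spec$fc_name, variant = spec$variant,
                epochs = spec$epochs, seed = seed, n_train = nrow(table))),
    class = "convboost_model")
}

#' @export
print.convboost_model <- function(x, ...) {
  cat(sprintf(
    "<convboost_model> %s (%s), %d descriptors, %d training records, %d epochs\n",
    x$meta$fc_name, x$meta$variant, length(x$features), x$meta$n_train,
    x$meta$epochs))
  invisible(x)
}

#' Soft vote of the two member probabilities
#'
#' Averages the members' CPP probabilities; the label is `"CPP"` when the
#' average exceeds 0.5 and `"nonCPP"` otherwise (a tie at exactly 0.5 is
#' called `"nonCPP"`). Vectorised, symmetric in its arguments and monotone
#' in each.
#'
#' @param p_cnn,p_xgb CPP probabilities in \[0, 1\].
#' @return Tibble with `label` and `probability`.
#' @examples
#' soft_vote(0.9, 0.7)  # CPP, 0.8
#' @export
soft_vote <- function(p_cnn, p_xgb) {
  stopifnot(length(p_cnn) == length(p_xgb))
  if (any(p_cnn < 0 | p_cnn > 1 | p_xgb < 0 | p_xgb > 1, na.rm = TRUE) ||
      anyNA(p_cnn) || anyNA(p_xgb)) {
    rlang::abort("Member probabilities must lie in [0, 1].")
  }
  p <- (p_cnn + p_xgb) / 2
  tibble::tibble(label = ifelse(p > 0.5, "CPP", "nonCPP"), probability = p)
}

#' Predict CPP status with a fitted ensemble
#'
#' Accepts either a feature table with the model's descriptor columns or a
#' peptide tibble with a `sequence` column (descriptors are then extracted
#' for the model's feature composition). Applies the stored scaler, both
#' members and the soft vote.
#'
#' @param object A [fit_convboost()] model.
#' @param newdata Feature table or peptide tibble.
#' @param ... Unused.
#' @return Tibble with `id`, `p_cnn`, `p_xgb`, `p_ensemble`, `label`.
#' @export
predict.convboost_model <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  if (!all(object$features %in% names(newdata)) &&
      "sequence" %in% names(newdata)) {
    newdata <- extract_features(newdata,
                                fc = object$meta$fc_name,
                                variant = object$meta$variant)
  }
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("Missing feature column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  xs <- scale(x, center = object$center, scale = object$scale)
  p_cnn <- unname(predict(object$cnn, xs)[, "CPP"])
  p_xgb <- unname(predict(object$booster, x))
  vote <- soft_vote(p_cnn, p_xgb)
  tibble::tibble(
    id = if ("id" %in% names(newdata)) newdata$id else seq_len(nrow(newdata)),
    p_cnn = unname(p_cnn), p_xgb = unname(p_xgb),
    p_ensemble = vote$probability, label = vote$label)
}

#' @rdname fit_convboost
#' @param x A `convboost_model`.
#' @param ... Unused.
#' @method glance convboost_model
#' @export
glance.convboost_model <- function(x, ...) {
  tibble::tibble(
    fc_name = x$meta$fc_name, variant = x$meta$variant,
    n_features = length(x$features), n_train = x$meta$n_train,
    epochs = x$meta$epochs,
    final_cnn_loss = x$cnn$history$loss[[nrow(x$cnn$history)]],
    xgb_rounds = x$xgb_params$n_estimators)
}

#' @rdname fit_convboost
#' @method tidy convboost_model
#' @export
tidy.convboost_model <- function(x, ...) {
  tibble::tibble(feature = x$features, center = unname(x$center),
                 scale = unname(x$scale))
}

#' Persist / restore a fitted ensemble
#'
#' Writes the model as a directory: a JSON manifest (composition,
#' features, scaler, XGBoost hyperparameters), the serialised network
#' weights and the XGBoost model file.
#'
#' @param model A `convboost_model`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly (`save_convboost`); the model (`load_convboost`).
#' @export
save_convboost <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- c(model$meta, list(
    features = model$features, center = unname(model$center),
    scale = unname(model$scale), xgb_params = model$xgb_params))
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model$cnn, file.path(dir, "cnn.rds"))
  xgboost::xgb.save(model$booster, file.path(dir, "xgb.model"))
  invisible(dir)
}

#' @rdname save_convboost
#' @export
load_convboost <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  structure(list(
    cnn = readRDS(file.path(dir, "cnn.rds")),
    booster = xgboost::xgb.load(file.path(dir, "xgb.model")),
    xgb_params = as.list(meta$xgb_params), tuning = NULL,
    center = setNames(meta$center, meta$features),
    scale = setNames(meta$scale, meta$features),
    features = meta$features,
    meta = list(fc_name = meta$fc_name, variant = meta$variant,
                epochs = meta$epochs, seed = meta$seed,
                n_train = meta$n_train)),
    class = "convboost_model")
}
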