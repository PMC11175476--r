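# Bayesian hyperparameter search for the gradient-boosted member.
#
# A Gaussian-process surrogate (RBF kernel on the unit-cube encoding of the
# search space, lengthscale chosen by marginal likelihood) is fitted to the
# cross-validated accuracies of evaluated configurations, and the next
# configuration maximises expected improvement over a random candidate set.
# The initial design is a maximin Latin hypercube. Everything is
# deterministic given the seed.

#' Default XGBoost hyperparameter search space
#'
#' Ranges for every tuned hyperparameter: number of trees, tree depth,
#' tree construction method, minimum child weight, column subsampling per
#' tree and per level, row subsampling, split-loss gamma, L1/L2 leaf
#' regularisation, learning rate and positive-class weight.
#'
#' @return A list of class `xgb_search_space`; each element describes one
#'   dimension (`type` = `"int"`, `"real"`, `"log"` or `"cat"`, with
#'   `lower`/`upper` or `values`).
#' @export
xgb_search_space <- function() {
  structure(list(
    n_estimators = list(type = "int", lower = 50, upper = 1000),
    max_depth = list(type = "int", lower = 2, upper = 12),
    tree_method = list(type = "cat", values = c("exact", "hist")),
    min_child_weight = list(type = "real", lower = 1, upper = 10),
    colsample_bytree = list(type = "real", lower = 0.5, upper = 1),
    colsample_bylevel = list(type = "real", lower = 0.5, upper = 1),
    subsample = list(type = "real", lower = 0.5, upper = 1),
    gamma = list(type = "real", lower = 0, upper = 10),
    reg_alpha = list(type = "real", lower = 0, upper = 10),
    reg_lambda = list(type = "real", lower = 0, upper = 10),
    learning_rate = list(type = "log", lower = 0.01, upper = 0.3),
    scale_pos_weight = list(type = "real", lower = 0.5, upper = 2)
  ), class = "xgb_search_space")
}

# encode a named hyperparameter list into the unit cube (inverse of decode)
.space_encode <- function(params, space) {
  u <- numeric(length(space))
  for (d in seq_along(space)) {
    s <- space[[d]]
    val <- params[[names(space)[[d]]]]
    u[[d]] <- switch(s$type,
      int = (val - s$lower) / (s$upper - s$lower),
      real = (val - s$lower) / (s$upper - s$lower),
      log = (log(val) - log(s$lower)) / (log(s$upper) - log(s$lower)),
      cat = (match(val, s$values) - 0.5) / length(s$values))
  }
  pmin(pmax(u, 0), 1)
}

# decode a unit-cube point into a named hyperparameter list
.space_decode <- function(u, space) {
  out <- list()
  for (d in seq_along(space)) {
    s <- space[[d]]
    out[[names(space)[[d]]]] <- switch(s$type,
      int = as.integer(round(s$lower + u[[d]] * (s$upper - s$lower))),
      real = s$lower + u[[d]] * (s$upper - s$lower),
      log = exp(log(s$lower) + u[[d]] * (log(s$upper) - log(s$lower))),
      cat = s$values[[pmin(length(s$values),
                           1L + floor(u[[d]] * length(s$values)))]])
  }
  out
}

# fixed default configuration used when tuning is switched off
.xgb_default_params <- function() {
  list(n_estimators = 300L, max_depth = 6L, tree_method = "exact",
       min_child_weight = 1, colsample_bytree = 0.9, colsample_bylevel = 1,
       subsample = 0.9, gamma = 0, reg_alpha = 0, reg_lambda = 1,
       learning_rate = 0.1, scale_pos_weight = 1)
}

.xgb_fit <- function(x, y01, params, seed) {
  dm <- xgboost::xgb.DMatrix(as.matrix(x), label = y01)
  .with_seed(seed, xgboost::xgb.train(
    params = list(
      objective = "binary:logistic",
      max_depth = params$max_depth,
      eta = params$learning_rate,
      tree_method = params$tree_method,
      min_child_weight = params$min_child_weight,
      colsample_bytree = params$colsample_bytree,
      colsample_bylevel = params$colsample_bylevel,
      subsample = params$subsample,
      gamma = params$gamma,
      alpha = params$reg_alpha,
      lambda = params$reg_lambda,
      scale_pos_weight = params$scale_pos_weight,
      seed = seed,
      nthread = 1),
    data = dm, nrounds = params$n_estimators, verbose = 0))
}

# stratified k-fold CV accuracy of one configuration
.xgb_cv_accuracy <- function(x, y01, params, folds, seed) {
  acc <- 0
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- .xgb_fit(x[tr, , drop = FALSE], y01[tr], params, seed)
    p <- predict(fit, as.matrix(x[!tr, , drop = FALSE]))
    acc <- acc + mean((p > 0.5) == (y01[!tr] == 1))
  }
  acc / length(unique(folds))
}

# GP marginal likelihood / posterior helpers (RBF kernel, unit cube inputs)
.gp_fit <- function(U, y) {
  n <- nrow(U)
  ym <- mean(y); ys <- stats::sd(y); if (!is.finite(ys) || ys == 0) ys <- 1
  yc <- (y - ym) / ys
  d2 <- as.matrix(stats::dist(U))^2
  best <- NULL
  for (l in c(0.1, 0.2, 0.3, 0.5, 1, 2)) {
    K <- exp(-d2 / (2 * l^2)) + diag(1e-4, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, forwardsolve(t(ch), yc))
    ll <- -0.5 * sum(yc * alpha) - sum(log(diag(ch)))
    if (is.null(best) || ll > best$ll) {
      best <- list(ll = ll, l = l, ch = ch, alpha = alpha,
                   U = U, ym = ym, ys = ys)
    }
  }
  best
}

.gp_predict <- function(gp, Unew) {
  d2 <- outer(rowSums(Unew^2), rowSums(gp$U^2), "+") -
    2 * Unew %*% t(gp$U)
  Ks <- exp(-pmax(d2, 0) / (2 * gp$l^2))
  mu <- as.vector(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$ch), t(Ks))
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = mu * gp$ys + gp$ym, sd = sqrt(s2) * gp$ys)
}

#' Tune XGBoost hyperparameters by Bayesian optimisation
#'
#' Sequential model-based search over [xgb_search_space()] maximising
#' stratified `cv_folds`-fold cross-validated accuracy on the supplied
#' feature table, then refits the best configuration on the full table.
#'
#' @param table Feature tibble (`id`, `label`, descriptor columns).
#' @param space An [xgb_search_space()].
#' @param n_iter Total configurations evaluated (initial Latin-hypercube
#'   design plus sequential proposals). Default 32.
#' @param cv_folds Inner cross-validation folds. Default 3.
#' @param seed Integer seed.
#' @details The first evaluated configuration is the fixed default
#'   configuration, warm-starting the search.
#' @return A list of class `xgb_tuned`: `best_params`, `best_score`,
#'   `booster` (fit on the full table), `log` (tibble of every evaluated
#'   configuration with its score).
#' @export
tune_xgboost <- function(table, space = xgb_search_space(), n_iter = 32L,
                         cv_folds = 3L, seed = 1L) {
  stopifnot(n_iter >= 1, cv_folds >= 2)
  if (length(space) == 0) rlang::abort("Empty search space.")
  xy <- .split_xy(table)
  folds <- stratified_folds(xy$label, k = cv_folds,
                            seed = .derive_seed(seed, "tune-folds"))
  d <- length(space)
  n_init <- min(n_iter, max(4L, d))
  U <- .with_seed(.derive_seed(seed, "tune-lhs"),
                  lhs::maximinLHS(n_init, d))
  # warm start: the first evaluated configuration is the package default,
  # so the search never reports a configuration worse than it
  U[1, ] <- .space_encode(.xgb_default_params(), space)
  scores <- numeric(0)
  log <- list()
  for (i in seq_len(n_iter)) {
    if (i > n_init) {
      gp <- .gp_fit(U, scores)
      cand <- .with_seed(.derive_seed(seed, paste0("tune-cand", i)),
                         matrix(stats::runif(512 * d), ncol = d))
      if (is.null(gp)) {
        unew <- cand[1, ]
      } else {
        pr <- .gp_predict(gp, cand)
        fbest <- max(scores)
        z <- (pr$mean - fbest) / pr$sd
        ei <- pr$sd * (z * stats::pnorm(z) + stats::dnorm(z))
        unew <- cand[which.max(ei), ]
      }
      U <- rbind(U, unew)
    }
    params <- .space_decode(U[i, ], space)
    sc <- .xgb_cv_accuracy(xy$x, xy$y01, params, folds,
                           seed = .derive_seed(seed, "tune-fit"))
    scores <- c(scores, sc)
    log[[i]] <- tibble::as_tibble(c(params, list(cv_accuracy = sc, iter = i)))
  }
  best <- which.max(scores)
  best_params <- .space_decode(U[best, ], space)
  booster <- .xgb_fit(xy$x, xy$y01, best_params,
                      seed = .derive_seed(seed, "tune-final"))
  structure(list(best_params = best_params, best_score = scores[[best]],
                 booster = booster, log = dplyr::bind_rows(log)),
            class = "xgb_tuned")
}

#' @export
print.xgb_tuned <- function(x, ...) {
  cat(sprintf("<xgb_tuned> %d configurations; best CV accuracy %.4f\n",
              nrow(x$log), x$best_score))
  invisible(x)
}
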