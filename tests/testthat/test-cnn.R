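test_that("the built network matches the reference architecture", {
  net <- build_cnn(13)
  types <- vapply(net$layers, `[[`, "", "type")
  conv <- net$layers[types == "conv1d"]
  dense <- net$layers[types == "dense"]
  expect_length(conv, 8)
  expect_equal(vapply(conv, `[[`, integer(1), "filters"),
               rep(c(32L, 64L, 128L, 256L), each = 2))
  expect_true(all(vapply(conv, `[[`, integer(1), "kernel") == 3L))
  expect_equal(vapply(dense, `[[`, integer(1), "units"),
               c(256L, 128L, 64L, 32L, 16L, 2L))
  expect_equal(sum(types == "dropout"), 1)
  expect_equal(net$layers[[which(types == "dropout")]]$rate, 0.5)
  # pools: size 2 immediately before the last conv group, size 3 after it
  pools <- which(types == "maxpool")
  expect_equal(vapply(net$layers[pools], `[[`, integer(1), "size"),
               c(2L, 3L))
  expect_equal(types[pools[1] + 1], "conv1d")
  expect_equal(net$layers[[pools[1] + 1]]$filters, 256L)
})

test_that("L1 regularisers sit on the documented layers only", {
  net <- build_cnn(13)
  types <- vapply(net$layers, `[[`, "", "type")
  conv <- net$layers[types == "conv1d"]
  act <- vapply(conv, `[[`, numeric(1), "activity_l1")
  bias <- vapply(conv, `[[`, numeric(1), "bias_l1")
  expect_equal(act, rep(c(0, 1e-3, 1e-3, 1e-3), each = 2))   # group 1 bare
  expect_equal(bias, rep(c(0, 0, 1e-2, 1e-2), each = 2))
  dense <- net$layers[types == "dense"]
  expect_equal(vapply(dense, `[[`, numeric(1), "activity_l1"),
               c(1e-3, 1e-3, 1e-3, 1e-3, 0, 0))
  expect_equal(vapply(dense, `[[`, numeric(1), "bias_l1"),
               c(1e-3, 1e-3, 1e-3, 0, 0, 0))
})

test_that("too-small inputs are rejected with the minimal admissible size", {
  expect_error(build_cnn(5), "at least 6")
  expect_silent(net <- build_cnn(6))
})

test_that("training is deterministic given the seed", {
  tab <- toy_feature_table(n_per_class = 16L, seed = 7)
  x <- scale(as.matrix(tab[, -(1:2)]))
  n1 <- train_cnn(build_cnn(13, seed = 5), x, tab$label, epochs = 3, seed = 9)
  n2 <- train_cnn(build_cnn(13, seed = 5), x, tab$label, epochs = 3, seed = 9)
  expect_identical(n1$history, n2$history)
  expect_identical(predict(n1, x), predict(n2, x))
  n3 <- train_cnn(build_cnn(13, seed = 5), x, tab$label, epochs = 3, seed = 10)
  expect_false(identical(n1$history$loss, n3$history$loss))
})

test_that("backpropagation matches finite differences", {
  sp <- cnn_spec(filters = c(4L, 5L, 6L, 7L), dense = c(8L, 6L, 5L, 4L, 3L),
                 dropout = 0)
  set.seed(3)
  x <- matrix(rnorm(5 * 8), 5, 8)
  y <- c("CPP", "nonCPP", "CPP", "nonCPP", "CPP")
  net <- build_cnn(8, sp, seed = 9)
  Y <- convboost:::.one_hot(y, net$classes)
  fw <- convboost:::.cnn_forward(net, x, training = TRUE)
  bw <- convboost:::.cnn_backward(net, fw$caches, Y)
  lossfun <- function(n) {
    f <- convboost:::.cnn_forward(n, x, training = TRUE)
    convboost:::.cnn_backward(n, f$caches, Y)$loss
  }
  eps <- 1e-6
  for (li in seq_along(net$layers)) {
    if (is.null(net$layers[[li]]$W)) next
    for (ix in sample(length(net$layers[[li]]$W), 3)) {
      n2 <- net; n2$layers[[li]]$W[ix] <- n2$layers[[li]]$W[ix] + eps
      n3 <- net; n3$layers[[li]]$W[ix] <- n3$layers[[li]]$W[ix] - eps
      num <- (lossfun(n2) - lossfun(n3)) / (2 * eps)
      expect_equal(bw$grads[[li]]$W[ix], num, tolerance = 1e-4)
    }
  }
})

test_that("a linearly separable table is fit to high accuracy", {
  tab <- toy_feature_table(n_per_class = 40L, shift = 3, seed = 17)
  x <- scale(as.matrix(tab[, -(1:2)]))
  net <- train_cnn(build_cnn(13, seed = 2), x, tab$label,
                   epochs = default_epochs("FC-STR"), seed = 4)
  expect_equal(nrow(net$history), 20)   # FC-STR default epoch count
  p <- predict(net, x)[, "CPP"]
  acc <- mean((p > 0.5) == (tab$label == "CPP"))
  # sanity oracle: logistic regression separates this table perfectly
  glm_acc <- {
    df <- data.frame(y = as.numeric(tab$label == "CPP"), x)
    m <- suppressWarnings(glm(y ~ ., data = df, family = binomial))
    mean((fitted(m) > 0.5) == df$y)
  }
  expect_gte(glm_acc, 0.99)
  expect_gt(acc, 0.95)
  # probabilities form a proper pair
  pm <- predict(net, x)
  expect_equal(rowSums(pm), rep(1, nrow(pm)), tolerance = 1e-9)
})

test_that("non-finite features are rejected before training", {
  tab <- toy_feature_table(n_per_class = 12L)
  x <- as.matrix(tab[, -(1:2)]); x[1, 1] <- NA
  expect_error(train_cnn(build_cnn(13), x, tab$label, epochs = 1),
               "Non-finite")
})
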