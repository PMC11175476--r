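# One-dimensional convolutional network for tabular descriptor vectors.
#
# The descriptor vector of a peptide is presented as a length-D, 1-channel
# signal in feature-composition order. Architecture: four groups of two
# conv1d layers (kernel 3, same padding, tanh) with 32/64/128/256 filters,
# a size-2 max pool before the last group and a size-3 max pool after it,
# dropout 0.5, then dense layers 256/128/64/32/16 (tanh) and a 2-way
# softmax trained with cross-entropy under Adam. L1 activity and bias
# regularisers are attached per layer (activity 1e-3 on conv groups 2-4
# and dense 256..32; bias 1e-2 on conv groups 3-4 and 1e-3 on dense
# 256..64). Implemented with im2col + matrix products; no external
# deep-learning runtime is involved.

#' Specification of the convolutional network
#'
#' All tunables of the network in one object; the defaults are the
#' package's reference architecture (see the package vignette).
#'
#' @param filters Filters per conv group (two layers each).
#' @param kernel Convolution kernel width.
#' @param dense Dense-layer widths.
#' @param dropout Dropout rate before the dense stack.
#' @param pool_before_last,pool_after_last Max-pool sizes around the last
#'   conv group.
#' @param conv_activity_l1,conv_bias_l1 Per-group L1 regulariser weights.
#' @param dense_activity_l1,dense_bias_l1 Per-dense-layer L1 weights.
#' @param learning_rate,batch_size Adam learning rate and minibatch size.
#' @return A list of class `cnn_spec`.
#' @export
cnn_spec <- function(filters = c(32L, 64L, 128L, 256L), kernel = 3L,
                     dense = c(256L, 128L, 64L, 32L, 16L), dropout = 0.5,
                     pool_before_last = 2L, pool_after_last = 3L,
                     conv_activity_l1 = c(0, 1e-3, 1e-3, 1e-3),
                     conv_bias_l1 = c(0, 0, 1e-2, 1e-2),
                     dense_activity_l1 = c(1e-3, 1e-3, 1e-3, 1e-3, 0),
                     dense_bias_l1 = c(1e-3, 1e-3, 1e-3, 0, 0),
                     learning_rate = 1e-3, batch_size = 32L) {
  stopifnot(length(conv_activity_l1) == length(filters),
            length(conv_bias_l1) == length(filters),
            length(dense_activity_l1) == length(dense),
            length(dense_bias_l1) == length(dense))
  structure(as.list(environment()), class = "cnn_spec")
}

.glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained convolutional network
#'
#' @param input_dim Number of input descriptors (length of the 1-channel
#'   input signal). Must be large enough that both pooling stages leave at
#'   least one position.
#' @param spec A [cnn_spec()].
#' @param seed Integer seed for weight initialisation (Glorot uniform).
#' @return An object of class `cnn_net` with introspectable `layers`
#'   (type, shapes, regulariser weights) and the `spec`.
#' @export
build_cnn <- function(input_dim, spec = cnn_spec(), seed = 1L) {
  stopifnot(input_dim >= 1)
  min_dim <- spec$pool_before_last * spec$pool_after_last
  if (input_dim %/% spec$pool_before_last %/% spec$pool_after_last < 1) {
    rlang::abort(sprintf(
      "input_dim = %d too small for pooling sizes %d and %d; need at least %d.",
      input_dim, spec$pool_before_last, spec$pool_after_last, min_dim))
  }
  k <- spec$kernel
  ngroups <- length(spec$filters)
  layers <- list()
  cin <- 1L
  len <- as.integer(input_dim)
  .with_seed(seed, {
    for (g in seq_len(ngroups)) {
      if (g == ngroups) {
        layers[[length(layers) + 1]] <- list(type = "maxpool",
                                             size = spec$pool_before_last)
        len <- len %/% spec$pool_before_last
      }
      for (j in 1:2) {
        f <- spec$filters[[g]]
        layers[[length(layers) + 1]] <- list(
          type = "conv1d", group = g, filters = f, kernel = k,
          activation = "tanh",
          activity_l1 = spec$conv_activity_l1[[g]],
          bias_l1 = spec$conv_bias_l1[[g]],
          W = .glorot(k * cin, f, k * cin, k * f), b = numeric(f))
        cin <- f
      }
    }
    layers[[length(layers) + 1]] <- list(type = "maxpool",
                                         size = spec$pool_after_last)
    len <- len %/% spec$pool_after_last
    layers[[length(layers) + 1]] <- list(type = "dropout", rate = spec$dropout)
    layers[[length(layers) + 1]] <- list(type = "flatten")
    din <- len * cin
    for (d in seq_along(spec$dense)) {
      u <- spec$dense[[d]]
      layers[[length(layers) + 1]] <- list(
        type = "dense", units = u, activation = "tanh",
        activity_l1 = spec$dense_activity_l1[[d]],
        bias_l1 = spec$dense_bias_l1[[d]],
        W = .glorot(din, u, din, u), b = numeric(u))
      din <- u
    }
    layers[[length(layers) + 1]] <- list(
      type = "dense", units = 2L, activation = "softmax",
      activity_l1 = 0, bias_l1 = 0,
      W = .glorot(din, 2L, din, 2L), b = numeric(2))
  })
  structure(list(layers = layers, spec = spec, input_dim = as.integer(input_dim),
                 classes = c("nonCPP", "CPP"), trained = FALSE),
            class = "cnn_net")
}

#' @export
print.cnn_net <- function(x, ...) {
  types <- vapply(x$layers, `[[`, "", "type")
  cat(sprintf(
    "<cnn_net> input %d; %d conv1d, %d dense, %d maxpool, %d dropout layer(s)%s\n",
    x$input_dim, sum(types == "conv1d"), sum(types == "dense"),
    sum(types == "maxpool"), sum(types == "dropout"),
    if (x$trained) "; trained" else ""))
  invisible(x)
}

# R wrappers over the compiled gather/scatter kernels
.im2col <- function(X, k) {
  d <- dim(X)
  im2col_1d(X, d[1], d[2], d[3], k)
}

.col2im <- function(dM, k, B, L, C) {
  col2im_1d(dM, B, L, C, k)
}

# forward pass; X matrix (B, input_dim). Returns probs and, if training,
# per-layer caches for backprop.
.cnn_forward <- function(net, X, training = FALSE) {
  B <- nrow(X)
  A <- array(X, c(B, ncol(X), 1L))
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "conv1d") {
      d <- dim(A)
      M <- .im2col(A, ly$kernel)
      Aout <- tanh_bias(M %*% ly$W, ly$b)
      if (training) caches[[i]] <- list(M = M, A = Aout, dims = d)
      dim(Aout) <- c(d[1], d[2], ly$filters)
      A <- Aout
    } else if (ly$type == "maxpool") {
      d <- dim(A); Lout <- d[2] %/% ly$size
      cur <- A[, seq(1, by = ly$size, length.out = Lout), , drop = FALSE]
      arg <- array(1L, dim(cur))
      if (ly$size > 1) for (j in 2:ly$size) {
        cand <- A[, seq(j, by = ly$size, length.out = Lout), , drop = FALSE]
        upd <- cand > cur
        cur[upd] <- cand[upd]
        arg[upd] <- j
      }
      if (training) caches[[i]] <- list(arg = arg, dims = d)
      A <- cur
    } else if (ly$type == "dropout") {
      if (training) {
        mask <- array(stats::runif(length(A)) >= ly$rate, dim(A)) /
          (1 - ly$rate)
        A <- A * mask
        caches[[i]] <- list(mask = mask)
      }
    } else if (ly$type == "flatten") {
      d <- dim(A)
      if (training) caches[[i]] <- list(dims = d)
      dim(A) <- c(d[1], d[2] * d[3])
    } else { # dense
      if (ly$activation == "tanh") {
        Aout <- tanh_bias(A %*% ly$W, ly$b)
      } else { # softmax
        Z <- A %*% ly$W
        Z <- Z + rep(ly$b, each = nrow(Z))
        Z <- Z - apply(Z, 1, max)
        E <- exp(Z)
        Aout <- E / rowSums(E)
      }
      if (training) caches[[i]] <- list(X = A, A = Aout)
      A <- Aout
    }
  }
  list(probs = A, caches = caches)
}

# backward pass; Y one-hot (B, 2). Returns list of grads per layer (W, b)
# and the regularised loss.
.cnn_backward <- function(net, caches, Y) {
  B <- nrow(Y)
  grads <- vector("list", length(net$layers))
  nl <- length(net$layers)
  P <- caches[[nl]]$A
  loss <- -mean(log(pmax(rowSums(P * Y), 1e-12)))
  dA <- NULL # gradient flowing backwards; for output handled specially
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    if (ly$type == "dense") {
      ca <- caches[[i]]
      if (ly$activation == "softmax") {
        dZ <- (ca$A - Y) / B
      } else {
        if (ly$activity_l1 > 0) {
          loss <- loss + ly$activity_l1 * sum(abs(ca$A)) / B
        }
        dZ <- backprop_tanh(dA, ca$A, ly$activity_l1 / B)
      }
      gW <- crossprod(ca$X, dZ)
      gb <- colSums(dZ)
      if (ly$bias_l1 > 0) {
        gb <- gb + ly$bias_l1 * sign(ly$b)
        loss <- loss + ly$bias_l1 * sum(abs(ly$b))
      }
      grads[[i]] <- list(W = gW, b = gb)
      dA <- tcrossprod(dZ, ly$W)
    } else if (ly$type == "flatten") {
      dim(dA) <- caches[[i]]$dims
    } else if (ly$type == "dropout") {
      if (!is.null(caches[[i]])) dA <- dA * caches[[i]]$mask
    } else if (ly$type == "maxpool") {
      ca <- caches[[i]]
      d <- ca$dims; Lout <- dim(dA)[2]
      dX <- array(0, d)
      for (j in seq_len(ly$size)) {
        sel <- ca$arg == j
        slice <- array(0, dim(dA))
        slice[sel] <- dA[sel]
        pos <- seq(j, by = ly$size, length.out = Lout)
        dX[, pos, ] <- dX[, pos, , drop = FALSE] + slice
      }
      dA <- dX
    } else { # conv1d
      ca <- caches[[i]]
      d <- ca$dims # input dims (B, L, Cin)
      Aout <- ca$A # (B*L, F)
      dAm <- dA
      dim(dAm) <- c(d[1] * d[2], ly$filters)
      if (ly$activity_l1 > 0) {
        loss <- loss + ly$activity_l1 * sum(abs(Aout)) / B
      }
      dZ <- backprop_tanh(dAm, Aout, ly$activity_l1 / B)
      gW <- crossprod(ca$M, dZ)
      gb <- colSums(dZ)
      if (ly$bias_l1 > 0) {
        gb <- gb + ly$bias_l1 * sign(ly$b)
        loss <- loss + ly$bias_l1 * sum(abs(ly$b))
      }
      grads[[i]] <- list(W = gW, b = gb)
      dM <- tcrossprod(dZ, ly$W)
      dA <- .col2im(dM, ly$kernel, d[1], d[2], d[3])
    }
  }
  list(grads = grads, loss = loss)
}

#' Train a convolutional network
#'
#' Minibatch Adam training for a fixed number of epochs (cross-entropy plus
#' the configured L1 activity/bias penalties). Deterministic for a given
#' seed. Features are expected to be standardised (see [fit_convboost()],
#' which handles scaling).
#'
#' @param net A [build_cnn()] network.
#' @param x Numeric matrix or tibble of features (rows = peptides), column
#'   count equal to `net$input_dim`.
#' @param y Labels: `"CPP"` / `"nonCPP"` character or factor vector.
#' @param epochs Number of passes over the data.
#' @param seed Integer seed driving shuffling, dropout and Adam state.
#' @param verbose Print per-epoch loss.
#' @return The trained `cnn_net`, with a `history` tibble
#'   (`epoch`, `loss`) attached.
#' @export
train_cnn <- function(net, x, y, epochs = 20L, seed = 1L, verbose = FALSE) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) rlang::abort("Non-finite feature values.")
  stopifnot(ncol(x) == net$input_dim, nrow(x) == length(y))
  Y <- .one_hot(y, net$classes)
  bs <- net$spec$batch_size
  lr <- net$spec$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
  for (i in seq_along(net$layers)) { # fresh copies: updates are in-place
    if (!is.null(net$layers[[i]]$W)) {
      net$layers[[i]]$W <- net$layers[[i]]$W + 0
      net$layers[[i]]$b <- net$layers[[i]]$b + 0
    }
  }
  mstate <- lapply(net$layers, function(ly) {
    if (!is.null(ly$W)) list(W = ly$W * 0, b = ly$b * 0) else NULL
  })
  vstate <- lapply(net$layers, function(ly) {
    if (!is.null(ly$W)) list(W = ly$W * 0, b = ly$b * 0) else NULL
  })
  tstep <- 0
  history <- numeric(epochs)
  .with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(x))
      ep_loss <- 0; nb <- 0
      for (start in seq(1, nrow(x), by = bs)) {
        idx <- ord[start:min(start + bs - 1, nrow(x))]
        fw <- .cnn_forward(net, x[idx, , drop = FALSE], training = TRUE)
        bw <- .cnn_backward(net, fw$caches, Y[idx, , drop = FALSE])
        tstep <- tstep + 1
        corr <- sqrt(1 - b2^tstep) / (1 - b1^tstep)
        for (i in seq_along(net$layers)) {
          g <- bw$grads[[i]]
          if (is.null(g)) next
          adam_step(net$layers[[i]]$W, g$W, mstate[[i]]$W, vstate[[i]]$W,
                    lr * corr, b1, b2, eps)
          adam_step(net$layers[[i]]$b, g$b, mstate[[i]]$b, vstate[[i]]$b,
                    lr * corr, b1, b2, eps)
        }
        ep_loss <- ep_loss + bw$loss; nb <- nb + 1
      }
      history[[ep]] <- ep_loss / nb
      if (verbose) message(sprintf("epoch %d/%d  loss %.4f", ep, epochs,
                                   history[[ep]]))
    }
  })
  net$trained <- TRUE
  net$history <- tibble::tibble(epoch = seq_len(epochs), loss = history)
  net
}

#' Class probabilities from a convolutional network
#'
#' @param object A trained `cnn_net`.
#' @param newdata Feature matrix/tibble with `input_dim` columns.
#' @param ... Unused.
#' @return Numeric matrix (rows = peptides) with columns `nonCPP`, `CPP`.
#' @export
predict.cnn_net <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  stopifnot(ncol(x) == object$input_dim)
  p <- .cnn_forward(object, x, training = FALSE)$probs
  colnames(p) <- object$classes
  p
}

.one_hot <- function(y, classes) {
  y <- as.character(y)
  bad <- setdiff(unique(y), classes)
  if (length(bad) > 0) {
    rlang::abort(sprintf("Unknown label(s): %s", paste(bad, collapse = ", ")))
  }
  Y <- matrix(0, length(y), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(y), match(y, classes))] <- 1
  Y
}

#' Default training epochs for each feature composition
#'
#' The reference epoch settings per composition: 25 for FC-SEQ, 20 for
#' FC-STR, 25 for FC-SEQ-STR, 20 for FC-Kendall.
#' @param fc_name Composition name.
#' @return Integer epoch count.
#' @export
default_epochs <- function(fc_name) {
  switch(fc_name,
    "FC-SEQ" = 25L, "FC-STR" = 20L, "FC-SEQ-STR" = 25L, "FC-Kendall" = 20L,
    rlang::abort(sprintf("Unknown feature composition '%s'.", fc_name)))
}
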