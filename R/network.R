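# The 16-6-1 feedforward quality-control classifier.
#
# A single hidden layer of six tanh neurons and one tanh output keeps the
# model small enough not to overfit a few thousand training segments while
# still capturing interactions between the features. Training minimizes a
# class-weighted sum of squared errors with an L2 weight penalty; the class
# weights (error gains) compensate for the scarcity of bad segments.

# Preserve the caller's RNG state while drawing from a local seed.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Initialize network parameters
#'
#' Weights and biases are drawn uniformly from `[-scale, scale]` with a seeded
#' generator, so initialization is reproducible and symmetric about zero.
#'
#' @param seed Integer seed for the weight draw.
#' @param n_input,n_hidden Architecture (defaults: 16 inputs, 6 hidden
#'   neurons, 1 output).
#' @param scale Half-width of the uniform initialization interval.
#' @return Object of class `qc_network` with fields `W1` (n_hidden x n_input),
#'   `b1`, `W2` (1 x n_hidden), `b2`.
#' @export
init_network <- function(seed = 1L, n_input = 16L, n_hidden = 6L, scale = 0.5) {
  with_local_seed(seed, {
    structure(list(
      W1 = matrix(stats::runif(n_hidden * n_input, -scale, scale), n_hidden, n_input),
      b1 = stats::runif(n_hidden, -scale, scale),
      W2 = matrix(stats::runif(n_hidden, -scale, scale), 1L, n_hidden),
      b2 = stats::runif(1L, -scale, scale)
    ), class = "qc_network")
  })
}

net_dims <- function(net) c(n_hidden = nrow(net$W1), n_input = ncol(net$W1))

pack_params <- function(net) c(net$W1, net$b1, net$W2, net$b2)

unpack_params <- function(par, n_input, n_hidden) {
  i <- 0L
  take <- function(n) {
    out <- par[i + seq_len(n)]
    i <<- i + n
    out
  }
  structure(list(
    W1 = matrix(take(n_hidden * n_input), n_hidden, n_input),
    b1 = take(n_hidden),
    W2 = matrix(take(n_hidden), 1L, n_hidden),
    b2 = take(1L)
  ), class = "qc_network")
}

#' Forward pass of the classifier
#'
#' `score = tanh(W2 %*% tanh(W1 x + b1) + b2)`, strictly inside (-1, 1).
#'
#' @param net A `qc_network`.
#' @param x A normalized feature vector, or a matrix with one segment per row.
#' @return Numeric score(s) in (-1, 1); positive scores mean "good".
#' @export
nn_forward <- function(net, x) {
  stopifnot(inherits(net, "qc_network"))
  X <- if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1L) else as.matrix(x)
  if (ncol(X) != ncol(net$W1)) {
    stop("dimension error: expected ", ncol(net$W1), " inputs, got ", ncol(X))
  }
  H <- tanh(sweep(X %*% t(net$W1), 2L, net$b1, "+"))
  drop(tanh(H %*% t(net$W2) + net$b2))
}

# Weighted SSE + L2 penalty and its gradient by backpropagation.
# Biases are not penalized.
nn_loss <- function(par, X, target, gain, lambda, n_input, n_hidden) {
  net <- unpack_params(par, n_input, n_hidden)
  H <- tanh(sweep(X %*% t(net$W1), 2L, net$b1, "+"))
  s <- drop(tanh(H %*% t(net$W2) + net$b2))
  sum(gain * (s - target)^2) + lambda * (sum(net$W1^2) + sum(net$W2^2))
}

nn_grad <- function(par, X, target, gain, lambda, n_input, n_hidden) {
  net <- unpack_params(par, n_input, n_hidden)
  Z1 <- sweep(X %*% t(net$W1), 2L, net$b1, "+")
  H <- tanh(Z1)
  s <- drop(tanh(H %*% t(net$W2) + net$b2))
  d2 <- (2 * gain * (s - target)) * (1 - s^2)          # n
  gW2 <- matrix(d2, nrow = 1L) %*% H + 2 * lambda * net$W2
  gb2 <- sum(d2)
  dH <- outer(d2, drop(net$W2)) * (1 - H^2)            # n x hidden
  gW1 <- t(dH) %*% X + 2 * lambda * net$W1
  gb1 <- colSums(dH)
  c(gW1, gb1, gW2, gb2)
}

#' Class-balancing error gains
#'
#' With unbalanced quality categories a plain SSE would let the network ignore
#' the rare bad segments. Each category's errors are weighted by
#' `N_total / (K * N_class)` (K = number of categories present), so every
#' category contributes equally to the loss.
#'
#' @param labels Factor or character vector of `good`/`tolerable`/`bad`.
#' @return Named numeric vector of gains for the categories present.
#' @export
class_gains <- function(labels) {
  counts <- table(factor(as.character(labels), levels = c("good", "tolerable", "bad")))
  counts <- counts[counts > 0]
  gains <- as.numeric(sum(counts) / (length(counts) * counts))
  stats::setNames(gains, names(counts))
}

#' Training configuration for the quality-control network
#'
#' @param seed Seed for weight initialization (and the internal fold split
#'   when `lambda` is a grid).
#' @param lambda L2 penalty weight(s). A vector triggers selection on an
#'   internal stratified 80/20 held-out fold, then a refit on all data.
#' @param gains Named per-class error gains; `NULL` computes [class_gains]
#'   from the training labels.
#' @param max_epochs Iteration budget for the optimizer.
#' @param learning_rate Step size for `method = "gd"`.
#' @param tol Relative convergence tolerance on the penalized loss.
#' @param method `"bfgs"` (quasi-Newton on the backpropagated gradient,
#'   default) or `"gd"` (plain full-batch gradient descent).
#' @param restarts Number of deterministic random initializations (seeds
#'   `seed`, `seed + 1`, ...); the fit with the lowest penalized loss is
#'   kept. The non-convex loss has plateaus where a single unlucky start can
#'   stall.
#' @return List of class `qc_training_config`.
#' @export
qc_training_config <- function(seed = 1L, lambda = 1e-3, gains = NULL,
                               max_epochs = 500L, learning_rate = 1e-3,
                               tol = 1e-10, method = c("bfgs", "gd"),
                               restarts = 3L) {
  method <- match.arg(method)
  stopifnot(max_epochs > 0, all(lambda >= 0), learning_rate > 0, restarts >= 1)
  if (!is.null(gains) && any(gains <= 0)) stop("class gains must be positive")
  structure(list(seed = as.integer(seed), lambda = lambda, gains = gains,
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, tol = tol, method = method,
                 restarts = as.integer(restarts)),
            class = "qc_training_config")
}

# Best fit over the configured restarts, by final penalized loss.
train_multistart <- function(X, target, gain, lambda, cfg) {
  best <- NULL
  for (r in seq_len(cfg$restarts)) {
    net0 <- init_network(cfg$seed + r - 1L, n_input = ncol(X))
    fit <- train_once(X, target, gain, lambda, cfg, net0)
    if (is.null(best) || fit$loss < best$loss) best <- fit
  }
  best
}

train_once <- function(X, target, gain, lambda, cfg, net0) {
  n_input <- ncol(X); n_hidden <- nrow(net0$W1)
  par <- pack_params(net0)
  if (cfg$method == "bfgs") {
    fit <- stats::optim(par, fn = nn_loss, gr = nn_grad, method = "BFGS",
                        control = list(maxit = cfg$max_epochs, reltol = cfg$tol),
                        X = X, target = target, gain = gain, lambda = lambda,
                        n_input = n_input, n_hidden = n_hidden)
    list(net = unpack_params(fit$par, n_input, n_hidden), loss = fit$value,
         epochs = as.integer(fit$counts[["function"]]), history = NULL)
  } else {
    history <- numeric(cfg$max_epochs)
    loss <- nn_loss(par, X, target, gain, lambda, n_input, n_hidden)
    epochs <- 0L
    for (e in seq_len(cfg$max_epochs)) {
      par <- par - cfg$learning_rate *
        nn_grad(par, X, target, gain, lambda, n_input, n_hidden)
      new_loss <- nn_loss(par, X, target, gain, lambda, n_input, n_hidden)
      history[e] <- new_loss
      epochs <- e
      if (abs(loss - new_loss) <= cfg$tol * (abs(loss) + 1e-12)) {
        loss <- new_loss
        break
      }
      loss <- new_loss
    }
    list(net = unpack_params(par, n_input, n_hidden), loss = loss,
         epochs = epochs, history = history[seq_len(epochs)])
  }
}

#' Train the quality-control network
#'
#' Minimizes `sum_i gain(class_i) * (score_i - target_i)^2 + lambda * ||W||^2`
#' with gradients obtained by backpropagation. Targets are +1 for `good`
#' segments and -1 for `tolerable` or `bad` ones: the network learns the
#' binary accept decision while the three-category gains preserve the class
#' balance of the loss.
#'
#' @param X Matrix of normalized feature vectors (rows = segments).
#' @param labels Quality labels (`good`/`tolerable`/`bad`) for the rows of `X`.
#' @param config A [qc_training_config].
#' @return List with `network` (the trained `qc_network`) and `report`
#'   (final penalized loss, epochs, selected lambda, training sensitivity and
#'   specificity, and the loss history for `method = "gd"`).
#' @export
train_qc_network <- function(X, labels, config = qc_training_config()) {
  X <- as.matrix(X)
  labels <- factor(as.character(labels), levels = c("good", "tolerable", "bad"))
  if (anyNA(labels)) stop("labels must be good, tolerable or bad")
  if (nrow(X) != length(labels)) stop("feature and label lengths differ")
  good <- labels == "good"
  if (all(good) || !any(good)) {
    stop("degenerate training set: need both good and not-good examples")
  }
  gains <- config$gains
  if (is.null(gains)) gains <- class_gains(labels)
  gain <- as.numeric(gains[as.character(labels)])
  if (anyNA(gain)) stop("gains must cover every label category present")
  target <- ifelse(good, 1, -1)

  lambda <- config$lambda
  if (length(lambda) > 1L) {
    # small grid: evaluate each candidate on a stratified held-out fold
    idx_val <- with_local_seed(config$seed + 1000L, {
      unlist(lapply(split(seq_along(labels), labels, drop = TRUE), function(ix) {
        sample(ix, max(1L, round(0.2 * length(ix))))
      }), use.names = FALSE)
    })
    idx_tr <- setdiff(seq_along(labels), idx_val)
    score_of <- vapply(lambda, function(l) {
      fit <- train_multistart(X[idx_tr, , drop = FALSE], target[idx_tr],
                              gain[idx_tr], l, config)
      acc <- nn_forward(fit$net, X[idx_val, , drop = FALSE]) > 0
      balanced_accuracy(labels[idx_val], acc)
    }, numeric(1))
    lambda <- lambda[which.max(score_of)]
  }

  fit <- train_multistart(X, target, gain, lambda, config)
  accepted <- nn_forward(fit$net, X) > 0
  report <- list(
    final_loss = fit$loss,
    epochs = fit$epochs,
    lambda = lambda,
    gains = gains,
    sensitivity = if (any(good)) mean(accepted[good]) else NA_real_,
    specificity = if (any(labels == "bad")) mean(!accepted[labels == "bad"]) else NA_real_,
    loss_history = fit$history
  )
  list(network = fit$net, report = report)
}

# Mean of sensitivity (on good) and specificity (on bad); used only for
# internal lambda selection. Falls back to accept-accuracy when a class is
# missing from the fold.
balanced_accuracy <- function(labels, accepted) {
  good <- labels == "good"
  bad <- labels == "bad"
  if (!any(good) || !any(bad)) return(mean(accepted == good))
  (mean(accepted[good]) + mean(!accepted[bad])) / 2
}

#' Accept/reject decision for normalized feature vectors
#'
#' A segment is accepted (classified good) when the network score is strictly
#' positive; a score of exactly zero is rejected, the conservative choice.
#'
#' @param net A trained `qc_network`.
#' @param x Normalized feature vector or matrix of rows.
#' @return Logical vector: `TRUE` = accepted.
#' @export
predict_accept <- function(net, x) {
  nn_forward(net, x) > 0
}

#' Save a quality-control model (network + normalizer) as JSON
#'
#' @param model List with elements `network` (`qc_network`), `normalizer`
#'   (`qc_normalizer`), and optionally `gains`, `config`, `mag_reference`.
#' @param path Output file path.
#' @export
save_qc_model <- function(model, path) {
  stopifnot(inherits(model$network, "qc_network"))
  obj <- list(
    architecture = as.list(net_dims(model$network)),
    W1 = model$network$W1, b1 = model$network$b1,
    W2 = model$network$W2, b2 = model$network$b2,
    normalizer = if (!is.null(model$normalizer)) {
      list(mean = model$normalizer$mean, sd = model$normalizer$sd,
           clip_sd = model$normalizer$clip_sd)
    },
    gains = model$gains,
    mag_reference = model$mag_reference,
    config = model$config
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load a quality-control model saved by [save_qc_model]
#'
#' @param path JSON file path.
#' @return List with `network`, `normalizer`, `gains`, `mag_reference`, `config`.
#' @export
load_qc_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nh <- obj$architecture$n_hidden
  ni <- obj$architecture$n_input
  net <- structure(list(
    W1 = matrix(unlist(obj$W1), nh, ni),
    b1 = as.numeric(obj$b1),
    W2 = matrix(unlist(obj$W2), 1L, nh),
    b2 = as.numeric(obj$b2)
  ), class = "qc_network")
  normalizer <- NULL
  if (!is.null(obj$normalizer)) {
    normalizer <- structure(list(
      mean = unlist(obj$normalizer$mean),
      sd = unlist(obj$normalizer$sd),
      clip_sd = obj$normalizer$clip_sd
    ), class = "qc_normalizer")
  }
  list(network = net, normalizer = normalizer,
       gains = if (!is.null(obj$gains)) unlist(obj$gains),
       mag_reference = obj$mag_reference, config = obj$config)
}
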