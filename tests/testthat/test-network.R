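# The 16-6-1 classifier: initialization, forward pass, training, decisions.

test_that("initialization is seeded, bounded and reproducible", {
  a <- init_network(5)
  b <- init_network(5)
  c <- init_network(6)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_identical(dim(a$W1), c(6L, 16L))
  expect_identical(dim(a$W2), c(1L, 6L))
  expect_true(all(abs(pack_params(a)) <= 0.5))
})

test_that("forward pass matches a hand-computed tanh composition", {
  net <- init_network(1, n_input = 2, n_hidden = 2)
  net$W1 <- matrix(c(0.5, -0.25, 1, 0.75), 2, 2)
  net$b1 <- c(0.1, -0.2)
  net$W2 <- matrix(c(2, -1), 1, 2)
  net$b2 <- 0.3
  x <- c(0.4, -1.2)
  h <- tanh(net$W1 %*% x + net$b1)
  expect_equal(nn_forward(net, x), drop(tanh(net$W2 %*% h + net$b2)),
               tolerance = 1e-12)

  zero <- net
  zero$W1[] <- 0; zero$b1[] <- 0; zero$W2[] <- 0; zero$b2 <- 0
  expect_identical(nn_forward(zero, x), 0)
  expect_error(nn_forward(net, c(1, 2, 3)), "dimension")

  set.seed(51)
  scores <- nn_forward(init_network(2), matrix(rnorm(50 * 16, 0, 3), 50, 16))
  expect_true(all(scores > -1 & scores < 1))
})

test_that("the analytic gradient matches finite differences", {
  set.seed(52)
  X <- matrix(rnorm(12 * 4), 12, 4)
  target <- sample(c(-1, 1), 12, replace = TRUE)
  gain <- runif(12, 0.5, 2)
  par <- runif(4 * 3 + 3 + 3 + 1, -0.5, 0.5)
  g <- nn_grad(par, X, target, gain, 0.01, n_input = 4, n_hidden = 3)
  num <- vapply(seq_along(par), function(i) {
    e <- rep(0, length(par)); e[i] <- 1e-6
    (nn_loss(par + e, X, target, gain, 0.01, 4, 3) -
       nn_loss(par - e, X, target, gain, 0.01, 4, 3)) / 2e-6
  }, numeric(1))
  expect_equal(g, num, tolerance = 1e-5)
})

test_that("training separates a two-cluster problem and is reproducible", {
  set.seed(53)
  X <- rbind(matrix(rnorm(150 * 16, 0.8, 1), 150, 16),
             matrix(rnorm(50 * 16, -0.8, 1), 50, 16))
  labels <- rep(c("good", "bad"), c(150, 50))
  cfg <- qc_training_config(seed = 3)
  fit <- train_qc_network(X, labels, cfg)
  expect_gte(fit$report$sensitivity, 0.95)
  expect_gte(fit$report$specificity, 0.95)
  fit2 <- train_qc_network(X, labels, cfg)
  expect_identical(fit$network, fit2$network)
  expect_error(train_qc_network(X, rep("good", 200), cfg), "degenerate training")
})

test_that("the independent nnet fit agrees on the separable problem", {
  skip_if_not_installed("nnet")
  set.seed(54)
  X <- rbind(matrix(rnorm(120 * 16, 0.9, 1), 120, 16),
             matrix(rnorm(80 * 16, -0.9, 1), 80, 16))
  labels <- rep(c("good", "bad"), c(120, 80))
  mine <- train_qc_network(X, labels, qc_training_config(seed = 1))
  ref <- nnet::nnet(X, as.numeric(labels == "good"), size = 6, decay = 1e-3,
                    maxit = 300, trace = FALSE)
  agree <- mean((predict(ref) > 0.5) == predict_accept(mine$network, X))
  expect_gte(agree, 0.95)
})

test_that("strong regularization shrinks weights and scores toward zero", {
  set.seed(55)
  X <- matrix(rnorm(60 * 16), 60, 16)
  labels <- rep(c("good", "bad"), 30)
  small <- train_qc_network(X, labels, qc_training_config(seed = 1, lambda = 1e-4))
  huge <- train_qc_network(X, labels, qc_training_config(seed = 1, lambda = 1e4))
  expect_lt(sum(huge$network$W1^2) + sum(huge$network$W2^2),
            0.01 * (sum(small$network$W1^2) + sum(small$network$W2^2)))
  expect_lt(max(abs(nn_forward(huge$network, X))), 0.1)
})

test_that("scaling all class gains and the penalty rescales the loss exactly", {
  set.seed(56)
  X <- matrix(rnorm(30 * 16), 30, 16)
  target <- rep(c(1, -1), 15)
  gain <- rep(c(1.2, 3.4), 15)
  par <- runif(16 * 6 + 6 + 6 + 1, -0.5, 0.5)
  l1 <- nn_loss(par, X, target, gain, 0.01, 16, 6)
  l2 <- nn_loss(par, X, target, 2 * gain, 0.02, 16, 6)
  expect_equal(l2, 2 * l1, tolerance = 1e-12)
  g1 <- nn_grad(par, X, target, gain, 0.01, 16, 6)
  expect_equal(nn_grad(par, X, target, 2 * gain, 0.02, 16, 6), 2 * g1,
               tolerance = 1e-12)
})

test_that("gradient descent decreases the weighted SSE monotonically", {
  set.seed(57)
  X <- matrix(rnorm(40 * 16), 40, 16)
  labels <- rep(c("good", "tolerable", "bad", "good"), 10)
  fit <- train_qc_network(X, labels,
                          qc_training_config(seed = 2, method = "gd",
                                             learning_rate = 1e-4,
                                             max_epochs = 200, restarts = 1))
  expect_true(all(diff(fit$report$loss_history) <= 1e-10))
})

test_that("class gains balance category contributions", {
  g <- class_gains(rep(c("good", "tolerable", "bad"), c(600, 300, 100)))
  expect_equal(unname(g["good"]), 1000 / (3 * 600))
  expect_equal(unname(g["bad"]), 1000 / (3 * 100))
  g2 <- class_gains(rep(c("good", "bad"), c(10, 10)))
  expect_equal(unname(g2), c(1, 1))
})

test_that("accept decisions follow the sign of the score, zero rejected", {
  set.seed(58)
  net <- init_network(4)
  X <- matrix(rnorm(100 * 16), 100, 16)
  expect_identical(predict_accept(net, X), nn_forward(net, X) > 0)
  zero <- net
  zero$W1[] <- 0; zero$b1[] <- 0; zero$W2[] <- 0; zero$b2 <- 0
  expect_false(predict_accept(zero, X[1, ]))
  strong <- zero
  strong$b2 <- 5
  expect_true(predict_accept(strong, X[1, ]))
})

test_that("models survive a JSON round trip", {
  set.seed(59)
  X <- matrix(rnorm(40 * 16), 40, 16)
  labels <- rep(c("good", "bad"), 20)
  fit <- train_qc_network(X, labels, qc_training_config(seed = 1))
  nm <- fit_normalizer(matrix(rnorm(32 * 2), ncol = 16) + 5)
  path <- tempfile(fileext = ".json")
  save_qc_model(list(network = fit$network, normalizer = nm,
                     gains = fit$report$gains, mag_reference = 1), path)
  back <- load_qc_model(path)
  expect_equal(back$network$W1, fit$network$W1, tolerance = 1e-12)
  expect_equal(unname(back$normalizer$mean), unname(nm$mean), tolerance = 1e-12)
  expect_equal(nn_forward(back$network, X), nn_forward(fit$network, X),
               tolerance = 1e-12)
})
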