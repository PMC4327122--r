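test_that("logsig matches its definition and stays stable at extremes", {
  expect_identical(logsig(0), 0.5)
  expect_equal(logsig(c(-2, 1.5)), 1 / (1 + exp(-c(-2, 1.5))))
  expect_identical(logsig(1000), 1)
  expect_identical(logsig(-1000), 0)
  # derivative identity s'(t) = s(t)(1 - s(t)) vs central differences
  h <- 1e-6
  for (t in c(-3, -0.7, 0, 1.2, 4)) {
    num <- (logsig(t + h) - logsig(t - h)) / (2 * h)
    expect_equal(num, logsig(t) * (1 - logsig(t)), tolerance = 1e-6)
  }
})

test_that("forward computes the two-layer pass", {
  m <- mini_net()
  # pencil-and-paper 2-2-2 pass for x = (1, -1)
  h <- 1 / (1 + exp(-c(0.1 - 0.2 + 0.05, 0.3 + 0.4 - 0.05)))
  expect_equal(forward(m, c(1, -1)),
               c(h[1] - h[2], 0.5 * h[1] + 0.25 * h[2] + 0.1))
  # all-zero weights give the zero output
  z <- m
  z$W1[] <- 0; z$b1[] <- 0; z$W2[] <- 0; z$b2[] <- 0
  expect_equal(forward(z, c(0.4, 2)), c(0, 0))
  expect_error(forward(m, c(1, 2, 3)), "length 2")
  # finite outputs on a batch of scaled inputs
  big <- new_bpnn(800L, 5L, 6L, seed = 3)
  x <- matrix(runif(800 * 4, -1, 1), 800)
  expect_true(all(is.finite(forward(big, x))))
})

test_that("back-propagated gradients match central finite differences", {
  set.seed(7)
  for (rep in 1:4) {
    n <- sample(3:8, 1); l <- sample(2:4, 1); m <- sample(2:4, 1)
    N <- sample(3:6, 1)
    model <- new_bpnn(n, l, m, seed = rep)
    X <- matrix(rnorm(n * N), n)
    Y <- matrix(rnorm(m * N), m)
    g <- bpnn_gradients(model, X, Y)
    loss <- function(mod) mean((forward(mod, X) - Y)^2)
    h <- 1e-6
    for (nm in c("W1", "b1", "W2", "b2")) {
      pick <- sample(length(model[[nm]]), min(4, length(model[[nm]])))
      for (i in pick) {
        up <- model; up[[nm]][i] <- up[[nm]][i] + h
        dn <- model; dn[[nm]][i] <- dn[[nm]][i] - h
        num <- (loss(up) - loss(dn)) / (2 * h)
        expect_equal(g[[nm]][i], num, tolerance = 1e-5)
      }
    }
  }
})

test_that("training solves a linearly separable two-class toy", {
  set.seed(5)
  X <- cbind(matrix(rnorm(4 * 20, -2, 0.3), 4), matrix(rnorm(4 * 20, 2, 0.3), 4))
  Y <- rbind(rep(c(1, 0), each = 20), rep(c(0, 1), each = 20))
  cfg <- training_config(pg = 1e-3, lr = 0.5, max_epochs = 4000,
                         patience = 50, seed = 2)
  model <- train_bpnn(X, Y, cfg, sizes = c(4L, 3L, 2L))
  expect_true(model$pg_reached)
  idx <- model$split$train
  pred <- apply(forward(model, X[, idx]), 2, which.max)
  truth <- apply(Y[, idx], 2, which.max)
  expect_equal(mean(pred == truth), 1)
})

test_that("training MSE is non-increasing at a small learning rate", {
  set.seed(6)
  X <- matrix(rnorm(3 * 30), 3)
  Y <- matrix(rnorm(2 * 30, sd = 0.3), 2)
  cfg <- training_config(pg = 1e-9, lr = 0.01, max_epochs = 300,
                         patience = 300, seed = 1)
  model <- train_bpnn(X, Y, cfg, sizes = c(3L, 3L, 2L))
  expect_true(all(diff(model$history$train) <= 1e-12))
})

test_that("identical seed, config and data give identical weights", {
  set.seed(8)
  X <- matrix(rnorm(5 * 24), 5)
  Y <- matrix(rnorm(3 * 24), 3)
  cfg <- training_config(pg = 1e-6, max_epochs = 50, seed = 9)
  m1 <- train_bpnn(X, Y, cfg, sizes = c(5L, 3L, 3L))
  m2 <- train_bpnn(X, Y, cfg, sizes = c(5L, 3L, 3L))
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  expect_identical(m1$history, m2$history)
})

test_that("early stopping restores the best-validation weights", {
  # noise targets overfit quickly, forcing a validation rise
  set.seed(10)
  X <- matrix(rnorm(6 * 40), 6)
  Y <- matrix(rnorm(2 * 40), 2)
  cfg <- training_config(pg = 1e-12, lr = 0.8, max_epochs = 2000,
                         patience = 6, seed = 3)
  model <- train_bpnn(X, Y, cfg, sizes = c(6L, 4L, 2L))
  va <- model$split$validation
  mse_va <- mean((forward(model, X[, va]) - Y[, va])^2)
  expect_equal(mse_va, model$best_validation, tolerance = 1e-12)
  expect_equal(mse_va, min(model$history$validation), tolerance = 1e-12)
})

test_that("the split is a seed-reproducible stratified partition", {
  labels <- rep(1:6, each = 20)
  s1 <- split_columns(labels, split = c(0.7, 0.15, 0.15), seed = 4)
  s2 <- split_columns(labels, split = c(0.7, 0.15, 0.15), seed = 4)
  expect_identical(s1, s2)
  all_idx <- sort(c(s1$train, s1$validation, s1$test))
  expect_identical(all_idx, seq_along(labels))
  expect_identical(length(intersect(s1$train, s1$validation)), 0L)
  expect_identical(length(intersect(s1$train, s1$test)), 0L)
  # stratification: every class contributes 14/3/3 of its 20 columns
  for (k in 1:6) {
    expect_identical(sum(labels[s1$train] == k), 14L)
    expect_identical(sum(labels[s1$test] == k), 3L)
  }
})

test_that("evaluate_mse matches its definition", {
  m <- mini_net()
  z <- m; z$W1[] <- 0; z$b1[] <- 0; z$W2[] <- 0; z$b2[] <- 0
  Y <- diag(2)[, c(1, 2, 1)]
  X <- matrix(rnorm(6), 2)
  # zero-output model vs one-hot targets: each column contributes 1/m
  expect_equal(evaluate_mse(z, X, Y), 1 / 2)
  z6 <- new_bpnn(8L, 5L, 6L, seed = 1)
  z6$W1[] <- 0; z6$b1[] <- 0; z6$W2[] <- 0; z6$b2[] <- 0
  expect_equal(evaluate_mse(z6, matrix(rnorm(16), 8), diag(6)[, c(2, 5)]),
               1 / 6)
  # model reproducing its targets exactly scores 0
  o <- forward(m, X)
  expect_equal(evaluate_mse(m, X, o), 0)
  # invariant under a joint column permutation
  p <- c(3, 1, 2)
  expect_equal(evaluate_mse(m, X[, p], Y[, p]), evaluate_mse(m, X, Y))
})

test_that("models survive a JSON round trip", {
  set.seed(11)
  X <- matrix(rnorm(5 * 24), 5)
  Y <- matrix(rnorm(2 * 24), 2)
  cfg <- training_config(pg = 1e-6, max_epochs = 20, seed = 1)
  model <- train_bpnn(X, Y, cfg, sizes = c(5L, 3L, 2L))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$W1, model$W1)
  expect_equal(back$scaling$centre, model$scaling$centre)
  expect_equal(forward(back, X), forward(model, X))
  expect_equal(back$history$validation, model$history$validation)
})
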