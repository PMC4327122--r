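## From-scratch back-propagation neural network.
##
## Architecture is a feed-forward net with one hidden layer: n = 800 input
## features (one 25-s window entry), l = 5 log-sigmoid hidden neurons and
## m = 6 linear output neurons, one per exercise.  Training is plain batch
## gradient descent on the mean squared error, with three stopping rules:
## the performance goal (target training MSE), validation-based early
## stopping, and a maximum epoch count.

#' Log-sigmoid transfer function
#'
#' `s(t) = 1 / (1 + exp(-t))`, the hidden-layer transfer function,
#' evaluated in a numerically stable form for large `|t|`.
#'
#' @param t numeric vector or matrix.
#' @return values in (0, 1).
#' @export
logsig <- function(t) {
  out <- t
  pos <- !is.na(t) & t >= 0
  out[pos] <- 1 / (1 + exp(-t[pos]))
  e <- exp(t[!pos])
  out[!pos] <- e / (1 + e)
  out
}

#' Training configuration
#'
#' @param pg performance goal: target training MSE at which training stops.
#' @param split train/validation/test fractions; positive, summing to 1.
#' @param lr learning rate of batch gradient descent.
#' @param momentum momentum coefficient (0 disables).
#' @param max_epochs epoch budget.
#' @param patience consecutive epochs without a new best validation MSE
#'   tolerated before early stopping (1 mirrors stopping at the first rise).
#' @param seed RNG seed controlling the split and the weight init.
#' @return a list of class `training_config`.
#' @export
training_config <- function(pg = 1e-5, split = c(0.70, 0.15, 0.15),
                            lr = 0.05, momentum = 0, max_epochs = 5000L,
                            patience = 6L, seed = 1L) {
  if (any(split <= 0) || abs(sum(split) - 1) > 1e-8)
    stop_contract("split fractions must be positive and sum to 1")
  if (pg <= 0) stop_contract("performance goal must be positive")
  structure(list(pg = pg, split = split, lr = lr, momentum = momentum,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "training_config")
}

#' Initialize an untrained network
#'
#' Weights and biases are drawn uniformly from `[-0.5, 0.5] / sqrt(fan_in)`;
#' the fan-in scaling keeps the 800-input hidden neurons out of sigmoid
#' saturation at the first epoch.
#'
#' @param n,l,m input / hidden / output layer sizes.
#' @param seed RNG seed.
#' @return a `bpnn_model` (untrained: no scaling, empty history).
#' @export
new_bpnn <- function(n = 800L, l = 5L, m = 6L, seed = 1L) {
  with_seed(derive_seed(seed, 11L), {
    structure(list(
      n = as.integer(n), l = as.integer(l), m = as.integer(m),
      W1 = matrix(stats::runif(l * n, -0.5, 0.5) / sqrt(n), l, n),
      b1 = stats::runif(l, -0.5, 0.5),
      W2 = matrix(stats::runif(m * l, -0.5, 0.5) / sqrt(l), m, l),
      b2 = stats::runif(m, -0.5, 0.5),
      scaling = NULL, history = NULL, trained = FALSE),
      class = "bpnn_model")
  })
}

#' @export
print.bpnn_model <- function(x, ...) {
  cat("<bpnn_model> ", x$n, "-", x$l, "-", x$m,
      if (isTRUE(x$trained)) " (trained)" else " (untrained)", "\n", sep = "")
  if (!is.null(x$history))
    cat("  epochs: ", nrow(x$history), ", stop: ", x$reason,
        ", test MSE: ", format(x$test_mse), "\n", sep = "")
  invisible(x)
}

## Apply the stored per-feature min-max scaling (fitted on training data).
scale_input <- function(model, x) {
  if (is.null(model$scaling)) return(x)
  (x - model$scaling$centre) / model$scaling$half
}

fit_scaling <- function(x) {
  lo <- apply(x, 1L, min)
  hi <- apply(x, 1L, max)
  half <- (hi - lo) / 2
  half[half == 0] <- 1   # constant features map to 0
  list(centre = (hi + lo) / 2, half = half)
}

#' Forward pass
#'
#' `output = W2 %*% s(W1 %*% x_scaled + b1) + b2` with the log-sigmoid
#' hidden transfer and linear output transfer.
#'
#' @param model a `bpnn_model`.
#' @param x numeric vector of length `n`, or an `n x k` matrix of columns.
#' @return an `m x k` output matrix (or length-`m` vector for vector input).
#' @export
forward <- function(model, x) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  if (nrow(x) != model$n)
    stop_contract("forward expects inputs of length ", model$n)
  xs <- scale_input(model, x)
  h <- logsig(model$W1 %*% xs + model$b1)
  o <- model$W2 %*% h + model$b2
  if (vec) drop(o) else o
}

#' Stratified train/validation/test split
#'
#' Columns are partitioned per exercise so every class contributes to each
#' set in the configured proportions; the three index sets are disjoint and
#' exhaustive, and reproducible from the seed.
#'
#' @param labels per-column exercise labels (or `NULL` for unstratified).
#' @param n number of columns (used when `labels` is `NULL`).
#' @param split fractions as in [training_config()].
#' @param seed RNG seed.
#' @return list of integer index vectors `train`, `validation`, `test`.
#' @export
split_columns <- function(labels, n = length(labels),
                          split = c(0.70, 0.15, 0.15), seed = 1L) {
  groups <- if (is.null(labels)) list(seq_len(n)) else
    split(seq_len(n), labels)
  with_seed(derive_seed(seed, 13L), {
    tr <- va <- te <- integer(0)
    for (g in groups) {
      g <- sample(g)
      ntr <- round(split[1L] * length(g))
      nva <- round(split[2L] * length(g))
      nva <- min(nva, length(g) - ntr)
      tr <- c(tr, g[seq_len(ntr)])
      va <- c(va, g[ntr + seq_len(nva)])
      te <- c(te, g[setdiff(seq_along(g), seq_len(ntr + nva))])
    }
    list(train = sort(tr), validation = sort(va), test = sort(te))
  })
}

#' Train the network
#'
#' Batch gradient-descent back-propagation minimizing the MSE between the
#' linear outputs and the one-hot targets.  Training stops when (a) the
#' training MSE reaches the performance goal, (b) the validation MSE has
#' not improved for `patience` consecutive epochs (weights are restored to
#' the best-validation epoch), or (c) the epoch budget is exhausted (best
#' validation weights are restored as well).  When the goal is not reached
#' the model is returned flagged, not raised.
#'
#' @param M training inputs: a `motion_matrix` from [build_matrices()] or a
#'   plain `n x N` matrix.
#' @param T targets: a `target_matrix` or plain `m x N` matrix.
#' @param config a [training_config()].
#' @param sizes optional `c(n, l, m)` override (defaults to the data and
#'   the 800-5-6 architecture for 800-row input).
#' @return a trained `bpnn_model` carrying the scaling constants, the full
#'   per-epoch train/validation MSE history, the split, the stop reason
#'   (`"pg"`, `"early_stop"` or `"max_epochs"`), `pg_reached`, and the test
#'   MSE computed once after stopping.
#' @export
train_bpnn <- function(M, T, config = training_config(), sizes = NULL) {
  fm <- flatten_cells(M)
  ft <- flatten_cells(T)
  X <- fm$mat; Y <- ft$mat
  if (ncol(X) != ncol(Y)) stop_contract("M and T must have equal columns")
  n <- nrow(X); m <- nrow(Y)
  l <- if (is.null(sizes)) 5L else sizes[2L]
  if (!is.null(sizes)) { n <- sizes[1L]; m <- sizes[3L] }
  if (nrow(X) != n || nrow(Y) != m) stop_contract("sizes inconsistent with data")

  idx <- split_columns(fm$label, n = ncol(X), split = config$split,
                       seed = config$seed)
  model <- new_bpnn(n, l, m, seed = config$seed)
  model$scaling <- fit_scaling(X[, idx$train, drop = FALSE])

  Xtr <- scale_input(model, X[, idx$train, drop = FALSE])
  Ytr <- Y[, idx$train, drop = FALSE]
  Xva <- scale_input(model, X[, idx$validation, drop = FALSE])
  Yva <- Y[, idx$validation, drop = FALSE]
  ntr <- ncol(Xtr)

  W1 <- model$W1; b1 <- model$b1; W2 <- model$W2; b2 <- model$b2
  vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- b2 * 0
  hist_tr <- hist_va <- numeric(config$max_epochs)
  best <- list(mse = Inf, epoch = 0L)
  since_best <- 0L
  reason <- "max_epochs"
  epoch <- 0L

  mse_of <- function(W1, b1, W2, b2, X, Y) {
    if (ncol(X) == 0L) return(NA_real_)
    O <- W2 %*% logsig(W1 %*% X + b1) + b2
    mean((O - Y)^2)
  }

  while (epoch < config$max_epochs) {
    epoch <- epoch + 1L
    H <- logsig(W1 %*% Xtr + b1)
    O <- W2 %*% H + b2
    E <- O - Ytr
    mse_tr <- mean(E^2)
    mse_va <- mse_of(W1, b1, W2, b2, Xva, Yva)
    hist_tr[epoch] <- mse_tr
    hist_va[epoch] <- mse_va

    if (!is.na(mse_va) && mse_va < best$mse) {
      best <- list(mse = mse_va, epoch = epoch,
                   W1 = W1, b1 = b1, W2 = W2, b2 = b2)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }
    if (mse_tr <= config$pg) { reason <- "pg"; break }
    if (!is.na(mse_va) && since_best >= config$patience) {
      reason <- "early_stop"; break
    }

    g <- bp_grad(W1, b1, W2, b2, Xtr, Ytr, H = H, E = E)
    vW2 <- config$momentum * vW2 - config$lr * g$W2
    vb2 <- config$momentum * vb2 - config$lr * g$b2
    vW1 <- config$momentum * vW1 - config$lr * g$W1
    vb1 <- config$momentum * vb1 - config$lr * g$b1
    W2 <- W2 + vW2; b2 <- b2 + vb2; W1 <- W1 + vW1; b1 <- b1 + vb1
  }

  if (reason != "pg" && best$epoch > 0L) {
    W1 <- best$W1; b1 <- best$b1; W2 <- best$W2; b2 <- best$b2
  }
  model$W1 <- W1; model$b1 <- b1; model$W2 <- W2; model$b2 <- b2
  model$trained <- TRUE
  model$history <- data.frame(epoch = seq_len(epoch),
                              train = hist_tr[seq_len(epoch)],
                              validation = hist_va[seq_len(epoch)])
  model$reason <- reason
  model$pg_reached <- reason == "pg"
  model$best_validation <- best$mse
  model$split <- idx
  model$config <- config
  Xte <- X[, idx$test, drop = FALSE]
  model$test_mse <- if (ncol(Xte)) {
    mean((forward(model, Xte) - Y[, idx$test, drop = FALSE])^2)
  } else NA_real_
  model
}

## Analytic gradients of mean((output - Y)^2) over all m x N entries.
bp_grad <- function(W1, b1, W2, b2, X, Y, H = NULL, E = NULL) {
  if (is.null(H)) H <- logsig(W1 %*% X + b1)
  if (is.null(E)) E <- W2 %*% H + b2 - Y
  dO <- 2 * E / (nrow(Y) * ncol(Y))
  dH <- (t(W2) %*% dO) * H * (1 - H)
  list(W2 = dO %*% t(H), b2 = rowSums(dO),
       W1 = dH %*% t(X), b1 = rowSums(dH))
}

#' Back-propagated gradients of the MSE loss
#'
#' Analytic gradients of `mean((forward(model, x) - y)^2)` with respect to
#' all weights and biases, at the model's current parameters.  Exposed so
#' the back-propagation arithmetic can be checked against finite
#' differences.
#'
#' @param model a `bpnn_model`.
#' @param x `n x N` input matrix (scaled through the model's stored
#'   scaling, like [forward()]).
#' @param y `m x N` target matrix.
#' @return list of gradients `W1`, `b1`, `W2`, `b2`.
#' @export
bpnn_gradients <- function(model, x, y) {
  xs <- scale_input(model, as.matrix(x))
  bp_grad(model$W1, model$b1, model$W2, model$b2, xs, as.matrix(y))
}

#' Mean squared error of a model on labelled data
#'
#' Mean over all output neurons and all columns of the squared difference
#' between network output and target.
#'
#' @param model a `bpnn_model`.
#' @param M inputs (`motion_matrix` or matrix).
#' @param T targets (`target_matrix` or matrix).
#' @return scalar MSE.
#' @export
evaluate_mse <- function(model, M, T) {
  X <- flatten_cells(M)$mat
  Y <- flatten_cells(T)$mat
  if (ncol(X) != ncol(Y)) stop_contract("M and T must have equal columns")
  mean((forward(model, X) - Y)^2)
}

#' Serialize / restore a model as JSON
#'
#' Stores sizes, weights, scaling constants, history, config, split and
#' stop diagnostics in one JSON file.
#'
#' @param model a `bpnn_model`.
#' @param path file path.
#' @return `path` (write) or the restored `bpnn_model` (read).
#' @export
write_model <- function(model, path) {
  obj <- unclass(model)
  obj$config <- unclass(obj$config)
  obj$W1 <- as.vector(obj$W1)   # column-major; reshaped on read
  obj$W2 <- as.vector(obj$W2)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  num_mat <- function(x, nr) matrix(as.numeric(x), nrow = nr)
  obj$W1 <- num_mat(obj$W1, obj$l)
  obj$W2 <- num_mat(obj$W2, obj$m)
  if (!is.null(obj$scaling)) obj$scaling <- lapply(obj$scaling, as.numeric)
  if (!is.null(obj$config)) class(obj$config) <- "training_config"
  if (!is.null(obj$history)) obj$history <- as.data.frame(obj$history)
  class(obj) <- "bpnn_model"
  obj
}
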