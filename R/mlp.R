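# Small feed-forward multilayer perceptron trained by online backpropagation
# (squared error, sigmoid units, momentum). Architecture fixed by config:
# two hidden layers of three neurons by default. Deterministic given the
# seed: weights start uniform in [-0.5, 0.5] and samples are visited in a
# fixed order.

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_fit <- function(X, y01, hidden = c(3L, 3L), learning_rate = 0.3,
                    momentum = 0.2, max_epochs = 500L, seed = 1L,
                    patience = 50L, tol = 1e-5) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y01) == n, all(y01 %in% c(0, 1)))
  sizes <- c(p, hidden, 1L)
  L <- length(sizes) - 1L
  W <- withr::with_seed(seed, lapply(seq_len(L), function(l) {
    matrix(stats::runif((sizes[l] + 1L) * sizes[l + 1L], -0.5, 0.5),
           sizes[l] + 1L, sizes[l + 1L])
  }))
  V <- lapply(W, function(w) w * 0) # momentum terms
  best_mse <- Inf; stale <- 0L
  for (epoch in seq_len(max_epochs)) {
    sse <- 0
    for (i in seq_len(n)) {
      a <- vector("list", L + 1L)
      a[[1L]] <- X[i, ]
      for (l in seq_len(L)) {
        a[[l + 1L]] <- sigmoid(drop(crossprod(W[[l]], c(a[[l]], 1))))
      }
      err <- a[[L + 1L]] - y01[i]
      sse <- sse + err^2
      delta <- err * a[[L + 1L]] * (1 - a[[L + 1L]])
      for (l in rev(seq_len(L))) {
        grad <- tcrossprod(c(a[[l]], 1), delta)
        if (l > 1L) {
          delta <- (W[[l]][seq_len(sizes[l]), , drop = FALSE] %*% delta) *
            a[[l]] * (1 - a[[l]])
          delta <- drop(delta)
        }
        V[[l]] <- momentum * V[[l]] - learning_rate * grad
        W[[l]] <- W[[l]] + V[[l]]
      }
    }
    mse <- sse / n
    # stop once essentially exact, or after `patience` epochs without
    # improvement (backprop plateaus are common early on, hence the window)
    if (mse < 1e-3) break
    if (mse < best_mse - tol) {
      best_mse <- mse
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  structure(list(W = W, sizes = sizes, epochs_run = epoch, mse = mse),
            class = "hippovol_mlp")
}

mlp_forward <- function(model, X) {
  A <- as.matrix(X)
  for (w in model$W) A <- sigmoid(cbind(A, 1) %*% w)
  drop(A)
}

# returns labels in {+1, -1}
mlp_predict <- function(model, X) {
  ifelse(mlp_forward(model, X) >= 0.5, 1L, -1L)
}
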