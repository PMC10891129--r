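# Independent step-by-step transcriptions of the three update rules, kept
# deliberately naive (scalar loops, no shared code with the package
# internals) so they can serve as an oracle for the fitting routines.

oracle_sgd <- function(x, y, theta, eta, epochs, order) {
  for (e in seq_len(epochs)) {
    for (k in seq_along(x)) {
      i <- order[k, e]
      r <- theta[1] + theta[2] * x[i] - y[i]
      t0 <- theta[1] - eta * 2 * r
      t1 <- theta[2] - eta * 2 * x[i] * r
      theta <- c(t0, t1)
    }
  }
  theta
}

oracle_batches <- function(m, batch_size) {
  starts <- seq(1, m, by = batch_size)
  lapply(starts, function(s) s:min(s + batch_size - 1, m))
}

oracle_batch_grad <- function(x, y, theta, idx) {
  r <- theta[1] + theta[2] * x[idx] - y[idx]
  c(2 * mean(r), 2 * mean(r * x[idx]))
}

oracle_rmsprop <- function(x, y, theta, eta, epochs, beta, eps,
                           batch_size, order) {
  v <- c(0, 0)
  for (e in seq_len(epochs)) {
    for (b in oracle_batches(length(x), batch_size)) {
      g <- oracle_batch_grad(x, y, theta, order[b, e])
      v <- beta * v + (1 - beta) * g^2
      theta <- theta - eta / sqrt(v + eps) * g
    }
  }
  theta
}

oracle_adam <- function(x, y, theta, eta, epochs, beta1, beta2, eps,
                        batch_size, order, time_scaled) {
  mm <- c(0, 0)
  v <- c(0, 0)
  t <- 0
  for (e in seq_len(epochs)) {
    for (b in oracle_batches(length(x), batch_size)) {
      g <- oracle_batch_grad(x, y, theta, order[b, e])
      t <- t + 1
      mm <- beta1 * mm + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      if (time_scaled) {
        mh <- mm / (1 - beta1^t)
        vh <- v / (1 - beta2^t)
      } else {
        mh <- mm / (1 - beta1)
        vh <- v / (1 - beta2)
      }
      theta <- theta - eta / (sqrt(vh) + eps) * mh
    }
  }
  theta
}

# A fixed 8-point dataset used by the oracle-equivalence tests.
oracle_dataset <- function() {
  x <- c(0.12, 0.25, 0.33, 0.47, 0.58, 0.66, 0.81, 0.94)
  y <- 0.5 + 0.79 * x + c(0.05, -0.02, 0.01, -0.04, 0.03, 0.00, -0.05, 0.02)
  structure(list(fn_id = "F1", x = x, y = y, m = 8L, noise_sd = 0,
                 seed = 0L),
            class = "regression_dataset")
}
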