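# From-scratch SGD, RMSprop and Adam fits of the two-parameter linear model
# H(x) = theta0 + theta1 * x. The tight per-example / per-batch loops live in
# src/optim_core.cpp; everything stochastic (parameter initialisation and
# per-epoch shuffles) is drawn here so that a run is reproducible from its
# two seeds alone and can be replayed step-by-step in plain R.

#' @useDynLib optconform, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

OPTIMIZER_METHODS <- c("sgd", "rmsprop", "adam")

#' Configuration for a linear-model optimizer run
#'
#' Defaults follow the simulation protocol: learning rate 0.001, at most
#' 3000 epochs (full passes over the data), stopping when the full-data
#' gradient norm drops to 0.001, mini-batches of 16 for RMSprop/Adam with
#' RMSprop decay 0.9 and epsilon 1e-6, Adam moments 0.9/0.999 with epsilon
#' 1e-8.
#'
#' @param method One of `"sgd"`, `"rmsprop"`, `"adam"`.
#' @param eta Learning rate, positive.
#' @param max_iters Maximum number of epochs (full passes).
#' @param grad_tol Stopping tolerance on the Euclidean norm of the full-data
#'   gradient, checked after each epoch. May be `Inf`.
#' @param batch_size Mini-batch size for RMSprop and Adam.
#' @param beta RMSprop decay rate of the squared-gradient accumulator.
#' @param beta1,beta2 Adam first/second-moment decay rates.
#' @param eps Numerical guard; defaults to 1e-6 for RMSprop (inside the
#'   square root) and 1e-8 for Adam (outside the square root).
#' @param bias_correction Adam bias-correction mode: `"time_scaled"`
#'   (default) divides the moment estimates by `1 - beta^t` as in the Adam
#'   reference algorithm; `"paper_literal"` divides by the constants
#'   `1 - beta1` and `1 - beta2`. The two coincide at the first step; see
#'   the methods vignette for why time-scaled is the default.
#' @param init_seed Seed for the `U(0, 1)` initialisation of both
#'   parameters.
#' @param shuffle_seed Seed for the per-epoch data shuffles (a separate
#'   stream, so initialisation and shuffling are independently
#'   reproducible).
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(method = c("sgd", "rmsprop", "adam"),
                             eta = 0.001, max_iters = 3000L,
                             grad_tol = 0.001, batch_size = 16L,
                             beta = 0.9, beta1 = 0.9, beta2 = 0.999,
                             eps = NULL,
                             bias_correction = c("time_scaled",
                                                 "paper_literal"),
                             init_seed = 1L, shuffle_seed = 2L) {
  method <- match.arg(method)
  bias_correction <- match.arg(bias_correction)
  if (is.null(eps)) eps <- if (method == "adam") 1e-8 else 1e-6
  stopifnot(eta > 0, max_iters >= 1, grad_tol > 0, batch_size >= 1,
            beta > 0, beta < 1, beta1 > 0, beta1 < 1,
            beta2 > 0, beta2 < 1, eps > 0)
  structure(
    list(method = method, eta = eta, max_iters = as.integer(max_iters),
         grad_tol = grad_tol, batch_size = as.integer(batch_size),
         beta = beta, beta1 = beta1, beta2 = beta2, eps = eps,
         bias_correction = bias_correction,
         init_seed = as.integer(init_seed),
         shuffle_seed = as.integer(shuffle_seed)),
    class = "optimizer_config"
  )
}

#' Mean-squared-error objective and its gradient
#'
#' `Q = (1/m) sum (theta0 + theta1 x_i - y_i)^2`, with gradient
#' `((2/m) sum r_i, (2/m) sum x_i r_i)` where `r_i` is the residual.
#'
#' @param params A list or numeric vector with elements `theta0`, `theta1`.
#' @param dataset A `regression_dataset` (or any list with `x` and `y`).
#' @return List with `Q` (scalar) and `grad` (length-2 numeric).
#' @export
objective_and_gradient <- function(params, dataset) {
  p <- as_linear_params(params)
  x <- dataset$x
  y <- dataset$y
  if (length(x) == 0L || length(x) != length(y)) {
    stop("dataset must contain matching nonempty x and y", call. = FALSE)
  }
  r <- p$theta0 + p$theta1 * x - y
  list(Q = mean(r^2),
       grad = c(2 * mean(r), 2 * mean(r * x)))
}

as_linear_params <- function(params) {
  if (inherits(params, "linear_model_params")) return(params)
  if (is.numeric(params) && length(params) == 2L) {
    params <- list(theta0 = params[[1]], theta1 = params[[2]])
  }
  stopifnot(is.list(params), !is.null(params$theta0), !is.null(params$theta1))
  structure(list(theta0 = as.numeric(params$theta0),
                 theta1 = as.numeric(params$theta1)),
            class = "linear_model_params")
}

#' Initial parameters and shuffle schedule for an optimizer run
#'
#' Draws `theta ~ U(0, 1)` under `init_seed` and a full schedule of
#' per-epoch permutations of the data under `shuffle_seed` (column `e` is
#' the shuffle used in epoch `e`). Exposed so an independent transcription
#' of the update rules can replay a fit exactly.
#'
#' @param config An `optimizer_config`.
#' @param m Number of training examples.
#' @return List with `theta` (length 2) and `order` (`m x max_iters`
#'   integer matrix of 1-based indices).
#' @export
optim_init <- function(config, m) {
  stopifnot(inherits(config, "optimizer_config"), m >= 1)
  theta <- with_seed(config$init_seed, stats::runif(2))
  order <- with_seed(config$shuffle_seed, {
    ord <- matrix(0L, nrow = m, ncol = config$max_iters)
    for (e in seq_len(config$max_iters)) ord[, e] <- sample.int(m)
    ord
  })
  list(theta = theta, order = order)
}

new_fit_result <- function(core, dataset, config) {
  if (!is.na(core$diverged_epoch)) {
    stop(sprintf("%s diverged (non-finite parameters) at epoch %d",
                 config$method, core$diverged_epoch), call. = FALSE)
  }
  params <- as_linear_params(c(core$theta0, core$theta1))
  structure(
    list(params = params,
         predictions = params$theta0 + params$theta1 * dataset$x,
         epochs_run = core$epochs_run,
         final_grad_norm = core$final_grad_norm,
         converged = core$converged,
         objective_trace = core$objective_trace,
         method = config$method,
         config = config),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> %s: theta = (%.4f, %.4f), epochs = %d, |grad| = %.3g, %s\n",
    x$method, x$params$theta0, x$params$theta1, x$epochs_run,
    x$final_grad_norm, if (x$converged) "converged" else "not converged"))
  invisible(x)
}

check_fit_args <- function(dataset, config, method) {
  stopifnot(inherits(dataset, "regression_dataset") ||
              (is.list(dataset) && !is.null(dataset$x) && !is.null(dataset$y)))
  stopifnot(inherits(config, "optimizer_config"))
  if (config$method != method) {
    stop(sprintf("config$method is '%s' but '%s' was requested",
                 config$method, method), call. = FALSE)
  }
  if (length(dataset$x) < 1L) stop("empty dataset", call. = FALSE)
}

#' Fit the linear model with per-example stochastic gradient descent
#'
#' Each epoch shuffles the data then sweeps it once, applying the
#' simultaneous per-example update
#' `theta0 <- theta0 - eta * 2 r_i`, `theta1 <- theta1 - eta * 2 x_i r_i`
#' with `r_i` the residual at the start-of-step parameters. After each
#' epoch the full-data gradient norm is checked against `grad_tol`.
#'
#' @param dataset A `regression_dataset`.
#' @param config An `optimizer_config` with `method = "sgd"`.
#' @return A `fit_result` with final parameters, predictions on the
#'   training `x`, the per-epoch objective trace and convergence flags.
#' @export
fit_sgd <- function(dataset, config = optimizer_config("sgd")) {
  check_fit_args(dataset, config, "sgd")
  ini <- optim_init(config, length(dataset$x))
  core <- .sgd_core(dataset$x, dataset$y, ini$theta[1], ini$theta[2],
                    config$eta, config$max_iters, config$grad_tol, ini$order)
  new_fit_result(core, dataset, config)
}

#' Fit the linear model with RMSprop
#'
#' Mini-batch updates `v <- beta v + (1 - beta) g^2`,
#' `theta <- theta - eta g / sqrt(v + eps)` per coordinate, where `g` is
#' the `2/|S|`-scaled batch gradient. Stopping as in [fit_sgd()].
#'
#' @inheritParams fit_sgd
#' @param config An `optimizer_config` with `method = "rmsprop"`.
#' @return A `fit_result`.
#' @export
fit_rmsprop <- function(dataset, config = optimizer_config("rmsprop")) {
  check_fit_args(dataset, config, "rmsprop")
  ini <- optim_init(config, length(dataset$x))
  core <- .rmsprop_core(dataset$x, dataset$y, ini$theta[1], ini$theta[2],
                        config$eta, config$max_iters, config$grad_tol,
                        config$beta, config$eps, config$batch_size,
                        ini$order)
  new_fit_result(core, dataset, config)
}

#' Fit the linear model with Adam
#'
#' Mini-batch first/second-moment updates with bias correction (see
#' [optimizer_config()] for the two correction modes) and update
#' `theta <- theta - eta * m_hat / (sqrt(v_hat) + eps)`. Stopping as in
#' [fit_sgd()].
#'
#' @inheritParams fit_sgd
#' @param config An `optimizer_config` with `method = "adam"`.
#' @return A `fit_result`.
#' @export
fit_adam <- function(dataset, config = optimizer_config("adam")) {
  check_fit_args(dataset, config, "adam")
  ini <- optim_init(config, length(dataset$x))
  core <- .adam_core(dataset$x, dataset$y, ini$theta[1], ini$theta[2],
                     config$eta, config$max_iters, config$grad_tol,
                     config$beta1, config$beta2, config$eps,
                     config$batch_size,
                     config$bias_correction == "time_scaled", ini$order)
  new_fit_result(core, dataset, config)
}

#' Dispatch a fit by method name
#' @param dataset A `regression_dataset`.
#' @param config An `optimizer_config`.
#' @return A `fit_result`.
#' @export
fit_linear_model <- function(dataset, config) {
  switch(config$method,
         sgd = fit_sgd(dataset, config),
         rmsprop = fit_rmsprop(dataset, config),
         adam = fit_adam(dataset, config))
}

#' Predict from fitted linear-model parameters
#'
#' @param object A `linear_model_params` (or a `fit_result`).
#' @param x Numeric vector of abscissae.
#' @param ... Unused.
#' @return `theta0 + theta1 * x`, elementwise.
#' @export
predict.linear_model_params <- function(object, x, ...) {
  stopifnot(is.numeric(x))
  object$theta0 + object$theta1 * x
}

#' @rdname predict.linear_model_params
#' @export
predict.fit_result <- function(object, x, ...) {
  predict(object$params, x)
}

#' Closed-form least-squares solution for the linear model
#'
#' The ordinary least-squares minimiser of the shared objective; used as
#' the independent reference the iterative fits are checked against.
#'
#' @param dataset A `regression_dataset`.
#' @return A `linear_model_params`.
#' @export
least_squares_params <- function(dataset) {
  cf <- stats::coef(stats::lm.fit(cbind(1, dataset$x), dataset$y))
  as_linear_params(unname(cf))
}

#' Serialize a fit result to a flat CSV
#'
#' One row per epoch of the objective trace plus a final summary row
#' holding the fitted parameters and convergence information.
#'
#' @param fit A `fit_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_csv <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  tr <- data.frame(row = "epoch", epoch = seq_along(fit$objective_trace),
                   Q = fit$objective_trace,
                   theta0 = NA_real_, theta1 = NA_real_,
                   converged = NA)
  summ <- data.frame(row = "summary", epoch = fit$epochs_run,
                     Q = fit$objective_trace[length(fit$objective_trace)],
                     theta0 = fit$params$theta0, theta1 = fit$params$theta1,
                     converged = fit$converged)
  utils::write.csv(rbind(tr, summ), path, row.names = FALSE)
  invisible(path)
}
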