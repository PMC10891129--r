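# The four benchmark generative functions of the simulation study and the
# sampler that turns them into noisy regression datasets.

TARGET_FN_IDS <- c("F1", "F2", "F3", "F4")

#' Evaluate a benchmark target function without noise
#'
#' The four generative functions used throughout the conformance study:
#' \describe{
#'   \item{F1}{`0.5 + 0.79 x` — a line.}
#'   \item{F2}{`1 - exp(-1 / (2 x))` — a saturating curve, defined for `x > 0`.}
#'   \item{F3}{`0.7 + 3 x^2` — a parabola.}
#'   \item{F4}{`(6 x - 2)^2 + sin(12 x - 4)` — the classic multimodal
#'     one-dimensional surrogate-modelling benchmark.}
#' }
#'
#' @param fn_id One of `"F1"`, `"F2"`, `"F3"`, `"F4"`.
#' @param x Numeric vector. For F2 every element must be strictly positive.
#' @return Numeric vector of noise-free function values.
#' @examples
#' eval_target_function("F1", 0)    # 0.5
#' eval_target_function("F2", 0.5)  # 1 - exp(-1)
#' @export
eval_target_function <- function(fn_id, x) {
  fn_id <- match.arg(fn_id, TARGET_FN_IDS)
  stopifnot(is.numeric(x))
  switch(fn_id,
    F1 = 0.5 + 0.79 * x,
    F2 = {
      if (any(x <= 0)) {
        stop("F2 is defined only for x > 0", call. = FALSE)
      }
      1 - exp(-1 / (2 * x))
    },
    F3 = 0.7 + 3 * x^2,
    F4 = (6 * x - 2)^2 + sin(12 * x - 4)
  )
}

#' Draw a regression dataset from a benchmark function
#'
#' Samples `x ~ U(0, 1)` (open interval, protecting F2's domain) and sets
#' `y = f(x) + eps`. The additive Gaussian noise term belongs to F1 and F3
#' only; F2 and F4 are deterministic curves, so for them `y` lies exactly on
#' the curve whatever `noise_sd` says.
#'
#' @param fn_id Target function id, see [eval_target_function()].
#' @param m Sample size, at least 2. Default 100.
#' @param seed Integer seed; regeneration with identical arguments is exact.
#' @param noise_sd Standard deviation of the noise on F1/F3. Default 0.2.
#' @return An object of class `regression_dataset`: a list with elements
#'   `fn_id`, `x`, `y`, `m`, `noise_sd`, `seed`.
#' @examples
#' d <- generate_regression_data("F1", m = 50, seed = 1, noise_sd = 0)
#' all.equal(d$y, 0.5 + 0.79 * d$x)
#' @export
generate_regression_data <- function(fn_id, m = 100L, seed = 1L,
                                     noise_sd = 0.2) {
  fn_id <- match.arg(fn_id, TARGET_FN_IDS)
  if (!is.numeric(m) || length(m) != 1L || m < 2) {
    stop("m must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("noise_sd must be a single nonnegative number", call. = FALSE)
  }
  m <- as.integer(m)
  dat <- with_seed(seed, {
    x <- stats::runif(m)
    # runif() cannot return 1 and returns 0 with vanishing probability;
    # resample any boundary draw so x is strictly inside (0, 1).
    while (any(bad <- (x <= 0 | x >= 1))) {
      x[bad] <- stats::runif(sum(bad))
    }
    y <- eval_target_function(fn_id, x)
    if (fn_id %in% c("F1", "F3") && noise_sd > 0) {
      y <- y + stats::rnorm(m, mean = 0, sd = noise_sd)
    }
    list(x = x, y = y)
  })
  structure(
    list(fn_id = fn_id, x = dat$x, y = dat$y, m = m,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "regression_dataset"
  )
}

#' @export
print.regression_dataset <- function(x, ...) {
  cat(sprintf("<regression_dataset> %s, m = %d, noise_sd = %g, seed = %d\n",
              x$fn_id, x$m, x$noise_sd, x$seed))
  invisible(x)
}

#' Write a regression dataset as a two-column CSV
#'
#' @param dataset A `regression_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_regression_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "regression_dataset"))
  utils::write.csv(data.frame(x = dataset$x, y = dataset$y),
                   path, row.names = FALSE)
  invisible(path)
}
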