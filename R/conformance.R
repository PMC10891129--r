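# The interpretability engine: repeated three-optimizer fits to one
# generative function, pairwise conformance distances between the fitted
# models, and a significance test over the runs.

#' Conformance distance between two fitted models' point sets
#'
#' For paired point sets `(x_a, z_a)` and `(x_b, z_b)`,
#' `sqrt(sum_i ((x_a_i - x_b_i)^2 + (z_a_i - z_b_i)^2))`. When the two
#' models share the abscissae (as in the study protocol, where all three
#' optimizers predict on the same x) the x-terms vanish and this is the
#' Euclidean distance between the prediction vectors.
#'
#' @param x_a,z_a Abscissae and predictions of model a.
#' @param x_b,z_b Abscissae and predictions of model b.
#' @return Nonnegative scalar distance; symmetric in (a, b).
#' @export
model_distance <- function(x_a, z_a, x_b, z_b) {
  n <- length(x_a)
  if (length(z_a) != n || length(x_b) != n || length(z_b) != n) {
    stop("all four vectors must have equal length", call. = FALSE)
  }
  sqrt(sum((x_a - x_b)^2 + (z_a - z_b)^2))
}

#' Welch two-sample t-test with degenerate-input conventions
#'
#' Two-sided two-sample t statistic with Welch (unequal-variance) degrees
#' of freedom, delegated to [stats::t.test()]. When both samples have zero
#' variance the test is undefined; by convention p = 1 if the means are
#' equal and p = 0 otherwise (with t = 0 / Inf-signed accordingly).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with elements `t`, `df` and `p`.
#' @export
welch_t_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    d <- mean(a) - mean(b)
    if (d == 0) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(d) * Inf, df = NA_real_, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Run the repeated-fit conformance study for one generative function
#'
#' Per run: draw a fresh dataset from `fn_id` (shared by all three
#' optimizers), fit the linear model with SGD, RMSprop and Adam, predict on
#' the shared x, and record `d_sa` (SGD vs Adam) and `d_sr` (SGD vs
#' RMSprop) via [model_distance()]. After all runs the two distance samples
#' are compared with [welch_t_test()]. Each run's dataset seed and the three
#' per-optimizer initialisation/shuffle seeds are derived from `base_seed`,
#' so any single run is individually reproducible.
#'
#' @param fn_id Target function id (`"F1"`..`"F4"`).
#' @param n_runs Number of runs; default 9.
#' @param m Sample size per run; default 100.
#' @param noise_sd Noise level passed to [generate_regression_data()].
#' @param base_seed Seed of the whole study.
#' @param configs Optional named list with elements `sgd`, `rmsprop`,
#'   `adam`, each an [optimizer_config()] used as a template (its seeds are
#'   replaced by the per-run derived seeds). Defaults to the protocol
#'   defaults.
#' @return An object of class `conformance_study` with elements `fn_id`,
#'   `runs`, `distances` (data frame `run, d_sa, d_sr`), `t_statistic`,
#'   `p_value`, `mean_d_sa`, `mean_d_sr`.
#' @export
run_conformance_study <- function(fn_id, n_runs = 9L, m = 100L,
                                  noise_sd = 0.2, base_seed = 1L,
                                  configs = NULL) {
  stopifnot(n_runs >= 2)
  fn_id <- match.arg(fn_id, TARGET_FN_IDS)
  if (is.null(configs)) {
    configs <- list(sgd = optimizer_config("sgd"),
                    rmsprop = optimizer_config("rmsprop"),
                    adam = optimizer_config("adam"))
  }
  stopifnot(all(c("sgd", "rmsprop", "adam") %in% names(configs)))
  # 7 independent substreams per run: data, then init + shuffle per optimizer
  seeds <- matrix(derive_seeds(base_seed, 7L * n_runs), nrow = 7L)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    s <- seeds[, r]
    dataset <- generate_regression_data(fn_id, m = m, seed = s[1],
                                        noise_sd = noise_sd)
    fits <- list()
    for (k in seq_along(OPTIMIZER_METHODS)) {
      meth <- OPTIMIZER_METHODS[k]
      cfg <- configs[[meth]]
      cfg$init_seed <- s[2 * k]
      cfg$shuffle_seed <- s[2 * k + 1]
      fits[[meth]] <- tryCatch(
        fit_linear_model(dataset, cfg),
        error = function(e) {
          stop(sprintf("run %d: %s", r, conditionMessage(e)), call. = FALSE)
        })
    }
    runs[[r]] <- structure(
      list(run_index = r, dataset = dataset,
           fit_sgd = fits$sgd, fit_rmsprop = fits$rmsprop,
           fit_adam = fits$adam,
           d_sa = model_distance(dataset$x, fits$sgd$predictions,
                                 dataset$x, fits$adam$predictions),
           d_sr = model_distance(dataset$x, fits$sgd$predictions,
                                 dataset$x, fits$rmsprop$predictions)),
      class = "conformance_run")
  }
  d_sa <- vapply(runs, `[[`, numeric(1), "d_sa")
  d_sr <- vapply(runs, `[[`, numeric(1), "d_sr")
  tt <- welch_t_test(d_sa, d_sr)
  structure(
    list(fn_id = fn_id, runs = runs,
         distances = data.frame(run = seq_len(n_runs), d_sa = d_sa,
                                d_sr = d_sr),
         t_statistic = tt$t, p_value = tt$p,
         mean_d_sa = mean(d_sa), mean_d_sr = mean(d_sr),
         n_runs = as.integer(n_runs), m = as.integer(m),
         noise_sd = noise_sd, base_seed = as.integer(base_seed)),
    class = "conformance_study")
}

#' @export
print.conformance_study <- function(x, ...) {
  cat(sprintf(
    "<conformance_study> %s: %d runs, mean d_SA = %.4g, mean d_SR = %.4g, p = %.3g\n",
    x$fn_id, x$n_runs, x$mean_d_sa, x$mean_d_sr, x$p_value))
  invisible(x)
}

#' Export study tables and figures
#'
#' Writes, under `out_dir`: a per-run distance CSV (`run, d_sa, d_sr` plus
#' one summary row with the means, t and p), a JSON summary, per-run
#' scatter plots of the three fitted models over the data, and a paired
#' boxplot of the two distance samples.
#'
#' @param study A completed `conformance_study`.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
export_conformance_outputs <- function(study, out_dir) {
  stopifnot(inherits(study, "conformance_study"))
  if (length(study$runs) == 0L) stop("study has no runs", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory",
                                 call. = FALSE)
  tag <- tolower(study$fn_id)
  paths <- character(0)

  csv <- file.path(out_dir, sprintf("distances_%s.csv", tag))
  tab <- rbind(
    data.frame(run = as.character(study$distances$run),
               d_sa = study$distances$d_sa, d_sr = study$distances$d_sr),
    data.frame(run = "mean", d_sa = study$mean_d_sa, d_sr = study$mean_d_sr))
  utils::write.csv(tab, csv, row.names = FALSE)
  paths <- c(paths, csv)

  js <- file.path(out_dir, sprintf("summary_%s.json", tag))
  jsonlite::write_json(
    list(fn_id = study$fn_id, n_runs = study$n_runs, m = study$m,
         noise_sd = study$noise_sd, base_seed = study$base_seed,
         mean_d_sa = study$mean_d_sa, mean_d_sr = study$mean_d_sr,
         t_statistic = study$t_statistic, p_value = study$p_value),
    js, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, js)

  fig <- file.path(out_dir, sprintf("fits_%s.png", tag))
  grDevices::png(fig, width = 1200, height = 900, res = 120)
  old <- graphics::par(mfrow = c(3, 3), mar = c(3, 3, 2, 1))
  for (run in study$runs) {
    d <- run$dataset
    o <- order(d$x)
    graphics::plot(d$x, d$y, pch = 16, cex = 0.5, col = "grey60",
                   xlab = "", ylab = "",
                   main = sprintf("%s run %d", study$fn_id, run$run_index))
    graphics::lines(d$x[o], run$fit_sgd$predictions[o], col = "black")
    graphics::lines(d$x[o], run$fit_adam$predictions[o], col = "red3")
    graphics::lines(d$x[o], run$fit_rmsprop$predictions[o], col = "blue3")
  }
  graphics::par(old)
  grDevices::dev.off()
  paths <- c(paths, fig)

  box <- file.path(out_dir, sprintf("distance_boxplot_%s.png", tag))
  grDevices::png(box, width = 600, height = 600, res = 120)
  graphics::boxplot(list(AdamSGD = study$distances$d_sa,
                         RMSpropSGD = study$distances$d_sr),
                    ylab = "conformance distance",
                    main = sprintf("%s (p = %.3g)", study$fn_id,
                                   study$p_value))
  grDevices::dev.off()
  paths <- c(paths, box)

  invisible(paths)
}
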