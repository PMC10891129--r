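#!/usr/bin/env Rscript
# Fits the two-parameter linear model to one noisy F1 dataset with each of
# the three from-scratch optimizers at the study defaults (eta = 0.001, at
# most 3000 epochs, gradient-norm stop at 0.001), and writes the per-epoch
# objective traces plus a parameter table against the least-squares
# reference.
#
# Usage: Rscript analysis/02_fit_optimizers.R [--seed S] [--out DIR]

suppressPackageStartupMessages(library(optconform))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_arg("--seed", "1"))
out <- get_arg("--out", "results/fits")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

seeds <- optconform:::derive_seeds(seed, 7L)
d <- generate_regression_data("F1", m = 100, seed = seeds[1],
                              noise_sd = 0.2)
ls_ref <- least_squares_params(d)
message(sprintf("least-squares reference: theta = (%.4f, %.4f)",
                ls_ref$theta0, ls_ref$theta1))

fits <- list(
  sgd = fit_sgd(d, optimizer_config("sgd", init_seed = seeds[2],
                                    shuffle_seed = seeds[3])),
  rmsprop = fit_rmsprop(d, optimizer_config("rmsprop",
                                            init_seed = seeds[4],
                                            shuffle_seed = seeds[5])),
  adam = fit_adam(d, optimizer_config("adam", init_seed = seeds[6],
                                      shuffle_seed = seeds[7])))
rows <- lapply(names(fits), function(nm) {
  f <- fits[[nm]]
  write_fit_csv(f, file.path(out, paste0("trace_", nm, ".csv")))
  message(sprintf(
    "%-8s theta = (%.4f, %.4f), epochs = %4d, |grad| = %.2e, %s", nm,
    f$params$theta0, f$params$theta1, f$epochs_run, f$final_grad_norm,
    if (f$converged) "converged" else "epoch budget reached"))
  data.frame(optimizer = nm, theta0 = f$params$theta0,
             theta1 = f$params$theta1, epochs = f$epochs_run,
             final_grad_norm = f$final_grad_norm, converged = f$converged,
             dist_to_ls = sqrt((f$params$theta0 - ls_ref$theta0)^2 +
                                 (f$params$theta1 - ls_ref$theta1)^2))
})
write.csv(do.call(rbind, rows), file.path(out, "parameters.csv"),
          row.names = FALSE)
jsonlite::write_json(list(command = "fit_optimizers", seed = seed,
                          out = out, fn = "F1", m = 100,
                          noise_sd = 0.2, sub_seeds = seeds),
                     file.path(out, "run_config.json"),
                     auto_unbox = TRUE)
message("wrote ", out)
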