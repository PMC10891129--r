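#!/usr/bin/env Rscript
# The transfer-evaluation experiment: pretrains the small CNN on the
# source task, then runs five-fold cross-validation of the binary
# classifier under the three weight-transfer modes (TFe, TFt, scratch)
# with Adam, plus the TFe model under RMSprop and SGD. Writes the
# fold-averaged metrics table and the combined confusion matrices.
# Expect a runtime in the tens of minutes on one CPU.
#
# Usage: Rscript analysis/05_transfer_eval.R [--seed S] [--out DIR]

suppressPackageStartupMessages(library(optconform))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_arg("--seed", "1"))
out <- get_arg("--out", "results/transfer")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

seeds <- optconform:::derive_seeds(seed, 6L)
corp <- generate_network_image_corpus(224, image_size = 64,
                                      seed = seeds[1])
src <- make_source_task_corpus(200, n_classes = 4, image_size = 64,
                               seed = seeds[2])
# desk-scale learning-rate override of the reference 1e-5 (see vignette)
train_cfg <- training_config(learning_rate = 1e-3, epochs = 10,
                             batch_size = 32, seed = seeds[3])
message("pretraining on the source task ...")
pre <- pretrain_source(layered_model_spec(n_classes = 4L,
                                          weight_seed = seeds[4]),
                       src, train_cfg)
spec_bin <- layered_model_spec(n_classes = 2L, weight_seed = seeds[5])

runs <- list(
  TFe_adam = transfer_config("tfe", optimizer_id = "adam",
                             training = train_cfg),
  TFt_adam = transfer_config("tft", freeze_blocks = 2,
                             optimizer_id = "adam", training = train_cfg),
  scratch_adam = transfer_config("scratch", optimizer_id = "adam",
                                 training = train_cfg),
  TFe_rmsprop = transfer_config("tfe", optimizer_id = "rmsprop",
                                training = train_cfg),
  TFe_sgd = transfer_config("tfe", optimizer_id = "sgd",
                            training = train_cfg))
reports <- list()
for (nm in names(runs)) {
  cfg <- runs[[nm]]
  message("five-fold CV: ", nm, " ...")
  pretrained <- if (cfg$mode == "scratch") NULL else pre
  rep <- five_fold_cv(corp, spec_bin, cfg, split_seed = seeds[6],
                      pretrained = pretrained)
  reports[[nm]] <- rep
  cm <- rep$combined_confusion
  message(sprintf("  mean BAC %.3f | combined tp=%d fp=%d tn=%d fn=%d",
                  rep$averages["bac"], cm$tp, cm$fp, cm$tn, cm$fn))
  write.csv(data.frame(count = c(tp = cm$tp, fp = cm$fp, tn = cm$tn,
                                 fn = cm$fn)),
            file.path(out, paste0("confusion_", nm, ".csv")))
}
tab <- cv_metrics_table(reports)
write.csv(tab, file.path(out, "metrics.csv"), row.names = FALSE)
print(tab)
jsonlite::write_json(list(command = "transfer_eval", seed = seed,
                          out = out, n_images = 224, image_size = 64,
                          learning_rate = 1e-3, epochs = 10,
                          batch_size = 32, sub_seeds = seeds),
                     file.path(out, "run_config.json"),
                     auto_unbox = TRUE)
message("wrote ", out)
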