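#!/usr/bin/env Rscript
# Generates the synthetic two-class regulatory-network image corpus (224
# images, balanced healthy/T2D, 64x64) and the 4-class source-task corpus,
# and persists both as PNG files with CSV manifests.
#
# Usage: Rscript analysis/04_generate_corpus.R [--seed S] [--out DIR]

suppressPackageStartupMessages(library(optconform))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_arg("--seed", "1"))
out <- get_arg("--out", "results/corpus")

seeds <- optconform:::derive_seeds(seed, 2L)
corp <- generate_network_image_corpus(224, image_size = 64,
                                      seed = seeds[1])
write_corpus(corp, file.path(out, "binary"))
dens <- tapply(corp$graph_stats$n_edges, corp$graph_stats$label, mean)
message(sprintf("binary corpus: %s; mean edges healthy %.1f vs T2D %.1f",
                paste(sprintf("%s=%d", names(table(corp$labels)),
                              as.integer(table(corp$labels))),
                      collapse = ", "),
                dens[["healthy"]], dens[["T2D"]]))

src <- make_source_task_corpus(200, n_classes = 4, image_size = 64,
                               seed = seeds[2])
write_corpus(src, file.path(out, "source"))
message(sprintf("source corpus: %d images, %d classes",
                length(src$images), length(src$class_names)))
jsonlite::write_json(list(command = "generate_corpus", seed = seed,
                          out = out, n_images = 224, image_size = 64,
                          source_images = 200, source_classes = 4,
                          sub_seeds = seeds),
                     file.path(out, "run_config.json"),
                     auto_unbox = TRUE)
message("wrote ", out)
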