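# The transfer protocol: pretrain the convolutional base on a multi-class
# source task, swap in a fresh binary classifier head, and train under one
# of three modes — TFe (feature extraction: the whole convolutional base
# frozen), TFt (fine-tuning: only the bottom blocks frozen) or scratch
# (nothing transferred, everything freshly initialised).

TRANSFER_MODES <- c("tfe", "tft", "scratch")

#' Transfer-mode configuration
#'
#' @param mode One of `"tfe"`, `"tft"`, `"scratch"`.
#' @param freeze_blocks For TFt: number of bottom conv blocks kept frozen;
#'   must satisfy `1 <= freeze_blocks < n_blocks`. Default 2.
#' @param optimizer_id Network optimizer: `"adam"` (default), `"rmsprop"`
#'   or `"sgd"`.
#' @param training A [training_config()].
#' @return An object of class `transfer_config`.
#' @export
transfer_config <- function(mode = c("tfe", "tft", "scratch"),
                            freeze_blocks = 2L,
                            optimizer_id = c("adam", "rmsprop", "sgd"),
                            training = training_config()) {
  mode <- match.arg(mode)
  optimizer_id <- match.arg(optimizer_id)
  stopifnot(inherits(training, "training_config"), freeze_blocks >= 1)
  structure(list(mode = mode, freeze_blocks = as.integer(freeze_blocks),
                 optimizer_id = optimizer_id, training = training),
            class = "transfer_config")
}

#' Pretrain a model on the multi-class source corpus
#'
#' Initialises a model from `spec` and trains all parameters on the source
#' task, giving the convolutional base the transferable weights the TFe and
#' TFt modes start from.
#'
#' @param spec A [layered_model_spec()] whose `n_classes` matches the
#'   source corpus.
#' @param corpus A multi-class `network_image_corpus`.
#' @param training A [training_config()].
#' @param optimizer_id Network optimizer; default `"adam"`.
#' @return A trained `layered_model`.
#' @export
pretrain_source <- function(spec, corpus, training,
                            optimizer_id = "adam") {
  stopifnot(inherits(spec, "layered_model_spec"),
            inherits(corpus, "network_image_corpus"))
  if (spec$n_classes != length(corpus$class_names)) {
    stop(sprintf("spec has %d classes but corpus has %d",
                 spec$n_classes, length(corpus$class_names)),
         call. = FALSE)
  }
  model <- init_layered_model(spec)
  train_layered_model(model, corpus$images, corpus$labels,
                      corpus$class_names, training, optimizer_id)
}

#' Replace the densely connected classifier with a fresh head
#'
#' The conv-block weights are left bit-identical; the dense layers are
#' re-initialised for `n_classes` outputs.
#'
#' @param model A `layered_model`.
#' @param n_classes New output width, at least 2.
#' @param head_seed Seed for the fresh head weights.
#' @return The adapted `layered_model`.
#' @export
adapt_classifier_head <- function(model, n_classes, head_seed = 1L) {
  stopifnot(inherits(model, "layered_model"))
  if (n_classes < 2) stop("n_classes must be at least 2", call. = FALSE)
  spec <- model$spec
  spec$n_classes <- as.integer(n_classes)
  model$spec <- spec
  model$dense <- with_seed(head_seed, init_dense_head(spec))
  attr(model, "history") <- NULL
  model
}

#' Attach the trainability mask for a transfer mode
#'
#' TFe freezes every conv block and trains only the head; TFt freezes the
#' bottom `freeze_blocks` blocks and trains the rest; scratch freezes
#' nothing and re-initialises all weights.
#'
#' @param model A `layered_model` (for TFe/TFt, a pretrained one with an
#'   adapted head).
#' @param config A [transfer_config()].
#' @param scratch_seed Seed used to re-initialise the weights in scratch
#'   mode; defaults to a stream derived from the training seed.
#' @return The model with a `"trainable"` attribute (logical vectors
#'   `conv`, `dense`).
#' @export
apply_transfer_mode <- function(model, config,
                                scratch_seed = derive_seeds(config$training$seed, 1L)) {
  stopifnot(inherits(model, "layered_model"),
            inherits(config, "transfer_config"))
  nb <- length(model$conv)
  mask <- all_trainable(model)
  if (config$mode == "tfe") {
    mask$conv[] <- FALSE
  } else if (config$mode == "tft") {
    if (config$freeze_blocks >= nb) {
      stop("TFt requires freeze_blocks < number of conv blocks (freezing all blocks is TFe)",
           call. = FALSE)
    }
    mask$conv[seq_len(config$freeze_blocks)] <- FALSE
  } else {
    model <- init_layered_model(model$spec, weight_seed = scratch_seed)
  }
  attr(model, "trainable") <- mask
  model
}

#' Train the classifier under a transfer configuration
#'
#' Trains only the tensors left trainable by [apply_transfer_mode()] with
#' the configured optimizer and categorical cross-entropy, dropout active
#' on the last fully-connected layer. Frozen tensors are bit-identical
#' before and after.
#'
#' @param model A `layered_model` with a `"trainable"` attribute (models
#'   without one are treated as fully trainable).
#' @param corpus A binary `network_image_corpus`.
#' @param config A [transfer_config()].
#' @return The trained `layered_model` (the mask is preserved).
#' @export
train_classifier <- function(model, corpus, config) {
  stopifnot(inherits(model, "layered_model"),
            inherits(corpus, "network_image_corpus"),
            inherits(config, "transfer_config"))
  if (length(corpus$images) == 0L) stop("empty corpus", call. = FALSE)
  mask <- attr(model, "trainable")
  if (is.null(mask)) mask <- all_trainable(model)
  out <- train_layered_model(model, corpus$images, corpus$labels,
                             corpus$class_names, config$training,
                             config$optimizer_id, trainable = mask)
  attr(out, "trainable") <- mask
  out
}
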