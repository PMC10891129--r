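# Five-fold cross-validation of the transfer protocol: random fold
# assignment, per-fold training and evaluation, the combined confusion
# matrix (elementwise sum over folds, so every image is tested exactly
# once) and fold-averaged metrics.

#' Random fold assignment
#'
#' Uniform random permutation chunking: items are permuted under
#' `split_seed` and cut into `n_folds` consecutive chunks whose sizes
#' differ by at most one (larger folds first). An optional stratified mode
#' applies the same chunking within each class.
#'
#' @param n Number of items.
#' @param n_folds Number of folds; default 5.
#' @param split_seed Integer seed.
#' @param labels Optional class labels of length `n`; when supplied,
#'   assignment is stratified by class.
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
fold_assignment <- function(n, n_folds = 5L, split_seed = 1L,
                            labels = NULL) {
  stopifnot(n >= n_folds, n_folds >= 2)
  sizes <- rep(n %/% n_folds, n_folds)
  extra <- n %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold <- integer(n)
  with_seed(split_seed, {
    if (is.null(labels)) {
      fold[sample.int(n)] <- rep(seq_len(n_folds), sizes)
    } else {
      stopifnot(length(labels) == n)
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        k <- length(idx)
        cs <- rep(k %/% n_folds, n_folds)
        ce <- k %% n_folds
        if (ce > 0) cs[seq_len(ce)] <- cs[seq_len(ce)] + 1L
        fold[idx[sample.int(k)]] <- rep(seq_len(n_folds), cs)
      }
    }
  })
  fold
}

#' Five-fold cross-validation of one model configuration
#'
#' Builds a fold assignment, then for each fold trains on the remaining
#' folds and evaluates on the held-out fold: class probabilities are
#' computed, the healthy-class score is thresholded at 0.5
#' ([predict_label()]), and the fold's confusion matrix and metrics are
#' recorded. For TFe/TFt modes a pretrained model must be supplied; its
#' head is re-initialised per fold before the trainability mask is
#' applied. Scratch mode initialises a fresh model per fold.
#'
#' @param corpus A binary `network_image_corpus` with at least `n_folds`
#'   images.
#' @param spec A [layered_model_spec()] (used in scratch mode; for
#'   TFe/TFt the pretrained model's own spec governs).
#' @param config A [transfer_config()].
#' @param split_seed Seed for the fold assignment and all per-fold
#'   sub-streams (head init, training shuffles/dropout, scratch init).
#' @param pretrained A pretrained `layered_model` (required for TFe/TFt).
#' @param n_folds Number of folds; default 5.
#' @param stratified Stratify the folds by class; default `FALSE`.
#' @return An object of class `cv_report`: `per_fold` (list of
#'   `confusion` + `metrics` per fold), `combined_confusion`, `averages`
#'   (mean of each metric over folds), `fold_assignment`.
#' @export
five_fold_cv <- function(corpus, spec, config, split_seed = 1L,
                         pretrained = NULL, n_folds = 5L,
                         stratified = FALSE) {
  stopifnot(inherits(corpus, "network_image_corpus"),
            inherits(config, "transfer_config"))
  n <- length(corpus$images)
  if (n < n_folds) stop("corpus smaller than the number of folds",
                        call. = FALSE)
  if (config$mode %in% c("tfe", "tft") && is.null(pretrained)) {
    stop("TFe/TFt modes require a pretrained model", call. = FALSE)
  }
  folds <- fold_assignment(n, n_folds, split_seed,
                           labels = if (stratified) corpus$labels else NULL)
  seeds <- matrix(derive_seeds(split_seed, 3L * n_folds), nrow = 3L)
  healthy_col <- match("healthy", corpus$class_names)
  per_fold <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    cfg <- config
    cfg$training$seed <- seeds[2, f]
    if (config$mode == "scratch") {
      model <- init_layered_model(spec, weight_seed = seeds[3, f])
      model <- apply_transfer_mode(model, cfg, scratch_seed = seeds[3, f])
    } else {
      model <- adapt_classifier_head(pretrained, 2L, head_seed = seeds[1, f])
      model <- apply_transfer_mode(model, cfg)
    }
    model <- train_classifier(model, corpus_subset(corpus, train_idx), cfg)
    probs <- predict_proba(model, corpus$images[test_idx])
    pred <- predict_label(probs[, healthy_col])
    cm <- confusion_matrix(corpus$labels[test_idx], pred)
    per_fold[[f]] <- list(confusion = cm, metrics = compute_metrics(cm))
  }
  comb <- structure(
    list(tp = sum(vapply(per_fold, function(z) z$confusion$tp, numeric(1))),
         fp = sum(vapply(per_fold, function(z) z$confusion$fp, numeric(1))),
         tn = sum(vapply(per_fold, function(z) z$confusion$tn, numeric(1))),
         fn = sum(vapply(per_fold, function(z) z$confusion$fn, numeric(1)))),
    class = "confusion_matrix")
  met <- vapply(per_fold,
                function(z) unlist(z$metrics, use.names = TRUE),
                numeric(5))
  structure(
    list(per_fold = per_fold, combined_confusion = comb,
         averages = rowMeans(met), fold_assignment = folds,
         mode = config$mode, optimizer_id = config$optimizer_id,
         split_seed = as.integer(split_seed)),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s/%s: mean BAC = %.3f, combined tp=%d fp=%d tn=%d fn=%d\n",
              x$mode, x$optimizer_id, x$averages["bac"],
              x$combined_confusion$tp, x$combined_confusion$fp,
              x$combined_confusion$tn, x$combined_confusion$fn))
  invisible(x)
}

#' Summarise CV reports as a metrics table
#'
#' One row per report, with the fold-averaged metrics — the layout of the
#' usual model-comparison tables (`model, optimizer, BAC, PRE, REC, F1`).
#'
#' @param reports Named list of `cv_report` objects (names become the
#'   `model` column).
#' @return A data frame.
#' @export
cv_metrics_table <- function(reports) {
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm, optimizer = r$optimizer_id,
               BAC = r$averages["bac"], ACC = r$averages["acc"],
               PRE = r$averages["pre"], REC = r$averages["rec"],
               F1 = r$averages["f1"], row.names = NULL)
  }))
}
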