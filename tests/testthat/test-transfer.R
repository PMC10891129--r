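# Transfer-protocol contracts at a small scale: 16-pixel images and short
# training budgets exercise the same code paths as the full corpus.

small_spec <- function(n_classes = 2L) {
  layered_model_spec(conv_filters = c(4L, 6L, 8L), kernel = 3L, pool = 2L,
                     hidden = 8L, n_classes = n_classes, image_size = 16L,
                     dropout_rate = 0.5, weight_seed = 3L)
}

small_corpus <- function(n = 16, seed = 1) {
  generate_network_image_corpus(n, image_size = 32, seed = seed)
}

shrink <- function(corpus, size = 16L) {
  # average-pool the 32px corpus down so the small spec can consume it
  corpus$images <- lapply(corpus$images, function(im) {
    arr <- array(0, c(size, size, 3))
    f <- dim(im)[1] / size
    for (ch in 1:3) {
      m <- im[, , ch]
      arr[, , ch] <- 0.25 * (m[c(TRUE, FALSE), c(TRUE, FALSE)] +
                               m[c(FALSE, TRUE), c(TRUE, FALSE)] +
                               m[c(TRUE, FALSE), c(FALSE, TRUE)] +
                               m[c(FALSE, TRUE), c(FALSE, TRUE)])
    }
    arr
  })
  corpus$image_size <- size
  corpus
}

fast_training <- function(seed = 9, epochs = 2, lr = 3e-3) {
  training_config(learning_rate = lr, epochs = epochs, batch_size = 8,
                  seed = seed)
}

test_that("pretraining fits the source task and is seed-deterministic", {
  src <- shrink(make_source_task_corpus(32, 4, 32, seed = 2))
  spec <- small_spec(n_classes = 4L)
  expect_error(pretrain_source(small_spec(2L), src, fast_training()),
               "classes")
  pre1 <- pretrain_source(spec, src, fast_training(epochs = 15))
  pre2 <- pretrain_source(spec, src, fast_training(epochs = 15))
  expect_identical(pre1$conv, pre2$conv)
  # trained features beat chance on the (training) source corpus
  acc <- mean(src$class_names[max.col(predict_proba(pre1, src$images))] ==
                src$labels)
  expect_gt(acc, 0.25)
  # 0 epochs returns the initialisation untouched
  pre0 <- pretrain_source(spec, src, fast_training(epochs = 0))
  expect_identical(pre0, init_layered_model(spec))
})

test_that("head adaptation swaps the classifier and preserves the base", {
  spec <- small_spec(4L)
  model <- init_layered_model(spec)
  ad <- adapt_classifier_head(model, 2L, head_seed = 11)
  expect_identical(ad$conv, model$conv)
  expect_equal(ad$spec$n_classes, 2L)
  expect_equal(dim(ad$dense[[2]]$W)[2], 2L)
  expect_false(identical(ad$dense[[1]]$W, model$dense[[1]]$W))
  # idempotent shape
  ad2 <- adapt_classifier_head(ad, 2L, head_seed = 12)
  expect_equal(dim(ad2$dense[[2]]$W)[2], 2L)
  expect_error(adapt_classifier_head(model, 1L), "n_classes")
})

test_that("transfer modes set the documented trainability masks", {
  model <- init_layered_model(small_spec())
  tfe <- apply_transfer_mode(model, transfer_config("tfe",
                                                    training = fast_training()))
  expect_equal(attr(tfe, "trainable")$conv, rep(FALSE, 3))
  expect_equal(attr(tfe, "trainable")$dense, rep(TRUE, 2))
  tft <- apply_transfer_mode(model,
                             transfer_config("tft", freeze_blocks = 2,
                                             training = fast_training()))
  expect_equal(attr(tft, "trainable")$conv, c(FALSE, FALSE, TRUE))
  expect_error(apply_transfer_mode(model,
                                   transfer_config("tft", freeze_blocks = 3,
                                                   training = fast_training())),
               "TFe")
  scr <- apply_transfer_mode(model, transfer_config("scratch",
                                                    training = fast_training()))
  expect_true(all(attr(scr, "trainable")$conv))
  expect_false(identical(scr$conv, model$conv)) # fresh initialisation
})

test_that("frozen tensors stay bit-identical while trainable ones move", {
  corp <- shrink(small_corpus(16, seed = 6))
  spec <- small_spec()
  base <- init_layered_model(spec, weight_seed = 21)

  cfg_tfe <- transfer_config("tfe", training = fast_training(seed = 31))
  m <- apply_transfer_mode(base, cfg_tfe)
  trained <- train_classifier(m, corp, cfg_tfe)
  expect_identical(trained$conv, base$conv)
  expect_false(identical(trained$dense, base$dense))

  cfg_tft <- transfer_config("tft", freeze_blocks = 2,
                             training = fast_training(seed = 32))
  m <- apply_transfer_mode(base, cfg_tft)
  trained <- train_classifier(m, corp, cfg_tft)
  expect_identical(trained$conv[1:2], base$conv[1:2])
  expect_false(identical(trained$conv[[3]], base$conv[[3]]))

  cfg_scr <- transfer_config("scratch", training = fast_training(seed = 33))
  m <- apply_transfer_mode(base, cfg_scr)
  trained <- train_classifier(m, corp, cfg_scr)
  for (j in 1:3) expect_false(identical(trained$conv[[j]], m$conv[[j]]))
  for (j in 1:2) expect_false(identical(trained$dense[[j]], m$dense[[j]]))

  expect_error(train_classifier(m, corpus_subset(corp, integer(0)),
                                cfg_scr),
               "empty")
})
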