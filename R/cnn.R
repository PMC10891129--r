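# A small layered convolutional network written with plain matrix algebra.
# Architecture: a stack of (3x3 same-padding convolution, ReLU, 2x2 max
# pool) blocks — the convolutional base / feature extraction part — then
# global average pooling, one hidden dense layer with ReLU and dropout, and
# a softmax output layer (the densely connected classifier). Trained with
# categorical cross-entropy. The im2col trick turns every convolution into
# one matrix product, which keeps CPU training of the desk-scale
# configurations in the seconds-to-minutes range.

#' Specification of the layered convolutional model
#'
#' @param conv_filters Integer vector: filters per conv block (at least
#'   one). Default `c(8, 16, 32)`.
#' @param kernel Odd kernel size; default 3.
#' @param pool Pooling factor per block; default 2.
#' @param hidden Width of the hidden dense layer; default 32.
#' @param dropout_rate Dropout rate on the last fully-connected layer
#'   during training; default 0.5.
#' @param n_classes Output width; default 2.
#' @param in_channels Input channels; default 3.
#' @param image_size Input side length in pixels; must be divisible by
#'   `pool^n_blocks`. Default 64.
#' @param weight_seed Seed for weight initialisation.
#' @return An object of class `layered_model_spec`.
#' @export
layered_model_spec <- function(conv_filters = c(8L, 16L, 32L), kernel = 3L,
                               pool = 2L, hidden = 32L, dropout_rate = 0.5,
                               n_classes = 2L, in_channels = 3L,
                               image_size = 64L, weight_seed = 1L) {
  stopifnot(length(conv_filters) >= 1, all(conv_filters >= 1),
            kernel %% 2 == 1, pool >= 1, hidden >= 1, n_classes >= 2,
            dropout_rate >= 0, dropout_rate < 1)
  if (image_size %% pool^length(conv_filters) != 0) {
    stop("image_size must be divisible by pool^(number of blocks)",
         call. = FALSE)
  }
  structure(
    list(conv_filters = as.integer(conv_filters), kernel = as.integer(kernel),
         pool = as.integer(pool), hidden = as.integer(hidden),
         dropout_rate = dropout_rate, n_classes = as.integer(n_classes),
         in_channels = as.integer(in_channels),
         image_size = as.integer(image_size),
         weight_seed = as.integer(weight_seed)),
    class = "layered_model_spec")
}

# He-scaled normal initialisation for one weight matrix.
he_init <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / nrow)), nrow, ncol)
}

init_dense_head <- function(spec) {
  fan_in <- spec$conv_filters[length(spec$conv_filters)]
  list(
    list(W = he_init(fan_in, spec$hidden), b = numeric(spec$hidden)),
    list(W = he_init(spec$hidden, spec$n_classes),
         b = numeric(spec$n_classes))
  )
}

#' Initialise a layered model from its spec
#'
#' @param spec A `layered_model_spec`.
#' @param weight_seed Seed; defaults to `spec$weight_seed`.
#' @return An object of class `layered_model` holding the conv-block and
#'   dense-layer weights.
#' @export
init_layered_model <- function(spec, weight_seed = spec$weight_seed) {
  stopifnot(inherits(spec, "layered_model_spec"))
  with_seed(weight_seed, {
    cin <- spec$in_channels
    conv <- vector("list", length(spec$conv_filters))
    for (j in seq_along(spec$conv_filters)) {
      f <- spec$conv_filters[j]
      conv[[j]] <- list(W = he_init(spec$kernel^2 * cin, f),
                        b = numeric(f))
      cin <- f
    }
    structure(list(spec = spec, conv = conv, dense = init_dense_head(spec)),
              class = "layered_model")
  })
}

#' @export
print.layered_model <- function(x, ...) {
  cat(sprintf(
    "<layered_model> %d conv blocks (%s filters), hidden %d, %d classes\n",
    length(x$conv), paste(x$spec$conv_filters, collapse = "/"),
    x$spec$hidden, x$spec$n_classes))
  invisible(x)
}

# Precomputed index geometry for every block at a given input size:
# im2col gather indices, padded-interior indices, and pooling lattices.
conv_geometry <- function(spec) {
  k <- spec$kernel
  p <- (k - 1L) %/% 2L
  H <- spec$image_size
  C <- spec$in_channels
  geoms <- vector("list", length(spec$conv_filters))
  for (j in seq_along(spec$conv_filters)) {
    Hp <- H + 2L * p
    pos <- as.vector(outer(seq_len(H), (seq_len(H) - 1L) * Hp, `+`))
    off <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * Hp, `+`))
    offc <- as.vector(outer(off, (0:(C - 1L)) * Hp * Hp, `+`))
    idx <- outer(pos, offc, `+`)
    interior <- as.vector(outer(as.vector(outer(seq_len(H) + p,
                                                (seq_len(H) + p - 1L) * Hp,
                                                `+`)),
                                (0:(C - 1L)) * Hp * Hp, `+`))
    Hq <- H %/% spec$pool
    lat <- vector("list", spec$pool^2)
    L <- 1L
    for (dc in 0:(spec$pool - 1L)) {
      for (dr in 0:(spec$pool - 1L)) {
        rows <- (seq_len(Hq) - 1L) * spec$pool + 1L + dr
        cols <- (seq_len(Hq) - 1L) * spec$pool + 1L + dc
        lat[[L]] <- as.vector(outer(rows, (cols - 1L) * H, `+`))
        L <- L + 1L
      }
    }
    geoms[[j]] <- list(H = H, Hp = Hp, C = C, F = spec$conv_filters[j],
                       idx = idx, interior = interior, lat = lat, Hq = Hq)
    H <- Hq
    C <- spec$conv_filters[j]
  }
  geoms
}

# Forward pass for one image (H x W x C array or (H*W) x C matrix).
# Returns the class probabilities plus all caches needed for backprop.
nn_forward_single <- function(model, img, geoms, drop_mask = NULL) {
  spec <- model$spec
  A <- matrix(as.vector(img), ncol = spec$in_channels)
  caches <- vector("list", length(model$conv))
  for (j in seq_along(model$conv)) {
    g <- geoms[[j]]
    pad <- numeric(g$Hp * g$Hp * g$C)
    pad[g$interior] <- A
    patch <- pad[g$idx]
    dim(patch) <- dim(g$idx)
    Z <- patch %*% model$conv[[j]]$W
    Z <- Z + rep(model$conv[[j]]$b, each = nrow(Z))
    R <- Z > 0
    A1 <- Z * R
    # max pool over the lattices
    best <- A1[g$lat[[1]], , drop = FALSE]
    which_lat <- matrix(1L, nrow(best), ncol(best))
    for (L in 2:length(g$lat)) {
      cand <- A1[g$lat[[L]], , drop = FALSE]
      upd <- cand > best
      which_lat[upd] <- L
      best[upd] <- cand[upd]
    }
    caches[[j]] <- list(patch = patch, relu = R, which_lat = which_lat)
    A <- best
  }
  feat <- colMeans(A)
  z1 <- as.vector(feat %*% model$dense[[1]]$W) + model$dense[[1]]$b
  a1 <- pmax(z1, 0)
  a1d <- if (is.null(drop_mask)) a1 else a1 * drop_mask
  logits <- as.vector(a1d %*% model$dense[[2]]$W) + model$dense[[2]]$b
  e <- exp(logits - max(logits))
  probs <- e / sum(e)
  list(probs = probs, caches = caches, feat = feat, z1 = z1, a1d = a1d,
       n_spatial = nrow(A))
}

# Backward pass for one image; returns per-tensor gradients of the
# cross-entropy loss of this image.
nn_backward_single <- function(model, fw, y_onehot, geoms,
                               drop_mask = NULL) {
  spec <- model$spec
  dlogits <- fw$probs - y_onehot
  gW2 <- outer(fw$a1d, dlogits)
  gb2 <- dlogits
  da1d <- as.vector(model$dense[[2]]$W %*% dlogits)
  da1 <- if (is.null(drop_mask)) da1d else da1d * drop_mask
  dz1 <- da1 * (fw$z1 > 0)
  gW1 <- outer(fw$feat, dz1)
  gb1 <- dz1
  dfeat <- as.vector(model$dense[[1]]$W %*% dz1)
  nb <- length(model$conv)
  dA <- matrix(rep(dfeat / fw$n_spatial, each = fw$n_spatial),
               nrow = fw$n_spatial)
  gconv <- vector("list", nb)
  for (j in nb:1) {
    g <- geoms[[j]]
    cache <- fw$caches[[j]]
    # unpool: route each pooled gradient to its argmax lattice position
    dFull <- matrix(0, g$H * g$H, g$F)
    for (L in seq_along(g$lat)) {
      sel <- cache$which_lat == L
      if (any(sel)) {
        tmp <- dA * sel
        dFull[g$lat[[L]], ] <- dFull[g$lat[[L]], ] + tmp
      }
    }
    dZ <- dFull * cache$relu
    gconv[[j]] <- list(W = crossprod(cache$patch, dZ), b = colSums(dZ))
    if (j > 1) {
      dpatch <- tcrossprod(dZ, model$conv[[j]]$W)
      dpad <- numeric(g$Hp * g$Hp * g$C)
      for (cc in seq_len(ncol(g$idx))) {
        ii <- g$idx[, cc]
        dpad[ii] <- dpad[ii] + dpatch[, cc]
      }
      dA <- matrix(dpad[g$interior], ncol = g$C)
    }
  }
  list(conv = gconv, dense = list(list(W = gW1, b = gb1),
                                  list(W = gW2, b = gb2)))
}

zero_like_grads <- function(model) {
  list(conv = lapply(model$conv, function(l)
         list(W = 0 * l$W, b = 0 * l$b)),
       dense = lapply(model$dense, function(l)
         list(W = 0 * l$W, b = 0 * l$b)))
}

add_grads <- function(a, b) {
  for (j in seq_along(a$conv)) {
    a$conv[[j]]$W <- a$conv[[j]]$W + b$conv[[j]]$W
    a$conv[[j]]$b <- a$conv[[j]]$b + b$conv[[j]]$b
  }
  for (j in seq_along(a$dense)) {
    a$dense[[j]]$W <- a$dense[[j]]$W + b$dense[[j]]$W
    a$dense[[j]]$b <- a$dense[[j]]$b + b$dense[[j]]$b
  }
  a
}

scale_grads <- function(a, s) {
  for (j in seq_along(a$conv)) {
    a$conv[[j]]$W <- a$conv[[j]]$W * s
    a$conv[[j]]$b <- a$conv[[j]]$b * s
  }
  for (j in seq_along(a$dense)) {
    a$dense[[j]]$W <- a$dense[[j]]$W * s
    a$dense[[j]]$b <- a$dense[[j]]$b * s
  }
  a
}

# Per-tensor first/second-moment state for the network optimizers.
new_opt_state <- function(model) {
  list(m = zero_like_grads(model), v = zero_like_grads(model), t = 0L)
}

# One optimizer step over all trainable tensors. `trainable` is a list
# with logical vectors `conv` and `dense` (one entry per block / layer).
apply_nn_update <- function(model, grads, state, optimizer_id, lr,
                            trainable) {
  upd_tensor <- function(w, g, m, v, t) {
    switch(optimizer_id,
      sgd = list(w = w - lr * g, m = m, v = v),
      rmsprop = {
        v <- 0.9 * v + 0.1 * g^2
        list(w = w - lr * g / sqrt(v + 1e-6), m = m, v = v)
      },
      adam = {
        m <- 0.9 * m + 0.1 * g
        v <- 0.999 * v + 0.001 * g^2
        mh <- m / (1 - 0.9^t)
        vh <- v / (1 - 0.999^t)
        list(w = w - lr * mh / (sqrt(vh) + 1e-8), m = m, v = v)
      })
  }
  state$t <- state$t + 1L
  for (j in seq_along(model$conv)) {
    if (!trainable$conv[j]) next
    for (part in c("W", "b")) {
      u <- upd_tensor(model$conv[[j]][[part]], grads$conv[[j]][[part]],
                      state$m$conv[[j]][[part]], state$v$conv[[j]][[part]],
                      state$t)
      model$conv[[j]][[part]] <- u$w
      state$m$conv[[j]][[part]] <- u$m
      state$v$conv[[j]][[part]] <- u$v
    }
  }
  for (j in seq_along(model$dense)) {
    if (!trainable$dense[j]) next
    for (part in c("W", "b")) {
      u <- upd_tensor(model$dense[[j]][[part]], grads$dense[[j]][[part]],
                      state$m$dense[[j]][[part]], state$v$dense[[j]][[part]],
                      state$t)
      model$dense[[j]][[part]] <- u$w
      state$m$dense[[j]][[part]] <- u$m
      state$v$dense[[j]][[part]] <- u$v
    }
  }
  list(model = model, state = state)
}

all_trainable <- function(model) {
  list(conv = rep(TRUE, length(model$conv)),
       dense = rep(TRUE, length(model$dense)))
}

#' Training hyperparameters for the layered model
#'
#' Defaults mirror the study's classification configuration: learning rate
#' 1e-5, 10 epochs, batch size 32, categorical cross-entropy loss. For the
#' small desk-scale network the drivers override the learning rate (see the
#' methods vignette); the override is recorded in the resulting objects.
#'
#' @param learning_rate Positive learning rate; default 1e-5.
#' @param epochs Number of epochs; default 10.
#' @param batch_size Mini-batch size; default 32.
#' @param seed Seed driving shuffling and dropout masks.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-5, epochs = 10L,
                            batch_size = 32L, seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 0, batch_size >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss = "categorical_crossentropy",
                 seed = as.integer(seed)),
            class = "training_config")
}

# Core training loop. `labels` are character; `class_names` fixes the
# one-hot / softmax column order. Dropout (inverted scaling) is applied to
# the last fully-connected layer only while training.
train_layered_model <- function(model, images, labels, class_names,
                                training, optimizer_id = "adam",
                                trainable = NULL) {
  stopifnot(inherits(model, "layered_model"),
            inherits(training, "training_config"),
            length(images) == length(labels), length(images) >= 1)
  optimizer_id <- match.arg(optimizer_id, c("adam", "rmsprop", "sgd"))
  if (is.null(trainable)) trainable <- all_trainable(model)
  cls <- match(labels, class_names)
  if (anyNA(cls)) stop("labels outside class_names", call. = FALSE)
  if (training$epochs == 0L) return(model)
  spec <- model$spec
  geoms <- conv_geometry(spec)
  p <- spec$dropout_rate
  n <- length(images)
  state <- new_opt_state(model)
  history <- numeric(training$epochs)
  with_seed(training$seed, {
    for (epoch in seq_len(training$epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      for (from in seq(1, n, by = training$batch_size)) {
        batch <- perm[from:min(from + training$batch_size - 1L, n)]
        grads <- zero_like_grads(model)
        for (i in batch) {
          mask <- if (p > 0) {
            (stats::runif(spec$hidden) >= p) / (1 - p)
          } else NULL
          y <- numeric(spec$n_classes)
          y[cls[i]] <- 1
          fw <- nn_forward_single(model, images[[i]], geoms, mask)
          ep_loss <- ep_loss - log(max(fw$probs[cls[i]], 1e-12))
          grads <- add_grads(grads,
                             nn_backward_single(model, fw, y, geoms, mask))
        }
        grads <- scale_grads(grads, 1 / length(batch))
        out <- apply_nn_update(model, grads, state, optimizer_id,
                               training$learning_rate, trainable)
        model <- out$model
        state <- out$state
      }
      history[epoch] <- ep_loss / n
    }
  })
  attr(model, "history") <- history
  model
}

#' Class probabilities for a set of images
#'
#' Runs the model in inference mode (no dropout).
#'
#' @param model A `layered_model`.
#' @param images List of image arrays matching the model's input size.
#' @return Numeric matrix, one row per image, one softmax column per class
#'   (column order = the corpus `class_names` order used in training).
#' @export
predict_proba <- function(model, images) {
  stopifnot(inherits(model, "layered_model"))
  geoms <- conv_geometry(model$spec)
  t(vapply(images,
           function(img) nn_forward_single(model, img, geoms)$probs,
           numeric(model$spec$n_classes)))
}
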