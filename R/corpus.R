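# Synthetic network-image corpora. Each image is a drawing of a random
# preferential-attachment graph (spring layout, antialiased edges, node
# discs scaled by degree) rasterised onto a white canvas — a controllable
# stand-in for rendered single-cell gene regulatory networks. The two-class
# corpus separates "healthy" from "T2D" by the attachment density of the
# underlying graph; the multi-class source corpus varies both density and
# graph size and is used only for source-task pretraining.

#' Default per-class graph-generator settings for the binary corpus
#'
#' Classes differ in attachment density: each new node attaches to
#' `edges_per_step` existing nodes, so with `n_nodes = 60` the healthy
#' class carries roughly three times the edges of the T2D class. The
#' `edge_count_margin` entry states the minimum between-class gap in mean
#' edge count the corpus is expected to exhibit.
#'
#' @return Named list with elements `healthy`, `T2D` (each a list of
#'   `n_nodes`, `edges_per_step`, `power`) and `edge_count_margin`.
#' @export
default_class_params <- function() {
  list(
    healthy = list(n_nodes = 60L, edges_per_step = 3L, power = 1),
    T2D = list(n_nodes = 60L, edges_per_step = 1L, power = 1),
    edge_count_margin = 60
  )
}

# Sample one preferential-attachment graph and its 2-D spring layout.
# Uses the R RNG; callers seed it.
sample_network_drawing <- function(params) {
  g <- igraph::sample_pa(params$n_nodes, power = params$power,
                         m = params$edges_per_step, directed = FALSE)
  layout <- igraph::layout_with_fr(g)
  list(graph = g, layout = layout,
       n_edges = igraph::ecount(g),
       degree = igraph::degree(g))
}

# Rasterise a graph drawing onto a white square canvas in [0, 1].
# Ink is accumulated additively (bilinear splatting of points sampled along
# each edge, filled discs for nodes) and the canvas is 1 - min(ink, 1), so
# strokes are dark on white. Returns an image_size x image_size matrix.
rasterize_drawing <- function(drawing, image_size) {
  sz <- image_size
  ink <- matrix(0, sz, sz)
  xy <- drawing$layout
  # normalise layout into the canvas with a margin
  margin <- 0.06 * sz
  rng <- apply(xy, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-9)
  px <- margin + (xy[, 1] - rng[1, 1]) / span[1] * (sz - 2 * margin)
  py <- margin + (xy[, 2] - rng[1, 2]) / span[2] * (sz - 2 * margin)

  splat <- function(ink, xs, ys, w) {
    # bilinear deposition of weight w at continuous positions (xs, ys)
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    for (corner in 1:4) {
      cx <- x0 + (corner == 2 | corner == 4)
      cy <- y0 + (corner == 3 | corner == 4)
      wt <- w * (1 - abs(xs - cx)) * (1 - abs(ys - cy))
      keep <- cx >= 1 & cx <= sz & cy >= 1 & cy <= sz & wt > 0
      if (any(keep)) {
        idx <- cy[keep] + (cx[keep] - 1) * sz
        agg <- rowsum(wt[keep], idx)
        ii <- as.integer(rownames(agg))
        ink[ii] <- ink[ii] + agg[, 1]
      }
    }
    ink
  }

  ed <- igraph::as_edgelist(drawing$graph, names = FALSE)
  if (nrow(ed) > 0) {
    for (e in seq_len(nrow(ed))) {
      a <- ed[e, 1]; b <- ed[e, 2]
      len <- sqrt((px[a] - px[b])^2 + (py[a] - py[b])^2)
      n <- max(2L, ceiling(2 * len))
      t <- seq(0, 1, length.out = n)
      ink <- splat(ink, px[a] + t * (px[b] - px[a]),
                   py[a] + t * (py[b] - py[a]), w = 0.45)
    }
  }
  # node discs, radius growing with degree so hubs stand out
  r_base <- max(1, sz / 55)
  for (v in seq_along(px)) {
    r <- r_base * (0.8 + 0.35 * sqrt(drawing$degree[v]))
    cx <- seq(floor(px[v] - r), ceiling(px[v] + r))
    cy <- seq(floor(py[v] - r), ceiling(py[v] + r))
    cx <- cx[cx >= 1 & cx <= sz]; cy <- cy[cy >= 1 & cy <= sz]
    if (length(cx) && length(cy)) {
      dd <- outer(cy - py[v], cx - px[v], function(a, b) sqrt(a^2 + b^2))
      ink[as.matrix(expand.grid(cy, cx))[as.vector(dd <= r), , drop = FALSE]] <-
        ink[as.matrix(expand.grid(cy, cx))[as.vector(dd <= r), , drop = FALSE]] + 1
    }
  }
  1 - pmin(ink, 1)
}

# One rendered image: grey raster replicated to 3 channels,
# values in [0, 1], array (size, size, 3).
render_network_image <- function(params, image_size) {
  drawing <- sample_network_drawing(params)
  gr <- rasterize_drawing(drawing, image_size)
  list(image = array(rep(gr, 3), dim = c(image_size, image_size, 3)),
       n_edges = drawing$n_edges)
}

new_corpus <- function(images, labels, class_names, class_params,
                       image_size, seed, n_edges) {
  structure(
    list(images = images, labels = labels, class_names = class_names,
         class_params = class_params, image_size = as.integer(image_size),
         seed = as.integer(seed),
         graph_stats = data.frame(label = labels, n_edges = n_edges)),
    class = "network_image_corpus")
}

#' @export
print.network_image_corpus <- function(x, ...) {
  cat(sprintf("<network_image_corpus> %d images (%dx%d), classes: %s\n",
              length(x$images), x$image_size, x$image_size,
              paste(sprintf("%s=%d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}

#' Generate the balanced two-class network-image corpus
#'
#' Renders `n_images` synthetic regulatory-network drawings, split evenly
#' between the `"T2D"` and `"healthy"` classes (in that class order: the
#' healthy class is the positive class at index 2, whose score feeds the
#' 0.5 decision threshold). Deterministic under `seed`.
#'
#' @param n_images Total image count, even when `balanced`; default 224.
#' @param image_size Pixels per side, at least 32; default 64.
#' @param class_params Per-class generator settings, see
#'   [default_class_params()].
#' @param seed Integer seed.
#' @param balanced Require equal class counts (default `TRUE`).
#' @return A `network_image_corpus`: images (list of
#'   `size x size x 3` arrays in `[0, 1]`), labels, class names,
#'   generator settings and per-image graph statistics.
#' @export
generate_network_image_corpus <- function(n_images = 224L, image_size = 64L,
                                          class_params = default_class_params(),
                                          seed = 1L, balanced = TRUE) {
  if (image_size < 32) stop("image_size must be at least 32", call. = FALSE)
  if (balanced && n_images %% 2L != 0L) {
    stop("balanced generation requires an even n_images", call. = FALSE)
  }
  n_t2d <- n_images %/% 2L
  n_healthy <- n_images - n_t2d
  labels <- c(rep("T2D", n_t2d), rep("healthy", n_healthy))
  out <- with_seed(seed, {
    lapply(labels, function(lb) render_network_image(class_params[[lb]],
                                                     image_size))
  })
  new_corpus(images = lapply(out, `[[`, "image"), labels = labels,
             class_names = c("T2D", "healthy"), class_params = class_params,
             image_size = image_size, seed = seed,
             n_edges = vapply(out, `[[`, numeric(1), "n_edges"))
}

#' Generate a multi-class source-task corpus
#'
#' A corpus of structurally distinct network drawings (classes vary in
#' graph size and attachment density) used to pretrain the convolutional
#' base before transfer to the binary task. Images are distributed as
#' evenly as possible over the classes. Deterministic under `seed`.
#'
#' @param n_images Total image count.
#' @param n_classes Number of source classes, at least 2; default 4.
#' @param image_size Pixels per side; default 64.
#' @param seed Integer seed.
#' @return A `network_image_corpus` with classes `"S1"`, `"S2"`, ...
#' @export
make_source_task_corpus <- function(n_images = 200L, n_classes = 4L,
                                    image_size = 64L, seed = 1L) {
  if (n_classes < 2) stop("n_classes must be at least 2", call. = FALSE)
  grid <- expand.grid(edges_per_step = c(1L, 3L, 6L, 2L),
                      n_nodes = c(40L, 80L, 25L))
  params <- lapply(seq_len(n_classes), function(k) {
    row <- grid[((k - 1L) %% nrow(grid)) + 1L, ]
    list(n_nodes = row$n_nodes, edges_per_step = row$edges_per_step,
         power = 1)
  })
  class_names <- paste0("S", seq_len(n_classes))
  names(params) <- class_names
  counts <- rep(n_images %/% n_classes, n_classes)
  counts[seq_len(n_images %% n_classes)] <- counts[seq_len(n_images %% n_classes)] + 1L
  labels <- rep(class_names, counts)
  out <- with_seed(seed, {
    lapply(labels, function(lb) render_network_image(params[[lb]],
                                                     image_size))
  })
  new_corpus(images = lapply(out, `[[`, "image"), labels = labels,
             class_names = class_names, class_params = params,
             image_size = image_size, seed = seed,
             n_edges = vapply(out, `[[`, numeric(1), "n_edges"))
}

#' Subset a corpus by image index
#' @param corpus A `network_image_corpus`.
#' @param idx Integer indices to keep.
#' @return A `network_image_corpus` with the selected images.
#' @export
corpus_subset <- function(corpus, idx) {
  stopifnot(inherits(corpus, "network_image_corpus"))
  new_corpus(images = corpus$images[idx], labels = corpus$labels[idx],
             class_names = corpus$class_names,
             class_params = corpus$class_params,
             image_size = corpus$image_size, seed = corpus$seed,
             n_edges = corpus$graph_stats$n_edges[idx])
}

#' Persist a corpus as PNG files plus a manifest
#'
#' Writes one PNG per image and a `manifest.csv` with columns
#' `filename,label`, so downstream steps can re-run from disk.
#'
#' @param corpus A `network_image_corpus`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "network_image_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fns <- sprintf("img_%04d_%s.png", seq_along(corpus$images), corpus$labels)
  for (i in seq_along(corpus$images)) {
    png::writePNG(corpus$images[[i]], file.path(dir, fns[i]))
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(filename = fns, label = corpus$labels),
                   manifest, row.names = FALSE)
  invisible(manifest)
}

#' Load a corpus from its PNG + manifest layout
#'
#' @param dir Directory written by [write_corpus()].
#' @param class_names Optional class ordering; defaults to `c("T2D",
#'   "healthy")` when those are the labels present, otherwise sorted
#'   unique labels.
#' @return A `network_image_corpus`.
#' @export
read_corpus <- function(dir, class_names = NULL) {
  manifest <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest)) stop("no manifest.csv in ", dir, call. = FALSE)
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  images <- lapply(tab$filename, function(f) {
    img <- png::readPNG(file.path(dir, f))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  })
  if (is.null(class_names)) {
    class_names <- if (setequal(unique(tab$label), c("T2D", "healthy"))) {
      c("T2D", "healthy")
    } else sort(unique(tab$label))
  }
  new_corpus(images = images, labels = tab$label, class_names = class_names,
             class_params = NULL,
             image_size = dim(images[[1]])[1], seed = NA_integer_,
             n_edges = rep(NA_real_, nrow(tab)))
}
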