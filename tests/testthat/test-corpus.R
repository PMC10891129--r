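# Corpus tests use 32-pixel images and small counts: the generator's
# behaviour (balance, determinism, class separation) does not depend on
# the canvas size.

test_that("balanced generation splits classes evenly", {
  corp <- generate_network_image_corpus(n_images = 12, image_size = 32,
                                        seed = 1)
  expect_equal(as.vector(table(corp$labels)), c(6, 6))
  expect_equal(corp$class_names, c("T2D", "healthy"))
  expect_length(corp$images, 12)
  expect_true(all(vapply(corp$images, function(im)
    all(dim(im) == c(32, 32, 3)), logical(1))))
  rng <- range(unlist(lapply(corp$images, range)))
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 1)
  expect_error(generate_network_image_corpus(n_images = 11,
                                             image_size = 32),
               "even")
  expect_error(generate_network_image_corpus(n_images = 10,
                                             image_size = 16),
               "image_size")
})

test_that("regeneration with the same seed is bit-identical", {
  a <- generate_network_image_corpus(8, 32, seed = 42)
  b <- generate_network_image_corpus(8, 32, seed = 42)
  expect_identical(a$images, b$images)
  expect_identical(a$labels, b$labels)
  c <- generate_network_image_corpus(8, 32, seed = 43)
  expect_false(identical(a$images, c$images))
})

test_that("classes differ in graph density by at least the stated margin", {
  corp <- generate_network_image_corpus(40, 32, seed = 7)
  means <- tapply(corp$graph_stats$n_edges, corp$graph_stats$label, mean)
  expect_gte(means[["healthy"]] - means[["T2D"]],
             default_class_params()$edge_count_margin)
  # ... and the images reflect it: denser graphs put more ink on canvas
  intensity <- vapply(corp$images, mean, numeric(1))
  expect_lt(mean(intensity[corp$labels == "healthy"]),
            mean(intensity[corp$labels == "T2D"]))
})

test_that("class separation grows with the attachment-density gap", {
  gap_stat <- function(eps_t2d) {
    cp <- default_class_params()
    cp$T2D$edges_per_step <- eps_t2d
    corp <- generate_network_image_corpus(20, 32, class_params = cp,
                                          seed = 3)
    means <- tapply(corp$graph_stats$n_edges, corp$graph_stats$label, mean)
    means[["healthy"]] - means[["T2D"]]
  }
  gaps <- vapply(c(3L, 2L, 1L), gap_stat, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("source-task corpus is balanced, distinct and reproducible", {
  src <- make_source_task_corpus(40, n_classes = 4, image_size = 32,
                                 seed = 5)
  expect_equal(as.vector(table(src$labels)), rep(10, 4))
  expect_identical(src$images,
                   make_source_task_corpus(40, 4, 32, seed = 5)$images)
  # at least one pair of classes differs clearly in mean pixel intensity
  per_class <- tapply(vapply(src$images, mean, numeric(1)), src$labels,
                      mean)
  expect_gt(max(per_class) - min(per_class), 0.02)
  expect_error(make_source_task_corpus(10, n_classes = 1), "n_classes")
})

test_that("a corpus round-trips through the PNG + manifest layout", {
  corp <- generate_network_image_corpus(6, 32, seed = 2)
  dir <- withr::local_tempdir()
  write_corpus(corp, dir)
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(manifest), 6)
  expect_setequal(names(manifest), c("filename", "label"))
  back <- read_corpus(dir)
  expect_equal(back$labels, corp$labels)
  expect_equal(back$class_names, corp$class_names)
  # 8-bit PNG quantisation: images equal to within half a grey level
  err <- max(abs(unlist(back$images) - unlist(corp$images)))
  expect_lt(err, 1 / 255)
})

test_that("corpus_subset keeps images, labels and stats aligned", {
  corp <- generate_network_image_corpus(10, 32, seed = 4)
  sub <- corpus_subset(corp, c(2, 9, 5))
  expect_length(sub$images, 3)
  expect_identical(sub$labels, corp$labels[c(2, 9, 5)])
  expect_identical(sub$images[[1]], corp$images[[2]])
  expect_identical(sub$graph_stats$n_edges,
                   corp$graph_stats$n_edges[c(2, 9, 5)])
})
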