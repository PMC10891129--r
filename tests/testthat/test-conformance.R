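test_that("model_distance matches hand arithmetic and is symmetric", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  z <- c(1, 2, 3, 4)
  expect_equal(model_distance(x, z, x, z), 0)
  expect_equal(model_distance(x, z, x, z + 1), 2) # sqrt(4 * 1^2)
  set.seed(5)
  xa <- runif(10); za <- rnorm(10); xb <- runif(10); zb <- rnorm(10)
  expect_equal(model_distance(xa, za, xb, zb),
               model_distance(xb, zb, xa, za))
  # joint permutation of the paired indices leaves the distance unchanged
  p <- sample.int(10)
  expect_equal(model_distance(xa[p], za[p], xb[p], zb[p]),
               model_distance(xa, za, xb, zb))
  expect_error(model_distance(1:3, 1:3, 1:2, 1:2), "equal length")
})

test_that("shared abscissae reduce the distance to the prediction-vector norm", {
  set.seed(6)
  x <- runif(50)
  za <- rnorm(50)
  zb <- rnorm(50)
  expect_equal(model_distance(x, za, x, zb),
               sqrt(sum((za - zb)^2)), tolerance = 1e-12)
})

test_that("welch test reproduces the closed-form case and conventions", {
  out <- welch_t_test(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_equal(out$t, -1, tolerance = 1e-12)
  expect_equal(out$df, 8, tolerance = 1e-12)
  expect_equal(out$p, 2 * pt(-1, 8), tolerance = 1e-12)
  # identical samples
  same <- welch_t_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # zero variance, unequal means
  sep <- welch_t_test(c(1, 1), c(2, 2))
  expect_equal(sep$p, 0)
  # scale invariance
  a <- c(1.2, 3.4, 2.2, 4.1); b <- c(2.0, 2.5, 3.9, 1.1)
  s1 <- welch_t_test(a, b)
  s2 <- welch_t_test(10 * a, 10 * b)
  expect_equal(s1$t, s2$t)
  expect_equal(s1$p, s2$p)
})

# small fast configs for structural study tests
fast_configs <- function() {
  list(sgd = optimizer_config("sgd", max_iters = 40),
       rmsprop = optimizer_config("rmsprop", max_iters = 40),
       adam = optimizer_config("adam", max_iters = 40))
}

test_that("the study runs the requested number of paired fits", {
  st <- run_conformance_study("F1", n_runs = 9, m = 30, base_seed = 77,
                              configs = fast_configs())
  expect_s3_class(st, "conformance_study")
  expect_length(st$runs, 9)
  expect_equal(nrow(st$distances), 9)
  expect_true(all(st$distances$d_sa >= 0 & st$distances$d_sr >= 0))
  expect_equal(st$mean_d_sa, mean(st$distances$d_sa))
  expect_equal(st$mean_d_sr, mean(st$distances$d_sr))
  expect_gte(st$p_value, 0)
  expect_lte(st$p_value, 1)
  # per-run datasets are fresh draws
  expect_false(identical(st$runs[[1]]$dataset$x, st$runs[[2]]$dataset$x))
  # distances recompute from the stored fits
  r1 <- st$runs[[1]]
  expect_equal(r1$d_sa,
               model_distance(r1$dataset$x, r1$fit_sgd$predictions,
                              r1$dataset$x, r1$fit_adam$predictions))
})

test_that("studies are reproducible under the base seed", {
  s1 <- run_conformance_study("F2", n_runs = 3, m = 25, base_seed = 5,
                              configs = fast_configs())
  s2 <- run_conformance_study("F2", n_runs = 3, m = 25, base_seed = 5,
                              configs = fast_configs())
  expect_identical(s1$distances, s2$distances)
  s3 <- run_conformance_study("F2", n_runs = 3, m = 25, base_seed = 6,
                              configs = fast_configs())
  expect_false(identical(s1$distances, s3$distances))
})

test_that("study export writes the distance table, summary and figures", {
  st <- run_conformance_study("F3", n_runs = 4, m = 20, base_seed = 9,
                              configs = fast_configs())
  dir <- withr::local_tempdir()
  paths <- export_conformance_outputs(st, dir)
  csv <- file.path(dir, "distances_f3.csv")
  expect_true(file.exists(csv))
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 5) # 4 runs + 1 summary row
  expect_equal(tab$run[5], "mean")
  expect_true(file.exists(file.path(dir, "summary_f3.json")))
  # identical export twice -> identical bytes
  dir2 <- withr::local_tempdir()
  export_conformance_outputs(st, dir2)
  expect_identical(readLines(csv), readLines(file.path(dir2,
                                                       "distances_f3.csv")))
  # degenerate study refuses to export
  broken <- st
  broken$runs <- list()
  expect_error(export_conformance_outputs(broken, withr::local_tempdir()),
               "no runs")
})
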