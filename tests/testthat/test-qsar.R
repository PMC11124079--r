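make_fps <- function(n, seed = 1, max_bonds = 5L) {
  # small fingerprint set over a ladder of particle sizes
  diams <- seq(10, 16, length.out = n)
  lapply(seq_len(n), function(i) {
    s <- make_particle(lattice_spec("rocksalt", 4.18, "Ni", diams[i]))
    build_fingerprint(s, thickness = 5, max_bonds = max_bonds)
  })
}

test_that("assemble_features implements the three concatenation designs", {
  ds <- make_qsar_dataset(8, 3, beta = c(1, 0, -1), seed = 1)
  expect_identical(assemble_features(ds, list(), sections = integer(0)), ds)

  fps <- make_fps(8)
  m <- 5L
  t2 <- assemble_features(qsar_dataset(matrix(numeric(0), 8, 0), ds$target),
                          fps, sections = c(1, 2))
  expect_identical(ncol(t2$features), as.integer(6 + 2 * m))  # 16 columns
  t3 <- assemble_features(ds, fps, sections = c(1, 2))
  expect_identical(ncol(t3$features), ncol(ds$features) + ncol(t2$features))

  expect_error(assemble_features(ds, fps[1:3], sections = 2), "one fingerprint per")
  fps_mixed <- c(fps[1:7], make_fps(1, max_bonds = 4L))
  expect_error(assemble_features(ds, fps_mixed, sections = 2), "mixed max_bonds")
})

test_that("leave-one-out linear evaluation is exact on noiseless data", {
  ds <- make_qsar_dataset(20, 3, beta = c(2, -1, 0.5), noise = 0, seed = 3)
  rep <- evaluate_loo_linear(ds)
  expect_lt(rep$mse, 1e-20)
  expect_identical(length(rep$predictions), 20L)
})

test_that("rank-deficient designs are reported with the offending column", {
  x <- matrix(rnorm(30), 15, 2)
  x <- cbind(x, x[, 1] + x[, 2])
  colnames(x) <- c("a", "b", "c")
  ds <- qsar_dataset(x, rnorm(15))
  expect_error(evaluate_loo_linear(ds), "collinear")
})

test_that("LOO MSE approximates the residual variance", {
  sigma <- 0.5
  n <- 100; p <- 3
  mses <- vapply(1:50, function(seed) {
    ds <- make_qsar_dataset(n, p, beta = c(1, -1, 0.5), noise = sigma, seed = seed)
    evaluate_loo_linear(ds)$mse
  }, numeric(1))
  se <- sd(mses) / sqrt(length(mses))
  # E[LOO MSE] = sigma^2 * (1 + (p+1)/n) to first order (leverage optimism)
  expect_lt(abs(mean(mses) - sigma^2 * (1 + (p + 1) / n)), 3 * se)
})

test_that("cross-validated logistic evaluation separates separable data", {
  set.seed(2)
  x <- matrix(rnorm(200 * 3), 200, 3)
  x[, 1] <- x[, 1] + ifelse(runif(200) < 0.5, 3, -3)  # wide margin on x1
  y <- as.integer(x[, 1] > 0)
  ds <- qsar_dataset(x, y)
  rep <- evaluate_cv_logistic(ds, folds = 10, oversample = FALSE, seed = 1)
  expect_equal(rep$balanced_accuracy, 1.0)
  expect_equal(rep$recall, 1.0)
})

test_that("fold metrics follow the confusion-count definitions", {
  conf <- matrix(c(9, 8, 2, 1), 1, 4,
                 dimnames = list(NULL, c("tp", "tn", "fp", "fn")))
  m <- nanofp:::classification_metrics(conf)
  expect_equal(m$balanced_accuracy, (0.9 + 0.8) / 2)
  expect_equal(m$precision, 9 / 11)
  expect_equal(m$recall, 0.9)
  expect_equal(m$false_positives, 2)
  expect_equal(m$false_negatives, 1)
})

test_that("oversampling duplicates only training folds and lifts minority recall", {
  # imbalanced classes (~90/10): oversampled recall should beat plain recall
  # in the majority of seeds
  wins <- 0L
  ties <- 0L
  for (seed in 1:20) {
    ds <- make_qsar_dataset(150, 3, beta = c(1.5, 1, -0.5), kind = "logistic",
                            seed = seed, intercept = -2.5)
    if (sum(ds$target == 1) < 15) next
    r_plain <- evaluate_cv_logistic(ds, folds = 5, oversample = FALSE, seed = seed)
    r_over <- evaluate_cv_logistic(ds, folds = 5, oversample = TRUE, seed = seed)
    if (r_over$recall > r_plain$recall) wins <- wins + 1L
    if (r_over$recall == r_plain$recall) ties <- ties + 1L
  }
  expect_gt(wins, (20 - ties) / 2)
})

test_that("ridge fallback handles wide, collinear feature blocks", {
  skip_if_not_installed("glmnet")
  set.seed(6)
  x <- matrix(rnorm(60 * 3), 60, 3)
  x <- cbind(x, x[, 1], x[, 1] + x[, 2])  # deliberately collinear
  y <- as.integer(x[, 1] + rnorm(60, sd = 0.3) > 0)
  ds <- qsar_dataset(x, y)
  rep <- evaluate_cv_logistic(ds, folds = 5, oversample = FALSE, seed = 2,
                              ridge = TRUE)
  expect_gt(rep$balanced_accuracy, 0.8)
})

test_that("single-class targets and non-binary targets are rejected", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(evaluate_cv_logistic(qsar_dataset(x, rep(1, 20))), "single class")
  expect_error(evaluate_cv_logistic(qsar_dataset(x, rnorm(20))), "binary")
})

test_that("predict_ldh is the fitted linear form", {
  model <- structure(
    list(kind = "linear", intercept = 3,
         coefficients = c(size = 0, concentration = 0),
         feature_names = c("size", "concentration"), protocol = "manual"),
    class = "fitted_qsar")
  expect_equal(predict_ldh(model, size_nm = 30, concentration_mg_L = 100), 3)

  # fitted on synthetic data: prediction is linear in the inputs
  set.seed(4)
  x <- cbind(size = runif(30, 10, 50), concentration = runif(30, 10, 200))
  y <- 0.3 + 0.01 * x[, 1] + 0.002 * x[, 2] + rnorm(30, sd = 0.01)
  fit <- fit_linear_qsar(qsar_dataset(x, y))
  p1 <- predict_ldh(fit, 10, 50)
  p2 <- predict_ldh(fit, 20, 100)
  p3 <- predict_ldh(fit, 30, 150)
  expect_equal(p2 - p1, p3 - p2, tolerance = 1e-8)

  expect_error(predict_ldh(fit, size_nm = 30), "missing feature")
})

test_that("read_qsar_csv round-trips a feature table", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1:5, b = (1:5)^2, y = 2 * (1:5)), f, row.names = FALSE)
  ds <- read_qsar_csv(f, "y")
  expect_identical(colnames(ds$features), c("a", "b"))
  expect_equal(ds$target, 2 * (1:5))
  expect_error(read_qsar_csv(f, "nope"), "no column")
})
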