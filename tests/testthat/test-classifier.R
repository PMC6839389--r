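# Network construction, SCG optimizer, training, prediction, persistence.

make_gaussian_data <- function(n_per_class, p = 10, sep = 6, seed = 41) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p, 0), n_per_class, p),
             matrix(rnorm(n_per_class * p, sep), n_per_class, p))
  labeled_dataset(x, rep(c("benign", "malignant"), each = n_per_class))
}

test_that("labeled_dataset accepts labels or one-hot targets and validates", {
  x <- matrix(rnorm(12), 6, 2)
  d <- labeled_dataset(x, c("b", "a", "a", "b", "a", "b"))
  expect_identical(d$class_names, c("a", "b"))
  expect_identical(d$labels, c(2L, 1L, 1L, 2L, 1L, 2L))
  expect_equal(rowSums(d$targets), rep(1, 6))
  expect_equal(d$targets[cbind(1:6, d$labels)], rep(1, 6))

  onehot <- d$targets
  d2 <- labeled_dataset(x, onehot, class_names = c("a", "b"))
  expect_identical(d2$labels, d$labels)

  bad <- onehot
  bad[1, ] <- c(1, 1)
  expect_error(labeled_dataset(x, bad), class = "sonodct_input_error")
  expect_error(labeled_dataset(x, rep("c", 6), class_names = c("a", "b")),
               class = "sonodct_input_error")
  expect_error(labeled_dataset(matrix(NA_real_, 2, 2), c("a", "b")),
               class = "sonodct_numeric_error")
})

test_that("init_network is seed-deterministic with the documented topology", {
  n1 <- init_network(c(384L, 10L, 10L, 2L), seed = 7)
  n2 <- init_network(c(384L, 10L, 10L, 2L), seed = 7)
  expect_identical(n1$weights, n2$weights)
  expect_equal(dim(n1$weights[[1]]), c(10L, 384L))
  expect_equal(dim(n1$weights[[2]]), c(10L, 10L))
  expect_equal(dim(n1$weights[[3]]), c(2L, 10L))
  expect_true(all(abs(n1$weights[[1]]) <= 1 / sqrt(384)))
  expect_identical(n1$biases[[1]], numeric(10))
  n3 <- init_network(c(384L, 10L, 10L, 2L), seed = 8)
  expect_false(identical(n1$weights, n3$weights))
  expect_error(init_network(c(5L)), class = "sonodct_config_error")
})

test_that("analytic gradient matches central finite differences", {
  set.seed(42)
  layer_sizes <- c(3L, 4L, 2L)
  X <- matrix(rnorm(18), 6, 3)
  targets <- diag(2)[sample(1:2, 6, replace = TRUE), ]
  w <- rnorm(3 * 4 + 4 * 2 + 4 + 2, sd = 0.5)
  for (reg in c(0, 0.3)) {
    fn <- function(w) sonodct:::.net_loss_grad(w, layer_sizes, X, targets, reg = reg)
    g <- fn(w)$grad
    h <- 1e-6
    g_num <- vapply(seq_along(w), function(i) {
      e <- numeric(length(w)); e[i] <- h
      (fn(w + e)$loss - fn(w - e)$loss) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - g_num)), 1e-6)
  }
})

test_that("SCG solves a convex quadratic to high precision", {
  set.seed(43)
  A <- crossprod(matrix(rnorm(25), 5, 5)) + diag(5)
  b <- rnorm(5)
  fn <- function(w) list(loss = 0.5 * sum(w * (A %*% w)) - sum(b * w),
                         grad = as.numeric(A %*% w - b))
  res <- sonodct:::.scg_optimize(numeric(5), fn, max_iter = 200L, grad_tol = 1e-10)
  expect_equal(res$w, as.numeric(solve(A, b)), tolerance = 1e-6)
  # accepted steps never increase the loss
  expect_true(all(diff(res$loss_curve) <= 1e-12))
})

test_that("train is deterministic given the seed", {
  d <- make_gaussian_data(20)
  m1 <- train(d, seed = 5)
  m2 <- train(d, seed = 5)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$biases, m2$biases)
  expect_identical(m1$training_meta$loss_curve, m2$training_meta$loss_curve)
  expect_identical(predict(m1, d$features), predict(m2, d$features))
  m3 <- train(d, seed = 6)
  expect_false(identical(m1$weights, m3$weights))
})

test_that("uninformative features converge to chance: CE = ln 2, accuracy 1/2", {
  x <- matrix(1, 40, 3)
  d <- labeled_dataset(x, rep(c("a", "b"), each = 20))
  m <- train(d, config = list(max_epochs = 200L), seed = 1)
  expect_equal(m$training_meta$final_train_loss, log(2), tolerance = 1e-3)
  metrics <- evaluate(m, d)
  expect_equal(metrics$accuracy, 0.5, tolerance = 1e-12)
})

test_that("well-separated Gaussian classes are learned nearly perfectly", {
  d <- make_gaussian_data(40)
  m <- train(d, seed = 2)
  test_idx <- m$training_meta$split$test
  held <- labeled_dataset(d$features[test_idx, , drop = FALSE],
                          d$class_names[d$labels[test_idx]],
                          class_names = d$class_names)
  metrics <- evaluate(m, held)
  expect_gte(metrics$accuracy, 0.9)
  expect_gte(metrics$auc, 0.95)
})

test_that("training errors name the failure", {
  x <- matrix(rnorm(10), 5, 2)
  d <- labeled_dataset(x, rep("only", 5), class_names = c("only", "absent"))
  err <- expect_error(train(d), class = "sonodct_training_error")
  expect_match(conditionMessage(err), "absent")
})

test_that("the gd fallback optimizer trains too", {
  d <- make_gaussian_data(15)
  m <- train(d, config = list(optimizer = "gd", max_epochs = 300L), seed = 3)
  expect_gte(evaluate(m, d)$accuracy, 0.9)
})

test_that("save_model/load_model reproduce predictions and decisions", {
  d <- make_gaussian_data(15)
  m <- train(d, seed = 4)
  p <- tempfile(fileext = ".json")
  save_model(m, p)
  m2 <- load_model(p)
  p1 <- predict(m, d$features)
  p2 <- predict(m2, d$features)
  # JSON stores decimal text, so posteriors agree to near machine precision
  # and the decisions agree exactly
  expect_equal(p2, p1, tolerance = 1e-12)
  expect_identical(max.col(p2), max.col(p1))
  expect_identical(m2$class_names, m$class_names)
  expect_identical(m2$layer_sizes, m$layer_sizes)

  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "other"), bad, auto_unbox = TRUE)
  expect_error(load_model(bad), class = "sonodct_format_error")
})

test_that("predict rejects mismatched feature length", {
  d <- make_gaussian_data(10)
  m <- train(d, seed = 1)
  expect_error(predict(m, matrix(0, 1, 3)), class = "sonodct_dimension_error")
})
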