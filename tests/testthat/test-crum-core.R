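test_that("gaussian kernel has closed form, symmetry and identity at zero distance", {
  expect_equal(gaussian_kernel(c(1, 2, 3), c(1, 2, 3), 0.7), 1.0)
  expect_equal(gaussian_kernel(c(0, 0), c(2, 0), 0.125), exp(-0.5))
  set.seed(42)
  for (i in 1:100) {
    x <- rnorm(3)
    u <- rnorm(3)
    g <- runif(1, 0.01, 2)
    expect_identical(gaussian_kernel(x, u, g), gaussian_kernel(u, x, g))
    expect_gt(gaussian_kernel(x, u, g), 0)
    expect_lte(gaussian_kernel(x, u, g), 1)
  }
  expect_error(gaussian_kernel(c(1, 2), c(1, 2, 3), 1), "dimension")
  expect_error(gaussian_kernel(c(1, 2), c(1, 2), -1), "positive")
})

test_that("kernel matrix agrees with elementwise kernel evaluations", {
  set.seed(7)
  X <- matrix(rnorm(12), 4, 3)
  U <- matrix(rnorm(6), 2, 3)
  Km <- kernel_matrix(X, U, 0.3)
  for (n in 1:4) {
    for (m in 1:2) {
      expect_equal(Km[n, m], gaussian_kernel(X[n, ], U[m, ], 0.3))
    }
  }
})

test_that("binary posterior follows the sigmoid kernel expansion", {
  units <- rbind(c(0, 0), c(1, 1))
  kern <- kernel_spec(1)
  m0 <- binary_crum(units, weights = c(0, 0), bias = 0, kernel = kern)
  expect_equal(predict_binary(m0, c(0.3, -0.2)), 0.5)

  m1 <- binary_crum(matrix(c(1, 2), 1), weights = 1, bias = 0, kernel = kern)
  expect_equal(predict_binary(m1, c(1, 2)), plogis(1))

  # with a single positive weight, moving away from the unit strictly
  # decreases the posterior
  d <- seq(0, 3, by = 0.5)
  p <- vapply(d, function(s) predict_binary(m1, c(1 + s, 2)), numeric(1))
  expect_true(all(diff(p) < 0))

  expect_error(predict_binary(m1, c(1, 2, 3)), "dimension")
})

test_that("binary posterior is strictly inside (0, 1) even for extreme weights", {
  kern <- kernel_spec(0.5)
  m <- binary_crum(matrix(0, 1, 1), weights = 1e4, bias = 1e4, kernel = kern)
  p <- predict_binary(m, 0)
  expect_lt(p, 1)
  expect_gt(p, 0)
  m2 <- binary_crum(matrix(0, 1, 1), weights = -1e4, bias = -1e4, kernel = kern)
  expect_gt(predict_binary(m2, 0), 0)
})

train_blob_crum <- function(seed = 101, sigma = 1, separation = 10) {
  data <- gaussian_blobs(
    rbind(c(0, 0), c(separation * sigma, 0)),
    n_per_class = 100L, sigma = sigma, seed = seed
  )
  pos <- data$features[data$labels == "class1", ]
  neg <- data$features[data$labels == "class2", ]
  cl <- kmeans_centers(data$features, 4L, seed = seed)
  kern <- kernel_spec(compute_gamma(cl$centers))
  list(
    model = train_binary_crum(pos, neg, cl$centers, kern),
    pos = pos, neg = neg, kern = kern, units = cl$centers
  )
}

test_that("well-separated blobs are classified perfectly at the 0.5 cutoff", {
  fit <- train_blob_crum()
  p_pos <- predict_binary(fit$model, fit$pos)
  p_neg <- predict_binary(fit$model, fit$neg)
  expect_true(all(p_pos > 0.5))
  expect_true(all(p_neg < 0.5))
})

test_that("training is deterministic and meets its own stationarity contract", {
  fit1 <- train_blob_crum()
  fit2 <- train_blob_crum()
  expect_identical(fit1$model$weights, fit2$model$weights)
  expect_identical(fit1$model$bias, fit2$model$bias)
  expect_identical(fit1$model$alpha, fit2$model$alpha)

  # gradient max-norm of the penalized loss at the solution
  expect_lte(fit1$model$fit$grad_max, 10 * fit1$model$fit$tol)
  # every inner Newton solve logged a non-increasing objective
  for (trace in fit1$model$fit$objective_traces) {
    expect_true(all(diff(trace) <= 1e-10))
  }
})

test_that("indistinguishable classes yield a near-symmetric mean posterior", {
  set.seed(303)
  X <- matrix(rnorm(400), ncol = 2)
  pos <- X[1:100, ]
  neg <- X[101:200, ]
  cl <- kmeans_centers(X, 4L, seed = 303)
  kern <- kernel_spec(compute_gamma(cl$centers))
  model <- suppressWarnings( # alpha may oscillate without class signal
    train_binary_crum(pos, neg, cl$centers, kern)
  )
  mean_p <- mean(predict_binary(model, X))
  expect_gte(mean_p, 0.45)
  expect_lte(mean_p, 0.55)
})

test_that("stronger fixed regularization shrinks the learned weights", {
  fit <- train_blob_crum()
  X <- rbind(fit$pos, fit$neg)
  t <- c(rep(1, nrow(fit$pos)), rep(0, nrow(fit$neg)))
  Phi <- cbind(kernel_matrix(X, fit$units, fit$kern$gamma), 1)
  beta0 <- rep(0, ncol(Phi))
  w_norm <- vapply(c(1e-6, 1e-2, 1, 1e2, 1e6), function(alpha) {
    beta <- mcrum:::crum_newton(beta0, Phi, t, alpha)$beta
    sqrt(sum(beta[-length(beta)]^2))
  }, numeric(1))
  expect_true(all(diff(w_norm) < 0))
})

test_that("degenerate and invalid training inputs are reported", {
  kern <- kernel_spec(1)
  units <- matrix(c(0, 5), ncol = 1)
  expect_warning(
    train_binary_crum(matrix(0, 1, 1), matrix(c(4, 5, 6), ncol = 1), units, kern),
    "single training point"
  )
  expect_error(
    train_binary_crum(matrix(0, 0, 1), matrix(1, 1, 1), units, kern),
    "at least one"
  )
})
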