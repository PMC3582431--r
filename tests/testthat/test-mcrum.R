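test_that("training partitions follow the coding matrix columns", {
  data <- make_blobs(seed = 61, n = 40L)
  ap <- train_mcrum(data, code = "ap", M = 4L, seed = 61)
  # all-pairs: each column sees exactly two of the three classes
  expect_identical(ap$train_counts, rep(80L, 3))
  expect_identical(length(ap$classifiers), 3L)

  ovr <- train_mcrum(data, code = "ovr", M = 4L, seed = 61)
  expect_identical(ovr$train_counts, rep(120L, 3))

  # a column whose positive class is absent from the data must be named
  sparse_labels <- ifelse(data$labels == "class3", "class2", data$labels)
  bad <- labeled_dataset(data$features, sparse_labels,
                         class_names = c("class1", "class2", "class3"))
  expect_error(
    train_mcrum(bad, code = "ovr", M = 4L, seed = 61),
    "column 3 has an empty positive"
  )
})

test_that("training with the same seed is byte-identical on disk", {
  data <- make_blobs(seed = 62, n = 30L)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  save_mcrum(train_mcrum(data, code = "ap", M = 4L, seed = 7), f1)
  save_mcrum(train_mcrum(data, code = "ap", M = 4L, seed = 7), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("threshold semantics: argmax above, unclassified below", {
  data <- make_blobs(seed = 63, n = 40L)
  model <- train_mcrum(data, code = "ap", M = 4L, seed = 63)
  pred0 <- predict_mcrum(model, data$features, decoder = "naive", threshold = 0)
  idx <- max.col(pred0$posterior, ties.method = "first")
  expect_identical(pred0$label, model$class_names[idx])
  expect_false(any(pred0$label == UNCLASSIFIED))

  for (t in c(0.6, 0.9, 0.999)) {
    pred_t <- predict_mcrum(model, data$features, decoder = "naive", threshold = t)
    maxp <- pred_t$posterior[cbind(seq_along(idx), idx)]
    expect_identical(pred_t$label == UNCLASSIFIED, maxp < t)
  }

  # rejected fraction is non-decreasing in the threshold
  fr <- vapply(seq(0, 0.95, by = 0.05), function(t) {
    mean(predict_mcrum(model, data$features, "naive", threshold = t)$label == UNCLASSIFIED)
  }, numeric(1))
  expect_true(!is.unsorted(fr))

  expect_error(
    predict_mcrum(model, data$features, decoder = "hard", threshold = 0.5),
    "hard decoding"
  )
  expect_error(
    predict_mcrum(model, data$features, decoder = "naive", threshold = 1),
    "threshold"
  )
})

test_that("separable three-class blobs are classified almost perfectly", {
  train <- make_blobs(seed = 64, n = 100L)
  test <- make_blobs(seed = 65, n = 100L)
  for (code in c("ap", "ovr")) {
    model <- train_mcrum(train, code = code, seed = 64)
    pred <- predict_mcrum(model, test$features, decoder = "naive")
    expect_gte(mean(pred$label == test$labels), 0.95)
  }
})

test_that("naive and Bradley-Terry decoding agree on a clustered non-linear task", {
  # ring-and-blobs layout: class 1 encircles class 2; linearly inseparable
  # but well clustered
  make_ring <- function(seed) {
    mcrum:::with_seed(seed, {
      n <- 80L
      theta <- runif(n, 0, 2 * pi)
      ring <- cbind(6 * cos(theta), 6 * sin(theta)) + matrix(rnorm(2 * n, sd = 0.5), n)
      inner <- matrix(rnorm(2 * n, sd = 0.8), n)
      far <- cbind(rnorm(n, 15, 0.8), rnorm(n, 0, 0.8))
      labeled_dataset(
        rbind(ring, inner, far),
        rep(c("ring", "inner", "far"), each = n)
      )
    })
  }
  train <- make_ring(71)
  test <- make_ring(72)
  model <- train_mcrum(train, code = "ap", seed = 71)
  p_naive <- predict_mcrum(model, test$features, decoder = "naive")
  p_gbt <- predict_mcrum(model, test$features, decoder = "gbt")
  expect_gte(mean(p_naive$label == p_gbt$label), 0.95)
  expect_gte(mean(p_naive$label == test$labels), 0.9)
})

test_that("models survive a lossless save/load round trip", {
  data <- make_blobs(seed = 66, n = 30L)
  model <- train_mcrum(data, code = "ap", M = 4L, seed = 66)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  save_mcrum(model, f1)
  loaded <- load_mcrum(f1)
  save_mcrum(loaded, f2)
  expect_identical(readLines(f1), readLines(f2))

  probe <- mcrum:::with_seed(100, matrix(rnorm(200), ncol = 2) * 5)
  for (dec in c("naive", "gbt")) {
    expect_identical(
      predict_mcrum(model, probe, decoder = dec)$posterior,
      predict_mcrum(loaded, probe, decoder = dec)$posterior
    )
  }
  expect_identical(
    predict_mcrum(model, probe, decoder = "hard")$label,
    predict_mcrum(loaded, probe, decoder = "hard")$label
  )
})

test_that("corrupt or foreign model files are rejected with schema errors", {
  data <- make_blobs(seed = 67, n = 20L)
  model <- train_mcrum(data, code = "ovr", M = 3L, seed = 67)
  f <- tempfile(fileext = ".json")
  save_mcrum(model, f)

  truncated <- tempfile(fileext = ".json")
  txt <- readLines(f)
  writeLines(substr(txt, 1, nchar(txt) %/% 2), truncated)
  expect_error(load_mcrum(truncated), "not a readable model file")

  foreign <- tempfile(fileext = ".json")
  writeLines('{"foo": 1}', foreign)
  expect_error(load_mcrum(foreign), "schema_version")

  wrong <- tempfile(fileext = ".json")
  writeLines(sub('"schema_version":"1.0"', '"schema_version":"9.9"', txt), wrong)
  expect_error(load_mcrum(wrong), "schema version 9.9")
})
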