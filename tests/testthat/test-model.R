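test_that("model specs pin the two architectures", {
  s1 <- model_spec(1)
  expect_equal(s1$recurrent_units, c(256, 128, 64))
  expect_equal(s1$dropout_rates, c(0.15, 0.20, 0.20))
  expect_equal(s1$dense_units, c(512, 256, 128))
  expect_equal(s1$output_activation, "sigmoid")
  expect_equal(s1$n_classes, 2)
  s2 <- model_spec(2)
  expect_equal(s2$recurrent_units, c(128, 64))
  expect_equal(s2$dropout_rates, c(0.15, 0.20))
  expect_equal(s2$dense_units, c(256, 128))
  expect_equal(s2$output_activation, "softmax")
  expect_equal(s2$n_classes, 3)
  expect_error(model_spec(1, recurrent_units = c(8, 4),
                          dropout_rates = c(0.1)), "equal length")
})

test_that("built models expose the specified layer widths", {
  m1 <- build_model(model_spec(1), seed = 1)
  expect_equal(model_widths(m1), c(256, 128, 64, 512, 256, 128))
  m2 <- build_model(model_spec(2), seed = 1)
  expect_equal(model_widths(m2), c(128, 64, 256, 128))
  # scaled-down divides widths by 8
  ms <- build_model(model_spec(1, scaled_down = TRUE), seed = 1)
  expect_equal(model_widths(ms), c(32, 16, 8, 64, 32, 16))
  expect_equal(ms$spec$input_length, 200)
})

test_that("training configs pair each scenario with its loss and optimizer", {
  t1 <- train_config(1)
  expect_equal(t1$loss, "binary_crossentropy")
  expect_equal(t1$optimizer, "rmsprop")
  expect_equal(t1$split, c(0.70, 0.15, 0.15))
  expect_equal(t1$epochs, 500L)
  t2 <- train_config(2)
  expect_equal(t2$loss, "categorical_crossentropy")
  expect_equal(t2$optimizer, "adam")
  expect_error(train_config(1, split = c(0.75, 0.15, 0.15)), "sum to 1")
})

test_that("split_dataset partitions exactly, stratified and reproducibly", {
  ds <- tiny_dataset(n = 100, len = 10, labels = c("a", "b"))
  sp <- split_dataset(ds, c(0.70, 0.15, 0.15), seed = 5)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 70L, validation = 15L, test = 15L))
  # stratification: each partition mirrors the 50/50 balance
  expect_equal(unname(table(sp$train$label)), c(35L, 35L),
               ignore_attr = TRUE)
  # disjoint and exhaustive
  all_ids <- c(sp$train$id, sp$validation$id, sp$test$id)
  expect_setequal(all_ids, ds$id)
  expect_equal(anyDuplicated(all_ids), 0L)
  # deterministic under the seed
  sp2 <- split_dataset(ds, c(0.70, 0.15, 0.15), seed = 5)
  expect_identical(sp$train$id, sp2$train$id)
  expect_error(split_dataset(ds, c(0.75, 0.15, 0.15)), "sum to 1")
  tiny <- tiny_dataset(n = 4, labels = c("a", "a", "a", "b"))
  expect_error(split_dataset(tiny), "fewer members")
})

test_that("a two-epoch smoke run records history and is seed-reproducible", {
  ds <- tiny_dataset(n = 60, len = 40, labels = c("a", "b"), seed = 2)
  x <- encode_matrix(ds, "bfdna", input_length = 40)
  spec <- model_spec(1, input_length = 40, recurrent_units = c(4),
                     dropout_rates = c(0.1), dense_units = c(8))
  tc <- train_config(1, epochs = 2, seed = 9)
  m1 <- train_model(build_model(spec, seed = 9), x, ds$label, config = tc)
  expect_equal(nrow(m1$history), 2L)
  expect_true(all(is.finite(m1$history$loss)))
  m2 <- train_model(build_model(spec, seed = 9), x, ds$label, config = tc)
  expect_identical(m1$history$loss, m2$history$loss)
})

test_that("training on separable synthetic data converges", {
  cfg <- preset_separable("strong", 2, n_per_class = 50,
                          length_range = c(200, 400), seed = 7)
  ds <- generate_dataset(cfg)
  x <- encode_matrix(ds, "bfdna", input_length = 100)
  spec <- model_spec(1, input_length = 100, scale = 16)
  tc <- train_config(1, epochs = 10, seed = 7)
  m <- train_model(build_model(spec, seed = 7), x, ds$label, config = tc)
  expect_gt(tail(m$history$acc, 1), 0.95)
})

test_that("evaluation emits a standard report row with matching marginals", {
  cfg <- preset_separable("strong", 3, n_per_class = 40,
                          length_range = c(200, 400), seed = 8)
  ds <- generate_dataset(cfg)
  res <- suppressWarnings(run_scenario(
    ds, "bfdna", 2,
    spec = model_spec(2, input_length = 80, scale = 16),
    config = train_config(2, epochs = 4, seed = 8)))
  ev <- res$evaluation
  expect_s3_class(ev, "evaluation_result")
  expect_named(ev$row, c("accuracy", "precision", "recall", "f1", "csi",
                         "gmean", "mcc", "kappa", "auc"))
  cm <- ev$report$confusion
  expect_equal(dim(cm), c(3L, 3L))
  # truth marginals equal the test-set class counts (stratified 6 per class)
  expect_equal(unname(rowSums(cm)),
               unname(table(res$splits$test$label)[rownames(cm)]),
               ignore_attr = TRUE)
  # no leakage between partitions
  expect_length(intersect(res$splits$train$id, res$splits$test$id), 0)
  expect_length(intersect(res$splits$train$id, res$splits$validation$id), 0)
  expect_length(intersect(res$splits$validation$id, res$splits$test$id), 0)
})

test_that("BFDNA is at least as accurate as integer encoding (5-seed median)", {
  acc_for <- function(scheme, seed) {
    ds <- generate_dataset(preset_separable(
      "strong", 2, n_per_class = 100, length_range = c(500, 1500),
      seed = seed))
    r <- run_scenario(ds, scheme, 1,
                      spec = model_spec(1, scaled_down = TRUE),
                      config = train_config(1, epochs = 10, seed = seed))
    r$evaluation$report$metrics[["accuracy"]]
  }
  seeds <- 1:5
  suppressWarnings({
    acc_bfdna <- vapply(seeds, function(s) acc_for("bfdna", s), numeric(1))
    acc_integer <- vapply(seeds, function(s) acc_for("integer", s),
                          numeric(1))
  })
  expect_gte(median(acc_bfdna), median(acc_integer))
})

test_that("labels outside the training universe are rejected", {
  ds <- tiny_dataset(n = 20, len = 20, labels = c("a", "b"))
  x <- encode_matrix(ds, "integer", input_length = 20)
  spec <- model_spec(1, input_length = 20, recurrent_units = c(3),
                     dropout_rates = c(0), dense_units = c(4))
  m <- train_model(build_model(spec, seed = 3), x, ds$label,
                   config = train_config(1, epochs = 1, seed = 3))
  expect_error(
    train_model(build_model(spec, seed = 3), x, rep(c("a", "zz"), 10),
                config = train_config(1, epochs = 1, seed = 3),
                class_levels = c("a", "b")),
    "universe")
  expect_error(evaluate_model(m, x[0, , drop = FALSE], character(0)),
               "empty test set")
})
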