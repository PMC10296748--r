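#' Specification of one of the two classifier stacks
#'
#' Scenario 1 (binary, human vs mouse enhancer): three bidirectional LSTM
#' layers of 256/128/64 units with SELU activation and dropout 0.15/0.20/0.20
#' after each, then batch normalization, flatten, dense layers of 512/256/128
#' units, and a single sigmoid output. Scenario 2 (3 classes: human enhancer,
#' mouse enhancer, no enhancer): BiLSTM 128/64 with dropout 0.15/0.20, batch
#' normalization, flatten, dense 256/128, softmax output.
#'
#' \code{scale} divides every layer width (e.g. \code{scale = 8} gives the
#' desk-scale stack used in the test suite); widths are floored at 1.
#'
#' @param scenario 1 or 2.
#' @param input_length Fixed model input length (default 1024 full-scale,
#'   200 when \code{scaled_down}).
#' @param scale Integer divisor applied to all unit counts (default 1).
#' @param scaled_down Convenience flag: sets \code{scale = 8} and
#'   \code{input_length = 200} unless given explicitly.
#' @param recurrent_units,dropout_rates,dense_units Optional overrides; the
#'   recurrent and dropout lists must have equal length.
#' @return A \code{model_spec} list.
#' @export
model_spec <- function(scenario, input_length = NULL, scale = NULL,
                       scaled_down = FALSE, recurrent_units = NULL,
                       dropout_rates = NULL, dense_units = NULL) {
  stopifnot(scenario %in% c(1, 2))
  if (scaled_down) {
    if (is.null(scale)) scale <- 8
    if (is.null(input_length)) input_length <- 200
  }
  if (is.null(scale)) scale <- 1
  if (is.null(input_length)) input_length <- 1024
  defaults <- if (scenario == 1) {
    list(recurrent_units = c(256, 128, 64),
         dropout_rates = c(0.15, 0.20, 0.20),
         dense_units = c(512, 256, 128),
         output_activation = "sigmoid", n_classes = 2)
  } else {
    list(recurrent_units = c(128, 64),
         dropout_rates = c(0.15, 0.20),
         dense_units = c(256, 128),
         output_activation = "softmax", n_classes = 3)
  }
  ru <- if (is.null(recurrent_units)) pmax(1L, defaults$recurrent_units %/% scale)
        else recurrent_units
  dr <- if (is.null(dropout_rates)) defaults$dropout_rates else dropout_rates
  du <- if (is.null(dense_units)) pmax(1L, defaults$dense_units %/% scale)
        else dense_units
  if (length(ru) != length(dr))
    stop("recurrent_units and dropout_rates must have equal length",
         call. = FALSE)
  structure(list(
    scenario = scenario, recurrent_units = ru, dropout_rates = dr,
    dense_units = du, recurrent_activation = "selu",
    output_activation = defaults$output_activation,
    n_classes = defaults$n_classes, input_length = input_length
  ), class = "model_spec")
}

#' Training configuration for one scenario
#'
#' Scenario 1 trains with binary cross-entropy and RMSProp; scenario 2 with
#' categorical cross-entropy and Adam. The default split is 70% training,
#' 15% validation, 15% test.
#'
#' @param scenario 1 or 2.
#' @param epochs Number of training epochs (default 500 at full scale).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Optimizer step size (default 0.001).
#' @param split Numeric (train, validation, test) fractions summing to 1.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return A \code{train_config} list.
#' @export
train_config <- function(scenario, epochs = 500, batch_size = 32,
                         learning_rate = 1e-3,
                         split = c(0.70, 0.15, 0.15), seed = 42) {
  stopifnot(scenario %in% c(1, 2), epochs >= 1, batch_size >= 1)
  if (abs(sum(split) - 1) > 1e-9)
    stop("split fractions must sum to 1", call. = FALSE)
  structure(list(
    scenario = scenario, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), learning_rate = learning_rate,
    split = split, seed = as.integer(seed),
    loss = if (scenario == 1) "binary_crossentropy"
           else "categorical_crossentropy",
    optimizer = if (scenario == 1) "rmsprop" else "adam"
  ), class = "train_config")
}

#' Build a classifier from a model specification
#'
#' Layer order: for each recurrent stage, a bidirectional LSTM emitting
#' per-position outputs followed by dropout; then batch normalization,
#' flatten, the dense stack (SELU), and a linear output layer whose
#' activation (sigmoid or softmax) is fused into the loss.
#'
#' @param spec A \code{\link{model_spec}}.
#' @param seed Integer seed for weight initialization.
#' @return A \code{bfdna_model} list with elements \code{layers},
#'   \code{spec}, \code{widths}.
#' @export
build_model <- function(spec, seed = 42) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(seed)
  layers <- list()
  d_in <- 1L
  for (k in seq_along(spec$recurrent_units)) {
    u <- spec$recurrent_units[k]
    layers <- c(layers, list(layer_bilstm(d_in, u)),
                list(layer_dropout(spec$dropout_rates[k])))
    d_in <- 2L * u
  }
  layers <- c(layers, list(layer_batchnorm(d_in)), list(layer_flatten()))
  d_in <- d_in * spec$input_length
  for (u in spec$dense_units) {
    layers <- c(layers, list(layer_dense(d_in, u, "selu")))
    d_in <- u
  }
  n_out <- if (spec$output_activation == "sigmoid") 1L else spec$n_classes
  layers <- c(layers, list(layer_dense(d_in, n_out, "linear")))
  structure(list(layers = layers, spec = spec,
                 widths = c(spec$recurrent_units, spec$dense_units)),
            class = "bfdna_model")
}

#' @export
print.bfdna_model <- function(x, ...) {
  cat(sprintf(
    "<bfdna_model> scenario %d: BiLSTM[%s] dropout[%s] -> BN -> flatten -> dense[%s] -> %s (%d classes), input length %d\n",
    x$spec$scenario, paste(x$spec$recurrent_units, collapse = ","),
    paste(x$spec$dropout_rates, collapse = ","),
    paste(x$spec$dense_units, collapse = ","),
    x$spec$output_activation, x$spec$n_classes, x$spec$input_length))
  invisible(x)
}

#' Trainable layer widths of a built model
#' @param model A \code{bfdna_model}.
#' @return Integer vector: recurrent units then dense units, in layer order.
#' @export
model_widths <- function(model) model$widths

#' Split a dataset into train / validation / test partitions
#'
#' Disjoint, exhaustive and reproducible under \code{seed}. With
#' \code{stratified = TRUE} (default) the split is performed per class using
#' largest-remainder rounding so every partition mirrors the class balance.
#'
#' @param dataset A \code{\link{dna_dataset}}.
#' @param fractions Numeric (train, validation, test) summing to 1.
#' @param seed Integer seed.
#' @param stratified Stratify by label (default \code{TRUE}).
#' @return List with elements \code{train}, \code{validation}, \code{test}.
#' @export
split_dataset <- function(dataset, fractions = c(0.70, 0.15, 0.15),
                          seed = 42, stratified = TRUE) {
  stopifnot(inherits(dataset, "dna_dataset"), nrow(dataset) > 0)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("split fractions must sum to 1", call. = FALSE)
  # Largest-remainder rounding with a cumulative-deficit tie-break: each
  # remainder seat goes to the partition furthest behind its running target
  # over the classes processed so far, so the aggregate sizes track
  # round(fractions * n) exactly whenever that is attainable.
  target <- c(0, 0, 0)
  alloc <- c(0, 0, 0)
  assign_sizes <- function(n) {
    raw <- fractions * n
    sizes <- floor(raw)
    rem <- n - sum(sizes)
    target <<- target + raw
    if (rem > 0) {
      deficit <- target - (alloc + sizes)
      extra <- order(deficit, decreasing = TRUE)[seq_len(rem)]
      sizes[extra] <- sizes[extra] + 1
    }
    alloc <<- alloc + sizes
    sizes
  }
  set.seed(seed)
  part <- integer(nrow(dataset))
  if (stratified) {
    for (cl in unique(dataset$label)) {
      ix <- which(dataset$label == cl)
      if (length(ix) < 3)
        stop(sprintf("class '%s' has fewer members (%d) than partitions",
                     cl, length(ix)), call. = FALSE)
      sizes <- assign_sizes(length(ix))
      shuffled <- sample(ix)
      part[shuffled] <- rep(1:3, times = sizes)
    }
  } else {
    sizes <- assign_sizes(nrow(dataset))
    shuffled <- sample(nrow(dataset))
    part[shuffled] <- rep(1:3, times = sizes)
  }
  out <- lapply(1:3, function(k) {
    d <- dataset[part == k, , drop = FALSE]
    class(d) <- c("dna_dataset", "data.frame")
    d
  })
  names(out) <- c("train", "validation", "test")
  out
}

# Encode labels for the network: scenario 1 -> 0/1 vector with the
# alphabetically first class positive; scenario 2 -> one-hot matrix over the
# alphabetically ordered class levels.
encode_labels <- function(labels, levels, scenario) {
  labels <- factor(labels, levels = levels)
  if (anyNA(labels)) stop("label outside the training label universe",
                          call. = FALSE)
  if (scenario == 1) {
    as.numeric(labels == levels[1])
  } else {
    y <- matrix(0, length(labels), length(levels),
                dimnames = list(NULL, levels))
    y[cbind(seq_along(labels), as.integer(labels))] <- 1
    y
  }
}

as_input_array <- function(x) {
  stopifnot(is.matrix(x))
  array(x, c(nrow(x), ncol(x), 1L))
}

#' Train a classifier
#'
#' Minibatch gradient training for \code{config$epochs} epochs with the
#' scenario's loss and optimizer. Per-epoch training and validation losses
#' and accuracies are recorded. Runs are reproducible on one device for a
#' fixed seed; a non-finite loss aborts with a diagnostic naming the epoch
#' and batch.
#'
#' @param model A \code{bfdna_model} from \code{\link{build_model}}.
#' @param x_train,x_val Encoded input matrices (rows = sequences).
#' @param y_train,y_val Label vectors (class names).
#' @param config A \code{\link{train_config}}.
#' @param class_levels Optional explicit class order (default: sorted unique
#'   training labels).
#' @param verbose Print per-epoch progress.
#' @return The trained model, with a \code{history} data frame attached.
#' @export
train_model <- function(model, x_train, y_train, x_val = NULL, y_val = NULL,
                        config, class_levels = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "bfdna_model"), inherits(config, "train_config"))
  scenario <- model$spec$scenario
  if (is.null(class_levels)) class_levels <- sort(unique(as.character(y_train)))
  if (scenario == 2 && length(class_levels) != model$spec$n_classes)
    stop("scenario 2 expects 3 classes", call. = FALSE)
  ytr <- encode_labels(y_train, class_levels, scenario)
  Xtr <- as_input_array(x_train)
  has_val <- !is.null(x_val)
  if (has_val) {
    yva <- encode_labels(y_val, class_levels, scenario)
    Xva <- as_input_array(x_val)
  }
  n <- nrow(x_train)
  opt <- make_optimizer(config$optimizer, config$learning_rate)
  set.seed(config$seed)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        acc = numeric(), val_loss = numeric(),
                        val_acc = numeric())
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n)
    batch_starts <- seq(1, n, by = config$batch_size)
    ep_loss <- 0; ep_n <- 0; correct <- 0
    for (bi in seq_along(batch_starts)) {
      ix <- ord[batch_starts[bi]:min(batch_starts[bi] + config$batch_size - 1, n)]
      xb <- Xtr[ix, , , drop = FALSE]
      yb <- if (scenario == 1) ytr[ix] else ytr[ix, , drop = FALSE]
      fw <- network_forward(model, xb, training = TRUE)
      model$layers <- fw$net$layers
      lg <- loss_and_grad(fw$out, yb, config$loss)
      if (!is.finite(lg$value))
        stop(sprintf("non-finite loss at epoch %d, batch %d", epoch, bi),
             call. = FALSE)
      grads <- network_backward(model, fw$caches, lg$dz)
      model$layers <- optimizer_step(opt, model$layers, grads)
      ep_loss <- ep_loss + lg$value * length(ix)
      ep_n <- ep_n + length(ix)
      correct <- correct + if (scenario == 1)
        sum((lg$prob >= 0.5) == (yb == 1))
      else sum(max.col(lg$prob) == max.col(yb))
    }
    val_loss <- NA_real_; val_acc <- NA_real_
    if (has_val) {
      ev <- network_forward(model, Xva, training = FALSE)
      lg <- loss_and_grad(ev$out, yva, config$loss)
      val_loss <- lg$value
      val_acc <- if (scenario == 1) mean((lg$prob >= 0.5) == (yva == 1))
                 else mean(max.col(lg$prob) == max.col(yva))
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss = ep_loss / ep_n, acc = correct / ep_n,
      val_loss = val_loss, val_acc = val_acc))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_acc %.3f",
                      epoch, ep_loss / ep_n, correct / ep_n, val_acc))
  }
  model$history <- history
  model$class_levels <- class_levels
  model
}

#' Predict class probabilities and labels
#'
#' @param object A trained \code{bfdna_model}.
#' @param x Encoded input matrix.
#' @param ... Unused.
#' @return List with \code{prob} (matrix, one column per class) and
#'   \code{label} (predicted class names). Binary models use a 0.5 decision
#'   threshold on the positive-class probability.
#' @export
predict.bfdna_model <- function(object, x, ...) {
  stopifnot(!is.null(object$class_levels))
  fw <- network_forward(object, as_input_array(x), training = FALSE)
  lv <- object$class_levels
  if (object$spec$scenario == 1) {
    p <- sigmoid(fw$out[, 1])
    prob <- cbind(p, 1 - p)
    colnames(prob) <- lv
    label <- ifelse(p >= 0.5, lv[1], lv[2])
  } else {
    prob <- softmax_rows(fw$out)
    colnames(prob) <- lv
    label <- lv[max.col(prob)]
  }
  list(prob = prob, label = label)
}

#' Evaluate a trained model on a held-out test set
#'
#' Delegates all scoring to \code{\link{metric_report}} and attaches the
#' scenario and encoding-scheme tags, giving one row of the standard
#' performance table per run.
#'
#' @param model A trained \code{bfdna_model}.
#' @param x_test Encoded test matrix (disjoint from training/validation).
#' @param y_test Test label vector.
#' @param scheme Encoding scheme tag carried into the result.
#' @return An \code{evaluation_result}: \code{report}
#'   (\code{\link{metric_report}}), \code{row} (one-row data frame),
#'   \code{scenario}, \code{scheme}.
#' @export
evaluate_model <- function(model, x_test, y_test, scheme = NA_character_) {
  if (nrow(x_test) == 0) stop("empty test set", call. = FALSE)
  pred <- predict(model, x_test)
  scores <- if (model$spec$scenario == 1) pred$prob[, 1] else pred$prob
  report <- metric_report(as.character(y_test), pred$label, scores = scores,
                          positive = model$class_levels[1])
  structure(list(report = report, row = report_row(report),
                 scenario = model$spec$scenario, scheme = scheme),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> scenario %d, scheme %s\n",
              x$scenario, x$scheme))
  print(x$report)
  invisible(x)
}

#' Run one scenario end to end
#'
#' Encode, split, build, train and evaluate in one call: the complete
#' workflow from labeled sequences to the nine-metric report.
#'
#' @param dataset A labeled \code{\link{dna_dataset}}.
#' @param scheme Encoding scheme name.
#' @param scenario 1 (binary) or 2 (3-class).
#' @param spec Optional \code{\link{model_spec}} override.
#' @param config Optional \code{\link{train_config}} override.
#' @param scaled_down Use the desk-scale stack (default \code{TRUE}).
#' @param mode Residue validation mode for encoding.
#' @param verbose Print training progress.
#' @return List: \code{evaluation} (an \code{evaluation_result}),
#'   \code{model}, \code{splits}, \code{history}.
#' @export
run_scenario <- function(dataset, scheme, scenario, spec = NULL,
                         config = NULL, scaled_down = TRUE,
                         mode = "strict", verbose = FALSE) {
  if (is.null(spec)) spec <- model_spec(scenario, scaled_down = scaled_down)
  if (is.null(config))
    config <- train_config(scenario,
                           epochs = if (scaled_down) 15 else 500)
  x <- encode_matrix(dataset, scheme, input_length = spec$input_length,
                     mode = mode)
  splits <- split_dataset(dataset, config$split, seed = config$seed)
  ix <- function(d) match(d$id, rownames(x))
  model <- build_model(spec, seed = config$seed)
  model <- train_model(model,
                       x[ix(splits$train), , drop = FALSE],
                       splits$train$label,
                       x[ix(splits$validation), , drop = FALSE],
                       splits$validation$label,
                       config, verbose = verbose)
  evaluation <- evaluate_model(model, x[ix(splits$test), , drop = FALSE],
                               splits$test$label, scheme = scheme)
  list(evaluation = evaluation, model = model, splits = splits,
       history = model$history)
}
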