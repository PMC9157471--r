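#' Configuration for the bidirectional LSTM splice-site classifier
#'
#' The classifier has four learnable/regularising stages, in order: an
#' embedding layer over the 4-token nucleotide vocabulary (token index 0 is
#' reserved for padding and never used by the 60-nt windows), a dropout layer
#' on the embedding outputs, a bidirectional LSTM layer, and a dense 3-way
#' softmax output. Training runs for up to `rounds * epochs_per_round` epochs
#' (default 5 x 10 = 50) of Adam on categorical cross-entropy; with
#' `early_stopping = TRUE` (default) training stops once held-out accuracy
#' has not improved by more than `min_delta` for `patience` consecutive
#' epochs.
#'
#' @param window_length Input window length in nucleotides (default 60).
#' @param vocab_size Number of nucleotide tokens (default 4).
#' @param embedding_dim Embedding dimension per token (default 8).
#' @param recurrent_units LSTM units per direction (default 60).
#' @param dropout_rate Dropout probability on embedding outputs, in \[0,1)
#'   (default 0.2).
#' @param n_classes Number of output classes (default 3: donor, acceptor,
#'   no-site).
#' @param epochs_per_round,rounds Epoch budget, `rounds` sets of
#'   `epochs_per_round` epochs (defaults 10 and 5, i.e. up to 50 epochs).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Integer seed for weight initialisation, shuffling and dropout.
#' @param early_stopping Stop when held-out accuracy plateaus (default TRUE).
#' @param patience Plateau length in epochs before stopping (default 3).
#' @param min_delta Minimum accuracy improvement that resets the plateau
#'   counter (default 1e-4).
#' @return An object of class `"splice_config"`.
#' @export
splice_config <- function(window_length = 60L, vocab_size = 4L,
                          embedding_dim = 8L, recurrent_units = 60L,
                          dropout_rate = 0.2, n_classes = 3L,
                          epochs_per_round = 10L, rounds = 5L,
                          batch_size = 32L, learning_rate = 1e-3,
                          seed = 1L, early_stopping = TRUE,
                          patience = 3L, min_delta = 1e-4) {
  cfg <- list(window_length = as.integer(window_length),
              vocab_size = as.integer(vocab_size),
              embedding_dim = as.integer(embedding_dim),
              recurrent_units = as.integer(recurrent_units),
              dropout_rate = dropout_rate,
              n_classes = as.integer(n_classes),
              epochs_per_round = as.integer(epochs_per_round),
              rounds = as.integer(rounds),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              seed = as.integer(seed),
              early_stopping = isTRUE(early_stopping),
              patience = as.integer(patience),
              min_delta = min_delta)
  if (cfg$window_length < 2L) stop("window_length must be at least 2")
  if (cfg$vocab_size != 4L) stop("vocab_size must be 4 (A, G, T, C)")
  if (cfg$embedding_dim < 1L) stop("embedding_dim must be positive")
  if (cfg$recurrent_units < 1L) stop("recurrent_units must be positive")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)")
  }
  if (cfg$n_classes != 3L) stop("n_classes must be 3")
  if (cfg$epochs_per_round < 1L || cfg$rounds < 1L) {
    stop("epochs_per_round and rounds must be positive")
  }
  if (cfg$batch_size < 1L) stop("batch_size must be positive")
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive")
  class(cfg) <- "splice_config"
  cfg
}

#' Total epoch budget of a configuration
#' @param config A [splice_config()].
#' @return `rounds * epochs_per_round`.
#' @export
total_epochs <- function(config) config$rounds * config$epochs_per_round

#' Build an (untrained) bidirectional LSTM splice-site model
#'
#' Initialises the weights of the four-layer architecture (embedding with 5
#' rows -- index 0 reserved -- Glorot-uniform LSTM kernels with forget-gate
#' bias 1, Glorot-uniform dense layer) deterministically from `config$seed`.
#' The untrained model already satisfies the prediction contract: softmax
#' probability rows over 3 classes.
#'
#' @param config A [splice_config()].
#' @return An object of class `"splice_model"`.
#' @export
build_model <- function(config = splice_config()) {
  stopifnot(inherits(config, "splice_config"))
  weights <- cpp_init_weights(config$embedding_dim, config$recurrent_units,
                              config$n_classes, config$seed)
  structure(list(config = config, weights = weights, history = NULL,
                 trained = FALSE, n_train = 0L, n_test = 0L),
            class = "splice_model")
}

.validate_x <- function(x, window_length) {
  if (!is.matrix(x)) stop("x must be an integer matrix of encoded windows")
  if (ncol(x) != window_length) {
    stop("x has ", ncol(x), " columns; model expects ", window_length)
  }
  storage.mode(x) <- "integer"
  if (any(x < 1L | x > 4L)) stop("encoded values must be in 1..4")
  x
}

.validate_y <- function(y, n, n_classes) {
  if (!is.matrix(y) || nrow(y) != n || ncol(y) != n_classes) {
    stop("label matrix must be ", n, " x ", n_classes)
  }
  if (!all(y %in% c(0, 1)) || !all(rowSums(y) == 1)) {
    stop("label matrix must be one-hot (one 1 per row)")
  }
  storage.mode(y) <- "double"
  y
}

#' Train a splice-site model on a train/test split
#'
#' Compiles and trains the model with categorical cross-entropy, the Adam
#' optimiser and an accuracy metric, evaluating the held-out partition after
#' every epoch to populate the training history. Training runs for up to
#' `total_epochs(config)` epochs, stopping early when held-out accuracy
#' plateaus (see [splice_config()]).
#'
#' @param model An untrained (or previously trained) `splice_model`.
#' @param split A [split_dataset()] result, or any list with `train_x`,
#'   `train_y`, `test_x`, `test_y`.
#' @param verbose Print per-epoch metrics (default FALSE).
#' @param target_accuracy Optional held-out accuracy at which training stops
#'   immediately (an assessment shortcut when only "reaches at least this
#'   accuracy within the epoch budget" matters; default NULL = train to the
#'   epoch budget / early-stopping plateau).
#' @return The trained `splice_model`, with `$history` (data frame of
#'   per-epoch `train_loss`, `train_acc`, `test_loss`, `test_acc`).
#' @export
compile_and_train <- function(model, split, verbose = FALSE,
                              target_accuracy = NULL) {
  stopifnot(inherits(model, "splice_model"))
  cfg <- model$config
  tx <- .validate_x(split$train_x, cfg$window_length)
  ty <- .validate_y(split$train_y, nrow(tx), cfg$n_classes)
  ex <- .validate_x(split$test_x, cfg$window_length)
  ey <- .validate_y(split$test_y, nrow(ex), cfg$n_classes)
  fit <- cpp_train(model$weights, tx, ty, ex, ey,
                   max_epochs = total_epochs(cfg),
                   batch = cfg$batch_size, lr = cfg$learning_rate,
                   dropout = cfg$dropout_rate, seed = cfg$seed,
                   early_stop = cfg$early_stopping, patience = cfg$patience,
                   min_delta = cfg$min_delta,
                   target_accuracy = if (is.null(target_accuracy)) 0
                                     else target_accuracy,
                   verbose = verbose)
  model$weights <- fit$weights
  model$history <- as.data.frame(fit$history)
  model$history$epoch <- seq_len(nrow(model$history))
  model$trained <- TRUE
  model$n_train <- nrow(tx)
  model$n_test <- nrow(ex)
  model
}

#' Fit the bidirectional LSTM splice-site classifier
#'
#' One-call interface: builds the four-layer model from `config` and trains
#' it on `split`. Equivalent to `compile_and_train(build_model(config),
#' split)`.
#'
#' @inheritParams compile_and_train
#' @param config A [splice_config()].
#' @return A trained `splice_model`.
#' @examples
#' \donttest{
#' sim <- simulate_genome(n_genes = 30, seed = 7)
#' wins <- truth_windows(sim, seed = 7)
#' split <- split_dataset(wins, seed = 17)
#' fit <- splice_rnn(split, splice_config(seed = 1))
#' summary(fit)
#' }
#' @export
splice_rnn <- function(split, config = splice_config(), verbose = FALSE,
                       target_accuracy = NULL) {
  compile_and_train(build_model(config), split, verbose = verbose,
                    target_accuracy = target_accuracy)
}

#' Predict splice-site class probabilities or labels
#'
#' @param object A `splice_model`.
#' @param newdata Integer matrix of encoded windows (n x window_length,
#'   values 1..4), a character vector of window strings, or a
#'   `splice_windows` data frame.
#' @param type `"prob"` for the n x 3 probability matrix (rows sum to 1),
#'   `"class"` for hard labels 0/1/2 (argmax; ties resolve to the no-site
#'   class 2, the conservative choice).
#' @param ... Unused.
#' @return Probability matrix or integer label vector.
#' @export
predict.splice_model <- function(object, newdata, type = c("prob", "class"),
                                 ...) {
  type <- match.arg(type)
  if (is.character(newdata)) newdata <- encode_windows(newdata)
  if (is.data.frame(newdata)) newdata <- encode_windows(newdata$residues)
  x <- .validate_x(newdata, object$config$window_length)
  p <- cpp_predict(object$weights, x)
  colnames(p) <- c("donor", "acceptor", "no_site")
  if (type == "prob") return(p)
  argmax_labels(p)
}

#' Argmax class labels with conservative tie-breaking
#'
#' @param p Probability matrix with columns donor, acceptor, no-site.
#' @return Integer labels 0/1/2; exact ties resolve to 2 (no-site).
#' @export
argmax_labels <- function(p) {
  apply(p, 1L, function(r) {
    m <- max(r)
    if (r[3L] == m) 2L else if (r[1L] == m) 0L else 1L
  })
}

#' Evaluate a model on encoded windows
#'
#' @param model A trained `splice_model`.
#' @param x Integer matrix of encoded windows.
#' @param y One-hot label matrix.
#' @return List with `loss` (mean categorical cross-entropy) and `accuracy`
#'   (fraction of argmax-correct rows).
#' @export
evaluate_model <- function(model, x, y) {
  stopifnot(inherits(model, "splice_model"))
  x <- .validate_x(x, model$config$window_length)
  y <- .validate_y(y, nrow(x), model$config$n_classes)
  cpp_evaluate(model$weights, x, y)
}

#' @export
print.splice_model <- function(x, ...) {
  cfg <- x$config
  cat("Bidirectional LSTM splice-site classifier\n")
  cat(sprintf("  embedding(%d tokens + pad -> %d) -> dropout(%.2f) -> ",
              cfg$vocab_size, cfg$embedding_dim, cfg$dropout_rate))
  cat(sprintf("BiLSTM(%d x 2) -> dense(%d, softmax)\n",
              cfg$recurrent_units, cfg$n_classes))
  cat(sprintf("  parameters: %d   window: %d nt\n",
              n_parameters(x), cfg$window_length))
  if (x$trained) {
    h <- x$history
    cat(sprintf("  trained %d epochs on %d windows (%d held out)\n",
                nrow(h), x$n_train, x$n_test))
    cat(sprintf("  final held-out accuracy: %.4f  loss: %.4f\n",
                h$test_acc[nrow(h)], h$test_loss[nrow(h)]))
  } else {
    cat("  (untrained)\n")
  }
  invisible(x)
}

#' @export
summary.splice_model <- function(object, ...) {
  print(object)
  if (object$trained) {
    cat("\nTraining history (last 5 epochs):\n")
    h <- object$history
    print(utils::tail(h[, c("epoch", "train_loss", "train_acc",
                            "test_loss", "test_acc")], 5L),
          row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.splice_model <- function(object, ...) object$weights

#' Number of learnable parameters
#'
#' @param model A `splice_model`.
#' @return Total parameter count over all weight matrices and biases.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$weights, length, integer(1)))
}

#' Plot training and held-out loss/accuracy curves
#'
#' @param x A trained `splice_model`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.splice_model <- function(x, ...) {
  if (!x$trained) stop("model is untrained; nothing to plot")
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$test_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "categorical cross-entropy",
                    main = "Loss", ...)
  graphics::legend("topright", c("train", "test"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_acc, h$test_acc), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "accuracy", main = "Accuracy", ...)
  graphics::legend("bottomright", c("train", "test"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Save / load a trained model
#'
#' The weights, configuration and training history round-trip through a
#' single RDS file; reloaded models give identical predictions.
#'
#' @param model A `splice_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "splice_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  m <- readRDS(path)
  if (!inherits(m, "splice_model")) stop("not a saved splice_model: ", path)
  m
}
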