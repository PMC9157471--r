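test_that("config validation rejects invalid fields", {
  expect_error(splice_config(dropout_rate = 1), "dropout_rate")
  expect_error(splice_config(n_classes = 2), "n_classes")
  expect_error(splice_config(learning_rate = 0), "learning_rate")
  expect_equal(total_epochs(splice_config()), 50L)
})

test_that("untrained model already satisfies the probability contract", {
  m <- build_model(splice_config(seed = 3))
  set.seed(1)
  x <- matrix(sample(1:4, 20 * 60, TRUE), 20, 60)
  p <- predict(m, x)
  expect_equal(dim(p), c(20L, 3L))
  expect_equal(rowSums(p), rep(1, 20), tolerance = 1e-5)
  expect_true(all(p >= 0))
  expect_error(predict(m, x - 1L), "1..4")
  expect_error(predict(m, x[, 1:59]), "59 columns")
})

test_that("parameter count matches the closed form", {
  for (cfg in list(splice_config(), splice_config(embedding_dim = 5,
                                                  recurrent_units = 17))) {
    m <- build_model(cfg)
    d <- cfg$embedding_dim; u <- cfg$recurrent_units
    want <- 5 * d + 2 * (4 * u * (d + u + 1)) + 2 * u * 3 + 3
    expect_equal(n_parameters(m), want)
  }
})

test_that("analytic gradients agree with finite differences", {
  m <- build_model(splice_config(embedding_dim = 3, recurrent_units = 4,
                                 window_length = 6, seed = 2))
  set.seed(1)
  x <- matrix(sample(1:4, 40 * 6, TRUE), 40, 6)
  y <- one_hot(sample(0:2, 40, TRUE))
  storage.mode(y) <- "double"
  lg <- spliceRNN:::cpp_loss_grad(m$weights, x, y)
  h <- 2e-2
  for (nm in names(m$weights)) {
    g <- lg$gradients[[nm]]
    for (k in order(abs(g), decreasing = TRUE)[seq_len(min(4, length(g)))]) {
      wp <- m$weights; wp[[nm]][k] <- wp[[nm]][k] + h
      wm <- m$weights; wm[[nm]][k] <- wm[[nm]][k] - h
      num <- (spliceRNN:::cpp_loss_grad(wp, x, y)$loss -
                spliceRNN:::cpp_loss_grad(wm, x, y)$loss) / (2 * h)
      expect_lt(abs(num - g[k]) / max(1e-4, abs(num) + abs(g[k])), 0.05)
    }
  }
})

test_that("a single-class dataset is fit to accuracy 1 within 2 epochs", {
  wins <- random_windows(60, seed = 5)
  wins <- wins[wins$label == 0L, ]
  x <- encode_windows(wins$residues)
  y <- one_hot(wins$label)
  split <- list(train_x = x, train_y = y, test_x = x, test_y = y)
  cfg <- splice_config(seed = 5, recurrent_units = 16, epochs_per_round = 2,
                       rounds = 1, early_stopping = FALSE)
  fit <- compile_and_train(build_model(cfg), split)
  expect_gte(max(fit$history$train_acc[1:2]), 1)
})

test_that("evaluate_model equals a hand-rolled argmax/cross-entropy oracle", {
  m <- cached_center_model()
  wins <- random_windows(50, seed = 21)
  x <- encode_windows(wins$residues)
  y <- one_hot(wins$label)
  got <- evaluate_model(m, x, y)
  p <- predict(m, x)
  acc_oracle <- mean(max.col(p, ties.method = "first") == wins$label + 1L)
  loss_oracle <- -mean(log(p[cbind(seq_len(nrow(p)), wins$label + 1L)] + 1e-8))
  expect_equal(got$accuracy, acc_oracle, tolerance = 1e-6)
  expect_equal(got$loss, loss_oracle, tolerance = 1e-4)
  expect_error(evaluate_model(m, x, y[1:10, ]), "one-hot|label matrix")
})

test_that("prediction is deterministic and row-consistent", {
  m <- cached_center_model()
  set.seed(2)
  x <- matrix(sample(1:4, 60, TRUE), 1, 60)[rep(1, 8), ]
  p <- predict(m, x)
  expect_equal(p, p[rep(1, 8), ], tolerance = 0)
  expect_identical(predict(m, x), predict(m, x))
})

test_that("training history trends downward and is seed-reproducible", {
  wins <- random_windows(150, seed = 6)
  split <- split_dataset(wins, seed = 6)
  cfg <- splice_config(seed = 6, recurrent_units = 16, epochs_per_round = 5,
                       rounds = 1, early_stopping = FALSE)
  f1 <- splice_rnn(split, cfg)
  f2 <- splice_rnn(split, cfg)
  h <- f1$history
  expect_lte(h$train_loss[nrow(h)], h$train_loss[1])
  expect_true(all(h$train_acc >= 0 & h$train_acc <= 1))
  expect_true(all(h$test_loss >= 0))
  # same seed + same data => identical run
  expect_equal(f1$history$test_acc, f2$history$test_acc, tolerance = 1e-12)
  expect_equal(coef(f1)$w_out, coef(f2)$w_out, tolerance = 1e-12)
})

test_that("models round-trip through save_model/load_model", {
  m <- cached_center_model()
  set.seed(3)
  probe <- matrix(sample(1:4, 12 * 60, TRUE), 12, 60)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(predict(m2, probe), predict(m, probe), tolerance = 1e-7)
  expect_identical(m2$config, m$config)
  expect_error(load_model(file.path(tempdir(), "nope.rds")), "not found")
  g <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), g)
  expect_error(load_model(g), "not a saved splice_model")
})

test_that("argmax ties resolve to the no-site class", {
  p <- rbind(c(0.4, 0.2, 0.4), c(0.5, 0.5, 0.0), c(0.2, 0.5, 0.3))
  expect_identical(argmax_labels(p), c(2L, 0L, 1L))
})
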