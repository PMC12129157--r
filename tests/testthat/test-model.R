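ns <- asNamespace("vocog")

test_that("analytic gradients match finite differences, including masking", {
  cfg <- tiny_config(input_dim = 6L)
  set.seed(11)
  xs <- list(matrix(rnorm(18), 3, 6), matrix(rnorm(12), 2, 6), matrix(rnorm(24), 4, 6))
  y <- c(1, 0, 1)
  P <- ns$init_params(cfg, seed = 5L)
  fw <- ns$net_forward(P, cfg, xs, keep = TRUE)
  G <- ns$net_backward(P, cfg, fw, y)
  lossfun <- function(P) ns$bce_loss(ns$net_forward(P, cfg, xs)$prob, y)
  eps <- 1e-5
  for (k in names(P)) {
    for (i in sample(length(P[[k]]), min(3, length(P[[k]])))) {
      Pp <- P; Pp[[k]][i] <- Pp[[k]][i] + eps
      Pm <- P; Pm[[k]][i] <- Pm[[k]][i] - eps
      num <- (lossfun(Pp) - lossfun(Pm)) / (2 * eps)
      expect_lt(abs(num - G[[k]][i]), 1e-7)
    }
  }
})

test_that("seeded initialization is reproducible and outputs are probabilities", {
  cfg <- tiny_config()
  expect_identical(ns$init_params(cfg, seed = 3L), ns$init_params(cfg, seed = 3L))
  P <- ns$init_params(cfg, seed = 3L)
  x <- matrix(rnorm(14 * 8), 14, 8)
  p <- ns$net_forward(P, cfg, list(x))$prob
  expect_length(p, 1L)
  expect_true(p >= 0 && p <= 1)
})

test_that("the forward pass is sensitive to time-step order", {
  cfg <- tiny_config()
  P <- ns$init_params(cfg, seed = 3L)
  set.seed(21)
  x <- matrix(rnorm(14 * 8), 14, 8)
  p_fwd <- ns$net_forward(P, cfg, list(x))$prob
  p_rev <- ns$net_forward(P, cfg, list(x[14:1, ]))$prob
  expect_false(isTRUE(all.equal(p_fwd, p_rev)))
})

test_that("the default architecture's parameter count matches closed form", {
  # independent arithmetic: FC-pre + 2 bidirectional LSTM layers + head
  lstm_block <- function(din, H) 2 * (din * 4 * H + H * 4 * H + 4 * H)
  expected <- (1028 * 1128 + 1128) + (1128 * 768 + 768) +
    lstm_block(768, 512) + lstm_block(1024, 512) +
    (1024 * 1024 + 1024) + (1024 * 512 + 512) + (512 + 1)
  expect_equal(ns$n_params(ns$init_params(model_config(), seed = 1L)), expected)
  expect_equal(expected, 15145225)
})

test_that("fitting separates an easy two-class sequence problem", {
  d <- tiny_dataset()
  fit <- vocog_fit(d$x, d$y, config = tiny_config(),
                   train = train_config(epochs = 60L, batch_size = 8L, lr = 3e-3,
                                        validation_split = 0.25, seed = 1L))
  expect_s3_class(fit, "vocog_fit")
  # best-so-far selection loss is non-increasing by construction
  best_path <- cummin(fit$history$val_loss)
  expect_true(all(diff(best_path) <= 0))
  expect_gte(roc_auc(fitted(fit), d$y)$auc, 0.95)
  expect_equal(residuals(fit), d$y - fitted(fit))
})

test_that("predictions are deterministic, thresholded at 0.5, and validated", {
  d <- tiny_dataset(n_per_class = 6L)
  fit <- vocog_fit(d$x, d$y, config = tiny_config(),
                   train = train_config(epochs = 20L, lr = 3e-3, seed = 2L))
  p1 <- predict(fit, d$x)
  expect_identical(p1, predict(fit, d$x))
  expect_identical(as.character(p1$decision),
                   ifelse(p1$probability >= 0.5, "CD", "CN"))
  expect_error(predict(fit, matrix(0, 3, 5)), "feature columns")
})

test_that("degenerate training inputs are rejected", {
  d <- tiny_dataset(n_per_class = 4L)
  expect_error(vocog_fit(d$x, rep(0, 8), config = tiny_config()), "each class")
  expect_error(vocog_fit(d$x, rep(2, 8), config = tiny_config()), "labels")
  expect_error(vocog_fit(d$x[1:3], d$y, config = tiny_config()), "labels|sequences")
})

test_that("training with flipped labels mirrors the predicted probabilities", {
  d <- tiny_dataset(n_per_class = 8L)
  tc <- train_config(epochs = 40L, lr = 3e-3, validation_split = 0, seed = 3L)
  fit1 <- vocog_fit(d$x, d$y, config = tiny_config(), train = tc)
  fit2 <- vocog_fit(d$x, 1 - d$y, config = tiny_config(), train = tc)
  # both runs solve the mirrored problem: probabilities anti-correlate
  expect_lt(stats::cor(fitted(fit1), fitted(fit2)), -0.9)
  expect_lt(mean(abs(fitted(fit2) - (1 - fitted(fit1)))), 0.25)
})

test_that("checkpoints round-trip through a single file", {
  d <- tiny_dataset(n_per_class = 4L)
  fit <- vocog_fit(d$x, d$y, config = tiny_config(),
                   train = train_config(epochs = 5L, lr = 1e-3, seed = 4L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, path)
  back <- load_model(path)
  expect_identical(predict(back, d$x), predict(fit, d$x))
  expect_error(suppressWarnings(load_model(withr::local_tempfile(fileext = ".rds"))),
               "cannot open")
})
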