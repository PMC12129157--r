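#' Fit the voice-based cognitive-decline classifier
#'
#' Trains the FC -> bidirectional-LSTM -> FC classifier on labeled window
#' feature sequences. Each training example is a `T x 1028` matrix (one row
#' per 5-second window, see [extract_features]) with a binary label: 1 for
#' cognitively declined (MMSE <= 23), 0 for cognitively normal.
#'
#' Feature columns are z-scored using statistics of the training data
#' (stored in the fit and re-applied at prediction time), the data are split
#' into a stratified training/validation partition, and the network is
#' trained with mini-batch Adam on binary cross-entropy. The parameters with
#' the lowest validation loss are retained.
#'
#' @param x List of feature-sequence matrices (each `T_i x input_dim`).
#' @param y Binary labels (0/1 vector, one per sequence).
#' @param config A [model_config].
#' @param train A [train_config].
#' @param verbose Print per-epoch losses (default `FALSE`).
#' @return An object of class `vocog_fit` with components `params`,
#'   `config`, `train`, `history` (per-epoch losses), `best_epoch`,
#'   `center`/`scale` (feature standardization), `fitted.values` (training
#'   probabilities at the selected parameters) and `y`.
#' @seealso [predict.vocog_fit], [evaluate_screening], [synth_corpus]
#' @export
vocog_fit <- function(x, y, config = model_config(), train = train_config(),
                      verbose = FALSE) {
  if (is.matrix(x)) x <- list(x)
  if (!is.list(x) || !length(x)) stopf("vocog_fit: x must be a non-empty list of matrices")
  y <- as.numeric(y)
  if (length(y) != length(x)) stopf("vocog_fit: %d sequences but %d labels", length(x), length(y))
  if (!all(y %in% c(0, 1))) stopf("vocog_fit: labels must be 0 (CN) or 1 (CD)")
  if (min(table(factor(y, levels = c(0, 1)))) < 2L)
    stopf("vocog_fit: need at least two examples of each class")
  x <- lapply(x, function(m) {
    m <- unclass(as.matrix(m))
    if (ncol(m) != config$input_dim)
      stopf("vocog_fit: sequence has %d feature columns, expected %d", ncol(m), config$input_dim)
    m
  })

  # per-column standardization from the full training pool
  pool <- do.call(rbind, x)
  center <- colMeans(pool)
  scale <- apply(pool, 2, stats::sd)
  scale[scale < 1e-8] <- 1
  x <- lapply(x, function(m) sweep(sweep(m, 2, center), 2, scale, `/`))

  n <- length(x)
  split <- with_seed(derive_seed(train$seed, "split"), {
    val <- unlist(lapply(c(0, 1), function(cl) {
      idx <- which(y == cl)
      k <- floor(train$validation_split * length(idx))
      if (k > 0) sample(idx, k) else integer(0)
    }))
    val
  })
  tr_idx <- setdiff(seq_len(n), split)
  if (length(split) && min(table(factor(y[tr_idx], levels = c(0, 1)))) < 1L)
    stopf("vocog_fit: validation split removed all examples of one class")

  P <- init_params(config, seed = derive_seed(train$seed, "init"))
  st <- adam_init(P)
  # P is updated in place by the optimizer, so snapshots must deep-copy
  bestP <- deep_copy(P); best_loss <- Inf; best_epoch <- 0L; stall <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0), val_loss = numeric(0))

  eval_loss <- function(P, idx) {
    if (!length(idx)) return(NA_real_)
    tot <- 0
    for (ch in split_chunks(idx, 32L)) {
      fw <- net_forward(P, config, x[ch])
      tot <- tot + bce_loss(fw$prob, y[ch]) * length(ch)
    }
    tot / length(idx)
  }

  for (ep in seq_len(train$epochs)) {
    ord <- with_seed(derive_seed(train$seed, paste0("epoch", ep)), sample(tr_idx))
    ep_loss <- 0
    for (bt in split_chunks(ord, train$batch_size)) {
      fw <- net_forward(P, config, x[bt], keep = TRUE)
      loss <- bce_loss(fw$prob, y[bt])
      if (!is.finite(loss))
        stopf("vocog_fit: non-finite loss at epoch %d; lower the learning rate", ep)
      G <- net_backward(P, config, fw, y[bt])
      adam_step(P, G, st, train$lr)
      ep_loss <- ep_loss + loss * length(bt)
    }
    ep_loss <- ep_loss / length(tr_idx)
    val_loss <- eval_loss(P, split)
    sel <- if (is.na(val_loss)) ep_loss else val_loss
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss, val_loss = val_loss))
    if (sel < best_loss) {
      # patience only resets on a material improvement; best weights are
      # snapshotted on any improvement
      stall <- if (sel < best_loss - train$min_delta) 0L else stall + 1L
      best_loss <- sel; bestP <- deep_copy(P); best_epoch <- ep
    } else {
      stall <- stall + 1L
    }
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %s%s", ep, ep_loss,
                      ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss)),
                      if (best_epoch == ep) "  *" else ""))
    if (stall >= train$patience) break
  }

  fitted <- numeric(n)
  for (ch in split_chunks(seq_len(n), 32L))
    fitted[ch] <- net_forward(bestP, config, x[ch])$prob

  structure(list(params = bestP, config = config, train = train,
                 history = hist, best_epoch = best_epoch, best_loss = best_loss,
                 center = center, scale = scale,
                 fitted.values = fitted, y = y,
                 val_idx = split, call = match.call()),
            class = "vocog_fit")
}

split_chunks <- function(idx, size) {
  if (!length(idx)) return(list())
  split(idx, ceiling(seq_along(idx) / size))
}

#' Predict cognitive-decline probability for feature sequences
#'
#' @param object A fitted [vocog_fit].
#' @param newdata A feature-sequence matrix or a list of them.
#' @param threshold Decision cutoff; a probability at or above it is called
#'   CD (default 0.5).
#' @param ... Unused.
#' @return A data frame with one row per sequence: `probability` and
#'   `decision` (factor `CN`/`CD`; CD iff probability >= threshold).
#' @export
predict.vocog_fit <- function(object, newdata, threshold = 0.5, ...) {
  if (missing(newdata)) {
    prob <- object$fitted.values
  } else {
    if (is.matrix(newdata)) newdata <- list(newdata)
    newdata <- lapply(newdata, function(m) {
      m <- unclass(as.matrix(m))
      if (ncol(m) != object$config$input_dim)
        stopf("predict: sequence has %d feature columns, expected %d",
              ncol(m), object$config$input_dim)
      sweep(sweep(m, 2, object$center), 2, object$scale, `/`)
    })
    prob <- numeric(length(newdata))
    for (ch in split_chunks(seq_along(newdata), 32L))
      prob[ch] <- net_forward(object$params, object$config, newdata[ch])$prob
  }
  data.frame(probability = prob,
             decision = factor(ifelse(prob >= threshold, "CD", "CN"),
                               levels = c("CN", "CD")))
}

#' @export
print.vocog_fit <- function(x, ...) {
  cfg <- x$config
  cat("Voice-based cognitive decline classifier (FC -> Bi-LSTM -> FC)\n")
  cat(sprintf("  input %d -> FC(%d, %d) -> BiLSTM(%d x %d/dir) -> FC(%d, %d) -> sigmoid\n",
              cfg$input_dim, cfg$fc_pre[1], cfg$fc_pre[2], cfg$lstm_layers,
              cfg$lstm_hidden, cfg$fc_head[1], cfg$fc_head[2]))
  cat(sprintf("  %s parameters; trained %d epochs (best epoch %d, loss %.4f)\n",
              format(n_params(x$params), big.mark = ","),
              nrow(x$history), x$best_epoch, x$best_loss))
  cat(sprintf("  %d training sequences (%d CD / %d CN)\n",
              length(x$y), sum(x$y == 1), sum(x$y == 0)))
  invisible(x)
}

#' @export
summary.vocog_fit <- function(object, ...) {
  print(object)
  pred <- object$fitted.values >= 0.5
  acc <- mean(pred == (object$y == 1))
  cat(sprintf("  training accuracy at 0.5 threshold: %.3f\n", acc))
  if (length(object$val_idx)) {
    vacc <- mean(pred[object$val_idx] == (object$y[object$val_idx] == 1))
    cat(sprintf("  validation accuracy: %.3f (%d sequences)\n", vacc, length(object$val_idx)))
  }
  cat("\nLoss history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.vocog_fit <- function(object, ...) object$params

#' @export
fitted.vocog_fit <- function(object, ...) object$fitted.values

#' @export
residuals.vocog_fit <- function(object, ...) object$y - object$fitted.values

#' @param x A fitted `vocog_fit`.
#' @param ... Passed to [graphics::matplot].
#' @describeIn vocog_fit Plot training and validation loss per epoch.
#' @export
plot.vocog_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l", lty = 1,
                    col = c("grey40", "firebrick"), xlab = "epoch",
                    ylab = "binary cross-entropy", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Save or load a model checkpoint
#'
#' The checkpoint is a single RDS file holding the complete fit: weights,
#' architecture and training configuration, feature standardization and the
#' training seed, so predictions are reproducible from the file alone.
#'
#' @param object A [vocog_fit].
#' @param path Checkpoint file path.
#' @return `path` invisibly; `load_model` returns the `vocog_fit`.
#' @export
save_model <- function(object, path) {
  if (!inherits(object, "vocog_fit")) stopf("save_model: expected a vocog_fit")
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "vocog_fit")) stopf("load_model: %s is not a vocog_fit checkpoint", path)
  obj
}
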