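#' Classifier architecture configuration
#'
#' The window-sequence classifier applies a two-layer fully connected stack
#' (1128 then 768 units, ReLU) to every 1028-value time step, feeds the
#' transformed sequence to a two-layer bidirectional LSTM with 512 hidden
#' units per direction, concatenates the final forward and backward hidden
#' states (1024 values) and classifies through two further fully connected
#' layers (1024 then 512 units, ReLU) ending in a single sigmoid unit.
#'
#' @param input_dim Per-step feature width (default 1028).
#' @param fc_pre Widths of the per-step fully connected stack.
#' @param lstm_hidden Hidden units per LSTM direction.
#' @param lstm_layers Number of stacked bidirectional LSTM layers.
#' @param fc_head Widths of the classification head.
#' @return A list of class `model_config`.
#' @export
model_config <- function(input_dim = 1028L, fc_pre = c(1128L, 768L),
                         lstm_hidden = 512L, lstm_layers = 2L,
                         fc_head = c(1024L, 512L)) {
  stopifnot(is_count(input_dim), length(fc_pre) == 2L, length(fc_head) == 2L,
            is_count(lstm_hidden), is_count(lstm_layers))
  structure(list(input_dim = as.integer(input_dim), fc_pre = as.integer(fc_pre),
                 lstm_hidden = as.integer(lstm_hidden),
                 lstm_layers = as.integer(lstm_layers),
                 fc_head = as.integer(fc_head)),
            class = "model_config")
}

#' Training configuration
#'
#' Binary cross-entropy loss optimized by Adam. The model with the lowest
#' validation loss across epochs is kept; training stops early when the
#' validation loss has not improved for `patience` epochs.
#'
#' @param epochs Maximum training epochs (default 50).
#' @param batch_size Sequences per gradient step (default 8).
#' @param lr Adam learning rate (default 1e-4).
#' @param validation_split Fraction of the data held out (stratified) for
#'   epoch selection (default 0.2; 0 selects by training loss).
#' @param seed Integer seed fixing initialization, the split and batch order.
#' @param patience Early-stopping patience in epochs.
#' @param min_delta Smallest validation-loss improvement that resets the
#'   patience counter (the best weights are still tracked on any
#'   improvement).
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 8L, lr = 1e-4,
                         validation_split = 0.2, seed = 1L, patience = 10L,
                         min_delta = 1e-4) {
  stopifnot(is_count(epochs), is_count(batch_size), lr > 0,
            validation_split >= 0, validation_split < 1, is_count(patience),
            min_delta >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, validation_split = validation_split,
                 seed = as.integer(seed), patience = as.integer(patience),
                 min_delta = min_delta),
            class = "train_config")
}

# ---- parameter initialization -------------------------------------------

# parameters live in a flat named list of arrays; keys mirror the layers
init_params <- function(cfg, seed = 1L) {
  H <- cfg$lstm_hidden
  shapes <- list(
    fc1.W = c(cfg$input_dim, cfg$fc_pre[1]), fc1.b = cfg$fc_pre[1],
    fc2.W = c(cfg$fc_pre[1], cfg$fc_pre[2]), fc2.b = cfg$fc_pre[2]
  )
  for (l in seq_len(cfg$lstm_layers)) {
    din <- if (l == 1L) cfg$fc_pre[2] else 2L * H
    for (d in c("f", "b")) {
      shapes[[sprintf("lstm%d.%s.W", l, d)]] <- c(din, 4L * H)
      shapes[[sprintf("lstm%d.%s.U", l, d)]] <- c(H, 4L * H)
      shapes[[sprintf("lstm%d.%s.b", l, d)]] <- 4L * H
    }
  }
  shapes$head1.W <- c(2L * H, cfg$fc_head[1]); shapes$head1.b <- cfg$fc_head[1]
  shapes$head2.W <- c(cfg$fc_head[1], cfg$fc_head[2]); shapes$head2.b <- cfg$fc_head[2]
  shapes$out.W <- c(cfg$fc_head[2], 1L); shapes$out.b <- 1L
  with_seed(seed, {
    lapply(shapes, function(sh) {
      k <- 1 / sqrt(sh[1])
      v <- stats::runif(prod(sh), -k, k)
      if (length(sh) == 2L) matrix(v, sh[1], sh[2]) else v
    })
  })
}

n_params <- function(params) sum(vapply(params, length, numeric(1)))

# ---- sequence batching --------------------------------------------------

# Sequences are batched into a single (Tm*B) x D matrix: row (t-1)*B + i is
# sequence i at time t (zero rows pad past each sequence's end). `rev_perm`
# reverses every sequence in time within its own length; it is an
# involution, so the same permutation maps reversed-time rows back.
pack_batch <- function(xs) {
  lengths <- vapply(xs, nrow, integer(1))
  B <- length(xs); Tm <- max(lengths); D <- ncol(xs[[1]])
  X <- matrix(0, Tm * B, D)
  rev_perm <- seq_len(Tm * B)
  for (i in seq_len(B)) {
    Ti <- lengths[i]
    rows <- (seq_len(Ti) - 1L) * B + i
    X[rows, ] <- xs[[i]]
    rev_perm[rows] <- rev(rows)
  }
  M <- matrix(0, Tm, B)
  for (t in seq_len(Tm)) M[t, ] <- as.numeric(t <= lengths)
  list(X = X, M = M, rev_perm = rev_perm, lengths = lengths, B = B, Tm = Tm)
}

# ---- LSTM forward / backward --------------------------------------------

# One direction over the stacked batch. The input-to-hidden product is one
# large GEMM; only the hidden recurrence steps through time. Masked steps
# carry the previous state through unchanged, so the state at the last time
# block is the final state of every sequence regardless of its length.
lstm_forward <- function(Xs, M, W, U, b, H, B, Tm) {
  Zx <- Xs %*% W + rep(b, each = Tm * B)
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  Gi <- matrix(0, Tm * B, H); Gf <- Gi; Gg <- Gi; Go <- Gi
  TC <- Gi; Cpre <- Gi; Hpre <- Gi; Hout <- Gi
  h <- matrix(0, B, H); cs <- matrix(0, B, H)
  for (t in seq_len(Tm)) {
    rows <- (t - 1L) * B + seq_len(B)
    z <- Zx[rows, , drop = FALSE] + h %*% U
    i <- sigmoid(z[, i1, drop = FALSE]); f <- sigmoid(z[, i2, drop = FALSE])
    g <- tanh(z[, i3, drop = FALSE]); o <- sigmoid(z[, i4, drop = FALSE])
    c_new <- f * cs + i * g
    tc <- tanh(c_new)
    m <- M[t, ]
    Hpre[rows, ] <- h; Cpre[rows, ] <- cs
    Gi[rows, ] <- i; Gf[rows, ] <- f; Gg[rows, ] <- g; Go[rows, ] <- o
    TC[rows, ] <- tc
    h <- m * (o * tc) + (1 - m) * h
    cs <- m * c_new + (1 - m) * cs
    Hout[rows, ] <- h
  }
  list(Hout = Hout, h_last = h,
       cache = list(Xs = Xs, Gi = Gi, Gf = Gf, Gg = Gg, Go = Go,
                    TC = TC, Cpre = Cpre, Hpre = Hpre))
}

lstm_backward <- function(cache, W, U, M, dHout, H, B, Tm) {
  dZ <- matrix(0, Tm * B, 4L * H)
  dh_carry <- matrix(0, B, H); dc_carry <- matrix(0, B, H)
  tU <- t(U)
  for (t in rev(seq_len(Tm))) {
    rows <- (t - 1L) * B + seq_len(B)
    dh <- dHout[rows, , drop = FALSE] + dh_carry
    dc <- dc_carry
    m <- M[t, ]
    dh_new <- m * dh; dh_pass <- (1 - m) * dh
    dc_new <- m * dc; dc_pass <- (1 - m) * dc
    i <- cache$Gi[rows, , drop = FALSE]; f <- cache$Gf[rows, , drop = FALSE]
    g <- cache$Gg[rows, , drop = FALSE]; o <- cache$Go[rows, , drop = FALSE]
    tc <- cache$TC[rows, , drop = FALSE]; cprev <- cache$Cpre[rows, , drop = FALSE]
    do_ <- dh_new * tc
    dc_new <- dc_new + dh_new * o * (1 - tc^2)
    di <- dc_new * g; df <- dc_new * cprev; dg <- dc_new * i
    dzt <- cbind(di * i * (1 - i), df * f * (1 - f),
                 dg * (1 - g^2), do_ * o * (1 - o))
    dZ[rows, ] <- dzt
    dh_carry <- dzt %*% tU + dh_pass
    dc_carry <- dc_new * f + dc_pass
  }
  list(dW = crossprod(cache$Xs, dZ), dU = crossprod(cache$Hpre, dZ),
       db = colSums(dZ), dXs = dZ %*% t(W))
}

# ---- full network -------------------------------------------------------

net_forward <- function(P, cfg, xs, keep = FALSE) {
  pb <- pack_batch(xs)
  B <- pb$B; Tm <- pb$Tm; H <- cfg$lstm_hidden
  nr <- Tm * B
  H1 <- relu(pb$X %*% P$fc1.W + rep(P$fc1.b, each = nr))
  H2 <- relu(H1 %*% P$fc2.W + rep(P$fc2.b, each = nr))
  inp <- H2
  lcaches <- vector("list", cfg$lstm_layers)
  h_last <- NULL
  for (l in seq_len(cfg$lstm_layers)) {
    kf <- sprintf("lstm%d.f", l); kb <- sprintf("lstm%d.b", l)
    fwd <- lstm_forward(inp, pb$M, P[[paste0(kf, ".W")]], P[[paste0(kf, ".U")]],
                        P[[paste0(kf, ".b")]], H, B, Tm)
    bwd <- lstm_forward(inp[pb$rev_perm, , drop = FALSE], pb$M,
                        P[[paste0(kb, ".W")]], P[[paste0(kb, ".U")]],
                        P[[paste0(kb, ".b")]], H, B, Tm)
    lcaches[[l]] <- list(fwd = fwd, bwd = bwd)
    inp <- cbind(fwd$Hout, bwd$Hout[pb$rev_perm, , drop = FALSE])
    h_last <- cbind(fwd$h_last, bwd$h_last)   # final fwd + final bwd state
  }
  S <- h_last                                  # B x 2H
  Z1 <- relu(S %*% P$head1.W + rep(P$head1.b, each = B))
  Z2 <- relu(Z1 %*% P$head2.W + rep(P$head2.b, each = B))
  logit <- as.numeric(Z2 %*% P$out.W) + P$out.b
  prob <- sigmoid(logit)
  out <- list(prob = prob, logit = logit)
  if (keep) out$cache <- list(pb = pb, H1 = H1, H2 = H2,
                              lcaches = lcaches, S = S, Z1 = Z1, Z2 = Z2)
  out
}

# binary cross-entropy, mean over the batch
bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

net_backward <- function(P, cfg, fwd, y) {
  cache <- fwd$cache
  pb <- cache$pb
  B <- pb$B; Tm <- pb$Tm; H <- cfg$lstm_hidden
  last_rows <- (Tm - 1L) * B + seq_len(B)
  G <- list()
  dlogit <- matrix((fwd$prob - y) / B, ncol = 1L)
  G$out.W <- crossprod(cache$Z2, dlogit)
  G$out.b <- sum(dlogit)
  dZ2 <- (dlogit %*% t(P$out.W)) * (cache$Z2 > 0)
  G$head2.W <- crossprod(cache$Z1, dZ2)
  G$head2.b <- colSums(dZ2)
  dZ1 <- (dZ2 %*% t(P$head2.W)) * (cache$Z1 > 0)
  G$head1.W <- crossprod(cache$S, dZ1)
  G$head1.b <- colSums(dZ1)
  dS <- dZ1 %*% t(P$head1.W)                  # B x 2H

  dinp <- NULL
  for (l in rev(seq_len(cfg$lstm_layers))) {
    kf <- sprintf("lstm%d.f", l); kb <- sprintf("lstm%d.b", l)
    lc <- cache$lcaches[[l]]
    if (l == cfg$lstm_layers) {
      dHf <- matrix(0, Tm * B, H); dHb <- matrix(0, Tm * B, H)
      dHf[last_rows, ] <- dS[, seq_len(H)]
      dHb[last_rows, ] <- dS[, H + seq_len(H)]   # final state of reversed pass
    } else {
      dHf <- dinp[, seq_len(H), drop = FALSE]
      dHb <- dinp[pb$rev_perm, H + seq_len(H), drop = FALSE]
    }
    bf <- lstm_backward(lc$fwd$cache, P[[paste0(kf, ".W")]], P[[paste0(kf, ".U")]],
                        pb$M, dHf, H, B, Tm)
    bb <- lstm_backward(lc$bwd$cache, P[[paste0(kb, ".W")]], P[[paste0(kb, ".U")]],
                        pb$M, dHb, H, B, Tm)
    G[[paste0(kf, ".W")]] <- bf$dW; G[[paste0(kf, ".U")]] <- bf$dU; G[[paste0(kf, ".b")]] <- bf$db
    G[[paste0(kb, ".W")]] <- bb$dW; G[[paste0(kb, ".U")]] <- bb$dU; G[[paste0(kb, ".b")]] <- bb$db
    dinp <- bf$dXs + bb$dXs[pb$rev_perm, , drop = FALSE]
  }
  dH2 <- dinp * (cache$H2 > 0)
  G$fc2.W <- crossprod(cache$H1, dH2)
  G$fc2.b <- colSums(dH2)
  dH1 <- (dH2 %*% t(P$fc2.W)) * (cache$H1 > 0)
  G$fc1.W <- crossprod(pb$X, dH1)
  G$fc1.b <- colSums(dH1)
  G
}

# ---- Adam optimizer ------------------------------------------------------

# Moment state is held in an environment and, with the parameters, updated
# in place by compiled code (see src/adam.cpp); the training loop owns all
# of these objects exclusively.
adam_init <- function(P) {
  e <- new.env(parent = emptyenv())
  e$m <- lapply(P, function(p) p * 0)
  e$v <- lapply(P, function(p) p * 0)
  e$t <- 0L
  e
}

adam_step <- function(P, G, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  # the compiled kernel pairs list elements by position
  .adam_update_inplace(P, G[names(P)], st$m, st$v, as.numeric(st$t),
                       lr, beta1, beta2, eps)
  invisible(P)
}

deep_copy <- function(P) lapply(P, function(p) p + 0)
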