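#' Per-frame fundamental frequency and voicing probability
#'
#' A probabilistic-YIN-style estimator producing two 100-value tracks per
#' 5-second window: the voicing probability in \[0, 1\] (low values mark
#' pauses and silence) and the fundamental frequency in Hz (0 for frames
#' deemed unvoiced). Frames are 64 ms long on a 50 ms hop, so a 5-s window
#' yields exactly 100 frames.
#'
#' The estimator computes the cumulative-mean-normalized difference (CMND)
#' function per frame; the pitch lag is the first local CMND minimum below
#' an absolute threshold (falling back to the global minimum), refined by
#' parabolic interpolation. The voicing probability is `1 - CMND` at the
#' chosen lag, zeroed for near-silent frames.
#'
#' @param window A 5-second standardized [audio_clip] (16 kHz).
#' @param fmin,fmax F0 search range in Hz (default 60--400, adult
#'   conversational speech).
#' @param frame_hop_s Analysis hop in seconds (default 0.05).
#' @param frame_length_s Analysis frame length in seconds (default 0.064).
#' @param threshold Absolute CMND threshold for the first-minimum pick
#'   (default 0.15).
#' @return A list with numeric vectors `f0` and `voiced_prob`, each of
#'   length `window_s / frame_hop_s` (100 for the canonical geometry).
#' @export
extract_f0_voicing <- function(window, fmin = 60, fmax = 400,
                               frame_hop_s = 0.05, frame_length_s = 0.064,
                               threshold = 0.15) {
  if (!inherits(window, "audio_clip")) stopf("extract_f0_voicing: expected an audio_clip")
  sr <- window$sample_rate
  x <- window$samples
  hop <- round(frame_hop_s * sr)
  n_frames <- floor(length(x) / hop)
  if (n_frames < 1L) stopf("extract_f0_voicing: window shorter than one frame")
  W <- round(frame_length_s * sr)
  tau_min <- max(2L, floor(sr / fmax))
  tau_max <- ceiling(sr / fmin)
  need <- W + tau_max
  xp <- c(x, numeric(max(0L, (n_frames - 1L) * hop + need - length(x))))
  idx <- outer(seq_len(need), (seq_len(n_frames) - 1L) * hop, `+`)
  Y <- matrix(xp[idx], nrow = need)          # frame + lag context, per column
  A <- Y[seq_len(W), , drop = FALSE]         # reference window
  e0 <- colSums(A^2)

  # shifted-window energies e(tau) = sum_{j=tau+1}^{tau+W} y_j^2, tau = 0..tau_max
  cs <- apply(Y^2, 2, cumsum)
  esh <- rbind(cs[W, ], cs[W + seq_len(tau_max), , drop = FALSE] -
                          cs[seq_len(tau_max), , drop = FALSE])

  # cross term c(tau) = sum_j a_j y_{j+tau} via zero-padded FFT cross-correlation
  nfft <- 2^ceiling(log2(need + W))
  FA <- stats::mvfft(rbind(A, matrix(0, nfft - W, n_frames)))
  FY <- stats::mvfft(rbind(Y, matrix(0, nfft - need, n_frames)))
  cc <- Re(stats::mvfft(Conj(FA) * FY, inverse = TRUE)) / nfft
  cross <- cc[seq_len(tau_max + 1L), , drop = FALSE]   # rows: tau = 0..tau_max

  d <- sweep(esh, 2, e0, `+`) - 2 * cross               # difference function
  d <- pmax(d, 0)
  # cumulative-mean normalization over tau = 1..tau_max
  dpos <- d[-1L, , drop = FALSE]
  csum <- apply(dpos, 2, cumsum)
  cmnd <- dpos * outer(seq_len(tau_max), rep(1, n_frames)) / pmax(csum, 1e-12)
  cmnd[csum < 1e-12] <- 1

  f0 <- numeric(n_frames)
  vp <- numeric(n_frames)
  rms <- sqrt(e0 / W)
  for (j in seq_len(n_frames)) {
    dj <- cmnd[, j]
    rng <- tau_min:tau_max
    below <- rng[dj[rng] < threshold]
    tau <- if (length(below)) {
      # first local minimum below threshold
      k <- below[1L]
      while (k < tau_max && dj[k + 1L] < dj[k]) k <- k + 1L
      k
    } else rng[which.min(dj[rng])]
    # parabolic interpolation of the CMND minimum
    ti <- tau
    if (tau > tau_min && tau < tau_max) {
      a <- dj[tau - 1L]; b <- dj[tau]; cc2 <- dj[tau + 1L]
      den <- a - 2 * b + cc2
      if (abs(den) > 1e-12) ti <- tau + 0.5 * (a - cc2) / den
    }
    p <- max(0, min(1, 1 - dj[tau]))
    if (rms[j] < 1e-4) p <- 0                 # energy gate: digital silence
    vp[j] <- p
    f0[j] <- if (p >= 0.5) min(max(sr / ti, fmin), fmax) else 0
  }
  list(f0 = f0, voiced_prob = vp)
}
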