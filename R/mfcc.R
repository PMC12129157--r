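#' MFCC extraction configuration
#'
#' Analysis geometry for mel-frequency cepstral coefficients: 20
#' coefficients over 25 ms frames on a 10 ms hop with a 40-filter mel bank.
#' The per-window aggregate is 3 x `n_mfcc` = 60 values.
#'
#' @param n_mfcc Number of cepstral coefficients (default 20).
#' @param frame_length_s,frame_hop_s Analysis frame geometry in seconds.
#' @param n_mels Number of mel filters (default 40).
#' @param fmin,fmax Mel filterbank frequency range in Hz (`fmax = NULL`
#'   means Nyquist).
#' @return A list of class `mfcc_config`.
#' @export
mfcc_config <- function(n_mfcc = 20L, frame_length_s = 0.025, frame_hop_s = 0.010,
                        n_mels = 40L, fmin = 0, fmax = NULL) {
  stopifnot(is_count(n_mfcc), is_count(n_mels), n_mfcc <= n_mels,
            frame_length_s > 0, frame_hop_s > 0)
  structure(list(n_mfcc = as.integer(n_mfcc), frame_length_s = frame_length_s,
                 frame_hop_s = frame_hop_s, n_mels = as.integer(n_mels),
                 fmin = fmin, fmax = fmax),
            class = "mfcc_config")
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# triangular mel filterbank: n_mels x (nfft/2 + 1)
mel_filterbank <- function(sr, nfft, n_mels, fmin = 0, fmax = sr / 2) {
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  bins <- (0:(nfft %/% 2)) * sr / nfft
  fb <- matrix(0, n_mels, length(bins))
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1L]; hi <- hz_pts[m + 2L]
    up <- (bins - lo) / (ce - lo)
    dn <- (hi - bins) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

# orthonormal DCT-II matrix, n_out x n_in
dct_matrix <- function(n_out, n_in) {
  M <- outer(0:(n_out - 1L), 0:(n_in - 1L),
             function(k, n) cos(pi * k * (2 * n + 1) / (2 * n_in)))
  M <- M * sqrt(2 / n_in)
  M[1L, ] <- M[1L, ] / sqrt(2)
  M
}

# mel power spectrogram of a window: n_mels x n_frames
mel_spectrogram <- function(window, cfg = mfcc_config()) {
  sr <- window$sample_rate
  flen <- round(cfg$frame_length_s * sr)
  hop <- round(cfg$frame_hop_s * sr)
  nfft <- 2^ceiling(log2(flen))
  frames <- stft_frames(window$samples, flen, hop) * hann_window(flen)
  spec <- stats::mvfft(rbind(frames, matrix(0, nfft - flen, ncol(frames))))
  pw <- Mod(spec[seq_len(nfft %/% 2 + 1L), , drop = FALSE])^2
  fmax <- if (is.null(cfg$fmax)) sr / 2 else cfg$fmax
  mel_filterbank(sr, nfft, cfg$n_mels, cfg$fmin, fmax) %*% pw
}

#' Aggregated MFCC features for one window
#'
#' Computes 20 MFCCs per analysis frame across a 5-second window and
#' aggregates them to a fixed 60-value vector: per-coefficient maximum over
#' frames (20), per-coefficient mean (20), and per-coefficient mean of the
#' first-order delta (20), concatenated in that order.
#'
#' @param window A 5-second standardized [audio_clip].
#' @param cfg An [mfcc_config].
#' @return A named numeric vector of length `3 * n_mfcc` (60 by default).
#' @export
extract_mfcc_agg <- function(window, cfg = mfcc_config()) {
  if (!inherits(window, "audio_clip")) stopf("extract_mfcc_agg: expected an audio_clip")
  expected <- round(5 * window$sample_rate)
  if (length(window$samples) != expected)
    stopf("extract_mfcc_agg: window has %d samples, expected %d (a full 5-s window)",
          length(window$samples), expected)
  logmel <- log(mel_spectrogram(window, cfg) + 1e-10)
  m <- dct_matrix(cfg$n_mfcc, cfg$n_mels) %*% logmel   # n_mfcc x n_frames
  nf <- ncol(m)
  # centered first-order delta with edge replication
  prv <- m[, c(1L, seq_len(nf - 1L)), drop = FALSE]
  nxt <- m[, c(seq_len(nf)[-1L], nf), drop = FALSE]
  delta <- (nxt - prv) / 2
  out <- c(apply(m, 1, max), rowMeans(m), rowMeans(delta))
  names(out) <- c(sprintf("mfcc_max_%02d", seq_len(cfg$n_mfcc)),
                  sprintf("mfcc_mean_%02d", seq_len(cfg$n_mfcc)),
                  sprintf("mfcc_dmean_%02d", seq_len(cfg$n_mfcc)))
  out
}
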