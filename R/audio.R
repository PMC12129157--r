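#' Audio clip container
#'
#' A lightweight container for a mono waveform: a numeric amplitude vector
#' (nominally in \[-1, 1\]) plus its sample rate in Hz. Multi-channel input is
#' mixed to mono by channel averaging.
#'
#' @param samples Numeric vector of amplitudes, or a matrix with one channel
#'   per column (averaged to mono).
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `audio_clip` with fields `samples` and
#'   `sample_rate`.
#' @examples
#' clip <- audio_clip(sin(2 * pi * 220 * seq(0, 1, by = 1 / 16000)), 16000)
#' clip_duration(clip)
#' @export
audio_clip <- function(samples, sample_rate) {
  if (is.matrix(samples)) samples <- rowMeans(samples)
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples)))
    stopf("audio_clip: samples must be finite numbers")
  if (!is_count(sample_rate)) stopf("audio_clip: sample_rate must be a positive integer")
  structure(list(samples = samples, sample_rate = as.integer(sample_rate)),
            class = "audio_clip")
}

#' @rdname audio_clip
#' @param clip An `audio_clip`.
#' @export
clip_duration <- function(clip) length(clip$samples) / clip$sample_rate

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %d samples @ %d Hz (%.2f s), peak %.3f\n",
              length(x$samples), x$sample_rate, clip_duration(x),
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

# snap amplitudes to the signed 16-bit grid (multiples of 1/32768)
quantize16 <- function(x) {
  q <- round(pmin(pmax(x, -1), 1) * 32768)
  pmin(pmax(q, -32768), 32767) / 32768
}

#' Standardize audio to the canonical analysis format
#'
#' Converts a clip to the pipeline's canonical format: 16 kHz mono with
#' amplitudes quantized to the 16-bit grid. Resampling uses polyphase
#' filtering (via \code{signal::resample}) so results are reproducible across
#' runs. Standardization is idempotent up to 16-bit quantization.
#'
#' @param clip An [audio_clip].
#' @param sample_rate Target rate in Hz (default 16000).
#' @return A standardized `audio_clip` at `sample_rate`.
#' @export
standardize <- function(clip, sample_rate = 16000L) {
  if (!inherits(clip, "audio_clip")) stopf("standardize: expected an audio_clip")
  if (length(clip$samples) == 0L) stopf("standardize: empty clip")
  x <- clip$samples
  if (clip$sample_rate != sample_rate) {
    g <- gcd_int(sample_rate, clip$sample_rate)
    x <- as.numeric(signal::resample(x, sample_rate / g, clip$sample_rate / g))
    # resample may over/undershoot by a sample; pin the duration
    n_target <- round(length(clip$samples) * sample_rate / clip$sample_rate)
    if (length(x) > n_target) x <- x[seq_len(n_target)]
    if (length(x) < n_target) x <- c(x, numeric(n_target - length(x)))
  }
  audio_clip(quantize16(x), sample_rate)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Normalize a clip to a target RMS level
#'
#' Rescales the waveform so its root-mean-square level matches
#' `target_dbfs` decibels relative to full scale, so recording-volume
#' differences do not leak into downstream features. Samples that would
#' exceed full scale after the gain are hard-limited to \[-1, 1\] with a
#' warning. An all-zero clip is returned unchanged with a warning.
#'
#' @param clip An [audio_clip].
#' @param target_dbfs Target RMS level in dBFS (default -20).
#' @return The gain-adjusted `audio_clip`.
#' @export
rms_normalize <- function(clip, target_dbfs = -20) {
  if (!inherits(clip, "audio_clip")) stopf("rms_normalize: expected an audio_clip")
  rms <- sqrt(mean(clip$samples^2))
  if (rms == 0) {
    warnf("rms_normalize: all-zero clip, returning unchanged")
    return(clip)
  }
  gain <- 10^((target_dbfs - 20 * log10(rms)) / 20)
  y <- clip$samples * gain
  if (any(abs(y) > 1)) {
    warnf("rms_normalize: %d samples peak-limited to full scale", sum(abs(y) > 1))
    y <- pmin(pmax(y, -1), 1)
  }
  audio_clip(y, clip$sample_rate)
}

# ---- short-time Fourier transform helpers (hann analysis/synthesis) ----

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)

stft_frames <- function(x, win_length, hop) {
  n_frames <- max(1L, 1L + floor((length(x) - win_length) / hop))
  idx <- outer(seq_len(win_length), (seq_len(n_frames) - 1L) * hop, `+`)
  pad <- c(x, numeric(max(0, max(idx) - length(x))))
  matrix(pad[idx], nrow = win_length)
}

#' Spectral-gating noise reduction
#'
#' A generic spectral-gating denoiser: a per-bin noise profile is estimated
#' from the lowest-energy 10% of analysis frames, and magnitude bins that
#' fall below `gate_factor` times the profile are attenuated by `strength`.
#' Output length equals input length; `strength = 0` is the identity.
#'
#' @param clip A standardized [audio_clip].
#' @param strength Attenuation amount in \[0, 1\]; 0 leaves the clip
#'   untouched, 1 zeroes gated bins. Default 0.5.
#' @param gate_factor Multiple of the noise profile below which a bin is
#'   gated (default 2).
#' @param win_length,hop STFT geometry in samples (hann window, default
#'   512/256, i.e. 32 ms frames at 16 kHz with 50% overlap).
#' @return The denoised `audio_clip`, same length as the input.
#' @export
denoise <- function(clip, strength = 0.5, gate_factor = 2,
                    win_length = 512L, hop = 256L) {
  if (!inherits(clip, "audio_clip")) stopf("denoise: expected an audio_clip")
  if (strength < 0 || strength > 1) stopf("denoise: strength must lie in [0, 1]")
  if (strength == 0) return(clip)
  x <- clip$samples
  if (length(x) < win_length) stopf("denoise: clip shorter than one analysis frame (%d samples)", win_length)
  w <- hann_window(win_length)
  frames <- stft_frames(x, win_length, hop) * w
  spec <- stats::mvfft(frames)
  mag <- Mod(spec)
  energy <- colSums(mag^2)
  k <- max(1L, floor(0.10 * length(energy)))
  quiet <- order(energy)[seq_len(k)]
  profile <- rowMeans(mag[, quiet, drop = FALSE])
  gate <- mag < profile * gate_factor
  gain <- 1 - strength * gate
  spec <- spec * gain
  rec <- Re(stats::mvfft(spec, inverse = TRUE)) / win_length
  # weighted overlap-add with hann synthesis window
  n_frames <- ncol(rec)
  out_len <- win_length + (n_frames - 1L) * hop
  y <- numeric(out_len)
  norm <- numeric(out_len)
  for (j in seq_len(n_frames)) {
    seg <- (j - 1L) * hop + seq_len(win_length)
    y[seg] <- y[seg] + rec[, j] * w
    norm[seg] <- norm[seg] + w^2
  }
  y <- y / pmax(norm, 1e-8)
  y <- y[seq_len(min(length(x), length(y)))]
  if (length(y) < length(x)) y <- c(y, x[(length(y) + 1L):length(x)])
  audio_clip(pmin(pmax(y, -1), 1), clip$sample_rate)
}
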