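# deterministic synthetic signals shared across tests

# harmonic vowel-like tone: f0 plus decaying harmonics, peak-normalized
make_vowel <- function(f0 = 220, dur_s = 5, sr = 16000, amp = 0.3, n_harm = 15) {
  t <- seq_len(round(dur_s * sr)) / sr
  y <- 0
  for (k in seq_len(n_harm)) y <- y + sin(2 * pi * k * f0 * t) / k^0.7
  audio_clip(amp * y / max(abs(y)), sr)
}

make_tone <- function(freq, dur_s = 5, sr = 16000, amp = 0.3) {
  audio_clip(amp * sin(2 * pi * freq * seq_len(round(dur_s * sr)) / sr), sr)
}

# a small architecture so model tests run in milliseconds
tiny_config <- function(input_dim = 8L) {
  model_config(input_dim = input_dim, fc_pre = c(6L, 5L), lstm_hidden = 4L,
               lstm_layers = 2L, fc_head = c(6L, 4L))
}

# easily separable sequence dataset for the tiny model: class shifts the mean
tiny_dataset <- function(n_per_class = 12L, T_ = 5L, D = 8L, gap = 1.5, seed = 99L) {
  set.seed(seed)
  xs <- c(lapply(seq_len(n_per_class), function(i) matrix(stats::rnorm(T_ * D), T_, D)),
          lapply(seq_len(n_per_class), function(i) matrix(stats::rnorm(T_ * D, mean = gap), T_, D)))
  list(x = xs, y = rep(c(0, 1), each = n_per_class))
}

expect_no_message <- function(object) testthat::expect_message(object, NA)
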