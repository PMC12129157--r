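test_that("WAV reading scales PCM to [-1, 1] and mixes stereo to mono", {
  # 2-s 16-bit 44100 Hz stereo file written by hand
  sr <- 44100L; n <- 2L * sr
  left <- round(sin(2 * pi * 440 * seq_len(n) / sr) * 16000)
  right <- round(sin(2 * pi * 220 * seq_len(n) / sr) * 8000)
  path <- withr::local_tempfile(fileext = ".wav")
  con <- file(path, "wb")
  w32 <- function(x) writeBin(as.integer(x), con, 4L, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + 4L * n)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L); w16(1L); w16(2L)
  w32(sr); w32(sr * 4L); w16(4L); w16(16L)
  writeChar("data", con, eos = NULL); w32(4L * n)
  inter <- as.integer(rbind(left, right))
  writeBin(inter, con, 2L, endian = "little")
  close(con)

  clip <- read_wav(path)
  expect_equal(length(clip$samples), n)
  expect_equal(clip$sample_rate, sr)
  expect_equal(clip$samples, (left / 32768 + right / 32768) / 2, tolerance = 1e-12)
})

test_that("WAV edge amplitudes map onto the 16-bit grid", {
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(audio_clip(c(rep(0, 100)), 16000L), path)
  expect_true(all(read_wav(path)$samples == 0))

  write_wav(audio_clip(rep(32767 / 32768, 100), 16000L), path)
  expect_true(all(abs(read_wav(path)$samples - 1) <= 1 / 32768))
})

test_that("write_wav / read_wav round-trips 16-bit samples bit-exactly", {
  set.seed(1)
  x <- round(runif(32000, -1, 1) * 32767) / 32768
  clip <- audio_clip(x, 16000L)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(clip, path)
  expect_identical(read_wav(path)$samples, clip$samples)
})

test_that("read_wav rejects non-WAV input naming the problem", {
  path <- withr::local_tempfile(fileext = ".wav")
  writeLines("not audio", path)
  expect_error(read_wav(path), "RIFF")
  expect_error(read_wav(file.path(tempdir(), "missing-xyz.wav")), "not found")
})

test_that("standardize resamples to 16 kHz with the expected sample count", {
  clip <- audio_clip(sin(2 * pi * 100 * seq_len(16000) / 8000), 8000L)  # 2 s at 8 kHz
  out <- standardize(clip)
  expect_equal(out$sample_rate, 16000L)
  expect_equal(length(out$samples), 32000L)
  expect_equal(clip_duration(out), 2)
})

test_that("standardize is idempotent and preserves a pure tone's frequency", {
  clip <- make_tone(440, dur_s = 2, sr = 48000)
  out <- standardize(clip)
  # dominant FFT peak stays at 440 Hz within one bin
  spec <- Mod(stats::fft(out$samples))
  half <- seq_len(length(out$samples) %/% 2)
  peak_hz <- (which.max(spec[half]) - 1) * 16000 / length(out$samples)
  expect_lt(abs(peak_hz - 440), 16000 / length(out$samples) + 1e-9)

  again <- standardize(out)
  expect_identical(again$samples, out$samples)
  expect_error(standardize(audio_clip(numeric(0), 16000L)), "empty")
})

test_that("rms_normalize hits the target level and is gain-invariant", {
  clip <- make_tone(200, dur_s = 1)
  rms_db <- function(c) 20 * log10(sqrt(mean(c$samples^2)))
  out <- rms_normalize(clip, target_dbfs = -20)
  expect_lt(abs(rms_db(out) + 20), 0.1)

  louder <- audio_clip(clip$samples * 3e-2 / max(abs(clip$samples)) , 16000L)
  a <- rms_normalize(clip, -20)$samples
  b <- rms_normalize(louder, -20)$samples
  expect_equal(a, b, tolerance = 1e-9)

  expect_warning(z <- rms_normalize(audio_clip(numeric(100), 16000L)), "all-zero")
  expect_true(all(z$samples == 0))
})

test_that("rms_normalize peak-limits with a warning instead of clipping silently", {
  # highly peaked signal: normalizing RMS up would push peaks past full scale
  x <- numeric(16000); x[seq(1, 16000, 400)] <- 0.9
  expect_warning(out <- rms_normalize(audio_clip(x, 16000L), target_dbfs = -3),
                 "peak-limited")
  expect_true(all(abs(out$samples) <= 1))
})

test_that("denoise raises the SNR of a tone in white noise and keeps length", {
  set.seed(42)
  sine <- make_tone(300, dur_s = 2)$samples
  noise <- rnorm(length(sine)) * sqrt(mean(sine^2))   # 0 dB SNR
  clip <- audio_clip(pmin(pmax(sine + noise, -1), 1), 16000L)
  out <- denoise(clip, strength = 0.8)
  snr <- function(y) 10 * log10(sum(sine^2) / sum((y - sine)^2))
  expect_equal(length(out$samples), length(clip$samples))
  expect_gt(snr(out$samples), snr(clip$samples))
})

test_that("denoise is the identity at zero strength and on silence", {
  clip <- make_tone(250, dur_s = 1)
  expect_identical(denoise(clip, strength = 0), clip)
  sil <- audio_clip(numeric(16000), 16000L)
  expect_true(all(denoise(sil, strength = 1)$samples == 0))
  expect_error(denoise(audio_clip(numeric(100), 16000L), 0.5), "shorter")
})
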