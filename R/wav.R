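#' Read a RIFF/WAVE file
#'
#' Reads PCM (8/16/24/32-bit) and IEEE float (32/64-bit) WAV files. Samples
#' are scaled to \[-1, 1\]; multi-channel audio is mixed to mono by channel
#' averaging; the original sample rate is preserved (use [standardize] for
#' the canonical 16 kHz format).
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_clip].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stopf("read_wav: file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stopf("read_wav: not a RIFF file: %s", path)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stopf("read_wav: not a WAVE file: %s", path)

  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) stopf("read_wav: no data chunk found in %s", path)
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      u16 <- function(i) as.integer(raw_fmt[i]) + 256L * as.integer(raw_fmt[i + 1L])
      u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
      fmt <- list(code = u16(1L), channels = u16(3L), rate = u32(5L), bits = u16(15L))
      if (fmt$code == 65534L && size >= 24L) fmt$code <- u16(25L)  # WAVE_FORMAT_EXTENSIBLE
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stopf("read_wav: data chunk precedes fmt chunk in %s", path)
      smp <- read_wav_data(con, size, fmt, path)
      n_frames <- length(smp) %/% fmt$channels
      mat <- matrix(smp[seq_len(n_frames * fmt$channels)], ncol = fmt$channels, byrow = TRUE)
      return(audio_clip(mat, fmt$rate))
    } else {
      readBin(con, "raw", size + (size %% 2L))  # skip chunk (word-aligned)
    }
  }
}

read_wav_data <- function(con, size, fmt, path) {
  if (fmt$code == 1L) {  # integer PCM
    switch(as.character(fmt$bits),
      "8"  = (as.integer(readBin(con, "raw", size)) - 128) / 128,
      "16" = readBin(con, "integer", size %/% 2L, 2L, signed = TRUE, endian = "little") / 32768,
      "24" = {
        b <- as.integer(readBin(con, "raw", size))
        n <- length(b) %/% 3L
        v <- b[seq(1, 3 * n, 3)] + 256 * b[seq(2, 3 * n, 3)] + 65536 * b[seq(3, 3 * n, 3)]
        ifelse(v >= 2^23, v - 2^24, v) / 2^23
      },
      "32" = readBin(con, "integer", size %/% 4L, 4L, endian = "little") / 2^31,
      stopf("read_wav: unsupported PCM bit depth %d in %s", fmt$bits, path))
  } else if (fmt$code == 3L) {  # IEEE float
    switch(as.character(fmt$bits),
      "32" = readBin(con, "double", size %/% 4L, 4L, endian = "little"),
      "64" = readBin(con, "double", size %/% 8L, 8L, endian = "little"),
      stopf("read_wav: unsupported float bit depth %d in %s", fmt$bits, path))
  } else {
    stopf("read_wav: unsupported WAV encoding (format code %d) in %s", fmt$code, path)
  }
}

#' Write an audio clip as 16-bit PCM WAV
#'
#' Writes the canonical output format: mono 16-bit little-endian PCM.
#' Reading the file back with [read_wav] round-trips samples bit-exactly
#' when they already lie on the 16-bit grid (as after [standardize]).
#'
#' @param clip An [audio_clip].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  if (!inherits(clip, "audio_clip")) stopf("write_wav: expected an audio_clip")
  pcm <- as.integer(pmin(pmax(round(clip$samples * 32768), -32768), 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, 4L, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + 2L * n)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(1L); w16(1L)                     # PCM, mono
  w32(clip$sample_rate); w32(clip$sample_rate * 2L)
  w16(2L); w16(16L)                    # block align, bits
  writeChar("data", con, eos = NULL); w32(2L * n)
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}
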