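#' Cut a clip into overlapping analysis windows
#'
#' Segments a standardized clip into 5-second windows with a 1-second
#' overlap (i.e. a 4-second hop): starts at 0, 4, 8, ... seconds while the
#' full window fits. Trailing audio shorter than a full window is discarded
#' (with a message); clips shorter than one window are rejected unless
#' `pad = TRUE`, which zero-pads the clip to one full window.
#'
#' @param clip A standardized [audio_clip].
#' @param window_s Window length in seconds (default 5).
#' @param hop_s Hop between window starts in seconds (default 4).
#' @param pad Zero-pad clips shorter than one window (default `FALSE`).
#' @return A list with `grid` (data frame of `start_s`, `end_s`) and
#'   `windows` (list of `audio_clip`s of exactly `window_s` seconds each).
#' @examples
#' clip <- audio_clip(numeric(16000 * 60), 16000)
#' seg <- make_segments(clip)
#' nrow(seg$grid)  # 14 windows for a 60-s clip
#' @export
make_segments <- function(clip, window_s = 5, hop_s = 4, pad = FALSE) {
  if (!inherits(clip, "audio_clip")) stopf("make_segments: expected an audio_clip")
  sr <- clip$sample_rate
  wlen <- round(window_s * sr)
  hlen <- round(hop_s * sr)
  x <- clip$samples
  if (length(x) < wlen) {
    if (!pad)
      stopf(paste0("make_segments: clip is %.2f s but one window needs %g s; ",
                   "zero-pad short clips with pad = TRUE (CLI flag --pad)"),
            clip_duration(clip), window_s)
    x <- c(x, numeric(wlen - length(x)))
  }
  n_win <- 1L + floor((length(x) - wlen) / hlen)
  starts <- (seq_len(n_win) - 1L) * hlen
  leftover <- length(x) - (starts[n_win] + wlen)
  if (leftover > 0)
    message(sprintf("make_segments: discarding trailing %.2f s (< one full window)",
                    leftover / sr))
  windows <- lapply(starts, function(s) audio_clip(x[s + seq_len(wlen)], sr))
  list(grid = data.frame(start_s = starts / sr, end_s = (starts + wlen) / sr),
       windows = windows)
}
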