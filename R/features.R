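#' Windowed feature sequence for one clip
#'
#' Runs the full per-window feature extraction over a standardized clip:
#' 5-second windows with a 1-second overlap, each described by 1028 values
#' laid out as `[embedding 768 | voiced_prob 100 | f0 100 | mfcc 60]`.
#'
#' @param clip A standardized 16 kHz [audio_clip].
#' @param encoder A `vocog_encoder` (default [encoder_mock]).
#' @param cfg An [mfcc_config].
#' @param fmin,fmax F0 search range in Hz.
#' @param pad Zero-pad clips shorter than one window (see [make_segments]).
#' @return A `T x 1028` matrix of class `feature_sequence` with attributes
#'   `layout` (named section widths), `starts_s` (window start times) and
#'   `encoder_id`.
#' @export
extract_features <- function(clip, encoder = encoder_mock(), cfg = mfcc_config(),
                             fmin = 60, fmax = 400, pad = FALSE) {
  if (!inherits(clip, "audio_clip")) stopf("extract_features: expected an audio_clip")
  if (clip$sample_rate != 16000L)
    stopf("extract_features: clip is %d Hz; run standardize() first", clip$sample_rate)
  seg <- make_segments(clip, pad = pad)
  rows <- lapply(seg$windows, function(w) {
    fv <- extract_f0_voicing(w, fmin = fmin, fmax = fmax)
    c(embed(w, encoder), fv$voiced_prob, fv$f0, extract_mfcc_agg(w, cfg))
  })
  fs <- do.call(rbind, rows)
  layout <- c(embedding = 768L, voiced_prob = 100L, f0 = 100L, mfcc = 3L * cfg$n_mfcc)
  structure(fs, layout = layout, starts_s = seg$grid$start_s,
            encoder_id = encoder$id, class = c("feature_sequence", class(fs)))
}

#' Write / read a feature sequence
#'
#' Features are dumped as a plain CSV (`T` rows x 1028 columns, no row
#' names) with a JSON sidecar (`<path>.json`) recording the column layout,
#' window start times and encoder provenance.
#'
#' @param fs A `feature_sequence` from [extract_features].
#' @param path Output CSV path.
#' @return `path` invisibly for `write_features`; a `feature_sequence` for
#'   `read_features`.
#' @export
write_features <- function(fs, path) {
  utils::write.csv(as.data.frame(unclass(fs)), path, row.names = FALSE)
  meta <- list(layout = as.list(attr(fs, "layout")),
               starts_s = attr(fs, "starts_s"),
               encoder_id = attr(fs, "encoder_id"),
               n_windows = nrow(fs))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  fs <- as.matrix(utils::read.csv(path, check.names = FALSE))
  dimnames(fs) <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(fs, "layout") <- unlist(meta$layout)
    attr(fs, "starts_s") <- meta$starts_s
    attr(fs, "encoder_id") <- meta$encoder_id
  }
  class(fs) <- c("feature_sequence", class(fs))
  fs
}
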