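#' Window embedding encoders
#'
#' The pipeline consumes one 768-dimensional embedding per 5-second window
#' through a pluggable encoder interface. `encoder_mock()` is the default:
#' a deterministic, dependency-free encoder that mean-pools the window's
#' gain-normalized log-mel spectrogram over time and maps it to 768
#' dimensions through a fixed, seeded random projection. Its job is pipeline
#' testability, not representation quality. `encoder_pretrained()` is the
#' adapter slot for a self-supervised speech model (e.g. a HuBERT-base
#' checkpoint, whose final hidden layer would be mean-pooled per window);
#' no weights ship with the package, so it raises an actionable error.
#'
#' @param seed Integer seed fixing the mock's random projection.
#' @param pooling Temporal pooling over spectrogram frames: `"mean"` or
#'   `"max"`.
#' @param n_mels Mel bands feeding the projection (default 40).
#' @return An object of class `vocog_encoder`.
#' @examples
#' enc <- encoder_mock(seed = 42)
#' win <- audio_clip(sin(2 * pi * 220 * seq_len(80000) / 16000), 16000)
#' length(embed(win, enc))  # 768
#' @export
encoder_mock <- function(seed = 42L, pooling = c("mean", "max"), n_mels = 40L) {
  pooling <- match.arg(pooling)
  proj <- with_seed(seed, matrix(stats::rnorm(n_mels * 768L) / sqrt(n_mels), n_mels, 768L))
  structure(list(name = "mock", id = sprintf("mock-seed%d-%s", seed, pooling),
                 seed = as.integer(seed), pooling = pooling,
                 n_mels = as.integer(n_mels), proj = proj),
            class = "vocog_encoder")
}

#' @rdname encoder_mock
#' @param model Identifier of the pre-trained speech model.
#' @export
encoder_pretrained <- function(model = "hubert-base") {
  stopf(paste0("encoder_pretrained: no pre-trained speech model weights are ",
               "bundled or installed (requested '%s'). Use encoder_mock() for a ",
               "deterministic dependency-free encoder, or plug in your own ",
               "embedding function via the encoder interface."), model)
}

#' @export
print.vocog_encoder <- function(x, ...) {
  cat(sprintf("<vocog_encoder> %s (%d -> 768, pooling %s)\n", x$id, x$n_mels, x$pooling))
  invisible(x)
}

#' Embed one window
#'
#' @param window A 5-second standardized [audio_clip].
#' @param encoder A `vocog_encoder` (see [encoder_mock]).
#' @return Numeric vector of length 768 with attribute `encoder_id`.
#' @rdname encoder_mock
#' @export
embed <- function(window, encoder = encoder_mock()) {
  if (!inherits(encoder, "vocog_encoder")) stopf("embed: expected a vocog_encoder")
  mel <- mel_spectrogram(window, mfcc_config(n_mels = encoder$n_mels))
  # floor relative to the spectrogram peak so a global gain shifts every bin
  # equally and cancels in the normalization below
  floor_ <- max(mel) * 1e-10
  if (floor_ == 0) floor_ <- 1e-10
  logmel <- log(mel + floor_)
  s <- stats::sd(logmel)
  norm <- if (s > 0) (logmel - mean(logmel)) / s else logmel * 0
  pooled <- switch(encoder$pooling,
                   mean = rowMeans(norm),
                   max = apply(norm, 1, max))
  v <- as.numeric(pooled %*% encoder$proj)
  structure(v, encoder_id = encoder$id)
}
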