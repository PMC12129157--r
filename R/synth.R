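#' Prosody phenotype parameters for synthetic speech
#'
#' Controls the speech-like signal simulator. The cognitively-declined (CD)
#' phenotype follows the direction of the clinical phenomenology — slower
#' articulation, longer and more frequent pauses, reduced pitch
#' variability — relative to the cognitively-normal (CN) phenotype; the
#' magnitudes are package defaults chosen to be learnable without being
#' trivially separable.
#'
#' @param syllable_rate Syllables per second of voiced speech (syllable
#'   duration is its reciprocal).
#' @param pause_ratio Target fraction of the clip that is silent, in
#'   (0, 0.9).
#' @param mean_pause_s Mean length of a single silent pause, seconds.
#' @param f0_mean,f0_sd Per-syllable fundamental frequency distribution
#'   (Hz); `f0_sd` is the prosodic pitch variability.
#' @param amp_jitter Relative amplitude jitter between syllables.
#' @return A list of class `phenotype_params`.
#' @export
phenotype_params <- function(syllable_rate, pause_ratio, mean_pause_s,
                             f0_mean, f0_sd, amp_jitter = 0.1) {
  stopifnot(syllable_rate > 0, mean_pause_s > 0, f0_mean > 0, f0_sd >= 0,
            amp_jitter >= 0)
  if (pause_ratio <= 0 || pause_ratio >= 0.9)
    stopf("phenotype_params: pause_ratio must lie in (0, 0.9)")
  structure(list(syllable_rate = syllable_rate, pause_ratio = pause_ratio,
                 mean_pause_s = mean_pause_s, f0_mean = f0_mean, f0_sd = f0_sd,
                 amp_jitter = amp_jitter),
            class = "phenotype_params")
}

#' @rdname phenotype_params
#' @export
phenotype_cn <- function() {
  phenotype_params(syllable_rate = 4.0, pause_ratio = 0.20, mean_pause_s = 0.4,
                   f0_mean = 180, f0_sd = 30)
}

#' @rdname phenotype_params
#' @export
phenotype_cd <- function() {
  phenotype_params(syllable_rate = 2.5, pause_ratio = 0.45, mean_pause_s = 1.2,
                   f0_mean = 180, f0_sd = 10)
}

# vowel-like spectral envelope: formant bumps over a weak floor
formant_envelope <- function(f) {
  exp(-((f - 500) / 300)^2) + 0.7 * exp(-((f - 1500) / 400)^2) +
    0.4 * exp(-((f - 2500) / 500)^2) + 0.25
}

# one voiced syllable: harmonic source under the vowel envelope
synth_syllable <- function(dur_s, f0, amp, sr) {
  n <- round(dur_s * sr)
  t <- seq_len(n) / sr
  K <- max(1L, floor(3800 / f0))
  y <- numeric(n)
  for (k in seq_len(K)) {
    a <- formant_envelope(k * f0) / k^0.7
    y <- y + a * sin(2 * pi * k * f0 * t + stats::runif(1, 0, 2 * pi))
  }
  # raised-cosine attack/decay over 15 ms
  ramp <- min(round(0.015 * sr), n %/% 2)
  env <- rep(1, n)
  if (ramp > 0) {
    env[seq_len(ramp)] <- 0.5 - 0.5 * cos(pi * seq_len(ramp) / ramp)
    env[n + 1 - seq_len(ramp)] <- env[seq_len(ramp)]
  }
  amp * env * y / max(abs(y))
}

#' Synthesize one speech-like utterance
#'
#' Generates a deterministic, dependency-free speech-like waveform:
#' alternating voiced runs of harmonic syllables (per-syllable F0 drawn
#' from `Normal(f0_mean, f0_sd)`, shaped by a fixed vowel-like formant
#' envelope and a raised-cosine amplitude contour) and silent pauses whose
#' lengths are steered so the realized silent fraction tracks
#' `pause_ratio`. Output is 16 kHz mono of exactly `duration_s` seconds;
#' identical `params` + `seed` give bit-identical waveforms.
#'
#' @param params A [phenotype_params].
#' @param duration_s Clip length in seconds (>= 5).
#' @param seed Integer seed.
#' @return An [audio_clip].
#' @export
synth_utterance <- function(params, duration_s = 60, seed = 1L) {
  if (!inherits(params, "phenotype_params")) stopf("synth_utterance: expected phenotype_params")
  if (duration_s < 5) stopf("synth_utterance: duration must be at least 5 s")
  pr <- params$pause_ratio
  run_mean <- params$mean_pause_s * (1 - pr) / pr
  syl_dur <- 1 / params$syllable_rate
  if (run_mean < syl_dur)
    stopf(paste0("synth_utterance: infeasible parameters: mean voiced run (%.2f s) ",
                 "is shorter than one syllable (%.2f s)"), run_mean, syl_dur)
  sr <- 16000L
  n_total <- round(duration_s * sr)
  with_seed(seed, {
    pieces <- list()
    n_acc <- 0L
    while (n_acc < n_total) {
      run <- run_mean * stats::runif(1, 0.8, 1.2)
      n_syl <- max(1L, round(run / syl_dur))
      for (s in seq_len(n_syl)) {
        f0 <- min(max(stats::rnorm(1, params$f0_mean, params$f0_sd), 80), 350)
        amp <- 0.35 * max(0.2, 1 + params$amp_jitter * stats::rnorm(1))
        syl <- synth_syllable(syl_dur, f0, min(amp, 0.95), sr)
        pieces[[length(pieces) + 1L]] <- syl
        n_acc <- n_acc + length(syl)
      }
      pause <- n_syl * syl_dur * pr / (1 - pr) * stats::runif(1, 0.9, 1.1)
      np <- round(pause * sr)
      pieces[[length(pieces) + 1L]] <- numeric(np)
      n_acc <- n_acc + np
    }
    x <- unlist(pieces)[seq_len(n_total)]
    audio_clip(quantize16(x), sr)
  })
}

#' Generate a labeled synthetic corpus
#'
#' `synth_clips` builds `n_per_class` CN and `n_per_class` CD clips in
#' memory, with synthetic MMSE scores drawn uniformly from 24--30 (CN) and
#' 10--23 (CD) so the labeling rule is exercised end to end.
#' `synth_corpus` additionally writes the WAV files, a `manifest.csv`
#' conforming to [load_manifest]'s schema and a `params.json` provenance
#' record to `out_dir`.
#'
#' @param n_per_class Clips per class.
#' @param seed Integer seed; an identical call is bit-reproducible.
#' @param duration_s Clip length in seconds (default 60).
#' @param cn,cd [phenotype_params] for the two classes.
#' @return `synth_clips`: a list with `clips` (list of [audio_clip]) and
#'   `manifest` (data frame with `subject_id`, `mmse`, `label`,
#'   `diagnosis`). `synth_corpus`: the manifest with a `wav_path` column,
#'   invisibly.
#' @export
synth_clips <- function(n_per_class, seed = 1L, duration_s = 60,
                        cn = phenotype_cn(), cd = phenotype_cd()) {
  stopifnot(is_count(n_per_class))
  n <- 2L * n_per_class
  cls <- rep(c(0L, 1L), each = n_per_class)
  mmse <- with_seed(derive_seed(seed, "mmse"), {
    ifelse(cls == 1L, sample(10:23, n, replace = TRUE), sample(24:30, n, replace = TRUE))
  })
  clips <- lapply(seq_len(n), function(i) {
    synth_utterance(if (cls[i] == 1L) cd else cn, duration_s,
                    seed = derive_seed(seed, paste0("clip", i)))
  })
  manifest <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                         mmse = as.integer(mmse),
                         label = label_from_mmse(mmse),
                         diagnosis = ifelse(cls == 1L, "synthetic-CD", "synthetic-CN"))
  stopifnot(identical(manifest$label, cls))
  list(clips = clips, manifest = manifest)
}

#' @rdname synth_clips
#' @param out_dir Output directory for WAVs and manifest.
#' @param force Overwrite a non-empty `out_dir` (default `FALSE`).
#' @export
synth_corpus <- function(n_per_class, out_dir, seed = 1L, duration_s = 60,
                         cn = phenotype_cn(), cd = phenotype_cd(), force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stopf("synth_corpus: %s is not empty; use force = TRUE to overwrite", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- synth_clips(n_per_class, seed = seed, duration_s = duration_s, cn = cn, cd = cd)
  wav_path <- file.path(out_dir, paste0(sc$manifest$subject_id, ".wav"))
  for (i in seq_along(sc$clips)) write_wav(sc$clips[[i]], wav_path[i])
  manifest <- cbind(sc$manifest[, "subject_id", drop = FALSE], wav_path,
                    sc$manifest[, c("mmse", "label", "diagnosis")])
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(list(n_per_class = n_per_class, seed = seed,
                            duration_s = duration_s, cn = unclass(cn), cd = unclass(cd)),
                       file.path(out_dir, "params.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Measured silent-frame fraction of a clip
#'
#' An energy-threshold oracle used to validate the simulator: the fraction
#' of 50 ms frames whose RMS falls below `threshold`.
#'
#' @param clip An [audio_clip].
#' @param frame_s Frame length in seconds (default 0.05).
#' @param threshold RMS silence threshold (default 1e-3).
#' @return The silent fraction in \[0, 1\].
#' @export
silent_fraction <- function(clip, frame_s = 0.05, threshold = 1e-3) {
  n <- round(frame_s * clip$sample_rate)
  f <- stft_frames(clip$samples, n, n)
  mean(sqrt(colMeans(f^2)) < threshold)
}
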