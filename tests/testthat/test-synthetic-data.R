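test_that("utterance synthesis is bit-reproducible and exact-length", {
  p <- phenotype_cn()
  a <- synth_utterance(p, duration_s = 12, seed = 9L)
  b <- synth_utterance(p, duration_s = 12, seed = 9L)
  expect_identical(a$samples, b$samples)
  expect_equal(length(a$samples), 12 * 16000L)
  expect_equal(a$sample_rate, 16000L)
  expect_true(all(abs(a$samples) <= 1))
  c_ <- synth_utterance(p, duration_s = 12, seed = 10L)
  expect_false(identical(a$samples, c_$samples))
})

test_that("the realized silent fraction tracks the pause_ratio target", {
  for (p in list(phenotype_cn(), phenotype_cd())) {
    clip <- synth_utterance(p, duration_s = 60, seed = 4L)
    expect_lt(abs(silent_fraction(clip) - p$pause_ratio), 0.05)
  }
})

test_that("per-syllable pitch variability is recoverable from the audio", {
  for (sd_target in c(10, 30)) {
    p <- phenotype_params(syllable_rate = 3, pause_ratio = 0.25, mean_pause_s = 0.5,
                          f0_mean = 180, f0_sd = sd_target)
    clip <- synth_utterance(p, duration_s = 60, seed = 11L)
    seg <- suppressMessages(make_segments(clip))
    f0 <- unlist(lapply(seg$windows, function(w) extract_f0_voicing(w)$f0))
    f0 <- f0[f0 > 0]
    expect_lt(abs(stats::sd(f0) - sd_target) / sd_target, 0.3)
  }
})

test_that("infeasible phenotype parameters are rejected", {
  # pauses so dominant that a voiced run cannot hold a single syllable
  bad <- phenotype_params(syllable_rate = 0.5, pause_ratio = 0.85,
                          mean_pause_s = 0.3, f0_mean = 180, f0_sd = 10)
  expect_error(synth_utterance(bad, duration_s = 10, seed = 1L), "infeasible")
  expect_error(phenotype_params(4, 0.95, 0.4, 180, 30), "pause_ratio")
  expect_error(synth_utterance(phenotype_cn(), duration_s = 3, seed = 1L), "at least 5")
})

test_that("default CN and CD phenotypes differ clearly in measured pausing", {
  cn_frac <- mean(vapply(1:3, function(i)
    silent_fraction(synth_utterance(phenotype_cn(), 60, seed = i)), numeric(1)))
  cd_frac <- mean(vapply(1:3, function(i)
    silent_fraction(synth_utterance(phenotype_cd(), 60, seed = 100L + i)), numeric(1)))
  expect_gte(cd_frac - cn_frac, 0.15)
})

test_that("corpus generation writes WAVs, a valid manifest, and provenance", {
  out <- file.path(withr::local_tempdir(), "corpus")
  man <- synth_corpus(3L, out, seed = 7L, duration_s = 5)
  expect_equal(nrow(man), 6L)
  expect_equal(sum(man$label == 1), 3L)
  expect_true(all(file.exists(man$wav_path)))
  expect_true(file.exists(file.path(out, "params.json")))

  rec <- load_manifest(file.path(out, "manifest.csv"))   # recomputes labels
  expect_equal(rec$label, man$label)
  expect_true(all(rec$mmse[rec$label == 1] <= 23 & rec$mmse[rec$label == 1] >= 10))
  expect_true(all(rec$mmse[rec$label == 0] >= 24 & rec$mmse[rec$label == 0] <= 30))

  expect_error(synth_corpus(3L, out, seed = 7L, duration_s = 5), "force")
  clip <- read_wav(man$wav_path[1])
  expect_equal(clip$sample_rate, 16000L)
  expect_equal(length(clip$samples), 5L * 16000L)
})

test_that("corpus generation is reproducible end to end", {
  d1 <- file.path(withr::local_tempdir(), "c1")
  d2 <- file.path(withr::local_tempdir(), "c2")
  m1 <- synth_corpus(2L, d1, seed = 5L, duration_s = 5)
  m2 <- synth_corpus(2L, d2, seed = 5L, duration_s = 5)
  expect_identical(m1$mmse, m2$mmse)
  for (i in seq_len(nrow(m1)))
    expect_identical(read_wav(m1$wav_path[i])$samples, read_wav(m2$wav_path[i])$samples)
})

test_that("shrinking the CN/CD phenotype gap erodes held-out recovery", {
  # dose-response sanity check at reduced scale: 12+12 training and 6+6
  # held-out 20-s clips per gap level; gap interpolates every phenotype
  # parameter between the CN value (gap 0) and the full CD value (gap 1)
  blend_cd <- function(gap) {
    cn <- unclass(phenotype_cn()); cd <- unclass(phenotype_cd())
    do.call(phenotype_params, Map(function(a, b) a + gap * (b - a), cn, cd))
  }
  auc_at_gap <- function(gap, seed = 11L) {
    sc <- synth_clips(18L, seed = seed, duration_s = 20, cd = blend_cd(gap))
    feats <- suppressMessages(lapply(sc$clips, extract_features,
                                     encoder = encoder_mock(42L)))
    y <- sc$manifest$label
    tr <- c(which(y == 0)[1:12], which(y == 1)[1:12])
    te <- setdiff(seq_along(y), tr)
    fit <- vocog_fit(feats[tr], y[tr],
                     train = train_config(epochs = 30L, seed = seed))
    roc_auc(predict(fit, feats[te])$probability, y[te])$auc
  }
  aucs <- vapply(c(1, 0.4, 0), auc_at_gap, numeric(1))
  expect_gte(aucs[1], 0.85)                  # full contrast is recoverable
  expect_true(aucs[3] >= 0.2 && aucs[3] <= 0.8)   # no contrast ~ chance
  # wide-tolerance monotone trend
  expect_gte(aucs[1] + 0.15, aucs[2])
  expect_gte(aucs[2] + 0.15, aucs[3])
})
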