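test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_speech_fragments = -1), "counts")
  expect_error(sim_config(pause_range = c(0.5, 0.12)), "pause_range")
  expect_error(sim_config(audio_fs = 8000), "audio_fs")
  expect_error(sim_config(n_speech_fragments = 100, total_duration = 10),
               "do not fit")
})

test_that("make_annotation lays out the requested windows", {
  # empty case: no speech fragments -> no word intervals
  cfg0 <- sim_config(seed = 2, n_speech_fragments = 0,
                     n_nonspeech_fragments = 2, n_noisy_fragments = 0)
  ann0 <- make_annotation(cfg0)
  expect_equal(nrow(ann0$words), 0)

  cfg <- sim_config(seed = 5, n_speech_fragments = 10,
                    n_nonspeech_fragments = 0, n_noisy_fragments = 0,
                    n_channels = 2)
  ann <- make_annotation(cfg)
  layout <- attr(ann, "fragment_layout")
  expect_equal(nrow(layout), 10)
  expect_true(all(layout$duration == 4))
  o <- order(layout$onset)
  expect_true(all(layout$onset[o][-1] >=
                    (layout$onset + layout$duration)[o][-10]))
})

test_that("internal pauses never exceed 0.5 s (exhaustive scan)", {
  cfg <- small_config(seed = 13)
  ann <- make_annotation(cfg)
  layout <- attr(ann, "fragment_layout")
  sp <- layout[layout$condition %in% c("speech", "noisy"), , drop = FALSE]
  worst <- 0
  for (i in seq_len(nrow(sp))) {
    w <- ann$words[ann$words$onset >= sp$onset[i] - 1e-9 &
                     ann$words$offset <= sp$onset[i] + sp$duration[i] + 1e-9, ]
    expect_gt(nrow(w), 0)
    gaps <- c(w$onset[1] - sp$onset[i],
              if (nrow(w) > 1) w$onset[-1] - w$offset[-nrow(w)],
              sp$onset[i] + sp$duration[i] - w$offset[nrow(w)])
    worst <- max(worst, gaps)
  }
  expect_lte(worst, 0.5)
})

test_that("hand labels cover every fragment window", {
  cfg <- small_config(seed = 3)
  ann <- make_annotation(cfg)
  layout <- attr(ann, "fragment_layout")
  expect_equal(nrow(ann$hand), nrow(layout))
  expect_true(all(ann$hand$label %in% c("0", "1", "2")))
})

test_that("synthesized audio respects the annotation and the SNR", {
  cfg <- small_config(seed = 21)
  ann <- make_annotation(cfg)
  audio <- synthesize_audio(ann, cfg)
  fs <- cfg$audio_fs
  # isolated speech is zero outside word intervals
  tt <- (seq_along(audio$isolated_speech$samples) - 1) / fs
  in_word <- logical(length(tt))
  for (i in seq_len(nrow(ann$words))) {
    in_word <- in_word | (tt >= ann$words$onset[i] - 1e-4 &
                            tt < ann$words$offset[i] + 1e-4)
  }
  expect_true(all(audio$isolated_speech$samples[!in_word] == 0))
  # nonspeech window: isolated zero there
  i0 <- floor(ann$nonspeech$onset[1] * fs) + 10
  i1 <- floor(ann$nonspeech$offset[1] * fs) - 10
  expect_true(all(audio$isolated_speech$samples[i0:i1] == 0))
  # SNR 0 dB in noisy fragments: speech and background RMS equal within 5%
  layout <- attr(ann, "fragment_layout")
  nz <- layout[layout$condition == "noisy", , drop = FALSE]
  for (i in seq_len(nrow(nz))) {
    j0 <- floor(nz$onset[i] * fs) + 1
    j1 <- j0 + round(nz$duration[i] * fs) - 1
    sp <- audio$isolated_speech$samples[j0:j1]
    bg <- audio$mixed$samples[j0:j1] - sp
    expect_lt(abs(sqrt(mean(sp^2)) / sqrt(mean(bg^2)) - 1), 0.05)
  }
})

test_that("infinite SNR means mixed equals isolated speech", {
  cfg <- sim_config(seed = 4, n_speech_fragments = 2,
                    n_nonspeech_fragments = 0, n_noisy_fragments = 1,
                    n_channels = 2, snr_noisy_db = Inf)
  ann <- make_annotation(cfg)
  audio <- synthesize_audio(ann, cfg)
  expect_identical(audio$mixed$samples, audio$isolated_speech$samples)
})

test_that("seed determinism and seed independence behave as contracted", {
  cfg <- small_config(seed = 31)
  a1 <- make_annotation(cfg)
  a2 <- make_annotation(cfg)
  expect_identical(a1$words, a2$words)
  w1 <- synthesize_audio(a1, cfg)
  w2 <- synthesize_audio(a2, cfg)
  expect_identical(w1$mixed$samples, w2$mixed$samples)
  cfg_b <- small_config(seed = 32)
  a3 <- make_annotation(cfg_b)
  expect_false(identical(a1$words$onset, a3$words$onset))
  # identical ground-truth contract across seeds
  expect_identical(default_ground_truth(cfg), default_ground_truth(cfg_b))
})

test_that("neural synthesis validates lag range and varies with seed only", {
  cfg <- sim_config(seed = 8, n_speech_fragments = 2,
                    n_nonspeech_fragments = 2, n_noisy_fragments = 0,
                    n_channels = 2, neural_fs = 512)
  ann <- make_annotation(cfg)
  audio <- synthesize_audio(ann, cfg)
  feats <- audio_feature_stream(audio$isolated_speech, ann,
                                total_duration = cfg$total_duration)
  expect_error(ground_truth("envelope_tracking", 1, 600, 1), "lag")
  truth <- ground_truth(rep("unresponsive", 2), c(0, 0), c(0, 0), c(1, 1))
  r1 <- synthesize_neural(feats, truth, cfg)
  r2 <- synthesize_neural(feats, truth, cfg)
  expect_identical(r1$samples, r2$samples)
  cfg2 <- cfg; cfg2$seed <- 9L
  r3 <- synthesize_neural(feats, truth, cfg2)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("make_fixture writes a bundle that round-trips", {
  cfg <- sim_config(seed = 6, n_speech_fragments = 3,
                    n_nonspeech_fragments = 3, n_noisy_fragments = 1,
                    n_channels = 3, neural_fs = 512)
  dir <- file.path(tempdir(), "fixture_test")
  fx <- make_fixture(cfg, dir)
  expect_true(all(file.exists(unlist(fx$paths))))
  ann <- read_annotation_tsv(fx$paths$annotation_tsv,
                             total_duration = cfg$total_duration)
  expect_equal(ann$words$onset, fx$annotation$words$onset, tolerance = 1e-6)
  rec <- read_neural(fx$paths$neural)
  expect_equal(nrow(rec$samples), cfg$n_channels)
  truth <- jsonlite::read_json(fx$paths$ground_truth, simplifyVector = TRUE)
  expect_equal(nrow(truth), cfg$n_channels)
  wav <- read_wav(fx$paths$isolated_wav)
  expect_equal(length(wav$samples), round(cfg$total_duration * cfg$audio_fs))
  unlink(dir, recursive = TRUE)
})

test_that("fragment windows fit inside the configured duration", {
  cfg <- small_config(seed = 17)
  ann <- make_annotation(cfg)
  layout <- attr(ann, "fragment_layout")
  expect_lte(sum(layout$duration), cfg$total_duration)
  expect_lte(max(layout$onset + layout$duration), cfg$total_duration)
})
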