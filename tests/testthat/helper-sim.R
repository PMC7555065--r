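# Shared fixtures for the test suite. Everything is generated in code;
# heavyweight fixtures are built once per test run and memoised here.

small_config <- function(seed = 11, ...) {
  sim_config(seed = seed, n_speech_fragments = 6, n_nonspeech_fragments = 6,
             n_noisy_fragments = 2, n_channels = 4, neural_fs = 512, ...)
}

# A single preprocessed fixture with strongly coupled channels, reused by
# the tracking and regression tests.
.fixture_cache <- new.env(parent = emptyenv())

tracked_fixture <- function() {
  if (!is.null(.fixture_cache$fx)) return(.fixture_cache$fx)
  cfg <- sim_config(seed = 7, n_speech_fragments = 8,
                    n_nonspeech_fragments = 8, n_noisy_fragments = 3,
                    n_channels = 6, neural_fs = 512)
  truth <- ground_truth(
    class = c("envelope_tracking", "envelope_tracking", "stg_like",
              "onoff_only", "unresponsive", "unresponsive"),
    gain = c(3, 3, 3, 3, 0, 0),
    lag = c(0, 300, 0, 0, 0, 0),
    noise_sd = rep(1, 6))
  ann <- make_annotation(cfg)
  audio <- synthesize_audio(ann, cfg)
  feats <- audio_feature_stream(audio$isolated_speech, ann,
                                total_duration = cfg$total_duration)
  feats_mixed <- audio_feature_stream(audio$mixed, ann,
                                      total_duration = cfg$total_duration)
  rec <- synthesize_neural(feats, truth, cfg)
  rec <- notch(rec, freqs = c(50, 100))
  rec <- common_average_reference(rec)
  hfb <- gabor_hfb(rec)
  sp <- extract_speech_fragments(ann, n_max = cfg$n_speech_fragments)
  ns <- extract_nonspeech_fragments(ann, n_match = cfg$n_nonspeech_fragments)
  nz <- extract_noisy_fragments(ann)
  fragset <- fragment_set(rbind(sp, ns))
  hfb <- zscore_over_fragments(hfb, fragset)
  .fixture_cache$fx <- list(cfg = cfg, truth = truth, ann = ann,
                            audio = audio, feats = feats,
                            feats_mixed = feats_mixed, rec = rec,
                            hfb = hfb, fragset = fragset, noisy = nz)
  .fixture_cache$fx
}

rms <- function(x) sqrt(mean(x^2))

# 1-based 100 Hz frame indices covered by a window [onset, onset+duration).
fragment_frames <- function(onset, duration) {
  seq.int(floor(onset * 100 + 1e-9) + 1L, length.out = round(duration * 100))
}

# Pure sinusoid helper.
sine_wave <- function(freq, dur, fs, amp = 1, phase = 0) {
  list(samples = amp * sin(2 * pi * freq * (0:(round(dur * fs) - 1)) / fs +
                             phase), fs = fs)
}
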