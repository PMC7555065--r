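#' Simulation configuration
#'
#' Describes a synthetic film-soundtrack-plus-neural-recording world: an
#' audio track alternating speech-like, nonspeech (music/noise) and noisy
#' speech fragments, and a multichannel neural recording whose designated
#' channels' 65-125 Hz amplitude follows the speech envelope at a known
#' lag and gain.
#'
#' @param seed integer seed; all randomness in the generator derives from
#'   it deterministically.
#' @param n_speech_fragments,n_nonspeech_fragments,n_noisy_fragments
#'   fragment counts (defaults mirror the emulated stimulus: 115/115/63).
#' @param fragment_duration analysis window length in seconds.
#' @param pause_range numeric length-2, range of within-fragment pauses in
#'   seconds; phrasal pauses in natural speech are at least 120-150 ms and
#'   fragments tolerate pauses up to 0.5 s.
#' @param total_duration total recording duration in seconds; `NULL`
#'   chooses a duration that fits all fragments with inter-fragment gaps.
#' @param audio_fs audio sampling rate, Hz (>= 14400 so the 7200 Hz
#'   filterbank ceiling is below Nyquist).
#' @param neural_fs neural sampling rate, Hz (2000 for high-density grids,
#'   512 for low-density clinical grids).
#' @param n_channels number of neural channels.
#' @param snr_noisy_db speech-to-background SNR inside noisy fragments, dB.
#' @param line_noise_hz mains frequency added to the neural signal.
#' @param hand_speech_dependence probability mass shifted between hand
#'   labels by condition; 0 (default) keeps hand labels independent of the
#'   speech condition so the hand-speech contingency null holds.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_speech_fragments = 115L,
                       n_nonspeech_fragments = 115L,
                       n_noisy_fragments = 63L,
                       fragment_duration = 4,
                       pause_range = c(0.12, 0.5),
                       total_duration = NULL,
                       audio_fs = 16000,
                       neural_fs = 2000,
                       n_channels = 8L,
                       snr_noisy_db = 0,
                       line_noise_hz = 50,
                       hand_speech_dependence = 0) {
  stop_if_not(n_speech_fragments >= 0 && n_nonspeech_fragments >= 0 &&
                n_noisy_fragments >= 0, "fragment counts must be >= 0")
  stop_if_not(fragment_duration > 0, "fragment_duration must be > 0")
  stop_if_not(length(pause_range) == 2 && pause_range[1] < pause_range[2],
              "pause_range must be (min, max) with min < max")
  stop_if_not(pause_range[1] >= 0.12 && pause_range[2] <= 0.5,
              "pause_range must lie within [0.12, 0.5] s")
  stop_if_not(audio_fs > 2 * 7200, "audio_fs must exceed 14400 Hz")
  stop_if_not(neural_fs > 250, "neural_fs too low for a 65-125 Hz band")
  n_frag <- n_speech_fragments + n_nonspeech_fragments + n_noisy_fragments
  # Inter-fragment gap of >= 0.5 s keeps windows of different conditions
  # disjoint; 1.0 s budgeted per fragment for layout slack.
  min_needed <- n_frag * (fragment_duration + 1.0) + 1.0
  if (is.null(total_duration)) total_duration <- min_needed
  stop_if_not(total_duration >= min_needed,
              "requested fragments do not fit in total_duration (need >= %.1f s)",
              min_needed)
  structure(list(seed = as.integer(seed),
                 n_speech_fragments = as.integer(n_speech_fragments),
                 n_nonspeech_fragments = as.integer(n_nonspeech_fragments),
                 n_noisy_fragments = as.integer(n_noisy_fragments),
                 fragment_duration = fragment_duration,
                 pause_range = pause_range,
                 total_duration = total_duration,
                 audio_fs = audio_fs, neural_fs = neural_fs,
                 n_channels = as.integer(n_channels),
                 snr_noisy_db = snr_noisy_db,
                 line_noise_hz = line_noise_hz,
                 hand_speech_dependence = hand_speech_dependence),
            class = "sim_config")
}

#' Per-channel ground truth for the neural simulator
#'
#' @param class character vector, one of `envelope_tracking`, `onoff_only`,
#'   `stg_like`, `unresponsive` per channel.
#' @param gain coupling amplitude (dimensionless) per channel.
#' @param lag audio-to-neural lag in ms (within [-100, 500] for tracking
#'   channels).
#' @param noise_sd pink-noise SD per channel (> 0).
#' @return a `ground_truth` data frame.
#' @export
ground_truth <- function(class, gain, lag, noise_sd) {
  n <- length(class)
  stop_if_not(all(class %in% c("envelope_tracking", "onoff_only",
                               "stg_like", "unresponsive")),
              "unknown ground-truth class")
  stop_if_not(all(lengths(list(gain, lag, noise_sd)) == n),
              "ground_truth fields must have equal length")
  stop_if_not(all(noise_sd > 0), "noise_sd must be > 0")
  trk <- class %in% c("envelope_tracking", "stg_like")
  stop_if_not(all(lag[trk] >= -100 & lag[trk] <= 500),
              "tracking-channel lag must be within [-100, 500] ms")
  structure(data.frame(channel = seq_len(n), class = class, gain = gain,
                       lag = lag, noise_sd = noise_sd,
                       stringsAsFactors = FALSE),
            class = c("ground_truth", "data.frame"))
}

#' Generate a synthetic soundtrack annotation
#'
#' Lays out the requested speech, nonspeech and noisy fragment windows
#' left to right with inter-fragment silent gaps, then fills each
#' speech/noisy window with phrases (word intervals) separated by pauses
#' drawn from `pause_range`, so no internal pause exceeds 0.5 s. Each
#' fragment window receives a hand label in \{0, 1, 2\} (no hand / hand
#' present / hand moving), independent of the condition by default.
#'
#' @param config a [sim_config()].
#' @return an [annotation][new_annotation] with attribute
#'   `fragment_layout`: the planted windows (onset, duration, condition).
#' @export
make_annotation <- function(config) {
  set.seed(child_seed(config$seed, "annotation"))
  n_frag <- config$n_speech_fragments + config$n_nonspeech_fragments +
    config$n_noisy_fragments
  conds <- c(rep("speech", config$n_speech_fragments),
             rep("noisy", config$n_noisy_fragments),
             rep("nonspeech", config$n_nonspeech_fragments))
  fd <- config$fragment_duration
  words <- list(); overlap <- list(); nonspeech <- list(); hand <- list()
  layout <- list()
  t0 <- 0.5
  slack <- config$total_duration - 0.5 - n_frag * (fd + 0.5)
  gaps <- if (n_frag > 0) {
    g <- stats::runif(n_frag)
    0.5 + g / sum(g) * max(slack - 0.5, 0)
  } else numeric(0)
  for (i in seq_len(n_frag)) {
    cond <- conds[i]
    win <- c(t0, t0 + fd)
    layout[[i]] <- data.frame(onset = t0, duration = fd, condition = cond,
                              stringsAsFactors = FALSE)
    if (cond %in% c("speech", "noisy")) {
      words[[length(words) + 1L]] <- fill_with_phrases(win, config)
      if (cond == "noisy") {
        overlap[[length(overlap) + 1L]] <-
          data.frame(onset = win[1], offset = win[2], label = "noise",
                     stringsAsFactors = FALSE)
      }
    } else {
      nonspeech[[length(nonspeech) + 1L]] <-
        data.frame(onset = win[1], offset = win[2], label = "music",
                   stringsAsFactors = FALSE)
    }
    p <- c(0.4, 0.2, 0.4)                      # no hand / present / moving
    if (config$hand_speech_dependence > 0 && cond != "nonspeech") {
      d <- config$hand_speech_dependence
      p <- p + c(-d * 0.4, 0, d * 0.4)
      p <- pmax(p, 0); p <- p / sum(p)
    }
    hand[[length(hand) + 1L]] <-
      data.frame(onset = win[1], offset = win[2],
                 label = as.character(sample(0:2, 1, prob = p)),
                 stringsAsFactors = FALSE)
    t0 <- t0 + fd + gaps[i]
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else
    data.frame(onset = numeric(0), offset = numeric(0),
               label = character(0), stringsAsFactors = FALSE)
  ann <- new_annotation(words = bind(words), overlap = bind(overlap),
                        nonspeech = bind(nonspeech), hand = bind(hand),
                        total_duration = config$total_duration)
  attr(ann, "fragment_layout") <- if (length(layout))
    do.call(rbind, layout) else
      data.frame(onset = numeric(0), duration = numeric(0),
                 condition = character(0), stringsAsFactors = FALSE)
  ann
}

# Fill one fragment window with word intervals: phrases of 1-4 words
# separated by pauses drawn from pause_range; fragment starts and ends on
# speech so the window is continuous speech per the <= 0.5 s pause rule.
fill_with_phrases <- function(win, config) {
  lo <- config$pause_range[1]; hi <- config$pause_range[2]
  on <- numeric(0); off <- numeric(0)
  t <- win[1]
  end <- win[2]
  repeat {
    n_words <- sample(1:4, 1)
    for (w in seq_len(n_words)) {
      dur <- stats::runif(1, 0.15, 0.5)
      if (t + dur > end) { dur <- end - t }
      if (dur < 0.05) break
      on <- c(on, t); off <- c(off, t + dur)
      t <- t + dur
      if (t >= end - 1e-9) break
      if (w < n_words) {
        gap <- stats::runif(1, 0.02, 0.1)     # within-phrase micro-gap
        if (t + gap >= end) { off[length(off)] <- end; t <- end }
        t <- t + gap
      }
    }
    if (t >= end - 1e-9) break
    pause <- stats::runif(1, lo, hi)
    if (t + pause + 0.15 > end) {
      # not enough room for a pause plus a word: extend the last word
      off[length(off)] <- end
      break
    }
    t <- t + pause
  }
  data.frame(onset = on, offset = off, label = "w", stringsAsFactors = FALSE)
}

#' Synthesize the mixed and isolated-speech audio tracks
#'
#' The isolated speech track is nonzero only inside word intervals: a
#' harmonic complex whose fundamental follows a random walk in
#' 100-300 Hz, amplitude-modulated at a syllabic rate (3-8 Hz). The mixed
#' track adds a music/noise-like background (filtered noise with slow AM)
#' inside nonspeech windows and, inside noisy windows, background scaled
#' so the within-fragment speech-to-background power ratio matches
#' `snr_noisy_db`.
#'
#' @param ann annotation from [make_annotation()].
#' @param config the [sim_config()] used to build `ann`.
#' @return list with `mixed` and `isolated_speech`, each a list
#'   `(samples, fs)`.
#' @export
synthesize_audio <- function(ann, config) {
  set.seed(child_seed(config$seed, "audio"))
  fs <- config$audio_fs
  n <- round(config$total_duration * fs)
  speech <- numeric(n)
  tt <- (seq_len(n) - 1) / fs
  # --- speech source: harmonic complex with random-walk f0 + syllabic AM
  for (i in seq_len(nrow(ann$words))) {
    i0 <- floor(ann$words$onset[i] * fs) + 1L
    i1 <- min(ceiling(ann$words$offset[i] * fs), n)
    if (i1 <= i0) next
    m <- i1 - i0 + 1L
    syl <- stats::runif(1, 3, 8)
    am <- 0.55 + 0.45 * sin(2 * pi * syl * tt[i0:i1] +
                              stats::runif(1, 0, 2 * pi))
    f0 <- 150 + cumsum(stats::rnorm(m, 0, 40 / sqrt(fs)))
    # prosodic stress: louder syllables carry higher f0 (a standard
    # property of natural speech; keeps pitch and envelope related
    # within words, not only through the shared voicing gate)
    f0 <- f0 * (0.85 + 0.25 * am)
    f0 <- pmin(pmax(f0, 100), 300)
    phase <- 2 * pi * cumsum(f0) / fs
    x <- 0.6 * sin(phase) + 0.3 * sin(2 * phase) + 0.15 * sin(3 * phase)
    ramp_n <- min(round(0.005 * fs), floor(m / 2))
    ramp <- rep(1, m)
    if (ramp_n > 0) {
      ramp[seq_len(ramp_n)] <- seq(0, 1, length.out = ramp_n)
      ramp[(m - ramp_n + 1L):m] <- seq(1, 0, length.out = ramp_n)
    }
    speech[i0:i1] <- 0.3 * x * am * ramp
  }
  # --- background: low-passed noise with slow "musical" AM
  background <- numeric(n)
  layout <- attr(ann, "fragment_layout")
  bg_windows <- rbind(
    if (nrow(ann$nonspeech)) cbind(ann$nonspeech$onset, ann$nonspeech$offset),
    if (!is.null(layout) && any(layout$condition == "noisy")) {
      nz <- layout[layout$condition == "noisy", , drop = FALSE]
      cbind(nz$onset, nz$onset + nz$duration)
    })
  # target background loudness: mean |amplitude| of the speech track over
  # speech windows, so speech and nonspeech fragments match in intensity
  # (the emulated stimulus shows no speech/nonspeech intensity difference)
  sp_wins <- layout[layout$condition == "speech", , drop = FALSE]
  sp_level <- if (nrow(sp_wins) > 0) {
    widx <- unlist(lapply(seq_len(nrow(sp_wins)), function(i) {
      seq.int(floor(sp_wins$onset[i] * fs) + 1L,
              min(ceiling((sp_wins$onset[i] + sp_wins$duration[i]) * fs), n))
    }))
    mean(abs(speech[widx]))                   # pauses included
  } else 0.1
  if (!is.null(bg_windows) && nrow(bg_windows) > 0 &&
      is.finite(config$snr_noisy_db)) {
    for (i in seq_len(nrow(bg_windows))) {
      i0 <- floor(bg_windows[i, 1] * fs) + 1L
      i1 <- min(ceiling(bg_windows[i, 2] * fs), n)
      if (i1 <= i0) next
      m <- i1 - i0 + 1L
      noise <- stats::rnorm(m)
      # crude low-pass: 3-point moving average cascade shapes it music-like
      for (k in 1:3) noise <- stats::filter(noise, rep(1 / 3, 3),
                                            circular = TRUE)
      noise <- as.numeric(noise)
      am <- 0.6 + 0.4 * sin(2 * pi * stats::runif(1, 0.5, 2) *
                              tt[i0:i1] + stats::runif(1, 0, 2 * pi))
      bg <- noise * am
      sp_pow <- mean(speech[i0:i1]^2)
      if (sp_pow > 0) {
        # noisy window: match SNR to speech within the window
        target <- sp_pow / 10^(config$snr_noisy_db / 10)
        bg <- bg * sqrt(target / mean(bg^2))
      } else {
        # match speech loudness up to ~10% natural per-scene variation
        bg <- bg * sp_level * exp(stats::rnorm(1, 0, 0.1)) / mean(abs(bg))
      }
      background[i0:i1] <- bg
    }
  }
  list(mixed = list(samples = speech + background, fs = fs),
       isolated_speech = list(samples = speech, fs = fs))
}

#' Default ground truth for a configuration
#'
#' Assigns channel classes round-robin: envelope trackers at lags spread
#' over \{0, 100, 300, 500\} ms, one `stg_like` reference channel, one
#' `onoff_only` channel, remainder `unresponsive`.
#'
#' @param config a [sim_config()].
#' @param gain coupling gain for responsive channels.
#' @param noise_sd pink-noise SD for all channels.
#' @param lags lag pool (ms) cycled over envelope-tracking channels.
#' @return a [ground_truth()].
#' @export
default_ground_truth <- function(config, gain = 3, noise_sd = 1,
                                 lags = c(0, 100, 300, 500)) {
  n <- config$n_channels
  cls <- rep("unresponsive", n)
  n_track <- max(ceiling(n / 2), min(n, 1))
  cls[seq_len(n_track)] <- "envelope_tracking"
  if (n >= n_track + 1) cls[n_track + 1] <- "stg_like"
  if (n >= n_track + 2) cls[n_track + 2] <- "onoff_only"
  lag <- numeric(n)
  lag[cls == "envelope_tracking"] <-
    rep_len(lags, sum(cls == "envelope_tracking"))
  g <- ifelse(cls == "unresponsive", 0, gain)
  ground_truth(cls, g, lag, rep(noise_sd, n))
}

#' Synthesize a multichannel neural recording coupled to audio features
#'
#' Each channel is pink noise plus a mains sinusoid; responsive channels
#' additionally carry 65-125 Hz band-limited noise whose instantaneous
#' amplitude is `1 + gain * feature(t - lag)` where the feature is the
#' standardized speech envelope (`envelope_tracking`, `stg_like`) or the
#' binary speech ON/OFF vector (`onoff_only`).
#'
#' @param features a [feature_stream][feature_stream] at 100 Hz covering
#'   the recording.
#' @param truth a [ground_truth()] with one row per channel.
#' @param config the [sim_config()].
#' @return a [raw_recording()] at `config$neural_fs`.
#' @export
synthesize_neural <- function(features, truth, config) {
  stop_if_not(nrow(truth) == config$n_channels,
              "ground truth must have one entry per channel")
  stop_if_not(all(abs(truth$lag) <= 1000),
              "lag outside representable range")
  set.seed(child_seed(config$seed, "neural"))
  fs <- config$neural_fs
  n <- round(config$total_duration * fs)
  tt <- (seq_len(n) - 1) / fs
  ft <- features$time
  env_z <- features$envelope / max(stats::sd(features$envelope), 1e-12)
  onoff <- features$onoff
  samples <- matrix(0, nrow = config$n_channels, ncol = n)
  for (ch in seq_len(config$n_channels)) {
    x <- pink_noise(n) * truth$noise_sd[ch]
    x <- x + 0.5 * truth$noise_sd[ch] *
      sin(2 * pi * config$line_noise_hz * tt)
    if (truth$class[ch] != "unresponsive" && truth$gain[ch] != 0) {
      feat <- if (truth$class[ch] == "onoff_only") onoff else env_z
      mod <- resample_linear(feat, ft + truth$lag[ch] / 1000, tt)
      amp <- pmax(1 + truth$gain[ch] * mod, 0)
      carrier <- band_limited_noise(n, fs, 65, 125)
      x <- x + carrier * amp
    }
    samples[ch, ] <- x
  }
  meta <- data.frame(
    id = sprintf("E%03d", seq_len(config$n_channels)),
    grid = "HD1", good = TRUE,
    anatomy = ifelse(truth$class == "stg_like", "STG", "dPCC"),
    stringsAsFactors = FALSE)
  raw_recording(samples, fs = fs, channel_meta = meta)
}

# 1/f-amplitude noise, unit SD, via frequency-domain shaping.
pink_noise <- function(n) {
  nfft <- next_pow2(n)
  spec <- stats::fft(stats::rnorm(nfft))
  f <- c(1, seq_len(nfft - 1))
  f <- pmin(f, nfft - f + 1)                  # symmetric bin distance
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  (x - mean(x)) / stats::sd(x)
}

# Gaussian noise band-passed to [f_lo, f_hi] by FFT masking, unit SD.
band_limited_noise <- function(n, fs, f_lo, f_hi) {
  nfft <- next_pow2(n)
  spec <- stats::fft(stats::rnorm(nfft))
  freq <- (seq_len(nfft) - 1) * fs / nfft
  freq <- pmin(freq, fs - freq)
  spec[freq < f_lo | freq > f_hi] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Writes the mixed and isolated WAVs, the annotation (TextGrid + TSV
#' mirror), the neural container (binary + JSON sidecar) and the ground
#' truth JSON, and returns the paths together with the in-memory objects.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if missing).
#' @param truth optional [ground_truth()]; defaults to
#'   [default_ground_truth()].
#' @return invisibly, a list of paths and the generated objects.
#' @export
make_fixture <- function(config, dir, truth = default_ground_truth(config)) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    stop_if_not(ok && dir.exists(dir), "cannot create fixture dir %s", dir)
  }
  ann <- make_annotation(config)
  audio <- synthesize_audio(ann, config)
  feats <- audio_feature_stream(audio$isolated_speech, ann,
                                total_duration = config$total_duration)
  rec <- synthesize_neural(feats, truth, config)
  paths <- list(
    mixed_wav = file.path(dir, "mixed.wav"),
    isolated_wav = file.path(dir, "isolated_speech.wav"),
    textgrid = file.path(dir, "annotation.TextGrid"),
    annotation_tsv = file.path(dir, "annotation.tsv"),
    neural = file.path(dir, "neural.f32"),
    ground_truth = file.path(dir, "ground_truth.json"))
  write_wav(paths$mixed_wav, audio$mixed$samples, config$audio_fs)
  write_wav(paths$isolated_wav, audio$isolated_speech$samples,
            config$audio_fs)
  write_textgrid(ann, paths$textgrid)
  write_annotation_tsv(ann, paths$annotation_tsv)
  write_neural(rec, paths$neural)
  jsonlite::write_json(truth, paths$ground_truth, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(list(paths = paths, annotation = ann, audio = audio,
                 features = feats, recording = rec, truth = truth,
                 config = config))
}
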