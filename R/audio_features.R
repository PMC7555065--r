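#' Cochlear-style log-frequency spectrogram
#'
#' A constant-Q-style time-frequency representation: the waveform is
#' analyzed with a Hann-windowed STFT at 8 ms hops, and the magnitude
#' spectrum of each frame is projected onto 128 logarithmically spaced
#' frequency channels between 180 and 7200 Hz using Gaussian weights
#' whose width is proportional to the channel's centre frequency
#' (constant Q). Each STFT magnitude bin is the modulus of a band-passed
#' analytic signal, i.e. a rectified and smoothed band-pass output, so
#' the representation is linear in input amplitude.
#'
#' @param wave list with `samples` (mono) and `fs` (Hz).
#' @param n_bins number of frequency channels.
#' @param f_range frequency range, Hz.
#' @param frame_step frame hop in seconds (8 ms, i.e. 125 frames/s).
#' @param win_length analysis window length in seconds.
#' @return a `spectrogram`: list with `magnitudes` (bins x frames),
#'   `center_freqs`, `frame_step`, `frame_times`.
#' @export
cochlear_spectrogram <- function(wave, n_bins = 128,
                                 f_range = c(180, 7200),
                                 frame_step = 0.008,
                                 win_length = 0.032) {
  fs <- wave$fs
  x <- wave$samples
  stop_if_not(all(is.finite(x)), "waveform contains non-finite samples")
  hop <- round(frame_step * fs)
  wl <- round(win_length * fs)
  stop_if_not(length(x) >= wl, "waveform shorter than one analysis frame")
  n_frames <- 1L + (length(x) - wl) %/% hop
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(wl) / (wl + 1))
  nfft <- next_pow2(wl)
  fft_freqs <- (seq_len(nfft %/% 2 + 1L) - 1L) * fs / nfft
  centers <- exp(seq(log(f_range[1]), log(f_range[2]),
                     length.out = n_bins))
  # Gaussian constant-Q weights; sigma at least one FFT bin wide so no
  # channel falls between bins.
  dfreq <- fs / nfft
  W <- sapply(centers, function(fc) {
    sig <- max(fc * 0.03, dfreq)
    w <- exp(-(fft_freqs - fc)^2 / (2 * sig^2))
    w / sum(w)
  })                                            # (nfft/2+1) x n_bins
  mags <- matrix(0, nrow = n_bins, ncol = n_frames)
  idx0 <- (seq_len(n_frames) - 1L) * hop
  frames <- matrix(0, nrow = nfft, ncol = n_frames)
  for (i in seq_len(n_frames)) {
    frames[seq_len(wl), i] <- x[idx0[i] + seq_len(wl)] * win
  }
  Fm <- Mod(stats::mvfft(frames))[seq_len(nfft %/% 2 + 1L), , drop = FALSE]
  mags <- crossprod(W, Fm)                      # n_bins x n_frames
  structure(list(magnitudes = mags, center_freqs = centers,
                 frame_step = frame_step,
                 frame_times = (idx0 + wl / 2) / fs),
            class = "spectrogram")
}

#' Spectral envelope at 100 Hz
#'
#' Per-frame mean of the spectrogram over its frequency channels,
#' linearly interpolated from the native 125 Hz frame rate onto 10 ms
#' frame centers.
#'
#' @param spec a [cochlear_spectrogram()].
#' @param duration output duration in seconds; defaults to the
#'   spectrogram span.
#' @return non-negative numeric vector at 100 Hz.
#' @export
spectral_envelope <- function(spec, duration = NULL) {
  env_native <- colMeans(spec$magnitudes)
  if (is.null(duration)) duration <- max(spec$frame_times)
  n_out <- round(duration * 100)
  out <- resample_linear(env_native, spec$frame_times,
                         frame_centers(n_out))
  pmax(out, 0)
}

#' Autocorrelation pitch contour at 100 Hz
#'
#' Per 10 ms frame, the fundamental frequency is the inverse of the lag
#' maximizing the window-corrected normalized autocorrelation (frame
#' autocorrelation divided by the window autocorrelation) within
#' `[1/ceiling, 1/floor]`, with parabolic interpolation around the peak.
#' Frames whose peak autocorrelation falls below `voicing_threshold` are
#' unvoiced and coded 0, so the series is defined everywhere.
#'
#' @param wave list with `samples`, `fs`.
#' @param floor,ceiling pitch search range, Hz.
#' @param voicing_threshold minimum normalized autocorrelation for a
#'   frame to count as voiced.
#' @param octave_cost penalty per octave below the ceiling applied to
#'   candidate strengths, favouring the shorter lag when a perfectly
#'   periodic signal peaks equally at its period and its multiples.
#' @return numeric vector at 100 Hz (Hz; 0 = unvoiced).
#' @export
pitch_autocorr <- function(wave, floor = 75, ceiling = 600,
                           voicing_threshold = 0.45, octave_cost = 0.02) {
  fs <- wave$fs
  stop_if_not(floor < ceiling && ceiling < fs / 2,
              "need floor < ceiling < fs/2")
  wl <- round(3 / floor * fs)                  # 3 periods of the floor
  stop_if_not(length(wave$samples) >= wl,
              "waveform shorter than 3 periods of the pitch floor")
  hop <- round(0.01 * fs)
  x <- wave$samples
  n_frames <- max(1L + (length(x) - wl) %/% hop, 1L)
  lag_min <- max(floor(fs / ceiling), 2)
  lag_max <- base::ceiling(fs / floor)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(wl) / (wl + 1))
  nfft <- next_pow2(2L * wl)
  # autocorrelation of the window itself, for Boersma's correction
  Wf <- stats::fft(c(win, rep(0, nfft - wl)))
  rw <- Re(stats::fft(Mod(Wf)^2, inverse = TRUE))[1:(lag_max + 1L)] / nfft
  rw <- rw / rw[1]
  sw <- sinc_weights()
  out <- numeric(n_frames)
  for (i in seq_len(n_frames)) {
    seg <- x[(i - 1L) * hop + seq_len(wl)]
    seg <- (seg - mean(seg)) * win
    if (sum(seg^2) < 1e-12) next
    Sf <- stats::fft(c(seg, rep(0, nfft - wl)))
    rx <- Re(stats::fft(Mod(Sf)^2, inverse = TRUE))[1:(lag_max + 1L)] / nfft
    rx <- rx / rx[1]
    r <- rx / rw                               # window-corrected
    # candidate lags = local maxima of r; parabolic interpolation of both
    # height and position (the sampled peak underestimates the height
    # whenever the true period falls between samples, which would
    # otherwise favour its on-sample integer multiples)
    ks <- (lag_min + 1L):(lag_max + 1L)         # 1-based: lag k at k+1
    ks <- ks[ks > 2L & ks < length(r)]
    is_max <- r[ks] > r[ks - 1L] & r[ks] >= r[ks + 1L]
    cand <- ks[is_max]
    if (length(cand) == 0L) next
    ref <- vapply(cand, function(k) sinc_peak(r, k, sw), numeric(2))
    lag <- ref[1, ]
    # the window correction can push r above 1 at long lags; a true
    # normalized autocorrelation cannot exceed 1
    height <- pmin(ref[2, ], 1)
    score <- height - octave_cost * log2(floor * lag / fs)
    best <- which.max(score)
    if (height[best] < voicing_threshold) next
    out[i] <- fs / lag[best]
  }
  out
}

# Sinc-interpolated refinement of a local maximum of a sampled sequence
# around 1-based index k0: returns c(lag, height) where lag is 0-based and
# fractional. Parabolic interpolation underestimates cusp-like peaks of
# autocorrelation sequences, which would bias the voiced/octave decision.
# The interpolation weights are independent of k0 away from the edges, so
# they are computed once (sinc_weights) and reused.
sinc_weights <- function(depth = 12L, grid = 0.02) {
  taus <- seq(-1, 1, by = grid)
  ks <- -depth:depth
  d <- outer(taus, ks, "-")
  w <- ifelse(abs(d) < 1e-9, 1, sin(pi * d) / (pi * d))
  list(w = w, taus = taus, depth = depth, grid = grid)
}

sinc_peak <- function(r, k0, sw = sinc_weights()) {
  depth <- sw$depth
  if (k0 - depth >= 1L && k0 + depth <= length(r)) {
    vals <- as.numeric(sw$w %*% r[(k0 - depth):(k0 + depth)])
  } else {
    ks <- max(k0 - depth, 1L):min(k0 + depth, length(r))
    d <- outer(k0 + sw$taus, ks, "-")
    w <- ifelse(abs(d) < 1e-9, 1, sin(pi * d) / (pi * d))
    vals <- as.numeric(w %*% r[ks])
  }
  j <- which.max(vals)
  c(k0 - 1 + sw$taus[j], vals[j])              # 0-based fractional lag
}

#' Binary sound ON/OFF series from intensity
#'
#' Frame intensity is the RMS in consecutive 10 ms frames expressed in
#' dB; frames louder than `I_max - margin_db` (with `I_max` the maximal
#' frame intensity) are ON.
#'
#' @param wave list with `samples`, `fs`.
#' @param margin_db threshold below the maximum, dB.
#' @return integer 0/1 vector at 100 Hz.
#' @export
sound_onoff <- function(wave, margin_db = 35) {
  stop_if_not(any(wave$samples != 0), "all-zero input: I_max undefined")
  block <- round(0.01 * wave$fs)
  n <- length(wave$samples)
  g <- ceiling(seq_len(n) / block)
  pow <- as.numeric(tapply(wave$samples^2, g, mean))
  db <- 10 * log10(pmax(pow, 1e-20))
  as.integer(db > max(db) - margin_db)
}

#' Per-fragment sound intensity
#'
#' Mean absolute sample amplitude (or RMS) within each fragment window.
#'
#' @param wave list with `samples`, `fs`.
#' @param fragset a [fragment_set()].
#' @param method `"meanabs"` (default) or `"rms"`.
#' @return numeric vector, one value per fragment.
#' @export
fragment_intensity <- function(wave, fragset,
                               method = c("meanabs", "rms")) {
  method <- match.arg(method)
  vapply(seq_len(nrow(fragset)), function(i) {
    i0 <- base::floor(fragset$onset[i] * wave$fs) + 1L
    i1 <- min(base::ceiling((fragset$onset[i] + fragset$duration[i]) *
                              wave$fs), length(wave$samples))
    stop_if_not(i1 >= i0, "empty fragment %d", i)
    seg <- wave$samples[i0:i1]
    if (method == "meanabs") mean(abs(seg)) else rms(seg)
  }, 0)
}

#' Full auditory feature stream at 100 Hz
#'
#' Bundles the three regressors on one time base: spectral envelope,
#' pitch contour (0 where unvoiced) and the binary speech ON/OFF vector
#' derived from the word annotation (frame-center membership).
#'
#' @param wave list with `samples`, `fs` (typically the isolated speech
#'   track).
#' @param ann an [annotation][new_annotation] (for the ON/OFF vector); if
#'   `NULL`, ON/OFF falls back to the intensity rule of [sound_onoff()].
#' @param total_duration series duration in seconds (defaults to the
#'   waveform duration).
#' @param pitch_floor,pitch_ceiling,voicing_threshold pitch parameters.
#' @return a `feature_stream`: list with `time`, `envelope`, `pitch`,
#'   `onoff`, all length `100 * total_duration`.
#' @export
audio_feature_stream <- function(wave, ann = NULL, total_duration = NULL,
                                 pitch_floor = 75, pitch_ceiling = 600,
                                 voicing_threshold = 0.45) {
  if (is.null(total_duration)) {
    total_duration <- length(wave$samples) / wave$fs
  }
  n <- round(total_duration * 100)
  tt <- frame_centers(n)
  spec <- cochlear_spectrogram(wave)
  env <- spectral_envelope(spec, duration = total_duration)
  pitch <- pitch_autocorr(wave, pitch_floor, pitch_ceiling,
                          voicing_threshold)
  pitch <- c(pitch, rep(0, max(n - length(pitch), 0)))[seq_len(n)]
  onoff <- if (!is.null(ann)) {
    as.integer(in_intervals(tt, ann$words$onset, ann$words$offset))
  } else {
    oo <- sound_onoff(wave)
    c(oo, rep(0L, max(n - length(oo), 0)))[seq_len(n)]
  }
  structure(list(time = tt, envelope = env[seq_len(n)], pitch = pitch,
                 onoff = onoff),
            class = "feature_stream")
}

#' @export
print.feature_stream <- function(x, ...) {
  cat(sprintf("<feature_stream> %d frames @ 100 Hz (%.1f s), %.0f%% ON\n",
              length(x$time), length(x$time) / 100,
              100 * mean(x$onoff)))
  invisible(x)
}

#' Write / read a feature stream as TSV
#'
#' Columns: `time`, `envelope`, `pitch`, `onoff`.
#'
#' @param feats a `feature_stream`.
#' @param path output path.
#' @return `read_feature_stream()` returns a `feature_stream`.
#' @export
write_feature_stream <- function(feats, path) {
  utils::write.table(
    data.frame(time = feats$time, envelope = feats$envelope,
               pitch = feats$pitch, onoff = feats$onoff),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_stream
#' @export
read_feature_stream <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  structure(list(time = df$time, envelope = df$envelope,
                 pitch = df$pitch, onoff = as.integer(df$onoff)),
            class = "feature_stream")
}
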