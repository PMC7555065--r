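#' Raw multichannel recording container
#'
#' @param samples numeric matrix, channels x time (arbitrary units).
#' @param fs sampling rate, Hz.
#' @param channel_meta data frame with one row per channel and columns
#'   `id`, `grid`, `good`, `anatomy`.
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(samples, fs, channel_meta = NULL) {
  samples <- as.matrix(samples)
  if (is.null(channel_meta)) {
    channel_meta <- data.frame(
      id = sprintf("E%03d", seq_len(nrow(samples))),
      grid = "G1", good = TRUE, anatomy = "unknown",
      stringsAsFactors = FALSE)
  }
  stop_if_not(nrow(channel_meta) == nrow(samples),
              "channel_meta must have one row per channel")
  stop_if_not(any(channel_meta$good), "at least one good channel required")
  structure(list(samples = samples, fs = fs, channel_meta = channel_meta),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%d good)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              sum(x$channel_meta$good)))
  invisible(x)
}

#' High-frequency-band amplitude matrix
#'
#' Channels x frames amplitude matrix on an exact 100 Hz frame grid.
#'
#' @param values numeric matrix channels x frames.
#' @param channel_meta per-channel metadata (as in [raw_recording()]).
#' @param zscored logical flag: values standardized over fragment frames.
#' @param edge_frames integer vector of frame indices whose wavelet
#'   support touched the recording edge (computed with reflection
#'   padding).
#' @return an object of class `hfb_matrix`.
#' @export
hfb_matrix <- function(values, channel_meta, zscored = FALSE,
                       edge_frames = integer(0)) {
  values <- as.matrix(values)
  good <- channel_meta$good
  stop_if_not(all(is.finite(values[good, , drop = FALSE])),
              "non-finite HFB values on good channels")
  structure(list(values = values, frame_rate = 100,
                 frame_times = frame_centers(ncol(values)),
                 channel_meta = channel_meta, zscored = zscored,
                 edge_frames = edge_frames),
            class = "hfb_matrix")
}

#' @export
print.hfb_matrix <- function(x, ...) {
  cat(sprintf("<hfb_matrix> %d channels x %d frames @ 100 Hz (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$zscored) "z-scored" else "raw amplitude"))
  invisible(x)
}

#' Flag bad channels
#'
#' Marks channels as bad (noisy/flat on visual inspection); they are kept
#' in the metadata but excluded from all subsequent computation.
#'
#' @param rec a [raw_recording()].
#' @param bad_ids character vector of channel ids to reject.
#' @return the recording with updated `good` flags.
#' @export
reject_channels <- function(rec, bad_ids) {
  if (length(bad_ids) == 0L) return(rec)
  unknown <- setdiff(bad_ids, rec$channel_meta$id)
  stop_if_not(length(unknown) == 0L, "unknown channel id(s): %s",
              paste(unknown, collapse = ", "))
  rec$channel_meta$good[rec$channel_meta$id %in% bad_ids] <- FALSE
  stop_if_not(any(rec$channel_meta$good), "all channels rejected")
  rec
}

# RBJ biquad notch coefficients (b, a) for centre f0 and -3 dB width bw.
biquad_notch <- function(f0, fs, bw = 4) {
  w0 <- 2 * pi * f0 / fs
  Q <- f0 / bw
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Direct-form II transposed biquad, single pass.
biquad_filter <- function(x, b, a) {
  xf <- stats::filter(x, b, method = "convolution", sides = 1)
  xf[is.na(xf)] <- b[1] * x[is.na(xf)]          # warm-up samples
  as.numeric(stats::filter(xf, -a[-1], method = "recursive"))
}

# Zero-phase (forward-backward) biquad with reflection padding.
filtfilt_biquad <- function(x, b, a) {
  npad <- min(length(x) - 1L, 3000L)
  xp <- reflect_pad(x, npad)
  y <- biquad_filter(xp, b, a)
  y <- rev(biquad_filter(rev(y), b, a))
  y[(npad + 1L):(npad + length(x))]
}

#' Notch filter for line noise
#'
#' Zero-phase second-order IIR notches (forward-backward biquad,
#' -3 dB width `bw` Hz) applied at each frequency in `freqs` to every
#' good channel.
#'
#' @param rec a [raw_recording()].
#' @param freqs notch centre frequencies, Hz (default mains fundamental
#'   and first harmonic).
#' @param bw -3 dB width of each notch, Hz.
#' @return filtered recording.
#' @export
notch <- function(rec, freqs = c(50, 100), bw = 4) {
  if (length(freqs) == 0L) return(rec)
  stop_if_not(all(freqs < rec$fs / 2), "notch frequency >= Nyquist")
  good <- which(rec$channel_meta$good)
  for (f0 in freqs) {
    co <- biquad_notch(f0, rec$fs, bw)
    for (ch in good) {
      rec$samples[ch, ] <- filtfilt_biquad(rec$samples[ch, ], co$b, co$a)
    }
  }
  rec
}

#' Common average referencing per grid
#'
#' Subtracts, at every sample, the mean over good channels within each
#' grid. Bad channels are left untouched.
#'
#' @param rec a [raw_recording()].
#' @return re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  for (g in unique(rec$channel_meta$grid)) {
    idx <- which(rec$channel_meta$grid == g & rec$channel_meta$good)
    stop_if_not(length(idx) >= 2,
                "grid %s has fewer than 2 good channels", g)
    avg <- colMeans(rec$samples[idx, , drop = FALSE])
    rec$samples[idx, ] <- sweep(rec$samples[idx, , drop = FALSE], 2, avg)
  }
  rec
}

# Complex Gabor atom at frequency f: Gaussian amplitude envelope with
# FWHM = fwhm_cycles / f seconds, truncated at +-4 sigma, normalized so
# a unit-amplitude real sinusoid at f yields modulus 1.
gabor_kernel <- function(f, fs, fwhm_cycles = 4) {
  fwhm <- fwhm_cycles / f
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- ceiling(4 * sigma * fs)
  t <- (-half:half) / fs
  env <- exp(-t^2 / (2 * sigma^2))
  k <- env * exp(1i * 2 * pi * f * t)
  k * (2 / sum(env))
}

#' Gabor-wavelet high-frequency-band amplitude
#'
#' Convolves each good channel with complex Gabor atoms at 1 Hz spaced
#' bins across `band`, takes the modulus per bin, averages over bins, and
#' resamples to 100 Hz by averaging the (smooth) amplitude within
#' consecutive 10 ms frames. Each atom's Gaussian amplitude envelope has
#' a full width at half maximum of `fwhm_cycles` periods of its centre
#' frequency. Edges are handled with reflection padding; frames whose
#' wavelet support touched an edge are flagged in `edge_frames`.
#'
#' @param rec a [raw_recording()] (ideally after [notch()] and
#'   [common_average_reference()]).
#' @param band frequency band (Hz), default 65-125 Hz.
#' @param bin_step bin spacing in Hz.
#' @param fwhm_cycles wavelet envelope FWHM in cycles.
#' @return an [hfb_matrix()] with raw (non-z-scored) amplitudes.
#' @export
gabor_hfb <- function(rec, band = c(65, 125), bin_step = 1,
                      fwhm_cycles = 4) {
  stop_if_not(band[1] > 0 && band[2] < rec$fs / 2,
              "band must lie within (0, fs/2)")
  freqs <- seq(band[1], band[2], by = bin_step)
  n <- ncol(rec$samples)
  n_frames <- base::ceiling(n / rec$fs * 100)
  good <- which(rec$channel_meta$good)
  values <- matrix(0, nrow = nrow(rec$samples), ncol = n_frames)
  # widest kernel (lowest frequency) defines padding and the edge flag
  max_half <- ceiling(4 * (fwhm_cycles / band[1]) /
                        (2 * sqrt(2 * log(2))) * rec$fs)
  kernels <- lapply(freqs, gabor_kernel, fs = rec$fs,
                    fwhm_cycles = fwhm_cycles)
  np <- n + 2L * max_half
  max_nk <- max(lengths(kernels))
  nfft <- next_pow2(np + max_nk - 1L)
  kfft <- lapply(kernels, function(k)
    stats::fft(c(k, rep(0, nfft - length(k)))))
  halves <- vapply(kernels, function(k) (length(k) - 1L) %/% 2L, 0L)
  for (ch in good) {
    xp <- reflect_pad(rec$samples[ch, ], max_half)
    X <- stats::fft(c(xp, rep(0, nfft - np)))
    amp <- numeric(n)
    for (j in seq_along(kfft)) {
      full <- stats::fft(X * kfft[[j]], inverse = TRUE) / nfft
      sel <- (halves[j] + max_half + 1L):(halves[j] + max_half + n)
      amp <- amp + Mod(full[sel])
    }
    values[ch, ] <- frame_average(amp / length(kernels), rec$fs)
  }
  edge <- base::ceiling(max_half / rec$fs * 100)
  hfb_matrix(values, rec$channel_meta, zscored = FALSE,
             edge_frames = c(seq_len(edge),
                             seq.int(n_frames - edge + 1L, n_frames)))
}

#' Z-score HFB amplitudes over fragment frames
#'
#' Per good channel, standardizes using the mean and SD computed over the
#' union of fragment frames; frames outside fragments are transformed
#' with the same parameters.
#'
#' @param hfb an [hfb_matrix()].
#' @param fragset a [fragment_set()] whose windows lie inside the
#'   recording span.
#' @return z-scored [hfb_matrix()].
#' @export
zscore_over_fragments <- function(hfb, fragset) {
  frames <- sort(unique(unlist(lapply(seq_len(nrow(fragset)), function(i)
    fragment_frames(fragset$onset[i], fragset$duration[i])))))
  stop_if_not(max(frames) <= ncol(hfb$values),
              "fragments extend beyond recording span")
  good <- which(hfb$channel_meta$good)
  for (ch in good) {
    v <- hfb$values[ch, frames]
    s <- stats::sd(v)
    stop_if_not(s > 0, "zero-variance channel %s",
                hfb$channel_meta$id[ch])
    hfb$values[ch, ] <- (hfb$values[ch, ] - mean(v)) / s
  }
  hfb$zscored <- TRUE
  hfb
}
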