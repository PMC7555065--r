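# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_if_not <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = call.)
}

# Frame centers of a 100 Hz grid covering [0, duration) seconds.
frame_centers <- function(n_frames, frame_rate = 100) {
  (seq_len(n_frames) - 0.5) / frame_rate
}

# Half-open interval membership: onset <= t < offset for any row.
in_intervals <- function(t, onsets, offsets) {
  if (length(onsets) == 0L) return(rep(FALSE, length(t)))
  idx <- findInterval(t, onsets)
  idx > 0L & t < offsets[pmax(idx, 1L)]
}

# Linear interpolation of a regularly sampled series onto new times.
# Times outside the support are clamped to the edge values.
resample_linear <- function(x, times_in, times_out) {
  stats::approx(times_in, x, xout = times_out, rule = 2)$y
}

# Next power of two >= n (FFT-friendly length).
next_pow2 <- function(n) 2^ceiling(log2(max(n, 2)))

# FFT-based full convolution of a real signal with a (possibly complex)
# kernel, returning the "same"-aligned part: output[i] corresponds to the
# kernel centered on input sample i. Kernel length must be odd.
conv_same <- function(x, kernel) {
  nx <- length(x)
  nk <- length(kernel)
  stopifnot(nk %% 2L == 1L)
  nfft <- next_pow2(nx + nk - 1L)
  X <- stats::fft(c(x, rep(0, nfft - nx)))
  K <- stats::fft(c(kernel, rep(0, nfft - nk)))
  full <- stats::fft(X * K, inverse = TRUE) / nfft
  half <- (nk - 1L) %/% 2L
  full[(half + 1L):(half + nx)]
}

# Reflection padding (no repeated edge sample).
reflect_pad <- function(x, n) {
  n <- min(n, length(x) - 1L)
  c(rev(x[2:(n + 1L)]), x, rev(x[(length(x) - n):(length(x) - 1L)]))
}

# Average samples into 10 ms frames by the time of each sample; works for
# any fs (512 Hz is not an integer multiple of the 100 Hz frame rate).
frame_average <- function(x, fs, frame_rate = 100) {
  n <- length(x)
  g <- floor((seq_len(n) - 1) / fs * frame_rate) + 1L
  as.numeric(rowsum(x, g) / tabulate(g))
}

# Root-mean-square.
rms <- function(x) sqrt(mean(x^2))

# Deterministic child seed derived from a base seed and a stream label,
# kept below 2^31 so it is a valid R integer.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}
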