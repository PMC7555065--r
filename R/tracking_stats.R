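#' Spearman rank correlation
#'
#' Computed from first principles as the Pearson-form covariance of
#' midrank-transformed series: `rho = cov(rank x, rank y) /
#' (sd(rank x) sd(rank y))`, with average ranks for ties.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the correlation coefficient in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  stop_if_not(length(x) == length(y), "x and y must have equal length")
  stop_if_not(length(x) >= 3, "need at least 3 observations")
  stop_if_not(stats::sd(x) > 0 && stats::sd(y) > 0,
              "Spearman correlation undefined for constant input")
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry))) / (n - 1)
  num / (stats::sd(rx) * stats::sd(ry))
}

#' Fisher z-transform of a correlation
#'
#' `z = atanh(rho) = 0.5 log((1 + rho) / (1 - rho))`, the
#' variance-stabilizing map applied before t tests on correlations.
#'
#' @param rho correlation(s), `|rho| < 1`.
#' @return transformed value(s).
#' @export
fisher_z <- function(rho) {
  stop_if_not(all(abs(rho) < 1), "|rho| must be < 1 for the Fisher transform")
  0.5 * log((1 + rho) / (1 - rho))
}

#' Lag-resolved Spearman cross-correlation
#'
#' Computes the Spearman correlation between an audio feature and a
#' neural series over a grid of lags (10 ms steps). Positive lag means
#' audio precedes the neural response: `rho(k) = spearman(audio[1:(T-k)],
#' neural[(1+k):T])`, symmetric for negative lags. The maximum and its
#' lag are reported; ties break toward the smallest `|lag|`.
#'
#' @param audio_feat,neural numeric series at 100 Hz, equal length.
#' @param lag_window `c(min, max)` lag window in ms.
#' @param step lag step in ms (multiple of 10).
#' @param min_overlap smallest number of overlapping frames allowed.
#' @return an `xcorr_profile`: list with `lags` (ms), `rho_per_lag`,
#'   `max_rho`, `argmax_lag`.
#' @export
lagged_xcorr_max <- function(audio_feat, neural,
                             lag_window = c(-100, 500), step = 10,
                             min_overlap = 300) {
  T_ <- length(audio_feat)
  stop_if_not(length(neural) == T_, "series must have equal length")
  lags_ms <- seq(lag_window[1], lag_window[2], by = step)
  lags_fr <- as.integer(round(lags_ms / 10))
  stop_if_not(T_ - max(abs(lags_fr)) >= max(min_overlap, 3),
              "lag window longer than fragment allows (overlap < %d frames)",
              max(min_overlap, 3))
  rho <- vapply(lags_fr, function(k) {
    if (k >= 0) {
      a <- audio_feat[seq_len(T_ - k)]
      b <- neural[(1L + k):T_]
    } else {
      a <- audio_feat[(1L - k):T_]
      b <- neural[seq_len(T_ + k)]
    }
    spearman_rho(a, b)
  }, 0)
  # tie-break toward smallest |lag|
  best <- which(rho >= max(rho) - 1e-12)
  best <- best[which.min(abs(lags_ms[best]))]
  structure(list(lags = lags_ms, rho_per_lag = rho,
                 max_rho = rho[best], argmax_lag = lags_ms[best]),
            class = "xcorr_profile")
}

#' Per-electrode condition contrast with Bonferroni correction
#'
#' Student t test (pooled variance when independent) between two sets of
#' per-fragment scalars, with two-sided parametric p values corrected
#' over the number of electrodes tested.
#'
#' @param valuesA,valuesB numeric vectors (per-fragment scalars).
#' @param paired logical.
#' @param m_electrodes multiplicity for the Bonferroni correction.
#' @param alpha family-wise significance level.
#' @return a one-row data frame: `t`, `df`, `p_raw`, `p_bonferroni`,
#'   `significant`, `direction`.
#' @export
condition_contrast <- function(valuesA, valuesB, paired = FALSE,
                               m_electrodes = 1, alpha = 0.05) {
  stop_if_not(length(valuesA) >= 2 && length(valuesB) >= 2,
              "need at least 2 values per group")
  if (paired) stop_if_not(length(valuesA) == length(valuesB),
                          "paired contrast needs equal group sizes")
  if (paired && all(valuesA == valuesB)) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(valuesA) - 1),
               p.value = 1)
  } else {
    stop_if_not(stats::var(valuesA) > 0 || stats::var(valuesB) > 0,
                "zero variance in both groups")
    tt <- stats::t.test(valuesA, valuesB, paired = paired,
                        var.equal = TRUE)
  }
  p_b <- min(1, tt$p.value * m_electrodes)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p_raw = tt$p.value, p_bonferroni = p_b,
             significant = p_b < alpha,
             direction = sign(unname(tt$statistic)))
}

# Per-electrode, per-fragment mean HFB values.
fragment_means <- function(hfb, fragset) {
  sapply(seq_len(nrow(fragset)), function(i) {
    fr <- fragment_frames(fragset$onset[i], fragset$duration[i])
    rowMeans(hfb$values[, fr, drop = FALSE])
  })                                            # channels x fragments
}

#' Speech-preference contrast and electrode selection mask
#'
#' Per electrode, averages the (z-scored) HFB amplitude over each 4-s
#' fragment and contrasts speech against nonspeech fragments with an
#' independent t test, Bonferroni-corrected over all good electrodes.
#' The mask of significantly speech-preferring electrodes (positive
#' direction) limits the multiplicity of all downstream analyses.
#'
#' @param hfb a z-scored [hfb_matrix()].
#' @param fragset a [fragment_set()] containing `speech` and `nonspeech`
#'   fragments.
#' @param alpha family-wise level.
#' @return list with `contrasts` (data frame per electrode) and `mask`
#'   (integer channel indices, significant positive electrodes).
#' @export
speech_preference <- function(hfb, fragset, alpha = 0.05) {
  sp <- fragset[fragset$condition == "speech", , drop = FALSE]
  ns <- fragset[fragset$condition == "nonspeech", , drop = FALSE]
  stop_if_not(nrow(sp) >= 2 && nrow(ns) >= 2,
              "need >= 2 fragments per condition")
  good <- which(hfb$channel_meta$good)
  mA <- fragment_means(hfb, sp)
  mB <- fragment_means(hfb, ns)
  res <- do.call(rbind, lapply(good, function(ch)
    condition_contrast(mA[ch, ], mB[ch, ], paired = FALSE,
                       m_electrodes = length(good), alpha = alpha)))
  res$channel <- good
  res$id <- hfb$channel_meta$id[good]
  mask <- res$channel[res$significant & res$direction > 0]
  list(contrasts = res, mask = mask)
}

# Shared core: per masked electrode, per fragment, max-lag Spearman rho of
# `series_for(ch)` vs a reference series; Fisher z; then a t test between
# two fragment groups.
xcorr_contrast_core <- function(hfb, ref_series, fragA, fragB, mask,
                                lag_window, paired, alpha,
                                ref_series_B = NULL,
                                min_overlap = 300) {
  stop_if_not(length(mask) > 0, "electrode mask is empty")
  stop_if_not(nrow(fragA) >= 2 && nrow(fragB) >= 2,
              "need >= 2 fragments per condition")
  if (is.null(ref_series_B)) ref_series_B <- ref_series
  profile_set <- function(ch, frags, ref) {
    out <- vapply(seq_len(nrow(frags)), function(i) {
      fr <- fragment_frames(frags$onset[i], frags$duration[i])
      prof <- lagged_xcorr_max(ref[fr], hfb$values[ch, fr],
                               lag_window = lag_window,
                               min_overlap = min_overlap)
      c(fisher_z(min(max(prof$max_rho, -0.999999), 0.999999)),
        prof$argmax_lag)
    }, numeric(2))
    list(z = out[1, ], lag = out[2, ])
  }
  res <- list(); lags <- list()
  for (ch in mask) {
    pA <- profile_set(ch, fragA, ref_series)
    pB <- profile_set(ch, fragB, ref_series_B)
    row <- condition_contrast(pA$z, pB$z, paired = paired,
                              m_electrodes = length(mask), alpha = alpha)
    row$channel <- ch
    row$mean_rho_A <- mean(tanh(pA$z))
    row$mean_rho_B <- mean(tanh(pB$z))
    row$best_lag_ms <- stats::median(pA$lag)
    res[[length(res) + 1L]] <- row
    lags[[length(lags) + 1L]] <- pA$lag
  }
  out <- do.call(rbind, res)
  out$id <- hfb$channel_meta$id[out$channel]
  attr(out, "lag_distributions") <- lags
  out
}

#' Envelope-tracking contrast (speech vs nonspeech)
#'
#' Per masked electrode and per fragment, the maximal lagged Spearman
#' correlation between the spectral envelope and the HFB response within
#' `lag_window`; Fisher-transformed maxima are contrasted between speech
#' and nonspeech fragments with independent t tests, Bonferroni-corrected
#' over the mask.
#'
#' @param hfb a z-scored [hfb_matrix()].
#' @param envelope spectral envelope at 100 Hz over the whole recording.
#' @param fragset [fragment_set()] with speech and nonspeech fragments.
#' @param lag_window lag window in ms.
#' @param mask electrode indices from [speech_preference()].
#' @param alpha family-wise level.
#' @return contrast data frame (one row per masked electrode) with
#'   attribute `lag_distributions`.
#' @export
envelope_tracking_contrast <- function(hfb, envelope, fragset,
                                       lag_window = c(-100, 500), mask,
                                       alpha = 0.05) {
  sp <- fragset[fragset$condition == "speech", , drop = FALSE]
  ns <- fragset[fragset$condition == "nonspeech", , drop = FALSE]
  stop_if_not(nrow(sp) > 0, "empty speech fragment set")
  xcorr_contrast_core(hfb, envelope, sp, ns, mask, lag_window,
                      paired = FALSE, alpha = alpha)
}

#' Coupling to a superior-temporal reference electrode
#'
#' Selects the STG candidate with the strongest mean envelope tracking
#' over speech fragments, then contrasts the per-fragment maximal lagged
#' correlation between that electrode's HFB and each masked electrode's
#' HFB in speech vs nonspeech fragments (window typically [-200, 200] ms,
#' since near-zero lags indicate parallel processing).
#'
#' @param hfb_all [hfb_matrix()] including the STG candidates.
#' @param envelope spectral envelope at 100 Hz.
#' @param stg_candidate_ids character channel ids of STG candidates.
#' @param mask electrode indices to test (excluding the reference).
#' @param fragset [fragment_set()].
#' @param lag_window lag window in ms.
#' @param alpha family-wise level.
#' @return list with `best_stg_id`, `best_stg_channel`, `contrasts`,
#'   `lag_distribution` (pooled argmax lags over speech fragments).
#' @export
stg_reference_coupling <- function(hfb_all, envelope, stg_candidate_ids,
                                   mask, fragset,
                                   lag_window = c(-200, 200),
                                   alpha = 0.05) {
  stop_if_not(length(stg_candidate_ids) > 0, "no STG candidates")
  stop_if_not(length(mask) > 0, "electrode mask is empty")
  cand <- match(stg_candidate_ids, hfb_all$channel_meta$id)
  stop_if_not(!anyNA(cand), "unknown STG candidate id")
  sp <- fragset[fragset$condition == "speech", , drop = FALSE]
  ns <- fragset[fragset$condition == "nonspeech", , drop = FALSE]
  mean_track <- vapply(cand, function(ch) {
    mean(vapply(seq_len(nrow(sp)), function(i) {
      fr <- fragment_frames(sp$onset[i], sp$duration[i])
      lagged_xcorr_max(envelope[fr], hfb_all$values[ch, fr],
                       lag_window = c(-100, 500))$max_rho
    }, 0))
  }, 0)
  best <- cand[which.max(mean_track)]
  ref <- hfb_all$values[best, ]
  mask2 <- setdiff(mask, best)
  out <- xcorr_contrast_core(hfb_all, ref, sp, ns, mask2, lag_window,
                             paired = FALSE, alpha = alpha)
  list(best_stg_id = hfb_all$channel_meta$id[best],
       best_stg_channel = best,
       best_stg_mean_rho = max(mean_track),
       contrasts = out,
       lag_distribution = unlist(attr(out, "lag_distributions")))
}

#' Noise-filtering contrast (isolated vs mixed envelope)
#'
#' On noisy speech fragments only: per masked electrode and fragment, the
#' maximal lagged correlation of the HFB response to the isolated-speech
#' envelope and to the mixed-track envelope; paired t tests on the
#' Fisher-transformed maxima (isolated minus mixed), Bonferroni over the
#' mask. A positive t means the electrode filters out the background.
#'
#' @param hfb z-scored [hfb_matrix()].
#' @param env_isolated,env_mixed envelopes at 100 Hz on one time base.
#' @param noisy_fragset [fragment_set()] of noisy fragments.
#' @param mask electrode indices.
#' @param lag_window lag window in ms.
#' @param alpha family-wise level.
#' @return contrast data frame per masked electrode.
#' @export
noise_filter_contrast <- function(hfb, env_isolated, env_mixed,
                                  noisy_fragset, mask,
                                  lag_window = c(-100, 500),
                                  alpha = 0.05) {
  stop_if_not(length(env_isolated) == length(env_mixed),
              "envelopes must share one time base")
  nz <- noisy_fragset[noisy_fragset$condition == "noisy", , drop = FALSE]
  stop_if_not(nrow(nz) >= 2, "need >= 2 noisy fragments")
  out <- xcorr_contrast_core(hfb, env_isolated, nz, nz, mask, lag_window,
                             paired = TRUE, alpha = alpha,
                             ref_series_B = env_mixed)
  names(out)[names(out) == "mean_rho_A"] <- "mean_rho_isolated"
  names(out)[names(out) == "mean_rho_B"] <- "mean_rho_mixed"
  out
}

#' Signed r-squared localizer statistic
#'
#' Squared point-biserial correlation between a binary move/rest label
#' and per-trial response values, signed by the direction of the mean
#' difference (move minus rest). The standard sensorimotor-mapping
#' statistic for localizer tasks.
#'
#' @param values per-trial scalars.
#' @param labels logical or 0/1 vector (TRUE/1 = move).
#' @return list with `signed_r2` and the parametric `p` of the
#'   underlying correlation.
#' @export
signed_r2 <- function(values, labels) {
  labels <- as.integer(as.logical(labels))
  stop_if_not(sum(labels == 1) >= 2 && sum(labels == 0) >= 2,
              "need >= 2 trials per class")
  r <- stats::cor(values, labels)
  s <- sign(mean(values[labels == 1]) - mean(values[labels == 0]))
  n <- length(values)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(signed_r2 = s * r^2,
       p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Fragment-intensity control contrast
#'
#' Independent t test of per-fragment sound intensity between speech and
#' nonspeech fragments; a non-significant result supports that HFB
#' differences are not driven by loudness.
#'
#' @param wave list with `samples`, `fs` (the mixed track).
#' @param fragset [fragment_set()].
#' @param method intensity summary, see [fragment_intensity()].
#' @return one-row data frame `t`, `df`, `p`.
#' @export
intensity_contrast <- function(wave, fragset, method = "meanabs") {
  sp <- fragset[fragset$condition == "speech", , drop = FALSE]
  ns <- fragset[fragset$condition == "nonspeech", , drop = FALSE]
  stop_if_not(nrow(sp) >= 2 && nrow(ns) >= 2,
              "need >= 2 fragments per condition")
  ia <- fragment_intensity(wave, sp, method)
  ib <- fragment_intensity(wave, ns, method)
  tt <- stats::t.test(ia, ib, var.equal = TRUE)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value)
}
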