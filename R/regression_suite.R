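#' Lag-align neural series per fragment
#'
#' Advances each fragment's neural series by its per-fragment lag (the
#' lag of maximal envelope correlation): `output[t] = input[t + lag]`.
#' Negative lags are clamped to 0 (only positive shifts up to 500 ms are
#' applied) and the trailing frames beyond the fragment are dropped, so
#' the design and response stay equal length.
#'
#' @param hfb an [hfb_matrix()] (one channel is selected by `channel`).
#' @param fragset a [fragment_set()].
#' @param per_fragment_lags numeric vector of lags in ms, one per
#'   fragment row.
#' @param channel channel index.
#' @return list of numeric vectors, one shifted series per fragment.
#' @export
lag_align <- function(hfb, fragset, per_fragment_lags, channel) {
  stop_if_not(length(per_fragment_lags) == nrow(fragset),
              "one lag per fragment required")
  clamped <- pmin(pmax(per_fragment_lags, 0), 500)
  n_clamped <- sum(per_fragment_lags < 0)
  out <- lapply(seq_len(nrow(fragset)), function(i) {
    fr <- fragment_frames(fragset$onset[i], fragset$duration[i])
    k <- as.integer(round(clamped[i] / 10))
    stop_if_not(k < length(fr), "lag >= fragment length")
    x <- hfb$values[channel, fr]
    x[(1L + k):length(x)]
  })
  attr(out, "lags_ms") <- clamped
  attr(out, "n_negative_clamped") <- n_clamped
  out
}

#' Ordinary least squares fit of HFB on the speech ON/OFF vector
#'
#' Single regression over all fragments concatenated (not one model per
#' fragment): `y = b0 + b1 x + e` with `x` the binary ON/OFF design. An
#' intercept is included; for z-scored responses it is near 0 but keeps
#' the residuals exactly orthogonal to the design. Reports per-
#' coefficient t statistics and the overall F against the intercept-only
#' model.
#'
#' @param y response (concatenated, possibly lag-aligned, HFB frames).
#' @param x binary ON/OFF design of the same length.
#' @return an `onoff_fit`: list with `beta`, `t`, `F`, `df1`, `df2`,
#'   `residuals`, `sigma`.
#' @export
onoff_ols <- function(y, x) {
  stop_if_not(length(y) == length(x), "y and x must have equal length")
  stop_if_not(stats::var(x) > 0, "constant regressor (all-ON or all-OFF)")
  n <- length(y)
  X <- cbind(intercept = 1, onoff = as.numeric(x))
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df2 <- n - 2L
  sigma2 <- rss / df2
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- fit$coefficients / se
  Fstat <- if (rss <= 0) {
    .Machine$double.xmax^0.5                  # exact fit: large finite F
  } else {
    ((tss - rss) / 1) / sigma2
  }
  structure(list(beta = fit$coefficients, t = tval, F = Fstat,
                 df1 = 1L, df2 = df2, residuals = res,
                 sigma = sqrt(sigma2)),
            class = "onoff_fit")
}

#' Fragment-permutation null for the ON/OFF regression F
#'
#' Shuffles the order of the fragments in the ON/OFF design (responses
#' fixed in their original order), refits the regression for each
#' permutation and records the F statistic. The significance threshold
#' is the empirical `(1 - alpha)` percentile of the permutation
#' distribution.
#'
#' @param y_frags list of per-fragment response vectors (e.g. from
#'   [lag_align()]).
#' @param x_frags list of per-fragment ON/OFF design vectors, each the
#'   same length as the matching response vector.
#' @param n_perm number of permutations.
#' @param alpha chance level; threshold is the `(1 - alpha)` percentile.
#' @param seed integer seed for the permutation stream.
#' @return a `permutation_null`: list with `observed_F`, `null_F`,
#'   `threshold`, `significant`, `p_perm`, `n_perm`, `alpha`, `seed`.
#' @export
permutation_f_test <- function(y_frags, x_frags, n_perm = 10000,
                               alpha = 0.001, seed = 1L) {
  K <- length(y_frags)
  stop_if_not(K >= 2, "need >= 2 fragments to permute")
  stop_if_not(length(x_frags) == K, "one design block per fragment")
  lens_y <- lengths(y_frags); lens_x <- lengths(x_frags)
  stop_if_not(all(lens_y == lens_x),
              "response and design blocks must match in length")
  if (n_perm < 1 / alpha) {
    warning("n_perm < 1/alpha: permutation threshold unreliable")
  }
  y <- unlist(y_frags, use.names = FALSE)
  obs <- onoff_ols(y, unlist(x_frags, use.names = FALSE))
  # Fast refit: with a single binary regressor the F statistic is a
  # monotone function of cor(x, y); permuting equal-length blocks keeps
  # sum(x) and sum(x^2) fixed, so only sum(x * y) changes.
  n <- length(y)
  same_len <- length(unique(lens_y)) == 1L
  set.seed(seed)
  if (same_len) {
    L <- lens_y[1]
    # D[i, j] = x_frags[[j]] . y_frags[[i]]
    Ym <- matrix(y, nrow = L)
    Xm <- vapply(x_frags, as.numeric, numeric(L))
    D <- crossprod(Ym, Xm)
    sx <- sum(unlist(x_frags)); sy <- sum(y)
    sxx <- sx                                  # binary: x^2 = x
    syy <- sum(y^2)
    null_F <- vapply(seq_len(n_perm), function(p) {
      perm <- sample.int(K)
      sxy <- sum(D[cbind(seq_len(K), perm)])
      r2num <- (n * sxy - sx * sy)^2
      r2den <- (n * sxx - sx^2) * (n * syy - sy^2)
      r2 <- r2num / r2den
      r2 / (1 - r2) * (n - 2)
    }, 0)
  } else {
    null_F <- vapply(seq_len(n_perm), function(p) {
      perm <- sample.int(K)
      xp <- unlist(x_frags[perm], use.names = FALSE)[seq_len(n)]
      onoff_ols(y, xp)$F
    }, 0)
  }
  thr <- stats::quantile(null_F, 1 - alpha, names = FALSE, type = 7)
  structure(list(observed_F = obs$F, null_F = null_F, threshold = thr,
                 significant = obs$F > thr,
                 p_perm = (1 + sum(null_F >= obs$F)) / (1 + n_perm),
                 n_perm = n_perm, alpha = alpha, seed = seed),
            class = "permutation_null")
}

#' Contrast of ON/OFF regression weights between conditions
#'
#' Independent two-sample t test over electrodes of the ON/OFF slope
#' fitted in speech fragments versus the slope fitted on the sound
#' ON/OFF control design in nonspeech fragments.
#'
#' @param betas_speech,betas_nonspeech per-electrode slope estimates.
#' @return one-row data frame `t`, `df`, `p`.
#' @export
onoff_condition_contrast <- function(betas_speech, betas_nonspeech) {
  stop_if_not(length(betas_speech) >= 2 && length(betas_nonspeech) >= 2,
              "need >= 2 electrodes per group")
  tt <- stats::t.test(betas_speech, betas_nonspeech, var.equal = TRUE)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value)
}

#' Partial Spearman correlation
#'
#' Rank-transforms all three series, residualizes `rank(y)` and
#' `rank(target)` on `rank(control)` by least squares, and returns the
#' Pearson correlation of the two residual series — the rank analogue of
#' a first-order partial correlation.
#'
#' @param y,target,control numeric series of equal length.
#' @return the partial correlation coefficient.
#' @export
partial_spearman <- function(y, target, control) {
  n <- length(y)
  stop_if_not(length(target) == n && length(control) == n,
              "series must have equal length")
  stop_if_not(stats::sd(y) > 0 && stats::sd(target) > 0 &&
                stats::sd(control) > 0, "constant input")
  ry <- rank(y); rt <- rank(target); rc <- rank(control)
  rtc <- stats::cor(rt, rc)
  stop_if_not(abs(rtc) <= 0.999, "control collinear with target")
  res_on <- function(a, b) stats::lm.fit(cbind(1, b), a)$residuals
  ey <- res_on(ry, rc)
  et <- res_on(rt, rc)
  stats::cor(ey, et)
}

#' Pitch-envelope interaction analysis
#'
#' Per fragment, the Spearman correlation between spectral envelope and
#' pitch contour; Fisher z; then one-sample t vs 0 within each
#' condition, an independent t between speech and nonspeech, and (when
#' isolated/mixed envelopes over noisy fragments are supplied) a paired
#' t between tracks. Fragments with constant pitch (no voicing) are
#' flagged and excluded.
#'
#' @param envelope,pitch series at 100 Hz over the whole recording.
#' @param fragset [fragment_set()] with speech and nonspeech fragments.
#' @param env_isolated,env_mixed optional envelopes for the paired
#'   isolated-vs-mixed comparison on noisy fragments.
#' @param noisy_fragset optional noisy [fragment_set()].
#' @return list of per-condition mean correlations, t tests, and the
#'   per-fragment values; `excluded` counts degenerate fragments.
#' @export
pitch_envelope_interaction <- function(envelope, pitch, fragset,
                                       env_isolated = NULL,
                                       env_mixed = NULL,
                                       noisy_fragset = NULL) {
  per_frag <- function(frags, env_series) {
    vapply(seq_len(nrow(frags)), function(i) {
      fr <- fragment_frames(frags$onset[i], frags$duration[i])
      p <- pitch[fr]
      if (stats::sd(p) == 0 || stats::sd(env_series[fr]) == 0)
        return(NA_real_)
      spearman_rho(env_series[fr], p)
    }, 0)
  }
  sp <- fragset[fragset$condition == "speech", , drop = FALSE]
  ns <- fragset[fragset$condition == "nonspeech", , drop = FALSE]
  rho_sp <- per_frag(sp, envelope)
  rho_ns <- per_frag(ns, envelope)
  excluded <- sum(is.na(rho_sp)) + sum(is.na(rho_ns))
  clip <- function(r) pmin(pmax(r, -0.999999), 0.999999)
  z_sp <- fisher_z(clip(stats::na.omit(rho_sp)))
  z_ns <- fisher_z(clip(stats::na.omit(rho_ns)))
  one_sp <- if (stats::sd(z_sp) > 0) stats::t.test(z_sp, mu = 0) else
    list(statistic = Inf * sign(mean(z_sp)), p.value = 0)
  two <- if (length(z_ns) >= 2) {
    stats::t.test(z_sp, z_ns, var.equal = TRUE)
  } else NULL
  out <- list(mean_rho_speech = mean(tanh(z_sp)),
              mean_rho_nonspeech = if (length(z_ns)) mean(tanh(z_ns))
              else NA_real_,
              one_sample_t_speech = unname(one_sp$statistic),
              one_sample_p_speech = one_sp$p.value,
              speech_vs_nonspeech_t = if (!is.null(two))
                unname(two$statistic) else NA_real_,
              speech_vs_nonspeech_p = if (!is.null(two))
                two$p.value else NA_real_,
              rho_speech = rho_sp, rho_nonspeech = rho_ns,
              excluded = excluded)
  if (!is.null(env_isolated) && !is.null(noisy_fragset)) {
    nz <- noisy_fragset[noisy_fragset$condition == "noisy", , drop = FALSE]
    ri <- per_frag(nz, env_isolated)
    rm_ <- per_frag(nz, env_mixed)
    keep <- !is.na(ri) & !is.na(rm_)
    pt <- stats::t.test(fisher_z(clip(ri[keep])), fisher_z(clip(rm_[keep])),
                        paired = TRUE)
    out$isolated_vs_mixed_t <- unname(pt$statistic)
    out$isolated_vs_mixed_p <- pt$p.value
  }
  out
}

#' OLS on the full auditory design and residual extraction
#'
#' Per electrode and condition, fits the HFB response over the
#' condition's fragments on an intercept, the spectral envelope, the
#' condition-specific ON/OFF vector (speech ON/OFF in speech fragments,
#' intensity-based sound ON/OFF in nonspeech) and the pitch contour, and
#' returns the residual series split back per fragment.
#'
#' @param hfb z-scored [hfb_matrix()].
#' @param envelope,onoff,pitch regressors at 100 Hz over the recording.
#' @param fragset [fragment_set()].
#' @param condition which condition's fragments to fit.
#' @param channel electrode index.
#' @return list with `fit` (lm.fit result + stats), `residuals_by_frag`,
#'   `fragments` (the rows used).
#' @export
auditory_ols_residuals <- function(hfb, envelope, onoff, pitch, fragset,
                                   condition, channel) {
  frags <- fragset[fragset$condition == condition, , drop = FALSE]
  stop_if_not(nrow(frags) > 0, "no fragments of condition %s", condition)
  fr_all <- unlist(lapply(seq_len(nrow(frags)), function(i)
    fragment_frames(frags$onset[i], frags$duration[i])))
  X <- cbind(intercept = 1, envelope = envelope[fr_all],
             onoff = onoff[fr_all], pitch = pitch[fr_all])
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, stats::sd) > 0)
  Xk <- X[, keep, drop = FALSE]
  qrX <- qr(Xk)
  stop_if_not(qrX$rank == ncol(Xk),
              "collinear design (columns: %s)",
              paste(colnames(Xk), collapse = ", "))
  y <- hfb$values[channel, fr_all]
  fit <- stats::lm.fit(Xk, y)
  res <- fit$residuals
  L <- round(frags$duration[1] * 100)
  res_by_frag <- split(res, rep(seq_len(nrow(frags)), each = L))
  list(fit = list(beta = fit$coefficients,
                  r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
                  dropped = colnames(X)[!keep]),
       residuals_by_frag = res_by_frag,
       fragments = frags)
}

#' Rank-based comparison of full and residual responses
#'
#' Kruskal-Wallis H (with tie correction) over the four groups of
#' per-electrode mean values (speech/nonspeech x full/residual), Dunn's
#' pairwise post hoc z tests (Holm-adjusted), and a two-way factorial
#' ANOVA (condition x data type + interaction) on the globally
#' rank-transformed values.
#'
#' @param groups named list of >= 2 numeric vectors (conventionally
#'   `speech_full`, `speech_resid`, `nonspeech_full`,
#'   `nonspeech_resid`).
#' @return a `group_comparison`: list with `H`, `df`, `p_kw`, `dunn`
#'   (data frame of pairwise z and adjusted p), and `rank_anova` (F and
#'   p for each factor and the interaction; `NULL` unless the group
#'   names encode a 2x2 design).
#' @export
rank_group_comparison <- function(groups) {
  k <- length(groups)
  stop_if_not(k >= 2, "need >= 2 groups")
  stop_if_not(all(vapply(groups, length, 0L) >= 2),
              "every group needs >= 2 values")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 0L)),
              levels = names(groups))
  n <- length(x)
  r <- rank(x)
  Rj <- tapply(r, g, sum)
  nj <- as.numeric(table(g))
  names(nj) <- levels(g)
  H <- 12 / (n * (n + 1)) * sum(Rj^2 / nj) - 3 * (n + 1)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- if (tie_corr > 0) H / tie_corr else 0   # all values tied

  df <- k - 1L
  p_kw <- stats::pchisq(H, df, lower.tail = FALSE)
  # Dunn pairwise z statistics on mean ranks
  mean_ranks <- Rj / nj
  pairs <- utils::combn(names(groups), 2)
  zs <- numeric(ncol(pairs)); ps <- numeric(ncol(pairs))
  sig2 <- (n * (n + 1) / 12 -
             sum(ties^3 - ties) / (12 * (n - 1)))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(sig2 * (1 / nj[a] + 1 / nj[b]))
    zs[i] <- (mean_ranks[a] - mean_ranks[b]) / se
    ps[i] <- 2 * stats::pnorm(-abs(zs[i]))
  }
  dunn <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     z = zs, p_raw = ps,
                     p_adj = stats::p.adjust(ps, method = "holm"),
                     stringsAsFactors = FALSE)
  # Two-way rank ANOVA if names parse as condition_datatype
  rank_anova <- NULL
  parts <- strsplit(names(groups), "_", fixed = TRUE)
  if (all(lengths(parts) == 2L)) {
    f1 <- factor(rep(vapply(parts, `[`, "", 1), nj))
    f2 <- factor(rep(vapply(parts, `[`, "", 2), nj))
    if (nlevels(f1) > 1 && nlevels(f2) > 1) {
      av <- stats::anova(stats::lm(r ~ f1 * f2))
      rank_anova <- data.frame(term = rownames(av)[1:3],
                               F = av$`F value`[1:3],
                               df1 = av$Df[1:3],
                               df2 = av$Df[4],
                               p = av$`Pr(>F)`[1:3],
                               stringsAsFactors = FALSE)
    }
  }
  structure(list(H = H, df = df, p_kw = p_kw, dunn = dunn,
                 rank_anova = rank_anova,
                 mean_ranks = as.numeric(mean_ranks)),
            class = "group_comparison")
}

#' Hand-covariate control analysis
#'
#' Regresses each electrode's concatenated HFB frames (over all speech
#' and nonspeech fragments) on the frame-expanded hand label (single
#' ordinal column by default, dummy coding optionally), re-runs the
#' speech-preference and envelope-tracking contrasts on the residuals,
#' and compares the original and updated per-electrode t statistics with
#' two-sided Wilcoxon signed-rank tests (exact for n <= 25) over the
#' originally significant electrodes.
#'
#' @param hfb z-scored [hfb_matrix()].
#' @param fragset [fragment_set()] with hand labels on every fragment.
#' @param envelope spectral envelope at 100 Hz.
#' @param alpha family-wise level for the re-run contrasts.
#' @param dummy_coding use two dummy columns instead of one ordinal.
#' @return list with `residual_hfb`, original and updated contrast
#'   tables, and the two Wilcoxon comparisons.
#' @export
covariate_control <- function(hfb, fragset, envelope, alpha = 0.05,
                              dummy_coding = FALSE) {
  both <- fragset[fragset$condition %in% c("speech", "nonspeech"), ,
                  drop = FALSE]
  stop_if_not(!anyNA(both$hand_label), "hand label missing on a fragment")
  fr_all <- unlist(lapply(seq_len(nrow(both)), function(i)
    fragment_frames(both$onset[i], both$duration[i])))
  L <- round(both$duration[1] * 100)
  hand_frames <- rep(both$hand_label, each = L)
  skipped <- stats::var(hand_frames) == 0
  res_hfb <- hfb
  if (skipped) {
    message("constant hand vector: regression skipped, HFB centered")
    for (ch in which(hfb$channel_meta$good)) {
      res_hfb$values[ch, fr_all] <-
        hfb$values[ch, fr_all] - mean(hfb$values[ch, fr_all])
    }
  } else {
    X <- if (dummy_coding) {
      stats::model.matrix(~ factor(hand_frames, levels = 0:2))
    } else {
      cbind(1, hand_frames)
    }
    for (ch in which(hfb$channel_meta$good)) {
      y <- hfb$values[ch, fr_all]
      res_hfb$values[ch, fr_all] <- stats::lm.fit(X, y)$residuals
    }
  }
  orig_pref <- speech_preference(hfb, both, alpha = alpha)
  new_pref <- speech_preference(res_hfb, both, alpha = alpha)
  wil <- function(t_old, t_new) {
    if (all(t_old == t_new)) {
      return(list(statistic = NA_real_, p.value = 1))
    }
    wt <- stats::wilcox.test(t_old, t_new, paired = TRUE,
                             exact = length(t_old) <= 25 &&
                               !any(t_old == t_new))
    list(statistic = unname(wt$statistic), p.value = wt$p.value)
  }
  # comparisons run over the originally significant electrodes; if none
  # reached significance (null fixtures) fall back to all good channels
  sig <- orig_pref$mask
  if (length(sig) == 0L) sig <- which(hfb$channel_meta$good)
  idxo <- match(sig, orig_pref$contrasts$channel)
  w_pref <- wil(orig_pref$contrasts$t[idxo], new_pref$contrasts$t[idxo])
  out <- list(residual_hfb = res_hfb, skipped = skipped,
              original_preference = orig_pref,
              updated_preference = new_pref,
              wilcoxon_preference = w_pref,
              retained = intersect(sig, new_pref$mask))
  if (length(sig) > 0) {
    orig_env <- envelope_tracking_contrast(hfb, envelope, both,
                                           mask = sig, alpha = alpha)
    new_env <- envelope_tracking_contrast(res_hfb, envelope, both,
                                          mask = sig, alpha = alpha)
    out$original_envelope <- orig_env
    out$updated_envelope <- new_env
    out$wilcoxon_envelope <- wil(orig_env$t, new_env$t)
  }
  out
}

#' Chi-square test of independence
#'
#' `chi2 = sum (O - E)^2 / E` with expected counts from the margins;
#' `df = (r - 1)(c - 1)`. For 2x2 tables the Yates continuity correction
#' subtracts 0.5 from each `|O - E|`.
#'
#' @param table integer matrix of observed counts (>= 2 rows and
#'   columns).
#' @param yates apply the continuity correction (2x2 only).
#' @return a `contingency_result`: list with `chi2`, `df`, `p`,
#'   `expected`, `yates`.
#' @export
chi2_independence <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  stop_if_not(nrow(table) >= 2 && ncol(table) >= 2,
              "need at least a 2x2 table")
  stop_if_not(all(table >= 0) && all(table == round(table)),
              "counts must be non-negative integers")
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  stop_if_not(all(rs > 0) && all(cs > 0), "zero margin in table")
  E <- outer(rs, cs) / n
  dev <- abs(table - E)
  if (yates) {
    stop_if_not(nrow(table) == 2 && ncol(table) == 2,
                "Yates correction applies to 2x2 tables only")
    dev <- pmax(dev - 0.5, 0)
  }
  chi2 <- sum(dev^2 / E)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 expected = E, yates = yates, n = n),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("chi^2(%d, N = %d) = %.2f, p = %.3g%s\n", x$df, x$n,
              x$chi2, x$p, if (x$yates) " (Yates-corrected)" else ""))
  invisible(x)
}
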