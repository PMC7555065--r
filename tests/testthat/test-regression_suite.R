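test_that("lag_align shifts per fragment and clamps negative lags", {
  vals <- matrix(seq_len(800) / 100, nrow = 1)
  meta <- data.frame(id = "E1", grid = "G", good = TRUE, anatomy = "dPCC",
                     stringsAsFactors = FALSE)
  h <- hfb_matrix(vals, meta)
  fr <- fragment_set(data.frame(onset = c(0, 4), duration = 4,
                                condition = "speech", hand_label = 0L))
  # lag 0 -> identity
  out0 <- lag_align(h, fr, c(0, 0), channel = 1)
  expect_equal(out0[[1]], vals[1, 1:400])
  # lag 100 ms -> output[t] = input[t + 10 frames], length 390
  out1 <- lag_align(h, fr, c(100, 0), channel = 1)
  expect_equal(length(out1[[1]]), 390)
  expect_equal(out1[[1]], vals[1, 11:400])
  # negative lags clamp to 0
  outn <- lag_align(h, fr, c(-200, 0), channel = 1)
  expect_equal(attr(outn, "lags_ms")[1], 0)
  expect_equal(attr(outn, "n_negative_clamped"), 1)
  expect_error(lag_align(h, fr, c(0, 0, 0), 1), "one lag per fragment")
})

test_that("lag alignment improves zero-lag correlation on planted coupling", {
  fx <- tracked_fixture()
  ch <- 2                                      # planted 300 ms lag
  sp <- fx$fragset[fx$fragset$condition == "speech", ]
  env <- fx$feats_mixed$envelope
  rho_unaligned <- mean(vapply(seq_len(nrow(sp)), function(i) {
    fr <- fragment_frames(sp$onset[i], sp$duration[i])
    spearman_rho(env[fr], fx$hfb$values[ch, fr])
  }, 0))
  aligned <- lag_align(fx$hfb, sp, rep(300, nrow(sp)), channel = ch)
  rho_aligned <- mean(vapply(seq_len(nrow(sp)), function(i) {
    fr <- fragment_frames(sp$onset[i], sp$duration[i])
    n <- length(aligned[[i]])
    spearman_rho(env[fr][seq_len(n)], aligned[[i]])
  }, 0))
  expect_gt(rho_aligned, rho_unaligned)
})

test_that("onoff_ols is exact on noiseless data and consistent at scale", {
  x <- rep(c(0, 1), each = 200)
  fit <- onoff_ols(2 * x + 1, x)
  expect_equal(unname(fit$beta["onoff"]), 2, tolerance = 1e-10)
  expect_equal(unname(fit$beta["intercept"]), 1, tolerance = 1e-10)
  expect_true(is.finite(fit$F) && fit$F > 1e10)
  # residual orthogonality to the design
  set.seed(8)
  y <- rnorm(400); x2 <- rbinom(400, 1, 0.5)
  fit2 <- onoff_ols(y, x2)
  expect_lt(abs(sum(fit2$residuals * x2)), 1e-6 * 400)
  expect_lt(abs(sum(fit2$residuals)), 1e-6 * 400)
  # matches lm oracle
  lm_fit <- lm(y ~ x2)
  expect_equal(unname(fit2$beta), unname(coef(lm_fit)), tolerance = 1e-10)
  expect_equal(fit2$F, unname(summary(lm_fit)$fstatistic[1]),
               tolerance = 1e-8)
  tval <- summary(lm_fit)$coefficients[, "t value"]
  expect_equal(unname(fit2$t), unname(tval), tolerance = 1e-8)
  # consistency at the emulated scale: slope 1 +- 0.02 at n = 46,000
  set.seed(9)
  xl <- rbinom(46000, 1, 0.7)
  yl <- xl + rnorm(46000)
  expect_lt(abs(onoff_ols(yl, xl)$beta["onoff"] - 1), 0.02)
  expect_error(onoff_ols(yl, rep(1, 46000)), "constant regressor")
})

test_that("permutation_f_test is deterministic and detects real structure", {
  set.seed(10)
  K <- 10
  x_frags <- replicate(K, rbinom(100, 1, 0.5), simplify = FALSE)
  y_frags <- lapply(x_frags, function(x) 0.5 * x + rnorm(100))
  p1 <- permutation_f_test(y_frags, x_frags, n_perm = 500, alpha = 0.01,
                           seed = 42)
  p2 <- permutation_f_test(y_frags, x_frags, n_perm = 500, alpha = 0.01,
                           seed = 42)
  expect_identical(p1$threshold, p2$threshold)
  expect_identical(p1$null_F, p2$null_F)
  expect_true(p1$significant)
  expect_gt(p1$observed_F, p1$threshold)
  # null data: observed F unremarkable
  y_null <- replicate(K, rnorm(100), simplify = FALSE)
  p0 <- permutation_f_test(y_null, x_frags, n_perm = 500, alpha = 0.01,
                           seed = 1)
  expect_lt(p0$observed_F, quantile(p0$null_F, 0.999))
  expect_warning(
    permutation_f_test(y_frags, x_frags, n_perm = 100, alpha = 0.001,
                       seed = 1), "unreliable")
})

test_that("fast blockwise permutation equals the generic refit path", {
  set.seed(11)
  K <- 6
  x_frags <- replicate(K, rbinom(50, 1, 0.5), simplify = FALSE)
  y_frags <- replicate(K, rnorm(50), simplify = FALSE)
  fast <- permutation_f_test(y_frags, x_frags, n_perm = 200, alpha = 0.05,
                             seed = 7)
  # brute-force oracle: same permutation stream, explicit refits
  set.seed(7)
  y <- unlist(y_frags)
  brute <- vapply(1:200, function(p) {
    perm <- sample.int(K)
    onoff_ols(y, unlist(x_frags[perm]))$F
  }, 0)
  expect_equal(fast$null_F, brute, tolerance = 1e-9)
})

test_that("onoff_condition_contrast compares beta populations", {
  set.seed(12)
  r <- onoff_condition_contrast(rnorm(10, 1, 0.1), rnorm(10, 0.2, 0.1))
  expect_lt(r$p, 0.001)
  r0 <- onoff_condition_contrast(rnorm(20), rnorm(20))
  expect_gt(r0$p, 0.001)
  expect_error(onoff_condition_contrast(1, rnorm(5)), "2 electrodes")
})

test_that("partial_spearman isolates and removes control contributions", {
  set.seed(13)
  n <- 400
  ctrl <- rnorm(n)
  # control independent of both: partial ~ simple Spearman
  x <- rnorm(n); y <- x + rnorm(n)
  expect_lt(abs(partial_spearman(y, x, ctrl) - spearman_rho(y, x)), 0.02)
  # y driven by control only: partial ~ 0
  y2 <- ctrl + 0.01 * rnorm(n)
  tgt <- rnorm(n)
  expect_lt(abs(partial_spearman(y2, tgt, ctrl)), 0.05)
  # target == control exactly -> error
  expect_error(partial_spearman(y, ctrl, ctrl), "collinear")
})

test_that("pitch_envelope_interaction reflects construction", {
  fx <- tracked_fixture()
  pe <- pitch_envelope_interaction(fx$feats$envelope, fx$feats$pitch,
                                   fx$fragset,
                                   env_isolated = fx$feats$envelope,
                                   env_mixed = fx$feats_mixed$envelope,
                                   noisy_fragset = fx$noisy)
  # shared syllabic gating: positive envelope-pitch correlation in speech
  expect_gt(pe$mean_rho_speech, 0)
  expect_lt(pe$one_sample_p_speech, 0.01)
  # nonspeech fragments have no voicing: all excluded or near zero
  expect_true(all(is.na(pe$rho_nonspeech)) ||
                mean(abs(pe$rho_nonspeech), na.rm = TRUE) <
                  pe$mean_rho_speech)
  # envelope = monotone function of pitch -> rho = 1 per fragment
  env_m <- exp(fx$feats$pitch / 300)
  fr1 <- fx$fragset[fx$fragset$condition == "speech", ][1:2, ]
  fr1 <- fragment_set(fr1)
  pe2 <- pitch_envelope_interaction(env_m, fx$feats$pitch, fr1)
  expect_true(all(abs(pe2$rho_speech - 1) < 1e-9))
})

test_that("auditory_ols_residuals is exact for linear combinations", {
  fx <- tracked_fixture()
  sp <- fx$fragset[fx$fragset$condition == "speech", ]
  fr_all <- unlist(lapply(seq_len(nrow(sp)), function(i)
    fragment_frames(sp$onset[i], sp$duration[i])))
  h2 <- fx$hfb
  h2$values[1, fr_all] <- 2 + 0.5 * fx$feats$envelope[fr_all] +
    1.5 * fx$feats$onoff[fr_all] - 0.2 * fx$feats$pitch[fr_all]
  res <- auditory_ols_residuals(h2, fx$feats$envelope, fx$feats$onoff,
                                fx$feats$pitch, fx$fragset, "speech",
                                channel = 1)
  expect_lt(var(unlist(res$residuals_by_frag)), 1e-10)
  expect_equal(length(res$residuals_by_frag), nrow(sp))
  # independent response: residual variance close to original
  set.seed(14)
  h3 <- fx$hfb
  h3$values[1, ] <- rnorm(ncol(h3$values))
  res3 <- auditory_ols_residuals(h3, fx$feats$envelope, fx$feats$onoff,
                                 fx$feats$pitch, fx$fragset, "speech",
                                 channel = 1)
  expect_gt(var(unlist(res3$residuals_by_frag)) /
              var(h3$values[1, fr_all]), 0.95)
  # collinear design errors
  expect_error(auditory_ols_residuals(h3, fx$feats$onoff, fx$feats$onoff,
                                      fx$feats$pitch, fx$fragset,
                                      "speech", 1), "collinear")
})

test_that("planted envelope coupling shrinks residual fragment means", {
  fx <- tracked_fixture()
  sp <- fx$fragset[fx$fragset$condition == "speech", ]
  res <- auditory_ols_residuals(fx$hfb, fx$feats$envelope, fx$feats$onoff,
                                fx$feats$pitch, fx$fragset, "speech",
                                channel = 1)
  full_means <- vapply(seq_len(nrow(sp)), function(i) {
    mean(fx$hfb$values[1, fragment_frames(sp$onset[i], sp$duration[i])])
  }, 0)
  resid_means <- vapply(res$residuals_by_frag, mean, 0)
  expect_lt(mean(resid_means), mean(full_means))
})

test_that("rank_group_comparison matches brute-force H and handles nulls", {
  # small instance: H from the textbook rank formula by brute force
  g <- list(a = c(1.2, 3.1, 2.5, 4), b = c(5.5, 6.1, 4.9, 7),
            c = c(0.4, 1.1, 2.2, 0.9))
  got <- rank_group_comparison(g)
  x <- unlist(g); r <- rank(x); n <- length(x)
  H_brute <- 12 / (n * (n + 1)) *
    sum(tapply(r, rep(names(g), lengths(g)), sum)^2 / 4) - 3 * (n + 1)
  expect_equal(got$H, H_brute, tolerance = 1e-12)  # no ties here
  # oracle: stats::kruskal.test
  kw <- kruskal.test(x, factor(rep(names(g), lengths(g))))
  expect_equal(got$H, unname(kw$statistic), tolerance = 1e-12)
  expect_equal(got$p_kw, kw$p.value, tolerance = 1e-12)
  expect_equal(nrow(got$dunn), 3)               # all pairs
  # four identical groups: H ~ 0, Dunn p ~ 1
  gid <- list(speech_full = 1:4, speech_resid = 1:4,
              nonspeech_full = 1:4, nonspeech_resid = 1:4)
  g0 <- rank_group_comparison(gid)
  expect_lt(g0$H, 1e-10)
  expect_true(all(g0$dunn$p_adj > 0.99))
  expect_equal(nrow(g0$dunn), 6)
  # rank ANOVA present for the 2x2 naming scheme
  expect_equal(nrow(g0$rank_anova), 3)
})

test_that("rank ANOVA detects a planted condition main effect only", {
  set.seed(15)
  g <- list(speech_full = rnorm(20, 2), speech_resid = rnorm(20, 2),
            nonspeech_full = rnorm(20), nonspeech_resid = rnorm(20))
  rc <- rank_group_comparison(g)
  av <- rc$rank_anova
  f_cond <- av$F[av$term == "f1"]
  f_int <- av$F[av$term == "f1:f2"]
  expect_gt(f_cond, 30)
  # interaction F should be unremarkable under its null distribution
  expect_lt(f_int, qf(0.999, 1, av$df2[1]))
  expect_lt(rc$p_kw, 1e-6)
})

test_that("tie-corrected H matches kruskal.test on tied data", {
  set.seed(16)
  for (i in 1:20) {
    x <- sample(1:4, 24, replace = TRUE)
    g <- split(x, rep(1:3, each = 8))
    names(g) <- c("a", "b", "c")
    got <- rank_group_comparison(g)
    kw <- kruskal.test(unlist(g), factor(rep(names(g), each = 8)))
    expect_equal(got$H, unname(kw$statistic), tolerance = 1e-12)
  }
})

test_that("chi2_independence reproduces the published contingency results", {
  # 2x3 speech-by-hand table, no correction
  tab <- matrix(c(114, 127, 61, 62, 107, 138), nrow = 2)
  r <- chi2_independence(tab)
  expect_equal(round(r$chi2, 2), 1.31)
  expect_equal(r$df, 2)
  expect_equal(r$n, 609)
  # collapsed 2x2 with Yates correction
  tab2 <- matrix(c(175, 189, 107, 138), nrow = 2)
  r2 <- chi2_independence(tab2, yates = TRUE)
  expect_equal(round(r2$chi2, 2), 0.97)
  # oracle: chisq.test
  expect_equal(r$chi2, unname(chisq.test(tab, correct = FALSE)$statistic),
               tolerance = 1e-10)
  expect_equal(r2$chi2, unname(chisq.test(tab2, correct = TRUE)$statistic),
               tolerance = 1e-10)
  # proportional rows -> exactly 0
  expect_equal(chi2_independence(matrix(c(10, 20, 30, 60), 2))$chi2, 0)
  expect_error(chi2_independence(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_error(chi2_independence(tab, yates = TRUE), "2x2")
})

test_that("covariate_control leaves planted electrodes significant", {
  fx <- tracked_fixture()
  cc <- covariate_control(fx$hfb, fx$fragset, fx$feats_mixed$envelope)
  # hand labels are independent of the neural data: every originally
  # significant electrode survives the covariate regression
  expect_setequal(cc$retained, cc$original_preference$mask)
  expect_false(cc$skipped)
})

test_that("covariate_control t-maps are unchanged under a pure null", {
  # channels with independent noise: t shifts are idiosyncratic, so the
  # signed-rank comparison of original vs updated t-maps stays null
  fx <- tracked_fixture()
  h0 <- fx$hfb
  set.seed(77)
  h0$values <- matrix(rnorm(length(h0$values)), nrow = nrow(h0$values))
  cc <- covariate_control(h0, fx$fragset, fx$feats_mixed$envelope)
  expect_gt(cc$wilcoxon_preference$p.value, 0.05)
  if (!is.null(cc$wilcoxon_envelope)) {
    expect_gt(cc$wilcoxon_envelope$p.value, 0.05)
  }
})

test_that("covariate_control collapses when the covariate is the signal", {
  fx <- tracked_fixture()
  both <- fx$fragset
  # make channel 1 a pure function of the hand label
  h2 <- fx$hfb
  L <- 400
  fr_all <- unlist(lapply(seq_len(nrow(both)), function(i)
    fragment_frames(both$onset[i], both$duration[i])))
  h2$values[1, fr_all] <- rep(both$hand_label, each = L) +
    rnorm(length(fr_all), 0, 1e-6)
  X <- cbind(1, rep(both$hand_label, each = L))
  resid <- lm.fit(X, h2$values[1, fr_all])$residuals
  expect_lt(var(resid), 1e-10)
})

test_that("constant hand labels skip the regression with a message", {
  fx <- tracked_fixture()
  fs2 <- fx$fragset
  fs2$hand_label <- 1L
  expect_message(covariate_control(fx$hfb, fs2, fx$feats_mixed$envelope),
                 "skipped")
})
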