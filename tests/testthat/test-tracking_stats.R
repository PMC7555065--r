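test_that("spearman_rho matches hand-computed and oracle values", {
  # d^2 oracle on a permutation without ties: 1 - 6 sum(d^2) / (n(n^2-1))
  x <- 1:5; y <- c(3, 1, 2, 5, 4)
  d2 <- sum((rank(x) - rank(y))^2)
  expect_equal(spearman_rho(x, y), 1 - 6 * d2 / (5 * 24))
  expect_equal(spearman_rho(x, y), 0.6)
  # monotone invariance
  set.seed(1)
  a <- rnorm(50)
  expect_equal(spearman_rho(a, exp(a)), 1)
  expect_equal(spearman_rho(a, -a^3 * 2 - 5), -1)
  expect_error(spearman_rho(a, rep(1, 50)), "constant")
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
})

test_that("spearman_rho equals Pearson on ranks (oracle identity, with ties)", {
  set.seed(2)
  for (i in 1:50) {
    x <- sample(1:8, 30, replace = TRUE)      # heavy ties
    y <- x + sample(1:5, 30, replace = TRUE)
    expect_equal(spearman_rho(x, y), cor(rank(x), rank(y)),
                 tolerance = 1e-12)
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("fisher_z matches its closed form and is antisymmetric", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  rhos <- seq(-0.9, 0.9, by = 0.3)
  expect_equal(fisher_z(-rhos), -fisher_z(rhos))
  expect_error(fisher_z(1), "Fisher")
})

test_that("lagged_xcorr_max recovers planted shifts and breaks ties to 0", {
  set.seed(3)
  base <- cumsum(rnorm(460))                  # smooth-ish series
  audio <- base[1:400]
  neural <- base[31:430]                      # audio precedes by 300 ms
  prof <- lagged_xcorr_max(audio[1:400], c(rep(0, 30), audio[1:370]) +
                             rnorm(400, 0, 1e-6))
  expect_equal(prof$argmax_lag, 300)
  expect_gt(prof$max_rho, 0.99)
  # degenerate window equals plain spearman
  p0 <- lagged_xcorr_max(audio, neural, lag_window = c(0, 0))
  expect_equal(p0$max_rho, spearman_rho(audio, neural))
  # invariance under monotone transforms of either series
  p1 <- lagged_xcorr_max(audio, neural)
  p2 <- lagged_xcorr_max(exp(audio / 10), neural)
  expect_equal(p1$rho_per_lag, p2$rho_per_lag, tolerance = 1e-12)
  # window longer than the fragment allows
  expect_error(lagged_xcorr_max(audio[1:320], neural[1:320]),
               "lag window")
})

test_that("condition_contrast handles degenerate and standard cases", {
  x <- rnorm(20)
  same <- condition_contrast(x, x, paired = TRUE)
  expect_equal(same$t, 0)
  expect_equal(same$p_raw, 1)
  r1 <- condition_contrast(rnorm(30, 1), rnorm(30), m_electrodes = 1)
  expect_equal(r1$p_bonferroni, r1$p_raw)
  r2 <- condition_contrast(rnorm(30, 1), rnorm(30), m_electrodes = 10)
  expect_equal(r2$p_bonferroni, min(1, r2$p_raw * 10), tolerance = 1e-12)
  # pooled-variance t equals t.test var.equal oracle
  set.seed(4)
  a <- rnorm(15); b <- rnorm(12, 0.5)
  got <- condition_contrast(a, b)
  want <- t.test(a, b, var.equal = TRUE)
  expect_equal(got$t, unname(want$statistic))
  expect_equal(got$df, unname(want$parameter))
})

test_that("condition_contrast has power at the emulated scale", {
  set.seed(5)
  rej <- vapply(1:100, function(i) {
    condition_contrast(rnorm(115, 1), rnorm(115), m_electrodes = 41,
                       alpha = 0.05)$significant
  }, NA)
  expect_gt(mean(rej), 0.99)
})

test_that("speech_preference recovers responsive channels on the fixture", {
  fx <- tracked_fixture()
  pref <- speech_preference(fx$hfb, fx$fragset)
  responsive <- which(fx$truth$gain > 0)
  expect_true(all(responsive %in% pref$mask))
  expect_equal(nrow(pref$contrasts), 6)
  expect_true(all(pref$contrasts$p_bonferroni >= pref$contrasts$p_raw))
})

test_that("envelope tracking contrast finds planted coupling and lags", {
  fx <- tracked_fixture()
  pref <- speech_preference(fx$hfb, fx$fragset)
  et <- envelope_tracking_contrast(fx$hfb, fx$feats_mixed$envelope,
                                   fx$fragset, mask = pref$mask)
  trk <- fx$truth$channel[fx$truth$class == "envelope_tracking"]
  sub <- et[et$channel %in% trk, ]
  expect_true(all(sub$significant))
  expect_equal(sub$best_lag_ms,
               fx$truth$lag[match(sub$channel, fx$truth$channel)],
               tolerance = 1e-9)
  expect_error(envelope_tracking_contrast(fx$hfb, fx$feats$envelope,
                                          fx$fragset, mask = integer(0)),
               "mask")
})

test_that("stg_reference_coupling selects the planted reference channel", {
  fx <- tracked_fixture()
  pref <- speech_preference(fx$hfb, fx$fragset)
  stg <- stg_reference_coupling(fx$hfb, fx$feats_mixed$envelope,
                                stg_candidate_ids = c("E003", "E005"),
                                mask = pref$mask, fragset = fx$fragset)
  expect_equal(stg$best_stg_id, "E003")       # the stg_like channel
  # channels driven by the same envelope at equal lags couple near lag 0
  ch1 <- stg$contrasts[stg$contrasts$channel == 1, ]
  expect_lte(abs(ch1$best_lag_ms), 10)
  expect_error(stg_reference_coupling(fx$hfb, fx$feats$envelope,
                                      character(0), pref$mask, fx$fragset),
               "candidates")
})

test_that("signed_r2 equals the signed squared point-biserial correlation", {
  set.seed(6)
  for (i in 1:20) {
    v <- c(rnorm(25, 1), rnorm(25))
    lab <- rep(c(1, 0), each = 25)
    got <- signed_r2(v, lab)
    r <- cor(v, lab)
    expect_equal(got$signed_r2, sign(mean(v[1:25]) - mean(v[26:50])) * r^2,
                 tolerance = 1e-12)
  }
  # values identical to labels -> +1
  expect_equal(signed_r2(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 0, 0, 0))$signed_r2, 1)
  # identical class distributions -> ~0
  set.seed(7)
  r0 <- signed_r2(rnorm(200), rep(c(0, 1), 100))
  expect_lt(abs(r0$signed_r2), 0.05)
  expect_error(signed_r2(1:5, c(1, 1, 1, 1, 0)), "2 trials")
})

test_that("noise filtering with identical envelopes gives t = 0", {
  fx <- tracked_fixture()
  nf <- noise_filter_contrast(fx$hfb, fx$feats_mixed$envelope,
                              fx$feats_mixed$envelope, fx$noisy,
                              mask = c(1, 2))
  expect_true(all(nf$t == 0))
  expect_true(all(nf$p_raw == 1))
})

test_that("intensity_contrast propagates and is sane on the fixture", {
  fx <- tracked_fixture()
  ic <- intensity_contrast(fx$audio$mixed, fx$fragset)
  expect_equal(ic$df, nrow(fx$fragset) - 2)
  expect_gt(ic$p, 0.001)                      # matched loudness by design
  one <- fx$fragset[c(1, nrow(fx$fragset)), ]
  expect_error(intensity_contrast(fx$audio$mixed, one), ">= 2 fragments")
})
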