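#' Run the full simulate-to-statistics pipeline
#'
#' Orchestrates: synthetic fixture generation (or loading), HFB
#' preprocessing (notch, common average reference, Gabor wavelets,
#' z-scoring), auditory feature extraction, fragment construction, the
#' tracking contrasts (speech preference, envelope tracking, noise
#' filtering) and the ON/OFF regression with its permutation null.
#' Deterministic given the config seed. Writes TSV/JSON outputs when
#' `out_dir` is given.
#'
#' @param config a [sim_config()].
#' @param truth optional [ground_truth()] (defaults to
#'   [default_ground_truth()]).
#' @param out_dir optional output directory for TSV/JSON result tables.
#' @param alpha family-wise level for the contrasts.
#' @param n_perm permutations for the ON/OFF F test (kept small by
#'   default here; raise to 10000 for publication-grade thresholds).
#' @param perm_alpha chance level of the permutation threshold (requires
#'   `n_perm >= 1 / perm_alpha` for a reliable percentile).
#' @param skip character vector of stages to skip: any of
#'   `"noise"`, `"regress"`.
#' @return a list bundle with every stage's outputs plus a ground-truth
#'   comparison table (`recovery`).
#' @export
run_pipeline <- function(config, truth = default_ground_truth(config),
                         out_dir = NULL, alpha = 0.05, n_perm = 1000,
                         perm_alpha = 0.001, skip = character(0)) {
  ann <- make_annotation(config)
  audio <- synthesize_audio(ann, config)
  feats <- audio_feature_stream(audio$isolated_speech, ann,
                                total_duration = config$total_duration)
  feats_mixed <- audio_feature_stream(audio$mixed, ann,
                                      total_duration = config$total_duration)
  rec <- synthesize_neural(feats, truth, config)
  rec <- notch(rec, freqs = c(config$line_noise_hz,
                              2 * config$line_noise_hz))
  if (sum(rec$channel_meta$good) >= 2) {
    rec <- common_average_reference(rec)
  }
  hfb <- gabor_hfb(rec)
  sp <- extract_speech_fragments(ann, n_max = config$n_speech_fragments)
  ns <- extract_nonspeech_fragments(ann,
                                    n_match = config$n_nonspeech_fragments)
  nz <- extract_noisy_fragments(ann)
  fragset <- fragment_set(rbind(sp, ns))
  hfb <- zscore_over_fragments(hfb, fragset)
  pref <- speech_preference(hfb, fragset, alpha = alpha)
  results <- list(config = config, truth = truth, annotation = ann,
                  features = feats, features_mixed = feats_mixed,
                  hfb = hfb, fragments = fragset,
                  noisy_fragments = nz,
                  intensity = intensity_contrast(audio$mixed, fragset),
                  preference = pref)
  mask <- pref$mask
  if (length(mask) > 0) {
    # The tracking envelope is that of the mixed track (what is heard);
    # inside clear-speech fragments it coincides with the isolated one.
    results$envelope_tracking <- envelope_tracking_contrast(
      hfb, feats_mixed$envelope, fragset, mask = mask, alpha = alpha)
    stg_ids <- hfb$channel_meta$id[hfb$channel_meta$anatomy == "STG"]
    if (length(stg_ids) > 0) {
      results$stg_coupling <- stg_reference_coupling(
        hfb, feats_mixed$envelope, stg_ids, mask, fragset, alpha = alpha)
    }
    if (!("noise" %in% skip) && nrow(nz) >= 2) {
      results$noise_filtering <- noise_filter_contrast(
        hfb, feats$envelope, feats_mixed$envelope, nz, mask,
        alpha = alpha)
    }
    if (!("regress" %in% skip)) {
      results$onoff_regression <- lapply(mask, function(ch) {
        et <- results$envelope_tracking
        lags <- rep(et$best_lag_ms[et$channel == ch],
                    sum(fragset$condition == "speech"))
        spf <- fragset[fragset$condition == "speech", , drop = FALSE]
        y_frags <- lag_align(hfb, spf, lags, channel = ch)
        x_frags <- lapply(seq_len(nrow(spf)), function(i) {
          v <- speech_onoff_vector(spf$onset[i], spf$duration[i], ann)
          k <- as.integer(round(attr(y_frags, "lags_ms")[i] / 10))
          v[seq_len(length(v) - k)]
        })
        fit <- onoff_ols(unlist(y_frags), unlist(x_frags))
        perm <- permutation_f_test(y_frags, x_frags, n_perm = n_perm,
                                   alpha = perm_alpha,
                                   seed = child_seed(config$seed,
                                                     paste0("perm", ch)))
        list(channel = ch, fit = fit, permutation = perm)
      })
    }
  }
  # ground-truth recovery table
  responsive <- truth$class %in% c("envelope_tracking", "stg_like")
  recovered <- truth$channel %in% mask
  results$recovery <- data.frame(
    channel = truth$channel, class = truth$class, gain = truth$gain,
    lag = truth$lag, in_mask = recovered,
    stringsAsFactors = FALSE)
  if (!is.null(results$envelope_tracking)) {
    et <- results$envelope_tracking
    results$recovery$est_lag_ms <-
      et$best_lag_ms[match(truth$channel, et$channel)]
  }
  if (!is.null(out_dir)) write_pipeline_outputs(results, out_dir)
  results
}

write_pipeline_outputs <- function(results, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  wt(results$preference$contrasts, "speech_preference.tsv")
  wt(results$fragments, "fragments.tsv")
  wt(results$recovery, "recovery.tsv")
  if (!is.null(results$envelope_tracking)) {
    wt(results$envelope_tracking, "envelope_tracking.tsv")
  }
  if (!is.null(results$noise_filtering)) {
    wt(results$noise_filtering, "noise_filtering.tsv")
  }
  summary <- list(
    config = unclass(results$config),
    mask = results$preference$mask,
    intensity = results$intensity,
    n_fragments = nrow(results$fragments))
  if (!is.null(results$onoff_regression)) {
    summary$onoff <- lapply(results$onoff_regression, function(r)
      list(channel = r$channel, F = r$fit$F,
           threshold = r$permutation$threshold,
           significant = r$permutation$significant))
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Thin wrapper used by `inst/cli/speechtrack`: parses
#' `--seed`, `--out`, `--n-speech`, `--n-nonspeech`, `--n-noisy`,
#' `--channels`, `--neural-fs`, `--n-perm` and runs [run_pipeline()].
#'
#' @param args character vector of command-line arguments.
#' @return invisibly, the pipeline result bundle.
#' @export
speechtrack_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  cfg <- sim_config(
    seed = as.integer(get_opt("--seed", "1")),
    n_speech_fragments = as.integer(get_opt("--n-speech", "10")),
    n_nonspeech_fragments = as.integer(get_opt("--n-nonspeech", "10")),
    n_noisy_fragments = as.integer(get_opt("--n-noisy", "4")),
    n_channels = as.integer(get_opt("--channels", "8")),
    neural_fs = as.numeric(get_opt("--neural-fs", "2000")))
  out <- get_opt("--out", file.path(tempdir(), "speechtrack_run"))
  n_perm <- as.integer(get_opt("--n-perm", "1000"))
  res <- run_pipeline(cfg, out_dir = out, n_perm = n_perm,
                      perm_alpha = max(0.001, 1 / n_perm))
  cat("outputs written to ", out, "\n", sep = "")
  invisible(res)
}
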