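#' Annotation container
#'
#' Holds the tiers of a soundtrack annotation: word boundaries, intervals
#' where speech overlaps music/noise, nonspeech sound intervals, and hand
#' (visual) labels. All intervals are half-open `[onset, offset)` seconds.
#'
#' @param words,overlap,nonspeech,hand data frames with columns `onset`,
#'   `offset` and (optionally) `label`, sorted or sortable by onset.
#' @param total_duration recording duration in seconds.
#' @return an object of class `annotation`.
#' @export
new_annotation <- function(words, overlap, nonspeech, hand,
                           total_duration) {
  norm <- function(df) {
    if (is.null(df) || nrow(df) == 0L) {
      return(data.frame(onset = numeric(0), offset = numeric(0),
                        label = character(0), stringsAsFactors = FALSE))
    }
    if (!"label" %in% names(df)) df$label <- ""
    stop_if_not(all(df$onset < df$offset),
                "annotation intervals must satisfy onset < offset")
    df <- df[order(df$onset), c("onset", "offset", "label")]
    rownames(df) <- NULL
    df
  }
  structure(list(words = norm(words), overlap = norm(overlap),
                 nonspeech = norm(nonspeech), hand = norm(hand),
                 total_duration = total_duration),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf(
    "<annotation> %.1f s: %d words, %d overlap, %d nonspeech, %d hand\n",
    x$total_duration, nrow(x$words), nrow(x$overlap), nrow(x$nonspeech),
    nrow(x$hand)))
  invisible(x)
}

#' Fragment sets
#'
#' A `fragment_set` is a data frame of 4-s analysis windows with columns
#' `onset`, `duration`, `condition` (`speech`, `nonspeech` or `noisy`) and
#' `hand_label` (0 = no hand, 1 = hand present, 2 = hand moving).
#'
#' @param df data frame with the columns above.
#' @return an object of classes `fragment_set`/`data.frame`.
#' @export
fragment_set <- function(df) {
  need <- c("onset", "duration", "condition", "hand_label")
  stop_if_not(all(need %in% names(df)),
              "fragment_set needs columns %s", paste(need, collapse = ", "))
  for (cond in unique(df$condition)) {
    sub <- df[df$condition == cond, , drop = FALSE]
    if (nrow(sub) > 1L) {
      o <- order(sub$onset)
      ok <- all(sub$onset[o][-1] >= (sub$onset + sub$duration)[o][-nrow(sub)])
      stop_if_not(ok, "fragments of condition '%s' overlap", cond)
    }
  }
  class(df) <- c("fragment_set", "data.frame")
  df
}

# Maximal speech "runs": words merged across gaps <= max_pause. Returns a
# data frame of run onset/offset plus, per run, its word list indices.
speech_runs <- function(words, max_pause) {
  if (nrow(words) == 0L) {
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  }
  on <- words$onset; off <- words$offset
  brk <- c(TRUE, on[-1] - off[-length(off)] > max_pause)
  run_id <- cumsum(brk)
  data.frame(onset = tapply(on, run_id, min),
             offset = tapply(off, run_id, max), row.names = NULL)
}

intersects_any <- function(onset, offset, df) {
  if (nrow(df) == 0L) return(FALSE)
  any(df$onset < offset & df$offset > onset)
}

hand_label_at <- function(ann, onset, offset) {
  if (nrow(ann$hand) == 0L) return(NA_integer_)
  hit <- which(ann$hand$onset < offset & ann$hand$offset > onset)
  if (length(hit) == 0L) return(NA_integer_)
  # label of the hand interval with the largest overlap
  ov <- pmin(ann$hand$offset[hit], offset) - pmax(ann$hand$onset[hit], onset)
  as.integer(ann$hand$label[hit[which.max(ov)]])
}

#' Extract labeled 4-s fragments from an annotation
#'
#' `extract_speech_fragments()` scans left to right through maximal speech
#' runs (words merged across pauses of at most `max_pause` seconds) and
#' tiles each run with non-overlapping windows of `fragment_duration`
#' seconds, so every window is continuous speech whose internal pauses are
#' all `<= max_pause`. Windows intersecting speech/noise overlap intervals
#' are excluded unless `allow_soft_overlap` is set (the "stationary and
#' soft background" exception, a caller judgment).
#'
#' `extract_nonspeech_fragments()` tiles nonspeech sound intervals with
#' windows containing no word intervals. `extract_noisy_fragments()`
#' returns speech windows whose words intersect overlap intervals (these
#' may overlap the clear-speech set).
#'
#' @param ann an [annotation][new_annotation].
#' @param n_max,n_match maximum number of fragments returned (fewer if the
#'   annotation does not support more).
#' @param max_pause longest pause allowed inside a speech fragment (s).
#' @param fragment_duration window length in seconds.
#' @param allow_soft_overlap logical; include windows that touch overlap
#'   intervals in the clear-speech set.
#' @return a [fragment_set()].
#' @export
extract_speech_fragments <- function(ann, n_max = Inf, max_pause = 0.5,
                                     fragment_duration = 4,
                                     allow_soft_overlap = FALSE) {
  runs <- speech_runs(ann$words, max_pause)
  out <- list()
  for (i in seq_len(nrow(runs))) {
    t0 <- runs$onset[i]
    while (t0 + fragment_duration <= runs$offset[i] + 1e-9) {
      if (length(out) >= n_max) break
      ok <- allow_soft_overlap ||
        !intersects_any(t0, t0 + fragment_duration, ann$overlap)
      if (ok) {
        out[[length(out) + 1L]] <- c(t0, fragment_duration)
        t0 <- t0 + fragment_duration
      } else {
        t0 <- t0 + fragment_duration
      }
    }
    if (length(out) >= n_max) break
  }
  build_fragset(out, "speech", ann)
}

#' @rdname extract_speech_fragments
#' @export
extract_nonspeech_fragments <- function(ann, n_match = Inf,
                                        fragment_duration = 4) {
  out <- list()
  for (i in seq_len(nrow(ann$nonspeech))) {
    t0 <- ann$nonspeech$onset[i]
    while (t0 + fragment_duration <= ann$nonspeech$offset[i] + 1e-9) {
      if (length(out) >= n_match) break
      if (!intersects_any(t0, t0 + fragment_duration, ann$words)) {
        out[[length(out) + 1L]] <- c(t0, fragment_duration)
      }
      t0 <- t0 + fragment_duration
    }
    if (length(out) >= n_match) break
  }
  build_fragset(out, "nonspeech", ann)
}

#' @rdname extract_speech_fragments
#' @export
extract_noisy_fragments <- function(ann, max_pause = 0.5,
                                    fragment_duration = 4) {
  runs <- speech_runs(ann$words, max_pause)
  out <- list()
  for (i in seq_len(nrow(runs))) {
    t0 <- runs$onset[i]
    while (t0 + fragment_duration <= runs$offset[i] + 1e-9) {
      w <- ann$words[ann$words$onset < t0 + fragment_duration &
                       ann$words$offset > t0, , drop = FALSE]
      if (nrow(w) > 0L &&
          any(vapply(seq_len(nrow(w)), function(k)
            intersects_any(w$onset[k], w$offset[k], ann$overlap), FALSE))) {
        out[[length(out) + 1L]] <- c(t0, fragment_duration)
      }
      t0 <- t0 + fragment_duration
    }
  }
  build_fragset(out, "noisy", ann)
}

build_fragset <- function(out, condition, ann) {
  if (length(out) == 0L) {
    return(fragment_set(data.frame(
      onset = numeric(0), duration = numeric(0),
      condition = character(0), hand_label = integer(0),
      stringsAsFactors = FALSE)))
  }
  m <- do.call(rbind, out)
  hl <- vapply(seq_len(nrow(m)), function(i)
    hand_label_at(ann, m[i, 1], m[i, 1] + m[i, 2]), 0L)
  fragment_set(data.frame(onset = m[, 1], duration = m[, 2],
                          condition = condition, hand_label = hl,
                          stringsAsFactors = FALSE))
}

#' Binary speech ON/OFF vector for one fragment
#'
#' One frame per 10 ms; a frame is 1 iff its center lies inside a word
#' interval (frame-center membership avoids double counting at
#' boundaries).
#'
#' @param onset,duration fragment window in seconds.
#' @param ann an [annotation][new_annotation].
#' @param frame_rate frames per second (100).
#' @return integer vector of 0/1 of length `duration * frame_rate`.
#' @export
speech_onoff_vector <- function(onset, duration, ann, frame_rate = 100) {
  n <- round(duration * frame_rate)
  centers <- onset + frame_centers(n, frame_rate)
  as.integer(in_intervals(centers, ann$words$onset, ann$words$offset))
}

# Frame indices (1-based, 100 Hz grid over the whole recording) covered by
# a fragment window.
fragment_frames <- function(onset, duration, frame_rate = 100) {
  first <- floor(onset * frame_rate + 1e-9) + 1L
  seq.int(first, length.out = round(duration * frame_rate))
}
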