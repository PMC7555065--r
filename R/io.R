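#' Read and write RIFF/WAVE audio
#'
#' Minimal mono/multichannel WAV support: 16-bit PCM and IEEE float32.
#' Samples are returned as a numeric vector (mono) scaled to [-1, 1] for
#' PCM. No pre-installed R package provides WAV I/O in this environment, so
#' the container is handled directly.
#'
#' @param path file path.
#' @param samples numeric vector in [-1, 1] (values are clipped for PCM).
#' @param fs sampling rate in Hz.
#' @param format `"float32"` (default, lossless for doubles within float
#'   precision) or `"pcm16"`.
#' @return `read_wav()` returns a list with `samples` and `fs`.
#' @export
write_wav <- function(path, samples, fs, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  n <- length(samples)
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "pcm16") {
    bits <- 16L; fmt <- 1L
    data_bytes <- n * 2L
  } else {
    bits <- 32L; fmt <- 3L
    data_bytes <- n * 4L
  }
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  byte_rate <- as.integer(fs * bits / 8L)
  writeBin(byte_rate, con, size = 4, endian = "little")
  writeBin(as.integer(bits / 8L), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "pcm16") {
    x <- pmin(pmax(samples, -1), 1)
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  stop_if_not(identical(riff, "RIFF"), "not a RIFF file: %s", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  stop_if_not(identical(wave, "WAVE"), "not a WAVE file: %s", path)
  fmt <- NULL; fs <- NULL; bits <- NULL; audio_fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      audio_fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      n_ch <- readBin(con, "integer", 1, size = 2, endian = "little")
      stop_if_not(n_ch == 1L, "only mono WAV supported (got %d channels)", n_ch)
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (sz > 16L) readBin(con, "raw", sz - 16L)
    } else if (id == "data") {
      if (audio_fmt == 1L && bits == 16L) {
        samples <- readBin(con, "integer", sz / 2L, size = 2,
                           endian = "little", signed = TRUE) / 32767
      } else if (audio_fmt == 3L && bits == 32L) {
        samples <- readBin(con, "numeric", sz / 4L, size = 4,
                           endian = "little")
      } else {
        stop("unsupported WAV encoding (fmt=", audio_fmt, ", bits=", bits, ")")
      }
    } else {
      readBin(con, "raw", sz)
    }
    if (!is.null(samples) && !is.null(fs)) break
  }
  list(samples = as.numeric(samples), fs = fs)
}

#' Write / read an annotation as a Praat TextGrid or a TSV mirror
#'
#' The TextGrid uses the long text format with interval tiers `words`,
#' `overlap`, `nonspeech` and `hand`. The TSV mirror has columns
#' `onset`, `offset`, `tier`, `label`. Intervals are half-open seconds.
#'
#' @param ann an `annotation` object (see [make_annotation()]).
#' @param path output path.
#' @return `read_annotation_tsv()` returns an `annotation` object.
#' @export
write_annotation_tsv <- function(ann, path) {
  rows <- list()
  add <- function(df, tier) {
    if (nrow(df) == 0L) return(NULL)
    lab <- if ("label" %in% names(df)) as.character(df$label) else ""
    rows[[length(rows) + 1L]] <<- data.frame(
      onset = df$onset, offset = df$offset, tier = tier, label = lab,
      stringsAsFactors = FALSE)
  }
  add(ann$words, "words")
  add(ann$overlap, "overlap")
  add(ann$nonspeech, "nonspeech")
  add(ann$hand, "hand")
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @param total_duration recording duration in seconds (stored in the
#'   annotation; inferred from the last offset when `NA`).
#' @export
read_annotation_tsv <- function(path, total_duration = NA_real_) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("numeric", "numeric",
                                         "character", "character"))
  pick <- function(tier) {
    sub <- df[df$tier == tier, , drop = FALSE]
    data.frame(onset = sub$onset, offset = sub$offset, label = sub$label,
               stringsAsFactors = FALSE)
  }
  if (is.na(total_duration)) total_duration <- max(df$offset, 0)
  new_annotation(words = pick("words"), overlap = pick("overlap"),
                 nonspeech = pick("nonspeech"), hand = pick("hand"),
                 total_duration = total_duration)
}

#' @rdname write_annotation_tsv
#' @export
write_textgrid <- function(ann, path) {
  dur <- ann$total_duration
  tiers <- list(words = ann$words, overlap = ann$overlap,
                nonspeech = ann$nonspeech, hand = ann$hand)
  # Fill gaps with empty-label intervals as Praat requires contiguous tiers.
  fill <- function(df) {
    lab <- if ("label" %in% names(df)) as.character(df$label) else
      rep("x", nrow(df))
    o <- order(df$onset)
    on <- df$onset[o]; off <- df$offset[o]; lab <- lab[o]
    res_on <- numeric(0); res_off <- numeric(0); res_lab <- character(0)
    cur <- 0
    for (i in seq_along(on)) {
      if (on[i] > cur) {
        res_on <- c(res_on, cur); res_off <- c(res_off, on[i])
        res_lab <- c(res_lab, "")
      }
      res_on <- c(res_on, on[i]); res_off <- c(res_off, off[i])
      res_lab <- c(res_lab, lab[i])
      cur <- off[i]
    }
    if (cur < dur) {
      res_on <- c(res_on, cur); res_off <- c(res_off, dur)
      res_lab <- c(res_lab, "")
    }
    data.frame(onset = res_on, offset = res_off, label = res_lab,
               stringsAsFactors = FALSE)
  }
  ln <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
          "xmin = 0", sprintf("xmax = %.10g", dur),
          "tiers? <exists>", sprintf("size = %d", length(tiers)),
          "item []:")
  k <- 0
  for (nm in names(tiers)) {
    k <- k + 1
    full <- fill(tiers[[nm]])
    ln <- c(ln,
            sprintf("    item [%d]:", k),
            '        class = "IntervalTier"',
            sprintf('        name = "%s"', nm),
            "        xmin = 0", sprintf("        xmax = %.10g", dur),
            sprintf("        intervals: size = %d", nrow(full)))
    for (i in seq_len(nrow(full))) {
      ln <- c(ln,
              sprintf("        intervals [%d]:", i),
              sprintf("            xmin = %.10g", full$onset[i]),
              sprintf("            xmax = %.10g", full$offset[i]),
              sprintf('            text = "%s"', full$label[i]))
    }
  }
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_textgrid <- function(path) {
  ln <- readLines(path)
  num <- function(s) as.numeric(sub('.*= *', '', s))
  txt <- function(s) sub('.*= *"(.*)"\\s*$', '\\1', s)
  dur <- num(ln[grep("^xmax", ln)[1]])
  item_idx <- grep("^\\s+item \\[", ln)
  tiers <- list()
  bounds <- c(item_idx, length(ln) + 1L)
  for (i in seq_along(item_idx)) {
    block <- ln[bounds[i]:(bounds[i + 1L] - 1L)]
    nm <- txt(block[grep("name =", block)[1]])
    xm <- block[grep("xmin =", block)]
    xx <- block[grep("xmax =", block)]
    tx <- block[grep("text =", block)]
    # first xmin/xmax pair is the tier itself
    df <- data.frame(onset = vapply(xm[-1], num, 0),
                     offset = vapply(xx[-1], num, 0),
                     label = vapply(tx, txt, ""),
                     stringsAsFactors = FALSE, row.names = NULL)
    tiers[[nm]] <- df[df$label != "", , drop = FALSE]
  }
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      label = character(0), stringsAsFactors = FALSE)
  new_annotation(words = tiers[["words"]] %||% empty,
                 overlap = tiers[["overlap"]] %||% empty,
                 nonspeech = tiers[["nonspeech"]] %||% empty,
                 hand = tiers[["hand"]] %||% empty,
                 total_duration = dur)
}

#' Write / read a multichannel neural recording container
#'
#' A documented binary container: little-endian float32, channel-major
#' (all samples of channel 1, then channel 2, ...), with a JSON sidecar
#' `<path>.json` holding `fs`, `n_samples` and per-channel metadata
#' (`id`, `grid`, `good`, `anatomy`).
#'
#' @param rec a `raw_recording` (see [raw_recording()]).
#' @param path output path for the binary payload.
#' @return `read_neural()` returns a `raw_recording`.
#' @export
write_neural <- function(rec, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$samples)), con, size = 4, endian = "little")
  meta <- list(fs = rec$fs, n_samples = ncol(rec$samples),
               channels = rec$channel_meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_neural
#' @export
read_neural <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ch <- as.data.frame(meta$channels, stringsAsFactors = FALSE)
  n_ch <- nrow(ch)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n_ch * meta$n_samples, size = 4,
               endian = "little")
  samples <- matrix(x, nrow = n_ch, ncol = meta$n_samples, byrow = TRUE)
  raw_recording(samples, fs = meta$fs, channel_meta = ch)
}
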