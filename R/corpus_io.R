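# Readers for the on-disk corpus layout and the feature-table format.
# All readers reject malformed inputs rather than silently coercing them.

#' Read a corpus manifest
#'
#' @param corpus_dir corpus root directory containing `manifest.csv`.
#' @return data frame with one row per segment.
#' @export
read_manifest <- function(corpus_dir) {
  path <- file.path(corpus_dir, "manifest.csv")
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("speaker_id", "word", "sibilant", "class", "wav_path",
            "t_start_s", "t_end_s")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  m
}

#' Load the audio samples of one segment
#'
#' Reads the segment's WAV file and returns the samples in the half-open
#' interval `[t_start_s, t_end_s)`; sample index = round(t * fs).
#'
#' @param record one manifest row (list or single-row data frame) with
#'   `wav_path`, `t_start_s`, `t_end_s`.
#' @param corpus_dir corpus root the `wav_path` is relative to.
#' @param fs expected sampling rate; a mismatch is an error.
#' @return list with `samples` and `fs`.
#' @export
load_segment <- function(record, corpus_dir = ".", fs = 44100) {
  if (record$t_end_s <= record$t_start_s)
    stop("t_end_s must exceed t_start_s", call. = FALSE)
  wav <- read_wav(file.path(corpus_dir, record$wav_path))
  if (wav$n_channels != 1L)
    stop("expected mono audio, got ", wav$n_channels, " channels",
         call. = FALSE)
  if (wav$fs != fs)
    stop("sampling rate mismatch: file has ", wav$fs, " Hz, expected ", fs,
         call. = FALSE)
  i0 <- round(record$t_start_s * fs)
  i1 <- round(record$t_end_s * fs)
  if (i1 > length(wav$samples))
    stop("segment end beyond file length", call. = FALSE)
  list(samples = wav$samples[(i0 + 1L):i1], fs = fs)
}

.read_mask_frame <- function(frame_dir, index, tag) {
  img_path <- file.path(frame_dir, sprintf("%03d_%s_img.png", index, tag))
  mask_path <- file.path(frame_dir, sprintf("%03d_%s_mask.png", index, tag))
  for (p in c(img_path, mask_path))
    if (!file.exists(p)) stop("missing frame file: ", p, call. = FALSE)
  gray <- round(png::readPNG(img_path) * 255)
  lab <- round(png::readPNG(mask_path) * 255)
  if (!all(lab %in% 0:4))
    stop("mask ", mask_path, " contains labels outside 0..4", call. = FALSE)
  list(gray = gray, labels = matrix(as.integer(lab), nrow(lab), ncol(lab)),
       camera = if (tag == "L") "left" else "right", frame_index = index)
}

#' Load the mask-frame pairs of one segment
#'
#' Returns the left/right camera frames of the segment, ordered by frame
#' index. The frame count must equal the segment's 33-ms audio frame count
#' (the synchronization contract); missing files or invalid labels are
#' errors.
#'
#' @param record one manifest row.
#' @param corpus_dir corpus root directory.
#' @param fs sampling rate used to derive the audio frame count.
#' @param frame_ms analysis frame duration (ms).
#' @return list of length n_frames; each element has `left` and `right`.
#' @export
load_mask_frames <- function(record, corpus_dir = ".", fs = 44100,
                             frame_ms = 33) {
  frame_dir <- file.path(corpus_dir, sub("\\.wav$", "", record$wav_path))
  if (!dir.exists(frame_dir))
    stop("frame directory not found: ", frame_dir, call. = FALSE)
  flen <- round(frame_ms * fs / 1000)
  n_frames <- floor((round(record$t_end_s * fs) -
                       round(record$t_start_s * fs)) / flen)
  lapply(seq_len(n_frames), function(i)
    list(left = .read_mask_frame(frame_dir, i, "L"),
         right = .read_mask_frame(frame_dir, i, "R")))
}

#' Write a feature table to CSV
#'
#' Accepts either a data frame or a named list of equally-named feature
#' vectors; writes one header row and one row per input with a stable
#' column order.
#'
#' @param rows data frame, or named list of named numeric vectors sharing
#'   one feature-name set.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  if (!is.data.frame(rows)) {
    if (length(rows)) {
      nm <- names(rows[[1]])
      same <- vapply(rows, function(r) identical(names(r), nm), logical(1))
      if (!all(same))
        stop("inconsistent feature sets across rows", call. = FALSE)
      rows <- cbind(data.frame(id = names(rows) %||%
                                 as.character(seq_along(rows))),
                    as.data.frame(do.call(rbind, rows)))
    } else {
      rows <- data.frame(id = character(0))
    }
  }
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_feature_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
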