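# Pipeline glue: hybrid per-frame feature matrices, per-speaker tables from
# either a simulated cohort (streamed, nothing kept on disk) or a corpus
# directory, and the feature catalog used for reporting.

#' Hybrid feature matrix for one segment
#'
#' Computes the 76 acoustic features per 33-ms frame and the 87 visual
#' features per camera per synchronized video frame, and binds them into an
#' n_frames x 250 matrix (`_L`/`_R` suffixes for the camera-specific
#' visual columns).
#'
#' @param samples audio sample vector of the segment.
#' @param frames list of left/right mask-frame pairs, one per audio frame.
#' @param cfg a [pipeline_config()].
#' @return numeric matrix with 250 named columns.
#' @export
extract_segment_features <- function(samples, frames, cfg = pipeline_config()) {
  ac <- extract_acoustic(samples, cfg)
  if (length(frames) != nrow(ac))
    stop("audio/video desynchronized: ", nrow(ac), " audio frames vs ",
         length(frames), " video frames", call. = FALSE)
  vis <- vapply(frames, function(fr)
    c(extract_visual(fr$left, cfg$gray_levels),
      extract_visual(fr$right, cfg$gray_levels)),
    numeric(174))
  vis <- t(matrix(vis, nrow = 174))
  colnames(vis) <- c(paste0(visual_feature_names(), "_L"),
                     paste0(visual_feature_names(), "_R"))
  cbind(ac, vis)
}

#' Catalog of the 250 hybrid features
#'
#' @return data frame with columns `feature`, `data` ("A" or "V"),
#'   `category` (time-domain/full-band/noise for acoustic; texture/mouth/
#'   lips/tongue for visual) and `camera` ("left", "right" or "none").
#' @export
feature_catalog <- function() {
  ac <- acoustic_feature_categories()
  vc <- visual_feature_categories()
  rbind(
    data.frame(feature = names(ac), data = "A", category = unname(ac),
               camera = "none"),
    data.frame(feature = paste0(names(vc), "_L"), data = "V",
               category = unname(vc), camera = "left"),
    data.frame(feature = paste0(names(vc), "_R"), data = "V",
               category = unname(vc), camera = "right"))
}

.speaker_vector <- function(segs, cfg) {
  mats <- lapply(segs, function(seg)
    extract_segment_features(seg$samples, seg$frames, cfg))
  aggregate_speaker(mats, cfg$crop_fraction)
}

.speaker_df <- function(ids, sibilant, classes, vecs) {
  M <- do.call(rbind, vecs)
  out <- cbind(data.frame(speaker_id = ids, sibilant = sibilant,
                          class = classes, stringsAsFactors = FALSE),
               as.data.frame(M, check.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Simulate a cohort and extract its per-speaker feature table
#'
#' Streams the simulation: each speaker's segments are generated, their
#' hybrid features extracted and aggregated, and the raw audio/frames
#' discarded, so arbitrarily large cohorts fit in memory. Equivalent to
#' [generate_cohort()] followed by [extract_corpus_features()].
#'
#' @param config a [cohort_config()].
#' @param cfg a [pipeline_config()].
#' @param progress print a dot per speaker to stderr.
#' @return data frame: speaker_id, sibilant, class and 250 feature columns.
#' @export
synth_speaker_table <- function(config, cfg = pipeline_config(),
                                progress = FALSE) {
  vecs <- list(); classes <- character(0)
  idx <- 0L
  for (class in names(config$group_sizes)) {
    for (g in seq_len(config$group_sizes[[class]])) {
      idx <- idx + 1L
      speaker <- .simulate_speaker(config, class, idx)
      vecs[[idx]] <- .speaker_vector(speaker$segments, cfg)
      classes[idx] <- class
      if (progress) cat(".", file = stderr())
    }
  }
  if (progress) cat("\n", file = stderr())
  .speaker_df(sprintf("SPK%03d", seq_len(idx)), config$sibilant, classes, vecs)
}

#' Extract the per-speaker feature table from a corpus directory
#'
#' Reads the manifest, loads every segment's audio and synchronized mask
#' frames, extracts the hybrid features and aggregates them per speaker.
#'
#' @param corpus_dir corpus root directory (see [generate_cohort()]).
#' @param cfg a [pipeline_config()].
#' @return data frame: speaker_id, sibilant, class and 250 feature columns.
#' @export
extract_corpus_features <- function(corpus_dir, cfg = pipeline_config()) {
  manifest <- read_manifest(corpus_dir)
  by_spk <- split(manifest, manifest$speaker_id)
  vecs <- lapply(by_spk, function(mrows) {
    segs <- lapply(seq_len(nrow(mrows)), function(i) {
      rec <- mrows[i, ]
      seg <- load_segment(rec, corpus_dir, cfg$fs)
      seg$frames <- load_mask_frames(rec, corpus_dir, cfg$fs, cfg$frame_ms)
      seg
    })
    .speaker_vector(segs, cfg)
  })
  .speaker_df(names(by_spk),
              vapply(by_spk, function(m) m$sibilant[1], character(1)),
              vapply(by_spk, function(m) m$class[1], character(1)), vecs)
}
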