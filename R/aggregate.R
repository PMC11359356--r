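# Per-speaker aggregation: crop 25 % of frames at each segment end, then
# average all retained frames of all of the speaker's segments column-wise.

#' Retained frame indices after end-cropping
#'
#' Drops `floor(fraction * n_frames)` frames at each end of a segment; at
#' least one frame is always retained.
#'
#' @param n_frames number of frames in the segment.
#' @param fraction fraction cropped at each end, in `[0, 0.5)`.
#' @return integer vector of retained (1-based) frame indices.
#' @export
#' @examples
#' crop_frames(8)   # drops 2 at each end
crop_frames <- function(n_frames, fraction = 0.25) {
  if (n_frames < 1) stop("n_frames must be at least 1", call. = FALSE)
  if (fraction < 0 || fraction >= 0.5)
    stop("fraction must lie in [0, 0.5)", call. = FALSE)
  k <- floor(fraction * n_frames)
  seq.int(k + 1L, n_frames - k)
}

#' Aggregate per-frame feature matrices into one speaker vector
#'
#' Each segment matrix is end-cropped with [crop_frames()], then all
#' retained frames across all segments are averaged column-wise with equal
#' weight per frame. The result is one feature vector per speaker,
#' ensuring data independence in the downstream tests.
#'
#' @param matrices list of per-frame feature matrices (one per segment,
#'   consistent columns).
#' @param fraction crop fraction at each segment end.
#' @return named numeric vector (column means over retained frames).
#' @export
aggregate_speaker <- function(matrices, fraction = 0.25) {
  if (length(matrices) == 0L)
    stop("no segment matrices to aggregate", call. = FALSE)
  nm <- colnames(matrices[[1]])
  kept <- lapply(matrices, function(m) {
    if (!identical(colnames(m), nm))
      stop("inconsistent feature columns across segments", call. = FALSE)
    m[crop_frames(nrow(m), fraction), , drop = FALSE]
  })
  colMeans(do.call(rbind, kept))
}
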