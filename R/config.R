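# Articulation classes, class profiles and configuration objects.

# canonical class order per sibilant; the /sh/ order (alveolar, dental,
# postalveolar) fixes the 1-2/1-3/2-3 labelling of post hoc pairs
.SIBILANTS <- c("s", "sh")
.CLASSES <- list(
  s  = c("dental", "interdental"),
  sh = c("alveolar", "dental", "postalveolar")
)

#' Allowed articulation classes for a sibilant
#'
#' The cohort design distinguishes two places of articulation for /s/
#' (dental, interdental) and three for /sh/ (alveolar, dental,
#' postalveolar); small residual classes (labiodental, addental, "other")
#' are out of scope.
#'
#' @param sibilant `"s"` or `"sh"`.
#' @return character vector of class names in canonical order.
#' @export
#' @examples
#' allowed_classes("s")
allowed_classes <- function(sibilant) {
  sibilant <- match_sibilant(sibilant)
  .CLASSES[[sibilant]]
}

match_sibilant <- function(sibilant) {
  if (length(sibilant) != 1L || !sibilant %in% .SIBILANTS)
    stop("unknown sibilant: must be one of ", paste(.SIBILANTS, collapse = ", "),
         call. = FALSE)
  sibilant
}

check_class <- function(sibilant, class) {
  ok <- allowed_classes(sibilant)
  if (!all(class %in% ok))
    stop(sprintf("articulation class '%s' not allowed for /%s/ (allowed: %s)",
                 paste(setdiff(class, ok), collapse = ", "), sibilant,
                 paste(ok, collapse = ", ")), call. = FALSE)
  invisible(class)
}

#' Class profile for the synthetic cohort simulator
#'
#' A `class_profile` bundles the articulation-class-dependent parameters the
#' simulator uses: the frication noise-band peak, four noise formants with
#' per-formant gains, tongue visibility probability and tongue area, mouth
#' geometry and image texture noise.
#'
#' @param noise_peak_hz frequency (Hz) of the noise-band spectral peak.
#' @param formant_freqs_hz four strictly increasing formant frequencies (Hz),
#'   all below the Nyquist frequency.
#' @param formant_gains_db four formant levels (dB, relative).
#' @param tongue_presence_prob per-frame probability that the tongue is
#'   visible, in `[0, 1]`.
#' @param tongue_area_mean_px mean visible tongue area (pixels).
#' @param tongue_area_sd_px between-frame SD of the tongue area (pixels).
#' @param mouth_axes_px outer mouth-ellipse semi-axes (pixels, c(horizontal,
#'   vertical)).
#' @param texture_noise_sd SD of the additive Gaussian gray-level noise.
#' @return an object of class `class_profile`.
#' @export
class_profile <- function(noise_peak_hz,
                          formant_freqs_hz,
                          formant_gains_db,
                          tongue_presence_prob,
                          tongue_area_mean_px,
                          tongue_area_sd_px,
                          mouth_axes_px = c(26, 15),
                          texture_noise_sd = 8) {
  stopifnot(length(formant_freqs_hz) == 4L, length(formant_gains_db) == 4L,
            all(diff(formant_freqs_hz) > 0))
  if (tongue_presence_prob < 0 || tongue_presence_prob > 1)
    stop("tongue_presence_prob must lie in [0, 1]", call. = FALSE)
  if (tongue_area_mean_px < 0)
    stop("tongue_area_mean_px must be non-negative", call. = FALSE)
  structure(list(noise_peak_hz = noise_peak_hz,
                 formant_freqs_hz = formant_freqs_hz,
                 formant_gains_db = formant_gains_db,
                 tongue_presence_prob = tongue_presence_prob,
                 tongue_area_mean_px = tongue_area_mean_px,
                 tongue_area_sd_px = tongue_area_sd_px,
                 mouth_axes_px = mouth_axes_px,
                 texture_noise_sd = texture_noise_sd),
            class = "class_profile")
}

# formant ladder anchored at the class noise peak; strongest gain at the peak
.profile_for_peak <- function(peak, presence, area_mean, area_sd) {
  class_profile(noise_peak_hz = peak,
                formant_freqs_hz = peak + c(0, 2000, 4500, 7000),
                formant_gains_db = c(0, -8, -12, -16),
                tongue_presence_prob = presence,
                tongue_area_mean_px = area_mean,
                tongue_area_sd_px = area_sd)
}

#' Default class profiles
#'
#' Shipped simulation profiles encoding the class effects the analysis is
#' meant to recover: for /s/, interdental productions show a more frequently
#' visible and larger tongue than dental ones; for /sh/, the three places of
#' articulation shift the frication noise-band peak.
#'
#' @param sibilant `"s"` or `"sh"`.
#' @return named list of [class_profile()] objects, one per allowed class.
#' @export
#' @examples
#' p <- default_profiles("s")
#' p$interdental$tongue_presence_prob > p$dental$tongue_presence_prob
default_profiles <- function(sibilant) {
  sibilant <- match_sibilant(sibilant)
  if (sibilant == "s") {
    list(
      dental      = .profile_for_peak(6500, presence = 0.15,
                                      area_mean = 300, area_sd = 75),
      interdental = .profile_for_peak(6000, presence = 0.75,
                                      area_mean = 900, area_sd = 225)
    )
  } else {
    list(
      alveolar     = .profile_for_peak(3200, presence = 0.30,
                                       area_mean = 400, area_sd = 100),
      dental       = .profile_for_peak(4800, presence = 0.30,
                                       area_mean = 400, area_sd = 100),
      postalveolar = .profile_for_peak(2600, presence = 0.30,
                                       area_mean = 400, area_sd = 100)
    )
  }
}

#' Cohort configuration
#'
#' Describes one synthetic cohort: which sibilant, how many speakers per
#' articulation class, how many segment realizations per speaker, segment
#' durations, image geometry and the master seed. The default group sizes
#' follow the study design (/s/: 113 dental + 31 interdental; /sh/: 106
#' alveolar + 27 dental + 29 postalveolar).
#'
#' @param sibilant `"s"` or `"sh"`.
#' @param group_sizes named integer vector, speakers per class; defaults to
#'   the study group sizes.
#' @param words_per_speaker segment realizations per speaker (default 3).
#' @param segment_duration_range_s segment duration range in seconds.
#' @param image_size_px c(rows, cols) of the camera frames.
#' @param fs audio sampling rate (Hz).
#' @param profiles named list of [class_profile()]s; defaults to
#'   [default_profiles()].
#' @param seed master integer seed; per-speaker sub-seeds are derived from it.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(sibilant,
                          group_sizes = NULL,
                          words_per_speaker = 3L,
                          segment_duration_range_s = c(0.30, 0.50),
                          image_size_px = c(64L, 64L),
                          fs = 44100,
                          profiles = NULL,
                          seed = 1L) {
  sibilant <- match_sibilant(sibilant)
  classes <- allowed_classes(sibilant)
  if (is.null(group_sizes)) {
    group_sizes <- if (sibilant == "s") c(dental = 113L, interdental = 31L)
                   else c(alveolar = 106L, dental = 27L, postalveolar = 29L)
  }
  check_class(sibilant, names(group_sizes))
  if (any(group_sizes <= 0) || words_per_speaker <= 0)
    stop("all counts must be positive", call. = FALSE)
  if (any(segment_duration_range_s <= 0) ||
      diff(segment_duration_range_s) < 0)
    stop("segment_duration_range_s must be a positive increasing interval",
         call. = FALSE)
  profiles <- profiles %||% default_profiles(sibilant)
  if (!all(names(group_sizes) %in% names(profiles)))
    stop("profiles missing for some classes", call. = FALSE)
  structure(list(sibilant = sibilant,
                 group_sizes = group_sizes[intersect(classes, names(group_sizes))],
                 words_per_speaker = as.integer(words_per_speaker),
                 segment_duration_range_s = segment_duration_range_s,
                 image_size_px = as.integer(image_size_px),
                 fs = fs,
                 profiles = profiles,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Pipeline configuration
#'
#' Processing constants shared by all stages: sampling rate, 33-ms
#' non-overlapping Hamming frames, the noise-band lower cutoff, 32 gray
#' levels for texture quantization, 25 % end-cropping before aggregation,
#' the significance level, the variance-ratio screening bounds and the
#' skewness threshold that triggers the log transform.
#'
#' @param fs sampling rate (Hz).
#' @param frame_ms analysis frame duration (ms).
#' @param noise_band_low_hz lower cutoff of the frication noise band (Hz).
#' @param gray_levels number of gray levels for texture quantization.
#' @param crop_fraction fraction of frames cropped at each end, in `[0, 0.5)`.
#' @param alpha significance level.
#' @param variance_ratio_bounds allowed range of pairwise group variance
#'   ratios.
#' @param skew_threshold absolute sample skewness beyond which a feature is
#'   log-transformed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(fs = 44100,
                            frame_ms = 33,
                            noise_band_low_hz = 2000,
                            gray_levels = 32L,
                            crop_fraction = 0.25,
                            alpha = 0.05,
                            variance_ratio_bounds = c(0.1, 10.0),
                            skew_threshold = 2.0) {
  if (crop_fraction < 0 || crop_fraction >= 0.5)
    stop("crop_fraction must lie in [0, 0.5)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (gray_levels < 2) stop("gray_levels must be at least 2", call. = FALSE)
  if (noise_band_low_hz >= fs / 2)
    stop("noise_band_low_hz must be below the Nyquist frequency", call. = FALSE)
  structure(list(fs = fs, frame_ms = frame_ms,
                 frame_len = round(frame_ms * fs / 1000),
                 noise_band_low_hz = noise_band_low_hz,
                 gray_levels = as.integer(gray_levels),
                 crop_fraction = crop_fraction,
                 alpha = alpha,
                 variance_ratio_bounds = variance_ratio_bounds,
                 skew_threshold = skew_threshold),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Any field of [pipeline_config()] may be overridden in the file; missing
#' fields keep their defaults.
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  keep <- intersect(names(cfg), names(formals(pipeline_config)))
  do.call(pipeline_config, cfg[keep])
}
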