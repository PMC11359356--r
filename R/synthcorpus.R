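# Synthetic multimodal cohort simulator: frication-noise audio segments and
# dual-camera articulator mask sequences with class-dependent structure
# (noise-band peak position; tongue visibility and area).

#' Synthesize one frication-noise segment
#'
#' White noise is shaped by a parallel bank of four second-order resonators
#' placed at the profile's formant frequencies; each branch is normalized to
#' unit RMS and scaled by its formant gain, so the noise-band spectral peak
#' sits at the formant with the highest gain (the profile's `noise_peak_hz`).
#' A -30 dB broadband noise floor keeps the spectrum non-degenerate.
#' Samples are quantized to the 16-bit grid so that a WAV round trip is
#' exact.
#'
#' @param profile a [class_profile()].
#' @param duration_s segment duration (s), positive.
#' @param fs sampling rate (Hz).
#' @param seed integer seed; equal seeds give identical samples.
#' @return list of class `audio_segment` with `samples` and `fs`.
#' @export
synth_fricative_segment <- function(profile, duration_s, fs = 44100,
                                    seed = 1L) {
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  if (any(profile$formant_freqs_hz >= fs / 2))
    stop("formant frequency at or above Nyquist", call. = FALSE)
  n <- round(duration_s * fs)
  bw <- 250                                 # resonator bandwidth (Hz)
  r <- exp(-pi * bw / fs)
  gains <- 10^(profile$formant_gains_db / 20)
  x <- with_seed(seed, {
    out <- numeric(n)
    for (k in seq_along(profile$formant_freqs_hz)) {
      th <- 2 * pi * profile$formant_freqs_hz[k] / fs
      br <- stats::filter(rnorm(n), c(2 * r * cos(th), -r^2),
                          method = "recursive")
      br <- as.numeric(br)
      out <- out + gains[k] * br / sqrt(mean(br^2))
    }
    out + 10^(-30 / 20) * rnorm(n)
  })
  x <- 0.2 * x / sqrt(mean(x^2))
  x <- round(pmax(-1, pmin(1, x)) * 32767) / 32767
  structure(list(samples = x, fs = fs), class = "audio_segment")
}

#' Welch-style spectral peak of a signal above a cutoff
#'
#' Averages the one-sided power spectra of non-overlapping 33-ms Hamming
#' frames and returns the frequency of the argmax at or above
#' `band_low_hz`. Used to verify that synthesized segments place their
#' noise-band peak where the class profile says.
#'
#' @param samples numeric signal.
#' @param fs sampling rate (Hz).
#' @param band_low_hz lower frequency cutoff (Hz).
#' @return peak frequency (Hz).
#' @export
segment_peak_frequency <- function(samples, fs = 44100, band_low_hz = 2000) {
  X <- frame_segment(samples, fs)
  P <- rowMeans(.power_spectrum_batch(X))
  f <- .fft_freqs(fs)
  keep <- f >= band_low_hz
  f[keep][which.max(P[keep])]
}

# raster of an ellipse on an H x W pixel grid
.ellipse_mask <- function(H, W, rc, cc, b, a) {
  r <- matrix(seq_len(H), H, W)
  ccol <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((ccol - cc) / a)^2 + ((r - rc) / b)^2 <= 1
}

# render one camera view of a mouth state; grids are precomputed row/col
# index matrices shared across frames
.render_view <- function(state, grids, profile) {
  rg <- grids$r; cg <- grids$c
  H <- nrow(rg); W <- ncol(rg)
  rc <- H / 2 + state$jr
  cc <- W / 2 + state$jc
  a <- profile$mouth_axes_px[1] * state$ja
  b <- profile$mouth_axes_px[2] * state$aperture * state$ja
  thick <- 4
  ell <- function(rc0, cc0, b0, a0) {
    ((cg - cc0) / a0)^2 + ((rg - rc0) / b0)^2 <= 1
  }
  outer <- ell(rc, cc, b, a)
  inner <- ell(rc, cc, max(b - thick, 1), max(a - thick, 1))
  lab <- matrix(0L, H, W)
  lab[outer] <- 1L                        # lips
  lab[inner] <- 4L                        # mouth interior
  if (state$teeth) {
    teeth <- ell(rc - 0.45 * b, cc, 0.22 * b, 0.55 * a) & inner
    lab[teeth] <- 2L
  }
  if (state$tongue_area > 0) {
    ar <- 1.8                             # tongue width/height aspect
    bt <- sqrt(state$tongue_area / (pi * ar))
    at <- ar * bt
    # the tongue may protrude over the lower lip but never covers the
    # upper mouth band, so the mouth ROI stays non-degenerate
    tongue <- ell(rc + 0.30 * b, cc, bt, at) & (rg > rc - 0.5 * b)
    lab[tongue] <- 3L
  }
  base <- c(40, 130, 210, 170, 70)[lab + 1L]
  gray <- base + rnorm(length(lab), sd = profile$texture_noise_sd)
  gray <- matrix(round(pmax(0, pmin(255, gray))), H, W)
  list(gray = gray, labels = lab)
}

#' Synthesize a dual-camera mask sequence
#'
#' Each frame carries one articulatory state: mouth aperture, whether the
#' tongue is visible (with probability `tongue_presence_prob`) and, if so,
#' its area drawn from a truncated normal. The left and right camera views
#' are independently jittered renderings (small translation and scale
#' perturbations) of that same state. Gray images are the label-dependent
#' base intensities plus Gaussian texture noise, rounded to 8-bit so a PNG
#' round trip is exact.
#'
#' @param profile a [class_profile()].
#' @param n_frames number of frames (>= 1).
#' @param image_size c(rows, cols) in pixels.
#' @param seed integer seed.
#' @return list of length `n_frames`; each element has `left` and `right`
#'   mask frames (lists with `gray`, `labels`, `camera`, `frame_index`).
#' @export
synth_mask_sequence <- function(profile, n_frames, image_size = c(64L, 64L),
                                seed = 1L) {
  if (n_frames < 1) stop("n_frames must be at least 1", call. = FALSE)
  H <- image_size[1]; W <- image_size[2]
  grids <- list(r = matrix(seq_len(H), H, W),
                c = matrix(seq_len(W), H, W, byrow = TRUE))
  with_seed(seed, {
    lapply(seq_len(n_frames), function(i) {
      state <- list(
        aperture = runif(1, 0.85, 1.15),
        teeth = runif(1) < 0.4,
        tongue_area = if (rbinom(1, 1, profile$tongue_presence_prob) == 1L)
          max(1, rnorm(1, profile$tongue_area_mean_px,
                       profile$tongue_area_sd_px)) else 0)
      views <- lapply(c("left", "right"), function(cam) {
        st <- state
        st$jr <- runif(1, -2, 2)
        st$jc <- runif(1, -2, 2)
        st$ja <- runif(1, 0.95, 1.05)
        v <- .render_view(st, grids, profile)
        v$camera <- cam
        v$frame_index <- i
        v
      })
      names(views) <- c("left", "right")
      views
    })
  })
}

# deterministic per-speaker / per-segment seed derivation: a stated counter
# scheme so any speaker can be regenerated in isolation
.derive_seed <- function(master, speaker_idx, slot) {
  (master %% 40000L) * 20011L + speaker_idx * 101L + slot
}

# speaker-level random effects applied to the class profile
.speaker_profile <- function(profile, seed) {
  with_seed(seed, {
    pr <- profile
    pr$noise_peak_shift <- rnorm(1, 0, 150)
    shift <- pr$noise_peak_shift
    pr$noise_peak_hz <- pr$noise_peak_hz + shift
    pr$formant_freqs_hz <- pr$formant_freqs_hz + shift
    lo <- stats::qlogis(min(max(pr$tongue_presence_prob, 1e-6), 1 - 1e-6))
    pr$tongue_presence_prob <- stats::plogis(lo + rnorm(1, 0, 0.5))
    if (profile$tongue_presence_prob == 0) pr$tongue_presence_prob <- 0
    if (profile$tongue_presence_prob == 1) pr$tongue_presence_prob <- 1
    pr$tongue_area_mean_px <- pr$tongue_area_mean_px * exp(rnorm(1, 0, 0.15))
    pr
  })
}

# generate one speaker's segments (audio + synchronized mask frames)
.simulate_speaker <- function(config, class, speaker_idx) {
  profile <- .speaker_profile(config$profiles[[class]],
                              .derive_seed(config$seed, speaker_idx, 0L))
  flen <- round(33 * config$fs / 1000)
  word <- if (config$sibilant == "s") "sa" else "sza"
  segs <- lapply(seq_len(config$words_per_speaker), function(j) {
    sseed <- .derive_seed(config$seed, speaker_idx, j)
    dur <- with_seed(sseed, runif(1, config$segment_duration_range_s[1],
                                  config$segment_duration_range_s[2]))
    n_frames <- max(1L, floor(round(dur * config$fs) / flen))
    n_samples <- n_frames * flen
    audio <- synth_fricative_segment(profile, n_samples / config$fs,
                                     config$fs, seed = 2L * sseed)
    frames <- synth_mask_sequence(profile, n_frames, config$image_size_px,
                                  seed = 2L * sseed + 1L)
    list(word = word, k = j, samples = audio$samples, fs = config$fs,
         n_frames = n_frames, frames = frames)
  })
  list(class = class, segments = segs)
}

#' Generate a synthetic corpus on disk
#'
#' Simulates the configured cohort and writes it in the standard corpus
#' layout: `corpus/<speaker>/<word>__<k>.wav` for the audio,
#' `corpus/<speaker>/<word>__<k>/<frame>_{L,R}_img.png` and
#' `..._{L,R}_mask.png` for the per-frame camera views, and a
#' `manifest.csv` listing every segment (speaker_id, word, sibilant, class,
#' wav_path, t_start_s, t_end_s). Audio and video are synchronized: the
#' number of video frames equals the number of 33-ms audio frames.
#' Regeneration with the same config (including seed) is byte-identical.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if missing).
#' @return the manifest as a data frame, invisibly.
#' @export
generate_cohort <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  idx <- 0L
  for (class in names(config$group_sizes)) {
    for (g in seq_len(config$group_sizes[[class]])) {
      idx <- idx + 1L
      spk <- sprintf("SPK%03d", idx)
      spk_dir <- file.path(out_dir, spk)
      dir.create(spk_dir, showWarnings = FALSE)
      speaker <- .simulate_speaker(config, class, idx)
      for (seg in speaker$segments) {
        base <- sprintf("%s__%d", seg$word, seg$k)
        wav_rel <- file.path(spk, paste0(base, ".wav"))
        write_wav(seg$samples, file.path(out_dir, wav_rel), fs = seg$fs)
        frame_dir <- file.path(spk_dir, base)
        dir.create(frame_dir, showWarnings = FALSE)
        for (i in seq_along(seg$frames)) {
          for (cam in c("left", "right")) {
            v <- seg$frames[[i]][[cam]]
            tag <- if (cam == "left") "L" else "R"
            png::writePNG(v$gray / 255,
                          file.path(frame_dir,
                                    sprintf("%03d_%s_img.png", i, tag)))
            png::writePNG(v$labels / 255,
                          file.path(frame_dir,
                                    sprintf("%03d_%s_mask.png", i, tag)))
          }
        }
        manifest[[length(manifest) + 1L]] <- data.frame(
          speaker_id = spk, word = seg$word, sibilant = config$sibilant,
          class = class, wav_path = wav_rel, t_start_s = 0,
          t_end_s = length(seg$samples) / seg$fs)
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
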