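# Acoustic battery: 4 time-domain + 24 full-band spectral + 48 noise-band
# spectral features per 33-ms frame.
#
# Conventions:
#  * segments are min-max normalized to [0, 1], then cut into non-overlapping
#    frames; each frame is mean-removed (the 0-1 normalization introduces a
#    DC offset that would otherwise swamp zero-crossing and spectral
#    descriptors) and Hamming-windowed;
#  * spectra are one-sided power spectra of the 2048-point zero-padded FFT;
#  * the noise band is [noise_band_low_hz, fs/2].

.EPS <- 1e-12

.PAIRS2 <- c("12", "13", "14", "23", "24", "34")
.PAIRS_D <- c("12", "23", "34")

#' Canonical acoustic feature names
#'
#' Returns the 76 feature names in canonical order: 4 time-domain, 24
#' full-band spectral, 48 noise-band spectral.
#' @return character vector of length 76.
#' @export
acoustic_feature_names <- function() {
  c("ZCRt", "STEt", "Pt", "HRt",
    "SCenf", "SSprf", "SSkf", "SCrf", "SDf", "SEf", "SFlaf", "SFlxf",
    "SRPf", "SKurtf", "SSlf", paste0("MFCC", 0:12),
    paste0("NFF", 1:4), paste0("NFFL", 1:4),
    paste0("NFFR", .PAIRS2), paste0("NFLR", .PAIRS2),
    paste0("NCC", 0:12), paste0("NE", 0:9),
    paste0("NFFD", .PAIRS_D), "NPA", "NPF")
}

#' Acoustic feature categories
#'
#' @return named character vector mapping each of the 76 acoustic feature
#'   names to `"time-domain"`, `"full-band"` or `"noise"`.
#' @export
acoustic_feature_categories <- function() {
  nm <- acoustic_feature_names()
  setNames(c(rep("time-domain", 4), rep("full-band", 24), rep("noise", 48)), nm)
}

#' Min-max normalize a segment to the 0-1 range
#'
#' @param samples numeric vector, length at least 2, not constant.
#' @return affine rescaling of `samples` with minimum 0 and maximum 1.
#' @export
#' @examples
#' normalize_segment(c(2, 4, 6))
normalize_segment <- function(samples) {
  if (length(samples) < 2L)
    stop("segment must contain at least 2 samples", call. = FALSE)
  r <- range(samples)
  if (r[1] == r[2])
    stop("constant segment: zero range, cannot normalize", call. = FALSE)
  (samples - r[1]) / (r[2] - r[1])
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Partition a segment into windowed analysis frames
#'
#' Cuts the signal into `frame_ms` frames (1455 samples at 44.1 kHz),
#' drops the trailing partial frame, removes each frame's mean and applies
#' a Hamming window.
#'
#' @param samples numeric vector.
#' @param fs sampling rate (Hz).
#' @param frame_ms frame duration (ms).
#' @param overlap fractional overlap between consecutive frames (default 0).
#' @return numeric matrix with one column per frame.
#' @export
frame_segment <- function(samples, fs = 44100, frame_ms = 33, overlap = 0) {
  flen <- round(frame_ms * fs / 1000)
  if (length(samples) < flen)
    stop("segment shorter than one frame (", flen, " samples)", call. = FALSE)
  step <- max(1L, round(flen * (1 - overlap)))
  starts <- seq.int(1L, length(samples) - flen + 1L, by = step)
  X <- vapply(starts, function(s) samples[s:(s + flen - 1L)], numeric(flen))
  X <- sweep(matrix(X, nrow = flen), 2, colMeans(matrix(X, nrow = flen)))
  X * hamming_window(flen)
}

# ---- time domain -------------------------------------------------------

# batch versions operate on a frames matrix (one column per frame)
.zcr_batch <- function(X) {
  n <- nrow(X)
  colSums(X[-1, , drop = FALSE] * X[-n, , drop = FALSE] < 0) / (n - 1)
}

.autocorr_batch <- function(X) {
  n <- nrow(X)
  nfft <- 2^ceiling(log2(2 * n))
  Y <- stats::mvfft(rbind(X, matrix(0, nfft - n, ncol(X))))
  Re(stats::mvfft(Mod(Y)^2, inverse = TRUE)) / nfft
}

.pitch_batch <- function(X, fs, f_lo = 50, f_hi = 500, voicing = 0.3) {
  r <- .autocorr_batch(X)
  lags <- seq.int(ceiling(fs / f_hi), floor(fs / f_lo))
  r0 <- r[1, ]
  r0[r0 <= 0] <- 1
  rn <- r[lags + 1L, , drop = FALSE] / rep(r0, each = length(lags))
  hr <- apply(rn, 2, max)
  best <- lags[apply(rn, 2, which.max)]
  pt <- ifelse(hr >= voicing, fs / best, 0)
  hr <- pmin(pmax(hr, 0), 1)
  list(Pt = pt, HRt = hr)
}

#' Time-domain features of one frame
#'
#' Zero-crossing rate (sign changes / (N-1)), short-term energy (mean squared
#' sample), autocorrelation pitch in the 50-500 Hz range (0 when the maximum
#' normalized autocorrelation falls below the 0.3 voicing threshold -- the
#' expected outcome for frication noise) and the harmonic ratio (that maximum,
#' clipped to `[0, 1]`).
#'
#' @param frame windowed frame vector (see [frame_segment()]).
#' @param fs sampling rate (Hz).
#' @return named numeric vector `c(ZCRt, STEt, Pt, HRt)`.
#' @export
time_domain_features <- function(frame, fs = 44100) {
  X <- matrix(frame, ncol = 1)
  if (all(frame == 0)) return(c(ZCRt = 0, STEt = 0, Pt = 0, HRt = 0))
  p <- .pitch_batch(X, fs)
  c(ZCRt = .zcr_batch(X), STEt = mean(frame^2), Pt = p$Pt, HRt = p$HRt)
}

# ---- spectra -----------------------------------------------------------

.NFFT <- 2048L

# one-sided power spectrum matrix (one column per frame)
.power_spectrum_batch <- function(X, nfft = .NFFT) {
  n <- nrow(X)
  if (nfft < n) stop("nfft smaller than frame length", call. = FALSE)
  Y <- stats::mvfft(rbind(X, matrix(0, nfft - n, ncol(X))))
  Mod(Y[seq_len(nfft / 2 + 1L), , drop = FALSE])^2
}

.fft_freqs <- function(fs, nfft = .NFFT) (0:(nfft / 2)) * fs / nfft

# mel filterbank (nfilt x nbins), triangular filters over [0, fs/2]
.mel_filterbank <- function(fs, nfft = .NFFT, nfilt = 26L) {
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- imel(seq(0, mel(fs / 2), length.out = nfilt + 2L))
  f <- .fft_freqs(fs, nfft)
  M <- matrix(0, nfilt, length(f))
  for (k in seq_len(nfilt)) {
    lo <- pts[k]; ce <- pts[k + 1]; hi <- pts[k + 2]
    up <- (f - lo) / (ce - lo)
    dn <- (hi - f) / (hi - ce)
    M[k, ] <- pmax(0, pmin(up, dn))
  }
  M
}

# orthonormal DCT-II matrix (ncoef x n)
.dct_matrix <- function(ncoef, n) {
  D <- outer(0:(ncoef - 1), 0:(n - 1),
             function(k, j) cos(pi * k * (2 * j + 1) / (2 * n)))
  D * sqrt(2 / n) * ifelse(seq_len(ncoef) == 1L, 1 / sqrt(2), 1)
}

.fullband_names <- function() acoustic_feature_names()[5:28]

# full-band features for a power-spectrum matrix; flux needs the previous
# frame's normalized spectrum, handled column-to-column (first frame = 0)
.fullband_batch <- function(P, fs, nfft = .NFFT, mel_fb = NULL) {
  f <- .fft_freqs(fs, nfft)
  K <- nrow(P); nfr <- ncol(P)
  tot <- colSums(P)
  zero <- tot <= 0
  tot[zero] <- 1
  cen <- colSums(f * P) / tot
  D <- f - rep(cen, each = K)
  m2 <- colSums(D^2 * P) / tot
  spread <- sqrt(m2)
  sk <- ifelse(m2 > 0, (colSums(D^3 * P) / tot) / m2^1.5, 0)
  ku <- ifelse(m2 > 0, (colSums(D^4 * P) / tot) / m2^2, 0)
  crest <- apply(P, 2, max) / (tot / K)
  Pden <- colSums(P[-1, , drop = FALSE])
  Pden[Pden <= 0] <- 1
  decrease <- colSums((P[-1, , drop = FALSE] - rep(P[1, ], each = K - 1)) /
                        (seq_len(K - 1))) / Pden
  p <- P / rep(tot, each = K)
  entropy <- -colSums(p * log(p + .EPS)) / log(K)
  flat <- exp(colMeans(log(P + .EPS))) / (tot / K)
  flux <- c(0, sqrt(colSums((p[, -1, drop = FALSE] -
                               p[, -nfr, drop = FALSE])^2)))
  if (nfr == 1L) flux <- 0
  roll <- vapply(seq_len(nfr), function(j)
    f[which(cumsum(P[, j]) >= 0.95 * tot[j])[1]], numeric(1))
  fbar <- mean(f)
  slope <- (colSums(f * P) - K * fbar * (tot / K)) / sum((f - fbar)^2)
  if (is.null(mel_fb)) mel_fb <- .mel_filterbank(fs, nfft)
  E <- log(mel_fb %*% P + .EPS)
  C <- .dct_matrix(13L, nrow(mel_fb)) %*% E
  out <- rbind(SCenf = cen, SSprf = spread, SSkf = sk, SCrf = crest,
               SDf = decrease, SEf = entropy, SFlaf = flat, SFlxf = flux,
               SRPf = roll, SKurtf = ku, SSlf = slope, C)
  rownames(out) <- .fullband_names()
  if (any(zero)) {
    warning("all-zero spectrum in ", sum(zero), " frame(s); features set to 0")
    out[, zero] <- 0
  }
  out
}

#' Full-band spectral features of one frame
#'
#' Spectral centroid, spread, skewness, crest, decrease, normalized entropy,
#' flatness, flux against the previous frame (0 for the first frame),
#' 95 % rolloff, kurtosis, slope and MFCC 0-12 from a 26-filter mel
#' filterbank.
#'
#' @param frame windowed frame vector.
#' @param prev_frame previous windowed frame, or `NULL` for the first frame.
#' @param fs sampling rate (Hz).
#' @return named numeric vector of 24 features.
#' @export
fullband_features <- function(frame, prev_frame = NULL, fs = 44100) {
  X <- matrix(frame, ncol = 1)
  if (!is.null(prev_frame)) X <- cbind(prev_frame, frame)
  P <- .power_spectrum_batch(X)
  out <- .fullband_batch(P, fs)
  out[, ncol(out)]
}

#' Noise-band power spectrum of one frame
#'
#' Restricts the frame's one-sided power spectrum to the frication noise band
#' `[band_low_hz, fs/2]`.
#'
#' @param frame windowed frame vector.
#' @param fs sampling rate (Hz).
#' @param band_low_hz lower band cutoff (Hz), strictly below Nyquist.
#' @return an object of class `noise_spectrum` with `freqs_hz`, `power`,
#'   `band_low_hz`, `band_high_hz`.
#' @export
noise_band_spectrum <- function(frame, fs = 44100, band_low_hz = 2000) {
  if (band_low_hz >= fs / 2)
    stop("empty noise band: band_low_hz must be below fs/2", call. = FALSE)
  P <- .power_spectrum_batch(matrix(frame, ncol = 1))[, 1]
  f <- .fft_freqs(fs)
  keep <- f >= band_low_hz
  structure(list(freqs_hz = f[keep], power = P[keep],
                 band_low_hz = band_low_hz, band_high_hz = fs / 2),
            class = "noise_spectrum")
}

# peak prominences for local maxima of y at indices pk (compiled)
.peak_prominence <- function(y, pk) .peak_prominence_cpp(y, as.integer(pk))

.moving_average <- function(y, w) {
  h <- (w - 1L) %/% 2L
  yp <- c(rep(y[1], h), y, rep(y[length(y)], h))
  as.numeric(stats::filter(yp, rep(1 / w, w), sides = 2))[(h + 1L):(h + length(y))]
}

#' Fricative formants from a noise-band spectrum
#'
#' Smooths the dB power spectrum with a 9-bin moving average, picks local
#' maxima, ranks them by topographic prominence and reports the four most
#' prominent peaks sorted by ascending frequency (NFF1-4) with their dB
#' levels (NFFL1-4). When fewer than four peaks exist the highest-frequency
#' peak is repeated; a peakless spectrum falls back to the global maximum.
#'
#' @param ns a `noise_spectrum` (see [noise_band_spectrum()]).
#' @param smooth_bins moving-average width in bins (odd, default 9).
#' @return list with `NFF` (Hz, ascending) and `NFFL` (dB), each length 4.
#' @export
fricative_formants <- function(ns, smooth_bins = 9L) {
  L <- 10 * log10(ns$power + .EPS)
  Ls <- .moving_average(L, smooth_bins)
  n <- length(Ls)
  pk <- which(Ls[-c(1, 2)] <= Ls[-c(1, n)] & Ls[-c(n - 1, n)] < Ls[-c(1, n)]) + 1L
  if (length(pk) == 0L) {
    warning("no local maxima in noise spectrum; using global peak")
    i <- which.max(ns$power)
    return(list(NFF = rep(ns$freqs_hz[i], 4),
                NFFL = rep(10 * log10(ns$power[i] + .EPS), 4)))
  }
  prom <- .peak_prominence(Ls, pk)
  ord <- order(-prom, -Ls[pk])
  top <- pk[ord[seq_len(min(4L, length(pk)))]]
  top <- sort(top)
  while (length(top) < 4L) top <- c(top, top[length(top)])
  list(NFF = ns$freqs_hz[top], NFFL = Ls[top])
}

#' Formant frequency/level ratios and distances
#'
#' `NFFRij = NFFi / NFFj` and `NFLRij = NFFLi / NFFLj` for the pairs 12, 13,
#' 14, 23, 24, 34; `NFFDij = NFFj - NFFi` for 12, 23, 34. A zero denominator
#' yields 0 with a warning.
#'
#' @param NFF four formant frequencies, ascending.
#' @param NFFL four formant levels (dB).
#' @return named numeric vector of 15 features.
#' @export
formant_ratios_distances <- function(NFF, NFFL) {
  ij <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  safe_ratio <- function(a, b) {
    bad <- b == 0
    if (any(bad)) warning("zero denominator in formant ratio; feature set to 0")
    ifelse(bad, 0, a / b)
  }
  nffr <- safe_ratio(NFF[ij[, 1]], NFF[ij[, 2]])
  nflr <- safe_ratio(NFFL[ij[, 1]], NFFL[ij[, 2]])
  nffd <- c(NFF[2] - NFF[1], NFF[3] - NFF[2], NFF[4] - NFF[3])
  setNames(c(nffr, nflr, nffd),
           c(paste0("NFFR", .PAIRS2), paste0("NFLR", .PAIRS2),
             paste0("NFFD", .PAIRS_D)))
}

#' Noise energies in ten equal-width sub-bands
#'
#' Partitions the noise band into 10 equal-width sub-bands and reports
#' `10*log10` of the summed power in each.
#'
#' @param ns a `noise_spectrum`.
#' @return named numeric vector `NE0` to `NE9` (dB).
#' @export
noise_energies <- function(ns) {
  edges <- seq(ns$band_low_hz, ns$band_high_hz, length.out = 11L)
  band <- pmin(findInterval(ns$freqs_hz, edges, rightmost.closed = TRUE), 10L)
  e <- vapply(1:10, function(k) sum(ns$power[band == k]), numeric(1))
  setNames(10 * log10(e + .EPS), paste0("NE", 0:9))
}

#' Noise-band cepstral coefficients
#'
#' 20 triangular filters linearly spaced over the noise band, log filter
#' energies, then an orthonormal DCT; the first 13 coefficients are
#' reported.
#'
#' @param ns a `noise_spectrum`.
#' @return named numeric vector `NCC0` to `NCC12`.
#' @export
noise_cepstral <- function(ns) {
  nfilt <- 20L
  pts <- seq(ns$band_low_hz, ns$band_high_hz, length.out = nfilt + 2L)
  f <- ns$freqs_hz
  M <- matrix(0, nfilt, length(f))
  for (k in seq_len(nfilt)) {
    up <- (f - pts[k]) / (pts[k + 1] - pts[k])
    dn <- (pts[k + 2] - f) / (pts[k + 2] - pts[k + 1])
    M[k, ] <- pmax(0, pmin(up, dn))
  }
  M <- M / rowSums(M)        # unit-weight filters: flat spectrum -> equal E
  E <- log(as.numeric(M %*% ns$power) + .EPS)
  setNames(as.numeric(.dct_matrix(13L, nfilt) %*% E), paste0("NCC", 0:12))
}

#' Noise-band spectral peak
#'
#' Frequency (`NPF`, Hz) and dB amplitude (`NPA`) of the power argmax in the
#' noise band; ties break toward the lower frequency.
#'
#' @param ns a `noise_spectrum`.
#' @return named numeric vector `c(NPA, NPF)`.
#' @export
noise_peak <- function(ns) {
  i <- which.max(ns$power)
  c(NPA = 10 * log10(ns$power[i] + .EPS), NPF = ns$freqs_hz[i])
}

# noise-band block (48 features) for one power-spectrum column
.noise_block <- function(P, f, band_low_hz, band_high_hz) {
  keep <- f >= band_low_hz
  ns <- structure(list(freqs_hz = f[keep], power = P[keep],
                       band_low_hz = band_low_hz, band_high_hz = band_high_hz),
                  class = "noise_spectrum")
  ff <- fricative_formants(ns)
  c(setNames(ff$NFF, paste0("NFF", 1:4)),
    setNames(ff$NFFL, paste0("NFFL", 1:4)),
    formant_ratios_distances(ff$NFF, ff$NFFL)[c(paste0("NFFR", .PAIRS2),
                                                paste0("NFLR", .PAIRS2))],
    noise_cepstral(ns),
    noise_energies(ns),
    formant_ratios_distances(ff$NFF, ff$NFFL)[paste0("NFFD", .PAIRS_D)],
    noise_peak(ns))
}

# noise-band block for all frames at once: filterbanks, band partitions and
# DCT matrices are built once per segment; only the per-frame peak picking
# loops (formant estimation) remain scalar
.noise_block_batch <- function(P, f, band_low_hz, band_high_hz) {
  keep <- f >= band_low_hz
  fn <- f[keep]
  Pn <- P[keep, , drop = FALSE]
  nfr <- ncol(Pn)
  # NE0-9: equal-width sub-bands
  edges <- seq(band_low_hz, band_high_hz, length.out = 11L)
  band <- pmin(findInterval(fn, edges, rightmost.closed = TRUE), 10L)
  NE <- 10 * log10(rowsum(Pn, band) + .EPS)
  # NCC0-12: 20 linear triangular filters + DCT
  nfilt <- 20L
  pts <- seq(band_low_hz, band_high_hz, length.out = nfilt + 2L)
  M <- matrix(0, nfilt, length(fn))
  for (k in seq_len(nfilt)) {
    up <- (fn - pts[k]) / (pts[k + 1] - pts[k])
    dn <- (pts[k + 2] - fn) / (pts[k + 2] - pts[k + 1])
    M[k, ] <- pmax(0, pmin(up, dn))
  }
  M <- M / rowSums(M)        # unit-weight filters, as in noise_cepstral()
  NCC <- .dct_matrix(13L, nfilt) %*% log(M %*% Pn + .EPS)
  # peak
  imax <- max.col(t(Pn), ties.method = "first")
  NPF <- fn[imax]
  NPA <- 10 * log10(Pn[cbind(imax, seq_len(nfr))] + .EPS)
  # formants from the smoothed dB spectrum, per frame
  L <- 10 * log10(Pn + .EPS)
  h <- 4L; n <- nrow(L)
  Lp <- rbind(L[rep(1L, h), , drop = FALSE], L, L[rep(n, h), , drop = FALSE])
  Ls <- stats::filter(Lp, rep(1 / 9, 9), sides = 2)
  Ls <- matrix(Ls[(h + 1L):(h + n), ], nrow = n)
  form <- vapply(seq_len(nfr), function(j) {
    y <- Ls[, j]
    pk <- which(y[-c(1, 2)] <= y[-c(1, n)] & y[-c(n - 1, n)] < y[-c(1, n)]) + 1L
    if (length(pk) == 0L) {
      nff <- rep(NPF[j], 4); nffl <- rep(NPA[j], 4)
    } else {
      prom <- .peak_prominence(y, pk)
      ord <- order(-prom, -y[pk])
      top <- sort(pk[ord[seq_len(min(4L, length(pk)))]])
      while (length(top) < 4L) top <- c(top, top[length(top)])
      nff <- fn[top]; nffl <- y[top]
    }
    rd <- formant_ratios_distances(nff, nffl)
    c(nff, nffl, rd)
  }, numeric(23))
  rbind(form[1:14, , drop = FALSE], form[15:20, , drop = FALSE],
        NCC, NE, form[21:23, , drop = FALSE],
        NPA = NPA, NPF = NPF)
}

#' Extract the 76-feature acoustic battery from a segment
#'
#' Normalizes the segment to the 0-1 range, partitions it into windowed
#' 33-ms frames and computes, per frame, the 4 time-domain, 24 full-band
#' spectral and 48 noise-band spectral features in canonical order.
#'
#' @param segment numeric sample vector, or a list with elements `samples`
#'   and optionally `fs`.
#' @param cfg a [pipeline_config()].
#' @return numeric matrix, one row per frame, 76 named columns.
#' @export
extract_acoustic <- function(segment, cfg = pipeline_config()) {
  samples <- if (is.list(segment)) segment$samples else segment
  fs <- if (is.list(segment) && !is.null(segment$fs)) segment$fs else cfg$fs
  X <- frame_segment(normalize_segment(samples), fs, cfg$frame_ms)
  td <- rbind(ZCRt = .zcr_batch(X), STEt = colMeans(X^2))
  pit <- .pitch_batch(X, fs)
  P <- .power_spectrum_batch(X)
  fb <- .fullband_batch(P, fs)
  f <- .fft_freqs(fs)
  nb <- .noise_block_batch(P, f, cfg$noise_band_low_hz, fs / 2)
  out <- t(rbind(td[1, , drop = FALSE], td[2, , drop = FALSE],
                 Pt = pit$Pt, HRt = pit$HRt, fb, nb))
  colnames(out) <- acoustic_feature_names()
  out
}
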