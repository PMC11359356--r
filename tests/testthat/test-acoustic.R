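fs <- 44100

test_that("segment normalization is a min-max affine map", {
  expect_equal(normalize_segment(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize_segment(c(-1, 1)), c(0, 1))
  expect_error(normalize_segment(c(0.3, 0.3, 0.3)), "constant")
  expect_error(normalize_segment(1), "at least 2")
  # idempotence
  set.seed(4)
  x <- rnorm(500)
  expect_equal(normalize_segment(normalize_segment(x)), normalize_segment(x))
})

test_that("framing yields floor(n/1455) windowed frames", {
  expect_equal(ncol(frame_segment(numeric(14553) + runif(14553), fs)), 10)
  expect_equal(ncol(frame_segment(runif(1455), fs)), 1)
  expect_error(frame_segment(runif(1454), fs), "shorter")
  set.seed(7)
  for (n in as.integer(seq(1455, 14550, length.out = 8))) {
    expect_equal(ncol(frame_segment(runif(n), fs)), floor(n / 1455))
  }
})

test_that("time-domain features match analytic expectations", {
  t <- (0:1454) / fs
  sine1k <- frame_segment(sin(2 * pi * 1000 * (0:2909) / fs), fs)[, 1]
  td <- time_domain_features(sine1k, fs)
  expect_lt(abs(td[["ZCRt"]] - 2 * 1000 / fs) / (2 * 1000 / fs), 0.05)
  expect_equal(time_domain_features(numeric(1455), fs)[["STEt"]], 0)
  sine200 <- frame_segment(sin(2 * pi * 200 * (0:4999) / fs), fs)[, 1]
  td2 <- time_domain_features(sine200, fs)
  expect_lt(abs(td2[["Pt"]] - 200), 5)
  expect_gte(td2[["HRt"]], 0.3)
  # frication-like noise is unvoiced: pitch reported as 0
  set.seed(2)
  tdn <- time_domain_features(frame_segment(rnorm(2910), fs)[, 1], fs)
  expect_true(tdn[["HRt"]] <= 1)
})

test_that("full-band features behave on known spectra", {
  tone <- frame_segment(sin(2 * pi * 5000 * (0:1454) / fs), fs)[, 1]
  fb <- fullband_features(tone, fs = fs)
  expect_lt(abs(fb[["SCenf"]] - 5000) / 5000, 0.01)
  expect_equal(fb[["SFlxf"]], 0)            # first frame has no predecessor
  expect_length(fb, 24)
  set.seed(11)
  noise <- frame_segment(rnorm(1455), fs)[, 1]
  fbn <- fullband_features(noise, fs = fs)
  expect_gt(fbn[["SFlaf"]], 0.4)
  expect_lte(fbn[["SFlaf"]], 1.0)
  # flux against an identical previous frame is 0
  expect_equal(fullband_features(tone, tone, fs)[["SFlxf"]], 0)
})

test_that("noise-band spectrum restricts to [band_low, fs/2]", {
  set.seed(3)
  fr <- frame_segment(rnorm(1455), fs)[, 1]
  ns <- noise_band_spectrum(fr, fs, 2000)
  expect_gte(min(ns$freqs_hz), 2000)
  expect_lte(max(ns$freqs_hz), fs / 2)
  expect_error(noise_band_spectrum(fr, fs, 22050), "empty noise band")
  full <- noise_band_spectrum(fr, fs, 0)
  expect_gte(sum(full$power), sum(ns$power))
})

test_that("fricative formant picking finds constructed peaks", {
  f <- seq(2000, 22050, by = fs / 2048)
  lp <- rep(1e-6, length(f))
  for (pk in c(3000, 5000, 7000, 9000))
    lp <- lp + 10 * exp(-(f - pk)^2 / (2 * 150^2))
  ns <- structure(list(freqs_hz = f, power = lp, band_low_hz = 2000,
                       band_high_hz = fs / 2), class = "noise_spectrum")
  ff <- fricative_formants(ns)
  expect_equal(ff$NFF, c(3000, 5000, 7000, 9000), tolerance = 25 / 3000)
  expect_true(all(diff(ff$NFF) >= 0))
  # single peak: padding repeats the highest-frequency peak
  lp1 <- 1e-6 + 10 * exp(-(f - 6000)^2 / (2 * 150^2))
  ns1 <- structure(list(freqs_hz = f, power = lp1, band_low_hz = 2000,
                        band_high_hz = fs / 2), class = "noise_spectrum")
  ff1 <- fricative_formants(ns1)
  expect_equal(length(unique(ff1$NFF)), 1L)
  # ascending order on random inputs
  set.seed(9)
  for (i in 1:5) {
    fr <- frame_segment(rnorm(1455), fs)[, 1]
    ffr <- fricative_formants(noise_band_spectrum(fr, fs, 2000))
    expect_true(all(diff(ffr$NFF) >= 0))
  }
})

test_that("formant ratios and distances follow the stated conventions", {
  out <- formant_ratios_distances(c(3000, 6000, 9000, 12000),
                                  c(10, 8, 6, 4))
  expect_equal(out[["NFFR12"]], 0.5)
  expect_equal(out[["NFFD23"]], 3000)
  expect_equal(out[["NFLR12"]], 10 / 8)
  eq <- formant_ratios_distances(rep(5000, 4), rep(3, 4))
  expect_true(all(eq[paste0("NFFR", c("12", "13", "14", "23", "24", "34"))] == 1))
  expect_true(all(eq[paste0("NFFD", c("12", "23", "34"))] == 0))
  expect_warning(z <- formant_ratios_distances(c(1, 2, 3, 4), c(1, 1, 1, 0)),
                 "zero denominator")
  expect_true(all(z[paste0("NFLR", c("14", "24", "34"))] == 0))
})

test_that("noise energies partition the band as equal-width dB sums", {
  f <- seq(2000, 22050, by = fs / 2048)
  flat <- structure(list(freqs_hz = f, power = rep(1, length(f)),
                         band_low_hz = 2000, band_high_hz = fs / 2),
                    class = "noise_spectrum")
  ne <- noise_energies(flat)
  expect_lt(diff(range(ne)), 0.1)
  low <- flat; low$power <- ifelse(f < 4005, 1, 0)
  nel <- noise_energies(low)
  expect_true(all(nel[1] > nel[-1]))
  scaled <- flat; scaled$power <- flat$power * 10
  expect_equal(unname(noise_energies(scaled) - ne), rep(10, 10),
               tolerance = 1e-6)
})

test_that("noise cepstrum of a flat spectrum concentrates in NCC0", {
  f <- seq(2000, 22050, by = fs / 2048)
  flat <- structure(list(freqs_hz = f, power = rep(2, length(f)),
                         band_low_hz = 2000, band_high_hz = fs / 2),
                    class = "noise_spectrum")
  ncc <- noise_cepstral(flat)
  expect_length(ncc, 13)
  expect_true(all(abs(ncc[-1]) < 1e-6))
  scaled <- flat; scaled$power <- flat$power * 7
  d <- noise_cepstral(scaled) - ncc
  expect_true(all(abs(d[-1]) < 1e-8))
  expect_gt(d[[1]], 0)
})

test_that("noise peak reports the argmax with low-frequency tie-break", {
  f <- seq(2000, 22050, by = fs / 2048)
  p <- rep(0.1, length(f))
  i3 <- which.min(abs(f - 3000)); i5 <- which.min(abs(f - 5000))
  p[c(i3, i5)] <- 2
  ns <- structure(list(freqs_hz = f, power = p, band_low_hz = 2000,
                       band_high_hz = fs / 2), class = "noise_spectrum")
  np <- noise_peak(ns)
  expect_equal(np[["NPF"]], f[i3])
  expect_gte(np[["NPF"]], 2000)
})

test_that("the acoustic battery emits 76 features in a 4/24/48 split", {
  prof <- default_profiles("sh")$alveolar
  seg <- synth_fricative_segment(prof, 0.5, fs, seed = 21)
  ac <- extract_acoustic(seg$samples)
  expect_equal(ncol(ac), 76)
  expect_equal(nrow(ac), floor(length(seg$samples) / 1455))
  cats <- acoustic_feature_categories()
  expect_equal(as.integer(table(cats)[c("time-domain", "full-band", "noise")]),
               c(4L, 24L, 48L))
  expect_identical(colnames(ac), acoustic_feature_names())
  expect_true(all(ac[, "NFF1"] <= ac[, "NFF2"] &
                    ac[, "NFF2"] <= ac[, "NFF3"] &
                    ac[, "NFF3"] <= ac[, "NFF4"]))
  expect_true(all(ac[, paste0("NFFD", c("12", "23", "34"))] >= 0))
})

test_that("synthesized segments place their spectral peak as configured", {
  prof <- default_profiles("sh")$alveolar
  seg <- synth_fricative_segment(prof, 1.0, fs, seed = 5)
  expect_lt(abs(segment_peak_frequency(seg$samples, fs, 2000) -
                  prof$noise_peak_hz), 200)
  # NPF recovery: median per-segment NPF error under 200 Hz over seeds
  errs <- vapply(1:25, function(i) {
    s <- synth_fricative_segment(prof, 0.5, fs, seed = 100 + i)
    abs(mean(extract_acoustic(s$samples)[, "NPF"]) - prof$noise_peak_hz)
  }, numeric(1))
  expect_lt(median(errs), 200)
})
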