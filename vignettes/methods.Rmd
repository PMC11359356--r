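---
title: "Methods: hybrid audio-visual assessment of sibilant articulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid audio-visual assessment of sibilant articulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Sibilants (/s/, /ʂ/) are produced by directing a turbulent air jet at the
teeth; *where* the constriction is formed — dental, interdental, alveolar,
postalveolar — determines whether the production is normative. `sibav`
treats articulation assessment as a feature-screening problem: extract a
rich hybrid description of each production (acoustic + visual), aggregate
to one vector per speaker, and rank features by how strongly their
distributions separate articulation classes under non-parametric tests.
The package deliberately stops at ranked effect sizes: it is a tool for
finding *candidate markers*, not a classifier.

## Signal processing choices

**Framing.** Audio is min–max normalized to [0, 1] within the annotated
sibilant segment, then cut into non-overlapping 33-ms frames (1455 samples
at 44.1 kHz; 33 ms is not an integer sample count, so the frame length is
the rounded value and a trailing partial frame is dropped). The 33-ms frame
matches the video frame period, so each video frame pairs with exactly one
audio frame — the synchronization contract every loader enforces.

**DC removal.** Min–max normalization to [0, 1] leaves a positive offset of
about 0.5 in every frame. A literal zero-crossing count on such a signal is
degenerate (the signal never changes sign), and the DC bin would dominate
all spectral moments. Each frame is therefore mean-removed before
windowing; for a zero-mean input this is a no-op, and for the normalized
signal it restores the intended definitions of ZCR, centroid, spread and
the rest.

**Spectra.** One-sided power spectra of the 2048-point zero-padded FFT
(bin width ≈ 21.5 Hz). The noise band is [2 kHz, fs/2]: frication noise
formants live above 2–3 kHz, and 2 kHz is the package default
(`pipeline_config(noise_band_low_hz = ...)`), configurable because the
exact cutoff is a modelling choice, not a measured constant.

**Fricative formants.** The noise-band dB spectrum is smoothed with a 9-bin
moving average; local maxima are ranked by topographic prominence and the
four most prominent peaks, sorted by frequency, become NFF1–4 with dB
levels NFFL1–4. Fewer than four peaks: the highest-frequency peak is
repeated (so ratios and distances stay defined); no peaks at all: the
global maximum (NPF/NPA) is substituted and a warning logged. Ratios are
oriented low/high (NFFRij = NFFi/NFFj, i < j) and distances high − low, so
NFFD ≥ 0 always.

**Pitch.** Autocorrelation pitch restricted to 50–500 Hz with a 0.3
voicing threshold. Frication is aperiodic, so `Pt = 0` is the *expected*
output on real segments; the feature exists to catch mis-segmented voiced
material. In synthetic cohorts `Pt` is constant zero and is excluded by
the zero-variance screen — by design.

**Noise cepstrum.** 20 triangular filters linearly spaced over the noise
band, normalized to unit weight so a flat spectrum yields exactly equal
filter energies (and hence NCC1–12 = 0), then an orthonormal DCT-II.

## Visual feature choices

The texture ROI is the union of the lips and mouth-interior labels; teeth
are excluded everywhere (missing teeth are a developmental norm in the
target age group and carry no diagnostic signal), and tongue pixels are
labelled separately. Intensities are quantized to 32 gray levels by
min–max binning *within the ROI*, which makes all matrix-family features
invariant to additive illumination shifts; 32 levels keeps the matrices
dense enough to capture coarse patterns rather than sensor noise.

GLCM: distance 1, four directions, symmetric, normalized, features on the
direction-summed matrix. GLRLM: per-direction matrices averaged. GLSZM:
8-connected zones. NGTDM: 3×3 neighborhoods restricted to in-mask pixels,
with ε-guarded denominators (a perfectly flat ROI has coarseness capped at
10⁶). These are the common radiomics defaults; the brute-force oracles in
the test suite pin the exact definitions.

Shape descriptors use: sub-pixel perimeter from the marching-squares
contour at level 0.5, lightly smoothed (two circular moving-average passes)
to remove the staircase bias that otherwise overestimates smooth
boundaries by ~6 %; circularity 2√(πA)/P as the 2-D reading of
"sphericity" and its reciprocal as "spherical disproportion"; ellipse axes
4√λ from the second central moments; Feret diameter as the maximum
distance between boundary-pixel centers (convex hull first). A rasterized
disk of radius 50 reproduces area, perimeter, diameter and axes within
1–2 %. An **empty mask yields zeros**, not missing values: a frame without
a visible tongue contributes zero area, so a speaker's mean tongue area
jointly encodes how often *and* how large the tongue appears — which is
exactly the quantity that separates interdental from dental /s/.

## Aggregation

Per-frame matrices are end-cropped by 25 % per side
(`floor(fraction · n)` frames, at least one frame always retained) and then
averaged over all retained frames of all of a speaker's segments with
equal weight per frame. Cropping must precede averaging: cropping removes
frames, and frames no longer exist after averaging — the only executable
order of the two stages. Pooling with equal weight per frame (rather than
per word) uses every observed frame equally; the choice is immaterial for
segments of similar length.

## Statistical battery

The pipeline is non-parametric throughout; Shapiro–Wilk and Brown–Forsythe
results are recorded per feature but do not gate testing. Features with
pooled |skewness| > 2 are log-transformed (`log(x − min + ε)`), identically
in all groups. The variance-ratio exclusion — any pairwise group variance
ratio outside [0.1, 10] removes the feature, even if only one pair
offends — is applied after the transform.

Mann–Whitney U uses midranks; the two-sided p is exact (null U
distribution) for tie-free samples with n₁ + n₂ ≤ 20 and a tie-corrected
normal approximation with continuity correction otherwise. The exact path
is verified against full permutation enumeration in the tests. The
rank-biserial correlation is reported as a magnitude |1 − 2U/(n₁n₂)|;
direction is read off the group medians, which the result table carries.
Note one internal tension: with k = 2 the Kruskal–Wallis χ²(1) p equals
the *uncorrected* normal Mann–Whitney p, so the two tests differ by the
continuity correction (≈ the width of one discrete U step). Kruskal–Wallis
uses the tie-corrected H, χ²(k−1) reference, and η² = (H − k + 1)/(n − k)
at full precision. Post hoc: pairwise Mann–Whitney with Bonferroni ×3
capped at 1, pairs labelled 1–2/1–3/2–3 in the canonical class order
(alveolar, dental, postalveolar for /ʂ/). No multiplicity correction is
applied *across* features; the output is a ranked screening table, and
adding FDR control across 250 features would change the question being
asked.

Effect-size bands: r_b low below 0.40, medium to 0.60, high above; η²
negligible below 0.01, low to 0.06, medium to 0.14, high above.

## The synthetic cohort: what it emulates, and what it does not

The simulator reproduces the study design: group sizes 113/31 for /s/ and
106/27/29 for /ʂ/, several segment realizations per speaker, segment
durations 0.30–0.50 s (9–15 frames), dual 64×64 camera views. Class
effects:

* **/s/**: interdental tongues are visible more often (0.75 vs 0.15 per
  frame) and larger (900 vs 300 px) than dental ones; the acoustic noise
  peak also shifts modestly (6000 vs 6500 Hz).
* **/ʂ/**: the noise-band peak sits at 3200 (alveolar), 4800 (dental) and
  2600 Hz (postalveolar); tongue statistics are identical across classes.

No quantitative class-effect magnitudes are available for such cohorts, so the
shipped values are free parameters chosen once: they make the intended
effects strong at the study's group sizes while leaving most features to
be decided by the data. Speakers carry random effects (noise-peak shift
SD 150 Hz; tongue presence jittered on the logit scale, SD 0.5; tongue
area multiplied by a log-normal factor, SD 0.15) so that speakers — the
statistical units — genuinely vary. Audio is white noise shaped by a
*parallel* bank of four second-order resonators (bandwidth 250 Hz), each
branch normalized to unit RMS and scaled by its formant gain: parallel
rather than cascade because only the parallel form gives independent
control of per-formant levels, which is what pins the spectral argmax to
the configured peak. Samples are quantized to the 16-bit grid and gray
images to 8 bits at generation time, so the on-disk corpus round-trips
exactly and regeneration from a seed is byte-identical. Per-speaker
sub-seeds follow a stated counter scheme
(`(seed mod 40000)·20011 + speaker·101 + slot`), so any speaker can be
regenerated in isolation.

What the simulator does **not** emulate: photorealistic appearance,
articulatory dynamics within a segment, segmentation errors and rejected
frames, inter-speaker anatomical variation beyond scale jitter, lighting
gradients, or coarticulation with neighboring sounds. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline *recovers
configured effects of realistic size through the full extraction path*,
not that the specific features found on real recordings would replicate.

### A structural interaction worth knowing about

With the shipped /s/ profiles, speaker-mean tongue area (`Ap_tongue`) has
a between-class variance ratio of roughly
p(1−p)A² ratio = (0.75·0.25·900²)/(0.15·0.85·300²) ≈ 13 from frame
sampling alone (≈ 26 with speaker-level effects) — outside the [0.1, 10]
admissible range, so the variance screen *excludes the simulator's own
flagship feature* from the /s/ analysis. Its pooled skewness (≈ 1.7) stays
below the log-transform threshold of 2, so the transform does not
intervene. `DFeret_tongue`, on the ≈ √area scale, has ratio ≈ 8 and passes
with very small p. This is a real interaction between a strong
zero-inflated effect and a variance-homogeneity exclusion rule — worth
remembering when interpreting screened-out features on real data: a
feature can be excluded *because* its effect is large.

## Numerical choices and degenerate inputs

* ε = 10⁻¹² guards all logs of power; NGTDM denominators use 10⁻⁶ with
  coarseness capped at 10⁶.
* Constant segments cannot be normalized (error); constant ROIs quantize
  to level 1 and produce the degenerate-but-defined texture values
  (ASM = 1, entropy 0, contrast 0, ...).
* All-zero spectra yield zero-valued full-band features with a warning.
* Ties in ranks use midranks with the standard tie corrections in both
  test statistics.
* Zero-variance groups exclude a feature with an explicit reason rather
  than producing NaN statistics.

## Problem sizes used by the test suite

The acceptance-style tests run 20 /s/ and 20 /ʂ/ cohorts at the full group
sizes (144 and 162 speakers) with one segment per speaker and 0.30–0.40 s
durations, and 40 null cohorts of 24 + 24 speakers for type-I calibration;
these sizes give stable pass/fail decisions while keeping the whole suite
runnable on a laptop. The shipped default for `words_per_speaker` is 3,
reflecting that several words containing the target sibilant are pooled
per speaker in a real session; the recovery tests use 1 because speaker
counts, not repetitions, drive the power of the rank tests.

## Known limitations

* The intensity block (IE, Imu, ...) is computed on raw gray values and is
  deliberately not illumination-invariant; between-camera intensity
  calibration is out of scope.
* Exact Mann–Whitney p-values are only used for n₁ + n₂ ≤ 20 without
  ties; cohort-scale analyses always use the approximation.
* The simulator's texture differences across classes arise indirectly
  (through geometry changes), so texture-feature findings on synthetic
  cohorts are weaker and less stable than shape or noise-band findings —
  mirroring, but not calibrated to, the pattern reported in clinical data.
* `eta_squared_kw` can legitimately return small negative values for
  H < k − 1; they are reported as-is and band to "negligible".
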