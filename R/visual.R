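# Visual battery: 63 texture features on the quantized mouth ROI plus
# 8 shape descriptors for each of mouth, lips and tongue (87 per camera).
#
# Mask label convention: 0 background, 1 lips, 2 teeth, 3 tongue,
# 4 mouth interior. The texture ROI is lips + mouth interior; teeth are
# never used; the mouth shape mask is every non-background label.

.GLCM_DIRS <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

.TEX_NAMES <- c(
  "Eh", "Hh", "Varh", "SDh", "Sh", "Kh",
  "IE", "IVar", "ISD", "Imin", "Imax", "Imu", "Imed", "IR", "IMAD",
  "IrMAD", "IRMS", "Ip10", "Ip90", "IIQR", "IS", "IK",
  paste0(c("ASM", "Con", "Ent", "Mean", "Var", "Cor", "Hom", "Dis",
           "AC", "SA"), "GLCM"),
  paste0(c("SRE", "LRE", "GLN", "RLN", "RP", "LGLRE", "HGRE", "SRLGLE",
           "SRHGLE", "LRLGLRE", "LRHGLRE", "GLV", "RV"), "GLRLM"),
  paste0(c("SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE", "HGZE", "SZLGE",
           "SZHGE", "LZLGE", "LZHGE", "GLV", "ZSV"), "GLSZM"),
  paste0(c("Coar", "Con", "Bus", "Com", "TS"), "NGTDM"))

.SHAPE_NAMES <- c("Ap", "P", "S", "SD", "Axmajor", "Axminor", "E", "DFeret")

#' Canonical visual feature names (one camera)
#'
#' 63 texture names followed by 8 shape names for each of mouth, lips and
#' tongue.
#' @return character vector of length 87.
#' @export
visual_feature_names <- function() {
  c(.TEX_NAMES, paste0(.SHAPE_NAMES, "_mouth"),
    paste0(.SHAPE_NAMES, "_lips"), paste0(.SHAPE_NAMES, "_tongue"))
}

#' Visual feature categories
#'
#' @return named character vector mapping the 87 per-camera visual feature
#'   names to `"texture"`, `"mouth"`, `"lips"` or `"tongue"`.
#' @export
visual_feature_categories <- function() {
  nm <- visual_feature_names()
  setNames(c(rep("texture", 63), rep("mouth", 8), rep("lips", 8),
             rep("tongue", 8)), nm)
}

#' Quantize a masked gray-level ROI
#'
#' Uniformly bins the in-mask intensities from their minimum to maximum into
#' `Ng` gray levels. A constant ROI maps to level 1 everywhere.
#'
#' @param gray_image numeric matrix of intensities.
#' @param mask logical matrix, same shape; must contain at least one pixel.
#' @param Ng number of gray levels (default 32).
#' @return list of class `quantized_roi` with integer `levels` (0 outside
#'   the mask), `mask` and `Ng`.
#' @export
quantize_roi <- function(gray_image, mask, Ng = 32L) {
  if (!any(mask)) stop("empty mask: cannot quantize ROI", call. = FALSE)
  vals <- gray_image[mask]
  r <- range(vals)
  lev <- matrix(0L, nrow(gray_image), ncol(gray_image))
  if (r[1] == r[2]) {
    lev[mask] <- 1L
  } else {
    lev[mask] <- pmin(Ng, floor((gray_image[mask] - r[1]) /
                                  (r[2] - r[1]) * Ng) + 1L)
  }
  structure(list(levels = lev, mask = mask, Ng = as.integer(Ng)),
            class = "quantized_roi")
}

#' Global histogram and intensity features
#'
#' Six histogram features from the normalized `Ng`-bin histogram of the
#' quantized ROI (energy, entropy in bits, variance, SD, skewness, excess
#' kurtosis) and sixteen intensity features from the raw in-mask values.
#'
#' @param gray_image numeric intensity matrix.
#' @param mask logical matrix.
#' @param q a [quantize_roi()] result for the same ROI.
#' @return named numeric vector of 22 features.
#' @export
global_features <- function(gray_image, mask, q = quantize_roi(gray_image, mask)) {
  p <- tabulate(q$levels[q$mask], q$Ng) / sum(q$mask)
  i <- seq_len(q$Ng)
  mu <- sum(i * p)
  v <- sum((i - mu)^2 * p)
  hist_feats <- c(
    Eh = sum(p^2),
    Hh = -sum(p[p > 0] * log2(p[p > 0])),
    Varh = v, SDh = sqrt(v),
    Sh = if (v > 0) sum((i - mu)^3 * p) / v^1.5 else 0,
    Kh = if (v > 0) sum((i - mu)^4 * p) / v^2 - 3 else 0)
  x <- gray_image[mask]
  xs <- sort(x)
  n <- length(xs)
  q7 <- function(prob) {                # type-7 quantile on sorted data
    h <- (n - 1) * prob
    lo <- floor(h)
    xs[lo + 1] + (h - lo) * (xs[min(lo + 2, n)] - xs[lo + 1])
  }
  qs <- vapply(c(0.10, 0.25, 0.5, 0.75, 0.90), q7, numeric(1))
  core <- xs[xs >= qs[1] & xs <= qs[5]]
  xv <- if (n > 1) sum((x - mean(x))^2) / (n - 1) else 0
  int_feats <- c(
    IE = sum(x^2), IVar = xv, ISD = sqrt(xv),
    Imin = xs[1], Imax = xs[n], Imu = mean(x), Imed = qs[3],
    IR = xs[n] - xs[1], IMAD = mean(abs(x - mean(x))),
    IrMAD = mean(abs(core - mean(core))),
    IRMS = sqrt(mean(x^2)), Ip10 = qs[1], Ip90 = qs[5],
    IIQR = qs[4] - qs[2],
    IS = sample_skewness(x), IK = sample_kurtosis(x))
  c(hist_feats, int_feats)
}

#' Gray-level co-occurrence matrix features
#'
#' Symmetric, normalized GLCM at distance 1, summed over the four standard
#' directions (0, 45, 90, 135 degrees) restricted to in-mask pixel pairs;
#' ten Haralick-style features.
#'
#' @param q a [quantize_roi()].
#' @param directions list of `c(drow, dcol)` offsets (default the four
#'   standard directions).
#' @return named numeric vector of 10 features.
#' @export
glcm_features <- function(q, directions = .GLCM_DIRS) {
  dr <- vapply(directions, `[`, integer(1), 1L)
  dc <- vapply(directions, `[`, integer(1), 2L)
  C <- .glcm_counts(q$levels, q$mask, q$Ng, dr, dc)
  tot <- sum(C)
  if (tot == 0) stop("no valid pixel pairs for GLCM", call. = FALSE)
  p <- C / tot
  i <- row(p); j <- col(p)
  mui <- sum(i * p)                    # symmetric: row and col means equal
  vi <- sum((i - mui)^2 * p)
  cor <- if (vi > 0) sum((i - mui) * (j - mui) * p) / vi else 0
  c(ASMGLCM = sum(p^2),
    ConGLCM = sum(p * (i - j)^2),
    EntGLCM = -sum(p[p > 0] * log2(p[p > 0])),
    MeanGLCM = mui,
    VarGLCM = vi,
    CorGLCM = cor,
    HomGLCM = sum(p / (1 + (i - j)^2)),
    DisGLCM = sum(p * abs(i - j)),
    ACGLCM = sum(i * j * p),
    SAGLCM = sum((i + j) * p))
}

.GLRLM_FEATS <- function(R, np) {
  nr <- sum(R)
  if (nr == 0) return(setNames(rep(0, 13), paste0(
    c("SRE", "LRE", "GLN", "RLN", "RP", "LGLRE", "HGRE", "SRLGLE", "SRHGLE",
      "LRLGLRE", "LRHGLRE", "GLV", "RV"), "GLRLM")))
  i <- row(R); l <- col(R)
  p <- R / nr
  mui <- sum(i * p); mul <- sum(l * p)
  c(SREGLRLM = sum(R / l^2) / nr,
    LREGLRLM = sum(R * l^2) / nr,
    GLNGLRLM = sum(rowSums(R)^2) / nr,
    RLNGLRLM = sum(colSums(R)^2) / nr,
    RPGLRLM = nr / np,
    LGLREGLRLM = sum(R / i^2) / nr,
    HGREGLRLM = sum(R * i^2) / nr,
    SRLGLEGLRLM = sum(R / (i^2 * l^2)) / nr,
    SRHGLEGLRLM = sum(R * i^2 / l^2) / nr,
    LRLGLREGLRLM = sum(R * l^2 / i^2) / nr,
    LRHGLREGLRLM = sum(R * i^2 * l^2) / nr,
    GLVGLRLM = sum(p * (i - mui)^2),
    RVGLRLM = sum(p * (l - mul)^2))
}

#' Gray-level run-length matrix features
#'
#' Run-length matrices computed per direction and averaged, then 13
#' Galloway-style features.
#'
#' @param q a [quantize_roi()].
#' @param directions list of `c(drow, dcol)` run directions.
#' @return named numeric vector of 13 features.
#' @export
glrlm_features <- function(q, directions = .GLCM_DIRS) {
  mats <- lapply(directions, function(d)
    .glrlm_counts(q$levels, q$mask, q$Ng, d[1], d[2]))
  R <- Reduce(`+`, mats) / length(mats)
  .GLRLM_FEATS(R, sum(q$mask))
}

#' Gray-level size-zone matrix features
#'
#' Zones are 8-connected components of equal gray level; 13 Thibault-style
#' features.
#'
#' @param q a [quantize_roi()].
#' @return named numeric vector of 13 features.
#' @export
glszm_features <- function(q) {
  z <- .glszm_zones(q$levels, q$mask)
  nz <- nrow(z)
  np <- sum(q$mask)
  nm <- paste0(c("SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE", "HGZE", "SZLGE",
                 "SZHGE", "LZLGE", "LZHGE", "GLV", "ZSV"), "GLSZM")
  if (nz == 0) return(setNames(rep(0, 13), nm))
  i <- z[, 1]; s <- z[, 2]
  p <- rep(1 / nz, nz)
  mui <- mean(i); mus <- mean(s)
  setNames(c(
    mean(1 / s^2), mean(s^2),
    sum(tapply(rep(1, nz), i, sum)^2) / nz,
    sum(tapply(rep(1, nz), s, sum)^2) / nz,
    nz / np,
    mean(1 / i^2), mean(i^2),
    mean(1 / (i^2 * s^2)), mean(i^2 / s^2),
    mean(s^2 / i^2), mean(i^2 * s^2),
    mean((i - mui)^2), mean((s - mus)^2)), nm)
}

#' Neighboring gray-tone difference matrix features
#'
#' Amadasun-King NGTDM over the 3x3 neighborhood (in-mask neighbors only):
#' coarseness, contrast, busyness, complexity and texture strength, with
#' epsilon-guarded denominators (coarseness capped at 1e6 for a perfectly
#' flat ROI).
#'
#' @param q a [quantize_roi()].
#' @return named numeric vector of 5 features.
#' @export
ngtdm_features <- function(q) {
  tb <- .ngtdm_table(q$levels, q$mask, q$Ng)
  s <- tb$s; n <- tb$n
  N <- sum(n)
  nm <- paste0(c("Coar", "Con", "Bus", "Com", "TS"), "NGTDM")
  if (N == 0) return(setNames(rep(0, 5), nm))
  p <- n / N
  act <- which(p > 0)
  ngp <- length(act)
  lev <- seq_along(p)
  den <- sum(p * s)
  coar <- if (den > 1e-6) 1 / den else 1e6
  contrast <- if (ngp > 1) {
    sum(outer(p[act], p[act]) * outer(lev[act], lev[act], `-`)^2) /
      (ngp * (ngp - 1)) * sum(s) / N
  } else 0
  bden <- sum(abs(outer(lev[act] * p[act], lev[act] * p[act], `-`)))
  bus <- if (bden > 0) den / bden else 0
  comp <- if (ngp > 1) {
    pi_ <- p[act]; si <- s[act]; li <- lev[act]
    sum(abs(outer(li, li, `-`)) *
          (outer(pi_ * si, pi_ * si, `+`)) / outer(pi_, pi_, `+`)) / N
  } else 0
  ts <- if (sum(s) > 0) {
    sum(outer(p[act], p[act], `+`) * outer(lev[act], lev[act], `-`)^2) / sum(s)
  } else 0
  setNames(c(coar, contrast, bus, comp, ts), nm)
}

# sub-pixel boundary length via marching-squares contour at level 0.5;
# two circular moving-average passes remove the staircase bias of the raw
# rasterized contour (which overestimates smooth boundaries by ~6 %)
.mask_perimeter <- function(mask) {
  pad <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1
  cl <- grDevices::contourLines(seq_len(nrow(pad)), seq_len(ncol(pad)),
                                pad, levels = 0.5)
  smooth_closed <- function(v) {
    n <- length(v)
    if (n < 4L) return(v)
    (v + v[c(2:n, 1L)] + v[c(n, 1:(n - 1L))]) / 3
  }
  total <- 0
  for (cc in cl) {
    x <- cc$x; y <- cc$y
    n <- length(x)
    if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n] }
    for (it in 1:2) { x <- smooth_closed(x); y <- smooth_closed(y) }
    x <- c(x, x[1]); y <- c(y, y[1])
    total <- total + sum(sqrt(diff(x)^2 + diff(y)^2))
  }
  total
}

#' Shape descriptors of a binary mask
#'
#' Pixel surface, boundary perimeter (sub-pixel contour length), circularity
#' `2*sqrt(pi*Ap)/P` (the 2-D reading of sphericity), its reciprocal, the
#' ellipse-equivalent major/minor axis lengths from second central moments,
#' elongation (minor/major) and the maximum Feret diameter between boundary
#' pixel centers. An empty mask yields all zeros, encoding object absence.
#'
#' @param mask logical matrix.
#' @return named numeric vector of 8 features.
#' @export
shape_features <- function(mask) {
  nm <- .SHAPE_NAMES
  ap <- sum(mask)
  if (ap == 0) return(setNames(rep(0, 8), nm))
  # all descriptors are translation invariant: crop to the bounding box so
  # the contour extraction works on the smallest possible grid
  rr <- range(which(rowSums(mask) > 0))
  cr <- range(which(colSums(mask) > 0))
  mask <- mask[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  per <- .mask_perimeter(mask)
  s <- if (per > 0) 2 * sqrt(pi * ap) / per else 0
  idx <- which(mask, arr.ind = TRUE)
  r <- idx[, 1] - mean(idx[, 1]); cl <- idx[, 2] - mean(idx[, 2])
  vrr <- sum(r * r) / ap; vcc <- sum(cl * cl) / ap; vrc <- sum(r * cl) / ap
  # eigenvalues of the 2x2 second-moment matrix, closed form
  tr2 <- (vrr + vcc) / 2
  d <- sqrt(max(0, tr2^2 - (vrr * vcc - vrc^2)))
  ev <- c(max(0, tr2 + d), max(0, tr2 - d))
  axmaj <- 4 * sqrt(ev[1]); axmin <- 4 * sqrt(ev[2])
  # boundary pixels: in-mask with at least one 4-neighbor outside
  pb <- rbind(mask[-1, , drop = FALSE], FALSE) &
    rbind(FALSE, mask[-nrow(mask), , drop = FALSE])
  pbl <- cbind(mask[, -1, drop = FALSE], FALSE) &
    cbind(FALSE, mask[, -ncol(mask), drop = FALSE])
  interior <- mask & pb & pbl
  bnd <- which(mask & !interior, arr.ind = TRUE)
  feret <- if (nrow(bnd) == 1L) 0 else {
    h <- if (nrow(bnd) > 3L) bnd[grDevices::chull(bnd), , drop = FALSE] else bnd
    max(stats::dist(h))
  }
  setNames(c(ap, per, s, if (s > 0) 1 / s else 0, axmaj, axmin,
             if (axmaj > 0) axmin / axmaj else 0, feret), nm)
}

#' Extract the 87-feature visual battery from one mask frame
#'
#' Computes 63 texture features (global histogram/intensity, GLCM, GLRLM,
#' GLSZM, NGTDM) on the mouth ROI -- the union of the lips and
#' mouth-interior labels, with 32-level quantization -- and 8 shape features
#' for each of the mouth (all non-background labels), lips and tongue masks.
#' Teeth pixels are ignored throughout. A frame without a visible tongue
#' yields a zero tongue-shape block.
#'
#' @param frame a mask frame: list with `gray` (numeric intensity matrix)
#'   and `labels` (integer label matrix, values 0-4).
#' @param Ng number of gray levels for texture quantization.
#' @return named numeric vector of 87 features.
#' @export
extract_visual <- function(frame, Ng = 32L) {
  lab <- frame$labels
  if (!all(lab %in% 0:4))
    stop("label mask contains values outside 0..4", call. = FALSE)
  roi <- lab == 1L | lab == 4L
  if (!any(roi))
    stop("missing mouth region (no lips or mouth-interior labels)",
         call. = FALSE)
  q <- quantize_roi(frame$gray, roi, Ng)
  tex <- c(global_features(frame$gray, roi, q),
           glcm_features(q), glrlm_features(q), glszm_features(q),
           ngtdm_features(q))
  out <- c(tex,
           setNames(shape_features(lab > 0L), paste0(.SHAPE_NAMES, "_mouth")),
           setNames(shape_features(lab == 1L), paste0(.SHAPE_NAMES, "_lips")),
           setNames(shape_features(lab == 3L), paste0(.SHAPE_NAMES, "_tongue")))
  names(out) <- visual_feature_names()
  out
}
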