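test_that("ROI quantization bins uniformly into Ng levels", {
  g <- matrix(0:255, 16, 16)
  m <- matrix(TRUE, 16, 16)
  q <- quantize_roi(g, m, 32)
  expect_equal(q$levels[g == 0][1], 1L)
  expect_equal(q$levels[g == 255][1], 32L)
  expect_lte(max(q$levels), 32L)
  qc <- quantize_roi(matrix(7, 4, 4), matrix(TRUE, 4, 4))
  expect_true(all(qc$levels == 1L))
  expect_error(quantize_roi(g, matrix(FALSE, 16, 16)), "empty mask")
})

test_that("global features handle degenerate and known histograms", {
  m <- matrix(TRUE, 8, 8)
  gc <- matrix(42, 8, 8)
  gf <- global_features(gc, m)
  expect_equal(gf[["Hh"]], 0)
  expect_equal(gf[["Eh"]], 1)
  expect_equal(gf[["ISD"]], 0)
  expect_equal(gf[["Imu"]], 42)
  # half 0, half 255: histogram entropy of 1 bit
  g2 <- matrix(rep(c(0, 255), 32), 8, 8)
  gf2 <- global_features(g2, m)
  expect_equal(gf2[["Hh"]], 1)
  # IIQR is p75 - p25, not p90 - p10
  gu <- matrix(1:100, 10, 10)
  gfu <- global_features(gu, matrix(TRUE, 10, 10))
  expect_equal(gfu[["IIQR"]], unname(diff(quantile(1:100, c(.25, .75)))))
  expect_equal(gfu[["Ip10"]], unname(quantile(1:100, .10)))
})

test_that("GLCM features match hand-enumerated cases", {
  qc <- quantize_roi(matrix(5, 6, 6), matrix(TRUE, 6, 6))
  g <- glcm_features(qc)
  expect_equal(g[["ConGLCM"]], 0)
  expect_equal(g[["DisGLCM"]], 0)
  expect_equal(g[["HomGLCM"]], 1)
  expect_equal(g[["ASMGLCM"]], 1)
  expect_equal(g[["EntGLCM"]], 0)
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2 * 255)
  qcb <- quantize_roi(cb, matrix(TRUE, 8, 8), 2)
  g0 <- glcm_features(qcb, directions = list(c(0L, 1L)))
  expect_equal(g0[["ConGLCM"]], 1)       # every horizontal pair differs by 1
})

test_that("GLRLM features match single-run closed forms", {
  q1 <- quantize_roi(matrix(3, 1, 10), matrix(TRUE, 1, 10))
  g <- glrlm_features(q1, directions = list(c(0L, 1L)))
  expect_equal(g[["LREGLRLM"]], 100)
  expect_equal(g[["RPGLRLM"]], 0.1)
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2 * 255)
  qcb <- quantize_roi(cb, matrix(TRUE, 8, 8), 2)
  gc <- glrlm_features(qcb, directions = list(c(0L, 1L)))
  expect_equal(gc[["SREGLRLM"]], 1)      # all runs have length 1
  expect_equal(gc[["RPGLRLM"]], 1)
})

test_that("GLSZM zones follow 8-connectivity", {
  qc <- quantize_roi(matrix(1, 5, 7), matrix(TRUE, 5, 7))
  g <- glszm_features(qc)
  expect_equal(g[["ZPGLSZM"]], 1 / 35)
  # checkerboard: diagonals share a level, so exactly 2 zones
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2 * 255)
  qcb <- quantize_roi(cb, matrix(TRUE, 8, 8), 2)
  gz <- glszm_features(qcb)
  expect_equal(gz[["ZPGLSZM"]], 2 / 64)
})

test_that("NGTDM features respond to local contrast", {
  qc <- quantize_roi(matrix(9, 6, 6), matrix(TRUE, 6, 6))
  nt <- ngtdm_features(qc)
  expect_equal(nt[["CoarNGTDM"]], 1e6)    # flat ROI: capped coarseness
  expect_equal(nt[["ConNGTDM"]], 0)
  g <- matrix(10, 7, 7); g[4, 4] <- 250
  nb <- ngtdm_features(quantize_roi(g, matrix(TRUE, 7, 7)))
  expect_gt(nb[["ConNGTDM"]], 0)
})

test_that("texture families agree with brute-force oracles", {
  dirs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  for (seed in 1:20) {
    q <- random_qroi(seed)
    expect_equal(unname(glcm_features(q)), oracle_glcm(q, dirs),
                 tolerance = 1e-10, label = paste("glcm seed", seed))
    expect_equal(unname(glrlm_features(q)), oracle_glrlm_features(q, dirs),
                 tolerance = 1e-10, label = paste("glrlm seed", seed))
    expect_equal(unname(glszm_features(q)), oracle_glszm_features(q),
                 tolerance = 1e-10, label = paste("glszm seed", seed))
    expect_equal(unname(ngtdm_features(q)), oracle_ngtdm_features(q),
                 tolerance = 1e-10, label = paste("ngtdm seed", seed))
  }
})

test_that("texture features are invariant to a constant intensity shift", {
  set.seed(31)
  g <- matrix(runif(144, 0, 200), 12, 12)
  m <- matrix(runif(144) < 0.85, 12, 12)
  q1 <- quantize_roi(g, m)
  q2 <- quantize_roi(g + 55, m)
  expect_equal(glcm_features(q1), glcm_features(q2))
  expect_equal(glrlm_features(q1), glrlm_features(q2))
  expect_equal(glszm_features(q1), glszm_features(q2))
  expect_equal(ngtdm_features(q1), ngtdm_features(q2))
})

test_that("shape features match closed forms on canonical masks", {
  sz <- 111; ctr <- 56
  disk <- outer(1:sz, 1:sz, function(i, j) (i - ctr)^2 + (j - ctr)^2 <= 50^2)
  sf <- shape_features(disk)
  expect_lt(abs(sf[["Ap"]] - pi * 2500) / (pi * 2500), 0.01)
  expect_lt(abs(sf[["DFeret"]] - 100), 2)
  expect_gt(sf[["S"]], 0.95); expect_lt(sf[["S"]], 1.05)
  expect_equal(sf[["SD"]], 1 / sf[["S"]])
  expect_equal(unname(shape_features(matrix(FALSE, 5, 5))), rep(0, 8))
  line <- matrix(FALSE, 5, 104); line[3, 3:102] <- TRUE
  sl <- shape_features(line)
  expect_lte(sl[["E"]], 0.15)
  expect_lt(abs(sl[["DFeret"]] - 99), 2)
})

test_that("shape features are translation invariant and scale ~linearly", {
  m1 <- matrix(FALSE, 40, 40); m1[5:20, 8:25] <- TRUE
  m2 <- matrix(FALSE, 40, 40); m2[15:30, 12:29] <- TRUE
  expect_equal(shape_features(m1), shape_features(m2))
  # 2x nearest-neighbour upsampling doubles lengths within 5 %
  big <- m1[rep(1:40, each = 2), rep(1:40, each = 2)]
  s1 <- shape_features(m1); s2 <- shape_features(big)
  for (f in c("Axmajor", "Axminor", "DFeret"))
    expect_lt(abs(s2[[f]] / s1[[f]] - 2), 0.1)
})

test_that("the visual battery emits 87 features with organ shape blocks", {
  prof <- default_profiles("s")$interdental
  fr <- synth_mask_sequence(prof, 2, seed = 12)[[1]]
  v <- extract_visual(fr$left)
  expect_length(v, 87)
  expect_identical(names(v), visual_feature_names())
  both <- c(extract_visual(fr$left), extract_visual(fr$right))
  expect_length(both, 174)
  # no tongue: tongue shape block is all zeros, the rest finite
  p0 <- prof; p0$tongue_presence_prob <- 0
  fr0 <- synth_mask_sequence(p0, 1, seed = 3)[[1]]$left
  v0 <- extract_visual(fr0)
  expect_true(all(v0[paste0(c("Ap", "P", "S", "SD", "Axmajor", "Axminor",
                              "E", "DFeret"), "_tongue")] == 0))
  expect_true(all(is.finite(v0)))
  bad <- fr0; bad$labels[1, 1] <- 7L
  expect_error(extract_visual(bad), "outside 0..4")
  none <- fr0; none$labels[] <- 0L
  expect_error(extract_visual(none), "missing mouth region")
  cnts <- table(visual_feature_categories())
  expect_equal(as.integer(cnts[c("texture", "mouth", "lips", "tongue")]),
               c(63L, 8L, 8L, 8L))
})

test_that("larger synthetic tongues increase aggregated tongue area", {
  areas <- seq(200, 1100, length.out = 10)
  mean_ap <- vapply(seq_along(areas), function(i) {
    pr <- class_profile(6000, c(6000, 8000, 10500, 13000), c(0, -8, -12, -16),
                        tongue_presence_prob = 1,
                        tongue_area_mean_px = areas[i], tongue_area_sd_px = 1)
    fr <- synth_mask_sequence(pr, 6, seed = 77)
    mean(vapply(fr, function(f) sum(f$left$labels == 3L), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ap) > 0))
})
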