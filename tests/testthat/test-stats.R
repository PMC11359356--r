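test_that("the normality screen flags skewed data and not normal data", {
  expect_error(normality_screen(c(1, 2)), "3 <= n")
  set.seed(14)
  rej_exp <- mean(vapply(1:100, function(i)
    normality_screen(rexp(200)) < 0.05, logical(1)))
  expect_gte(rej_exp, 0.95)
  rej_norm <- mean(vapply(1:1000, function(i)
    normality_screen(rnorm(200)) < 0.05, logical(1)))
  expect_lt(abs(rej_norm - 0.05), 0.03)
})

test_that("the log transform triggers on high skewness and reduces it", {
  set.seed(2)
  sym <- rnorm(200)
  out <- maybe_log_transform(sym, 2)
  expect_false(out$transformed)
  expect_identical(out$values, sym)
  ln <- exp(rnorm(300, 0, 1.5))
  out2 <- maybe_log_transform(ln, 2)
  expect_true(out2$transformed)
  expect_lt(abs(sibav:::sample_skewness(out2$values)),
            abs(sibav:::sample_skewness(ln)))
  expect_false(maybe_log_transform(ln, Inf)$transformed)
})

test_that("Brown-Forsythe matches the median-centered Levene test", {
  g <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  bf <- brown_forsythe(g)
  expect_equal(bf$statistic, 0)
  expect_equal(bf$p, 1)
  expect_error(brown_forsythe(list(1, 2)), "2 observations")
  set.seed(6)
  # power against a 25x variance ratio
  rej <- mean(vapply(1:100, function(i) {
    brown_forsythe(list(rnorm(50, 0, 1), rnorm(50, 0, 5)))$p < 0.05
  }, logical(1)))
  expect_gte(rej, 0.90)
  # agreement with car::leveneTest (independent implementation)
  skip_if_not_installed("car")
  x <- c(rnorm(20), rnorm(25, 0, 2), rnorm(15, 0, 0.5))
  f <- factor(rep(1:3, c(20, 25, 15)))
  lv <- car::leveneTest(x, f, center = median)
  ours <- brown_forsythe(split(x, f))
  expect_equal(ours$statistic, lv[1, "F value"], tolerance = 1e-10)
  expect_equal(ours$p, lv[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("the variance-ratio screen applies the pairwise 10x rule", {
  set.seed(8)
  mk <- function(sds) lapply(sds, function(s) rnorm(60, 0, s))
  scale_to_var <- function(g, v) g / sd(g) * sqrt(v)
  g <- Map(scale_to_var, mk(c(1, 1)), c(1, 12))
  expect_false(variance_ratio_screen(g)$ok)
  g2 <- Map(scale_to_var, mk(c(1, 1, 1)), c(1, 1, 9.9))
  expect_true(variance_ratio_screen(g2)$ok)
  g3 <- Map(scale_to_var, mk(c(1, 1, 1)), c(1, 5, 0.09))
  s3 <- variance_ratio_screen(g3)
  expect_false(s3$ok)                     # the (5, 0.09) pair breaks the rule
  expect_gt(s3$worst_ratio, 10)
  z <- list(rep(1, 10), rnorm(10))
  expect_match(variance_ratio_screen(z)$reason, "zero variance")
})

test_that("Mann-Whitney U, p and rank-biserial match reference results", {
  out <- mann_whitney_rb(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$U, 0)
  expect_equal(out$rb, 1)
  same <- mann_whitney_rb(c(5, 7, 9, 11), c(5, 7, 9, 11))
  expect_equal(same$rb, 0)
  expect_error(mann_whitney_rb(numeric(0), 1), "empty")
  set.seed(9)
  # exact path equals base wilcox.test exact p on tie-free small samples
  for (i in 1:10) {
    g1 <- rnorm(6); g2 <- rnorm(7)
    ours <- mann_whitney_rb(g1, g2)
    ref <- wilcox.test(g1, g2, exact = TRUE)
    expect_true(ours$exact)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
  # approximate path equals the tie-corrected continuity-corrected normal
  for (i in 1:10) {
    g1 <- rnorm(25); g2 <- rnorm(30)
    ours <- mann_whitney_rb(g1, g2)
    ref <- wilcox.test(g1, g2, exact = FALSE, correct = TRUE)
    expect_false(ours$exact)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact Mann-Whitney p equals full enumeration on small samples", {
  set.seed(13)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    g1 <- rnorm(n1); g2 <- rnorm(n2)
    ours <- mann_whitney_rb(g1, g2)
    oracle <- oracle_mw_enumeration(g1, g2)
    expect_equal(ours$U, oracle$U, label = paste("U seed", i))
    expect_equal(ours$p, oracle$p, tolerance = 1e-12,
                 label = paste("p seed", i))
  }
})

test_that("Kruskal-Wallis H, p and eta-squared are consistent", {
  expect_equal(round(eta_squared_kw(35.575, 3, 162), 3), 0.211)
  g <- list(rep(2, 5), rep(2, 5), rep(2, 5))
  expect_equal(kruskal_eta2(g)$H, 0)
  set.seed(21)
  x <- list(rnorm(15), rnorm(12, 0.5), rnorm(18, 1))
  ours <- kruskal_eta2(x)
  ref <- kruskal.test(x)
  expect_equal(ours$H, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  # k = 2 reduces to the uncorrected normal Mann-Whitney p
  g1 <- rnorm(30); g2 <- rnorm(25, 0.3)
  kw <- kruskal_eta2(list(g1, g2))
  mw_ref <- wilcox.test(g1, g2, exact = FALSE, correct = FALSE)
  expect_equal(kw$p, mw_ref$p.value, tolerance = 1e-9)
})

test_that("Bonferroni post hoc multiplies pairwise p by 3, capped at 1", {
  set.seed(3)
  g <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20, 3))
  ph <- bonferroni_posthoc(g)
  raw <- vapply(list(c(1, 2), c(1, 3), c(2, 3)), function(ij)
    mann_whitney_rb(g[[ij[1]]], g[[ij[2]]])$p, numeric(1))
  expect_equal(unname(ph), pmin(1, 3 * raw))
  same <- list(rep(1:5, 2), rep(1:5, 2), rep(1:5, 2))
  expect_true(all(bonferroni_posthoc(same) == 1))
  expect_error(bonferroni_posthoc(list(1:3, 4:6)), "exactly 3")
})

test_that("effect sizes are banded by the stated thresholds", {
  expect_equal(classify_effect(0.439, "MW"), "medium")
  expect_equal(classify_effect(0.39, "MW"), "low")
  expect_equal(classify_effect(0.65, "MW"), "high")
  expect_equal(classify_effect(0.211, "KW"), "high")
  expect_equal(classify_effect(0.005, "KW"), "negligible")
  expect_equal(classify_effect(0.03, "KW"), "low")
  expect_equal(classify_effect(0.10, "KW"), "medium")
})

test_that("run_study screens, tests, filters and ranks features", {
  set.seed(44)
  n1 <- 40; n2 <- 40
  tb <- data.frame(
    speaker_id = sprintf("S%02d", 1:(n1 + n2)),
    sibilant = "s",
    class = rep(c("dental", "interdental"), c(n1, n2)),
    stringsAsFactors = FALSE)
  tb$NPF <- c(rnorm(n1, 6500, 150), rnorm(n2, 6000, 150))   # strong effect
  tb$ZCRt <- rnorm(n1 + n2)                                 # null
  tb$STEt <- c(rnorm(n1, 0, 1), rnorm(n2, 0, 6))            # ratio 36: excluded
  tb$Pt <- 0                                                # zero variance
  st <- run_study(tb, pipeline_config())
  expect_s3_class(st, "sib_study")
  expect_true(all(st$results$p < 0.05))
  expect_true(all(diff(st$results$effect) <= 0))
  expect_true("NPF" %in% st$results$feature)
  expect_true(all(c("STEt", "Pt") %in% st$excluded$feature))
  expect_false("STEt" %in% st$all$feature)
  # alpha = 1 reports every tested feature
  st_all <- run_study(tb, pipeline_config(alpha = 0.999999))
  expect_equal(sort(st_all$results$feature), sort(st_all$all$feature))
  expect_error(run_study(tb[tb$class == "dental", ]), "2 articulation")
  # ranked export carries a row-number column
  csv <- withr::local_tempfile(fileext = ".csv")
  write_results(st, csv)
  back <- read.csv(csv)
  expect_equal(back$No., seq_len(nrow(st$results)))
  expect_output(print(st), "Articulation study")
})
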