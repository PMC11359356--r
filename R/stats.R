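# Non-parametric statistical battery: distribution screening, optional log
# transform, variance-ratio exclusion, Mann-Whitney U with rank-biserial
# correlation (two groups) or Kruskal-Wallis with eta-squared and
# Bonferroni post hoc tests (three groups), and effect-size-ranked output.

#' Shapiro-Wilk normality screen
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return the Shapiro-Wilk p-value (recorded descriptively; the pipeline
#'   is non-parametric regardless of the outcome).
#' @export
normality_screen <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  if (length(unique(values)) == 1L) return(0)
  shapiro.test(values)$p.value
}

#' Log-transform a feature when its skewness is high
#'
#' If `|sample skewness| > skew_threshold`, applies
#' `log(x - min(x) + eps)` (the shift guarantees positivity); otherwise
#' returns the input unchanged. Applied to the pooled values of a feature
#' so every group receives the identical transform.
#'
#' @param values numeric vector (pooled over groups).
#' @param skew_threshold absolute skewness threshold (default 2).
#' @return list with `values` and logical `transformed`.
#' @export
maybe_log_transform <- function(values, skew_threshold = 2) {
  sk <- sample_skewness(values)
  if (is.finite(sk) && abs(sk) > skew_threshold) {
    eps <- 1e-6 * max(1, diff(range(values, finite = TRUE)))
    list(values = log(values - min(values) + eps), transformed = TRUE)
  } else {
    list(values = values, transformed = FALSE)
  }
}

#' Brown-Forsythe test of variance homogeneity
#'
#' Median-centered Levene test: a one-way F test on the absolute deviations
#' from the group medians.
#'
#' @param groups list of numeric vectors (each of length >= 2).
#' @return list with `statistic` (F), `p`, `df1`, `df2`.
#' @export
brown_forsythe <- function(groups) {
  k <- length(groups)
  if (k < 2 || any(lengths(groups) < 2))
    stop("Brown-Forsythe requires >= 2 groups with >= 2 observations each",
         call. = FALSE)
  z <- lapply(groups, function(g) abs(g - median(g)))
  n <- lengths(z)
  N <- sum(n)
  zbar <- mean(unlist(z))
  zg <- vapply(z, mean, numeric(1))
  ssb <- sum(n * (zg - zbar)^2)
  ssw <- sum(vapply(z, function(x) sum((x - mean(x))^2), numeric(1)))
  if (ssw == 0) {
    stat <- if (ssb == 0) 0 else Inf
  } else {
    stat <- (ssb / (k - 1)) / (ssw / (N - k))
  }
  list(statistic = stat, p = pf(stat, k - 1, N - k, lower.tail = FALSE),
       df1 = k - 1, df2 = N - k)
}

#' Variance-ratio exclusion screen
#'
#' Computes the variance ratio for every ordered pair of groups; the
#' feature is kept only when every ratio lies within `bounds`
#' (default 0.1 to 10). In multigroup analyses a single offending pair
#' excludes the feature. A zero-variance group excludes the feature
#' outright.
#'
#' @param groups list of numeric vectors.
#' @param bounds allowed ratio interval.
#' @return list with `ok`, `worst_ratio` and `reason` (`NA` when kept).
#' @export
variance_ratio_screen <- function(groups, bounds = c(0.1, 10)) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  v <- vapply(groups, var, numeric(1))
  if (any(!is.finite(v)) || any(v == 0))
    return(list(ok = FALSE, worst_ratio = Inf, reason = "zero variance"))
  ratios <- outer(v, v, `/`)
  worst <- max(ratios)
  ok <- all(ratios >= bounds[1] & ratios <= bounds[2])
  list(ok = ok, worst_ratio = worst,
       reason = if (ok) NA_character_ else
         sprintf("variance ratio %.3g outside [%g, %g]", worst,
                 bounds[1], bounds[2]))
}

# midranks of pooled data plus the tie-correction ingredients
.pooled_ranks <- function(x) {
  r <- rank(x)
  t <- table(x)
  list(ranks = r, tie_term = sum(t^3 - t), has_ties = any(t > 1))
}

#' Mann-Whitney U test with rank-biserial effect size
#'
#' U from midranks with tie correction. The two-sided p-value is exact
#' (from the null U distribution) for tie-free samples with
#' `n1 + n2 <= 20`, and a tie-corrected normal approximation with
#' continuity correction otherwise. The rank-biserial correlation is
#' reported as a magnitude, `rb = |1 - 2U/(n1 n2)|`; direction is read off
#' the group medians.
#'
#' @param g1,g2 numeric vectors.
#' @return list with `U` (first-sample U), `p`, `rb`, `exact`.
#' @export
mann_whitney_rb <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 1 || n2 < 1) stop("empty group", call. = FALSE)
  pr <- .pooled_ranks(c(g1, g2))
  u1 <- sum(pr$ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  mu <- n1 * n2 / 2
  exact <- !pr$has_ties && (n1 + n2) <= 20
  if (exact) {
    p <- min(1, 2 * stats::pwilcox(min(u1, u2), n1, n2))
  } else {
    n <- n1 + n2
    sig2 <- n1 * n2 / 12 * ((n + 1) - pr$tie_term / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  list(U = u1, p = p, rb = abs(1 - 2 * u1 / (n1 * n2)), exact = exact)
}

#' Kruskal-Wallis test with eta-squared effect size
#'
#' Tie-corrected H with a chi-squared (k-1) reference distribution;
#' `eta^2 = (H - k + 1)/(n - k)` (reported at full precision, possibly
#' <= 0 for tiny H).
#'
#' @param groups list of k >= 2 numeric vectors.
#' @return list with `H`, `p`, `eta2`, `df`.
#' @export
kruskal_eta2 <- function(groups) {
  k <- length(groups)
  if (k < 2 || any(lengths(groups) < 1))
    stop("need >= 2 non-empty groups", call. = FALSE)
  n <- lengths(groups)
  N <- sum(n)
  pr <- .pooled_ranks(unlist(groups))
  idx <- rep(seq_len(k), n)
  rs <- tapply(pr$ranks, idx, sum)
  H <- 12 / (N * (N + 1)) * sum(rs^2 / n) - 3 * (N + 1)
  corr <- 1 - pr$tie_term / (N^3 - N)
  if (corr > 0) H <- H / corr
  list(H = H, p = pchisq(H, k - 1, lower.tail = FALSE),
       eta2 = eta_squared_kw(H, k, N), df = k - 1)
}

#' Eta-squared from a Kruskal-Wallis H statistic
#'
#' `eta^2 = (H - k + 1)/(n - k)`.
#'
#' @param H Kruskal-Wallis statistic.
#' @param k number of groups.
#' @param n total number of observations.
#' @return eta-squared.
#' @export
#' @examples
#' eta_squared_kw(35.575, 3, 162)
eta_squared_kw <- function(H, k, n) (H - k + 1) / (n - k)

#' Bonferroni-adjusted pairwise Mann-Whitney post hoc tests
#'
#' For three groups, runs the pairwise Mann-Whitney tests 1-2, 1-3, 2-3
#' (in the canonical class order) and Bonferroni-adjusts the p-values
#' (multiplied by 3, capped at 1).
#'
#' @param groups named list of three numeric vectors.
#' @return named numeric vector of adjusted p-values (`p_12`, `p_13`,
#'   `p_23`).
#' @export
bonferroni_posthoc <- function(groups) {
  if (length(groups) != 3)
    stop("post hoc analysis expects exactly 3 groups", call. = FALSE)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  raw <- vapply(pairs, function(ij)
    mann_whitney_rb(groups[[ij[1]]], groups[[ij[2]]])$p, numeric(1))
  setNames(stats::p.adjust(raw, method = "bonferroni"),
           c("p_12", "p_13", "p_23"))
}

#' Effect-size band
#'
#' Rank-biserial correlation (`test = "MW"`): low below 0.40, medium
#' 0.40-0.59, high 0.60 and above (absolute value). Eta-squared
#' (`test = "KW"`): negligible below 0.01, low 0.01-0.05, medium
#' 0.06-0.13, high above 0.14.
#'
#' @param effect effect-size value.
#' @param test `"MW"` (rank-biserial) or `"KW"` (eta-squared).
#' @return one of `"negligible"`, `"low"`, `"medium"`, `"high"`.
#' @export
classify_effect <- function(effect, test = c("MW", "KW")) {
  test <- match.arg(test)
  e <- abs(effect)
  if (test == "MW") {
    if (e >= 0.60) "high" else if (e >= 0.40) "medium" else "low"
  } else {
    if (e >= 0.14) "high" else if (e >= 0.06) "medium"
    else if (e >= 0.01) "low" else "negligible"
  }
}

#' Run the full statistical study on a speaker table
#'
#' For each feature: skewness screen with optional log transform,
#' variance-ratio exclusion, Shapiro-Wilk and Brown-Forsythe screens
#' (recorded, not gating), then the Mann-Whitney U test with rank-biserial
#' correlation (two classes) or the Kruskal-Wallis test with eta-squared
#' and Bonferroni post hoc pairwise tests (three classes). The result table
#' keeps only features with `p < alpha` and is sorted by effect size,
#' descending.
#'
#' @param speaker_table data frame from [synth_speaker_table()] or
#'   [extract_corpus_features()]: `speaker_id`, `sibilant`, `class` plus
#'   feature columns.
#' @param cfg a [pipeline_config()] (alpha, variance-ratio bounds, skewness
#'   threshold).
#' @return object of class `sib_study`: list with `results` (the filtered,
#'   ranked table), `all` (every tested feature), `excluded`, `screens`
#'   (per-feature Shapiro-Wilk and Brown-Forsythe p-values), `alpha`,
#'   `classes`, `n`.
#' @export
run_study <- function(speaker_table, cfg = pipeline_config()) {
  sib <- unique(speaker_table$sibilant)
  if (length(sib) != 1L)
    stop("speaker table mixes sibilants; analyze one at a time",
         call. = FALSE)
  classes <- intersect(allowed_classes(sib), unique(speaker_table$class))
  k <- length(classes)
  if (k < 2) stop("need at least 2 articulation classes", call. = FALSE)
  cls <- factor(speaker_table$class, levels = classes)
  if (any(table(cls) < 3))
    stop("each class needs at least 3 speakers", call. = FALSE)
  catalog <- feature_catalog()
  feats <- intersect(catalog$feature, names(speaker_table))
  if (length(feats) == 0) stop("no feature columns found", call. = FALSE)
  test_used <- if (k == 2) "MW" else "KW"
  rows <- list(); excl <- list(); scr <- list()
  for (f in feats) {
    vals <- speaker_table[[f]]
    if (!all(is.finite(vals))) {
      excl[[f]] <- data.frame(feature = f, reason = "non-finite values",
                              worst_ratio = NA_real_)
      next
    }
    tr <- maybe_log_transform(vals, cfg$skew_threshold)
    groups <- split(tr$values, cls)
    vs <- variance_ratio_screen(groups, cfg$variance_ratio_bounds)
    if (!vs$ok) {
      excl[[f]] <- data.frame(feature = f, reason = vs$reason,
                              worst_ratio = vs$worst_ratio)
      next
    }
    sw <- vapply(groups, function(g)
      if (length(unique(g)) > 1L) normality_screen(g) else 0, numeric(1))
    bf <- brown_forsythe(groups)
    scr[[f]] <- data.frame(feature = f, bf_p = bf$p,
                           t(setNames(sw, paste0("sw_p_", classes))))
    meds <- vapply(groups, median, numeric(1))
    meta <- catalog[catalog$feature == f, ]
    if (k == 2) {
      tst <- mann_whitney_rb(groups[[1]], groups[[2]])
      row <- data.frame(feature = f, data = meta$data,
                        category = meta$category, camera = meta$camera,
                        test = "MW", statistic = tst$U, p = tst$p,
                        effect = tst$rb,
                        effect_band = classify_effect(tst$rb, "MW"),
                        p_12 = NA_real_, p_13 = NA_real_, p_23 = NA_real_,
                        transformed = tr$transformed)
    } else {
      tst <- kruskal_eta2(groups)
      ph <- bonferroni_posthoc(groups)
      row <- data.frame(feature = f, data = meta$data,
                        category = meta$category, camera = meta$camera,
                        test = "KW", statistic = tst$H, p = tst$p,
                        effect = tst$eta2,
                        effect_band = classify_effect(tst$eta2, "KW"),
                        p_12 = ph[["p_12"]], p_13 = ph[["p_13"]],
                        p_23 = ph[["p_23"]],
                        transformed = tr$transformed)
    }
    row <- cbind(row, t(setNames(meds, paste0("median_", classes))))
    rows[[f]] <- row
  }
  all_res <- do.call(rbind, rows)
  rownames(all_res) <- NULL
  results <- all_res[all_res$p < cfg$alpha, , drop = FALSE]
  results <- results[order(-results$effect), , drop = FALSE]
  rownames(results) <- NULL
  structure(list(results = results, all = all_res,
                 excluded = if (length(excl)) do.call(rbind, excl)
                            else data.frame(feature = character(0),
                                            reason = character(0),
                                            worst_ratio = numeric(0)),
                 screens = if (length(scr)) do.call(rbind, scr) else NULL,
                 alpha = cfg$alpha, test = test_used,
                 classes = classes, n = as.integer(table(cls))),
            class = "sib_study")
}

#' @export
print.sib_study <- function(x, ...) {
  cat(sprintf("Articulation study (%s): %d classes (%s), n = %s\n",
              x$test, length(x$classes), paste(x$classes, collapse = ", "),
              paste(x$n, collapse = "/")))
  cat(sprintf("%d features tested, %d excluded by screening, %d significant at alpha = %g\n",
              nrow(x$all) %||% 0L, nrow(x$excluded), nrow(x$results),
              x$alpha))
  if (nrow(x$results)) {
    cat("Top features by effect size:\n")
    print(utils::head(x$results[, c("feature", "data", "category", "camera",
                                    "p", "statistic", "effect",
                                    "effect_band")], 10), digits = 3)
  }
  invisible(x)
}

#' Write the ranked result table to CSV
#'
#' @param study a `sib_study`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(study, path) {
  res <- study$results
  res <- cbind(No. = seq_len(nrow(res)), res)
  write.csv(res, path, row.names = FALSE)
  invisible(path)
}

#' Box plot of a feature across articulation classes
#'
#' @param speaker_table per-speaker feature table.
#' @param feature feature column name.
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the boxplot statistics.
#' @export
plot_feature <- function(speaker_table, feature, ...) {
  invisible(boxplot(speaker_table[[feature]] ~ speaker_table$class,
                    xlab = "articulation class", ylab = feature, ...))
}
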