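# Thin contracts over the standard statistical routines used throughout the
# analyses: signed-rank for paired data, rank-sum for unpaired, one-way
# ANOVA with Tukey-Kramer (or rank-based) post-hocs, Pearson correlation.

test_result <- function(statistic, p, n, method, alternative = "two.sided") {
  structure(list(statistic = unname(statistic), p = p, n = n,
                 method = method, alternative = alternative),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g (n = %s)%s\n",
              x$method, x$statistic, x$p, paste(x$n, collapse = "/"),
              significance_band(x$p)))
  invisible(x)
}

# Significance bands as conventionally reported.
significance_band <- function(p) {
  if (p < 0.001) " ***" else if (p < 0.01) " **" else if (p < 0.05) " *" else ""
}

# Exact two-sided signed-rank p for differences d (ties handled by
# midranks): dynamic programming over the 2^n equiprobable sign patterns.
# Midranks are multiples of 1/2, so doubling gives integer support.
exact_signrank_p <- function(d) {
  r2 <- as.integer(round(2 * rank(abs(d))))
  v2 <- sum(r2[d > 0])
  counts <- 1
  for (r in r2) counts <- c(counts, numeric(r)) + c(numeric(r), counts)
  probs <- counts / sum(counts)
  lower <- sum(probs[seq_len(v2 + 1)])          # P(V2 <= v2)
  upper <- sum(probs[(v2 + 1):length(probs)])   # P(V2 >= v2)
  min(1, 2 * min(lower, upper))
}

#' Paired comparison by the Wilcoxon signed-rank test (two-sided)
#'
#' Zero differences are removed first; at least 5 informative pairs are
#' required.  For up to 25 informative pairs the p-value is exact
#' (enumeration of all sign patterns via dynamic programming, with midranks
#' for tied differences); beyond that the normal approximation with tie and
#' continuity corrections is used.
#'
#' @param x,y equal-length paired samples.
#' @return a `test_result` (statistic V = positive-rank sum, p,
#'   n = informative pairs).
#' @export
paired_compare <- function(x, y) {
  if (length(x) != length(y)) stop_fmt("paired samples must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) stop_fmt("all differences are zero: test undefined")
  if (length(d) < 5) stop_fmt("need at least 5 nonzero differences")
  v <- sum(rank(abs(d))[d > 0])
  p <- if (length(d) <= 25) exact_signrank_p(d)
       else suppressWarnings(wilcox.test(d, exact = FALSE,
                                         correct = TRUE)$p.value)
  test_result(c(V = v), p, length(d), "Wilcoxon signed-rank")
}

#' Unpaired comparison by the Wilcoxon rank-sum test (two-sided)
#'
#' @param x,y independent samples.
#' @return a `test_result` (statistic W, p, n per group).
#' @export
unpaired_compare <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop_fmt("need at least 2 values per group")
  wt <- suppressWarnings(wilcox.test(x, y, exact = length(c(x, y)) <= 50 &&
                                       !anyDuplicated(c(x, y))))
  test_result(wt$statistic, wt$p.value, c(length(x), length(y)),
              "Wilcoxon rank-sum")
}

#' Multi-group comparison: one-way ANOVA with post-hoc tests
#'
#' Omnibus one-way ANOVA followed by all pairwise comparisons: Tukey-Kramer
#' adjusted p-values (`posthoc = "tukey"`, valid for unequal group sizes) or
#' rank-based pairwise Wilcoxon tests with Holm correction
#' (`posthoc = "kruskal"`, in which case the Kruskal-Wallis omnibus is also
#' reported).
#'
#' @param values numeric response vector.
#' @param group grouping vector (>= 2 groups, each with >= 2 values).
#' @param posthoc `"tukey"` or `"kruskal"`.
#' @return list with `omnibus` (a `test_result` for the ANOVA F),
#'   `pairwise` (data.frame `group1`, `group2`, `p_adj`), and, for the
#'   rank-based option, `kruskal` (a `test_result`).
#' @export
group_compare <- function(values, group, posthoc = c("tukey", "kruskal")) {
  posthoc <- match.arg(posthoc)
  group <- factor(group)
  if (nlevels(group) < 2) stop_fmt("need at least 2 groups")
  if (any(table(group) < 2)) stop_fmt("each group needs at least 2 values")
  fit <- aov(values ~ group)
  an <- summary(fit)[[1]]
  omnibus <- test_result(an$`F value`[1], an$`Pr(>F)`[1],
                         as.integer(table(group)), "one-way ANOVA")
  if (posthoc == "tukey") {
    tk <- TukeyHSD(fit)$group
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- data.frame(group1 = vapply(pairs, `[`, "", 1),
                           group2 = vapply(pairs, `[`, "", 2),
                           p_adj = unname(tk[, "p adj"]))
    list(omnibus = omnibus, pairwise = pairwise)
  } else {
    kw <- kruskal.test(values, group)
    pw <- pairwise.wilcox.test(values, group, p.adjust.method = "holm",
                               exact = FALSE)
    m <- pw$p.value
    idx <- which(!is.na(m), arr.ind = TRUE)
    pairwise <- data.frame(group1 = rownames(m)[idx[, 1]],
                           group2 = colnames(m)[idx[, 2]],
                           p_adj = m[idx])
    list(omnibus = omnibus,
         kruskal = test_result(kw$statistic, kw$p.value,
                               as.integer(table(group)), "Kruskal-Wallis"),
         pairwise = pairwise)
  }
}

#' Pearson correlation with two-sided p
#'
#' @param x,y numeric vectors with at least 3 finite pairs; zero variance in
#'   either is an error.
#' @return list with `r`, `p`, `n`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop_fmt("length mismatch")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop_fmt("need at least 3 finite pairs")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) stop_fmt("zero variance")
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Grubbs single-outlier screen (two-sided)
#'
#' Optional pre-filter: tests whether the sample's most extreme value is an
#' outlier at level `alpha` using the closed-form critical value based on
#' the t distribution.  Off by default in all analyses; when applied, the
#' removed index is reported so the screening is auditable.
#'
#' @param x numeric sample (n >= 3).
#' @param alpha significance level (default 0.05).
#' @return list with `outlier_index` (`NA` if none), `statistic` (G),
#'   `critical`.
#' @export
grubbs_screen <- function(x, alpha = 0.05) {
  n <- length(x)
  if (n < 3) stop_fmt("need at least 3 values")
  s <- sd(x)
  if (s == 0) return(list(outlier_index = NA_integer_, statistic = 0, critical = NA_real_))
  dev <- abs(x - mean(x))
  g <- max(dev) / s
  tcrit <- qt(1 - alpha / (2 * n), n - 2)
  crit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  list(outlier_index = if (g > crit) which.max(dev) else NA_integer_,
       statistic = g, critical = crit)
}
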