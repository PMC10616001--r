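new_test_result <- function(test, statistic, p, n, details = list(),
                            degenerate = FALSE) {
  structure(
    list(test = test, statistic = unname(statistic), p = unname(p), n = n,
         details = details, degenerate = degenerate),
    class = "covpet_test"
  )
}

#' @export
print.covpet_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s\n", x$test,
              x$statistic, x$p, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Normality (Shapiro-Wilk per group) + homoscedasticity (Levene) gate used
# to pick parametric vs rank-based tests, at alpha = 0.05.
gate_parametric <- function(groups, alpha = 0.05) {
  sw_ok <- all(vapply(groups, function(g) {
    if (length(unique(g)) < 3L) return(FALSE)
    stats::shapiro.test(g)$p.value > alpha
  }, logical(1)))
  if (!sw_ok) return(FALSE)
  y <- unlist(groups)
  f <- factor(rep(seq_along(groups), lengths(groups)))
  lev <- car::leveneTest(y, f, center = mean)
  lev[["Pr(>F)"]][1] > alpha
}

#' Two-group comparison (two-sample t or Mann-Whitney)
#'
#' In `mode = "auto"` the test follows the study's "as appropriate" rule
#' made explicit: a pooled-variance two-sample t-test when both groups pass
#' Shapiro-Wilk normality and Levene's homoscedasticity test at alpha = 0.05,
#' otherwise the two-sided Mann-Whitney U test (exact when the combined n is
#' at most 20 and there are no ties; tie-corrected normal approximation with
#' continuity correction otherwise). Either test can be forced.
#'
#' @param a,b Numeric samples, at least 3 values each.
#' @param mode `"auto"`, `"t"`, or `"mw"`.
#' @return A `covpet_test` result (`test`, `statistic`, `p`, `n`,
#'   `details`).
#' @export
compare_two <- function(a, b, mode = c("auto", "t", "mw")) {
  mode <- match.arg(mode)
  stopifnot(length(a) >= 3L, length(b) >= 3L)
  if (mode == "auto") mode <- if (gate_parametric(list(a, b))) "t" else "mw"
  n <- c(length(a), length(b))
  if (mode == "t") {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    return(new_test_result("two-sample t (pooled)", tt$statistic,
                           tt$p.value, n, list(df = unname(tt$parameter))))
  }
  if (length(unique(c(a, b))) == 1L)
    return(new_test_result("Mann-Whitney U", length(a) * length(b) / 2, 1, n,
                           degenerate = TRUE))
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && sum(n) <= 20L
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact)
  )
  new_test_result("Mann-Whitney U", wt$statistic, wt$p.value, n,
                  list(exact = exact))
}

#' Paired two-sided t-test
#'
#' @param pre,post Equal-length paired numeric vectors (same subject order).
#' @return A `covpet_test`; zero-variance differences are flagged degenerate
#'   with statistic 0 and `p = NA`.
#' @export
paired_compare <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2L)
  d <- pre - post
  if (stats::sd(d) < .Machine$double.eps * max(1, max(abs(d))))
    return(new_test_result("paired t", 0, NA_real_, length(pre),
                           degenerate = TRUE))
  tt <- stats::t.test(pre, post, paired = TRUE)
  new_test_result("paired t", tt$statistic, tt$p.value, length(pre),
                  list(df = unname(tt$parameter),
                       mean_difference = unname(tt$estimate)))
}

# Dunn's rank-based pairwise z tests after Kruskal-Wallis, with tie
# correction and Bonferroni adjustment over the pairs.
dunn_posthoc <- function(groups) {
  y <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  rk <- rank(y)
  N <- length(y)
  tie_sizes <- table(y)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  mean_rk <- tapply(rk, g, mean)
  ns <- lengths(groups)
  pairs <- utils::combn(seq_along(groups), 2)
  npairs <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ])
  out$z <- apply(pairs, 2, function(pr) {
    (mean_rk[pr[1]] - mean_rk[pr[2]]) /
      sqrt(v0 * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
  })
  out$p_adjusted <- pmin(1, 2 * stats::pnorm(-abs(out$z)) * npairs)
  out
}

#' Three-group comparison (one-way ANOVA or Kruskal-Wallis) with post hoc
#'
#' Under the same normality/homoscedasticity gate as [compare_two()]: a
#' one-way ANOVA followed by pairwise pooled-SD t-tests with Bonferroni
#' adjustment when the gate passes, otherwise the Kruskal-Wallis test (tie
#' corrected) followed by Dunn's pairwise z tests with Bonferroni
#' adjustment.
#'
#' @param groups List of at least 3 numeric samples, each of length >= 3
#'   (two groups are accepted and degrade gracefully).
#' @param mode `"auto"`, `"anova"`, or `"kw"`.
#' @return A `covpet_test`; `details$posthoc` holds the pairwise table.
#' @export
compare_three <- function(groups, mode = c("auto", "anova", "kw")) {
  mode <- match.arg(mode)
  stopifnot(is.list(groups), length(groups) >= 2L, all(lengths(groups) >= 2L))
  if (mode == "auto") mode <- if (gate_parametric(groups)) "anova" else "kw"
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (mode == "anova") {
    av <- stats::anova(stats::lm(y ~ g))
    ph <- stats::pairwise.t.test(y, g, p.adjust.method = "bonferroni",
                                 pool.sd = TRUE)
    return(new_test_result("one-way ANOVA", av$`F value`[1], av$`Pr(>F)`[1],
                           lengths(groups),
                           list(df = av$Df, posthoc = ph$p.value)))
  }
  kw <- stats::kruskal.test(y, g)
  new_test_result("Kruskal-Wallis", kw$statistic, kw$p.value,
                  lengths(groups),
                  list(df = unname(kw$parameter),
                       posthoc = dunn_posthoc(groups)))
}

#' Pearson chi-square test on a 2x2 table, without continuity correction
#'
#' The study's printed gender chi-squares are Pearson statistics without
#' Yates correction; this wrapper pins that convention down.
#'
#' @param table 2x2 matrix of non-negative integer counts, positive margins.
#' @return A `covpet_test` with `statistic` the Pearson X-squared (df = 1).
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("table margins must be positive")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  new_test_result("Pearson chi-square", ct$statistic, ct$p.value,
                  sum(table), list(df = 1, expected = ct$expected))
}

#' Pearson or Spearman correlation with a two-sided p value
#'
#' Spearman rank correlation uses midranks for ties and the t approximation
#' for its p value.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `covpet_test` with `statistic` the correlation coefficient.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  new_test_result(paste(method, "correlation"), ct$estimate, ct$p.value,
                  length(x))
}

#' Compare two dependent correlations sharing one variable (Steiger's Z)
#'
#' Tests whether cor(x, y) differs from cor(x, z) when both involve the
#' shared variable x, given cor(y, z) — the comparison the study ran (via
#' MedCalc) between the TBG correlations with lg(TMTV) and with lg(TLG).
#' Uses Fisher's z transform with Steiger's pooled-correlation covariance
#' term:
#' \deqn{Z = (z_{xy} - z_{xz}) \sqrt{\frac{n-3}{2 - 2\bar{s}}}}
#' where \eqn{\bar{s} = \bar\psi / (1-\bar{r}^2)^2},
#' \eqn{\bar{r} = (r_{xy}+r_{xz})/2}, and
#' \eqn{\bar\psi = r_{yz}(1-2\bar{r}^2) - \bar{r}^2(1-2\bar{r}^2-r_{yz}^2)/2}.
#'
#' @param r_xy,r_xz The two correlations being compared (|r| < 1).
#' @param r_yz Correlation between the two non-shared variables (|r| < 1).
#' @param n Sample size (>= 4).
#' @return A `covpet_test` with `statistic` the signed Z and a two-sided
#'   normal p value.
#' @export
compare_dependent_correlations <- function(r_xy, r_xz, r_yz, n) {
  if (any(abs(c(r_xy, r_xz, r_yz)) >= 1)) stop("|r| must be < 1")
  if (n < 4) stop("need n >= 4")
  det3 <- 1 + 2 * r_xy * r_xz * r_yz - r_xy^2 - r_xz^2 - r_yz^2
  if (det3 < -1e-12) stop("correlation triple is not positive semidefinite")
  rb <- (r_xy + r_xz) / 2
  psi <- r_yz * (1 - 2 * rb^2) - rb^2 * (1 - 2 * rb^2 - r_yz^2) / 2
  s <- psi / (1 - rb^2)^2
  z <- (atanh(r_xy) - atanh(r_xz)) * sqrt((n - 3) / (2 - 2 * s))
  new_test_result("Steiger Z (dependent correlations)", z,
                  2 * stats::pnorm(-abs(z)), n,
                  list(r_xy = r_xy, r_xz = r_xz, r_yz = r_yz))
}
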