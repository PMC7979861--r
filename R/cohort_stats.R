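# Association and survival statistics for cohort-level comparisons.
# Thin, explicit wrappers around the base R and survival implementations,
# with the conventions (two-sided tests, exact where feasible) fixed.

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration when both samples together hold at most 12
#' observations without ties; otherwise the normal approximation with tie
#' correction.
#'
#' @param x,y Numeric samples.
#' @return List with `U` and `p`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty group", call. = FALSE)
  exact <- (length(x) + length(y) <= 12) && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by summation of hypergeometric probabilities no larger than
#' the observed table's; odds ratio reported as the sample odds ratio
#' `ad/bc` (infinite when `bc = 0`), with the conditional exact confidence
#' interval.
#'
#' @param a,b,c,d Cell counts, row-wise.
#' @return List with `odds_ratio`, `p`, `ci95`.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("all-zero table", call. = FALSE)
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(m, alternative = "two.sided")
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else a * d / (b * c)
  list(odds_ratio = or, p = ft$p.value, ci95 = unname(ft$conf.int))
}

#' Kaplan-Meier curves, log-rank test and Mantel-Haenszel hazard ratio
#'
#' Two-group survival comparison: Mantel-Cox log-rank statistic, hazard
#' ratio estimated from the log-rank observed/expected decomposition as
#' `(O2/E2) / (O1/E1)` with a log-normal 95% interval
#' (`SE = sqrt(1/E1 + 1/E2)`), and the Kaplan-Meier curves for both
#' groups. A Cox proportional-hazards estimate is available with
#' `estimator = "cox"`.
#'
#' @param time Survival/censoring times (> 0).
#' @param event Event indicator (0/1).
#' @param group Two-level grouping; the hazard ratio is for the second
#'   level relative to the first.
#' @param estimator `"mantel-haenszel"` (default) or `"cox"`.
#' @return List with `chisq`, `p`, `hr`, `hr_ci95` and `km` (a data frame
#'   of curve points: `group`, `time`, `surv`).
#' @export
km_logrank <- function(time, event, group,
                       estimator = c("mantel-haenszel", "cox")) {
  estimator <- match.arg(estimator)
  group <- factor(group)
  if (nlevels(group) != 2) stop("exactly two groups required",
                                call. = FALSE)
  if (any(table(group) == 0)) stop("empty group", call. = FALSE)
  if (sum(event) < 1) stop("at least one event required", call. = FALSE)
  stopifnot(all(time > 0), all(event %in% c(0, 1)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- sd$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  if (estimator == "mantel-haenszel") {
    log_hr <- log(sd$obs[2] / sd$exp[2]) - log(sd$obs[1] / sd$exp[1])
    se <- sqrt(1 / sd$exp[1] + 1 / sd$exp[2])
  } else {
    cx <- survival::coxph(survival::Surv(time, event) ~ group)
    log_hr <- unname(stats::coef(cx))
    se <- sqrt(unname(stats::vcov(cx)[1, 1]))
  }
  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  km <- data.frame(
    group = rep(levels(group), sf$strata %||% length(sf$time)),
    time = sf$time, surv = sf$surv, stringsAsFactors = FALSE)
  list(chisq = chisq, p = p, hr = exp(log_hr),
       hr_ci95 = exp(log_hr + c(-1.96, 1.96) * se), km = km)
}

#' Spearman rank correlation
#'
#' @param x,y Numeric vectors (n >= 3).
#' @return List with `rho` and `p`.
#' @export
spearman <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' @param groups List of numeric vectors.
#' @return List with `H` and `p`.
#' @export
kruskal <- function(groups) {
  if (sum(lengths(groups)) < 3) stop("need at least 3 observations",
                                     call. = FALSE)
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Shapiro-Wilk normality gate
#'
#' Routes mean-versus-median comparisons: samples passing Shapiro-Wilk at
#' `alpha` in both groups are compared with Welch's t-test, otherwise the
#' Wilcoxon rank-sum test is used.
#'
#' @param x Numeric sample (3-5000 observations).
#' @param alpha Normality significance level (default 0.05).
#' @return `"normal"` or `"skewed"`.
#' @export
shapiro_gate <- function(x, alpha = 0.05) {
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::shapiro.test(x)$p.value > alpha) "normal" else "skewed"
}

#' Compare two samples, choosing the test by normality
#'
#' Welch's t-test when both samples pass the Shapiro-Wilk gate, Wilcoxon
#' rank-sum otherwise.
#'
#' @param x,y Numeric samples.
#' @return List with `test` (`"welch"`/`"wilcoxon"`) and `p`.
#' @export
compare_two_groups <- function(x, y) {
  if (shapiro_gate(x) == "normal" && shapiro_gate(y) == "normal") {
    list(test = "welch",
         p = stats::t.test(x, y, var.equal = FALSE)$p.value)
  } else {
    list(test = "wilcoxon",
         p = suppressWarnings(stats::wilcox.test(x, y)$p.value))
  }
}

#' Neutrophil-to-lymphocyte and platelet-to-lymphocyte ratios
#'
#' @param neutrophils,lymphocytes,platelets Blood counts (same units for
#'   numerator and denominator; lymphocytes > 0).
#' @return Data frame with `nlr` and `plr`.
#' @export
clinical_indices <- function(neutrophils, lymphocytes, platelets) {
  if (any(lymphocytes <= 0)) stop("lymphocytes must be > 0", call. = FALSE)
  data.frame(nlr = neutrophils / lymphocytes,
             plr = platelets / lymphocytes)
}
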