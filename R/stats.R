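# Univariate statistics: Wilcoxon rank-sum feature screening, two-sample t
# from published summary statistics, and Youden-index threshold selection.

#' Wilcoxon rank-sum test of two samples
#'
#' Midranks for ties. The p-value is exact (distribution-enumeration) when
#' the pooled size is at most 12 and there are no ties, and otherwise the
#' normal approximation with tie and continuity correction.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return A list with `statistic` (the rank sum of `x` in the pooled
#'   ranking), `p_value` (two-sided), and `exact` (logical).
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop_config("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 12L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  rank_sum <- unname(ht$statistic) + length(x) * (length(x) + 1) / 2
  list(statistic = rank_sum, p_value = ht$p.value, exact = exact)
}

#' Screen peak-matrix features with the Wilcoxon rank-sum test
#'
#' Tests every cluster case-vs-control and keeps those with `p < alpha`.
#' The expression direction in cases is taken from group medians (the
#' natural location summary for a rank test); group means are reported
#' alongside.
#'
#' @param pm A `peak_matrix` with both groups present.
#' @param alpha Retention threshold on the raw p-value (default 0.05; no
#'   multiplicity correction, mirroring raw-P screening).
#' @param p_adjust Optional p-adjustment method passed to
#'   [stats::p.adjust()] (default `"none"`); when not `"none"`, retention
#'   uses the adjusted p.
#' @return A data frame sorted by ascending p: `mz`, `statistic`,
#'   `p_value`, `direction` (`"up"`/`"down"` in cases), `median_case`,
#'   `median_control`, `mean_case`, `mean_control`.
#' @export
screen_features <- function(pm, alpha = 0.05, p_adjust = "none") {
  grp <- pm$labels$group
  if (!all(c("case", "control") %in% grp))
    stop_config("both groups must be present for screening")
  case_cols <- grp == "case"; ctrl_cols <- grp == "control"
  res <- lapply(seq_len(nrow(pm$intensity)), function(i) {
    xc <- pm$intensity[i, case_cols]; xn <- pm$intensity[i, ctrl_cols]
    w <- wilcoxon_rank_sum(xc, xn)
    mc <- stats::median(xc); mn <- stats::median(xn)
    dir <- if (mc > mn) "up" else if (mc < mn) "down"
           else if (mean(xc) >= mean(xn)) "up" else "down"
    data.frame(mz = pm$mz[i], statistic = w$statistic, p_value = w$p_value,
               direction = dir, median_case = mc, median_control = mn,
               mean_case = mean(xc), mean_control = mean(xn),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  p_used <- stats::p.adjust(res$p_value, method = p_adjust)
  res <- res[p_used < alpha, , drop = FALSE]
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Group summary triple
#'
#' @param mean,sd,n Group mean, standard deviation (>= 0) and size (>= 2).
#' @return A list of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  if (sd < 0) stop_config("sd must be >= 0")
  if (n < 2) stop_config("n must be >= 2")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' Two-sample pooled-variance t-test from summary statistics
#'
#' Computes the classical pooled t statistic directly from (mean, sd, n)
#' triples, as needed to check published tables that report only summaries:
#' \deqn{t = (\bar a - \bar b) / \sqrt{s_p^2 (1/n_a + 1/n_b)},\quad
#'       s_p^2 = \frac{(n_a-1)s_a^2 + (n_b-1)s_b^2}{n_a+n_b-2}.}
#' The sign follows `a - b`. With equal group sizes this coincides with the
#' Welch statistic.
#'
#' @param a,b [group_summary()] objects (or lists with `mean`, `sd`, `n`).
#' @return A list with `statistic`, `df`, `p_value` (two-sided).
#' @export
#' @examples
#' summary_t(group_summary(307.48, 74.68, 40),
#'           group_summary(157.41, 82.62, 40))$statistic
summary_t <- function(a, b) {
  if (!inherits(a, "group_summary")) a <- do.call(group_summary, a[c("mean", "sd", "n")])
  if (!inherits(b, "group_summary")) b <- do.call(group_summary, b[c("mean", "sd", "n")])
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  t <- if (se == 0) {
    if (a$mean == b$mean) 0 else sign(a$mean - b$mean) * Inf
  } else (a$mean - b$mean) / se
  list(statistic = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df))
}

#' Youden index
#'
#' @param sensitivity,specificity Fractions in `[0, 1]`.
#' @return J = sensitivity + specificity - 1.
#' @export
#' @examples
#' youden(0.90, 1.00)
youden <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  sensitivity + specificity - 1
}

#' Youden-optimal threshold for a single feature
#'
#' Scans every midpoint between sorted unique feature values, in both
#' orientations (cases above or below the threshold), and returns the
#' threshold maximizing the Youden index J. Ties are broken toward the
#' lower threshold, with the "cases high" orientation preferred at equal
#' threshold.
#'
#' @param values Numeric feature values.
#' @param labels Character vector (`"case"`/`"control"`) or factor, same
#'   length.
#' @return A list with `threshold`, `J`, `direction` (`"case_high"` or
#'   `"case_low"`), `sensitivity`, `specificity`.
#' @export
best_cut <- function(values, labels) {
  labels <- as.character(labels)
  is_case <- labels == "case"
  if (!any(is_case) || !all(labels %in% c("case", "control")) ||
      all(is_case))
    stop_config("labels must contain both 'case' and 'control'")
  u <- sort(unique(values))
  thresholds <- if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2 else u
  n_case <- sum(is_case); n_ctrl <- sum(!is_case)
  best <- list(J = -Inf)
  for (thr in thresholds) {
    for (dir in c("case_high", "case_low")) {
      pred_case <- if (dir == "case_high") values > thr else values < thr
      sens <- sum(pred_case & is_case) / n_case
      spec <- sum(!pred_case & !is_case) / n_ctrl
      J <- sens + spec - 1
      if (J > best$J + 1e-12)
        best <- list(threshold = thr, J = J, direction = dir,
                     sensitivity = sens, specificity = spec)
    }
  }
  best
}
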