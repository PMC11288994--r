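#' Wilson score interval for a binomial proportion
#'
#' @param successes number of successes (length 1).
#' @param trials number of trials, > 0.
#' @param level confidence level.
#' @return named numeric vector `c(lower, upper)`, contained in `[0, 1]`.
#' @export
#' @examples
#' wilson_ci(3470, 221429)   # sepsis incidence interval
wilson_ci <- function(successes, trials, level = 0.95) {
  if (length(trials) != 1L || is.na(trials) || trials <= 0) fail("`trials` must be a positive count")
  if (successes < 0 || successes > trials) fail("`successes` must lie in [0, trials]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  centre <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

# Wald interval, offered behind ci_method = "wald"
wald_ci <- function(successes, trials, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  half <- z * sqrt(p * (1 - p) / trials)
  c(lower = max(0, p - half), upper = min(1, p + half))
}

#' Cross-tabulate screening flags against the sepsis label
#'
#' @param flags logical vector of positive screening results.
#' @param labels logical vector of inpatient sepsis labels.
#' @return object of class `confusion`: list with `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' confusion(c(TRUE, FALSE), c(TRUE, FALSE))
confusion <- function(flags, labels) {
  if (length(flags) != length(labels)) {
    fail("`flags` (%d) and `labels` (%d) differ in length", length(flags), length(labels))
  }
  if (anyNA(flags) || anyNA(labels)) {
    fail("`flags`/`labels` contain missing entries; drop complete-case exclusions upstream")
  }
  structure(list(tp = sum(flags & labels), fp = sum(flags & !labels),
                 fn = sum(!flags & labels), tn = sum(!flags & !labels)),
            class = "confusion")
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,fn,tn non-negative integer cell counts.
#' @return object of class `confusion`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) fail("confusion counts must be non-negative integers")
  structure(as.list(counts), class = "confusion")
}

#' Diagnostic accuracy statistics for a dichotomous screening rule
#'
#' Sensitivity, specificity, predictive values, likelihood ratios, the
#' dichotomous-rule AUROC (the two-segment trapezoid, (Se + Sp)/2) and the
#' positivity rate, each proportion with a 95% Wilson confidence interval.
#' When no case screens positive the PPV is undefined and reported as `NA`
#' (flagged, not zero); a specificity of 1 gives an infinite positive
#' likelihood ratio. The AUROC interval combines the Se and Sp binomial
#' variances (Wald); the LR intervals are not reported.
#'
#' @param cm a [confusion()] object.
#' @param level confidence level for the intervals.
#' @param ci_method `"wilson"` (default) or `"wald"`.
#' @return object of class `accuracy_summary`: data frame with one row per
#'   statistic (`estimate`, `lower`, `upper`).
#' @export
#' @examples
#' accuracy_summary(confusion_counts(tp = 57, fp = 814, fn = 21, tn = 3611))
accuracy_summary <- function(cm, level = 0.95, ci_method = c("wilson", "wald")) {
  ci_method <- match.arg(ci_method)
  ci_fun <- if (ci_method == "wilson") wilson_ci else wald_ci
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  n_pos <- tp + fn; n_neg <- fp + tn; n <- n_pos + n_neg
  if (n_pos == 0 || n_neg == 0) fail("accuracy_summary needs both sepsis and non-sepsis cases")
  se <- tp / n_pos
  sp <- tn / n_neg
  prop_row <- function(x, m) {
    ci <- ci_fun(x, m, level)
    c(estimate = x / m, ci)
  }
  ppv <- if (tp + fp > 0) prop_row(tp, tp + fp) else c(estimate = NA_real_, lower = NA_real_, upper = NA_real_)
  npv <- if (tn + fn > 0) prop_row(tn, tn + fn) else c(estimate = NA_real_, lower = NA_real_, upper = NA_real_)
  lr_plus <- if (sp < 1) se / (1 - sp) else Inf
  lr_minus <- if (sp > 0) (1 - se) / sp else NA_real_
  auroc <- (se + sp) / 2
  z <- stats::qnorm(1 - (1 - level) / 2)
  auroc_sd <- sqrt((se * (1 - se) / n_pos + sp * (1 - sp) / n_neg) / 4)
  rows <- rbind(
    sensitivity = prop_row(tp, n_pos),
    specificity = prop_row(tn, n_neg),
    ppv = ppv,
    npv = npv,
    lr_plus = c(estimate = lr_plus, lower = NA_real_, upper = NA_real_),
    lr_minus = c(estimate = lr_minus, lower = NA_real_, upper = NA_real_),
    auroc = c(estimate = auroc,
              lower = max(0, auroc - z * auroc_sd),
              upper = min(1, auroc + z * auroc_sd)),
    positivity_rate = prop_row(tp + fp, n))
  out <- data.frame(statistic = rownames(rows), rows, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, class = c("accuracy_summary", "data.frame"),
            confusion = cm, n = n, ppv_undefined = tp + fp == 0)
}

# convenience accessor: accuracy_stat(summ, "sensitivity")
accuracy_stat <- function(summ, stat) {
  summ$estimate[match(stat, summ$statistic)]
}

#' McNemar's chi-squared test for paired screening results
#'
#' Compares two screening tools on the same cases using the discordant
#' counts b (first positive only) and c (second positive only):
#' chi2 = (b - c)^2 / (b + c), referred to a chi-squared distribution with
#' one degree of freedom. No continuity correction by default (available
#' behind `correct = TRUE`). With no discordant pairs the statistic is 0
#' and p = 1 by convention, flagged as degenerate.
#'
#' @param x,y logical vectors of positive screening results, paired by case.
#' @param correct apply the continuity correction.
#' @return list: `statistic`, `p_value`, `b`, `c`, `degenerate`.
#' @export
#' @examples
#' mcnemar(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
mcnemar <- function(x, y, correct = FALSE) {
  if (length(x) != length(y)) fail("paired vectors differ in length")
  if (anyNA(x) || anyNA(y)) fail("paired flags contain missing entries")
  b <- sum(x & !y)
  cc <- sum(!x & y)
  if (b + cc == 0) {
    return(list(statistic = 0, p_value = 1, b = b, c = cc, degenerate = TRUE))
  }
  num <- if (correct) max(0, abs(b - cc) - 1)^2 else (b - cc)^2
  stat <- num / (b + cc)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       b = b, c = cc, degenerate = FALSE)
}

#' Pearson chi-squared test with Cramer's V
#'
#' Uncorrected Pearson chi-squared on a contingency table plus the
#' Cramer's V effect size, `sqrt(chi2 / (n * (min(r, c) - 1)))`.
#'
#' @param tab matrix (or table) of non-negative counts, at least 2x2.
#' @return list: `chi2`, `p_value`, `v`, `df`, `n`.
#' @export
#' @examples
#' cramers_v(matrix(c(30, 10, 70, 90), nrow = 2))
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) fail("counts must be non-negative")
  if (nrow(tab) < 2 || ncol(tab) < 2) fail("table must be at least 2x2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    fail("zero marginal in contingency table")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  v <- sqrt(unname(ct$statistic) / (n * (min(dim(tab)) - 1)))
  list(chi2 = unname(ct$statistic), p_value = unname(ct$p.value), v = v,
       df = unname(ct$parameter), n = n)
}

#' Bonferroni-adjusted rejection decisions
#'
#' Rejects H0 for `p <= alpha / m` with `m` the number of tests.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise error rate.
#' @param m number of tests (defaults to `length(p_values)`).
#' @return logical vector of rejections (empty input gives an empty vector).
#' @export
bonferroni <- function(p_values, alpha = 0.05, m = length(p_values)) {
  if (length(p_values) == 0L) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) fail("p-values must be in [0, 1]")
  p_values <= alpha / m
}

#' Evaluate a score panel against the sepsis labels
#'
#' Builds, per tool (and the combined any/all rules), the confusion matrix
#' and accuracy summary. Cases with an undefined flag for a tool
#' (complete-case exclusions) are dropped for that tool, with the exclusion
#' count recorded; the combined rules use cases where all four flags are
#' defined.
#'
#' @param panel a [score_panel()] data frame.
#' @param outcomes outcome records with `case_id` and `sepsis`.
#' @return named list of `accuracy_summary` objects (`qsofa`, `sirs`,
#'   `mews`, `news2`, `all_tools`, `any_tool`), each with an `"excluded"`
#'   attribute.
#' @export
evaluate_panel <- function(panel, outcomes) {
  labels <- outcomes$sepsis[match(panel$case_id, outcomes$case_id)]
  if (anyNA(labels)) fail("panel contains case_ids absent from outcomes")
  out <- list()
  for (tool in TOOLS) {
    flag <- panel[[paste0(tool, "_pos")]]
    keep <- !is.na(flag)
    summ <- accuracy_summary(confusion(flag[keep], labels[keep]))
    attr(summ, "excluded") <- sum(!keep)
    out[[tool]] <- summ
  }
  flags4 <- panel[, paste0(TOOLS, "_pos")]
  keep <- stats::complete.cases(flags4)
  for (mode in c("all", "any")) {
    combo <- combined_rule(flags4[keep, ], mode)
    summ <- accuracy_summary(confusion(combo, labels[keep]))
    attr(summ, "excluded") <- sum(!keep)
    out[[paste0(mode, if (mode == "all") "_tools" else "_tool")]] <- summ
  }
  out
}
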