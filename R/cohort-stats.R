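#' Incidence of a condition among EMS cases
#'
#' Diagnosed cases over all cases, with a Wilson 95% confidence interval.
#'
#' @param outcomes outcome records with logical condition columns.
#' @param condition one of `"sepsis"`, `"mi"`, `"stroke"`.
#' @return list: `n_cases`, `n_total`, `estimate` (proportion), `lower`,
#'   `upper`.
#' @export
#' @examples
#' oc <- data.frame(sepsis = c(TRUE, FALSE, FALSE))
#' incidence(oc, "sepsis")
incidence <- function(outcomes, condition = c("sepsis", "mi", "stroke")) {
  condition <- match.arg(condition)
  n <- nrow(outcomes)
  if (n == 0L) fail("empty cohort")
  k <- sum(outcomes[[condition]])
  ci <- wilson_ci(k, n)
  list(n_cases = k, n_total = n, estimate = k / n,
       lower = unname(ci["lower"]), upper = unname(ci["upper"]))
}

#' Case fatality within a window
#'
#' Deaths among diagnosed cases: in hospital, or within 30 days of EMS
#' contact (`death_day <= 30`, day 0 = the day of EMS use).
#'
#' @param outcomes outcome records.
#' @param condition condition defining the denominator.
#' @param window `"hospital"` or `"30d"`.
#' @return list as in [incidence()] (denominator = diagnosed cases).
#' @export
case_fatality <- function(outcomes, condition = c("sepsis", "mi", "stroke"),
                          window = c("hospital", "30d")) {
  condition <- match.arg(condition)
  window <- match.arg(window)
  diag <- outcomes[outcomes[[condition]], , drop = FALSE]
  n <- nrow(diag)
  if (n == 0L) fail("no diagnosed %s cases", condition)
  deaths <- if (window == "hospital") {
    sum(diag$died_in_hospital)
  } else {
    sum(!is.na(diag$death_day) & diag$death_day <= 30)
  }
  ci <- wilson_ci(deaths, n)
  list(n_cases = deaths, n_total = n, estimate = deaths / n,
       lower = unname(ci["lower"]), upper = unname(ci["upper"]))
}

# at least one slot documented, per case, for one variable
documented_any_slot <- function(cases, v) {
  !is.na(cases[[slot_col(v, 1)]]) | !is.na(cases[[slot_col(v, 2)]])
}

#' Documentation completeness table
#'
#' Per screening-relevant variable: the share of cases with at least one
#' documented assessment (Wilson 95% CI), overall and per group, plus the
#' uncorrected Pearson chi-squared p-value and Cramer's V for the
#' association between completeness and group. Grouping is either by staff
#' type (`"staff"`: paramedics vs emergency physicians) or by the linked
#' inpatient sepsis label (`"sepsis_label"`, requires `outcomes`). A final
#' row reports the share of cases with all seven variables documented.
#'
#' @param cases EMS case records (apply [plausibility_filter()] first so
#'   that implausible entries do not count as documented).
#' @param group_by `"staff"` or `"sepsis_label"`.
#' @param outcomes outcome records (needed for `"sepsis_label"`).
#' @return data frame: `variable`, overall rate and CI, per-group rates and
#'   CIs, `chi2`, `p_value`, `cramers_v`; attribute `"group_sizes"`.
#' @export
completeness_table <- function(cases, group_by = c("staff", "sepsis_label"),
                               outcomes = NULL) {
  group_by <- match.arg(group_by)
  if (nrow(cases) == 0L) fail("empty cohort")
  group <- if (group_by == "staff") {
    factor(cases$staff, levels = c("EP", "PM"))
  } else {
    if (is.null(outcomes)) fail("`outcomes` required to group by sepsis_label")
    sep <- outcomes$sepsis[match(cases$case_id, outcomes$case_id)]
    if (anyNA(sep)) fail("cases contain case_ids absent from outcomes")
    factor(ifelse(sep, "with_sepsis", "without_sepsis"),
           levels = c("with_sepsis", "without_sepsis"))
  }
  if (any(table(group) == 0)) fail("empty group in `%s` stratification", group_by)
  doc <- vapply(DOC_VARS, function(v) documented_any_slot(cases, v),
                logical(nrow(cases)))
  doc <- cbind(doc, all_seven = rowSums(doc) == length(DOC_VARS))
  rows <- lapply(colnames(doc), function(v) {
    d <- doc[, v]
    ci <- wilson_ci(sum(d), length(d))
    row <- data.frame(variable = v, rate = mean(d),
                      lower = unname(ci["lower"]), upper = unname(ci["upper"]),
                      stringsAsFactors = FALSE)
    for (g in levels(group)) {
      dg <- d[group == g]
      cig <- wilson_ci(sum(dg), length(dg))
      row[[paste0("rate_", g)]] <- mean(dg)
      row[[paste0("lower_", g)]] <- unname(cig["lower"])
      row[[paste0("upper_", g)]] <- unname(cig["upper"])
    }
    tab <- table(group, factor(d, levels = c(FALSE, TRUE)))
    if (any(colSums(tab) == 0)) { # no variation: no association
      row$chi2 <- 0; row$p_value <- 1; row$cramers_v <- 0
    } else {
      cv <- cramers_v(tab)
      row$chi2 <- cv$chi2; row$p_value <- cv$p_value; row$cramers_v <- cv$v
    }
    row
  })
  out <- do.call(rbind, rows)
  structure(out, group_sizes = table(group))
}

#' Documented sepsis suspicion rate per staff stratum
#'
#' @param cases EMS case records with `staff` and `suspicion_documented`.
#' @param staff `"PM"`, `"EP"`, or `"all"`.
#' @return list: `n_cases` (suspicions), `n_total`, `estimate`, `lower`,
#'   `upper`.
#' @export
#' @examples
#' cs <- data.frame(staff = c("EP", "EP"), suspicion_documented = c(TRUE, FALSE))
#' suspicion_rate(cs, "EP")
suspicion_rate <- function(cases, staff = c("all", "PM", "EP")) {
  staff <- match.arg(staff)
  sub <- if (staff == "all") cases else cases[cases$staff == staff, , drop = FALSE]
  n <- nrow(sub)
  if (n == 0L) fail("empty staff stratum `%s`", staff)
  k <- sum(sub$suspicion_documented)
  ci <- wilson_ci(k, n)
  list(n_cases = k, n_total = n, estimate = k / n,
       lower = unname(ci["lower"]), upper = unname(ci["upper"]))
}
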