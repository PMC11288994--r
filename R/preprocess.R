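#' Transform medically implausible values to missing
#'
#' Applies the plausibility ranges to every vital column found in `x` —
#' either plain columns (`rr`, `temp`, ...) or two-slot columns (`rr_1`,
#' `rr_2`, ...). Out-of-range values become `NA`; in-range values are
#' untouched, so the filter is idempotent. Unknown consciousness codes are
#' also cleared. The number of replacements per column is recorded in the
#' `"plausibility_log"` attribute.
#'
#' @param x data frame of EMS case records or vitals.
#' @param ranges plausibility ranges, see [default_plausibility()].
#' @return `x` with implausible entries set to `NA`.
#' @export
#' @examples
#' v <- vital_set(temp = c(36.9, 12), spo2 = c(101, 100))
#' plausibility_filter(v)
plausibility_filter <- function(x, ranges = default_plausibility()) {
  log <- integer(0)
  for (v in NUMERIC_VITALS) {
    for (col in intersect(c(v, slot_col(v, 1), slot_col(v, 2)), names(x))) {
      vals <- x[[col]]
      rng <- ranges[[v]]
      bad <- !is.na(vals) & (vals < rng[1] | vals > rng[2])
      if (v == "gcs") bad <- bad | (!is.na(vals) & vals != round(vals))
      if (any(bad)) x[[col]][bad] <- NA_real_
      log[col] <- sum(bad)
    }
  }
  for (col in intersect(c("consciousness", slot_col("consciousness", 1),
                          slot_col("consciousness", 2)), names(x))) {
    vals <- x[[col]]
    bad <- !is.na(vals) & !vals %in% CONSC_LEVELS
    if (any(bad)) x[[col]][bad] <- NA_character_
    log[col] <- sum(bad)
  }
  structure(x, plausibility_log = log)
}

#' Resolve the two assessment slots into one analysis value per vital
#'
#' A vital is considered documented if either of the two assessments during
#' EMS care carries a value. By default the first assessment takes
#' precedence when both are present (first-contact values are the
#' screening-relevant ones); `precedence = "worst"` instead picks, per
#' vital, the slot value scoring more NEWS2 points (ties go to the first
#' slot). Provenance (`<vital>_src`: `"first"`, `"second"` or `"missing"`)
#' is recorded per vital.
#'
#' @param cases EMS case records with `<vital>_1` / `<vital>_2` columns,
#'   already plausibility-filtered.
#' @param precedence `"first"` (default) or `"worst"`.
#' @param tables score tables (used only by `"worst"`).
#' @return data frame of resolved vitals: identifier/demographic columns
#'   carried through, one column per vital plus `<vital>_src`.
#' @export
resolve_assessment <- function(cases, precedence = c("first", "worst"),
                               tables = default_score_tables()) {
  precedence <- match.arg(precedence)
  carry <- intersect(c("case_id", "age", "sex", "staff", "transported",
                       "suspicion_documented"), names(cases))
  out <- cases[, carry, drop = FALSE]
  for (v in VITALS) {
    v1 <- cases[[slot_col(v, 1)]]
    v2 <- cases[[slot_col(v, 2)]]
    if (is.null(v1) || is.null(v2)) fail("cases lack slot columns for `%s`", v)
    use_second <- is.na(v1) & !is.na(v2)
    if (precedence == "worst") {
      both <- !is.na(v1) & !is.na(v2)
      if (any(both)) {
        p1 <- news2_component_points(v, v1[both], tables)
        p2 <- news2_component_points(v, v2[both], tables)
        use_second[both] <- p2 > p1
      }
    }
    val <- ifelse(use_second, v2, v1)
    # ifelse() drops types; restore
    if (is.logical(v1)) val <- as.logical(val)
    out[[v]] <- val
    out[[paste0(v, "_src")]] <- ifelse(is.na(val), "missing",
                                ifelse(use_second, "second", "first"))
  }
  out
}

# NEWS2 points for one vital (gcs scored via the qSOFA mentation rule),
# used to decide which slot is "worse"
news2_component_points <- function(vital, values, tables) {
  if (vital == "gcs") return(ifelse(values < 15, 1, 0))
  for (comp in tables$news2$components) {
    if (comp$vital == vital) return(lookup_points(comp, values))
  }
  rep(0, length(values))
}

#' Map the Glasgow Coma Scale onto ACVPU
#'
#' Default convention: 15 is alert (A); 13-14 responds to voice (V); 9-12
#' responds to pain (P); 8 and below unresponsive (U). "C" (new confusion)
#' is never auto-derived — it can only come from documented data. The
#' mapping is a convention, not a validated crosswalk, and is overridable.
#'
#' @param gcs integer vector, 3-15 or `NA`.
#' @param cuts named integer vector giving the minimum GCS for `A`, `V`
#'   and `P` (everything below `P`'s minimum is `U`).
#' @return character vector of ACVPU categories.
#' @export
#' @examples
#' gcs_to_acvpu(c(15, 14, 10, 7))
gcs_to_acvpu <- function(gcs, cuts = c(A = 15, V = 13, P = 9)) {
  out <- rep(NA_character_, length(gcs))
  out[!is.na(gcs) & gcs >= cuts["A"]] <- "A"
  out[!is.na(gcs) & gcs < cuts["A"] & gcs >= cuts["V"]] <- "V"
  out[!is.na(gcs) & gcs < cuts["V"] & gcs >= cuts["P"]] <- "P"
  out[!is.na(gcs) & gcs < cuts["P"]] <- "U"
  out
}

#' Fill undocumented consciousness from the GCS
#'
#' A documented consciousness category always wins; where it is missing but
#' a GCS is documented, the category is derived via [gcs_to_acvpu()]
#' (provenance `"derived-gcs"`); otherwise it stays missing.
#'
#' @param resolved resolved vitals from [resolve_assessment()].
#' @param cuts mapping cut-offs, see [gcs_to_acvpu()].
#' @return `resolved` with consciousness filled where derivable.
#' @export
derive_consciousness <- function(resolved, cuts = c(A = 15, V = 13, P = 9)) {
  idx <- is.na(resolved$consciousness) & !is.na(resolved$gcs)
  if (any(idx)) {
    resolved$consciousness[idx] <- gcs_to_acvpu(resolved$gcs[idx], cuts)
    if ("consciousness_src" %in% names(resolved)) {
      resolved$consciousness_src[idx] <- "derived-gcs"
    }
  }
  resolved
}

#' Reference value tables for imputation strategies
#'
#' `normal_values()` returns clinically normal values that score zero
#' points in all four instruments (verified at load: a fully "normal"
#' record has qSOFA = SIRS = MEWS = NEWS2 = 0). `worst_values()` returns
#' values attaining the maximal point row of every instrument's table
#' simultaneously (e.g. a respiratory rate of 40 scores 3 in NEWS2 and
#' MEWS and 1 in qSOFA and SIRS).
#'
#' @param tables score tables used for the zero/maximal-score verification.
#' @return named list of one value per vital.
#' @export
#' @examples
#' normal_values()$temp
normal_values <- function(tables = default_score_tables()) {
  # rr = 12, not 16: MEWS awards 1 point for a respiratory rate of 15-20,
  # so 16 would violate the zero-score invariant
  nv <- list(rr = 12, spo2 = 98, on_oxygen = FALSE, sbp = 120, hr = 75,
             temp = 37.0, gcs = 15, consciousness = "A")
  df <- as.data.frame(nv, stringsAsFactors = FALSE)
  for (tool in TOOLS) {
    if (compute_score(df, tool, tables) != 0L) {
      fail("normal-value table scores non-zero in %s", tool)
    }
  }
  nv
}

#' @rdname normal_values
#' @export
worst_values <- function(tables = default_score_tables()) {
  wv <- list(rr = 40, spo2 = 85, on_oxygen = TRUE, sbp = 60, hr = 140,
             temp = 34.0, gcs = 3, consciousness = "U")
  df <- as.data.frame(wv, stringsAsFactors = FALSE)
  for (tool in TOOLS) {
    if (compute_score(df, tool, tables) != tables[[tool]]$max_score) {
      fail("worst-value table does not attain the maximum in %s", tool)
    }
  }
  wv
}

#' Apply a missing-data strategy to resolved vitals
#'
#' Four strategies for the vitals that remain undocumented after slot
#' resolution:
#'
#' * `complete_case` — impute nothing; downstream scoring returns an
#'   undefined score for any tool with a missing required input.
#' * `missing_as_normal` — substitute the zero-scoring normal values
#'   ([normal_values()]); by construction this can only lower scores, so
#'   sensitivities under this strategy bound the others from below.
#' * `hotdeck` — seeded stratified hot-deck: each missing value is drawn
#'   from the documented values of donors in the same age band x staff
#'   stratum (outcome-blind). An empty donor stratum falls back to the
#'   global donor pool with a warning.
#' * `missing_as_worst` — substitute the maximal-scoring values
#'   ([worst_values()]).
#'
#' Provenance columns are updated to `imputed-<strategy>` for every filled
#' cell. Apart from `complete_case` the result has no missing vitals.
#'
#' @param resolved resolved vitals from [resolve_assessment()] (after
#'   [derive_consciousness()]).
#' @param strategy one of `"complete_case"`, `"missing_as_normal"`,
#'   `"hotdeck"`, `"missing_as_worst"`.
#' @param seed integer seed for the hot-deck draws.
#' @param age_breaks age band boundaries for the hot-deck strata.
#' @param tables score tables (for the normal/worst value verification).
#' @return `resolved` with the strategy applied; attribute `"strategy"`
#'   records the name.
#' @export
apply_missing_strategy <- function(resolved,
                                   strategy = c("complete_case", "missing_as_normal",
                                                "hotdeck", "missing_as_worst"),
                                   seed = 1L,
                                   age_breaks = c(18, 45, 65, 80, Inf),
                                   tables = default_score_tables()) {
  strategy <- match.arg(strategy)
  if (strategy == "complete_case") {
    attr(resolved, "strategy") <- strategy
    return(resolved)
  }
  fill <- switch(strategy,
    missing_as_normal = normal_values(tables),
    missing_as_worst  = worst_values(tables),
    hotdeck           = NULL)
  if (strategy == "hotdeck") {
    set.seed(seed)
    band <- cut(resolved$age %||% rep(50, nrow(resolved)),
                breaks = age_breaks, right = FALSE, include.lowest = TRUE)
    stratum <- interaction(band, resolved$staff %||% "all", drop = FALSE)
  }
  for (v in VITALS) {
    miss <- is.na(resolved[[v]])
    if (!any(miss)) next
    if (strategy == "hotdeck") {
      donors_all <- resolved[[v]][!miss]
      if (length(donors_all) == 0L) {
        fail("hotdeck: no documented donor values at all for `%s`", v)
      }
      for (s in levels(stratum)) {
        idx <- miss & stratum == s
        if (!any(idx)) next
        donors <- resolved[[v]][!miss & stratum == s]
        if (length(donors) == 0L) {
          warning(sprintf("hotdeck: empty donor stratum %s for `%s`; using global pool", s, v),
                  call. = FALSE)
          donors <- donors_all
        }
        resolved[[v]][idx] <- donors[sample.int(length(donors), sum(idx), replace = TRUE)]
      }
    } else {
      resolved[[v]][miss] <- fill[[v]]
    }
    src <- paste0(v, "_src")
    if (src %in% names(resolved)) {
      resolved[[src]][miss] <- paste0("imputed-", strategy)
    }
  }
  attr(resolved, "strategy") <- strategy
  resolved
}

#' One-call preprocessing: filter, resolve, derive, impute
#'
#' Chains [plausibility_filter()], [resolve_assessment()],
#' [derive_consciousness()] and [apply_missing_strategy()].
#'
#' @inheritParams resolve_assessment
#' @inheritParams apply_missing_strategy
#' @param ranges plausibility ranges.
#' @return resolved vitals ready for [score_panel()].
#' @export
preprocess_cases <- function(cases, strategy = "hotdeck", seed = 1L,
                             precedence = "first",
                             ranges = default_plausibility(),
                             tables = default_score_tables()) {
  cases <- plausibility_filter(cases, ranges)
  resolved <- resolve_assessment(cases, precedence, tables)
  resolved <- derive_consciousness(resolved)
  apply_missing_strategy(resolved, strategy, seed = seed, tables = tables)
}
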