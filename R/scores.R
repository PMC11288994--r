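#' Construct a set of vital sign values
#'
#' Convenience constructor for a one-row (or vectorized) data frame of the
#' eight vitals used by the screening instruments. Unspecified vitals are
#' missing.
#'
#' @param rr respiratory rate, breaths/min.
#' @param spo2 peripheral oxygen saturation, percent.
#' @param on_oxygen logical, supplemental oxygen in use.
#' @param sbp systolic blood pressure, mmHg.
#' @param hr heart rate, beats/min.
#' @param temp body temperature, degrees Celsius.
#' @param gcs Glasgow Coma Scale, integer 3-15.
#' @param consciousness ACVPU category, one of `"A","C","V","P","U"`.
#' @return data frame with one column per vital.
#' @export
#' @examples
#' vital_set(rr = 24, sbp = 95, gcs = 13)
vital_set <- function(rr = NA_real_, spo2 = NA_real_, on_oxygen = NA,
                      sbp = NA_real_, hr = NA_real_, temp = NA_real_,
                      gcs = NA_real_, consciousness = NA_character_) {
  if (!all(is.na(consciousness) | consciousness %in% CONSC_LEVELS)) {
    fail("consciousness must be one of %s", paste(CONSC_LEVELS, collapse = ","))
  }
  data.frame(rr = rr, spo2 = spo2, on_oxygen = as.logical(on_oxygen),
             sbp = sbp, hr = hr, temp = temp, gcs = gcs,
             consciousness = as.character(consciousness),
             stringsAsFactors = FALSE)
}

# interval lookup over lower bounds; values below the first bound are an
# error upstream (plausibility filtering guarantees coverage)
lookup_points <- function(comp, values) {
  if (comp$type == "interval") {
    x <- quantize_vital(comp$vital, values)
    idx <- findInterval(x, comp$lower)
    below <- !is.na(x) & idx == 0L
    if (any(below)) {
      fail("%s value %s below plausibility range; run plausibility_filter() first",
           comp$vital, format(min(x[below])))
    }
    pts <- comp$points[idx]
    pts[is.na(x)] <- NA_real_
    pts
  } else if (comp$type == "category") {
    as.numeric(comp$points[match(values, names(comp$points))])
  } else { # binary
    ifelse(is.na(values), NA_real_, ifelse(as.logical(values), comp$points, 0))
  }
}

compute_score <- function(vitals, tool, tables = default_score_tables(),
                          on_missing = c("error", "na")) {
  on_missing <- match.arg(on_missing)
  tab <- tables[[tool]]
  if (is.null(tab)) fail("unknown screening tool `%s`", tool)
  n <- nrow(vitals)
  total <- numeric(n)
  missing_any <- rep(FALSE, n)
  for (comp in tab$components) {
    values <- vitals[[comp$vital]]
    if (is.null(values)) fail("input lacks a `%s` column required by %s", comp$vital, tool)
    if (!is.null(comp$fallback) && anyNA(values)) {
      # qSOFA mentation: fall back on the consciousness category when the
      # GCS is undocumented (altered mentation iff not alert)
      fb <- vitals[[comp$fallback]]
      if (!is.null(fb)) {
        idx <- is.na(values) & !is.na(fb)
        values[idx] <- ifelse(fb[idx] == "A", 15, 3)
      }
    }
    pts <- lookup_points(comp, values)
    if (on_missing == "error" && anyNA(pts)) {
      fail("cannot compute %s: missing `%s` in %d case(s); apply a missing-data strategy first",
           tool, comp$vital, sum(is.na(pts)))
    }
    missing_any <- missing_any | is.na(pts)
    pts[is.na(pts)] <- 0
    total <- total + pts
  }
  total[missing_any] <- NA_real_
  as.integer(total)
}

#' Screening score calculators
#'
#' Compute the prehospital-adapted screening scores for each row of a
#' vitals table (one resolved value per vital; see [resolve_assessment()]
#' and [apply_missing_strategy()]).
#'
#' * `score_qsofa()`: respiratory rate >= 22, systolic blood pressure
#'   <= 100, altered mentation (GCS < 15, or consciousness not "A" when the
#'   GCS is undocumented); range 0-3.
#' * `score_sirs()`: temperature > 38.0 or < 36.0, heart rate > 90,
#'   respiratory rate > 20; leukocyte count and paCO2 omitted (not
#'   available prehospital); range 0-3.
#' * `score_mews()`: systolic pressure, heart rate, respiratory rate,
#'   temperature and AVPU; urine output omitted; range 0-14.
#' * `score_news2()`: respiratory rate, SpO2 (scale 1), supplemental
#'   oxygen, systolic pressure, heart rate, consciousness (ACVPU) and
#'   temperature; range 0-20.
#'
#' @param vitals data frame with one column per vital (see [vital_set()]).
#' @param tables score tables from [load_score_tables()].
#' @param on_missing `"error"` (default) fails naming the missing vital;
#'   `"na"` returns an undefined score for affected rows (complete-case
#'   analysis).
#' @return integer vector of scores, `NA` where undefined.
#' @export
#' @examples
#' score_qsofa(vital_set(rr = 24, sbp = 95, gcs = 13))  # 3
#' score_news2(vital_set(rr = 16, spo2 = 97, on_oxygen = FALSE, sbp = 120,
#'                       hr = 75, temp = 37, consciousness = "A"))  # 0
score_qsofa <- function(vitals, tables = default_score_tables(),
                        on_missing = c("error", "na")) {
  compute_score(vitals, "qsofa", tables, on_missing)
}

#' @rdname score_qsofa
#' @export
score_sirs <- function(vitals, tables = default_score_tables(),
                       on_missing = c("error", "na")) {
  compute_score(vitals, "sirs", tables, on_missing)
}

#' @rdname score_qsofa
#' @export
score_mews <- function(vitals, tables = default_score_tables(),
                       on_missing = c("error", "na")) {
  compute_score(vitals, "mews", tables, on_missing)
}

#' @rdname score_qsofa
#' @export
score_news2 <- function(vitals, tables = default_score_tables(),
                        on_missing = c("error", "na")) {
  compute_score(vitals, "news2", tables, on_missing)
}

#' Dichotomize a score at the tool's recommended threshold
#'
#' Positivity thresholds: qSOFA >= 2, SIRS >= 2, MEWS >= 4, NEWS2 >= 5.
#'
#' @param tool one of `"qsofa"`, `"sirs"`, `"mews"`, `"news2"`.
#' @param score integer score vector (`NA` allowed: undefined stays `NA`).
#' @param tables score tables from [load_score_tables()].
#' @return logical vector: positive screening result.
#' @export
#' @examples
#' screen_positive("mews", 3:5)
screen_positive <- function(tool, score, tables = default_score_tables()) {
  tab <- tables[[tool]]
  if (is.null(tab)) fail("unknown screening tool `%s`", tool)
  score >= tab$threshold
}

#' Score panel: all four tools for every case
#'
#' Computes the four scores and their positivity flags for each row of a
#' resolved vitals table. Under the complete-case strategy rows with a
#' missing required vital get an undefined (`NA`) score and flag for the
#' affected tool only; every other strategy must have removed all
#' missingness, so an unexpected `NA` is an error.
#'
#' @param resolved resolved vitals (see [apply_missing_strategy()]), with a
#'   `case_id` column.
#' @param strategy character label recorded in the output (the missing-data
#'   strategy that produced `resolved`).
#' @param tables score tables from [load_score_tables()].
#' @return data frame: `case_id`, `strategy`, `<tool>` score and
#'   `<tool>_pos` flag per tool.
#' @export
score_panel <- function(resolved, strategy = attr(resolved, "strategy") %||% "unknown",
                        tables = default_score_tables()) {
  on_missing <- if (identical(strategy, "complete_case")) "na" else "error"
  out <- data.frame(case_id = resolved$case_id %||% seq_len(nrow(resolved)),
                    strategy = strategy, stringsAsFactors = FALSE)
  for (tool in TOOLS) {
    sc <- compute_score(resolved, tool, tables, on_missing)
    out[[tool]] <- sc
    out[[paste0(tool, "_pos")]] <- screen_positive(tool, sc, tables)
  }
  out
}
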