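#' Default plausibility ranges for prehospital vital signs
#'
#' Closed intervals of medically acceptable values. Values outside these
#' ranges are treated as documentation errors and transformed to missing
#' by [plausibility_filter()]. The defaults are deliberately wide (they
#' bound what a monitor could plausibly read, not what is clinically
#' normal) and can be overridden per vital.
#'
#' @param ... named length-2 numeric vectors overriding individual ranges,
#'   e.g. `temp = c(30, 43)`.
#' @return named list of `c(lower, upper)` ranges for `temp`, `rr`, `hr`,
#'   `sbp`, `spo2` and `gcs`.
#' @export
#' @examples
#' default_plausibility()$temp
default_plausibility <- function(...) {
  ranges <- list(
    temp = c(25, 45),
    rr   = c(1, 80),
    hr   = c(10, 280),
    sbp  = c(40, 320),
    spo2 = c(40, 100),
    gcs  = c(3, 15)
  )
  override <- list(...)
  for (nm in names(override)) {
    r <- override[[nm]]
    if (!nm %in% names(ranges)) fail("unknown vital `%s` in plausibility override", nm)
    if (!is.numeric(r) || length(r) != 2L || r[1] >= r[2]) {
      fail("plausibility range for `%s` must be c(lower, upper) with lower < upper", nm)
    }
    ranges[[nm]] <- r
  }
  ranges
}

# quantize before table lookup: integers for counts/pressures, one decimal
# for temperature (avoids float ambiguity at cut-offs such as 38.05)
quantize_vital <- function(vital, x) {
  if (vital == "temp") round_half_up(x, 1) else round_half_up(x, 0)
}

#' Load and validate the screening score tables
#'
#' Reads the versioned JSON definition of the four prehospital-adapted
#' instruments (qSOFA, SIRS, MEWS, NEWS2): per tool an ordered list of
#' components mapping value intervals (or consciousness categories, or the
#' supplemental-oxygen flag) to integer points, the omitted in-hospital
#' variables, and the positivity threshold (qSOFA and SIRS >= 2, MEWS >= 4,
#' NEWS2 >= 5). Interval coverage of the plausibility range, disjointness
#' (bounds strictly increasing), non-negative points and the stated score
#' maxima are all verified at load; a malformed table is an error, not a
#' silently wrong score.
#'
#' @param path path to a score-table JSON file; defaults to the table
#'   shipped with the package.
#' @param ranges plausibility ranges from [default_plausibility()]; interval
#'   components must start at the range's lower bound.
#' @return a validated score-table list, one element per tool.
#' @export
#' @examples
#' tabs <- load_score_tables()
#' tabs$news2$threshold
load_score_tables <- function(path = NULL,
                              ranges = default_plausibility()) {
  path <- path %||% system.file("extdata", "score_tables.json",
                                package = "sepsiscreen", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  tools <- raw$tools
  if (is.null(tools) || !all(TOOLS %in% names(tools))) {
    fail("score-table file must define tools: %s", paste(TOOLS, collapse = ", "))
  }
  out <- lapply(names(tools), function(tn) {
    tool <- tools[[tn]]
    thr <- tool$threshold
    if (!is.numeric(thr) || thr < 1) fail("%s: threshold must be >= 1", tn)
    comps <- lapply(tool$components, function(comp) {
      comp$points <- if (comp$type == "category") {
        unlist(comp$points)
      } else {
        as.numeric(unlist(comp$points))
      }
      comp$lower <- as.numeric(unlist(comp$lower))
      validate_component(tn, comp, ranges)
      comp
    })
    maxima <- vapply(comps, function(comp) max(unlist(comp$points)), numeric(1))
    if (sum(maxima) != tool$max_score) {
      fail("%s: component maxima sum to %d, stated max_score is %d",
           tn, sum(maxima), tool$max_score)
    }
    list(label = tool$label %||% tn, threshold = as.integer(thr),
         max_score = as.integer(tool$max_score), components = comps,
         omitted = unlist(tool$omitted))
  })
  names(out) <- names(tools)
  structure(out, class = "score_tables",
            schema_version = raw$schema_version, source = path)
}

validate_component <- function(tool, comp, ranges) {
  if (any(unlist(comp$points) < 0)) fail("%s/%s: negative points", tool, comp$vital)
  if (comp$type == "interval") {
    lo <- comp$lower
    if (length(lo) != length(comp$points)) {
      fail("%s/%s: %d interval bounds vs %d point values",
           tool, comp$vital, length(lo), length(comp$points))
    }
    if (any(diff(lo) <= 0)) fail("%s/%s: interval bounds must strictly increase (disjointness)", tool, comp$vital)
    rng <- ranges[[comp$vital]]
    if (is.null(rng)) fail("%s/%s: no plausibility range for vital", tool, comp$vital)
    if (lo[1] != rng[1]) {
      fail("%s/%s: intervals start at %s, plausibility range starts at %s (coverage)",
           tool, comp$vital, lo[1], rng[1])
    }
    if (lo[length(lo)] > rng[2]) fail("%s/%s: last interval beyond plausibility range", tool, comp$vital)
  } else if (comp$type == "category") {
    if (!setequal(names(comp$points), CONSC_LEVELS)) {
      fail("%s/%s: category points must cover levels %s",
           tool, comp$vital, paste(CONSC_LEVELS, collapse = ","))
    }
  } else if (comp$type == "binary") {
    if (length(comp$points) != 1L) fail("%s/%s: binary component needs a single point value", tool, comp$vital)
  } else {
    fail("%s/%s: unknown component type `%s`", tool, comp$vital, comp$type)
  }
  invisible(TRUE)
}

# memoised default table
the <- new.env(parent = emptyenv())

default_score_tables <- function() {
  if (is.null(the$tables)) the$tables <- load_score_tables()
  the$tables
}

# vitals a tool needs (consciousness fallback makes gcs OR consciousness
# acceptable for qSOFA; both count as the mentation input)
tool_required_vitals <- function(tool, tables = default_score_tables()) {
  vapply(tables[[tool]]$components, function(comp) comp$vital, character(1))
}
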