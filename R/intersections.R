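#' Partition cases by the combination of tools that flagged them
#'
#' Every case falls into exactly one of the 16 subsets of
#' {qSOFA, SIRS, MEWS, NEWS2} according to which tools screened it
#' positive. Counts and percentages are reported for all cases and,
#' separately, among the true sepsis cases (the true-positive partition).
#' Cases with any undefined flag are an error: the missing-data strategy
#' must resolve flags first (under complete-case, exclude such cases from
#' the intersection analysis entirely for consistent denominators).
#'
#' @param flags data frame / matrix of four logical columns named
#'   `qsofa_pos`, `sirs_pos`, `mews_pos`, `news2_pos` (or bare tool names).
#' @param labels logical vector of sepsis labels, same length.
#' @return object of class `combination_partition`: 16-row data frame with
#'   one logical column per tool, `n`, `pct`, `n_sepsis`, `pct_sepsis`.
#' @export
#' @examples
#' f <- data.frame(qsofa_pos = c(TRUE, FALSE), sirs_pos = FALSE,
#'                 mews_pos = FALSE, news2_pos = c(TRUE, FALSE))
#' combination_counts(f, labels = c(TRUE, FALSE))
combination_counts <- function(flags, labels) {
  flags <- normalize_flags(flags)
  if (anyNA(flags)) fail("undefined screening flags; resolve the missing-data strategy first")
  if (length(labels) != nrow(flags)) fail("`labels` length does not match `flags`")
  if (anyNA(labels)) fail("`labels` contain missing entries")
  grid <- expand.grid(qsofa = c(FALSE, TRUE), sirs = c(FALSE, TRUE),
                      mews = c(FALSE, TRUE), news2 = c(FALSE, TRUE))
  key <- function(m) m[, 1] + 2 * m[, 2] + 4 * m[, 3] + 8 * m[, 4]
  case_key <- key(flags)
  n_all <- tabulate(case_key + 1L, nbins = 16L)
  n_sep <- tabulate(case_key[labels] + 1L, nbins = 16L)
  n_total <- nrow(flags)
  n_sepsis <- sum(labels)
  out <- cbind(grid,
               n = n_all,
               pct = if (n_total > 0) 100 * n_all / n_total else rep(NA_real_, 16),
               n_sepsis = n_sep,
               pct_sepsis = if (n_sepsis > 0) 100 * n_sep / n_sepsis else rep(NA_real_, 16))
  structure(out, class = c("combination_partition", "data.frame"),
            n_total = n_total, n_sepsis = n_sepsis)
}

normalize_flags <- function(flags) {
  flags <- as.data.frame(flags)
  want <- paste0(TOOLS, "_pos")
  if (all(want %in% names(flags))) flags <- flags[, want]
  else if (all(TOOLS %in% names(flags))) flags <- flags[, TOOLS]
  else if (ncol(flags) == 4L) names(flags) <- TOOLS
  else fail("`flags` must provide one logical column per tool (%s)", paste(TOOLS, collapse = ", "))
  names(flags) <- TOOLS
  for (tool in TOOLS) flags[[tool]] <- as.logical(flags[[tool]])
  flags
}

#' Cases uniquely flagged by a single tool
#'
#' @param partition a [combination_counts()] result.
#' @param tool tool name.
#' @return list: `n`, `pct` (of all cases), `n_sepsis`, `pct_sepsis`
#'   (share of sepsis cases predicted only by this tool).
#' @export
unique_to_tool <- function(partition, tool) {
  if (!tool %in% TOOLS) fail("unknown screening tool `%s`", tool)
  idx <- partition[[tool]] & rowSums(partition[, TOOLS]) == 1
  row <- partition[idx, ]
  list(n = row$n, pct = row$pct, n_sepsis = row$n_sepsis, pct_sepsis = row$pct_sepsis)
}

#' Combined any/all screening rules
#'
#' `"any"`: positive if at least one of the four tools flags the case
#' (logical OR); `"all"`: positive only if all four do (logical AND).
#'
#' @param flags four logical columns, one per tool.
#' @param mode `"any"` or `"all"`.
#' @return logical vector, one entry per case.
#' @export
#' @examples
#' combined_rule(data.frame(q = TRUE, s = FALSE, m = FALSE, n = FALSE), "any")
combined_rule <- function(flags, mode = c("any", "all")) {
  mode <- match.arg(mode)
  flags <- normalize_flags(flags)
  m <- as.matrix(flags)
  if (mode == "any") rowSums(m) > 0 else rowSums(m) == 4L
}
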