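# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial ("half-up") rounding to a fixed number of decimals, used for
#' report formatting and for quantizing vital signs before score-table
#' lookup. Base `round()` rounds half to even, which makes clinical
#' cut-offs such as a temperature of 38.05 ambiguous.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 38.05), c(0, 0, 1))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop() without the call, with sprintf-style formatting
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    fail("`%s` must be a single number in [0, 1] (got %s)",
         field, paste(format(x), collapse = ", "))
  }
  invisible(x)
}

# vital sign keys used throughout the package
VITALS <- c("rr", "spo2", "on_oxygen", "sbp", "hr", "temp", "gcs",
            "consciousness")
# the seven documentation-completeness variables (supplemental oxygen is
# documented together with oxygen saturation)
DOC_VARS <- c("temp", "rr", "gcs", "spo2", "sbp", "hr", "consciousness")
NUMERIC_VITALS <- c("rr", "spo2", "sbp", "hr", "temp", "gcs")
CONSC_LEVELS <- c("A", "C", "V", "P", "U")
TOOLS <- c("qsofa", "sirs", "mews", "news2")

slot_col <- function(vital, slot) paste0(vital, "_", slot)
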