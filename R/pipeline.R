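#' Load and validate a pipeline configuration
#'
#' The configuration is JSON with a `cohort` block (fields of
#' [cohort_config()]; `doc_rates` and `fatality` as nested maps), an
#' optional `strategies` array (missing-data strategies to analyse), an
#' optional slot `precedence`, and an optional top-level `seed` overriding
#' the cohort seed. Validation failures name the offending field.
#'
#' @param path path to a JSON configuration file; `NULL` gives defaults.
#' @return list with `cohort` (a validated [cohort_config()]),
#'   `strategies` and `precedence`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) fail("configuration file `%s` not found", path)
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cohort_args <- raw$cohort %||% list()
  if (!is.null(cohort_args$doc_rates)) {
    cohort_args$doc_rates <- lapply(cohort_args$doc_rates, unlist)
  }
  if (!is.null(cohort_args$fatality)) {
    cohort_args$fatality <- lapply(cohort_args$fatality, unlist)
  }
  if (!is.null(cohort_args$severity_shift)) {
    cohort_args$severity_shift <- as.list(unlist(cohort_args$severity_shift))
  }
  if (!is.null(cohort_args$vital_params)) {
    cohort_args$vital_params <- lapply(cohort_args$vital_params, unlist)
  }
  if (!is.null(cohort_args$suspicion_rates)) {
    cohort_args$suspicion_rates <- unlist(cohort_args$suspicion_rates)
  }
  if (!is.null(raw$seed)) cohort_args$seed <- raw$seed
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(cohort_args), known)
  if (length(unknown)) fail("unknown configuration field(s): %s", paste(unknown, collapse = ", "))
  cohort <- do.call(cohort_config, cohort_args)
  strategies <- raw$strategies %||% "hotdeck"
  strategies <- vapply(strategies, normalize_strategy, character(1), USE.NAMES = FALSE)
  precedence <- raw$precedence %||% "first"
  if (!precedence %in% c("first", "worst")) fail("`precedence` must be \"first\" or \"worst\"")
  list(cohort = cohort, strategies = strategies, precedence = precedence)
}

normalize_strategy <- function(s) {
  map <- c(complete_case = "complete_case", normal = "missing_as_normal",
           missing_as_normal = "missing_as_normal", hotdeck = "hotdeck",
           worst = "missing_as_worst", missing_as_worst = "missing_as_worst")
  out <- map[s]
  if (is.na(out)) fail("unknown missing-data strategy `%s`", s)
  unname(out)
}

summary_to_row <- function(summ) {
  stats::setNames(summ$estimate, summ$statistic)
}

#' Table of screening accuracy per tool and combined rule
#'
#' Flattens [evaluate_panel()] output into a report table (one column per
#' statistic, one row per rule), estimates as proportions.
#'
#' @param evaluation result of [evaluate_panel()].
#' @return data frame with a `rule` column and one column per statistic.
#' @export
accuracy_table <- function(evaluation) {
  rows <- lapply(names(evaluation), function(nm) {
    est <- summary_to_row(evaluation[[nm]])
    data.frame(rule = nm, t(est), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full synthetic screening study
#'
#' Simulates a cohort, preprocesses it under each requested missing-data
#' strategy, scores the four tools, evaluates their accuracy against the
#' inpatient sepsis label, partitions tool intersections, and computes the
#' cohort epidemiology. All outputs are CSV (plus a markdown report and a
#' JSON manifest) under `out_dir`; a rerun with the same configuration and
#' seed is bit-identical.
#'
#' @param config path to a JSON configuration, or a list as returned by
#'   [load_config()], or `NULL` for defaults.
#' @param out_dir output directory.
#' @param seed optional integer overriding the configured seed.
#' @param strategies optional character vector overriding the configured
#'   missing-data strategies.
#' @return invisibly, the list of written file paths.
#' @export
run_pipeline <- function(config = NULL, out_dir = "sepsiscreen-run",
                         seed = NULL, strategies = NULL) {
  cfg <- if (is.character(config) || is.null(config)) load_config(config) else config
  if (!is.null(seed)) cfg$cohort$seed <- as.integer(seed)
  if (!is.null(strategies)) {
    cfg$strategies <- vapply(strategies, normalize_strategy, character(1), USE.NAMES = FALSE)
  }
  validate_cohort_config(cfg$cohort)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    paths <<- c(paths, p)
    p
  }

  coh <- simulate_cohort(cfg$cohort)
  write_cohort(coh, out_dir, cfg$cohort)
  paths <- c(paths, file.path(out_dir, c("cases.csv", "outcomes.csv", "manifest.json")))

  filtered <- plausibility_filter(coh$cases)
  report <- c("# Synthetic prehospital sepsis screening study", "")

  # cohort epidemiology
  epi <- do.call(rbind, lapply(c("sepsis", "mi", "stroke"), function(cond) {
    inc <- incidence(coh$outcomes, cond)
    cfh <- case_fatality(coh$outcomes, cond, "hospital")
    cf30 <- case_fatality(coh$outcomes, cond, "30d")
    data.frame(condition = cond, n = inc$n_cases,
               incidence = inc$estimate, incidence_lower = inc$lower,
               incidence_upper = inc$upper,
               cfr_hospital = cfh$estimate, cfr_30d = cf30$estimate,
               stringsAsFactors = FALSE)
  }))
  emit(epi, "epidemiology.csv")
  comp_staff <- completeness_table(filtered, "staff")
  emit(comp_staff, "completeness_by_staff.csv")
  comp_sep <- completeness_table(filtered, "sepsis_label", coh$outcomes)
  emit(comp_sep, "completeness_by_sepsis.csv")
  susp <- do.call(rbind, lapply(c("all", "PM", "EP"), function(s) {
    r <- suspicion_rate(coh$cases, s)
    data.frame(staff = s, suspicions = r$n_cases, n = r$n_total,
               rate = r$estimate, lower = r$lower, upper = r$upper)
  }))
  emit(susp, "suspicion_rates.csv")
  report <- c(report, "## Cohort epidemiology",
              md_table(round_df(epi, 4)), "",
              "## Sepsis suspicion by staff", md_table(round_df(susp, 4)), "")

  for (strategy in cfg$strategies) {
    resolved <- preprocess_cases(filtered, strategy = strategy,
                                 seed = cfg$cohort$seed + 10L,
                                 precedence = cfg$precedence)
    panel <- score_panel(resolved)
    emit(panel, sprintf("panel_%s.csv", strategy))
    evaluation <- evaluate_panel(panel, coh$outcomes)
    acc <- accuracy_table(evaluation)
    emit(acc, sprintf("accuracy_%s.csv", strategy))
    flags4 <- panel[, paste0(TOOLS, "_pos")]
    keep <- stats::complete.cases(flags4)
    labels <- coh$outcomes$sepsis[match(panel$case_id, coh$outcomes$case_id)]
    part <- combination_counts(flags4[keep, , drop = FALSE], labels[keep])
    emit(as.data.frame(part), sprintf("intersections_%s.csv", strategy))
    report <- c(report,
                sprintf("## Screening accuracy (strategy: %s)", strategy),
                md_table(round_df(acc, 4)), "")
  }
  report_path <- file.path(out_dir, "report.md")
  writeLines(report, report_path)
  paths <- c(paths, report_path)
  invisible(paths)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round_half_up, digits = digits)
  df
}

md_table <- function(df) {
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

# ---- command-line interface -------------------------------------------------

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) fail("unexpected argument `%s`", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      opts[[key]] <- TRUE; i <- i + 1L
    } else {
      opts[[key]] <- args[[i + 1L]]; i <- i + 2L
    }
  }
  opts
}

read_resolved_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  if ("on_oxygen" %in% names(df)) df$on_oxygen <- as.logical(df$on_oxygen)
  df
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `preprocess`, `score`, `evaluate`, `intersect`,
#' `cohort-stats`, `run`. Common flags: `--config <json>`, `--seed <int>`,
#' `--missing-strategy {complete_case,normal,hotdeck,worst}`,
#' `--out-dir <dir>`. All tabular I/O is headered CSV, UTF-8, missing
#' values as empty fields. Invoke from a script as
#' `sepsiscreen_cli(commandArgs(trailingOnly = TRUE))`; errors signal a
#' condition (wrap in `tryCatch` to map onto a non-zero exit status).
#'
#' @param args character vector of command-line arguments.
#' @return invisibly, `0L` on success.
#' @export
sepsiscreen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) fail("usage: sepsiscreen <simulate|preprocess|score|evaluate|intersect|cohort-stats|run> [--flags]")
  cmd <- args[[1L]]
  opts <- parse_cli_args(args[-1L])
  out_dir <- opts[["out-dir"]] %||% "."
  seed <- if (!is.null(opts$seed)) as.integer(opts$seed) else NULL
  strategy <- if (!is.null(opts[["missing-strategy"]])) {
    normalize_strategy(opts[["missing-strategy"]])
  } else "hotdeck"

  switch(cmd,
    simulate = {
      cfg <- load_config(opts$config)
      if (!is.null(seed)) cfg$cohort$seed <- seed
      write_cohort(simulate_cohort(cfg$cohort), out_dir, cfg$cohort)
    },
    preprocess = {
      coh <- read_cohort(opts[["in-dir"]] %||% ".")
      resolved <- preprocess_cases(coh$cases, strategy = strategy,
                                   seed = seed %||% 1L)
      utils::write.csv(resolved, file.path(out_dir, sprintf("resolved_%s.csv", strategy)),
                       row.names = FALSE, na = "")
    },
    score = {
      resolved <- read_resolved_csv(opts[["in"]])
      panel <- score_panel(resolved, strategy = strategy)
      utils::write.csv(panel, opts[["out"]] %||% file.path(out_dir, "panel.csv"),
                       row.names = FALSE, na = "")
    },
    evaluate = {
      panel <- read_resolved_csv(opts[["panel"]])
      for (col in paste0(TOOLS, "_pos")) panel[[col]] <- as.logical(panel[[col]])
      outcomes <- utils::read.csv(opts[["outcomes"]], na.strings = "",
                                  stringsAsFactors = FALSE)
      acc <- accuracy_table(evaluate_panel(panel, outcomes))
      utils::write.csv(acc, opts[["out"]] %||% file.path(out_dir, "accuracy.csv"),
                       row.names = FALSE, na = "")
    },
    intersect = {
      panel <- read_resolved_csv(opts[["panel"]])
      for (col in paste0(TOOLS, "_pos")) panel[[col]] <- as.logical(panel[[col]])
      outcomes <- utils::read.csv(opts[["outcomes"]], na.strings = "",
                                  stringsAsFactors = FALSE)
      labels <- outcomes$sepsis[match(panel$case_id, outcomes$case_id)]
      flags4 <- panel[, paste0(TOOLS, "_pos")]
      keep <- stats::complete.cases(flags4)
      part <- combination_counts(flags4[keep, , drop = FALSE], labels[keep])
      utils::write.csv(as.data.frame(part),
                       opts[["out"]] %||% file.path(out_dir, "intersections.csv"),
                       row.names = FALSE, na = "")
    },
    `cohort-stats` = {
      coh <- read_cohort(opts[["in-dir"]] %||% ".")
      filtered <- plausibility_filter(coh$cases)
      utils::write.csv(completeness_table(filtered, "staff"),
                       file.path(out_dir, "completeness_by_staff.csv"),
                       row.names = FALSE, na = "")
    },
    run = {
      run_pipeline(opts$config, out_dir = out_dir, seed = seed,
                   strategies = if (!is.null(opts[["missing-strategy"]])) strategy)
    },
    fail("unknown subcommand `%s`", cmd)
  )
  invisible(0L)
}
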