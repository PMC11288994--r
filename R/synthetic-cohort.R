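#' Configuration for the synthetic EMS cohort generator
#'
#' Bundles every tunable of the generator with defaults encoding the
#' documentation structure the analysis assumes: per-variable documentation
#' rates by staff type, an inpatient sepsis prevalence of 78/4503 in the
#' linked adult cohort, vital sign distributions shifted in septic cases,
#' implausible-value contamination and mortality follow-up.
#'
#' @param n_cases number of EMS cases to generate.
#' @param sepsis_prevalence,mi_prevalence,stroke_prevalence label
#'   probabilities (labels are non-exclusive, as in claims data).
#' @param doc_rates named list, one entry per documentation variable
#'   (`temp`, `rr`, `gcs`, `spo2`, `sbp`, `hr`, `consciousness`), each a
#'   named vector `c(PM = , EP = )` of probabilities that at least one
#'   assessment slot is documented.
#' @param ep_fraction fraction of cases attended by emergency physicians
#'   (the rest by paramedics).
#' @param implausible_rate fraction of documented numeric values replaced
#'   by medically implausible ones.
#' @param severity_shift named list of additive mean shifts applied to the
#'   true vitals of septic cases (e.g. `rr = +8` breaths/min).
#' @param vital_params named list of `c(mean, sd)` for the non-septic
#'   truncated-normal vital distributions.
#' @param oxygen_prob,oxygen_prob_septic probability of supplemental oxygen.
#' @param confusion_prob,confusion_prob_septic probability that an alert
#'   patient is documented as newly confused ("C").
#' @param fatality named list per condition (`sepsis`, `mi`, `stroke`,
#'   `none`) of `c(hospital = , d30 = )` case-fatality probabilities, with
#'   `hospital <= d30`.
#' @param suspicion_rates named vector `c(PM = , EP = )`: probability that
#'   staff document a sepsis suspicion.
#' @param doc_correlation one-factor Gaussian-copula loading tying the
#'   seven documentation indicators together (0 = independent). The
#'   default 0.65 yields a joint all-seven-documented share near 8%, which
#'   independent missingness cannot reach.
#' @param missingness `"MCAR"` (default) or `"MAR"`; under MAR the
#'   documentation log-odds increase by `mar_strength` for septic cases.
#' @param mar_strength log-odds shift for MAR missingness.
#' @param exact_counts logical; draw exactly `round(prevalence * n)` sepsis
#'   labels instead of independent Bernoulli draws.
#' @param seed integer seed; identical configuration and seed give
#'   byte-identical cohorts.
#' @return validated `cohort_config` list.
#' @export
#' @examples
#' cfg <- cohort_config(n_cases = 100, seed = 7)
#' cfg$sepsis_prevalence
cohort_config <- function(n_cases = 4503,
                          sepsis_prevalence = 78 / 4503,
                          mi_prevalence = 0.026,
                          stroke_prevalence = 0.027,
                          doc_rates = default_doc_rates(),
                          ep_fraction = 3483 / 110419,
                          implausible_rate = 0.01,
                          severity_shift = list(rr = 8, spo2 = -6, sbp = -25,
                                                hr = 25, temp = 1.5, gcs = -3),
                          vital_params = list(rr = c(16, 4), spo2 = c(97, 2.5),
                                              sbp = c(135, 25), hr = c(85, 18),
                                              temp = c(36.8, 0.6), gcs = c(14.7, 1.0)),
                          oxygen_prob = 0.15, oxygen_prob_septic = 0.40,
                          confusion_prob = 0.02, confusion_prob_septic = 0.10,
                          fatality = list(sepsis = c(hospital = 0.316, d30 = 0.317),
                                          mi = c(hospital = 0.125, d30 = 0.134),
                                          stroke = c(hospital = 0.100, d30 = 0.118),
                                          none = c(hospital = 0.015, d30 = 0.020)),
                          suspicion_rates = c(PM = 0, EP = 5 / 3483),
                          doc_correlation = 0.65,
                          missingness = c("MCAR", "MAR"),
                          mar_strength = 0,
                          exact_counts = FALSE,
                          seed = 1L) {
  cfg <- list(n_cases = n_cases, sepsis_prevalence = sepsis_prevalence,
              mi_prevalence = mi_prevalence, stroke_prevalence = stroke_prevalence,
              doc_rates = doc_rates, ep_fraction = ep_fraction,
              implausible_rate = implausible_rate, severity_shift = severity_shift,
              vital_params = vital_params, oxygen_prob = oxygen_prob,
              oxygen_prob_septic = oxygen_prob_septic,
              confusion_prob = confusion_prob,
              confusion_prob_septic = confusion_prob_septic,
              fatality = fatality, suspicion_rates = suspicion_rates,
              doc_correlation = doc_correlation,
              missingness = match.arg(missingness), mar_strength = mar_strength,
              exact_counts = isTRUE(exact_counts), seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' Table-style default documentation rates
#'
#' Completeness rates (probability that at least one assessment slot is
#' documented) per variable and staff type, encoding the study cohort's
#' documentation structure: temperature is by far the least documented
#' variable, respiratory rate is documented twice as often by emergency
#' physicians as by paramedics, and consciousness is the best documented
#' paramedic variable.
#'
#' @return named list of `c(PM = , EP = )` rates for the seven variables.
#' @export
default_doc_rates <- function() {
  list(temp          = c(PM = 0.177, EP = 0.198),
       rr            = c(PM = 0.270, EP = 0.533),
       gcs           = c(PM = 0.781, EP = 0.678),
       spo2          = c(PM = 0.790, EP = 0.854),
       sbp           = c(PM = 0.788, EP = 0.869),
       hr            = c(PM = 0.815, EP = 0.887),
       consciousness = c(PM = 0.869, EP = 0.686))
}

validate_cohort_config <- function(cfg) {
  n <- cfg$n_cases
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != round(n)) {
    fail("`n_cases` must be a single non-negative integer")
  }
  for (f in c("sepsis_prevalence", "mi_prevalence", "stroke_prevalence",
              "ep_fraction", "implausible_rate", "doc_correlation")) {
    check_fraction(cfg[[f]], f)
  }
  if (!is.list(cfg$doc_rates) || !all(DOC_VARS %in% names(cfg$doc_rates))) {
    fail("`doc_rates` must define rates for all of: %s", paste(DOC_VARS, collapse = ", "))
  }
  for (v in DOC_VARS) {
    r <- cfg$doc_rates[[v]]
    if (!all(c("PM", "EP") %in% names(r))) fail("`doc_rates$%s` must name PM and EP", v)
    for (s in c("PM", "EP")) check_fraction(unname(r[[s]]), sprintf("doc_rates$%s[%s]", v, s))
  }
  for (cond in c("sepsis", "mi", "stroke", "none")) {
    fr <- cfg$fatality[[cond]]
    if (is.null(fr) || !all(c("hospital", "d30") %in% names(fr))) {
      fail("`fatality$%s` must name hospital and d30 probabilities", cond)
    }
    check_fraction(unname(fr[["hospital"]]), sprintf("fatality$%s[hospital]", cond))
    check_fraction(unname(fr[["d30"]]), sprintf("fatality$%s[d30]", cond))
    if (fr[["d30"]] < fr[["hospital"]]) {
      fail("`fatality$%s`: 30-day fatality cannot be below hospital fatality", cond)
    }
  }
  for (s in c("PM", "EP")) {
    check_fraction(unname(cfg$suspicion_rates[[s]]), sprintf("suspicion_rates[%s]", s))
  }
  invisible(cfg)
}

# inverse-CDF truncated normal draw
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic EMS cohort
#'
#' Draws `n_cases` prehospital case records with complete ("true",
#' pre-missingness) vitals plus linked inpatient outcome records. Septic
#' cases' vitals are drawn from the severity-shifted distributions;
#' condition labels are non-exclusive; deaths follow independent Bernoulli
#' hospital/30-day processes with the death day uniform on the follow-up
#' window. Apply [inject_missingness()] and [inject_implausible()] to
#' obtain realistic documentation.
#'
#' @param config a [cohort_config()].
#' @return list with `cases` (one row per EMS contact, two slot columns
#'   per vital) and `outcomes` (sepsis/MI/stroke labels and mortality).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_cases = 50, seed = 3))
#' table(coh$outcomes$sepsis)
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_cases
  if (n == 0L) {
    return(list(cases = empty_cases(), outcomes = empty_outcomes()))
  }
  set.seed(config$seed)
  case_id <- sprintf("case_%06d", seq_len(n))

  sepsis <- if (config$exact_counts) {
    k <- round(config$sepsis_prevalence * n)
    seq_len(n) %in% sample.int(n, k)
  } else {
    runif(n) < config$sepsis_prevalence
  }
  mi <- runif(n) < config$mi_prevalence
  stroke <- runif(n) < config$stroke_prevalence

  staff <- ifelse(runif(n) < config$ep_fraction, "EP", "PM")
  age <- pmin(pmax(round(rnorm(n, 62, 21)), 18), 105)
  sex <- ifelse(runif(n) < 0.55, "male", "female")

  ranges <- default_plausibility()
  true <- list()
  for (v in c("rr", "spo2", "sbp", "hr", "temp")) {
    p <- config$vital_params[[v]]
    shift <- config$severity_shift[[v]] %||% 0
    true[[v]] <- rtruncnorm(n, p[1] + shift * sepsis, p[2],
                            ranges[[v]][1], ranges[[v]][2])
  }
  gp <- config$vital_params$gcs
  gshift <- config$severity_shift$gcs %||% 0
  true$gcs <- pmin(pmax(round(rnorm(n, gp[1] + gshift * sepsis, gp[2])), 3), 15)
  true$on_oxygen <- runif(n) < ifelse(sepsis, config$oxygen_prob_septic,
                                      config$oxygen_prob)
  consc <- gcs_to_acvpu(true$gcs)
  confused <- consc == "A" &
    runif(n) < ifelse(sepsis, config$confusion_prob_septic, config$confusion_prob)
  consc[confused] <- "C"
  true$consciousness <- consc

  cases <- data.frame(case_id = case_id, age = age, sex = sex, staff = staff,
                      transported = runif(n) < 0.85,
                      suspicion_documented =
                        runif(n) < unname(config$suspicion_rates[staff]),
                      stringsAsFactors = FALSE)
  # slot 2 re-measures slot 1 with small drift
  drift <- list(rr = 2, spo2 = 1.5, sbp = 8, hr = 5, temp = 0.2)
  for (v in VITALS) {
    v1 <- true[[v]]
    v2 <- if (v %in% names(drift)) {
      pmin(pmax(v1 + rnorm(n, 0, drift[[v]]), ranges[[v]][1]), ranges[[v]][2])
    } else v1
    cases[[slot_col(v, 1)]] <- v1
    cases[[slot_col(v, 2)]] <- v2
  }
  for (v in c("rr", "spo2", "sbp", "hr")) {
    cases[[slot_col(v, 1)]] <- round(cases[[slot_col(v, 1)]])
    cases[[slot_col(v, 2)]] <- round(cases[[slot_col(v, 2)]])
  }
  cases$temp_1 <- round(cases$temp_1, 1)
  cases$temp_2 <- round(cases$temp_2, 1)

  # mortality: hospital death with probability p_hosp; additional
  # out-of-hospital deaths bring the 30-day marginal up to p_d30
  cond <- ifelse(sepsis, "sepsis", ifelse(mi, "mi", ifelse(stroke, "stroke", "none")))
  p_hosp <- vapply(cond, function(cc) config$fatality[[cc]][["hospital"]], numeric(1))
  p_d30 <- vapply(cond, function(cc) config$fatality[[cc]][["d30"]], numeric(1))
  died_hosp <- runif(n) < p_hosp
  p_extra <- ifelse(p_hosp < 1, (p_d30 - p_hosp) / (1 - p_hosp), 0)
  died_30_extra <- !died_hosp & runif(n) < p_extra
  death_day <- rep(NA_integer_, n)
  dead <- died_hosp | died_30_extra
  death_day[dead] <- sample(0:30, sum(dead), replace = TRUE)

  outcomes <- data.frame(case_id = case_id, sepsis = sepsis, mi = mi,
                         stroke = stroke, died_in_hospital = died_hosp,
                         death_day = death_day, stringsAsFactors = FALSE)
  list(cases = cases, outcomes = outcomes)
}

empty_cases <- function() {
  cols <- c("case_id", "age", "sex", "staff", "transported",
            "suspicion_documented",
            unlist(lapply(VITALS, function(v) c(slot_col(v, 1), slot_col(v, 2)))))
  df <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  df
}

empty_outcomes <- function() {
  data.frame(case_id = character(0), sepsis = logical(0), mi = logical(0),
             stroke = logical(0), died_in_hospital = logical(0),
             death_day = integer(0), stringsAsFactors = FALSE)
}

#' Inject per-variable documentation missingness
#'
#' Blanks out both assessment slots of each documentation variable so that
#' the probability of at least one documented slot matches the configured
#' rate for the case's staff stratum. A one-factor Gaussian copula
#' (`doc_correlation`) correlates the seven indicators within a case while
#' leaving the marginal rates untouched; documented cases carry the value
#' in both slots (55%), the first only (30%) or the second only (15%).
#' Supplemental oxygen shares the oxygen saturation indicator. Under
#' `mechanism = "MAR"` the documentation log-odds of septic cases shift by
#' `mar_strength` (marginal rates then drift; only MCAR rates are
#' contractual).
#'
#' @param cases complete cases from [generate_cohort()].
#' @param doc_rates per-variable, per-staff documentation rates (see
#'   [default_doc_rates()]).
#' @param seed integer seed.
#' @param doc_correlation copula factor loading in `[0, 1]`.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param mar_strength log-odds shift under MAR.
#' @param septic logical vector (required for MAR): the severity indicator.
#' @return `cases` with missingness applied.
#' @export
inject_missingness <- function(cases, doc_rates = default_doc_rates(),
                               seed = 1L, doc_correlation = 0,
                               mechanism = c("MCAR", "MAR"),
                               mar_strength = 0, septic = NULL) {
  mechanism <- match.arg(mechanism)
  n <- nrow(cases)
  if (n == 0L) return(cases)
  for (v in DOC_VARS) {
    r <- doc_rates[[v]]
    if (is.null(r)) fail("`doc_rates` lacks variable `%s`", v)
    for (s in c("PM", "EP")) check_fraction(unname(r[[s]]), sprintf("doc_rates$%s[%s]", v, s))
  }
  check_fraction(doc_correlation, "doc_correlation")
  set.seed(seed)
  rho <- doc_correlation
  z <- rnorm(n) # shared documentation-propensity factor
  for (v in DOC_VARS) {
    rate <- unname(doc_rates[[v]][cases$staff])
    if (mechanism == "MAR") {
      if (is.null(septic)) fail("MAR missingness needs the `septic` indicator")
      rate <- stats::plogis(stats::qlogis(pmin(pmax(rate, 1e-12), 1 - 1e-12)) +
                              mar_strength * septic)
    }
    u <- stats::pnorm(rho * z + sqrt(1 - rho^2) * rnorm(n))
    documented <- u < rate
    pattern <- runif(n)
    drop1 <- !documented | (documented & pattern >= 0.55 & pattern < 0.70)
    drop2 <- !documented | (documented & pattern >= 0.70)
    blank <- function(col, idx) {
      cases[[col]][idx] <<- if (is.character(cases[[col]])) NA_character_ else NA
      invisible(NULL)
    }
    blank(slot_col(v, 1), drop1)
    blank(slot_col(v, 2), drop2)
    if (v == "spo2") { # oxygen flag is documented with the saturation
      blank(slot_col("on_oxygen", 1), drop1)
      blank(slot_col("on_oxygen", 2), drop2)
    }
  }
  cases
}

#' Contaminate documented values with implausible entries
#'
#' Replaces the given fraction of documented numeric slot values with
#' values outside the plausibility ranges (e.g. a body temperature of
#' 12 degrees C), emulating transcription errors. Replacements are logged
#' in the `"implausible_log"` attribute (`case_id`, `variable`, `slot`,
#' original and injected value).
#'
#' @param cases case records (after missingness injection).
#' @param rate fraction of documented numeric values to corrupt.
#' @param seed integer seed.
#' @param ranges plausibility ranges the injected values must violate.
#' @return `cases` with contamination applied.
#' @export
inject_implausible <- function(cases, rate = 0.01, seed = 1L,
                               ranges = default_plausibility()) {
  check_fraction(rate, "implausible_rate")
  n <- nrow(cases)
  log <- list()
  if (rate == 0 || n == 0L) {
    return(structure(cases, implausible_log =
                       data.frame(case_id = character(0), variable = character(0),
                                  slot = integer(0), original = numeric(0),
                                  injected = numeric(0))))
  }
  set.seed(seed)
  for (v in NUMERIC_VITALS) {
    rng <- ranges[[v]]
    for (slot in 1:2) {
      col <- slot_col(v, slot)
      doc <- which(!is.na(cases[[col]]))
      hit <- doc[runif(length(doc)) < rate]
      if (length(hit) == 0L) next
      below <- runif(length(hit)) < 0.5
      lo_vals <- round_half_up(runif(length(hit), max(rng[1] - 15, 0), rng[1] - 0.5), 1)
      hi_vals <- round_half_up(runif(length(hit), rng[2] + 0.5, rng[2] + 15), 1)
      inj <- ifelse(below, lo_vals, hi_vals)
      if (v == "gcs") inj <- round(inj)
      log[[length(log) + 1L]] <-
        data.frame(case_id = cases$case_id[hit], variable = v, slot = slot,
                   original = cases[[col]][hit], injected = inj,
                   stringsAsFactors = FALSE)
      cases[[col]][hit] <- inj
    }
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(case_id = character(0), variable = character(0),
               slot = integer(0), original = numeric(0), injected = numeric(0))
  structure(cases, implausible_log = log)
}

#' Generate a documentation-realistic cohort in one call
#'
#' [generate_cohort()] followed by [inject_missingness()] and
#' [inject_implausible()], all driven by the configuration. Sub-seeds are
#' derived deterministically from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with `cases` and `outcomes` as in [generate_cohort()].
#' @export
simulate_cohort <- function(config) {
  coh <- generate_cohort(config)
  coh$cases <- inject_missingness(coh$cases, config$doc_rates,
                                  seed = config$seed + 1L,
                                  doc_correlation = config$doc_correlation,
                                  mechanism = config$missingness,
                                  mar_strength = config$mar_strength,
                                  septic = coh$outcomes$sepsis)
  coh$cases <- inject_implausible(coh$cases, config$implausible_rate,
                                  seed = config$seed + 2L)
  coh
}

#' Read/write the cohort CSV schema
#'
#' `write_cohort()` writes `cases.csv`, `outcomes.csv` and a
#' `manifest.json` (schema version, seed, configuration and its hash) to a
#' directory; missing values are encoded as empty fields. `read_cohort()`
#' reads them back.
#'
#' @param cohort list with `cases` and `outcomes`.
#' @param dir output directory (created if absent).
#' @param config optional [cohort_config()] recorded in the manifest.
#' @return `write_cohort()`: the directory, invisibly. `read_cohort()`:
#'   list with `cases`, `outcomes` and `manifest`.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$cases, file.path(dir, "cases.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE, na = "")
  cfg_json <- if (!is.null(config)) {
    jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA, null = "null")
  } else NULL
  manifest <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("sepsiscreen")),
    seed = config$seed %||% NA,
    config = if (!is.null(cfg_json)) jsonlite::fromJSON(cfg_json) else NULL,
    config_hash = if (!is.null(cfg_json)) {
      tmp <- tempfile(); writeLines(as.character(cfg_json), tmp)
      unname(tools::md5sum(tmp))
    } else NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cases <- utils::read.csv(file.path(dir, "cases.csv"),
                           na.strings = "", stringsAsFactors = FALSE)
  for (col in grep("^(on_oxygen)_[12]$", names(cases), value = TRUE)) {
    cases[[col]] <- as.logical(cases[[col]])
  }
  for (col in intersect(c("transported", "suspicion_documented"), names(cases))) {
    cases[[col]] <- as.logical(cases[[col]])
  }
  outcomes <- utils::read.csv(file.path(dir, "outcomes.csv"),
                              na.strings = "", stringsAsFactors = FALSE)
  man_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(man_path)) jsonlite::read_json(man_path) else NULL
  list(cases = cases, outcomes = outcomes, manifest = manifest)
}
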