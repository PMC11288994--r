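test_that("plausibility filter clears out-of-range values and is idempotent", {
  v <- vital_set(temp = c(36.9, 12, NA), spo2 = c(101, 100, 50),
                 rr = c(0.5, 16, 90), gcs = c(15, 7.5, 16))
  f <- plausibility_filter(v)
  expect_equal(f$temp, c(36.9, NA, NA))
  expect_equal(f$spo2, c(NA, 100, 50))  # 101 out, boundary 100 kept
  expect_equal(f$rr, c(NA, 16, NA))
  expect_equal(f$gcs, c(15, NA, NA))    # non-integer and > 15 both implausible
  expect_identical(strip(plausibility_filter(f)), strip(f))
  log <- attr(f, "plausibility_log")
  expect_equal(unname(log["temp"]), 1L)
})

test_that("plausibility filter handles two-slot case tables", {
  coh <- small_cohort(n = 300, seed = 21, implausible_rate = 0.2)
  filtered <- plausibility_filter(coh$cases)
  rng <- default_plausibility()
  for (v in c("temp", "rr", "hr", "sbp", "spo2", "gcs")) {
    for (slot in 1:2) {
      vals <- filtered[[paste0(v, "_", slot)]]
      expect_true(all(is.na(vals) | (vals >= rng[[v]][1] & vals <= rng[[v]][2])),
                  info = paste(v, slot))
    }
  }
  # injected implausible values were actually cleared
  log <- attr(coh$cases, "implausible_log")
  expect_gt(nrow(log), 0)
  i <- 1L
  col <- paste0(log$variable[i], "_", log$slot[i])
  row <- match(log$case_id[i], filtered$case_id)
  expect_true(is.na(filtered[[col]][row]))
})

test_that("slot resolution: first wins, second fills, both missing stays missing", {
  cases <- data.frame(case_id = c("a", "b", "c"))
  for (v in c("rr", "spo2", "sbp", "hr", "temp", "gcs")) {
    cases[[paste0(v, "_1")]] <- c(80, NA, NA)
    cases[[paste0(v, "_2")]] <- c(110, 110, NA)
  }
  cases$on_oxygen_1 <- c(FALSE, NA, NA); cases$on_oxygen_2 <- c(TRUE, TRUE, NA)
  cases$consciousness_1 <- c("A", NA, NA); cases$consciousness_2 <- c("V", "V", NA)
  r <- resolve_assessment(cases)
  expect_equal(r$hr, c(80, 110, NA))
  expect_equal(r$hr_src, c("first", "second", "missing"))
  expect_equal(r$consciousness, c("A", "V", NA))
  expect_identical(r$on_oxygen, c(FALSE, TRUE, NA))
})

test_that("worst-of-both precedence picks the higher-scoring slot", {
  cases <- data.frame(case_id = "a")
  one <- list(rr = 16, spo2 = 98, on_oxygen = FALSE, sbp = 120, hr = 75,
              temp = 37, gcs = 15, consciousness = "A")
  two <- list(rr = 28, spo2 = 91, on_oxygen = FALSE, sbp = 120, hr = 75,
              temp = 37, gcs = 15, consciousness = "A")
  for (v in names(one)) {
    cases[[paste0(v, "_1")]] <- one[[v]]
    cases[[paste0(v, "_2")]] <- two[[v]]
  }
  r <- resolve_assessment(cases, precedence = "worst")
  expect_equal(r$rr, 28)       # 3 NEWS2 points beat 0
  expect_equal(r$spo2, 91)
  expect_equal(r$sbp, 120)     # tie goes to the first slot
  expect_equal(r$sbp_src, "first")
})

test_that("GCS to ACVPU mapping and consciousness precedence", {
  expect_equal(gcs_to_acvpu(c(15, 14, 13, 12, 9, 8, 3, NA)),
               c("A", "V", "V", "P", "P", "U", "U", NA))
  resolved <- data.frame(case_id = 1:3, gcs = c(15, 7, NA),
                         consciousness = c("V", NA, NA),
                         consciousness_src = c("first", "missing", "missing"),
                         stringsAsFactors = FALSE)
  d <- derive_consciousness(resolved)
  expect_equal(d$consciousness, c("V", "U", NA))  # documented wins; derived; missing
  expect_equal(d$consciousness_src, c("first", "derived-gcs", "missing"))
})

test_that("normal values score zero and worst values score the maximum everywhere", {
  tabs <- load_score_tables()
  nv <- as.data.frame(normal_values(tabs), stringsAsFactors = FALSE)
  wv <- as.data.frame(worst_values(tabs), stringsAsFactors = FALSE)
  expect_equal(score_qsofa(nv), 0L); expect_equal(score_qsofa(wv), 3L)
  expect_equal(score_sirs(nv), 0L);  expect_equal(score_sirs(wv), 3L)
  expect_equal(score_mews(nv), 0L);  expect_equal(score_mews(wv), 14L)
  expect_equal(score_news2(nv), 0L); expect_equal(score_news2(wv), 20L)
})

test_that("missing rr under missing_as_worst attains each tool's maximal rr row", {
  resolved <- data.frame(case_id = "a", rr = NA_real_, spo2 = 98,
                         on_oxygen = FALSE, sbp = 120, hr = 75, temp = 37,
                         gcs = 15, consciousness = "A", stringsAsFactors = FALSE)
  r <- apply_missing_strategy(resolved, "missing_as_worst")
  expect_equal(score_news2(r), 3L)
  expect_equal(score_mews(r), 3L)
  expect_equal(score_qsofa(r), 1L)
  expect_equal(score_sirs(r), 1L)
})

test_that("strategies fill (or preserve) missingness as contracted", {
  coh <- small_cohort(n = 300, seed = 31)
  filtered <- plausibility_filter(coh$cases)
  resolved <- derive_consciousness(resolve_assessment(filtered))
  vitals <- c("rr", "spo2", "on_oxygen", "sbp", "hr", "temp", "gcs", "consciousness")

  cc <- apply_missing_strategy(resolved, "complete_case")
  expect_identical(strip(cc), strip(resolved))  # no imputation

  for (s in c("missing_as_normal", "hotdeck", "missing_as_worst")) {
    filled <- apply_missing_strategy(resolved, s, seed = 7)
    for (v in vitals) expect_false(anyNA(filled[[v]]), info = paste(s, v))
  }
  # provenance updated
  nm <- apply_missing_strategy(resolved, "missing_as_normal")
  was_missing <- is.na(resolved$temp)
  expect_true(all(nm$temp_src[was_missing] == "imputed-missing_as_normal"))

  # hotdeck determinism: same seed identical, different seed differs
  h1 <- apply_missing_strategy(resolved, "hotdeck", seed = 7)
  h2 <- apply_missing_strategy(resolved, "hotdeck", seed = 7)
  h3 <- apply_missing_strategy(resolved, "hotdeck", seed = 8)
  expect_identical(strip(h1), strip(h2))
  expect_false(identical(strip(h1), strip(h3)))
})

test_that("hotdeck falls back to the global donor pool with a warning", {
  resolved <- data.frame(case_id = 1:4, age = c(20, 20, 90, 90),
                         staff = c("PM", "PM", "EP", "EP"),
                         rr = c(16, 18, NA, NA), spo2 = 98, on_oxygen = FALSE,
                         sbp = 120, hr = 75, temp = 37, gcs = 15,
                         consciousness = "A", stringsAsFactors = FALSE)
  # no EP donor for rr in the 80+ band: must fall back
  expect_warning(filled <- apply_missing_strategy(resolved, "hotdeck", seed = 1),
                 "global pool")
  expect_true(all(filled$rr %in% c(16, 18)))
})

test_that("missing-as-normal dominance: scores never exceed any other strategy", {
  coh <- small_cohort(n = 500, seed = 41)
  filtered <- plausibility_filter(coh$cases)
  resolved <- derive_consciousness(resolve_assessment(filtered))
  panels <- lapply(c(normal = "missing_as_normal", hotdeck = "hotdeck",
                     worst = "missing_as_worst", cc = "complete_case"),
                   function(s) score_panel(apply_missing_strategy(resolved, s, seed = 3)))
  for (tool in c("qsofa", "sirs", "mews", "news2")) {
    base <- panels$normal[[tool]]
    for (other in c("hotdeck", "worst", "cc")) {
      sc <- panels[[other]][[tool]]
      ok <- !is.na(sc)  # complete-case exclusions drop out
      expect_true(all(base[ok] <= sc[ok]), info = paste(tool, other))
    }
  }
  # consequence on a fixed cohort: Se(normal) <= Se(other), Sp(normal) >= Sp(other)
  labels <- coh$outcomes$sepsis
  for (tool in c("qsofa", "sirs", "mews", "news2")) {
    a_n <- accuracy_summary(confusion(panels$normal[[paste0(tool, "_pos")]], labels))
    for (other in c("hotdeck", "worst")) {
      a_o <- accuracy_summary(confusion(panels[[other]][[paste0(tool, "_pos")]], labels))
      expect_lte(a_n$estimate[a_n$statistic == "sensitivity"],
                 a_o$estimate[a_o$statistic == "sensitivity"])
      expect_gte(a_n$estimate[a_n$statistic == "specificity"],
                 a_o$estimate[a_o$statistic == "specificity"])
    }
  }
})
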