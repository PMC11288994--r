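test_that("score tables load and are validated", {
  tabs <- load_score_tables()
  expect_s3_class(tabs, "score_tables")
  expect_equal(tabs$qsofa$threshold, 2L)
  expect_equal(tabs$sirs$threshold, 2L)
  expect_equal(tabs$mews$threshold, 4L)
  expect_equal(tabs$news2$threshold, 5L)
  expect_setequal(tabs$sirs$omitted, c("leukocyte_count", "paco2"))
  expect_equal(tabs$mews$omitted, "urine_output")
})

test_that("malformed score tables are rejected at load", {
  raw <- jsonlite::read_json(system.file("extdata", "score_tables.json",
                                         package = "sepsiscreen"),
                             simplifyVector = FALSE)
  bad <- raw
  # overlapping intervals (non-increasing bounds)
  bad$tools$mews$components[[1]]$lower <- list(40, 40, 81, 101, 200)
  p <- tempfile(fileext = ".json")
  on.exit(unlink(p))
  jsonlite::write_json(bad, p, auto_unbox = TRUE)
  expect_error(load_score_tables(p), "strictly increase")
  bad <- raw
  # coverage gap at the bottom of the plausibility range
  bad$tools$news2$components[[1]]$lower <- list(5, 9, 12, 21, 25)
  jsonlite::write_json(bad, p, auto_unbox = TRUE)
  expect_error(load_score_tables(p), "coverage")
})

test_that("hand-worked score examples are reproduced", {
  expect_equal(score_qsofa(vital_set(rr = c(16, 22, 24), sbp = c(120, 100, 95),
                                     gcs = c(15, 15, 13))),
               c(0L, 2L, 3L))
  expect_equal(score_sirs(vital_set(temp = c(37, 38.5, 35.5), hr = c(70, 95, 91),
                                    rr = c(14, 22, 20))),
               c(0L, 3L, 2L))  # rr = 20 is NOT > 20
  expect_equal(score_mews(vital_set(sbp = c(120, 85, 101), hr = c(70, 105, 51),
                                    rr = c(12, 22, 15), temp = c(37, 38.6, 38.4),
                                    consciousness = c("A", "V", "A"))),
               c(0L, 7L, 1L))
  expect_equal(score_news2(vital_set(rr = c(16, 25, 21), spo2 = c(97, 93, 96),
                                     on_oxygen = c(FALSE, TRUE, FALSE),
                                     sbp = c(120, 95, 111), hr = c(75, 115, 91),
                                     consciousness = c("A", "V", "A"),
                                     temp = c(37, 35.4, 38.1))),
               c(0L, 15L, 4L))
})

test_that("qSOFA mentation falls back on consciousness when GCS is missing", {
  v <- vital_set(rr = 16, sbp = 120, gcs = NA, consciousness = c("A", "V"))
  expect_equal(score_qsofa(v), c(0L, 1L))
})

test_that("positivity thresholds dichotomize as recommended", {
  expect_true(screen_positive("qsofa", 2L))
  expect_false(screen_positive("qsofa", 1L))
  expect_false(screen_positive("mews", 3L))
  expect_true(screen_positive("mews", 4L))
  expect_true(screen_positive("news2", 5L))
  expect_false(screen_positive("news2", 4L))
  expect_true(screen_positive("sirs", 2L))
  expect_error(screen_positive("meows", 3L), "unknown screening tool")
})

test_that("missing required vitals raise an error naming the vital", {
  v <- vital_set(rr = 16, sbp = NA, gcs = 15)
  expect_error(score_qsofa(v), "sbp")
  expect_equal(score_qsofa(v, on_missing = "na"), NA_integer_)
})

test_that("calculators agree with the brute-force oracle on a dense grid", {
  tabs <- load_score_tables()
  normal <- normal_values(tabs)
  # per-vital sweeps at the stated resolution, other vitals held normal
  sweeps <- list(rr = 1:80, spo2 = 40:100, sbp = 40:320, hr = 10:280,
                 temp = seq(25, 45, by = 0.1), gcs = 3:15,
                 consciousness = c("A", "C", "V", "P", "U"),
                 on_oxygen = c(TRUE, FALSE))
  grid <- do.call(rbind, lapply(names(sweeps), function(v) {
    g <- as.data.frame(normal, stringsAsFactors = FALSE)[rep(1, length(sweeps[[v]])), ]
    g[[v]] <- sweeps[[v]]
    g
  }))
  # plus random joint combinations
  grid <- rbind(grid, random_vitals(4000, seed = 99))
  expect_equal(score_qsofa(grid, tabs),
               as.integer(mapply(oracle_qsofa, grid$rr, grid$sbp, grid$gcs)))
  expect_equal(score_sirs(grid, tabs),
               as.integer(mapply(oracle_sirs, grid$temp, grid$hr, grid$rr)))
  expect_equal(score_mews(grid, tabs),
               as.integer(mapply(oracle_mews, grid$sbp, grid$hr, grid$rr,
                                 grid$temp, grid$consciousness)))
  expect_equal(score_news2(grid, tabs),
               as.integer(mapply(oracle_news2, grid$rr, grid$spo2, grid$on_oxygen,
                                 grid$sbp, grid$hr, grid$consciousness, grid$temp)))
  # range invariant on the same grid
  expect_true(all(score_qsofa(grid) %in% 0:3))
  expect_true(all(score_sirs(grid) %in% 0:3))
  expect_true(all(score_mews(grid) %in% 0:14))
  expect_true(all(score_news2(grid) %in% 0:20))
})

test_that("each interval component is U-shaped or monotone with minimum 0", {
  tabs <- load_score_tables()
  for (tool in c("qsofa", "sirs", "mews", "news2")) {
    for (comp in tabs[[tool]]$components) {
      if (comp$type != "interval") next
      pts <- comp$points
      expect_equal(min(pts), 0, info = sprintf("%s/%s", tool, comp$vital))
      # points decrease to the normal bin then increase: one sign change
      # pattern at most on each side of the minimum
      imin <- which.min(pts)
      expect_true(all(diff(pts[seq_len(imin)]) <= 0),
                  info = sprintf("%s/%s left arm", tool, comp$vital))
      expect_true(all(diff(pts[imin:length(pts)]) >= 0),
                  info = sprintf("%s/%s right arm", tool, comp$vital))
    }
  }
})

test_that("score_panel scores all four tools and flags positivity", {
  coh <- small_cohort(n = 200, seed = 11)
  resolved <- preprocess_cases(coh$cases, "missing_as_normal")
  panel <- score_panel(resolved)
  expect_equal(nrow(panel), 200)
  for (tool in c("qsofa", "sirs", "mews", "news2")) {
    expect_false(anyNA(panel[[tool]]))
    expect_equal(panel[[paste0(tool, "_pos")]],
                 panel[[tool]] >= load_score_tables()[[tool]]$threshold)
  }
  expect_equal(panel$strategy, rep("missing_as_normal", 200))
})
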