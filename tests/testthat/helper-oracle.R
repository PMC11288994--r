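# Independent brute-force scorers: plain if/else transcriptions of the
# instruments, deliberately not sharing code with the package's
# table-driven lookup. Scalar in, scalar out.

oracle_qsofa <- function(rr, sbp, gcs) {
  (rr >= 22) + (sbp <= 100) + (gcs < 15)
}

oracle_sirs <- function(temp, hr, rr) {
  temp <- round_half_up(temp, 1)
  (temp > 38.0 || temp < 36.0) + (hr > 90) + (rr > 20)
}

oracle_mews <- function(sbp, hr, rr, temp, consc) {
  temp <- round_half_up(temp, 1)
  p_sbp <- if (sbp <= 70) 3 else if (sbp <= 80) 2 else if (sbp <= 100) 1 else if (sbp <= 199) 0 else 2
  p_hr <- if (hr <= 40) 2 else if (hr <= 50) 1 else if (hr <= 100) 0 else if (hr <= 110) 1 else if (hr <= 129) 2 else 3
  p_rr <- if (rr < 9) 2 else if (rr <= 14) 0 else if (rr <= 20) 1 else if (rr <= 29) 2 else 3
  p_temp <- if (temp < 35) 2 else if (temp <= 38.4) 0 else 2
  p_consc <- switch(consc, A = 0, C = 1, V = 1, P = 2, U = 3)
  p_sbp + p_hr + p_rr + p_temp + p_consc
}

oracle_news2 <- function(rr, spo2, on_oxygen, sbp, hr, consc, temp) {
  temp <- round_half_up(temp, 1)
  p_rr <- if (rr <= 8) 3 else if (rr <= 11) 1 else if (rr <= 20) 0 else if (rr <= 24) 2 else 3
  p_spo2 <- if (spo2 <= 91) 3 else if (spo2 <= 93) 2 else if (spo2 <= 95) 1 else 0
  p_o2 <- if (on_oxygen) 2 else 0
  p_sbp <- if (sbp <= 90) 3 else if (sbp <= 100) 2 else if (sbp <= 110) 1 else if (sbp <= 219) 0 else 3
  p_hr <- if (hr <= 40) 3 else if (hr <= 50) 1 else if (hr <= 90) 0 else if (hr <= 110) 1 else if (hr <= 130) 2 else 3
  p_consc <- if (consc == "A") 0 else 3
  p_temp <- if (temp <= 35.0) 3 else if (temp <= 36.0) 1 else if (temp <= 38.0) 0 else if (temp <= 39.0) 1 else 2
  p_rr + p_spo2 + p_o2 + p_sbp + p_hr + p_consc + p_temp
}

# random in-range vitals tables for property tests
random_vitals <- function(n, seed = 1) {
  set.seed(seed)
  vital_set(rr = sample(1:80, n, TRUE),
            spo2 = sample(40:100, n, TRUE),
            on_oxygen = sample(c(TRUE, FALSE), n, TRUE),
            sbp = sample(40:320, n, TRUE),
            hr = sample(10:280, n, TRUE),
            temp = round(runif(n, 25, 45), 1),
            gcs = sample(3:15, n, TRUE),
            consciousness = sample(c("A", "C", "V", "P", "U"), n, TRUE))
}

small_cohort <- function(n = 400, seed = 42, ...) {
  simulate_cohort(cohort_config(n_cases = n, seed = seed, ...))
}

# percentage rounded half-up to 1 decimal, as printed in reports
pct1 <- function(x) round_half_up(100 * x, 1)

# drop non-structural attributes (logs, strategy tags) before comparison
strip <- function(d) {
  attributes(d) <- attributes(d)[c("names", "row.names", "class")]
  d
}
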