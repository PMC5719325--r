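test_that("ABCD2 scoring reproduces the worked example patients and extremes", {
  pts <- data.frame(
    age_band = c("70-74", "70-74", "18-59", "60-64"),
    sbp = c(156, 115, 120, 150),
    clinical_feature = c("speech_no_weakness", "speech_no_weakness",
                         "other", "unilateral_weakness"),
    duration_band = c("ge60min", "lt10min", "lt10min", "ge60min"),
    diabetes = c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(abcd2_score(pts), c(5L, 2L, 0L, 7L))
  expect_identical(abcd_score(pts), c(5L, 2L, 0L, 6L))
  expect_error(abcd2_score(transform(pts, sbp = -1)), "sbp")
  expect_error(abcd2_score(transform(pts, duration_band = "2h")), "duration")
})

test_that("risk classification uses the >4 threshold and rejects bad scores", {
  expect_identical(classify_risk(c(0L, 4L, 5L, 7L)),
                   c("low", "low", "high", "high"))
  expect_error(classify_risk(8L), "\\[0, 7\\]")
  expect_error(classify_risk(-1L))
  expect_error(classify_risk(3.5))
})

test_that("apply_ratio repartitions the true-TIA share and conserves the mix", {
  cfg <- population_config()
  for (r in c(0.5, 1, 2.5, 5, 7)) {
    m <- apply_ratio(cfg, r)$mix
    expect_equal(sum(m), 1, tolerance = 1e-12)
    expect_equal(m[["high_risk_tia"]] / m[["low_risk_tia"]], r,
                 tolerance = 1e-12)
    expect_equal(m[["high_risk_tia"]] + m[["low_risk_tia"]], cfg$tia_share,
                 tolerance = 1e-12)
    expect_identical(m[c("tia_mimic", "minor_stroke")],
                     cfg$mix[c("tia_mimic", "minor_stroke")])
  }
  m1 <- apply_ratio(cfg, 1)$mix
  expect_equal(unname(m1[["high_risk_tia"]]), 0.165)
  expect_error(apply_ratio(cfg, 0), "positive")
  expect_error(apply_ratio(cfg, -2), "positive")
})

test_that("expected GP fraction equals the class-weighted hand oracle", {
  cfg <- population_config()
  oracle <- cfg$mix[["high_risk_tia"]] * 0.723 +
    cfg$mix[["low_risk_tia"]] * 0.879 +
    cfg$mix[["tia_mimic"]] * 0.879 +
    cfg$mix[["minor_stroke"]] * 0.574
  expect_equal(expected_gp_fraction(cfg), oracle, tolerance = 1e-12)
})

test_that("generated cohorts have the configured statistical structure", {
  cfg <- population_config()
  co <- generate_cohort(cfg, years = 21, seed = 101) # ~10^4 patients
  n <- nrow(co)
  expect_gt(n, 9000)

  # class proportions within 3 binomial SE of the configured mix
  p_hat <- prop.table(table(factor(co$diagnosis, names(cfg$mix))))
  for (cl in names(cfg$mix)) {
    se <- sqrt(cfg$mix[[cl]] * (1 - cfg$mix[[cl]]) / n)
    expect_lt(abs(p_hat[[cl]] - cfg$mix[[cl]]), 3 * se)
  }

  # score-based risk always consistent with the diagnosis class
  expect_true(all((co$abcd2 > 4) == (co$risk == "high")))
  expect_true(all(co$risk[co$diagnosis %in% c("high_risk_tia", "minor_stroke")]
                  == "high"))
  expect_identical(co$abcd2 - co$abcd, as.integer(co$diabetes))

  # bounds and enums
  expect_true(all(co$onset_time >= 0 & co$onset_time < 21 * 364))
  tod <- (co$onset_time - floor(co$onset_time)) * 24
  expect_true(all(tod >= cfg$onset_hours[1] & tod <= cfg$onset_hours[2]))
  expect_true(all(co$age >= 18 & co$age <= 105))
  expect_true(all(co$sbp >= 70 & co$sbp <= 260))
  expect_true(all(co$route %in% c("gp", "ed")))

  # carotid surgery flag close to its configured probability
  expect_lt(abs(mean(co$cea_flag) - cfg$cea_prob),
            3 * sqrt(cfg$cea_prob * (1 - cfg$cea_prob) / n))
})

test_that("a degenerate mix produces only high-risk TIA with ABCD2 > 4", {
  cfg <- population_config(tia_share = 1, mimic_share = 0, minor_share = 0,
                           high_low_ratio = 1e12)
  co <- generate_cohort(cfg, years = 2, seed = 7)
  expect_true(all(co$diagnosis == "high_risk_tia"))
  expect_true(all(co$abcd2 > 4))
})

test_that("identical seeds reproduce identical patient streams", {
  cfg <- population_config()
  a <- generate_cohort(cfg, 2, seed = 99)
  b <- generate_cohort(cfg, 2, seed = 99)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(cfg, 2, seed = 100)))
  # bitwise equality survives serialisation
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(a, f1); write_cohort_csv(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("annual arrival counts have the configured mean", {
  cfg <- population_config()
  counts <- vapply(1:100, function(s) nrow(generate_cohort(cfg, 1, s)),
                   numeric(1))
  se <- sqrt(cfg$annual_referrals / 100) # Poisson SE of the mean
  expect_lt(abs(mean(counts) - cfg$annual_referrals), 3 * se)
})

test_that("configuration validation rejects inconsistent inputs", {
  expect_error(population_config(annual_referrals = 0), "positive")
  expect_error(population_config(tia_share = 0.5), "sum to 1")
  expect_error(population_config(cea_prob = 1.2), "probabilities")
  expect_error(generate_cohort(population_config(), years = 0, seed = 1),
               "positive")
})
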