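test_that("two-anchor calibration matches a bisection oracle and its anchors", {
  p1 <- 0.08; t1 <- 7; p2 <- 0.12; t2 <- 30
  b <- calibrate_weibull(p1, t1, p2, t2)

  # independent oracle: bisection on the shape ratio equation
  a1 <- -log(1 - p1); a2 <- -log(1 - p2)
  k_oracle <- uniroot(function(k) (t2 / t1)^k - a2 / a1,
                      c(1e-4, 10), tol = 1e-14)$root
  expect_equal(b$shape, k_oracle, tolerance = 1e-8)
  expect_lt(b$shape, 1) # decreasing hazard

  expect_lt(abs(pweibull(t1, b$shape, b$scale) - p1), 1e-10)
  expect_lt(abs(pweibull(t2, b$shape, b$scale) - p2), 1e-10)
})

test_that("calibration recovers the exponential special case and round-trips", {
  p1 <- 0.05; t1 <- 10; t2 <- 40
  p2 <- 1 - (1 - p1)^(t2 / t1) # constant-hazard identity
  b <- calibrate_weibull(p1, t1, p2, t2)
  expect_equal(b$shape, 1, tolerance = 1e-12)

  b0 <- calibrate_weibull(0.08, 7, 0.12, 30)
  b1 <- calibrate_weibull(pweibull(5, b0$shape, b0$scale), 5,
                          pweibull(120, b0$shape, b0$scale), 120)
  expect_equal(b1$shape, b0$shape, tolerance = 1e-9)
  expect_equal(b1$scale, b0$scale, tolerance = 1e-6 * b0$scale)

  expect_error(calibrate_weibull(0.12, 7, 0.08, 30), "p1 < p2")
  expect_error(calibrate_weibull(0.08, 30, 0.12, 7), "t1 < t2")
})

test_that("hazard_at reduces to the textbook Weibull hazard", {
  b <- calibrate_weibull(0.08, 7, 0.12, 30)
  prof <- hazard_profile(b, multiplier = 2)
  t <- c(0.5, 1, 7, 30, 180, 365)
  textbook <- dweibull(t, b$shape, b$scale) / (1 - pweibull(t, b$shape, b$scale))
  # the multiplier acts proportionally on a hazard this small
  expect_equal(hazard_at(prof, t), 2 * textbook, tolerance = 1e-6)
  expect_error(hazard_at(prof, 0), "positive")

  # hr = 1 makes treatment timing irrelevant
  p1 <- hazard_profile(b, 1.5, treatment_hr = 1, treatment_start = 3)
  p2 <- hazard_profile(b, 1.5, treatment_hr = 1)
  expect_identical(hazard_at(p1, t), hazard_at(p2, t))
  expect_identical(cumulative_hazard(p1, t), cumulative_hazard(p2, t))

  # decreasing shape: hazard monotone non-increasing on each side of treatment
  p3 <- hazard_profile(b, 1, treatment_hr = 0.2, treatment_start = 10)
  grid1 <- seq(0.1, 9.9, by = 0.1); grid2 <- seq(10.1, 50, by = 0.1)
  expect_true(all(diff(hazard_at(p3, grid1)) <= 0))
  expect_true(all(diff(hazard_at(p3, grid2)) <= 0))
})

test_that("cumulative hazard agrees with numerical integration of the hazard", {
  b <- calibrate_weibull(0.08, 7, 0.12, 30)
  prof <- hazard_profile(b, multiplier = 1.7, treatment_hr = 0.2,
                         treatment_start = 2.5)
  for (t in c(1, 2.5, 10, 100)) {
    num <- integrate(function(x) hazard_at(prof, x), 1e-12, t,
                     rel.tol = 1e-10)$value
    expect_equal(cumulative_hazard(prof, t), num, tolerance = 1e-6)
  }
  expect_equal(survival_at(prof, 30), exp(-cumulative_hazard(prof, 30)))
})

test_that("an example high-risk patient dominates a low-risk one pointwise", {
  # high: ABCD2 5, undiagnosed AF, cholesterol 5.8
  # low:  ABCD2 2, AF on warfarin, cholesterol 6.0
  cfg <- risk_config()
  pats <- data.frame(abcd2 = c(5L, 2L),
                     af_status = c("undiagnosed_af", "af_on_warfarin"),
                     cholesterol = c(5.8, 6.0),
                     diagnosis = c("high_risk_tia", "low_risk_tia"))
  m <- hazard_multiplier(pats, cfg)
  hi <- hazard_profile(cfg$baseline, m[1])
  lo <- hazard_profile(cfg$baseline, m[2])
  t <- c(0.25, 1, 7, 30, 90, 365)
  expect_true(all(hazard_at(hi, t) > hazard_at(lo, t)))
  expect_true(all(survival_at(hi, t) < survival_at(lo, t)))
})

test_that("event sampling matches the closed-form Weibull distribution", {
  b <- calibrate_weibull(0.08, 7, 0.12, 30)
  prof <- hazard_profile(b, multiplier = 1, treatment_hr = 1)
  s <- sample_event_time(prof, n = 1e5, seed = 404, censored_at = Inf)
  expect_true(all(s$event == "major_stroke"))
  ks <- suppressWarnings(ks.test(s$event_time, pweibull, b$shape, b$scale))
  expect_gt(ks$p.value, 0.01)

  # survival convergence at fixed horizons, binomial 3 SE
  for (t in c(7, 30, 90, 365)) {
    p <- survival_at(prof, t)
    expect_lt(abs(mean(s$event_time > t) - p), 3 * sqrt(p * (1 - p) / 1e5))
  }
})

test_that("a zero covariate multiplier yields no events", {
  prof <- hazard_profile(calibrate_weibull(), multiplier = 0)
  s <- sample_event_time(prof, n = 1000, seed = 1)
  expect_true(all(s$event == "none"))
})

test_that("earlier treatment never hastens the event under a common draw", {
  b <- calibrate_weibull(0.08, 7, 0.12, 30)
  u <- runif(1e4) # coupling draws
  early <- hazard_profile(b, 2, treatment_hr = 0.2, treatment_start = 0.5)
  late <- hazard_profile(b, 2, treatment_hr = 0.2, treatment_start = 5)
  t_early <- sample_event_time(early, u = u, censored_at = Inf)$event_time
  t_late <- sample_event_time(late, u = u, censored_at = Inf)$event_time
  expect_true(all(t_early >= t_late - 1e-9))
})

test_that("post-stroke mortality follows its piecewise-exponential model", {
  # zero rate: no deaths
  d0 <- sample_post_stroke_death(500, treatment_start = 1, rate = 0, seed = 2)
  expect_true(all(d0$event == "none"))

  # treatment multiplier 1: timing of treatment is irrelevant (common draws)
  u <- runif(2000)
  d1 <- sample_post_stroke_death(u = u, treatment_start = 1, rate = 0.3,
                                 treatment_mult = 1)
  d2 <- sample_post_stroke_death(u = u, treatment_start = 200, rate = 0.3,
                                 treatment_mult = 1)
  expect_identical(d1$event, d2$event)
  expect_equal(d1$event_time, d2$event_time, tolerance = 1e-9)

  # Poisson-style oracle: untreated rate r for one year
  n <- 4000; r <- 0.3
  d <- sample_post_stroke_death(n, treatment_start = Inf, rate = r,
                                censored_at = 365, seed = 11)
  p <- 1 - exp(-r)
  expect_lt(abs(sum(d$event == "post_stroke_death") - n * p),
            3 * sqrt(n * p * (1 - p)))
})

test_that("cohort follow-up resolves competing events and treatment timing", {
  cfg <- population_config()
  co <- generate_cohort(cfg, 2, seed = 77)
  run <- run_scenario(co, scenario_preset("h2-original"), 2, seed = 77)
  rk <- risk_config()
  fu <- simulate_followup(co, run$records, rk, seed = 3)
  expect_identical(fu, simulate_followup(co, run$records, rk, seed = 3))
  expect_true(all(fu$event %in% c("none", "major_stroke", "post_stroke_death")))
  expect_true(all(fu$event_time[fu$event != "none"] <= rk$followup_days))
  expect_true(all(is.na(fu$event_time[fu$event == "none"])))
  # post-stroke deaths only follow minor strokes
  expect_true(all(co$diagnosis[fu$event == "post_stroke_death"] == "minor_stroke"))
  # mimics carry a small multiplier, so proportionally few events
  ev <- tapply(fu$event != "none", co$diagnosis, mean)
  expect_lt(ev[["tia_mimic"]], ev[["high_risk_tia"]])
})
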