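test_that("referral times follow the GP-hours and ED rules", {
  cfg <- population_config()
  co <- mk_cohort(onset = c(at(0, 9),    # Monday 09:00, GP open
                            at(5, 20),   # Saturday 20:00, GP closed
                            at(1, 7),    # Tuesday 07:00, before opening
                            at(2, 14)),  # Wednesday 14:00
                  route = c("gp", "gp", "gp", "ed"))
  ref <- refer(co, cfg)
  expect_equal(ref[1], at(0, 9))       # referred at consultation
  expect_equal(ref[2], at(7, 8))       # next opening: Monday 08:00
  expect_equal(ref[3], at(1, 8))       # same day at opening
  expect_equal(ref[4], at(2, 16))      # ED: two hours after arrival
})

test_that("ED-referred high-risk patients are seen within 2h under ward review", {
  sc <- scenario_preset("h2-modified")
  co <- mk_cohort(at(1, 14), risk = "high", route = "ed") # Tuesday 14:00
  run <- run_scenario(co, sc, 1, seed = 1)
  expect_equal(run$records$seen_time, at(1, 18))          # by 18:00 same day
  expect_identical(run$records$modality, "ward_unscheduled")
})

test_that("same-day referrals are allocated high-risk first, then by time", {
  # 3 high + 3 low referred on Monday; next clinic Tuesday has 4 slots,
  # following clinic Friday has 4. Oracle: sort by (not high, referral).
  sc <- mk_scenario(c(0, 4, 0, 0, 4))
  onset <- at(0, c(10, 9, 11, 8.5, 12, 13))
  risk <- c("low", "high", "high", "low", "high", "low")
  co <- mk_cohort(onset, risk = risk, route = "gp")
  run <- run_scenario(co, sc, 1, seed = 1)

  oracle_order <- order(risk != "high", onset)
  expected_seen <- numeric(6)
  expected_seen[oracle_order] <- c(rep(at(1, 9), 4), rep(at(4, 9), 2))
  expect_equal(run$records$seen_time, expected_seen)
  # the Tuesday slots hold the 3 high-risk ids and the earliest-referred low
  tues <- run$records$id[run$records$seen_time == at(1, 9)]
  expect_setequal(tues, c(2, 3, 5, 4))
})

test_that("admit-if-breach admits high-risk patients who cannot be seen in 24h", {
  sc <- scenario_preset("h2-original") # clinics Mon/Tue/Wed only
  co <- mk_cohort(at(3, 10), risk = "high", route = "gp") # Thursday 10:00
  run <- run_scenario(co, sc, 1, seed = 1)
  expect_identical(run$records$modality, "admission")
  expect_equal(run$records$seen_time, run$records$referral_time)
  expect_false(run$records$high_risk_breach)
})

test_that("ward-timed policy sees high-risk at 17:00 or 10:00 next day", {
  sc <- scenario_preset("h2-modified")
  co <- mk_cohort(at(0, c(9 + 59 / 60, 10 + 1 / 60)), risk = "high",
                  route = "gp")
  run <- run_scenario(co, sc, 1, seed = 1)
  expect_equal(run$records$seen_time, c(at(0, 17), at(1, 10)))
  expect_true(all(run$records$modality == "ward_unscheduled"))
  delays <- run$records$seen_time - run$records$referral_time
  expect_true(all(delays <= 1))
})

test_that("breach flags use strict 24h / 7-day thresholds", {
  rec <- data.frame(risk = c("high", "high", "low", "low"),
                    referral_time = 0,
                    seen_time = c(0.99, 1.01, 6.9, 7.1),
                    placed = TRUE)
  rec <- flag_breaches(rec)
  expect_identical(rec$high_risk_breach, c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(rec$low_risk_breach, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("slot accounting conserves and zero arrivals leave all slots unused", {
  co <- generate_cohort(population_config(), 1, seed = 5)
  run <- run_scenario(co, scenario_preset("h1-original"), 1, seed = 5)
  expect_identical(run$tally$used + run$tally$unused, run$tally$provided)
  expect_identical(run$tally$used, sum(!is.na(run$calendar$occupied_by)))

  empty <- mk_cohort(numeric(0))
  run0 <- run_scenario(empty, scenario_preset("h1-original"), 1, seed = 5)
  expect_identical(run0$tally$used, 0L)
  expect_identical(run0$tally$unused, run0$tally$provided)
  expect_identical(sum(run0$records$high_risk_breach), 0L)
})

test_that("replaying the same cohort, scenario and seed is bitwise identical", {
  co <- generate_cohort(population_config(), 2, seed = 21)
  for (preset in c("h1-modified", "h2-original")) {
    sc <- scenario_preset(preset)
    a <- run_scenario(co, sc, 2, seed = 8)
    b <- run_scenario(co, sc, 2, seed = 8)
    expect_identical(a$records, b$records)
    expect_identical(a$calendar, b$calendar)
  }
})

test_that("no slot is double-booked and no patient is seen twice", {
  co <- generate_cohort(population_config(annual_referrals = 900), 1, seed = 3)
  run <- run_scenario(co, scenario_preset("h1-modified"), 1, seed = 3)
  occ <- run$calendar$occupied_by
  expect_false(any(duplicated(occ[!is.na(occ)])))
  sr <- run$records$slot_ref
  expect_false(any(duplicated(sr[!is.na(sr)])))
  expect_identical(anyDuplicated(run$records$id), 0L)
})

test_that("adding demand never shortens the original patients' delays", {
  cfg <- population_config()
  a <- generate_cohort(cfg, 2, seed = 31)
  b <- generate_cohort(cfg, 2, seed = 32)
  b$id <- b$id + nrow(a)
  both <- rbind(a, b)
  both <- both[order(both$onset_time), ]

  sc <- scenario_preset("h1-original")
  r1 <- run_scenario(a, sc, 2, seed = 9)$records
  r2 <- run_scenario(both, sc, 2, seed = 9)$records
  r2a <- r2[match(a$id, r2$id), ]
  keep <- r1$placed & r2a$placed
  d1 <- r1$seen_time[keep] - r1$referral_time[keep]
  d2 <- r2a$seen_time[keep] - r2a$referral_time[keep]
  expect_true(all(d2 >= d1 - 1e-9))
  expect_gte(median(d2), median(d1))
})

test_that("cohorts outside the horizon are rejected", {
  co <- mk_cohort(400)
  expect_error(run_scenario(co, scenario_preset("h1-original"), 1, seed = 1),
               "horizon")
})
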