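# Shared fixtures: hand-built cohorts and minimal scenarios for engine tests.

# A minimal cohort with every column the pipeline touches. Referral times
# for "gp" rows equal onset when onset falls inside GP opening hours.
mk_cohort <- function(onset, risk = "low", route = "gp", diagnosis = NULL) {
  n <- length(onset)
  risk <- rep_len(risk, n)
  route <- rep_len(route, n)
  if (is.null(diagnosis))
    diagnosis <- ifelse(risk == "high", "high_risk_tia", "low_risk_tia")
  data.frame(
    id = seq_len(n), onset_time = onset, age = rep_len(70, n),
    sex = rep_len("male", n), diagnosis = rep_len(diagnosis, n), risk = risk,
    age_band = rep_len("70-74", n), sbp = rep_len(150, n),
    clinical_feature = rep_len("other", n),
    duration_band = rep_len("lt10min", n), diabetes = rep_len(FALSE, n),
    abcd2 = ifelse(risk == "high", 5L, 2L),
    abcd = ifelse(risk == "high", 5L, 2L), af_status = rep_len("none", n),
    cholesterol = rep_len(5.5, n), cea_flag = rep_len(FALSE, n),
    route = route)
}

# A bare scenario around a weekly pattern (no leave, policy of choice)
mk_scenario <- function(slots, policy = "order_of_referral_priority", ...) {
  service_scenario("h1", "custom", weekly_pattern(slots), leave_model(),
                   policy = policy, ...)
}

# day helper: time of day `hours` on global day index `day` (0 = Monday)
at <- function(day, hours) day + hours / 24
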