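# Synthetic referral population: demographics, ABCD2 components, diagnosis
# classes, onset timing and presentation route.

#' Diagnosis classes, clinical features and duration bands
#'
#' Enumerations used throughout the package. Diagnosis classes follow the
#' four-way split of a suspected-TIA referral stream: high-risk TIA
#' (ABCD2 > 4), low-risk TIA (ABCD2 <= 4), TIA mimic (non-vascular final
#' diagnosis) and minor (non-disabling) stroke.
#'
#' @name enums
#' @keywords internal
NULL

diagnosis_classes <- c("high_risk_tia", "low_risk_tia", "tia_mimic", "minor_stroke")
clinical_features <- c("unilateral_weakness", "speech_no_weakness", "other")
duration_bands <- c("lt10min", "10to59min", "ge60min")
age_bands <- c("18-59", "60-64", "65-69", "70-74", "75-79", "80-84", "85+")

days_per_week <- 7L
weeks_per_year <- 52L
days_per_year <- 364L # 52 exact weeks so weekly clinic patterns tile the year

#' Assign an age band
#'
#' Maps an age in years to the ordinal band used in the ABCD2 age component.
#' Any band above "18-59" scores the age point (age >= 60).
#'
#' @param age Numeric vector of ages in years.
#' @return Character vector of bands (one of `"18-59"`, `"60-64"`, ...,
#'   `"85+"`).
#' @export
age_band <- function(age) {
  stopifnot(is.numeric(age), all(is.finite(age)), all(age >= 0))
  as.character(cut(age, c(0, 60, 65, 70, 75, 80, 85, Inf),
                   labels = age_bands, right = FALSE))
}

validate_components <- function(components) {
  need <- c("age_band", "sbp", "clinical_feature", "duration_band", "diabetes")
  if (!is.data.frame(components) || !all(need %in% names(components)))
    stop("risk components must be a data frame with columns: ",
         paste(need, collapse = ", "))
  if (!all(components$age_band %in% age_bands))
    stop("invalid age_band value")
  if (!is.numeric(components$sbp) || any(components$sbp <= 0))
    stop("sbp must be positive (mm Hg)")
  if (!all(components$clinical_feature %in% clinical_features))
    stop("invalid clinical_feature value")
  if (!all(components$duration_band %in% duration_bands))
    stop("invalid duration_band value")
  if (!is.logical(components$diabetes) || anyNA(components$diabetes))
    stop("diabetes must be TRUE/FALSE")
  components
}

#' ABCD2 and ABCD stroke-risk scores
#'
#' Computes the ABCD2 score (0-7) from its clinical components:
#' age >= 60 scores 1; blood pressure >= 140 mm Hg systolic scores 1;
#' unilateral weakness scores 2, speech disturbance without weakness 1;
#' symptom duration >= 60 min scores 2, 10-59 min scores 1; diabetes
#' scores 1. `abcd_score()` is the same score without the diabetes point
#' (range 0-6).
#'
#' @param components Data frame of risk components with columns `age_band`
#'   (see [age_band()]), `sbp` (systolic blood pressure, mm Hg),
#'   `clinical_feature` (`"unilateral_weakness"`, `"speech_no_weakness"` or
#'   `"other"`), `duration_band` (`"lt10min"`, `"10to59min"`, `"ge60min"`)
#'   and `diabetes` (logical). One row per patient.
#' @return Integer vector of scores.
#' @examples
#' x <- data.frame(age_band = "70-74", sbp = 156,
#'                 clinical_feature = "speech_no_weakness",
#'                 duration_band = "ge60min", diabetes = FALSE)
#' abcd2_score(x) # 5
#' @export
abcd2_score <- function(components) {
  abcd_score(components) + as.integer(validate_components(components)$diabetes)
}

#' @rdname abcd2_score
#' @export
abcd_score <- function(components) {
  components <- validate_components(components)
  a <- as.integer(components$age_band != "18-59")
  b <- as.integer(components$sbp >= 140)
  cl <- c(unilateral_weakness = 2L, speech_no_weakness = 1L, other = 0L)
  d <- c(lt10min = 0L, "10to59min" = 1L, ge60min = 2L)
  unname(a + b + cl[components$clinical_feature] + d[components$duration_band])
}

#' Classify ABCD2 score into high/low stroke risk
#'
#' High risk is defined as ABCD2 > 4, matching the UK guideline threshold
#' for the 24-hour specialist-assessment target.
#'
#' @param score Integer vector of ABCD2 scores in \[0, 7\].
#' @return Character vector, `"high"` or `"low"`.
#' @export
classify_risk <- function(score) {
  if (!is.numeric(score) || anyNA(score) || any(score != round(score)) ||
      any(score < 0) || any(score > 7))
    stop("score must be an integer in [0, 7]")
  ifelse(score > 4, "high", "low")
}

#' Population configuration
#'
#' Defines the statistical structure of the synthetic referral stream: the
#' annual referral rate, the diagnosis mix (with the true-TIA share split
#' between high and low risk at `high_low_ratio`), class-specific GP
#' referral probabilities, demographics and the onset/presentation timing
#' model. Defaults emulate a ~490 referrals/year two-hospital suspected-TIA
#' population: 60% TIA mimics, 33% true TIA split 2.5:1 high:low, 7% minor
#' stroke; age 74 +/- 12; 48.9% female; per-class systolic blood pressure
#' distributions; GP referral probabilities of 72.3% (high-risk TIA),
#' 87.9% (low-risk TIA and mimic) and 57.4% (minor stroke); 4.1% flagged
#' for carotid endarterectomy.
#'
#' Onset times are uniform over waking hours (07:00-23:00), homogeneous
#' across days of the week. The GP route is only available 08:00-18:30
#' Monday-Friday; a GP-destined patient whose onset falls outside those
#' hours defers to the next GP opening with probability `gp_defer_prob`
#' and otherwise re-routes to the emergency department.
#'
#' @param annual_referrals Expected referrals per (364-day) year.
#' @param high_low_ratio High:low ratio splitting the true-TIA share.
#' @param tia_share,mimic_share,minor_share Diagnosis-class shares; must sum
#'   to 1 with the implied high/low split.
#' @param gp_prob_by_class Named numeric: unconditional GP-referral
#'   probability per diagnosis class.
#' @param cea_prob Probability a patient is flagged for carotid
#'   endarterectomy.
#' @param mean_age,sd_age,age_range Age model (normal, truncated).
#' @param prop_female Proportion female.
#' @param sbp_by_class Named list of `c(mean, sd)` per class (mm Hg);
#'   truncated to `sbp_range`.
#' @param sbp_range Truncation bounds for systolic blood pressure.
#' @param feature_probs,duration_probs,diabetes_prob Marginals for the
#'   ABCD2 clinical feature, duration band and diabetes components
#'   (resampled within class so the score agrees with the diagnosis).
#' @param af_probs Marginal for atrial-fibrillation status
#'   (`none`/`undiagnosed_af`/`af_on_warfarin`).
#' @param chol_mean,chol_sd Cholesterol model (mmol/L).
#' @param onset_hours Waking-hour window for symptom onset (hours, 24h clock).
#' @param gp_hours,gp_days GP opening hours (24h clock) and days
#'   (0 = Monday ... 6 = Sunday).
#' @param gp_defer_prob Probability an out-of-hours GP-destined patient
#'   waits for the next GP opening rather than attending the ED.
#' @param gp_delay_days Delay (days) from GP consultation to referral.
#' @return An object of class `tia_population_config`.
#' @seealso [generate_cohort()], [apply_ratio()]
#' @export
population_config <- function(annual_referrals = 490,
                              high_low_ratio = 2.5,
                              tia_share = 0.33,
                              mimic_share = 0.60,
                              minor_share = 0.07,
                              gp_prob_by_class = c(high_risk_tia = 0.723,
                                                   low_risk_tia = 0.879,
                                                   tia_mimic = 0.879,
                                                   minor_stroke = 0.574),
                              cea_prob = 0.041,
                              mean_age = 74, sd_age = 12,
                              age_range = c(18, 105),
                              prop_female = 0.489,
                              sbp_by_class = list(
                                high_risk_tia = c(147, 22),
                                low_risk_tia = c(147, 22),
                                tia_mimic = c(143, 26),
                                minor_stroke = c(144, 18)),
                              sbp_range = c(70, 260),
                              feature_probs = c(unilateral_weakness = 0.45,
                                                speech_no_weakness = 0.25,
                                                other = 0.30),
                              duration_probs = c(lt10min = 0.25,
                                                 "10to59min" = 0.35,
                                                 ge60min = 0.40),
                              diabetes_prob = 0.15,
                              af_probs = c(none = 0.85,
                                           undiagnosed_af = 0.10,
                                           af_on_warfarin = 0.05),
                              chol_mean = 5.5, chol_sd = 1.0,
                              onset_hours = c(7, 23),
                              gp_hours = c(8, 18.5),
                              gp_days = 0:4,
                              gp_defer_prob = 0.5,
                              gp_delay_days = 0) {
  if (annual_referrals <= 0) stop("annual_referrals must be positive")
  if (high_low_ratio <= 0) stop("high_low_ratio must be positive")
  mix <- c(high_risk_tia = tia_share * high_low_ratio / (1 + high_low_ratio),
           low_risk_tia = tia_share / (1 + high_low_ratio),
           tia_mimic = mimic_share,
           minor_stroke = minor_share)
  if (abs(sum(mix) - 1) > 1e-9)
    stop("diagnosis mix must sum to 1 (got ", sum(mix), ")")
  probs <- c(gp_prob_by_class, cea_prob, prop_female, gp_defer_prob,
             feature_probs, duration_probs, diabetes_prob, af_probs)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (abs(sum(feature_probs) - 1) > 1e-9 || abs(sum(duration_probs) - 1) > 1e-9 ||
      abs(sum(af_probs) - 1) > 1e-9)
    stop("feature, duration and AF marginals must each sum to 1")
  stopifnot(all(names(gp_prob_by_class) == diagnosis_classes),
            all(names(sbp_by_class) == diagnosis_classes))
  structure(list(
    annual_referrals = annual_referrals, high_low_ratio = high_low_ratio,
    tia_share = tia_share, mix = mix, gp_prob_by_class = gp_prob_by_class,
    cea_prob = cea_prob, mean_age = mean_age, sd_age = sd_age,
    age_range = age_range, prop_female = prop_female,
    sbp_by_class = sbp_by_class, sbp_range = sbp_range,
    feature_probs = feature_probs, duration_probs = duration_probs,
    diabetes_prob = diabetes_prob, af_probs = af_probs,
    chol_mean = chol_mean, chol_sd = chol_sd, onset_hours = onset_hours,
    gp_hours = gp_hours, gp_days = gp_days, gp_defer_prob = gp_defer_prob,
    gp_delay_days = gp_delay_days), class = "tia_population_config")
}

#' @export
print.tia_population_config <- function(x, ...) {
  cat("TIA population configuration\n")
  cat(sprintf("  annual referrals: %g (high:low TIA ratio %g:1)\n",
              x$annual_referrals, x$high_low_ratio))
  cat("  diagnosis mix:",
      paste(sprintf("%s %.1f%%", names(x$mix), 100 * x$mix), collapse = ", "),
      "\n")
  invisible(x)
}

#' Repartition the true-TIA share at a new high:low ratio
#'
#' Used for the risk-mix sensitivity sweep: the true-TIA share of the mix
#' (base case 33%) is split between high and low risk at the given ratio;
#' the mimic and minor-stroke shares are unchanged.
#'
#' @param config A [population_config()].
#' @param ratio Positive high:low ratio (e.g. 2.5 for the base case; 1, 5
#'   and 7 in the sweep).
#' @return A new `tia_population_config`.
#' @export
apply_ratio <- function(config, ratio) {
  stopifnot(inherits(config, "tia_population_config"))
  if (!is.numeric(ratio) || length(ratio) != 1 || !is.finite(ratio) || ratio <= 0)
    stop("ratio must be a positive number")
  config$high_low_ratio <- ratio
  config$mix[["high_risk_tia"]] <- config$tia_share * ratio / (1 + ratio)
  config$mix[["low_risk_tia"]] <- config$tia_share / (1 + ratio)
  stopifnot(abs(sum(config$mix) - 1) < 1e-9)
  config
}

#' Expected overall GP-referral fraction
#'
#' The class-size-weighted mean of the per-class GP referral probabilities,
#' i.e. the unconditional probability that a referral arrives via the GP
#' before any out-of-hours re-routing to the emergency department.
#'
#' @param config A [population_config()].
#' @return A single probability.
#' @export
expected_gp_fraction <- function(config) {
  stopifnot(inherits(config, "tia_population_config"))
  sum(config$mix * config$gp_prob_by_class[names(config$mix)])
}

# TRUE where the GP route is open at simulation time t (days; day 0 = Monday)
gp_open_at <- function(t, config) {
  dow <- floor(t) %% 7
  tod <- (t - floor(t)) * 24
  dow %in% config$gp_days &
    tod >= config$gp_hours[1] & tod <= config$gp_hours[2]
}

# Earliest time >= t at which the GP route is open (vectorised)
next_gp_opening <- function(t, config) {
  open <- gp_open_at(t, config)
  out <- t
  idx <- which(!open)
  if (length(idx)) {
    ti <- t[idx]
    day <- floor(ti)
    tod <- (ti - day) * 24
    # before opening on a GP day: same day at opening time
    same <- (day %% 7) %in% config$gp_days & tod < config$gp_hours[1]
    day[!same] <- day[!same] + 1
    # advance to the next GP day at opening time
    for (k in 1:7) {
      notgp <- !((day %% 7) %in% config$gp_days)
      if (!any(notgp)) break
      day[notgp] <- day[notgp] + 1
    }
    out[idx] <- day + config$gp_hours[1] / 24
  }
  out
}

# Rejection-sample ABCD2 components so that (score > 4) == target_high.
# Always feasible: weakness + 60min + diabetes gives 5 regardless of age/BP,
# and "other"/"<10min"/no-diabetes gives at most A + B = 2.
sample_components <- function(n, band, sbp, target_high, config) {
  feat <- character(n); dur <- character(n); dm <- logical(n)
  todo <- seq_len(n)
  while (length(todo)) {
    m <- length(todo)
    feat[todo] <- sample(clinical_features, m, TRUE, config$feature_probs)
    dur[todo] <- sample(duration_bands, m, TRUE, config$duration_probs)
    dm[todo] <- stats::runif(m) < config$diabetes_prob
    sc <- abcd2_score(data.frame(age_band = band[todo], sbp = sbp[todo],
                                 clinical_feature = feat[todo],
                                 duration_band = dur[todo],
                                 diabetes = dm[todo]))
    todo <- todo[(sc > 4) != target_high[todo]]
  }
  data.frame(clinical_feature = feat, duration_band = dur, diabetes = dm)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Generate a synthetic referral cohort
#'
#' Draws a Poisson number of referrals over the horizon, with onset days
#' uniform over the horizon, onset time-of-day uniform over waking hours,
#' diagnosis classes from the configured mix, ABCD2 components sampled so
#' that score-based risk agrees with the diagnosis class (high-risk TIA and
#' minor stroke score > 4; low-risk TIA and mimic score <= 4), and
#' presentation route drawn from the class GP probability modulated by GP
#' opening hours. Reproducible under a fixed seed.
#'
#' @param config A [population_config()].
#' @param years Horizon in 364-day model years (> 0).
#' @param seed Integer seed.
#' @return A data frame, one row per patient, ordered by onset time, with
#'   columns `id`, `onset_time` (days; day 0 = Monday 00:00 of week 1),
#'   `age`, `sex`, `diagnosis`, `risk` (`"high"`/`"low"`, the operational
#'   triage class), `age_band`, `sbp`, `clinical_feature`, `duration_band`,
#'   `diabetes`, `abcd2`, `abcd`, `af_status`, `cholesterol`, `cea_flag`,
#'   `route` (`"gp"`/`"ed"`).
#' @examples
#' cohort <- generate_cohort(population_config(), years = 1, seed = 1)
#' table(cohort$diagnosis)
#' @export
generate_cohort <- function(config, years, seed) {
  stopifnot(inherits(config, "tia_population_config"))
  if (!is.numeric(years) || years <= 0) stop("years must be positive")
  set.seed(seed)
  horizon <- years * days_per_year
  n <- stats::rpois(1, config$annual_referrals * years)
  day <- floor(stats::runif(n, 0, horizon))
  tod <- stats::runif(n, config$onset_hours[1], config$onset_hours[2]) / 24
  onset <- day + tod

  diagnosis <- sample(diagnosis_classes, n, TRUE, config$mix)
  age <- rnorm_trunc(n, config$mean_age, config$sd_age,
                     config$age_range[1], config$age_range[2])
  sex <- ifelse(stats::runif(n) < config$prop_female, "female", "male")
  sbp_mean <- vapply(config$sbp_by_class, `[`, numeric(1), 1)[diagnosis]
  sbp_sd <- vapply(config$sbp_by_class, `[`, numeric(1), 2)[diagnosis]
  sbp <- rnorm_trunc(n, sbp_mean, sbp_sd, config$sbp_range[1], config$sbp_range[2])

  band <- age_band(age)
  target_high <- diagnosis %in% c("high_risk_tia", "minor_stroke")
  comp <- sample_components(n, band, sbp, target_high, config)
  score2 <- abcd2_score(cbind(data.frame(age_band = band, sbp = sbp), comp))
  score1 <- score2 - as.integer(comp$diabetes)

  af <- sample(names(config$af_probs), n, TRUE, config$af_probs)
  chol <- rnorm_trunc(n, config$chol_mean, config$chol_sd, 1, 15)
  cea <- stats::runif(n) < config$cea_prob

  wants_gp <- stats::runif(n) < config$gp_prob_by_class[diagnosis]
  ooh <- !gp_open_at(onset, config)
  defer <- stats::runif(n) < config$gp_defer_prob
  route <- ifelse(wants_gp & (!ooh | defer), "gp", "ed")

  out <- data.frame(
    id = seq_len(n), onset_time = onset, age = age, sex = sex,
    diagnosis = diagnosis,
    risk = ifelse(target_high, "high", "low"),
    age_band = band, sbp = sbp,
    clinical_feature = comp$clinical_feature,
    duration_band = comp$duration_band, diabetes = comp$diabetes,
    abcd2 = score2, abcd = score1, af_status = af, cholesterol = chol,
    cea_flag = cea, route = route)
  out <- out[order(out$onset_time), ]
  out$id <- seq_len(n)
  rownames(out) <- NULL
  out
}

#' Write a cohort to CSV
#'
#' Adds an ISO-like `onset_stamp` column (`"D<day>T<hh>:<mm>"`, day 0 =
#' Monday of week 1) and writes one row per patient in the documented
#' column order of [generate_cohort()].
#'
#' @param cohort A cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  d <- floor(cohort$onset_time)
  mins <- round((cohort$onset_time - d) * 24 * 60)
  cohort$onset_stamp <- sprintf("D%04dT%02d:%02d", d, mins %/% 60, mins %% 60)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
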