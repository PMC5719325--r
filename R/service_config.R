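# Clinic calendars: weekly slot patterns, specialist leave, allocation
# policies and hypothetical weekend variants.

allocation_policies <- c("order_of_referral_priority", "reserved_plus_extra",
                         "admit_if_breach", "ward_timed")

#' Weekly clinic pattern
#'
#' The number of routine clinic slots offered on each day of the week
#' (Monday..Sunday), optionally with per-day discrete distributions for
#' days whose capacity varies week to week, and the clinic start time of
#' day. All of a day's slots are treated as occurring at the clinic start
#' time; intra-clinic timing is not modelled.
#'
#' @param slots Numeric vector of 5 (Mon-Fri, weekend padded with 0) or 7
#'   non-negative slot counts.
#' @param stochastic_days Optional named list mapping a day name
#'   (`"mon"`..`"sun"`) to a named probability vector over slot counts,
#'   e.g. `list(mon = c("4" = 0.5, "6" = 0.5))`. Sampled independently
#'   each week.
#' @param clinic_start Clinic start time of day in hours (default 09:00).
#' @return An object of class `tia_weekly_pattern`.
#' @export
weekly_pattern <- function(slots, stochastic_days = NULL, clinic_start = 9) {
  if (length(slots) == 5) slots <- c(slots, 0, 0)
  if (length(slots) != 7 || any(slots < 0) || any(slots != round(slots)))
    stop("slots must be 5 or 7 non-negative integer counts (Mon..Sun)")
  dn <- c("mon", "tue", "wed", "thu", "fri", "sat", "sun")
  slots <- stats::setNames(as.integer(slots), dn)
  if (!is.null(stochastic_days)) {
    if (!all(names(stochastic_days) %in% dn))
      stop("stochastic_days must be named by day (mon..sun)")
    for (d in names(stochastic_days)) {
      p <- stochastic_days[[d]]
      if (abs(sum(p) - 1) > 1e-9 || any(p < 0))
        stop("stochastic day distributions must sum to 1")
      if (anyNA(as.integer(names(p)))) stop("slot counts must be named integers")
    }
  }
  structure(list(slots = slots, stochastic_days = stochastic_days,
                 clinic_start = clinic_start),
            class = "tia_weekly_pattern")
}

#' Specialist leave model
#'
#' Each of `n_specialists` owns `slots_owned` slots of the weekly pattern
#' and is absent for `weeks_absent` weeks per year. If no cover is
#' provided, the owned slots are cancelled in absent weeks; with cover the
#' calendar is unaffected.
#'
#' @param n_specialists Number of specialists (0 disables the model).
#' @param weeks_absent Weeks of absence per specialist per year (0-52).
#' @param cover_provided Is absence covered by another specialist?
#' @param slots_owned Slots per week owned by each specialist.
#' @return An object of class `tia_leave_model`.
#' @export
leave_model <- function(n_specialists = 0, weeks_absent = 0,
                        cover_provided = TRUE, slots_owned = 0) {
  if (weeks_absent < 0 || weeks_absent > 52)
    stop("weeks_absent must lie in [0, 52]")
  stopifnot(n_specialists >= 0, slots_owned >= 0)
  structure(list(n_specialists = as.integer(n_specialists),
                 weeks_absent = as.integer(weeks_absent),
                 cover_provided = isTRUE(cover_provided),
                 slots_owned = as.integer(slots_owned)),
            class = "tia_leave_model")
}

#' Service scenario
#'
#' A hospital service configuration: its weekly clinic pattern, leave
#' model, allocation policy and weekend options. Four presets describing
#' real services are available through [scenario_preset()]; hypothetical
#' weekend variants are derived with [make_weekend_variant()].
#'
#' Allocation policies:
#' \describe{
#'   \item{`order_of_referral_priority`}{all patients take the next free
#'     slot in order of referral; among same-day referrals, high-risk
#'     patients are placed first.}
#'   \item{`reserved_plus_extra`}{as above, plus the last slot of each
#'     clinic day is reserved for high-risk referrals (opening to any
#'     patient 24 hours before it starts), and when the next eligible slot
#'     would miss the 24-hour target an on-demand extra slot is created
#'     (at most one per day, on any day of the week).}
#'   \item{`admit_if_breach`}{a high-risk patient whose next slot would
#'     miss the 24-hour target is admitted at referral (counting as seen
#'     and treated immediately); low-risk patients queue for slots.}
#'   \item{`ward_timed`}{high-risk patients are seen on the ward on any
#'     day of the week: referrals before 10:00 at 17:00 the same day,
#'     later referrals at 10:00 the next day; low-risk patients queue for
#'     slots.}
#' }
#'
#' @param hospital `"h1"` or `"h2"`.
#' @param variant Label, e.g. `"original"`, `"modified"`, `"weekend_17"`,
#'   `"custom"`.
#' @param pattern A [weekly_pattern()].
#' @param leave A [leave_model()].
#' @param policy One of the four allocation policies.
#' @param weekend_high_risk_slots If `TRUE`, weekend slots in the pattern
#'   are reserved high-risk slots.
#' @param ward_review If `TRUE`, high-risk patients referred from the
#'   emergency department are seen by a specialist on the ward within two
#'   hours of referral.
#' @param name Display name.
#' @return An object of class `tia_service_scenario`.
#' @export
service_scenario <- function(hospital = c("h1", "h2"), variant = "custom",
                             pattern, leave = leave_model(),
                             policy = allocation_policies,
                             weekend_high_risk_slots = FALSE,
                             ward_review = FALSE,
                             name = NULL) {
  hospital <- match.arg(hospital)
  policy <- match.arg(policy)
  stopifnot(inherits(pattern, "tia_weekly_pattern"),
            inherits(leave, "tia_leave_model"))
  weekday_min <- min_weekly_weekday_slots(pattern)
  if (!leave$cover_provided &&
      leave$n_specialists * leave$slots_owned > weekday_min)
    stop("leave model inconsistent with pattern: owned slots (",
         leave$n_specialists * leave$slots_owned,
         ") exceed the weekly weekday total (", weekday_min, ")")
  if (is.null(name)) name <- paste(hospital, variant, sep = "-")
  structure(list(hospital = hospital, variant = variant, pattern = pattern,
                 leave = leave, policy = policy,
                 weekend_high_risk_slots = isTRUE(weekend_high_risk_slots),
                 ward_review = isTRUE(ward_review), name = name),
            class = "tia_service_scenario")
}

#' @export
print.tia_service_scenario <- function(x, ...) {
  cat(sprintf("TIA service scenario '%s' (policy: %s)\n", x$name, x$policy))
  cat("  weekly slots (Mon..Sun):", paste(x$pattern$slots, collapse = " "),
      sprintf(" ~%.0f slots/year\n", expected_annual_slots(x)))
  if (x$weekend_high_risk_slots) cat("  weekend high-risk slots enabled\n")
  invisible(x)
}

# minimum possible weekday slot total (stochastic days at their minimum)
min_weekly_weekday_slots <- function(pattern) {
  s <- pattern$slots[1:5]
  dn <- names(pattern$slots)
  for (d in names(pattern$stochastic_days)) {
    i <- match(d, dn)
    if (i <= 5) s[i] <- min(as.integer(names(pattern$stochastic_days[[d]])))
  }
  sum(s)
}

#' Expected weekly and annual slot counts
#'
#' `expected_weekly_slots()` sums the pattern with stochastic days at
#' their expectation; `expected_annual_slots()` multiplies by 52 weeks and
#' subtracts the expected uncovered leave loss.
#'
#' @param pattern A [weekly_pattern()].
#' @param scenario A [service_scenario()].
#' @return A single number.
#' @export
expected_weekly_slots <- function(pattern) {
  s <- as.numeric(pattern$slots)
  dn <- names(pattern$slots)
  for (d in names(pattern$stochastic_days)) {
    p <- pattern$stochastic_days[[d]]
    s[match(d, dn)] <- sum(as.integer(names(p)) * p)
  }
  sum(s)
}

#' @rdname expected_weekly_slots
#' @export
expected_annual_slots <- function(scenario) {
  stopifnot(inherits(scenario, "tia_service_scenario"))
  lost <- 0
  lv <- scenario$leave
  if (!lv$cover_provided)
    lost <- lv$n_specialists * lv$weeks_absent * lv$slots_owned
  expected_weekly_slots(scenario$pattern) * weeks_per_year - lost
}

#' Named service presets
#'
#' The four service configurations as modelled from the two study
#' hospitals:
#' \describe{
#'   \item{`h1-original`}{16 slots/week (Mon-Fri 2,4,4,4,2), four
#'     specialists each absent ~7 weeks/year without cover; simple
#'     order-of-referral allocation with same-day high-risk priority.}
#'   \item{`h1-modified`}{17 slots/week (4,4,2,3,4), same leave model;
#'     reserved end-of-clinic high-risk slots plus on-demand extra slots.}
#'   \item{`h2-original`}{12 slots/week (Mon 6, Tue 4, Wed 2), leave fully
#'     covered; high-risk patients who cannot be seen within 24 hours are
#'     admitted.}
#'   \item{`h2-modified`}{Mon 4-or-6 (50/50 each week), Wed 4, Fri 4,
#'     leave covered; high-risk patients seen on the ward at fixed times
#'     any day of the week, with a two-hour ward review for ED referrals.}
#' }
#'
#' @param name Preset name.
#' @return A [service_scenario()].
#' @export
scenario_preset <- function(name = c("h1-original", "h1-modified",
                                     "h2-original", "h2-modified")) {
  name <- match.arg(name)
  switch(name,
    "h1-original" = service_scenario(
      "h1", "original", weekly_pattern(c(2, 4, 4, 4, 2)),
      leave_model(4, 7, cover_provided = FALSE, slots_owned = 4),
      policy = "order_of_referral_priority"),
    "h1-modified" = service_scenario(
      "h1", "modified", weekly_pattern(c(4, 4, 2, 3, 4)),
      leave_model(4, 7, cover_provided = FALSE, slots_owned = 4),
      policy = "reserved_plus_extra"),
    "h2-original" = service_scenario(
      "h2", "original", weekly_pattern(c(6, 4, 2, 0, 0)),
      leave_model(2, 7, cover_provided = TRUE, slots_owned = 6),
      policy = "admit_if_breach"),
    "h2-modified" = service_scenario(
      "h2", "modified",
      weekly_pattern(c(4, 0, 4, 0, 4),
                     stochastic_days = list(mon = c("4" = 0.5, "6" = 0.5))),
      leave_model(2, 7, cover_provided = TRUE, slots_owned = 6),
      policy = "ward_timed", ward_review = TRUE))
}

#' Derive a weekend-service variant
#'
#' Adds reserved high-risk slots on Saturday and Sunday and rescales the
#' weekday pattern to the requested weekly total. Weekday slots are removed
#' one at a time from the day with the largest count, ties broken towards
#' the latest weekday. Reductions of more than five slots per week are
#' rejected. The two-hour emergency-department ward review is enabled,
#' since weekend working implies specialist presence seven days a week.
#'
#' @param base A [service_scenario()] without stochastic weekday capacity.
#' @param weekday_slots Target weekday slots per week (at least the base
#'   total minus 5).
#' @param weekend_slots Length-2 count of high-risk slots on Saturday and
#'   Sunday (default one each).
#' @return A new [service_scenario()].
#' @export
make_weekend_variant <- function(base, weekday_slots, weekend_slots = c(1, 1)) {
  stopifnot(inherits(base, "tia_service_scenario"))
  if (!is.null(base$pattern$stochastic_days))
    stop("weekend variants of stochastic weekday patterns are not supported")
  wd <- base$pattern$slots[1:5]
  cur <- sum(wd)
  if (weekday_slots < 0) stop("weekday_slots must be non-negative")
  if (weekday_slots > cur)
    stop("weekday_slots exceeds the base pattern (", cur, ")")
  if (cur - weekday_slots > 5)
    stop("reduction of ", cur - weekday_slots,
         " slots/week exceeds the supported maximum of five")
  while (sum(wd) > weekday_slots) {
    day <- max(which(wd == max(wd))) # largest count, latest weekday
    wd[day] <- wd[day] - 1L
  }
  pat <- weekly_pattern(c(wd, weekend_slots),
                        clinic_start = base$pattern$clinic_start)
  lv <- base$leave
  if (lv$n_specialists > 0) # fewer clinics per specialist after reduction
    lv$slots_owned <- min(lv$slots_owned,
                          sum(wd) %/% lv$n_specialists)
  service_scenario(base$hospital, sprintf("weekend_%d", weekday_slots),
                   pat, lv, base$policy,
                   weekend_high_risk_slots = TRUE, ward_review = TRUE,
                   name = sprintf("%s-weekend-%d", base$hospital, weekday_slots))
}

#' Build a dated clinic calendar
#'
#' Instantiates the weekly pattern on every week of the horizon, samples
#' stochastic-day capacities, marks reserved high-risk slots (the last
#' slot of each weekday clinic under the `reserved_plus_extra` policy, and
#' all weekend slots when weekend working is enabled), assigns specialist
#' ownership, and removes owned slots in uncovered absence weeks. Absence
#' weeks are drawn uniformly per year, non-overlapping between specialists
#' when feasible.
#'
#' @param scenario A [service_scenario()].
#' @param years Horizon in whole 364-day years (>= 1).
#' @param seed Integer seed (stochastic capacities and leave weeks).
#' @return A data frame of slots ordered by time then within-day sequence:
#'   `slot_id`, `week`, `day` (global day index, 0 = first Monday), `seq`
#'   (within-day order), `time` (days), `kind` (`"routine"` or
#'   `"reserved_high_risk"`), `specialist` (0 = unowned), `occupied_by`
#'   (patient id, `NA` until a simulation run fills it).
#' @export
build_calendar <- function(scenario, years, seed) {
  stopifnot(inherits(scenario, "tia_service_scenario"))
  if (!is.numeric(years) || years < 1 || years != round(years))
    stop("years must be a whole number >= 1")
  set.seed(seed)
  pat <- scenario$pattern
  nweeks <- weeks_per_year * years
  dn <- names(pat$slots)

  counts <- matrix(rep(as.integer(pat$slots), each = nweeks), nweeks, 7)
  for (d in names(pat$stochastic_days)) {
    p <- pat$stochastic_days[[d]]
    counts[, match(d, dn)] <-
      sample(as.integer(names(p)), nweeks, TRUE, p)
  }

  cnt <- as.vector(t(counts)) # week-major, Mon..Sun within week
  week <- rep(rep(seq_len(nweeks), each = 7), cnt)
  dow <- rep(rep(1:7, nweeks), cnt)
  seqd <- sequence(cnt)
  day <- (week - 1L) * 7L + dow - 1L
  time <- day + pat$clinic_start / 24

  # specialist ownership only materialises when leave can cancel slots
  specialist <- integer(length(day))
  lv <- scenario$leave
  leave_bites <- !lv$cover_provided && lv$n_specialists > 0 &&
    lv$slots_owned > 0 && lv$weeks_absent > 0
  if (leave_bites) {
    wk <- dow <= 5
    widx <- stats::ave(seq_len(sum(wk)), week[wk], FUN = seq_along)
    owned <- widx <= lv$n_specialists * lv$slots_owned
    sp <- integer(sum(wk))
    sp[owned] <- (widx[owned] - 1L) %% lv$n_specialists + 1L
    specialist[wk] <- sp

    keep <- rep(TRUE, length(day))
    for (y in seq_len(years)) {
      wks <- (y - 1L) * weeks_per_year + seq_len(weeks_per_year)
      need <- lv$n_specialists * lv$weeks_absent
      if (need <= weeks_per_year) {
        drawn <- sample(wks, need)
        absent <- split(drawn, rep(seq_len(lv$n_specialists),
                                   each = lv$weeks_absent))
      } else {
        absent <- lapply(seq_len(lv$n_specialists),
                         function(s) sample(wks, lv$weeks_absent))
      }
      for (s in seq_len(lv$n_specialists))
        keep[specialist == s & week %in% absent[[s]]] <- FALSE
    }
    week <- week[keep]; dow <- dow[keep]; seqd <- seqd[keep]
    day <- day[keep]; time <- time[keep]; specialist <- specialist[keep]
  }

  # slot kinds are assigned on the surviving slots, so the reserved
  # end-of-clinic slot is the last slot actually taking place that day
  kind <- rep("routine", length(day))
  if (scenario$policy == "reserved_plus_extra" && length(day))
    kind[dow <= 5 & !duplicated(day, fromLast = TRUE)] <- "reserved_high_risk"
  if (scenario$weekend_high_risk_slots)
    kind[dow >= 6] <- "reserved_high_risk"

  cal <- data.frame(week = week, day = day, seq = seqd, time = time,
                    kind = kind, specialist = specialist,
                    occupied_by = rep(NA_integer_, length(day)))
  cal$slot_id <- seq_len(nrow(cal))
  rownames(cal) <- NULL
  cal[, c("slot_id", "week", "day", "seq", "time", "kind", "specialist",
          "occupied_by")]
}

#' Write a clinic calendar to CSV
#'
#' @param calendar A calendar from [build_calendar()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calendar_csv <- function(calendar, path) {
  utils::write.csv(calendar, path, row.names = FALSE)
  invisible(path)
}
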