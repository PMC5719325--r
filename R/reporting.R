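# Batch simulation, run-level summaries, 99% quasi-confidence aggregation,
# sensitivity sweeps and report rendering.

#' Quasi-confidence interval over run-level means
#'
#' `mean(x) +/- z * sd(x) / sqrt(n)` with the normal multiplier
#' (z = 2.576 at the default 99% level). The interval reflects only the
#' simulation's sampling variability across runs, not any parameter
#' uncertainty, hence "quasi".
#'
#' @param x Numeric vector of run-level means (length >= 2).
#' @param level Confidence level (default 0.99).
#' @return Named vector `c(mean, lower, upper)`.
#' @export
quasi_ci <- function(x, level = 0.99) {
  if (length(x) < 2) stop("need at least 2 runs")
  z <- stats::qnorm((1 + level) / 2)
  m <- mean(x)
  half <- z * stats::sd(x) / sqrt(length(x))
  c(mean = m, lower = m - half, upper = m + half)
}

# one-run outcome summary restricted to the reported (post-warm-up) years
summarise_run <- function(cohort, sim, fu, costs, years, warmup, pop_config) {
  ny <- years - warmup
  yr <- floor(cohort$onset_time / days_per_year) + 1
  rep_pat <- yr > warmup
  rec <- sim$records[rep_pat, ]
  coh <- cohort[rep_pat, ]
  fur <- fu[rep_pat, ]

  cal <- sim$calendar
  cal_yr <- floor(cal$time / days_per_year) + 1
  cal_rep <- cal[cal_yr > warmup, ]
  ex_day_yr <- floor((rec$seen_time[rec$modality %in% "extra_slot"])) %/%
    days_per_year + 1
  tally <- list(provided = nrow(cal_rep),
                used = sum(!is.na(cal_rep$occupied_by)),
                unused = sum(is.na(cal_rep$occupied_by)),
                extra = sum(rec$modality %in% "extra_slot"),
                ward = sum(rec$modality %in% "ward_unscheduled"),
                admissions = sum(rec$modality %in% "admission"),
                unplaced = sum(!rec$placed))

  hi <- rec$risk == "high" & rec$placed
  delays <- rec$seen_time[hi] - rec$referral_time[hi]
  n_hi_seen <- sum(hi)
  n_hi_within <- sum(delays <= 1)
  cost <- cost_scenario(rec, tally, coh, costs, followup = fur)

  list(stats = data.frame(
    referrals_py = nrow(rec) / ny,
    strokes_py = sum(fur$event == "major_stroke") / ny,
    deaths_py = sum(fur$event == "post_stroke_death") / ny,
    high_breaches_py = sum(rec$high_risk_breach) / ny,
    low_breaches_py = sum(rec$low_risk_breach) / ny,
    high_seen_py = n_hi_seen / ny,
    attainment_pct = 100 * n_hi_within / max(1, n_hi_seen),
    slots_provided_py = tally$provided / ny,
    slots_used_py = tally$used / ny,
    slots_unused_py = tally$unused / ny,
    extra_py = tally$extra / ny,
    ward_py = tally$ward / ny,
    admissions_py = tally$admissions / ny,
    unplaced_py = tally$unplaced / ny,
    cost_py = attr(cost, "total") / ny),
    delays = delays)
}

#' Run a batch of simulations for one scenario
#'
#' Runs the full pipeline (cohort generation, scenario simulation,
#' follow-up) `runs` times. Each run simulates `years` years of arrivals
#' of which the first `warmup` years are excluded from statistics as a
#' queue warm-up. Every run uses three independent sub-seeds (population,
#' calendar, risk) derived from `seed`, so batches started from the same
#' seed share random streams across scenarios (common random numbers).
#'
#' @param scenario A [service_scenario()].
#' @param pop_config A [population_config()].
#' @param risk_cfg A [risk_config()].
#' @param costs A [cost_table()].
#' @param runs Number of runs (default 100).
#' @param years Simulated years of arrivals per run (default 12).
#' @param warmup Warm-up years excluded from statistics (default 1).
#' @param seed Integer master seed.
#' @return An object of class `tia_batch`: `runs` (data frame, one row of
#'   per-year outcome means per run), `delays` (high-risk
#'   referral-to-seen delays in days, pooled over runs and reported
#'   years), and metadata (`scenario`, `pop_config`, `seed`, ...).
#' @seealso [aggregate_runs()], [sensitivity_sweep()]
#' @export
run_batch <- function(scenario, pop_config = population_config(),
                      risk_cfg = risk_config(), costs = cost_table(),
                      runs = 100, years = 12, warmup = 1, seed = 1) {
  stopifnot(runs >= 1, years > warmup)
  set.seed(seed)
  sub <- matrix(sample.int(2^31 - 2, 3 * runs), runs, 3)
  rows <- vector("list", runs)
  delays <- vector("list", runs)
  for (r in seq_len(runs)) {
    cohort <- generate_cohort(pop_config, years, sub[r, 1])
    sim <- run_scenario(cohort, scenario, years, sub[r, 2], pop_config)
    fu <- simulate_followup(cohort, sim$records, risk_cfg, sub[r, 3])
    s <- summarise_run(cohort, sim, fu, costs, years, warmup, pop_config)
    rows[[r]] <- s$stats
    delays[[r]] <- s$delays
  }
  structure(list(runs = do.call(rbind, rows), delays = unlist(delays),
                 scenario = scenario$name, policy = scenario$policy,
                 pop_config = pop_config, risk_cfg = risk_cfg,
                 n_runs = runs, years = years, warmup = warmup, seed = seed),
            class = "tia_batch")
}

#' @export
print.tia_batch <- function(x, ...) {
  cat(sprintf("TIA simulation batch: %s, %d runs x %d years (%d warm-up)\n",
              x$scenario, x$n_runs, x$years, x$warmup))
  print(aggregate_runs(x))
  invisible(x)
}

#' Aggregate a batch into scenario-level outcomes
#'
#' Means with 99% quasi-confidence intervals over run-level annual means
#' for every outcome (referrals, strokes, post-stroke deaths, breaches,
#' attainment, slot utilisation, cost), breach percentages against the
#' expected high- and low-risk denominators implied by the population
#' configuration, and the median (IQR) high-risk referral-to-seen delay
#' pooled over all patients in all reported years.
#'
#' @param batch A `tia_batch` from [run_batch()].
#' @param level Confidence level (default 0.99).
#' @return An object of class `tia_aggregate`: `stats` (data frame with
#'   `metric`, `mean`, `lower`, `upper`), `delay` (median and quartiles),
#'   `breach_pct` (high/low percentages and denominators) and metadata.
#' @export
aggregate_runs <- function(batch, level = 0.99) {
  stopifnot(inherits(batch, "tia_batch"))
  runs <- batch$runs
  if (nrow(runs) < 2) stop("need at least 2 runs to aggregate")
  ci <- t(vapply(names(runs), function(m) quasi_ci(runs[[m]], level),
                 numeric(3)))
  stats <- data.frame(metric = rownames(ci), mean = ci[, 1],
                      lower = ci[, 2], upper = ci[, 3], row.names = NULL)
  q <- stats::quantile(batch$delays, c(0.25, 0.5, 0.75), names = FALSE)
  mix <- batch$pop_config$mix
  denom_high <- batch$pop_config$annual_referrals *
    (mix[["high_risk_tia"]] + mix[["minor_stroke"]])
  denom_low <- batch$pop_config$annual_referrals *
    (mix[["low_risk_tia"]] + mix[["tia_mimic"]])
  breach_pct <- c(
    high = 100 * mean(runs$high_breaches_py) / denom_high,
    low = 100 * mean(runs$low_breaches_py) / denom_low,
    denom_high = denom_high, denom_low = denom_low)
  structure(list(stats = stats,
                 delay = c(median = q[2], q1 = q[1], q3 = q[3]),
                 breach_pct = breach_pct, scenario = batch$scenario,
                 n_runs = nrow(runs), level = level),
            class = "tia_aggregate")
}

#' @export
print.tia_aggregate <- function(x, ...) {
  cat(sprintf("Scenario %s (%d runs, %.0f%% quasi-CI)\n",
              x$scenario, x$n_runs, 100 * x$level))
  g <- function(m) x$stats[x$stats$metric == m, ]
  line <- function(lbl, m, fmt = "%.1f")
    cat(sprintf(paste0("  %-38s", fmt, " (", fmt, " to ", fmt, ")\n"),
                lbl, g(m)$mean, g(m)$lower, g(m)$upper))
  line("Patients presenting/year", "referrals_py")
  line("Major strokes post TIA/year", "strokes_py", "%.2f")
  line("Post-stroke deaths/year", "deaths_py", "%.2f")
  line("High-risk breaches/year", "high_breaches_py")
  line("Low-risk breaches/year", "low_breaches_py")
  cat(sprintf("  %-38s%.1f%% / %.1f%% (denoms %.0f / %.0f)\n",
              "Breach % (high / low)", x$breach_pct[["high"]],
              x$breach_pct[["low"]], x$breach_pct[["denom_high"]],
              x$breach_pct[["denom_low"]]))
  line("24h attainment (% of high risk seen)", "attainment_pct")
  cat(sprintf("  %-38s%.2f (IQR %.2f-%.2f)\n",
              "Referral-to-seen, high risk (days)", x$delay[["median"]],
              x$delay[["q1"]], x$delay[["q3"]]))
  line("Routine slots provided/year", "slots_provided_py")
  line("Routine slots unused/year", "slots_unused_py")
  line("Cost/year (GBP)", "cost_py", "%.0f")
  invisible(x)
}

#' Sensitivity sweep over the high:low risk ratio
#'
#' Re-runs one or more scenarios at each high:low ratio (base-case 2.5:1;
#' 1:1, 5:1 and 7:1 by default), repartitioning the true-TIA share with
#' [apply_ratio()]. The same master seed is used at every ratio and for
#' every scenario, so comparisons are made under common random numbers;
#' at the configuration's own ratio the batch reproduces the base-case
#' batch exactly.
#'
#' @param scenarios A [service_scenario()] or list of them.
#' @param pop_config A [population_config()].
#' @param ratios Numeric vector of high:low ratios.
#' @param ... Passed to [run_batch()] (`risk_cfg`, `costs`, `runs`,
#'   `years`, `warmup`, `seed`).
#' @return A data frame with one row per (ratio, scenario): attainment,
#'   breaches, strokes and delay summaries, with the full batches in the
#'   `batches` attribute (named `"<ratio>/<scenario>"`).
#' @export
sensitivity_sweep <- function(scenarios, pop_config = population_config(),
                              ratios = c(1, 2.5, 5, 7), ...) {
  if (inherits(scenarios, "tia_service_scenario")) scenarios <- list(scenarios)
  out <- list()
  batches <- list()
  for (ratio in ratios) {
    cfg <- apply_ratio(pop_config, ratio)
    for (sc in scenarios) {
      b <- run_batch(sc, cfg, ...)
      a <- aggregate_runs(b)
      g <- function(m) a$stats$mean[a$stats$metric == m]
      out[[length(out) + 1]] <- data.frame(
        ratio = ratio, scenario = sc$name,
        attainment_pct = g("attainment_pct"),
        high_breaches_py = g("high_breaches_py"),
        low_breaches_py = g("low_breaches_py"),
        strokes_py = g("strokes_py"),
        median_delay = a$delay[["median"]])
      batches[[paste(ratio, sc$name, sep = "/")]] <- b
    }
  }
  structure(do.call(rbind, out), batches = batches)
}

#' Write aggregate results to report files
#'
#' Emits an outcome table CSV (one column per scenario, labelled rows in
#' the style of a service-comparison table), a long-format CSV of the
#' utilisation/breach bar decomposition (used and unused routine slots,
#' extra slots, unscheduled ward reviews, admissions, high- and low-risk
#' breaches, all per year) and a JSON file with the full aggregates.
#'
#' @param aggregates Named list of [aggregate_runs()] results (names used
#'   as column headers; unnamed lists fall back to scenario names).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of the files written, invisibly.
#' @export
render_outputs <- function(aggregates, dir, prefix = "tia") {
  if (inherits(aggregates, "tia_aggregate")) aggregates <- list(aggregates)
  if (is.null(names(aggregates)))
    names(aggregates) <- vapply(aggregates, `[[`, "", "scenario")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  pull <- function(a, m) a$stats$mean[a$stats$metric == m]
  row_defs <- c(
    "Total no of patients presenting" = "referrals_py",
    "Major strokes post TIA (mean/year)" = "strokes_py",
    "Post-stroke deaths (mean/year)" = "deaths_py",
    "No of high-risk breaches/year" = "high_breaches_py",
    "No of low-risk breaches/year" = "low_breaches_py",
    "24h attainment (% of high-risk seen)" = "attainment_pct",
    "Routine clinic slots provided/year" = "slots_provided_py",
    "Routine clinic slots unused/year" = "slots_unused_py",
    "Cost of service provision (GBP/year)" = "cost_py")
  tab <- data.frame(outcome = names(row_defs))
  for (nm in names(aggregates))
    tab[[nm]] <- vapply(row_defs, pull, numeric(1), a = aggregates[[nm]])
  med <- tab[1, , drop = FALSE]
  med$outcome <- "Median referral-to-seen, high risk (days)"
  for (nm in names(aggregates)) med[[nm]] <- aggregates[[nm]]$delay[["median"]]
  tab <- rbind(tab, med)
  f_tab <- file.path(dir, paste0(prefix, "-outcomes.csv"))
  utils::write.csv(tab, f_tab, row.names = FALSE)

  bar_defs <- c(slots_used = "slots_used_py", slots_unused = "slots_unused_py",
                extra_slots = "extra_py", unscheduled = "ward_py",
                admissions = "admissions_py",
                high_breaches = "high_breaches_py",
                low_breaches = "low_breaches_py")
  bars <- do.call(rbind, lapply(names(aggregates), function(nm)
    data.frame(scenario = nm, component = names(bar_defs),
               per_year = vapply(bar_defs, pull, numeric(1),
                                 a = aggregates[[nm]]))))
  f_bar <- file.path(dir, paste0(prefix, "-utilisation.csv"))
  utils::write.csv(bars, f_bar, row.names = FALSE)

  f_json <- file.path(dir, paste0(prefix, "-aggregates.json"))
  jsonlite::write_json(
    lapply(aggregates, function(a)
      list(scenario = a$scenario, n_runs = a$n_runs, stats = a$stats,
           delay = as.list(a$delay), breach_pct = as.list(a$breach_pct))),
    f_json, auto_unbox = TRUE, digits = NA)
  invisible(c(f_tab, f_bar, f_json))
}
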