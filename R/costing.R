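# Pathway costing from a configurable unit-cost table.

#' Unit-cost table
#'
#' Unit costs in GBP for every pathway component. The shipped defaults are
#' PLACEHOLDER values chosen only to make scenario totals order-of-
#' magnitude plausible (low hundreds of thousands of pounds per year for a
#' ~490-patient service); they are structural inputs, not reference costs,
#' and every analysis should supply its own table for its price year.
#' Routine clinic slots are charged whether used or unused.
#'
#' @param gp_visit,ed_attendance,ambulance,clinic_slot,unscheduled_ward_review,admission_per_day,cea_surgery,annual_drug_cost,acute_stroke_admission
#'   Non-negative unit costs in GBP.
#' @param price_year Required label for the price year of the table.
#' @return An object of class `tia_cost_table`.
#' @export
cost_table <- function(gp_visit = 36, ed_attendance = 138, ambulance = 230,
                       clinic_slot = 150, unscheduled_ward_review = 150,
                       admission_per_day = 300, cea_surgery = 3000,
                       annual_drug_cost = 250, acute_stroke_admission = 4000,
                       price_year = "PLACEHOLDER") {
  costs <- c(gp_visit = gp_visit, ed_attendance = ed_attendance,
             ambulance = ambulance, clinic_slot = clinic_slot,
             unscheduled_ward_review = unscheduled_ward_review,
             admission_per_day = admission_per_day,
             cea_surgery = cea_surgery, annual_drug_cost = annual_drug_cost,
             acute_stroke_admission = acute_stroke_admission)
  if (anyNA(costs) || any(costs < 0)) stop("all unit costs must be >= 0")
  if (is.null(price_year) || !nzchar(price_year))
    stop("a price-year label is required")
  structure(c(as.list(costs), list(price_year = price_year)),
            class = "tia_cost_table")
}

#' Cost a completed scenario run
#'
#' Accumulates per-component costs: GP visits and ambulance/ED attendance
#' (pre-hospital, identical across scenarios for a common cohort), every
#' provided routine or reserved clinic slot (used or unused) plus any
#' extra slots, unscheduled ward reviews, admissions, carotid surgery,
#' annual preventative therapy for non-mimic patients and acute admissions
#' for subsequent major strokes (when follow-up results are supplied).
#' The grand total equals the component sum exactly.
#'
#' @param records Pathway records (possibly filtered to reported years).
#' @param tally Slot tally, matching the filtering of `records` (list with
#'   `provided`, `extra`, `ward`, `admissions`).
#' @param cohort The matching cohort rows (columns `route`, `cea_flag`,
#'   `diagnosis`).
#' @param table A [cost_table()].
#' @param followup Optional follow-up results from [simulate_followup()]
#'   (adds acute stroke admission costs).
#' @param admission_los_days Length of stay per TIA admission, days.
#' @return An object of class `tia_cost_breakdown`: data frame of
#'   components (`component`, `n`, `unit_cost`, `cost`) with a `total`
#'   attribute.
#' @export
cost_scenario <- function(records, tally, cohort, table = cost_table(),
                          followup = NULL, admission_los_days = 1) {
  stopifnot(inherits(table, "tia_cost_table"))
  need <- c("gp_visit", "ed_attendance", "ambulance", "clinic_slot",
            "unscheduled_ward_review", "admission_per_day", "cea_surgery",
            "annual_drug_cost")
  missing <- setdiff(need, names(table))
  if (length(missing)) stop("missing unit cost: ", paste(missing, collapse = ", "))
  n_gp <- sum(cohort$route == "gp")
  n_ed <- sum(cohort$route == "ed")
  n_strokes <- if (is.null(followup)) 0 else sum(followup$event == "major_stroke")
  rows <- data.frame(
    component = c("gp_visit", "ambulance", "ed_attendance", "clinic_slots",
                  "extra_slots", "ward_reviews", "admissions", "cea_surgery",
                  "drug_therapy", "stroke_care"),
    n = c(n_gp, n_ed, n_ed, tally$provided, tally$extra, tally$ward,
          tally$admissions, sum(cohort$cea_flag),
          sum(cohort$diagnosis != "tia_mimic"), n_strokes),
    unit_cost = c(table$gp_visit, table$ambulance, table$ed_attendance,
                  table$clinic_slot, table$clinic_slot,
                  table$unscheduled_ward_review,
                  table$admission_per_day * admission_los_days,
                  table$cea_surgery, table$annual_drug_cost,
                  table$acute_stroke_admission))
  rows$cost <- rows$n * rows$unit_cost
  structure(rows, total = sum(rows$cost), price_year = table$price_year,
            class = c("tia_cost_breakdown", "data.frame"))
}

#' @export
print.tia_cost_breakdown <- function(x, ...) {
  cat(sprintf("Cost breakdown (price year: %s)\n", attr(x, "price_year")))
  print.data.frame(x)
  cat(sprintf("Total: GBP %.2f\n", attr(x, "total")))
  invisible(x)
}
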