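# YAML/JSON configuration input.

#' Read a model configuration file
#'
#' Reads a YAML (or JSON) file with optional top-level sections
#' `population`, `scenario`, `risk` and `costs`; each section's entries
#' are passed as arguments to [population_config()],
#' [service_scenario()]/[scenario_preset()], [risk_config()] and
#' [cost_table()] respectively, so any omitted entry keeps its default.
#' A `scenario` section may either name a `preset` or give `hospital`,
#' `policy`, `pattern` (`slots`, optional `stochastic_days`,
#' `clinic_start`) and `leave` fields.
#'
#' @param path Path to a YAML/JSON file.
#' @return A list with elements `population`, `scenario`, `risk`, `costs`
#'   (only those present in the file).
#' @examples
#' cfg <- read_model_config(system.file("extdata", "example-config.yaml",
#'                                      package = "tiaflow"))
#' names(cfg)
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(raw$population)) {
    pop <- raw$population
    for (nm in intersect(names(pop), c("gp_prob_by_class", "feature_probs",
                                       "duration_probs", "af_probs")))
      pop[[nm]] <- unlist(pop[[nm]])
    for (nm in intersect(names(pop), c("age_range", "sbp_range",
                                       "onset_hours", "gp_hours", "gp_days")))
      pop[[nm]] <- as.numeric(unlist(pop[[nm]]))
    if (!is.null(pop$sbp_by_class))
      pop$sbp_by_class <- lapply(pop$sbp_by_class, as.numeric)
    out$population <- do.call(population_config, pop)
  }
  if (!is.null(raw$scenario)) {
    sc <- raw$scenario
    if (!is.null(sc$preset)) {
      out$scenario <- scenario_preset(sc$preset)
    } else {
      pat <- weekly_pattern(
        as.numeric(unlist(sc$pattern$slots)),
        stochastic_days = lapply(sc$pattern$stochastic_days, unlist),
        clinic_start = sc$pattern$clinic_start %||% 9)
      lv <- do.call(leave_model, sc$leave %||% list())
      out$scenario <- service_scenario(
        hospital = sc$hospital %||% "h1", variant = sc$variant %||% "custom",
        pattern = pat, leave = lv, policy = sc$policy,
        weekend_high_risk_slots = isTRUE(sc$weekend_high_risk_slots),
        ward_review = isTRUE(sc$ward_review), name = sc$name)
    }
  }
  if (!is.null(raw$risk)) {
    rk <- raw$risk
    for (nm in intersect(names(rk), c("af_mult", "class_mult")))
      rk[[nm]] <- unlist(rk[[nm]])
    out$risk <- do.call(risk_config, rk)
  }
  if (!is.null(raw$costs)) out$costs <- do.call(cost_table, raw$costs)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
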