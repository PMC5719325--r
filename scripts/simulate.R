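#!/usr/bin/env Rscript

# Thin command-line wrapper over run_batch()/render_outputs().
#
# Usage:
#   Rscript scripts/simulate.R --scenario h1-modified --runs 100 --years 12 \
#     --seed 1 --out results/h1-modified
# --scenario accepts a preset name (h1-original, h1-modified, h2-original,
# h2-modified, optionally with ":weekend:<weekday_slots>" appended to derive
# a weekend variant) or a path to a YAML configuration file with `scenario`
# (and optionally `population`, `risk`, `costs`) sections.

suppressPackageStartupMessages({
  library(optparse)
  library(tiaflow)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--scenario", type = "character", default = "h1-original"),
  make_option("--runs", type = "integer", default = 100L),
  make_option("--years", type = "integer", default = 12L),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/simulation"))))

pop <- population_config()
risk <- risk_config()
costs <- cost_table()

if (file.exists(opts$scenario)) {
  cfg <- read_model_config(opts$scenario)
  scenario <- cfg$scenario
  if (!is.null(cfg$population)) pop <- cfg$population
  if (!is.null(cfg$risk)) risk <- cfg$risk
  if (!is.null(cfg$costs)) costs <- cfg$costs
} else if (grepl(":weekend:", opts$scenario, fixed = TRUE)) {
  parts <- strsplit(opts$scenario, ":weekend:", fixed = TRUE)[[1]]
  scenario <- make_weekend_variant(scenario_preset(parts[1]),
                                   as.integer(parts[2]))
} else {
  scenario <- scenario_preset(opts$scenario)
}

batch <- run_batch(scenario, pop, risk, costs,
                   runs = opts$runs, years = opts$years, seed = opts$seed)
agg <- aggregate_runs(batch)
print(agg)
files <- render_outputs(stats::setNames(list(agg), scenario$name), opts$out)
cat("wrote:", paste(files, collapse = ", "), "\n")
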