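# Scenario builders used across test files. Everything is constructed in
# code; no fixtures beyond the packaged scenario are read from disk.

fixed_spec <- function(x) dist_spec(x, family = "fixed")

# Flat survival (nobody ever dies or progresses) over `cycles` months:
# exposure is exactly `cycles` alive-months, stable throughout.
flat_survival <- function(cycles) {
  s <- survival_curve(rep(1, cycles + 1), anchor_month = cycles)
  list(os = s, pfs = s)
}

simple_strategy <- function(name, drug, u_stable, u_prog = u_stable,
                            crossover = 0, aes = list()) {
  strategy_spec(name,
                monthly_drug_cost = fixed_spec(drug),
                adverse_events = aes,
                utility_stable = fixed_spec(u_stable),
                utility_progression = fixed_spec(u_prog),
                crossover_monthly_cost = crossover)
}

# Two-strategy scenario with flat survival over `cycles` months and fully
# fixed parameters; lifetime totals are exactly drug * cycles and
# u * cycles / 12, which makes expectations hand-computable.
two_arm_flat_scenario <- function(cycles = 10,
                                  drug = c(a = 0, b = 1000),
                                  u = c(a = 0.12, b = 0.24),
                                  wtp = 1e5) {
  cea_scenario(
    strategies = list(simple_strategy("a", drug[["a"]], u[["a"]]),
                      simple_strategy("b", drug[["b"]], u[["b"]])),
    survival = list(a = flat_survival(cycles), b = flat_survival(cycles)),
    wtp_default = wtp, max_cycles = cycles)
}

# Variant of the flat scenario where strategy b's drug cost is a gamma
# with a chosen sd while everything else stays fixed.
two_arm_gamma_cost_scenario <- function(cycles = 12, base = 5000/3,
                                        sd = 255, u = c(a = 0.1, b = 0.3)) {
  half_width <- 1.96 * sd
  b <- strategy_spec("b",
                     monthly_drug_cost = dist_spec(base, base - half_width,
                                                   base + half_width, "gamma"),
                     utility_stable = fixed_spec(u[["b"]]),
                     utility_progression = fixed_spec(u[["b"]]))
  cea_scenario(
    strategies = list(simple_strategy("a", 0, u[["a"]]), b),
    survival = list(a = flat_survival(cycles), b = flat_survival(cycles)),
    wtp_default = 1e5, max_cycles = cycles)
}

# Write a scenario to a temp file and return the path (JSON by default).
scenario_tempfile <- function(scenario, ext = ".json") {
  path <- tempfile(fileext = ext)
  write_scenario(scenario, path)
  path
}

fixture_path <- function() {
  system.file("extdata", "table1_melanoma.yaml", package = "melcea",
              mustWork = TRUE)
}
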