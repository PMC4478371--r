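# Cohort accrual engine: turns a strategy's economics plus an occupancy
# trace into lifetime totals of cost and QALYs.

#' Engine settings
#'
#' @param cycle_length_months cycle length (default 1).
#' @param discount_rate_annual annual discount rate, applied per cycle as
#'   `(1 + r)^(-t/12)` with `t` in months (default 0: undiscounted).
#' @param half_cycle if `TRUE`, accrue on the trapezoidal average of the
#'   start- and end-of-cycle occupancy instead of the start-of-cycle state.
#' @param ae_costs_on `"alive"` (default): toxicity-management costs accrue
#'   on all alive occupancy, like drug cost; `"stable"`: on the
#'   progression-free state only.
#' @return list of class `cea_settings`.
#' @export
cea_settings <- function(cycle_length_months = 1L, discount_rate_annual = 0,
                         half_cycle = FALSE,
                         ae_costs_on = c("alive", "stable")) {
  ae_costs_on <- match.arg(ae_costs_on)
  assert_num(cycle_length_months, "cycle_length_months", min = 1e-9)
  assert_num(discount_rate_annual, "discount_rate_annual", min = 0)
  structure(list(cycle_length_months = cycle_length_months,
                 discount_rate_annual = discount_rate_annual,
                 half_cycle = isTRUE(half_cycle),
                 ae_costs_on = ae_costs_on),
            class = "cea_settings")
}

settings_from_scenario <- function(scenario) {
  cea_settings(cycle_length_months = scenario$cycle_length_months,
               discount_rate_annual = scenario$discount_rate_annual,
               half_cycle = scenario$settings$half_cycle,
               ae_costs_on = scenario$settings$ae_costs_on)
}

#' Expected toxicity-management cost per cycle
#'
#' Sum over a strategy's adverse events of base-case monthly probability
#' times base-case management cost: the probability-weighted side-effect
#' cost charged in every cycle on drug.
#'
#' @param strategy a [strategy_spec()].
#' @return expected cost in USD per cycle (>= 0).
#' @export
expected_ae_cost_per_cycle <- function(strategy) {
  stopifnot(inherits(strategy, "strategy_spec"))
  if (length(strategy$adverse_events) == 0) return(0)
  sum(vapply(strategy$adverse_events, function(a)
    a$monthly_probability$base * a$management_cost$base, numeric(1)))
}

#' Composite health-state utility under adverse events
#'
#' Mixture expectation over disjoint adverse-event states:
#' `(1 - sum(p)) * u_base + sum(p * u_ae)`. This is how a drug-specific
#' state utility is assembled when per-event utilities are available; the
#' bundled scenario instead carries the composite utilities directly.
#'
#' @param u_base utility of the health state without adverse events.
#' @param ae_probs probabilities of the (disjoint) adverse-event states;
#'   must sum to at most 1.
#' @param ae_utils utilities of the adverse-event states, same length.
#' @return composite utility in `[0, 1]`.
#' @examples
#' composite_state_utility(0.8, 0.5, 0.4) # 0.6
#' @export
composite_state_utility <- function(u_base, ae_probs = numeric(0),
                                    ae_utils = numeric(0)) {
  assert_num(u_base, "u_base", 0, 1)
  if (length(ae_probs) != length(ae_utils))
    validation_error("ae_probs and ae_utils must have the same length")
  if (length(ae_probs) == 0) return(u_base)
  assert_num(ae_probs, "ae_probs", 0, 1, len = length(ae_probs))
  assert_num(ae_utils, "ae_utils", 0, 1, len = length(ae_utils))
  p <- sum(ae_probs)
  if (p > 1 + 1e-12)
    validation_error(sprintf("adverse-event probabilities sum to %.6g > 1", p))
  (1 - p) * u_base + sum(ae_probs * ae_utils)
}

# Discounted occupancy accrual sums over cycles t = 0..T-1. These weights
# make every lifetime total affine in the economic parameters:
#   cost = (drug + ae) * alive + crossover * progressed   [per cycle]
#   qaly = (u_s * stable + u_p * progressed) * cycle_length / 12.
# Shared by run_cohort, threshold_monthly_price and the PSA fast path.
accrual_sums <- function(occupancy, settings) {
  n <- nrow(occupancy)
  if (n < 2L)
    validation_error("occupancy must cover at least one full cycle (>= 2 rows)")
  i <- seq_len(n - 1L)
  st <- occupancy$stable[i]; pr <- occupancy$progressed[i]
  if (settings$half_cycle) {
    st <- (st + occupancy$stable[i + 1L]) / 2
    pr <- (pr + occupancy$progressed[i + 1L]) / 2
  }
  t_months <- occupancy$cycle[i] * settings$cycle_length_months
  disc <- (1 + settings$discount_rate_annual)^(-t_months / 12)
  list(cycles = occupancy$cycle[i], disc = disc,
       stable = st, progressed = pr,
       w_stable = disc * st, w_progressed = disc * pr,
       A_stable = sum(disc * st), A_progressed = sum(disc * pr),
       A_alive = sum(disc * (st + pr)))
}

#' Run one strategy's cohort over an occupancy trace
#'
#' Accrues, for cycles `t = 0 .. T-1` using start-of-cycle occupancy (or
#' the trapezoidal cycle average when `half_cycle` is set):
#' * cost: `(drug + expected AE cost) * alive + crossover * progressed`
#'   (with the AE term on stable occupancy only under
#'   `ae_costs_on = "stable"`),
#' * QALYs: `(u_stable * stable + u_prog * progressed) * cycle_length / 12`,
#'
#' both multiplied by the per-cycle discount factor. The last row of the
#' occupancy trace marks the end of the horizon and accrues nothing itself.
#'
#' @param strategy a [strategy_spec()].
#' @param occupancy an `occupancy` trace from [occupancy_from_survival()].
#' @param settings a [cea_settings()].
#' @return object of class `cea_result`: list with `strategy`,
#'   `total_cost`, `total_qaly` and the per-cycle `trace` data frame
#'   (occupancy plus `cycle_cost`, `cycle_qaly`, `cum_cost`, `cum_qaly`).
#' @export
run_cohort <- function(strategy, occupancy, settings = cea_settings()) {
  stopifnot(inherits(strategy, "strategy_spec"),
            inherits(occupancy, "occupancy"),
            inherits(settings, "cea_settings"))
  acc <- accrual_sums(occupancy, settings)
  ae <- expected_ae_cost_per_cycle(strategy)
  drug <- strategy$monthly_drug_cost$base
  ae_occ <- if (settings$ae_costs_on == "alive") acc$stable + acc$progressed else acc$stable
  cycle_cost <- acc$disc * (drug * (acc$stable + acc$progressed) +
                            ae * ae_occ +
                            strategy$crossover_monthly_cost * acc$progressed)
  cycle_qaly <- acc$disc *
    (strategy$utility_stable$base * acc$stable +
     strategy$utility_progression$base * acc$progressed) *
    settings$cycle_length_months / 12
  trace <- data.frame(cycle = acc$cycles,
                      stable = acc$stable, progressed = acc$progressed,
                      cycle_cost = cycle_cost, cycle_qaly = cycle_qaly,
                      cum_cost = cumsum(cycle_cost), cum_qaly = cumsum(cycle_qaly))
  structure(list(strategy = strategy$name,
                 total_cost = sum(cycle_cost),
                 total_qaly = sum(cycle_qaly),
                 trace = trace),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> %s: total cost $%s, total QALYs %.4f (%d cycles)\n",
              x$strategy, format(round(x$total_cost, 2), big.mark = ","),
              x$total_qaly, nrow(x$trace)))
  invisible(x)
}

# Extrapolate a strategy's curves to the scenario horizon and truncate the
# trace once the cohort is effectively extinct (dead >= 1 - 1e-6), so flat
# absorbing tails do not burn cycles.
strategy_occupancy <- function(scenario, name) {
  sv <- scenario$survival[[name]]
  if (is.null(sv)) validation_error(sprintf("unknown strategy: %s", name))
  anchor <- scenario$settings$anchor_month
  os <- extrapolate_curve(sv$os, scenario$max_cycles, anchor_month = anchor)
  pfs <- extrapolate_curve(sv$pfs, scenario$max_cycles, anchor_month = anchor)
  occ <- occupancy_from_survival(os, pfs)
  gone <- which(occ$dead >= 1 - 1e-6)
  if (length(gone) > 0 && gone[1] < nrow(occ))
    occ <- occ[seq_len(gone[1]), , drop = FALSE]
  class(occ) <- c("occupancy", "data.frame")
  occ
}

#' Run every strategy of a scenario
#'
#' Extrapolates each strategy's OS/PFS curves to the scenario horizon,
#' builds the occupancy trace, and accrues lifetime totals.
#'
#' @param scenario a [cea_scenario()].
#' @return named list of [run_cohort()] results, one per strategy, of
#'   class `cea_results`.
#' @examples
#' res <- run_scenario(make_melanoma_like_scenario(seed = 1))
#' vapply(res, `[[`, numeric(1), "total_cost")
#' @export
run_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "cea_scenario"))
  settings <- settings_from_scenario(scenario)
  out <- lapply(names(scenario$strategies), function(nm) {
    run_cohort(scenario$strategies[[nm]], strategy_occupancy(scenario, nm),
               settings)
  })
  names(out) <- names(scenario$strategies)
  class(out) <- c("cea_results", "list")
  out
}

#' @export
as.data.frame.cea_results <- function(x, ...) {
  data.frame(name = vapply(x, `[[`, character(1), "strategy"),
             total_cost = vapply(x, `[[`, numeric(1), "total_cost"),
             total_qaly = vapply(x, `[[`, numeric(1), "total_qaly"),
             row.names = NULL)
}

#' @export
print.cea_results <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}
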