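# Efficiency frontier: strict and extended dominance, ICERs, net monetary
# benefit, and price/effect thresholds.

#' Incremental cost-effectiveness ratio
#'
#' `(cost_a - cost_b) / (qaly_a - qaly_b)`, the extra spend per extra QALY
#' of strategy A over strategy B. Undefined when the QALYs are equal:
#' returns `NA` so the caller can report plain cost dominance instead.
#'
#' @param cost_a,qaly_a totals of the (usually costlier) strategy.
#' @param cost_b,qaly_b totals of the comparator.
#' @return USD per QALY, or `NA_real_` when `qaly_a == qaly_b`.
#' @examples
#' icer(38547, 0.3385, 15221, 0.1820)
#' @export
icer <- function(cost_a, qaly_a, cost_b, qaly_b) {
  if (qaly_a == qaly_b) return(NA_real_)
  (cost_a - cost_b) / (qaly_a - qaly_b)
}

#' Net monetary benefit
#'
#' `wtp * qaly - cost`: the strategy with the highest NMB at a given
#' willingness-to-pay is the optimal one. (Vectorized.)
#'
#' @param cost total cost, USD.
#' @param qaly total effectiveness, QALYs.
#' @param wtp willingness-to-pay threshold, USD/QALY (>= 0).
#' @return USD.
#' @examples
#' nmb(15221, 0.1820, 1e5) # 2979
#' @export
nmb <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) validation_error("wtp must be >= 0", "wtp")
  wtp * qaly - cost
}

#' Incremental effect needed to meet a threshold
#'
#' QALY gain required for a given incremental cost to reach an ICER equal
#' to the willingness-to-pay: `inc_cost / wtp`.
#'
#' @param inc_cost incremental cost, USD.
#' @param wtp willingness-to-pay, USD/QALY (> 0).
#' @return QALYs.
#' @export
required_incremental_qaly <- function(inc_cost, wtp) {
  if (any(wtp <= 0)) validation_error("wtp must be > 0", "wtp")
  inc_cost / wtp
}

#' Break-even total lifetime cost
#'
#' Total cost at which a strategy's ICER against a comparator exactly
#' equals the willingness-to-pay: `comparator_cost + wtp * inc_qaly`.
#'
#' @param comparator_cost comparator's total cost, USD.
#' @param inc_qaly incremental QALYs of the strategy over the comparator
#'   (> 0 for the relation to be meaningful).
#' @param wtp willingness-to-pay, USD/QALY.
#' @return USD.
#' @export
break_even_total_cost <- function(comparator_cost, inc_qaly, wtp) {
  comparator_cost + wtp * inc_qaly
}

results_frame <- function(results) {
  if (inherits(results, "data.frame")) {
    check_keys(results, c("name", "total_cost", "total_qaly"),
               c("name", "total_cost", "total_qaly"), "results")
    df <- results
  } else {
    stopifnot(is.list(results),
              all(vapply(results, inherits, logical(1), "cea_result")))
    df <- data.frame(name = vapply(results, `[[`, character(1), "strategy"),
                     total_cost = vapply(results, `[[`, numeric(1), "total_cost"),
                     total_qaly = vapply(results, `[[`, numeric(1), "total_qaly"))
  }
  if (anyDuplicated(df$name))
    validation_error("duplicate strategy names", "results")
  df
}

#' Build the cost-effectiveness frontier
#'
#' Orders strategies from least to most expensive, flags strict dominance
#' (another strategy costs no more and delivers no fewer QALYs, with at
#' least one strict inequality; exact ties flag the later-listed strategy),
#' then removes extended dominance iteratively until the ICERs along the
#' frontier are strictly increasing. ICERs are computed against the next
#' cheaper frontier member.
#'
#' @param results list of [run_cohort()] results (or a `cea_results`
#'   object), or a data frame with columns `name`, `total_cost`,
#'   `total_qaly`. At least 2 strategies.
#' @return data frame of class `frontier_table` ordered by total cost, with
#'   columns `name`, `total_cost`, `total_qaly`, `status` (`"frontier"`,
#'   `"dominated"`, `"extended_dominated"`), `comparator`, `inc_cost`,
#'   `inc_qaly`, `icer`.
#' @examples
#' tab <- data.frame(name = c("dacarbazine", "dabrafenib", "vemurafenib"),
#'                   total_cost = c(15221, 38547, 49938),
#'                   total_qaly = c(0.1820, 0.3385, 0.2905))
#' build_frontier(tab)
#' @export
build_frontier <- function(results) {
  df <- results_frame(results)
  n <- nrow(df)
  if (n < 2) validation_error("need at least 2 strategies", "results")
  df$input_order <- seq_len(n)
  df$status <- "frontier"

  # strict dominance (with the deterministic tie rule)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cheaper <- df$total_cost[j] <= df$total_cost[i]
      better <- df$total_qaly[j] >= df$total_qaly[i]
      strict <- df$total_cost[j] < df$total_cost[i] ||
        df$total_qaly[j] > df$total_qaly[i]
      tie <- df$total_cost[j] == df$total_cost[i] &&
        df$total_qaly[j] == df$total_qaly[i] && j < i
      if ((cheaper && better && strict) || tie) {
        df$status[i] <- "dominated"
        break
      }
    }
  }

  # extended dominance on the survivors, ordered by cost (then input order)
  ord <- order(df$total_cost, -df$total_qaly, df$input_order)
  df <- df[ord, , drop = FALSE]
  repeat {
    live <- which(df$status == "frontier")
    if (length(live) < 3) break
    cost <- df$total_cost[live]; qaly <- df$total_qaly[live]
    icers <- diff(cost) / diff(qaly)
    bad <- which(icers[-length(icers)] >= icers[-1])
    if (length(bad) == 0) break
    df$status[live[bad[1] + 1L]] <- "extended_dominated"
  }

  live <- which(df$status == "frontier")
  df$comparator <- NA_character_
  df$inc_cost <- NA_real_
  df$inc_qaly <- NA_real_
  df$icer <- NA_real_
  if (length(live) > 1) {
    for (k in 2:length(live)) {
      i <- live[k]; j <- live[k - 1L]
      df$comparator[i] <- df$name[j]
      df$inc_cost[i] <- df$total_cost[i] - df$total_cost[j]
      df$inc_qaly[i] <- df$total_qaly[i] - df$total_qaly[j]
      df$icer[i] <- icer(df$total_cost[i], df$total_qaly[i],
                         df$total_cost[j], df$total_qaly[j])
    }
  }
  df$input_order <- NULL
  rownames(df) <- NULL
  class(df) <- c("frontier_table", "data.frame")
  df
}

#' @export
print.frontier_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$total_cost <- round(y$total_cost, 2)
  y$inc_cost <- round(y$inc_cost, 2)
  y$icer <- round_half_up(y$icer, 0)
  print(y)
  invisible(x)
}

#' Threshold monthly drug price
#'
#' The monthly price at which a strategy's ICER against a comparator
#' exactly equals the willingness-to-pay. Total cost is affine in the
#' monthly price by construction of [run_cohort()]:
#' `total_cost(price) = fixed + price * exposure`, where exposure is the
#' discounted sum of alive occupancy over all cycles, so the threshold is
#' solved exactly:
#' `price = (wtp * (Q_s - Q_c) + C_c - fixed) / exposure`.
#'
#' @param scenario a [cea_scenario()].
#' @param strategy name of the strategy whose price is solved for.
#' @param comparator name of the comparator strategy.
#' @param wtp willingness-to-pay, USD/QALY; defaults to the scenario's.
#' @return threshold price in USD per month.
#' @export
threshold_monthly_price <- function(scenario, strategy, comparator,
                                    wtp = scenario$wtp_default) {
  stopifnot(inherits(scenario, "cea_scenario"))
  if (is.null(scenario$strategies[[strategy]]))
    validation_error(sprintf("unknown strategy: %s", strategy))
  if (is.null(scenario$strategies[[comparator]]))
    validation_error(sprintf("unknown comparator: %s", comparator))
  settings <- settings_from_scenario(scenario)
  s <- scenario$strategies[[strategy]]
  occ_s <- strategy_occupancy(scenario, strategy)
  acc <- accrual_sums(occ_s, settings)
  exposure <- acc$A_alive
  if (exposure <= 0)
    validation_error("strategy has zero alive exposure; threshold price undefined")
  ae_occ <- if (settings$ae_costs_on == "alive") acc$A_alive else acc$A_stable
  fixed <- expected_ae_cost_per_cycle(s) * ae_occ +
    s$crossover_monthly_cost * acc$A_progressed
  q_s <- (s$utility_stable$base * acc$A_stable +
          s$utility_progression$base * acc$A_progressed) *
    settings$cycle_length_months / 12
  comp <- run_cohort(scenario$strategies[[comparator]],
                     strategy_occupancy(scenario, comparator), settings)
  (wtp * (q_s - comp$total_qaly) + comp$total_cost - fixed) / exposure
}
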