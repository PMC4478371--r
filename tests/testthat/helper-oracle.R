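# Independent oracles, written against the documented accounting rules
# rather than against the package internals: a scalar cycle-by-cycle
# accrual loop, and a frontier finder based on net-monetary-benefit
# maximization over candidate thresholds.

# Spreadsheet-style accrual: explicit loop, scalar arithmetic only.
oracle_cohort_totals <- function(drug, ae_probs, ae_costs, u_stable, u_prog,
                                 crossover, occ, cycle_length = 1,
                                 discount = 0, half_cycle = FALSE,
                                 ae_on = "alive") {
  total_cost <- 0
  total_qaly <- 0
  for (i in seq_len(nrow(occ) - 1L)) {
    st <- occ$stable[i]
    pr <- occ$progressed[i]
    if (half_cycle) {
      st <- (st + occ$stable[i + 1L]) / 2
      pr <- (pr + occ$progressed[i + 1L]) / 2
    }
    disc <- (1 + discount)^(-(occ$cycle[i] * cycle_length) / 12)
    ae <- 0
    for (j in seq_along(ae_probs)) ae <- ae + ae_probs[j] * ae_costs[j]
    alive <- st + pr
    cost <- drug * alive + ae * (if (ae_on == "alive") alive else st) +
      crossover * pr
    total_cost <- total_cost + disc * cost
    total_qaly <- total_qaly + disc * (u_stable * st + u_prog * pr) * cycle_length / 12
  }
  c(cost = total_cost, qaly = total_qaly)
}

oracle_cohort_for_strategy <- function(strategy, occ, cycle_length = 1,
                                       discount = 0, half_cycle = FALSE,
                                       ae_on = "alive") {
  oracle_cohort_totals(
    drug = strategy$monthly_drug_cost$base,
    ae_probs = vapply(strategy$adverse_events, function(a) a$monthly_probability$base, numeric(1)),
    ae_costs = vapply(strategy$adverse_events, function(a) a$management_cost$base, numeric(1)),
    u_stable = strategy$utility_stable$base,
    u_prog = strategy$utility_progression$base,
    crossover = strategy$crossover_monthly_cost,
    occ = occ, cycle_length = cycle_length, discount = discount,
    half_cycle = half_cycle, ae_on = ae_on)
}

# Textbook frontier by enumeration: a strategy is on the frontier iff it is
# the unique NMB maximizer at some positive willingness-to-pay. Candidate
# thresholds are all pairwise cost/QALY slopes; evaluation happens at
# midpoints between consecutive candidates (continuous random instances
# make ties measure-zero).
oracle_frontier_status <- function(cost, qaly) {
  n <- length(cost)
  dominated <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (cost[j] <= cost[i] && qaly[j] >= qaly[i] &&
          (cost[j] < cost[i] || qaly[j] > qaly[i])) dominated[i] <- TRUE
      if (cost[j] == cost[i] && qaly[j] == qaly[i] && j < i) dominated[i] <- TRUE
    }
  }
  slopes <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (qaly[i] != qaly[j]) {
      s <- (cost[i] - cost[j]) / (qaly[i] - qaly[j])
      if (is.finite(s) && s > 0) slopes <- c(slopes, s)
    }
  }
  cand <- sort(unique(c(0, slopes)))
  evals <- c((cand[-1] + cand[-length(cand)]) / 2, max(cand) + 1)
  on_frontier <- logical(n)
  for (lambda in evals) {
    b <- lambda * qaly - cost
    top <- which(b == max(b))
    if (length(top) == 1) on_frontier[top] <- TRUE
  }
  status <- ifelse(dominated, "dominated",
                   ifelse(on_frontier, "frontier", "extended_dominated"))
  # strictly dominated strategies can still be transient NMB maximizers in
  # degenerate instances; dominance takes precedence by construction above
  status
}

# Random valid monotone survival-curve pair (PFS <= OS), n months.
random_curve_pair <- function(n = 9, seed = 1) {
  melcea:::with_seed(seed, {
    os <- cumprod(c(1, runif(n - 1, 0.7, 1)))
    f <- cumprod(c(1, runif(n - 1, 0.6, 1)))
    list(os = survival_curve(os, anchor_month = n - 1),
         pfs = survival_curve(os * f, anchor_month = n - 1))
  })
}
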