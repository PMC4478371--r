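# Sensitivity analysis: one-way deterministic sweeps, Monte-Carlo PSA with
# per-parameter seeded substreams, and cost-effectiveness acceptability
# curves.

# ---- parameter paths -----------------------------------------------------

# Enumerate every dist_spec parameter of a scenario as a flat table of
# slash-separated paths: "<strategy>/monthly_drug_cost",
# "<strategy>/utility_stable", "<strategy>/utility_progression",
# "<strategy>/ae/<event>_<grade>/monthly_probability|management_cost".
param_table <- function(scenario) {
  out <- list()
  for (nm in names(scenario$strategies)) {
    s <- scenario$strategies[[nm]]
    out[[length(out) + 1L]] <- list(path = paste0(nm, "/monthly_drug_cost"),
                                    strategy = nm, kind = "drug_cost",
                                    ae = NA_integer_, spec = s$monthly_drug_cost)
    out[[length(out) + 1L]] <- list(path = paste0(nm, "/utility_stable"),
                                    strategy = nm, kind = "utility_stable",
                                    ae = NA_integer_, spec = s$utility_stable)
    out[[length(out) + 1L]] <- list(path = paste0(nm, "/utility_progression"),
                                    strategy = nm, kind = "utility_progression",
                                    ae = NA_integer_, spec = s$utility_progression)
    for (j in seq_along(s$adverse_events)) {
      a <- s$adverse_events[[j]]
      stem <- sprintf("%s/ae/%s_%s", nm, a$name, a$grade_band)
      out[[length(out) + 1L]] <- list(path = paste0(stem, "/monthly_probability"),
                                      strategy = nm, kind = "ae_prob",
                                      ae = j, spec = a$monthly_probability)
      out[[length(out) + 1L]] <- list(path = paste0(stem, "/management_cost"),
                                      strategy = nm, kind = "ae_cost",
                                      ae = j, spec = a$management_cost)
    }
  }
  out
}

# Resolve a parameter path to its dist_spec (base value for scalars).
resolve_param <- function(scenario, path) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  s <- scenario$strategies[[parts[1]]]
  if (is.null(s)) validation_error(sprintf("unknown strategy in path: %s", path))
  if (length(parts) == 2 && parts[2] == "crossover_monthly_cost")
    return(list(kind = "scalar", value = s$crossover_monthly_cost))
  if (length(parts) == 2 &&
      parts[2] %in% c("monthly_drug_cost", "utility_stable", "utility_progression"))
    return(list(kind = "dist", spec = s[[parts[2]]]))
  if (length(parts) == 4 && parts[2] == "ae" &&
      parts[4] %in% c("monthly_probability", "management_cost")) {
    key <- vapply(s$adverse_events, function(a)
      sprintf("%s_%s", a$name, a$grade_band), character(1))
    j <- match(parts[3], key)
    if (!is.na(j)) return(list(kind = "dist", spec = s$adverse_events[[j]][[parts[4]]]))
  }
  validation_error(sprintf("cannot resolve parameter path: %s", path))
}

# Return a copy of the scenario with the parameter's base value replaced;
# the range is widened if the new value falls outside it (DSA sweeps may
# go beyond the stated range).
set_param <- function(scenario, path, value) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  resolve_param(scenario, path) # validates the path
  s <- scenario$strategies[[parts[1]]]
  bump <- function(d) dist_spec(value, min(d$low, value), max(d$high, value), d$family)
  if (length(parts) == 2 && parts[2] == "crossover_monthly_cost") {
    s$crossover_monthly_cost <- value
  } else if (length(parts) == 2) {
    s[[parts[2]]] <- bump(s[[parts[2]]])
  } else {
    key <- vapply(s$adverse_events, function(a)
      sprintf("%s_%s", a$name, a$grade_band), character(1))
    j <- match(parts[3], key)
    s$adverse_events[[j]][[parts[4]]] <- bump(s$adverse_events[[j]][[parts[4]]])
  }
  scenario$strategies[[parts[1]]] <- s
  scenario
}

# ---- one-way deterministic sensitivity analysis --------------------------

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the whole model at each grid value of a single parameter,
#' everything else held at base case, and reports per-strategy totals plus
#' the ICER of the parameter's strategy against a comparator. The value at
#' which that ICER crosses the willingness-to-pay threshold is interpolated
#' linearly between adjacent grid points (exact when the relation is
#' affine, as it is for drug-price sweeps) and attached as attribute
#' `"crossing"`.
#'
#' @param scenario a [cea_scenario()].
#' @param param_path slash-separated parameter path, e.g.
#'   `"dabrafenib/monthly_drug_cost"`.
#' @param grid numeric vector of values to sweep.
#' @param comparator comparator strategy name; defaults to the cheapest
#'   base-case strategy other than the parameter's own.
#' @param wtp threshold for the crossing; defaults to the scenario's.
#' @return data frame of class `dsa_table`: `value`, `cost_<s>` and
#'   `qaly_<s>` per strategy, and `icer` (target vs comparator), with
#'   attributes `"crossing"`, `"target"`, `"comparator"`.
#' @export
one_way_dsa <- function(scenario, param_path, grid,
                        comparator = NULL, wtp = scenario$wtp_default) {
  stopifnot(inherits(scenario, "cea_scenario"))
  if (length(grid) < 1) validation_error("grid must be non-empty", "grid")
  resolve_param(scenario, param_path)
  target <- strsplit(param_path, "/", fixed = TRUE)[[1]][1]
  if (is.null(comparator)) {
    base <- as.data.frame(run_scenario(scenario))
    others <- base[base$name != target, , drop = FALSE]
    comparator <- others$name[which.min(others$total_cost)]
  }
  rows <- lapply(grid, function(v) {
    res <- as.data.frame(run_scenario(set_param(scenario, param_path, v)))
    ic <- icer(res$total_cost[res$name == target],
               res$total_qaly[res$name == target],
               res$total_cost[res$name == comparator],
               res$total_qaly[res$name == comparator])
    cols <- c(list(value = v),
              stats::setNames(as.list(res$total_cost), paste0("cost_", res$name)),
              stats::setNames(as.list(res$total_qaly), paste0("qaly_", res$name)),
              list(icer = ic))
    as.data.frame(cols)
  })
  out <- do.call(rbind, rows)
  crossing <- NA_real_
  d <- out$icer - wtp
  ok <- !is.na(d)
  for (i in seq_len(nrow(out) - 1L)) {
    if (ok[i] && ok[i + 1L] && d[i] != d[i + 1L] &&
        sign(d[i]) != sign(d[i + 1L])) {
      crossing <- out$value[i] +
        (wtp - out$icer[i]) * (out$value[i + 1L] - out$value[i]) /
        (out$icer[i + 1L] - out$icer[i])
      break
    }
    if (ok[i] && d[i] == 0) { crossing <- out$value[i]; break }
  }
  attr(out, "crossing") <- crossing
  attr(out, "target") <- target
  attr(out, "comparator") <- comparator
  class(out) <- c("dsa_table", "data.frame")
  out
}

# ---- probabilistic sensitivity analysis ----------------------------------

#' Monte-Carlo probabilistic sensitivity analysis
#'
#' Draws every non-fixed parameter independently from its fitted beta or
#' gamma distribution ([fit_distribution()]), rebuilds each strategy's
#' per-cycle economics, and accrues lifetime totals on the base-case
#' survival curves (survival is not varied: the scenario states
#' distributions only for probabilities, utilities and costs). The
#' acceptability curve records, at each willingness-to-pay grid point, the
#' proportion of iterations in which each strategy has the highest net
#' monetary benefit (ties go to the cheaper strategy).
#'
#' Reproducibility: each parameter gets its own RNG substream whose seed is
#' derived deterministically from the master seed and the parameter's path,
#' so results do not depend on parameter declaration order and are
#' bitwise-reproducible given `(seed, n, scenario)`.
#'
#' @param scenario a [cea_scenario()].
#' @param n_iterations number of Monte-Carlo iterations (>= 1; the bundled
#'   analysis uses 10,000).
#' @param seed master seed (required; the caller's RNG state is restored).
#' @param wtp_grid willingness-to-pay grid, default $0--$300,000 in $5,000
#'   steps.
#' @param ess effective sample size for range-free beta parameters (see
#'   [fit_distribution()]).
#' @return object of class `psa_result`: list with `samples` (one row per
#'   iteration: parameter draws, then `cost_<s>`/`qaly_<s>` per strategy),
#'   `ceac` (a `ceac_curve` data frame: `wtp`, then one proportion column
#'   per strategy), `wtp_grid`, `strategies`, `seed`, `n`.
#' @examples
#' psa <- run_psa(make_melanoma_like_scenario(seed = 1),
#'                n_iterations = 200, seed = 7)
#' ceac_report(psa$ceac, wtp = 1e5)
#' @export
run_psa <- function(scenario, n_iterations, seed,
                    wtp_grid = seq(0, 300000, by = 5000), ess = 20) {
  stopifnot(inherits(scenario, "cea_scenario"))
  if (missing(seed)) validation_error("seed must be supplied", "seed")
  if (!is.numeric(n_iterations) || n_iterations < 1)
    validation_error("n_iterations must be >= 1", "n_iterations")
  n <- as.integer(n_iterations)
  if (length(wtp_grid) < 1 || any(wtp_grid < 0))
    validation_error("wtp_grid must be non-negative", "wtp_grid")

  params <- param_table(scenario)
  draws <- matrix(NA_real_, n, length(params),
                  dimnames = list(NULL, vapply(params, `[[`, character(1), "path")))
  for (k in seq_along(params)) {
    fd <- fit_distribution(params[[k]]$spec, ess = ess)
    draws[, k] <- with_seed(sub_seed(seed, params[[k]]$path),
                            draw_distribution(fd, n))
  }

  settings <- settings_from_scenario(scenario)
  snames <- names(scenario$strategies)
  cost <- matrix(NA_real_, n, length(snames), dimnames = list(NULL, snames))
  qaly <- matrix(NA_real_, n, length(snames), dimnames = list(NULL, snames))
  base_cost <- numeric(length(snames))
  for (si in seq_along(snames)) {
    nm <- snames[si]
    s <- scenario$strategies[[nm]]
    acc <- accrual_sums(strategy_occupancy(scenario, nm), settings)
    idx <- which(vapply(params, function(p) p$strategy == nm, logical(1)))
    kind <- vapply(params[idx], `[[`, character(1), "kind")
    col <- function(k) draws[, idx[kind == k], drop = FALSE]
    ae_sum <- if (any(kind == "ae_prob")) {
      rowSums(col("ae_prob") * col("ae_cost"))
    } else rep(0, n)
    ae_occ <- if (settings$ae_costs_on == "alive") acc$A_alive else acc$A_stable
    cost[, si] <- drop(col("drug_cost")) * acc$A_alive + ae_sum * ae_occ +
      s$crossover_monthly_cost * acc$A_progressed
    qaly[, si] <- (drop(col("utility_stable")) * acc$A_stable +
                   drop(col("utility_progression")) * acc$A_progressed) *
      settings$cycle_length_months / 12
    base_cost[si] <- run_cohort(s, strategy_occupancy(scenario, nm), settings)$total_cost
  }

  # CEAC: arg-max NMB per iteration per threshold; ties resolved in favour
  # of the cheaper strategy (by base-case cost), then input order.
  pref <- order(base_cost)
  ceac <- matrix(NA_real_, length(wtp_grid), length(snames),
                 dimnames = list(NULL, snames))
  for (w in seq_along(wtp_grid)) {
    nmb_mat <- wtp_grid[w] * qaly[, pref, drop = FALSE] - cost[, pref, drop = FALSE]
    best <- pref[max.col(nmb_mat, ties.method = "first")]
    ceac[w, ] <- tabulate(best, nbins = length(snames)) / n
  }
  ceac_df <- data.frame(wtp = wtp_grid, ceac, check.names = FALSE)
  names(ceac_df) <- c("wtp", snames)
  class(ceac_df) <- c("ceac_curve", "data.frame")

  samples <- data.frame(iteration = seq_len(n), draws, check.names = FALSE)
  for (nm in snames) samples[[paste0("cost_", nm)]] <- cost[, nm]
  for (nm in snames) samples[[paste0("qaly_", nm)]] <- qaly[, nm]

  structure(list(samples = samples, ceac = ceac_df, wtp_grid = wtp_grid,
                 strategies = snames, seed = seed, n = n),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations, %d strategies, seed %d\n",
              x$n, length(x$strategies), x$seed))
  invisible(x)
}

#' Read acceptability proportions off a CEAC
#'
#' @param curve a `ceac_curve` data frame from [run_psa()].
#' @param wtp willingness-to-pay; must lie within the curve's grid range.
#'   The nearest grid point is reported.
#' @return named numeric vector of per-strategy proportions (sums to 1).
#' @export
ceac_report <- function(curve, wtp) {
  stopifnot(inherits(curve, "ceac_curve"))
  assert_num(wtp, "wtp")
  if (wtp < min(curve$wtp) || wtp > max(curve$wtp))
    validation_error(sprintf("wtp %s outside CEAC grid [%s, %s]",
                             wtp, min(curve$wtp), max(curve$wtp)), "wtp")
  i <- which.min(abs(curve$wtp - wtp))
  out <- as.numeric(curve[i, -1])
  names(out) <- names(curve)[-1]
  out
}
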