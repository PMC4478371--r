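# Scenario inputs: strategy/adverse-event constructors, YAML/JSON loading
# with strict schema validation, result CSV writers, and the bundled
# melanoma fixture.

SCHEMA_VERSION <- 1L

#' Specify one adverse event of a treatment strategy
#'
#' @param name event name (e.g. `"diarrhea"`).
#' @param grade_band `"g12"` (grades 1--2) or `"g34"` (grades 3--4).
#' @param monthly_probability [dist_spec()]: probability of the event per
#'   monthly cycle on drug.
#' @param management_cost [dist_spec()]: management cost in USD per month
#'   on treatment.
#' @param ae_state_utility optional utility of the adverse-event health
#'   state in `[0, 1]`, used by [composite_state_utility()]; `NULL` when
#'   composite utilities are supplied directly.
#' @return object of class `ae_spec`.
#' @export
adverse_event_spec <- function(name, grade_band = c("g12", "g34"),
                               monthly_probability, management_cost,
                               ae_state_utility = NULL) {
  grade_band <- match.arg(grade_band)
  assert_string(name, "adverse_event/name")
  stopifnot(inherits(monthly_probability, "dist_spec"),
            inherits(management_cost, "dist_spec"))
  fld <- sprintf("adverse_events/%s_%s", name, grade_band)
  assert_num(monthly_probability$base, paste0(fld, "/monthly_probability"), 0, 1)
  assert_num(management_cost$base, paste0(fld, "/management_cost"), 0)
  if (!is.null(ae_state_utility))
    assert_num(ae_state_utility, paste0(fld, "/ae_state_utility"), 0, 1)
  structure(list(name = name, grade_band = grade_band,
                 monthly_probability = monthly_probability,
                 management_cost = management_cost,
                 ae_state_utility = ae_state_utility),
            class = "ae_spec")
}

#' Specify one treatment strategy's economic parameterization
#'
#' @param name strategy name (unique within a scenario).
#' @param monthly_drug_cost [dist_spec()], 2013 USD per month.
#' @param adverse_events list of [adverse_event_spec()] objects.
#' @param utility_stable,utility_progression [dist_spec()] composite health
#'   state utilities in `[0, 1]` (drug-specific, adverse events folded in).
#' @param crossover_monthly_cost USD added per unit of progressed-state
#'   occupancy per cycle; models comparator-arm patients crossing over to
#'   the experimental drug on progression. 0 for no crossover.
#' @return object of class `strategy_spec`.
#' @export
strategy_spec <- function(name, monthly_drug_cost, adverse_events = list(),
                          utility_stable, utility_progression,
                          crossover_monthly_cost = 0) {
  assert_string(name, "strategy/name")
  fld <- function(f) sprintf("strategies/%s/%s", name, f)
  stopifnot(inherits(monthly_drug_cost, "dist_spec"),
            inherits(utility_stable, "dist_spec"),
            inherits(utility_progression, "dist_spec"))
  assert_num(monthly_drug_cost$base, fld("monthly_drug_cost"), 0)
  assert_num(utility_stable$base, fld("utility_stable"), 0, 1)
  assert_num(utility_progression$base, fld("utility_progression"), 0, 1)
  if (utility_stable$family == "beta" &&
      (utility_stable$low < 0 || utility_stable$high > 1))
    validation_error("utility range outside [0,1]", fld("utility_stable"))
  assert_num(crossover_monthly_cost, fld("crossover_monthly_cost"), 0)
  if (!all(vapply(adverse_events, inherits, logical(1), "ae_spec")))
    validation_error("adverse_events must be a list of adverse_event_spec objects",
                     fld("adverse_events"))
  structure(list(name = name, monthly_drug_cost = monthly_drug_cost,
                 adverse_events = adverse_events,
                 utility_stable = utility_stable,
                 utility_progression = utility_progression,
                 crossover_monthly_cost = crossover_monthly_cost),
            class = "strategy_spec")
}

#' Assemble a complete analysis scenario
#'
#' @param strategies list of [strategy_spec()] objects.
#' @param survival named list, one entry per strategy name, each a list
#'   with elements `os` and `pfs` ([survival_curve()] objects).
#' @param wtp_default willingness-to-pay threshold in USD/QALY (> 0).
#' @param cycle_length_months cycle length (default 1 month).
#' @param max_cycles lifetime-horizon cap in cycles (default 600 = 50
#'   years); the trace also stops once the cohort is effectively dead
#'   (dead >= 1 - 1e-6).
#' @param discount_rate_annual annual discount rate (default 0).
#' @param settings list: `anchor_month` for DEALE (default 8),
#'   `half_cycle` trapezoidal correction flag (default `FALSE`),
#'   `ae_costs_on` `"alive"` or `"stable"` (which occupancy carries
#'   toxicity-management costs; default `"alive"`).
#' @param description free-text provenance note.
#' @return object of class `cea_scenario`.
#' @seealso [load_scenario()], [run_scenario()]
#' @export
cea_scenario <- function(strategies, survival, wtp_default = 1e5,
                         cycle_length_months = 1L, max_cycles = 600L,
                         discount_rate_annual = 0,
                         settings = list(), description = NULL) {
  if (!all(vapply(strategies, inherits, logical(1), "strategy_spec")))
    validation_error("strategies must be a list of strategy_spec objects", "strategies")
  nms <- vapply(strategies, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    validation_error("duplicate strategy names", "strategies")
  names(strategies) <- nms
  assert_num(wtp_default, "wtp_default")
  if (wtp_default <= 0) validation_error("wtp_default must be > 0", "wtp_default")
  assert_num(cycle_length_months, "cycle_length_months", min = 1)
  assert_num(max_cycles, "max_cycles", min = 1)
  assert_num(discount_rate_annual, "discount_rate_annual", min = 0)
  defaults <- list(anchor_month = 8L, half_cycle = FALSE, ae_costs_on = "alive")
  check_keys(settings, names(defaults), character(0), "settings")
  settings <- utils::modifyList(defaults, settings)
  if (!settings$ae_costs_on %in% c("alive", "stable"))
    validation_error('ae_costs_on must be "alive" or "stable"', "settings/ae_costs_on")
  for (nm in nms) {
    sv <- survival[[nm]]
    if (is.null(sv) || !inherits(sv$os, "survival_curve") ||
        !inherits(sv$pfs, "survival_curve"))
      validation_error("every strategy needs both an os and a pfs survival curve",
                       sprintf("survival/%s", nm))
  }
  extra <- setdiff(names(survival), nms)
  if (length(extra) > 0)
    validation_error(sprintf("survival curves for unknown strategies: %s",
                             paste(extra, collapse = ", ")), "survival")
  structure(list(schema_version = SCHEMA_VERSION,
                 description = description,
                 strategies = strategies,
                 survival = survival[nms],
                 wtp_default = wtp_default,
                 cycle_length_months = as.integer(cycle_length_months),
                 max_cycles = as.integer(max_cycles),
                 discount_rate_annual = discount_rate_annual,
                 settings = settings),
            class = "cea_scenario")
}

#' @export
print.cea_scenario <- function(x, ...) {
  cat(sprintf("<cea_scenario> %d strategies: %s\n  WTP $%s/QALY, %d-month cycles, horizon %d cycles, discount %.1f%%\n",
              length(x$strategies), paste(names(x$strategies), collapse = ", "),
              format(x$wtp_default, big.mark = ","), x$cycle_length_months,
              x$max_cycles, 100 * x$discount_rate_annual))
  invisible(x)
}

# ---- parsing -------------------------------------------------------------

parse_dist <- function(x, path) {
  check_keys(x, c("base", "low", "high", "family"), "base", path)
  tryCatch(
    dist_spec(as.numeric(x$base),
              as.numeric(x$low %||% x$base),
              as.numeric(x$high %||% x$base),
              family = x$family %||% "fixed"),
    error = function(e) validation_error(conditionMessage(e), path))
}

parse_curve <- function(x, path, base_dir) {
  if (!is.null(x$csv)) {
    check_keys(x, c("csv", "anchor_month"), "csv", path)
    f <- x$csv
    if (!file.exists(f)) f <- file.path(base_dir, x$csv)
    if (!file.exists(f))
      stop(errorCondition(sprintf("survival file not found: %s [field: %s]", x$csv, path),
                          class = c("melcea_io_error", "error")))
    return(read_survival_csv(f, anchor_month = x$anchor_month %||% 8L))
  }
  check_keys(x, c("months", "survival", "anchor_month"), "survival", path)
  tryCatch(
    survival_curve(as.numeric(x$survival),
                   months = as.numeric(x$months %||% (seq_along(x$survival) - 1)),
                   anchor_month = x$anchor_month %||% 8L),
    error = function(e) validation_error(conditionMessage(e), path))
}

#' Load and validate a scenario file
#'
#' Reads a YAML or JSON scenario (dispatch on file extension; anything not
#' ending in `.json` is parsed as YAML, of which JSON is a subset). The
#' file must carry `schema_version: 1`; unknown keys anywhere in the
#' document are rejected, and every invariant of the constructors is
#' checked. Survival curves may be given inline (`months` + `survival`
#' arrays) or as a reference `{csv: path}` relative to the scenario file.
#'
#' @param path scenario file path.
#' @return a validated [cea_scenario()].
#' @examples
#' sc <- load_scenario(system.file("extdata", "table1_melanoma.yaml",
#'                                 package = "melcea"))
#' names(sc$strategies)
#' @export
load_scenario <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(sprintf("scenario file not found: %s", path),
                        class = c("melcea_io_error", "error")))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  scenario_from_list(raw, base_dir = dirname(path))
}

# Build a cea_scenario from a parsed nested list; shared by YAML and JSON.
scenario_from_list <- function(raw, base_dir = ".") {
  check_keys(raw, c("schema_version", "description", "strategies", "survival",
                    "wtp_default", "cycle_length_months", "max_cycles",
                    "discount_rate_annual", "settings"),
             c("schema_version", "strategies", "survival"), "<root>")
  if (!identical(as.integer(raw$schema_version), SCHEMA_VERSION))
    validation_error(sprintf("unsupported schema_version %s (this reader understands %d)",
                             raw$schema_version, SCHEMA_VERSION), "schema_version")
  strategies <- lapply(raw$strategies, function(s) {
    p <- sprintf("strategies/%s", s$name %||% "?")
    check_keys(s, c("name", "monthly_drug_cost", "adverse_events",
                    "utility_stable", "utility_progression",
                    "crossover_monthly_cost"),
               c("name", "monthly_drug_cost", "utility_stable",
                 "utility_progression"), p)
    aes <- lapply(s$adverse_events %||% list(), function(a) {
      ap <- sprintf("%s/adverse_events/%s", p, a$name %||% "?")
      check_keys(a, c("name", "grade_band", "monthly_probability",
                      "management_cost", "ae_state_utility"),
                 c("name", "grade_band", "monthly_probability", "management_cost"), ap)
      adverse_event_spec(a$name, a$grade_band,
                         parse_dist(a$monthly_probability, paste0(ap, "/monthly_probability")),
                         parse_dist(a$management_cost, paste0(ap, "/management_cost")),
                         ae_state_utility = a$ae_state_utility)
    })
    strategy_spec(s$name,
                  parse_dist(s$monthly_drug_cost, paste0(p, "/monthly_drug_cost")),
                  adverse_events = aes,
                  utility_stable = parse_dist(s$utility_stable, paste0(p, "/utility_stable")),
                  utility_progression = parse_dist(s$utility_progression,
                                                   paste0(p, "/utility_progression")),
                  crossover_monthly_cost = s$crossover_monthly_cost %||% 0)
  })
  survival <- lapply(raw$survival, function(sv) {
    check_keys(sv, c("os", "pfs"), c("os", "pfs"), "survival")
    list(os = parse_curve(sv$os, "survival/os", base_dir),
         pfs = parse_curve(sv$pfs, "survival/pfs", base_dir))
  })
  cea_scenario(strategies, survival,
               wtp_default = raw$wtp_default %||% 1e5,
               cycle_length_months = raw$cycle_length_months %||% 1L,
               max_cycles = raw$max_cycles %||% 600L,
               discount_rate_annual = raw$discount_rate_annual %||% 0,
               settings = raw$settings %||% list(),
               description = raw$description)
}

# ---- serialization -------------------------------------------------------

dist_to_list <- function(d) list(base = d$base, low = d$low, high = d$high,
                                 family = d$family)

scenario_to_list <- function(sc) {
  list(schema_version = sc$schema_version,
       description = sc$description,
       wtp_default = sc$wtp_default,
       cycle_length_months = sc$cycle_length_months,
       max_cycles = sc$max_cycles,
       discount_rate_annual = sc$discount_rate_annual,
       settings = sc$settings,
       strategies = unname(lapply(sc$strategies, function(s) {
         list(name = s$name,
              monthly_drug_cost = dist_to_list(s$monthly_drug_cost),
              utility_stable = dist_to_list(s$utility_stable),
              utility_progression = dist_to_list(s$utility_progression),
              crossover_monthly_cost = s$crossover_monthly_cost,
              adverse_events = lapply(s$adverse_events, function(a) {
                out <- list(name = a$name, grade_band = a$grade_band,
                            monthly_probability = dist_to_list(a$monthly_probability),
                            management_cost = dist_to_list(a$management_cost))
                if (!is.null(a$ae_state_utility)) out$ae_state_utility <- a$ae_state_utility
                out
              }))
       })),
       survival = lapply(sc$survival, function(sv) {
         list(os = list(months = sv$os$months, survival = sv$os$survival,
                        anchor_month = sv$os$anchor_month),
              pfs = list(months = sv$pfs$months, survival = sv$pfs$survival,
                         anchor_month = sv$pfs$anchor_month))
       }))
}

#' Write a scenario back to disk
#'
#' JSON output (`.json` extension) round-trips all numeric fields exactly;
#' YAML output (any other extension) is written with 15 significant digits.
#'
#' @param scenario a [cea_scenario()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "cea_scenario"))
  lst <- scenario_to_list(scenario)
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path, precision = 15L)
  }
  invisible(path)
}

#' Read a survival curve from CSV
#'
#' Expected columns: `month` (integer, 0-based) and `survival` (real in
#' `[0, 1]`), UTF-8, `.` decimal separator.
#'
#' @param path CSV file.
#' @param anchor_month DEALE anchor for the resulting curve (default 8).
#' @return a [survival_curve()].
#' @export
read_survival_csv <- function(path, anchor_month = 8L) {
  if (!file.exists(path))
    stop(errorCondition(sprintf("survival file not found: %s", path),
                        class = c("melcea_io_error", "error")))
  df <- utils::read.csv(path)
  check_keys(df, c("month", "survival"), c("month", "survival"), path)
  ord <- order(df$month)
  survival_curve(df$survival[ord], months = df$month[ord],
                 anchor_month = anchor_month)
}

#' Write a survival curve to CSV
#' @param curve a [survival_curve()].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(curve, path) {
  stopifnot(inherits(curve, "survival_curve"))
  utils::write.csv(data.frame(month = curve$months, survival = curve$survival),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write analysis results to CSV
#'
#' Generic writer for the package's result containers. Monetary columns
#' are written at 2 decimals, QALYs at 6, ICERs at the nearest dollar;
#' strategy rows are ordered by total cost ascending.
#'
#' @param result a `frontier_table`, `cea_result`, list of `cea_result`s,
#'   or `ceac_curve`.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) UseMethod("write_results")

#' @export
write_results.frontier_table <- function(result, path) {
  df <- as.data.frame(result)[, c("name", "total_cost", "total_qaly",
                                  "inc_cost", "inc_qaly", "icer", "status")]
  df <- df[order(df$total_cost), , drop = FALSE]
  df$total_cost <- round(df$total_cost, 2)
  df$inc_cost <- round(df$inc_cost, 2)
  df$total_qaly <- round(df$total_qaly, 6)
  df$inc_qaly <- round(df$inc_qaly, 6)
  df$icer <- round_half_up(df$icer, 0)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
write_results.cea_result <- function(result, path) {
  write_results(list(result), path)
}

#' @export
write_results.list <- function(result, path) {
  stopifnot(all(vapply(result, inherits, logical(1), "cea_result")))
  df <- data.frame(name = vapply(result, `[[`, character(1), "strategy"),
                   total_cost = round(vapply(result, `[[`, numeric(1), "total_cost"), 2),
                   total_qaly = round(vapply(result, `[[`, numeric(1), "total_qaly"), 6))
  df <- df[order(df$total_cost), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_results.ceac_curve <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The bundled metastatic-melanoma scenario
#'
#' Loads the packaged fixture `table1_melanoma.yaml`: the 2013-USD economic
#' parameterization (monthly drug costs, adverse-event probabilities and
#' management costs, composite health-state utilities, and the
#' chemotherapy-arm crossover cost rule) for dacarbazine, dabrafenib and
#' vemurafenib. The survival curves bundled with it are synthetic
#' exponential stand-ins calibrated by median survival -- the trial
#' Kaplan-Meier curves are not publicly tabulated -- so lifetime totals
#' from this scenario are illustrative, not reproductions of published
#' totals.
#'
#' @return a [cea_scenario()].
#' @export
melanoma_scenario <- function() {
  load_scenario(system.file("extdata", "table1_melanoma.yaml",
                            package = "melcea", mustWork = TRUE))
}
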