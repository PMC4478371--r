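# Survival curves (OS / PFS), DEALE constant-hazard extrapolation, and
# conversion to three-state occupancy in the partitioned-survival style.

#' Construct a monthly survival curve
#'
#' Holds survival probabilities S(t) on an integer month grid 0, 1, 2, ...
#' for one endpoint (overall survival or progression-free survival) of one
#' treatment arm. `S(0)` must be 1 and the curve must be nonincreasing;
#' upward wiggles below 1e-12 (floating noise from digitization) are
#' flattened silently.
#'
#' @param survival numeric vector of survival probabilities in `[0, 1]`.
#' @param months integer month grid; must start at 0 with step 1. Defaults
#'   to `0:(length(survival) - 1)`.
#' @param anchor_month month at which the extrapolation hazard is read off
#'   the curve (default 8, the follow-up of the registration trials the
#'   bundled scenario emulates).
#' @return an object of class `survival_curve` with fields `months`,
#'   `survival`, `anchor_month`, `hazard` (`NA` until extrapolated) and
#'   `extrapolated`.
#' @seealso [deale_hazard()], [extrapolate_curve()], [occupancy_from_survival()]
#' @export
survival_curve <- function(survival, months = seq_along(survival) - 1,
                           anchor_month = 8L) {
  if (!is.numeric(survival) || length(survival) < 2L || anyNA(survival))
    validation_error("survival must be a numeric vector of length >= 2 without NA", "survival")
  if (!is.numeric(months) || length(months) != length(survival))
    validation_error("months must align with survival", "months")
  months <- as.integer(round(months))
  if (months[1] != 0L || any(diff(months) != 1L))
    validation_error("months must start at 0 with step 1", "months")
  if (any(survival < 0) || any(survival > 1))
    validation_error("survival probabilities must lie in [0, 1]", "survival")
  if (abs(survival[1] - 1) > 1e-12)
    validation_error("S(0) must equal 1", "survival")
  survival[1] <- 1
  up <- diff(survival) > 0
  if (any(diff(survival) > 1e-12))
    validation_error("survival curve must be nonincreasing", "survival")
  if (any(up)) survival <- cummin(survival)
  assert_num(anchor_month, "anchor_month", min = 1)
  structure(list(months = months, survival = survival,
                 anchor_month = as.integer(anchor_month),
                 hazard = NA_real_, extrapolated = FALSE),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> months 0..%d%s, anchor %d%s\n",
              max(x$months),
              if (x$extrapolated) " (extrapolated)" else "",
              x$anchor_month,
              if (is.na(x$hazard)) "" else sprintf(", hazard %.6g/month", x$hazard)))
  invisible(x)
}

curve_at <- function(curve, month) {
  i <- match(as.integer(month), curve$months)
  if (anyNA(i)) validation_error(sprintf("month %s outside curve range 0..%d",
                                         paste(month[is.na(i)], collapse = ","),
                                         max(curve$months)))
  curve$survival[i]
}

#' DEALE constant hazard from a survival curve
#'
#' The declining exponential approximation of life expectancy (DEALE) reads
#' a single constant hazard off the observed curve at an anchor time:
#' `hazard = -log(S(anchor)) / anchor` per month. The hazard is used to
#' extend the curve to a lifetime horizon; the approximation is good when
#' survival is short relative to background mortality, as in advanced
#' melanoma.
#'
#' @param curve a [survival_curve()].
#' @param anchor_month anchor time in months; defaults to the curve's own.
#' @return constant hazard per month (>= 0).
#' @examples
#' sc <- survival_curve(exp(-(0:8) * log(2) / 8))
#' deale_hazard(sc)            # log(2)/8: median-8-month exponential
#' @export
deale_hazard <- function(curve, anchor_month = curve$anchor_month) {
  stopifnot(inherits(curve, "survival_curve"))
  assert_num(anchor_month, "anchor_month", min = 1)
  if (anchor_month > max(curve$months))
    validation_error(sprintf("anchor month %d beyond observed curve (max %d)",
                             anchor_month, max(curve$months)), "anchor_month")
  s <- curve_at(curve, anchor_month)
  if (s <= 0)
    validation_error(sprintf(
      "S(%d) = 0: hazard is infinite; shorten the anchor month to the last time with positive survival",
      anchor_month), "anchor_month")
  -log(s) / anchor_month
}

#' Extend a survival curve to a lifetime horizon (DEALE)
#'
#' Keeps the observed segment up to the anchor month untouched and replaces
#' everything beyond it with the constant-hazard exponential tail
#' `S(t) = S(anchor) * exp(-hazard * (t - anchor))`.
#'
#' @param curve a [survival_curve()].
#' @param horizon_cycles last month of the extended grid; must be at least
#'   the observed curve length.
#' @param anchor_month anchor for the hazard (defaults to the curve's own).
#' @return a `survival_curve` on months `0:horizon_cycles` with `hazard`
#'   filled in and `extrapolated = TRUE`.
#' @examples
#' sc <- survival_curve(exp(-(0:8) * log(2) / 8))
#' ext <- extrapolate_curve(sc, 16)
#' ext$survival[17] # 0.25: one extra half-life
#' @export
extrapolate_curve <- function(curve, horizon_cycles,
                              anchor_month = curve$anchor_month) {
  stopifnot(inherits(curve, "survival_curve"))
  assert_num(horizon_cycles, "horizon_cycles", min = 1)
  horizon_cycles <- as.integer(horizon_cycles)
  if (horizon_cycles < max(curve$months))
    validation_error(sprintf("horizon %d shorter than observed curve (max month %d)",
                             horizon_cycles, max(curve$months)), "horizon_cycles")
  h <- deale_hazard(curve, anchor_month)
  months <- 0:horizon_cycles
  s_anchor <- curve_at(curve, anchor_month)
  surv <- numeric(length(months))
  obs_keep <- months <= anchor_month
  surv[obs_keep] <- curve$survival[match(months[obs_keep], curve$months)]
  tail_idx <- which(!obs_keep)
  surv[tail_idx] <- s_anchor * exp(-h * (months[tail_idx] - anchor_month))
  out <- survival_curve(surv, months, anchor_month = anchor_month)
  out$hazard <- h
  out$extrapolated <- TRUE
  out
}

#' Pointwise average of two survival curves
#'
#' Used to pool the chemotherapy comparator arms of two trials with similar
#' populations into a single curve: the arithmetic mean of the survival
#' probabilities at each month.
#'
#' @param a,b `survival_curve` objects on the same month grid.
#' @return a `survival_curve`; anchor month taken from `a`.
#' @export
average_curves <- function(a, b) {
  stopifnot(inherits(a, "survival_curve"), inherits(b, "survival_curve"))
  if (length(a$months) != length(b$months) || any(a$months != b$months))
    validation_error("curves must share the same month grid")
  survival_curve((a$survival + b$survival) / 2, a$months,
                 anchor_month = a$anchor_month)
}

#' Three-state occupancy from OS and PFS curves
#'
#' Partitioned-survival bookkeeping: at each month the cohort splits as
#' `stable = PFS`, `progressed = OS - PFS`, `dead = 1 - OS`, so rows always
#' sum to 1. Digitized inputs can place PFS slightly above OS; violations
#' up to 1e-9 are clipped silently, up to 0.05 clipped with a warning, and
#' anything larger is rejected as inconsistent input.
#'
#' @param os,pfs `survival_curve` objects on the same month grid (usually
#'   already extrapolated with [extrapolate_curve()]).
#' @param horizon_cycles last cycle of the trace; defaults to the full
#'   common grid.
#' @return a data frame of class `occupancy` with columns `cycle`,
#'   `stable`, `progressed`, `dead`.
#' @examples
#' os  <- extrapolate_curve(survival_curve(exp(-(0:8) * log(2) / 9)), 60)
#' pfs <- extrapolate_curve(survival_curve(exp(-(0:8) * log(2) / 3)), 60)
#' head(occupancy_from_survival(os, pfs))
#' @export
occupancy_from_survival <- function(os, pfs, horizon_cycles = NULL) {
  stopifnot(inherits(os, "survival_curve"), inherits(pfs, "survival_curve"))
  if (length(os$months) != length(pfs$months) || any(os$months != pfs$months))
    validation_error("OS and PFS must share the same month grid")
  horizon_cycles <- as.integer(horizon_cycles %||% max(os$months))
  if (horizon_cycles > max(os$months))
    validation_error("horizon exceeds curve grid; extrapolate first", "horizon_cycles")
  keep <- os$months <= horizon_cycles
  s_os <- os$survival[keep]
  s_pfs <- pfs$survival[keep]
  excess <- s_pfs - s_os
  mx <- max(excess)
  if (mx > 0.05)
    validation_error(sprintf(
      "PFS exceeds OS by up to %.4g (> 0.05): inconsistent survival inputs", mx))
  if (mx > 1e-9)
    warning(sprintf("PFS exceeds OS by up to %.4g at %d month(s); clipping PFS to OS",
                    mx, sum(excess > 1e-9)))
  s_pfs <- pmin(s_pfs, s_os)
  out <- data.frame(cycle = os$months[keep],
                    stable = s_pfs,
                    progressed = s_os - s_pfs,
                    dead = 1 - s_os)
  class(out) <- c("occupancy", "data.frame")
  out
}

#' Per-cycle conditional transition probabilities (diagnostic)
#'
#' The trace is defined by occupancy, not by a transition matrix; this
#' derives one consistent set of per-cycle conditional probabilities for a
#' stable -> progressed -> dead chain that reproduces the trace. Deaths in
#' each cycle are attributed to the progressed state first (up to its
#' occupancy) and to stable disease only for the remainder; patients never
#' move backwards. Intended for model inspection, not for computation.
#'
#' @param occupancy an `occupancy` data frame.
#' @return data frame with columns `cycle`, `p_stable_stay`,
#'   `p_stable_progress`, `p_stable_die`, `p_prog_stay`, `p_prog_die`,
#'   one row per transition (cycle t -> t+1).
#' @seealso [occupancy_from_transitions()] for the consistency check.
#' @export
transition_probabilities <- function(occupancy) {
  stopifnot(inherits(occupancy, "occupancy"))
  n <- nrow(occupancy) - 1L
  res <- data.frame(cycle = occupancy$cycle[seq_len(n)],
                    p_stable_stay = NA_real_, p_stable_progress = NA_real_,
                    p_stable_die = NA_real_, p_prog_stay = NA_real_,
                    p_prog_die = NA_real_)
  for (i in seq_len(n)) {
    st <- occupancy$stable[i]; pr <- occupancy$progressed[i]
    d_new <- occupancy$dead[i + 1L] - occupancy$dead[i]
    from_prog <- min(pr, d_new)
    from_stable <- d_new - from_prog
    p_ss <- if (st > 0) occupancy$stable[i + 1L] / st else 1
    p_sd <- if (st > 0) from_stable / st else 0
    res$p_stable_stay[i] <- p_ss
    res$p_stable_die[i] <- p_sd
    res$p_stable_progress[i] <- max(1 - p_ss - p_sd, 0)
    res$p_prog_die[i] <- if (pr > 0) from_prog / pr else 0
    res$p_prog_stay[i] <- 1 - res$p_prog_die[i]
  }
  res
}

#' Rebuild an occupancy trace from conditional transition probabilities
#'
#' Forward-simulates the cohort under the chain returned by
#' [transition_probabilities()], starting from the first row of the trace
#' it was derived from. Used as a consistency diagnostic: the rebuilt trace
#' must match the original.
#'
#' @param tp output of [transition_probabilities()].
#' @param start named numeric with `stable`, `progressed`, `dead`
#'   (defaults to the all-stable cohort).
#' @return an `occupancy` data frame with `nrow(tp) + 1` rows.
#' @export
occupancy_from_transitions <- function(tp, start = c(stable = 1, progressed = 0, dead = 0)) {
  n <- nrow(tp)
  st <- numeric(n + 1L); pr <- numeric(n + 1L); dd <- numeric(n + 1L)
  st[1] <- start[["stable"]]; pr[1] <- start[["progressed"]]; dd[1] <- start[["dead"]]
  for (i in seq_len(n)) {
    st[i + 1L] <- st[i] * tp$p_stable_stay[i]
    pr[i + 1L] <- pr[i] * tp$p_prog_stay[i] + st[i] * tp$p_stable_progress[i]
    dd[i + 1L] <- dd[i] + st[i] * tp$p_stable_die[i] + pr[i] * tp$p_prog_die[i]
  }
  out <- data.frame(cycle = c(tp$cycle, tp$cycle[n] + 1L),
                    stable = st, progressed = pr, dead = dd)
  class(out) <- c("occupancy", "data.frame")
  out
}
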