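# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial rounding as used when reporting ICERs and QALY thresholds:
#' ties are rounded away from zero, unlike [base::round()] which rounds
#' half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_half_up(0.23325, 4) # 0.2333
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Condition constructor for input-validation failures; `field` is a
# slash-separated path into the scenario so messages pinpoint the offender.
validation_error <- function(msg, field = NULL) {
  if (!is.null(field)) msg <- sprintf("%s [field: %s]", msg, field)
  stop(errorCondition(msg, class = c("melcea_validation_error", "error")))
}

assert_num <- function(x, field, min = -Inf, max = Inf, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(!is.finite(x)))
    validation_error(sprintf("expected %d finite numeric value(s)", len), field)
  if (any(x < min) || any(x > max))
    validation_error(sprintf("value %s outside [%s, %s]",
                             paste(signif(x[x < min | x > max], 10), collapse = ", "),
                             min, max), field)
  invisible(x)
}

assert_string <- function(x, field) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    validation_error("expected a non-empty string", field)
  invisible(x)
}

# Reject unknown keys so typos in scenario files fail loudly.
check_keys <- function(x, allowed, required, path) {
  nm <- names(x)
  if (is.null(nm) && length(x) > 0)
    validation_error("expected a named mapping", path)
  unknown <- setdiff(nm, allowed)
  if (length(unknown) > 0)
    validation_error(sprintf("unknown key(s): %s", paste(unknown, collapse = ", ")), path)
  missing <- setdiff(required, nm)
  if (length(missing) > 0)
    validation_error(sprintf("missing required key(s): %s", paste(missing, collapse = ", ")), path)
  invisible(x)
}

# Deterministic, platform-independent string hash on [0, 2^31 - 2].
# All intermediates stay below 2^53 so double arithmetic is exact.
str_hash <- function(s) {
  p <- 2147483647
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% p
  h
}

# Derive an independent substream seed from a master seed and a parameter
# path. Used by the PSA so that draw streams are keyed by parameter name,
# not declaration order.
sub_seed <- function(master, path) {
  p <- 2147483647
  as.integer((((str_hash(path) + 1) * 131071) %% p + (master %% p)) %% p)
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards (same contract as withr::with_seed, kept dependency-free).
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
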