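# Parameter uncertainty specifications (base / low / high triples with a
# distribution family tag) and their method-of-moments fits for the PSA.

#' Specify a parameter with its uncertainty range
#'
#' A `dist_spec` is the unit of parameterization throughout the package:
#' a base-case value plus a low/high sensitivity range and a distribution
#' family used by the probabilistic sensitivity analysis. Probabilities
#' take `family = "beta"`, costs `family = "gamma"`; `family = "fixed"`
#' marks a parameter that is never varied.
#'
#' @param base base-case value, in native units (USD, probability, utility).
#' @param low,high sensitivity-analysis range; must bracket `base`.
#'   Default to `base` (no range information).
#' @param family one of `"fixed"`, `"beta"`, `"gamma"`.
#' @return an object of class `dist_spec`.
#' @examples
#' dist_spec(988.86, 678.29, 1356.85, "gamma")
#' @export
dist_spec <- function(base, low = base, high = base,
                      family = c("fixed", "beta", "gamma")) {
  family <- match.arg(family)
  assert_num(base, "base")
  assert_num(low, "low")
  assert_num(high, "high")
  if (low > base || base > high)
    validation_error(sprintf("range must satisfy low <= base <= high (got %s <= %s <= %s)",
                             low, base, high))
  if (family == "beta" && (low < 0 || high > 1))
    validation_error("beta family requires 0 <= low and high <= 1")
  if (family == "gamma" && low < 0)
    validation_error("gamma family requires low >= 0")
  structure(list(base = base, low = low, high = high, family = family),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec %s> base %s [%s, %s]\n", x$family, x$base, x$low, x$high))
  invisible(x)
}

is_zero_width <- function(spec) spec$low == spec$high

#' Fit a sampling distribution to a parameter specification
#'
#' Converts a [dist_spec()] into a concrete beta, gamma or degenerate
#' distribution whose mean equals the base-case value, by the method of
#' moments with the low/high range read as a central 95% interval:
#' `sd = (high - low) / (2 * 1.96)`.
#'
#' Two situations carry no usable range information and fall back to a
#' mean-preserving effective-sample-size beta, `alpha = base * ess`,
#' `beta = (1 - base) * ess`:
#' * an uninformative printed range of 0--1 (common for utilities);
#' * a zero-width beta spec (a probability printed without a range).
#'
#' A method-of-moments beta whose implied variance reaches the maximum
#' `mean * (1 - mean)` also falls back, with a warning. Zero-width gamma
#' specs and `family = "fixed"` yield point masses.
#'
#' @param spec a [dist_spec()].
#' @param ess effective sample size for the fallback beta (default 20).
#' @return an object of class `fitted_distribution` with elements
#'   `family`, shape parameters, and the originating `spec`.
#' @examples
#' fit_distribution(dist_spec(988.86, 678.29, 1356.85, "gamma"))
#' @export
fit_distribution <- function(spec, ess = 20) {
  stopifnot(inherits(spec, "dist_spec"))
  out <- function(family, a = NA_real_, b = NA_real_, value = NA_real_) {
    structure(list(family = family, shape1 = a, shape2 = b, value = value,
                   source = spec), class = "fitted_distribution")
  }
  m <- spec$base
  if (spec$family == "fixed") return(out("fixed", value = m))
  if (spec$family == "beta") {
    if (m <= 0 || m >= 1) return(out("fixed", value = m))
    ess_fit <- out("beta", a = m * ess, b = (1 - m) * ess)
    if (is_zero_width(spec) || (spec$low <= 0 && spec$high >= 1))
      return(ess_fit)
    v <- ((spec$high - spec$low) / (2 * 1.96))^2
    if (v >= m * (1 - m)) {
      warning(sprintf(
        "beta range for base %s implies variance >= mean*(1-mean); using effective-sample-size fit (ess = %s)",
        m, ess))
      return(ess_fit)
    }
    nu <- m * (1 - m) / v - 1
    return(out("beta", a = m * nu, b = (1 - m) * nu))
  }
  # gamma
  if (m == 0 || is_zero_width(spec)) return(out("fixed", value = m))
  v <- ((spec$high - spec$low) / (2 * 1.96))^2
  out("gamma", a = m^2 / v, b = v / m) # shape, scale
}

#' Mean of a fitted distribution
#' @param fd a `fitted_distribution`.
#' @return the distribution mean (equals the source base value).
#' @export
dist_mean <- function(fd) {
  stopifnot(inherits(fd, "fitted_distribution"))
  switch(fd$family,
         fixed = fd$value,
         beta  = fd$shape1 / (fd$shape1 + fd$shape2),
         gamma = fd$shape1 * fd$shape2)
}

#' Draw Monte-Carlo samples from a fitted distribution
#'
#' @param fd a `fitted_distribution` from [fit_distribution()].
#' @param n number of draws.
#' @return numeric vector of length `n`; uses the current RNG stream.
#' @export
draw_distribution <- function(fd, n) {
  stopifnot(inherits(fd, "fitted_distribution"), n >= 0)
  switch(fd$family,
         fixed = rep(fd$value, n),
         beta  = stats::rbeta(n, fd$shape1, fd$shape2),
         gamma = stats::rgamma(n, shape = fd$shape1, scale = fd$shape2))
}

#' @export
print.fitted_distribution <- function(x, ...) {
  cat(switch(x$family,
             fixed = sprintf("<fitted point mass at %s>\n", x$value),
             beta  = sprintf("<fitted beta(%0.6g, %0.6g), mean %0.6g>\n",
                             x$shape1, x$shape2, dist_mean(x)),
             gamma = sprintf("<fitted gamma(shape %0.6g, scale %0.6g), mean %0.6g>\n",
                             x$shape1, x$shape2, dist_mean(x))))
  invisible(x)
}
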