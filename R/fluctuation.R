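# Mutation-rate estimation from fluctuation assays via the Lea-Coulson
# median estimator: solve r = m (1.24 + ln m) for the expected mutations
# per culture m at the observed median mutant count r, then mu = m / N
# with N the median viable titer.

#' Solve the Lea-Coulson median equation for m
#'
#' Finds the unique root of `f(m) = r - 1.24 m - m ln(m)` on the admissible
#' branch `m > exp(-1.24)`, where `f` is strictly decreasing. The bracket
#' starts at `[max(r/10, 1e-6), max(10 r, 10)]` and expands geometrically
#' if needed, then the root is bisected and Newton-refined to the requested
#' relative tolerance.
#'
#' @param r_median positive median number of mutant colonies per culture.
#' @param tol relative tolerance on m.
#' @return the solution m (positive real).
#' @export
lea_coulson_m <- function(r_median, tol = 1e-10) {
  if (!is.finite(r_median) || r_median <= 0)
    stop("the median estimator is undefined for a non-positive median ",
         "mutant count; use more cultures so that the median exceeds zero")
  f <- function(m) r_median - 1.24 * m - m * log(m)
  lo <- max(r_median / 10, 1e-6)
  hi <- max(10 * r_median, 10)
  while (f(lo) < 0 && lo > .Machine$double.xmin) lo <- lo / 10
  while (f(hi) > 0 && hi < .Machine$double.xmax / 10) hi <- hi * 10
  m <- uniroot(f, c(lo, hi), tol = min(tol, 1e-12) * max(1, hi))$root
  # Newton polish: f'(m) = -(2.24 + ln m)
  for (i in 1:50) {
    step <- f(m) / (2.24 + log(m))
    m_new <- m + step
    if (!is.finite(m_new) || m_new <= 0) break
    m <- m_new
    if (abs(step) <= tol * m) break
  }
  m
}

#' Mutation rate from mutations per culture and viable titer
#'
#' `mu = m / n_median`: the per-cell, per-division mutation probability.
#'
#' @param m expected mutations per culture (positive).
#' @param n_median median viable count on permissive plates (positive).
#' @return mutation rate mu.
#' @export
mutation_rate <- function(m, n_median) {
  stopifnot(m > 0, n_median > 0)
  m / n_median
}

#' Estimate the mutation rate from fluctuation-assay cultures
#'
#' Takes the median of the mutant counts and of the titers (an even number
#' of cultures yields the mean of the two central order statistics),
#' solves the Lea-Coulson equation and divides by the median titer.
#'
#' @param data a [fluctuation_data()].
#' @param tol relative tolerance passed to [lea_coulson_m()].
#' @return an object of class `fluctuation_estimate`: list with `m`, `mu`,
#'   `r_median`, `n_median`, `lc_constant` (1.24), `n_cultures` and
#'   `true_mu` (when simulated).
#' @export
estimate_from_cultures <- function(data, tol = 1e-10) {
  stopifnot(inherits(data, "fluctuation_data"))
  r_median <- median(data$r_values)
  n_median <- median(data$titers)
  m <- lea_coulson_m(r_median, tol = tol)
  structure(list(m = m,
                 mu = mutation_rate(m, n_median),
                 r_median = r_median,
                 n_median = n_median,
                 lc_constant = 1.24,
                 n_cultures = length(data$r_values),
                 true_mu = data$true_mu),
            class = "fluctuation_estimate")
}

#' @export
print.fluctuation_estimate <- function(x, ...) {
  cat(sprintf(
    "fluctuation estimate: m = %.4g (median r = %g, N cultures = %d)\n",
    x$m, x$r_median, x$n_cultures))
  cat(sprintf("mutation rate mu = %.4g per cell per division (median titer %g)\n",
              x$mu, x$n_median))
  if (!is.null(x$true_mu))
    cat(sprintf("simulated truth: mu = %.4g\n", x$true_mu))
  invisible(x)
}
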