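# Analytic engine: exact conditional rates via Poisson thinning, and
# population rates by Gauss-Legendre quadrature over the Exponential frailty.
#
# Conditional on lambda_1, the total offense count over years 1..t is
# Poisson with mean S_t = sum_i lambda_i, so
#   P(>=1 offense by t)          = 1 - exp(-S_t)
#   P(>=1 charged offense by t)  = 1 - exp(-r * S_t)
# the latter because independently charging each offense with probability r
# thins the Poisson process to rate r * lambda_i.

#' Exact cumulative rates conditional on a year-1 hazard
#'
#' @param lambda_1 Year-1 Poisson mean, \eqn{\ge 0}.
#' @param r Per-offense charge probability in \eqn{[0, 1]}.
#' @param schedule A [desistance_schedule()] or bare numeric \code{d}.
#' @param t Checkpoint year(s), integers \eqn{\ge 1}. Vectorised.
#'
#' @return A data frame with columns \code{year}, \code{cum_actual},
#'   \code{cum_charged}.
#' @examples
#' conditional_rates(0.05, r = 0.5, schedule = 0, t = 25)
#' @export
conditional_rates <- function(lambda_1, r, schedule, t) {
  lambda_1 <- check_lambda(lambda_1, "lambda_1")
  if (length(lambda_1) != 1L) stop("`lambda_1` must be a single value",
                                   call. = FALSE)
  if (!is.numeric(r) || length(r) != 1L || r < 0 || r > 1) {
    stop("`r` must be a probability in [0, 1]", call. = FALSE)
  }
  t <- as.integer(t)
  if (any(is.na(t)) || any(t < 1L)) stop("`t` must be integers >= 1",
                                         call. = FALSE)
  traj <- hazard_trajectory(lambda_1, schedule, horizon = max(t))
  s <- cumsum(traj$lambda)[t]
  data.frame(year = t,
             cum_actual = -expm1(-s),
             cum_charged = -expm1(-r * s))
}

# Cumulative hazard matrix over quadrature nodes: row = node (lambda_1
# value), column = checkpoint year. The recurrence is nonlinear in
# lambda_1, so it is iterated at every node (vectorised across nodes).
cum_hazard_nodes <- function(lam1, schedule, checkpoints) {
  horizon <- max(checkpoints)
  s <- numeric(length(lam1))
  out <- matrix(NA_real_, length(lam1), length(checkpoints))
  lam <- lam1
  k <- 1L
  for (yr in seq_len(horizon)) {
    s <- s + lam
    if (yr == checkpoints[k]) {
      out[, k] <- s
      k <- k + 1L
    }
    if (yr < horizon) lam <- next_lambda(lam, schedule)
  }
  out
}

# Laguerre rules depend only on the order; cache them across calls.
# (Used by the per-year trajectory summaries, where the calibrated mu
# keeps the integrand well scaled.)
laguerre_cache <- new.env(parent = emptyenv())
laguerre_rule <- function(n) {
  key <- as.character(n)
  if (is.null(laguerre_cache[[key]])) {
    laguerre_cache[[key]] <- pracma::gaussLaguerre(n, 0)
  }
  laguerre_cache[[key]]
}

# E[1 - exp(-thin * S_t(lambda_1))] for lambda_1 ~ Exponential(mean mu),
# by adaptive Gauss-Kronrod on the lambda_1 scale. The integrand has two
# scales (the population density on scale mu, the conditional rate on
# scale 1/(thin * t)); adaptivity handles any ratio of the two, which a
# fixed-order rule does not.
population_rate_one <- function(mu, thin, schedule, checkpoint, tol) {
  f <- function(lam1) {
    s <- cum_hazard_nodes(lam1, schedule, checkpoint)[, 1L]
    -expm1(-thin * s) * stats::dexp(lam1, rate = 1 / mu)
  }
  q <- stats::integrate(f, 0, Inf, rel.tol = 1e-10, abs.tol = tol / 10,
                        stop.on.error = FALSE)
  if (q$message != "OK" || q$abs.error > tol) {
    stop(sprintf(
      "quadrature did not converge: %s, abs.error %.3g > tol %.3g (mu=%g, thin=%g, d=%g, t=%d)",
      q$message, q$abs.error, tol, mu, thin, schedule$d, checkpoint),
      call. = FALSE)
  }
  q$value
}

#' Population cumulative rates by quadrature over the Exponential frailty
#'
#' Integrates the exact conditional rates of [conditional_rates()] against
#' the Exponential(mean \code{mu}) density of the year-1 hazard, using
#' adaptive Gauss-Kronrod quadrature on \eqn{(0, \infty)}. Each returned
#' value carries an estimated quadrature error below \code{tol}, enforced
#' from the integrator's own error estimate.
#'
#' This is the deterministic counterpart of [run_mc()]: same model, no
#' sampling noise. It is the default engine for calibration.
#'
#' @param mu Exponential-population mean of the year-1 hazard, \eqn{> 0}.
#' @param r Per-offense charge probability in \eqn{[0, 1]}.
#' @param schedule A [desistance_schedule()] or bare numeric \code{d}.
#' @param checkpoints Checkpoint years (default \code{c(5,10,15,20,25)}).
#' @param tol Maximum acceptable quadrature error per value (default 1e-8).
#'
#' @return A \code{"rate_estimates"} data frame (standard errors are zero;
#'   attribute \code{method = "analytic"}).
#' @examples
#' population_rates(0.0287, r = 1, schedule = 0.123)
#' @export
population_rates <- function(mu, r, schedule, checkpoints = c(5L, 10L, 15L, 20L, 25L),
                             tol = 1e-8) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0) {
    stop("`mu` must be a single finite number > 0", call. = FALSE)
  }
  if (!is.numeric(r) || length(r) != 1L || r < 0 || r > 1) {
    stop("`r` must be a probability in [0, 1]", call. = FALSE)
  }
  schedule <- as_schedule(schedule)
  checkpoints <- as.integer(checkpoints)
  if (any(checkpoints < 1L) || is.unsorted(checkpoints, strictly = TRUE)) {
    stop("`checkpoints` must be strictly increasing years >= 1", call. = FALSE)
  }
  actual <- vapply(checkpoints, function(t) {
    population_rate_one(mu, 1, schedule, t, tol)
  }, numeric(1))
  charged <- if (r == 1) actual else vapply(checkpoints, function(t) {
    population_rate_one(mu, r, schedule, t, tol)
  }, numeric(1))
  df <- data.frame(
    year = checkpoints,
    actual = actual,
    charged = charged,
    actual_se = 0,
    charged_se = 0
  )
  new_rate_estimates(df, method = "analytic", n_iterations = NA_integer_)
}
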