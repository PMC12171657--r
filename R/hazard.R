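# Deterministic hazard core: the annual odds-decrement recurrence and the
# conversions among a Poisson mean, the annual probability of >=1 offense,
# and the annual odds of reoffending.

#' Annual desistance schedule
#'
#' Desistance is modelled as a fixed proportional decrease in the *odds* of
#' reoffending each year: if this year's odds are \eqn{o}, next year's are
#' \eqn{(1-d)\,o}. The schedule stores the annual decrement \code{d} and its
#' retention factor \code{1 - d}, which multiplies the odds each year.
#'
#' @param d Annual proportional decrease in the odds of reoffending, a single
#'   number in \eqn{[0, 1]}. \code{d = 0.123} (odds retained at 0.877) is the
#'   headline empirical estimate the package's default scenarios use;
#'   \code{d = 0} is the constant-hazard limiting case.
#'
#' @return An object of class \code{"desistance_schedule"}: a list with
#'   elements \code{d} and \code{retention = 1 - d}.
#' @examples
#' desistance_schedule(0.123)
#' desistance_schedule(0)$retention
#' @export
desistance_schedule <- function(d) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d)) {
    stop("`d` must be a single finite number", call. = FALSE)
  }
  if (d < 0 || d > 1) {
    stop("`d` must lie in [0, 1]; got ", format(d), call. = FALSE)
  }
  structure(list(d = as.numeric(d), retention = 1 - as.numeric(d)),
            class = "desistance_schedule")
}

#' @export
print.desistance_schedule <- function(x, ...) {
  cat(sprintf(
    "Desistance schedule: odds of reoffending decrease %.4g%% per year (retention %.4g)\n",
    100 * x$d, x$retention))
  invisible(x)
}

# Accept either a schedule object or a bare numeric d everywhere downstream.
as_schedule <- function(x) {
  if (inherits(x, "desistance_schedule")) x else desistance_schedule(x)
}

check_lambda <- function(lambda, arg = "lambda") {
  if (!is.numeric(lambda) || length(lambda) == 0L) {
    stop("`", arg, "` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(lambda)) || any(lambda < 0)) {
    stop("`", arg, "` must be finite and >= 0", call. = FALSE)
  }
  as.numeric(lambda)
}

#' One-year update of the Poisson reoffending mean
#'
#' Applies the desistance recurrence: the odds of reoffending,
#' \eqn{e^{\lambda} - 1}, are multiplied by the retention factor \eqn{1 - d},
#' and the result is mapped back to a Poisson mean. In closed form
#' \deqn{\lambda_{i+1} = \log\!\big(1 + (1-d)(e^{\lambda_i} - 1)\big),}
#' computed with \code{expm1}/\code{log1p} so that tiny hazards
#' (\eqn{\lambda \sim 10^{-12}}) do not lose precision to cancellation.
#'
#' The decrement is applied unconditionally every year, whether or not an
#' offense occurred that year.
#'
#' @param lambda Current-year Poisson mean(s), finite and \eqn{\ge 0}.
#'   Vectorised.
#' @param schedule A [desistance_schedule()], or a bare numeric \code{d}.
#'
#' @return Next-year Poisson mean(s), in \eqn{[0, \lambda]}.
#' @examples
#' next_lambda(0.1, 0.123)
#' # odds are preserved up to the retention factor:
#' odds_reoffense(next_lambda(0.1, 0.123)) / odds_reoffense(0.1)  # 0.877
#' @export
next_lambda <- function(lambda, schedule) {
  lambda <- check_lambda(lambda)
  schedule <- as_schedule(schedule)
  rho <- schedule$retention
  if (rho == 0) return(rep.int(0, length(lambda)))
  out <- log1p(rho * expm1(lambda))
  # exact alternative form 1 + rho*(e^l - 1) = e^l * (rho + (1-rho) e^-l)
  # avoids expm1() overflow for large hazards
  big <- lambda > 30
  if (any(big)) {
    out[big] <- lambda[big] + log(rho + (1 - rho) * exp(-lambda[big]))
  }
  out
}

#' Annual probability of at least one offense
#'
#' For a Poisson mean \eqn{\lambda}, the probability of one or more events in
#' the year is \eqn{1 - e^{-\lambda}}.
#'
#' @param lambda Poisson mean(s), \eqn{\ge 0}. Vectorised.
#' @return Probability in \eqn{[0, 1)}.
#' @export
prob_reoffense <- function(lambda) {
  lambda <- check_lambda(lambda)
  -expm1(-lambda)
}

#' Annual odds of at least one offense
#'
#' The odds \eqn{p/(1-p)} with \eqn{p = 1 - e^{-\lambda}} reduce to
#' \eqn{e^{\lambda} - 1}.
#'
#' @param lambda Poisson mean(s), \eqn{\ge 0}. Vectorised.
#' @return Odds, \eqn{\ge 0}.
#' @export
odds_reoffense <- function(lambda) {
  lambda <- check_lambda(lambda)
  expm1(lambda)
}

#' Invert probability or odds back to a Poisson mean
#'
#' \code{lambda_from_prob(p)} returns \eqn{-\log(1-p)};
#' \code{lambda_from_odds(o)} returns \eqn{\log(1+o)}. Together with
#' [prob_reoffense()] and [odds_reoffense()] these conversions round-trip to
#' machine precision.
#'
#' @param p Probability in \eqn{[0, 1)}. Vectorised.
#' @return Poisson mean \eqn{\ge 0}.
#' @export
lambda_from_prob <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p >= 1)) {
    stop("`p` must be in [0, 1)", call. = FALSE)
  }
  -log1p(-p)
}

#' @rdname lambda_from_prob
#' @param odds Odds \eqn{\ge 0}. Vectorised.
#' @export
lambda_from_odds <- function(odds) {
  if (!is.numeric(odds) || any(!is.finite(odds)) || any(odds < 0)) {
    stop("`odds` must be finite and >= 0", call. = FALSE)
  }
  log1p(odds)
}

#' Multi-year hazard trajectory
#'
#' Iterates the desistance recurrence from a starting Poisson mean
#' \code{lambda_1} over \code{horizon} years and reports, for each year, the
#' Poisson mean, the annual probability of \eqn{\ge 1} offense, and the annual
#' odds. Years are indexed 1..\code{horizon}; \code{lambda_1} applies to
#' year 1.
#'
#' @param lambda_1 Year-1 Poisson mean, \eqn{\ge 0}.
#' @param schedule A [desistance_schedule()] or bare numeric \code{d}.
#' @param horizon Number of years, integer \eqn{\ge 1}.
#'
#' @return A data frame of class \code{"hazard_trajectory"} with columns
#'   \code{year}, \code{lambda}, \code{prob}, \code{odds}.
#' @examples
#' hazard_trajectory(0.1, 0.123, horizon = 3)
#' @export
hazard_trajectory <- function(lambda_1, schedule, horizon = 25L) {
  lambda_1 <- check_lambda(lambda_1, "lambda_1")
  if (length(lambda_1) != 1L) {
    stop("`lambda_1` must be a single value", call. = FALSE)
  }
  schedule <- as_schedule(schedule)
  if (!is.numeric(horizon) || length(horizon) != 1L || !is.finite(horizon) ||
      horizon < 1 || horizon != round(horizon)) {
    stop("`horizon` must be an integer >= 1", call. = FALSE)
  }
  horizon <- as.integer(horizon)
  lambdas <- numeric(horizon)
  lambdas[1L] <- lambda_1
  if (horizon > 1L) {
    for (i in 2:horizon) {
      lambdas[i] <- next_lambda(lambdas[i - 1L], schedule)
    }
  }
  out <- data.frame(
    year = seq_len(horizon),
    lambda = lambdas,
    prob = prob_reoffense(lambdas),
    odds = odds_reoffense(lambdas)
  )
  class(out) <- c("hazard_trajectory", "data.frame")
  attr(out, "d") <- schedule$d
  out
}
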