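# Scenario container shared by the Monte Carlo and analytic engines.

#' Specify one simulated offender population
#'
#' Bundles the parameters of a single scenario: the Exponential-population
#' mean \code{mu} of the year-1 Poisson hazard, the per-offense charge
#' probability \code{r} (the Binomial thinning probability that an offense
#' is ever charged), the desistance schedule, the horizon, the checkpoint
#' years at which cumulative rates are reported, and the Monte Carlo
#' iteration count and seed.
#'
#' @param mu Exponential-population mean of the year-1 Poisson mean,
#'   expected offenses/year, \eqn{> 0}.
#' @param r Per-offense charge probability in \eqn{[0, 1]}.
#' @param schedule A [desistance_schedule()] or bare numeric \code{d}
#'   (default 0.123).
#' @param horizon Simulation horizon in years (default 25).
#' @param checkpoints Strictly increasing years within \code{1..horizon} at
#'   which cumulative rates are reported (default \code{c(5,10,15,20,25)}).
#' @param n_iterations Monte Carlo trial count (default 30000).
#' @param seed Integer RNG seed (default 1).
#' @param sampling How the year-1 hazards are drawn from the Exponential
#'   population: \code{"lhs"} (Latin Hypercube stratification, the default
#'   sampling type of the spreadsheet risk-analysis tools this model family
#'   was originally run in) or \code{"iid"} (plain Monte Carlo). Yearly
#'   offense and charge counts are ordinary conditional draws either way.
#'
#' @return An object of class \code{"scenario_spec"}.
#' @examples
#' scenario_spec(mu = 0.0287, r = 1)
#' @export
scenario_spec <- function(mu, r, schedule = 0.123, horizon = 25L,
                          checkpoints = c(5L, 10L, 15L, 20L, 25L),
                          n_iterations = 30000L, seed = 1L,
                          sampling = c("lhs", "iid")) {
  sampling <- match.arg(sampling)
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0) {
    stop("`mu` must be a single finite number > 0", call. = FALSE)
  }
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0 || r > 1) {
    stop("`r` must be a single probability in [0, 1]", call. = FALSE)
  }
  schedule <- as_schedule(schedule)
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 1 ||
      horizon != round(horizon)) {
    stop("`horizon` must be an integer >= 1", call. = FALSE)
  }
  horizon <- as.integer(horizon)
  checkpoints <- as.integer(checkpoints)
  if (length(checkpoints) == 0L || any(is.na(checkpoints)) ||
      any(checkpoints < 1L) || any(checkpoints > horizon) ||
      is.unsorted(checkpoints, strictly = TRUE)) {
    stop("`checkpoints` must be strictly increasing years within 1..horizon",
         call. = FALSE)
  }
  if (!is.numeric(n_iterations) || length(n_iterations) != 1L ||
      n_iterations < 1 || n_iterations != round(n_iterations)) {
    stop("`n_iterations` must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  structure(list(
    mu = as.numeric(mu), r = as.numeric(r), schedule = schedule,
    horizon = horizon, checkpoints = checkpoints,
    n_iterations = as.integer(n_iterations), seed = as.integer(seed),
    sampling = sampling
  ), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario: mu =", format(x$mu), " r =", format(x$r),
      " d =", format(x$schedule$d), " horizon =", x$horizon, "years\n")
  cat("  checkpoints:", paste(x$checkpoints, collapse = ", "),
      " iterations:", x$n_iterations, " seed:", x$seed,
      " sampling:", x$sampling, "\n")
  invisible(x)
}

# Plain-list form used for JSON sidecars.
spec_as_list <- function(spec) {
  list(mu = spec$mu, r = spec$r, d = spec$schedule$d, horizon = spec$horizon,
       checkpoints = spec$checkpoints, n_iterations = spec$n_iterations,
       seed = spec$seed, sampling = spec$sampling)
}

new_rate_estimates <- function(df, method, n_iterations, spec = NULL) {
  class(df) <- c("rate_estimates", "data.frame")
  attr(df, "method") <- method
  attr(df, "n_iterations") <- n_iterations
  attr(df, "spec") <- spec
  df
}

#' @export
print.rate_estimates <- function(x, digits = 4, ...) {
  cat(sprintf("Cumulative reoffending rates (%s", attr(x, "method")))
  if (identical(attr(x, "method"), "monte_carlo")) {
    cat(sprintf(", %d iterations", attr(x, "n_iterations")))
  }
  cat(")\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
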