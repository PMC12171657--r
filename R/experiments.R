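# Scripted scenario studies: the charge-rate table, the desistance-rate
# sensitivity grid, and the per-year population trajectory series.

T1_R <- c(1.00, 0.75, 0.50, 0.35, 0.25, 0.15, 0.05)
T2_D <- c(0.20, 0.123, 0.05, 0)

#' Actual reoffending rates across charge rates
#'
#' For each charge rate \code{r}, calibrates the population mean to the
#' charged-rate anchor (analytic calibration), runs the Monte Carlo engine,
#' and reports the cumulative actual reoffending rate at each checkpoint.
#' A second set of rows reports the same scenarios evaluated with the
#' deterministic analytic engine, for comparison free of sampling noise.
#'
#' @param n_iterations Monte Carlo iterations per scenario (default 30000).
#' @param seed RNG seed, shared by every scenario so that rows differ only
#'   through their parameters (common random numbers; default 20250122).
#' @param d Annual desistance rate (default 0.123).
#' @param target_rate Charged-rate anchor at year \code{horizon}
#'   (default 0.185).
#' @param r_values Charge rates, one row each (default
#'   \code{c(1, .75, .5, .35, .25, .15, .05)}).
#' @param horizon,checkpoints Scenario horizon and reporting years.
#'
#' @return A data frame with columns \code{mu_r}, \code{r},
#'   \code{y5 ... y25} (proportions), \code{method}, \code{n_iterations},
#'   \code{seed}; Monte Carlo rows first, ordered by descending \code{r}.
#' @export
replicate_table1 <- function(n_iterations = 30000L, seed = 20250122L,
                             d = 0.123, target_rate = 0.185,
                             r_values = T1_R, horizon = 25L,
                             checkpoints = c(5L, 10L, 15L, 20L, 25L)) {
  if (n_iterations < 1000L) stop("`n_iterations` must be >= 1000", call. = FALSE)
  schedule <- as_schedule(d)
  one <- function(r) {
    cal <- calibrate_mu(r, schedule, target_rate, horizon)
    spec <- scenario_spec(cal$mu, r, schedule, horizon, checkpoints,
                          n_iterations, seed = seed)
    mc <- run_mc(spec)
    an <- population_rates(cal$mu, r, schedule, checkpoints)
    rate_cols <- function(est) {
      stats::setNames(as.list(est$actual), paste0("y", checkpoints))
    }
    rbind(
      data.frame(mu_r = cal$mu, r = r, rate_cols(mc),
                 method = "monte_carlo", n_iterations = n_iterations,
                 seed = seed),
      data.frame(mu_r = cal$mu, r = r, rate_cols(an),
                 method = "analytic", n_iterations = NA_integer_,
                 seed = NA_integer_)
    )
  }
  rows <- lapply(r_values, one)
  out <- do.call(rbind, rows)
  out <- out[order(out$method != "monte_carlo", -out$r), ]
  rownames(out) <- NULL
  attr(out, "target_rate") <- target_rate
  attr(out, "d") <- schedule$d
  out
}

#' Actual reoffending rates across charge and desistance rates
#'
#' Full sensitivity grid: for every desistance rate \code{d} and charge rate
#' \code{r}, the population mean is freshly calibrated (with that same
#' \code{d}) to the charged-rate anchor, and the cumulative actual rate is
#' reported at each horizon, by Monte Carlo and analytically.
#'
#' @inheritParams replicate_table1
#' @param d_values Desistance rates (default \code{c(.20, .123, .05, 0)}).
#' @param horizons Reporting years (default \code{c(5, 25)}).
#' @param anchor_year Calibration anchor year (default 25).
#'
#' @return A long data frame with columns \code{d}, \code{r}, \code{mu_r},
#'   \code{horizon}, \code{rate}, \code{method}.
#' @export
replicate_table2 <- function(n_iterations = 30000L, seed = 20250122L,
                             d_values = T2_D, r_values = T1_R,
                             horizons = c(5L, 25L), target_rate = 0.185,
                             anchor_year = 25L) {
  if (n_iterations < 1000L) stop("`n_iterations` must be >= 1000", call. = FALSE)
  horizons <- sort(as.integer(horizons))
  grid <- expand.grid(r = r_values, d = d_values,
                      KEEP.OUT.ATTRS = FALSE)[, c("d", "r")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    d <- grid$d[i]
    r <- grid$r[i]
    cal <- calibrate_mu(r, d, target_rate, anchor_year)
    spec <- scenario_spec(cal$mu, r, d, horizon = max(horizons),
                          checkpoints = horizons,
                          n_iterations = n_iterations, seed = seed)
    mc <- run_mc(spec)
    an <- population_rates(cal$mu, r, d, checkpoints = horizons)
    rbind(
      data.frame(d = d, r = r, mu_r = cal$mu, horizon = horizons,
                 rate = mc$actual, method = "monte_carlo"),
      data.frame(d = d, r = r, mu_r = cal$mu, horizon = horizons,
                 rate = an$actual, method = "analytic")
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "target_rate") <- target_rate
  attr(out, "seed") <- seed
  attr(out, "n_iterations") <- n_iterations
  out
}

#' Per-year population trajectory series
#'
#' For each charge rate, calibrates \eqn{\mu_r} and computes three per-year
#' population summaries by quadrature over the Exponential frailty:
#' the expected annual probability of \eqn{\ge 1} offense
#' \eqn{E[1 - e^{-\lambda_i}]}, the expected annual odds
#' \eqn{E[e^{\lambda_i} - 1]}, and the mean hazard \eqn{E[\lambda_i]}.
#' The probability series is unconditional (not restricted to offenders who
#' have not yet reoffended).
#'
#' @param schedule A [desistance_schedule()] or bare numeric \code{d}.
#' @param r_values Charge rates.
#' @param mu_values Optional pre-calibrated population means matching
#'   \code{r_values}; calibrated to \code{target_rate} if omitted.
#' @param horizon Years (default 25).
#' @param target_rate Charged-rate anchor used when calibrating.
#' @param n_nodes Quadrature order.
#'
#' @return A long data frame with columns \code{r}, \code{year},
#'   \code{measure} (\code{"prob"}, \code{"odds"}, \code{"lambda"}),
#'   \code{value}.
#' @export
trajectory_series <- function(schedule = 0.123, r_values = T1_R,
                              mu_values = NULL, horizon = 25L,
                              target_rate = 0.185, n_nodes = 256L) {
  schedule <- as_schedule(schedule)
  if (is.null(mu_values)) {
    mu_values <- vapply(r_values, function(r) {
      calibrate_mu(r, schedule, target_rate, horizon)$mu
    }, numeric(1))
  }
  stopifnot(length(mu_values) == length(r_values))
  gl <- laguerre_rule(n_nodes)
  rows <- lapply(seq_along(r_values), function(i) {
    lam <- mu_values[i] * gl$x
    out <- vector("list", horizon)
    for (yr in seq_len(horizon)) {
      out[[yr]] <- data.frame(
        r = r_values[i], year = yr,
        measure = c("prob", "odds", "lambda"),
        value = c(sum(gl$w * -expm1(-lam)),
                  sum(gl$w * expm1(lam)),
                  sum(gl$w * lam))
      )
      if (yr < horizon) lam <- next_lambda(lam, schedule)
    }
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "d") <- schedule$d
  attr(out, "mu_values") <- stats::setNames(mu_values, r_values)
  out
}

# CSV + JSON-sidecar writers shared by the CLI. The sidecar carries the
# full parameterization so a run can be reproduced from it alone.
write_with_sidecar <- function(df, path, provenance) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(provenance, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
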