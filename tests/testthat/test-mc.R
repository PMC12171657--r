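test_that("scenario specification validates its constraints", {
  expect_error(scenario_spec(mu = 0, r = 1), "> 0")
  expect_error(scenario_spec(mu = 0.1, r = 1.5), "\\[0, 1\\]")
  expect_error(scenario_spec(mu = 0.1, r = 1, checkpoints = c(10, 5)),
               "strictly increasing")
  expect_error(scenario_spec(mu = 0.1, r = 1, checkpoints = 30),
               "strictly increasing")
  spec <- scenario_spec(0.1, 0.5, 0.123)
  expect_s3_class(spec, "scenario_spec")
  expect_identical(spec$sampling, "lhs")
})

test_that("degenerate trials behave as forced by the model", {
  set.seed(1)
  out <- simulate_trial(0, r = 1, schedule = 0.123)
  expect_true(is.na(out$first_offense_year) && is.na(out$first_charge_year))
  # r = 0: offenses can occur but are never charged
  set.seed(2)
  outs <- replicate(200, simulate_trial(2, r = 0, schedule = 0)$first_charge_year)
  expect_true(all(is.na(outs)))
  # r = 1: the first offense is always charged in the same year
  set.seed(3)
  for (i in 1:100) {
    out <- simulate_trial(1.5, r = 1, schedule = 0.123)
    expect_identical(out$first_offense_year, out$first_charge_year)
  }
  # in general a charge can come no earlier than the first offense
  set.seed(4)
  for (i in 1:200) {
    out <- simulate_trial(0.8, r = 0.3, schedule = 0.123)
    if (!is.na(out$first_charge_year)) {
      expect_true(out$first_charge_year >= out$first_offense_year)
    }
  }
})

test_that("rate estimates are reproducible, ordered and bounded", {
  spec <- scenario_spec(0.0287, 1, 0.123, n_iterations = 5000, seed = 11)
  a <- run_mc(spec)
  b <- run_mc(spec)
  expect_identical(a, b)

  for (r in c(1, 0.25)) {
    est <- run_mc(scenario_spec(0.1123, r, 0.123, n_iterations = 5000, seed = 12))
    expect_true(all(est$actual >= 0 & est$actual <= 1))
    expect_true(all(diff(est$actual) >= 0))
    expect_true(all(diff(est$charged) >= 0))
    expect_true(all(est$actual >= est$charged))
  }
  # with full charging the two rates coincide trial by trial
  full <- run_mc(scenario_spec(0.0287, 1, 0.123, n_iterations = 5000, seed = 13))
  expect_identical(full$actual, full$charged)
  # vanishing population hazard
  tiny <- run_mc(scenario_spec(1e-9, 1, 0.123, n_iterations = 5000, seed = 14))
  expect_true(all(tiny$actual < 1e-3))
})

test_that("Monte Carlo rates agree with the analytic engine within 3 SE", {
  for (r in c(1, 0.5, 0.05)) {
    for (d in c(0, 0.123, 0.2)) {
      spec <- scenario_spec(0.1, r, d, n_iterations = 10000,
                            seed = 1000 + round(1000 * (r + d)))
      mc <- run_mc(spec)
      an <- population_rates(0.1, r, d)
      se <- pmax(mc$actual_se, 1e-4)
      expect_true(all(abs(mc$actual - an$actual) <= 3 * se),
                  label = sprintf("actual rates r=%g d=%g", r, d))
      se_c <- pmax(mc$charged_se, 1e-4)
      expect_true(all(abs(mc$charged - an$charged) <= 3 * se_c),
                  label = sprintf("charged rates r=%g d=%g", r, d))
    }
  }
})

test_that("Binomial charging is equivalent to direct Poisson thinning", {
  # direct thinning oracle: simulate charged offenses as Poisson(r * lambda_i)
  thinned_mc <- function(mu, r, d, n, seed, checkpoints = c(5, 15, 25)) {
    set.seed(seed)
    lam <- stats::qexp((sample.int(n) - stats::runif(n)) / n, rate = 1 / mu)
    first_chg <- rep.int(NA_integer_, n)
    for (yr in 1:25) {
      c_i <- stats::rpois(n, r * lam)
      first_chg[is.na(first_chg) & c_i > 0L] <- yr
      lam <- next_lambda(lam, d)
    }
    vapply(checkpoints, function(t) mean(!is.na(first_chg) & first_chg <= t),
           numeric(1))
  }
  mc <- run_mc(scenario_spec(0.1123, 0.25, 0.123, n_iterations = 20000,
                             seed = 5, checkpoints = c(5, 15, 25)))
  direct <- thinned_mc(0.1123, 0.25, 0.123, n = 20000, seed = 6)
  expect_true(all(abs(mc$charged - direct) <= 3 * sqrt(2) * mc$charged_se))
})

test_that("checkpoint rates are non-decreasing in the population mean", {
  rates25 <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.5), function(mu) {
    run_mc(scenario_spec(mu, 0.5, 0.123, n_iterations = 5000, seed = 99))$actual[5]
  }, numeric(1))
  expect_true(all(diff(rates25) > 0))
})

test_that("iid sampling remains available and consistent with the oracle", {
  spec <- scenario_spec(0.0287, 1, 0.123, n_iterations = 20000, seed = 21,
                        sampling = "iid")
  mc <- run_mc(spec)
  an <- population_rates(0.0287, 1, 0.123)
  expect_true(all(abs(mc$actual - an$actual) <= 3 * mc$actual_se))
})
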