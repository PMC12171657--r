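test_that("charge-rate table has the documented shape and orderings", {
  t1 <- replicate_table1(n_iterations = 2000, seed = 5)
  expect_setequal(t1$method, c("monte_carlo", "analytic"))
  mc <- t1[t1$method == "monte_carlo", ]
  expect_identical(mc$r, t1_r)           # descending r
  expect_true(all(diff(order(-mc$r)) == 1))
  # cumulative monotonicity within each row
  rates <- as.matrix(mc[, paste0("y", t1_years)])
  expect_true(all(apply(rates, 1, function(x) all(diff(x) >= 0))))
  # solved means strictly increase as r falls
  expect_true(all(diff(mc$mu_r) > 0))
  # analytic rows carry the same calibrated means
  an <- t1[t1$method == "analytic", ]
  expect_equal(an$mu_r, mc$mu_r)
  expect_error(replicate_table1(n_iterations = 10), ">= 1000")
})

test_that("sensitivity grid calibrates each desistance rate separately", {
  t2 <- replicate_table2(n_iterations = 2000, seed = 5,
                         d_values = c(0.2, 0), r_values = c(1, 0.05))
  expect_identical(sort(unique(t2$horizon)), c(5L, 25L))
  an <- t2[t2$method == "analytic", ]
  # every (d, r) cell is anchored: charged rate at 25y equals the target,
  # so for r = 1 the actual 25-year rate equals 0.185 exactly
  r1 <- an[an$r == 1 & an$horizon == 25, ]
  expect_equal(r1$rate, rep(0.185, nrow(r1)), tolerance = 1e-7)
  # at fixed (d, horizon), lower charge rate means higher actual rate
  for (d in c(0.2, 0)) for (h in c(5, 25)) {
    g <- an[an$d == d & an$horizon == h, ]
    expect_gt(g$rate[g$r == 0.05], g$rate[g$r == 1])
  }
  # short-run rates rise with d (reoffending concentrates early),
  # long-run rates barely move
  g5 <- an[an$r == 1 & an$horizon == 5, ]
  expect_gt(g5$rate[g5$d == 0.2], g5$rate[g5$d == 0])
})

test_that("trajectory series decline under desistance and stay flat without", {
  tr <- trajectory_series(0.123, r_values = c(1, 0.05))
  expect_setequal(unique(tr$measure), c("prob", "odds", "lambda"))
  for (r in c(1, 0.05)) for (m in c("prob", "odds", "lambda")) {
    v <- tr$value[tr$r == r & tr$measure == m]
    expect_length(v, 25)
    expect_true(all(diff(v) < 0))
  }
  # odds decline geometrically at the retention factor for every offender,
  # hence for the population mean odds as well
  o <- tr$value[tr$r == 1 & tr$measure == "odds"]
  expect_equal(o[-1] / o[-25], rep(0.877, 24), tolerance = 1e-9)

  flat <- trajectory_series(0, r_values = 1)
  for (m in c("prob", "odds", "lambda")) {
    v <- flat$value[flat$measure == m]
    expect_equal(v, rep(v[1], 25), tolerance = 1e-12)
  }
  # year-1 population probability has the closed form mu / (1 + mu)
  mu1 <- attr(flat, "mu_values")[["1"]]
  expect_equal(flat$value[flat$measure == "prob" & flat$year == 1],
               mu1 / (1 + mu1), tolerance = 1e-9)
})

test_that("table outputs round-trip through CSV with a provenance sidecar", {
  t1 <- replicate_table1(n_iterations = 2000, seed = 5)
  path <- tempfile("table1-", fileext = ".csv")
  on.exit(unlink(c(path, sub("csv$", "json", path))), add = TRUE)
  write_with_sidecar(t1, path, list(seed = 5, n_iterations = 2000))
  back <- utils::read.csv(path)
  expect_equal(back$y25, t1$y25, tolerance = 1e-12)
  sidecar <- jsonlite::fromJSON(sub("csv$", "json", path))
  expect_identical(sidecar$seed, 5L)
})
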