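# a compact uncertain model: mini city with a dominant ERF uncertainty, a
# small emission-factor uncertainty and an unconnected dummy draw
importance_fixture <- function(n = 1000, seed = 11) {
  b <- generate_city("mini")
  b$decisions <- decision_table(
    decision = "Fuel_policy", option = "Clean", target = "emission_factors",
    selector = list(list(Pollutant = "PM2.5")), change = "multiply",
    value = 0.5)
  dists <- list(
    input_distribution("ERF", "lognormal", c(meanlog = 0, sdlog = 1),
                       target = "rr10", kind = "scale"),
    input_distribution("PM factor", "normal", c(mean = 1, sd = 0.05),
                       target = "emission_factors",
                       selector = list(Pollutant = "PM2.5"), kind = "scale",
                       lower = 0),
    input_distribution("dummy", "normal", c(mean = 0, sd = 1)))
  res <- suppressMessages(run_model(b, dists = dists, mode = "monte_carlo",
                                    n_iter = n, seed = seed))
  res
}

test_that("a single dominant input drives rank correlation above 0.99", {
  b <- generate_city("mini")
  dists <- list(input_distribution("PM factor", "normal",
                                   c(mean = 1, sd = 0.3),
                                   target = "emission_factors",
                                   selector = list(Pollutant = "PM2.5"),
                                   kind = "scale", lower = 0.01))
  res <- suppressMessages(run_model(b, dists = dists, mode = "monte_carlo",
                                    n_iter = 500, seed = 3))
  daly_tot <- it_aggregate(res$daly, "Iteration")
  imp <- importance(res$draws, daly_tot, mode = "absolute")
  expect_gt(imp$rho, 0.99)
})

test_that("an input independent of the outcome stays inside the null band", {
  res <- importance_fixture(n = 1000, seed = 11)
  imp <- importance(res$draws, res$value, mode = "absolute")
  dummy <- imp$rho[imp$variable == "dummy"]
  expect_true(all(dummy < 0.08))  # 95 % null bound ~ 1.96/sqrt(1000)
})

test_that("incremental mode is exactly zero at the BAU option", {
  res <- importance_fixture(n = 200, seed = 5)
  inc <- incremental_values(res$value)
  bau <- it_filter(inc, list(Fuel_policy = "BAU"))
  expect_true(all(bau$Result == 0))
  imp <- importance(res$draws, res$value, mode = "incremental")
  expect_true(all(is.na(imp$rho[imp$combination == "BAU"])))
  expect_false(anyNA(imp$rho[imp$combination != "BAU" &
                               imp$variable != "dummy"]))
})

test_that("the dominant ERF uncertainty ranks first in both modes", {
  res <- importance_fixture(n = 1000, seed = 11)
  imp <- rbind(importance(res$draws, res$value, mode = "absolute"),
               importance(res$draws, res$value, mode = "incremental"))
  rng <- importance_ranges(imp)
  for (md in c("absolute", "incremental")) {
    top <- rng$variable[rng$mode == md][1L]
    expect_equal(top, "ERF")
  }
  # and decisively so in absolute mode
  abs_rng <- rng[rng$mode == "absolute", ]
  expect_gt(abs_rng$rho_max[abs_rng$variable == "ERF"],
            max(abs_rng$rho_max[abs_rng$variable != "ERF"]))
})

test_that("correlation spread halves when the sample size quadruples", {
  # O(n^-1/2) convergence of the null correlation over repeated seeds
  b <- generate_city("mini")
  dists <- list(
    input_distribution("pm", "normal", c(mean = 1, sd = 0.2),
                       target = "emission_factors",
                       selector = list(Pollutant = "PM2.5"), kind = "scale",
                       lower = 0),
    input_distribution("dummy", "normal", c(mean = 0, sd = 1)))
  rho_null <- function(n, seed) {
    res <- suppressMessages(run_model(b, dists = dists,
                                      mode = "monte_carlo", n_iter = n,
                                      seed = seed))
    imp <- importance(res$draws, it_aggregate(res$daly, "Iteration"),
                      mode = "absolute")
    imp$rho[imp$variable == "dummy"]
  }
  seeds <- 1:20
  sp_small <- stats::sd(vapply(seeds, function(s) rho_null(50, s),
                               numeric(1)))
  sp_large <- stats::sd(vapply(seeds, function(s) rho_null(200, s),
                               numeric(1)))
  expect_lt(sp_large, sp_small)
  expect_equal(sp_small / sp_large, 2, tolerance = 0.6)
})

test_that("zero-variance inputs give NA, and mismatched iterations error", {
  res <- importance_fixture(n = 50, seed = 2)
  draws <- res$draws
  draws$flat <- indexed_table(data.frame(Iteration = 1:50, Result = 1),
                              unit = "", name = "flat")
  imp <- importance(draws, res$value, mode = "absolute")
  expect_true(all(is.na(imp$rho[imp$variable == "flat"])))
  short <- indexed_table(data.frame(Iteration = 1:10, Result = rnorm(10)),
                         unit = "", name = "short")
  expect_error(importance(list(short = short), res$value), "iteration")
})
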