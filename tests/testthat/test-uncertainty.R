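test_that("distribution medians and samples behave as declared", {
  dn <- input_distribution("x", "normal", c(mean = 100, sd = 10))
  expect_equal(dist_median(dn), 100)
  du <- input_distribution("u", "uniform", c(min = 2, max = 6))
  expect_equal(dist_median(du), 4)
  dp <- input_distribution("p", "point", c(value = 7))
  expect_equal(dist_median(dp), 7)
  expect_equal(dist_sample(dp, 5), rep(7, 5))
  dl <- input_distribution("l", "lognormal", c(meanlog = 0, sdlog = 1))
  expect_equal(dist_median(dl), 1)
  # triangular quantiles: median of a symmetric triangle is the mode
  dt <- input_distribution("t", "triangular", c(min = 0, mode = 5, max = 10))
  expect_equal(dist_median(dt), 5)
  set.seed(1)
  s <- dist_sample(dt, 5000)
  expect_true(all(s >= 0 & s <= 10))
  expect_equal(mean(s), 5, tolerance = 0.1)
  # truncation restricts support without reshaping the kept region
  dtr <- input_distribution("n", "normal", c(mean = 0, sd = 1),
                            lower = 0)
  set.seed(2)
  str_ <- dist_sample(dtr, 2000)
  expect_true(all(str_ >= 0))
  expect_error(input_distribution("b", "uniform", c(min = 5, max = 1)),
               "max < min")
  expect_error(input_distribution("b", "normal", c(mean = 1)), "sd")
})

test_that("sampling is deterministic under a fixed seed and CLT-consistent", {
  d <- input_distribution("x", "normal", c(mean = 100, sd = 10),
                          target = "tab", kind = "replace")
  tab <- list(tab = it_tab(Time = 2010, Result = 1))
  s1 <- sample_inputs(tab, list(d), n_iter = 10000, seed = 123)
  s2 <- sample_inputs(tab, list(d), n_iter = 10000, seed = 123)
  expect_identical(s1$draws$x$Result, s2$draws$x$Result)
  # sample mean within 3 standard errors of 100
  expect_lt(abs(mean(s1$draws$x$Result) - 100), 3 * 10 / sqrt(10000))
  # the targeted table gained an Iteration index with the draws
  expect_true("Iteration" %in% names(s1$inputs$tab))
  expect_equal(sort(s1$inputs$tab$Result), sort(s1$draws$x$Result))
})

test_that("scale draws multiply only selector-matched cells", {
  tab <- list(t = it_tab(Fuel = c("peat", "wood"), Result = c(10, 20)))
  d <- input_distribution("f", "uniform", c(min = 2, max = 2),
                          target = "t", selector = list(Fuel = "peat"),
                          kind = "scale")
  out <- sample_inputs(tab, list(d), n_iter = 3, seed = 1)$inputs$t
  expect_equal(sort(unique(out$Result[out$Fuel == "peat"])), 20)
  expect_equal(sort(unique(out$Result[out$Fuel == "wood"])), 20)
  expect_equal(nrow(out), 6L)
  # zero-match selectors error
  d2 <- input_distribution("f", "point", c(value = 2), target = "t",
                           selector = list(Fuel = "coal"))
  expect_error(sample_inputs(tab, list(d2), 2, 1), "matches no rows")
})

test_that("monetize combines CO2 and DALY at the nominal valuations", {
  expect_equal(monetize(0, 0), 0)
  expect_equal(monetize(1000, 2), 1000 * 15 + 2 * 50000)
  expect_equal(monetize(1000, 2), 115000)
  # linear in both arguments
  expect_equal(monetize(2000, 4), 2 * monetize(1000, 2))
  co2 <- it_tab(Time = c(2010, 2011), Result = c(100, 200), unit = "t/a")
  daly <- it_tab(Time = c(2010, 2011), Result = c(1, 2), unit = "DALY/a")
  v <- monetize(co2, daly)
  expect_equal(sort(v$Result), sort(c(100 * 15 + 50000, 200 * 15 + 1e5)))
  expect_equal(it_unit(v), "EUR/a")
})

test_that("point distributions make Monte Carlo reproduce the deterministic run", {
  b <- generate_city("mini")
  dists <- list(input_distribution("pm factor", "point", c(value = 1),
                                   target = "emission_factors",
                                   selector = list(Pollutant = "PM2.5"),
                                   kind = "scale"))
  det <- suppressMessages(run_model(b, dists = dists))
  mc <- suppressMessages(run_model(b, dists = dists, mode = "monte_carlo",
                                   n_iter = 4, seed = 9))
  daly_mc <- it_aggregate(mc$daly, "Time", how = "mean",
                          drop_iteration = TRUE)
  expect_tables_equal(det$daly, daly_mc, tol = 1e-12)
})

test_that("MC mean of a linear chain stays within 3 standard errors", {
  b <- generate_city("mini")
  sd_rel <- 0.2
  dists <- list(input_distribution("pm factor", "normal",
                                   c(mean = 1, sd = sd_rel),
                                   target = "emission_factors",
                                   selector = list(Pollutant = "PM2.5"),
                                   kind = "scale", lower = 0))
  n <- 10000
  det <- suppressMessages(run_model(b, dists = dists))
  mc <- suppressMessages(run_model(b, dists = dists, mode = "monte_carlo",
                                   n_iter = n, seed = 42))
  # emissions (exactly linear in the sampled factor): mean within 3 s.e.
  em_det <- it_filter(det$emissions, list(Pollutant = "PM2.5", Time = 2010))
  em_mc <- it_filter(mc$emissions, list(Pollutant = "PM2.5", Time = 2010))
  se <- sd_rel * em_det$Result / sqrt(n)
  expect_lt(abs(mean(em_mc$Result) - em_det$Result), 3 * se)
  # deterministic output approximates the MC median under a monotone chain
  expect_equal(stats::median(em_mc$Result), em_det$Result,
               tolerance = 3 * se / em_det$Result)
})

test_that("distributions may not target the renovation policy tables", {
  b <- generate_city("mini")
  d <- list(input_distribution("r", "normal", c(mean = 1, sd = 0.1),
                               target = "renovation_rate", kind = "scale"))
  expect_error(run_model(b, dists = d, mode = "monte_carlo", n_iter = 2,
                         seed = 1), "renovation")
  expect_error(run_model(b, dists = list(
    input_distribution("x", "normal", c(mean = 1, sd = 1), target = "demand")),
    mode = "monte_carlo"), "seed")
})
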