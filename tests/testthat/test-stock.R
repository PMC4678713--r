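test_that("eligibility respects age gate and renovation state", {
  # all built 2005: nothing older than 30 years at 2010
  s <- tiny_stock(area = 500, built = 2005)
  expect_equal(nrow(eligible_area(s, 2010, 30)), 0L)
  # mixed ages: only the 1960 cohort exceeds the gate (2010-1990 = 20 <= 30)
  s2 <- indexed_table(
    data.frame(Built = c(1960, 1990), Building = "residential",
               Heating = "district", Renovation = "none",
               Result = c(1000, 500)), unit = "m2")
  e <- eligible_area(s2, 2010, 30)
  expect_equal(sum(e$Result), 1000)
  # previously renovated cohorts are excluded
  s3 <- tiny_stock(area = 1000, built = 1960, renovation = "windows")
  expect_equal(nrow(eligible_area(s3, 2010, 30)), 0L)
})

test_that("renovation moves the policy rate of eligible area, conserving totals", {
  s <- tiny_stock(area = 1000, built = 1960)
  pol <- renovation_policy(0.03, 30, default_shares)
  out <- renovation_step(s, pol, t = 2010)
  expect_equal(sum(out$Result), 1000)
  moved <- sum(out$Result[out$Renovation != "none"])
  expect_equal(moved, 30)
  # depth split follows depth_shares
  expect_equal(it_filter(out, list(Renovation = "total_sheath"))$Result,
               30 * 0.2)
  # zero rate is the identity
  expect_equal(as.data.frame(renovation_step(s, renovation_policy(0, 30,
               default_shares), t = 2010)), as.data.frame(s))
  # 4.5 %/a of 200 m2 eligible into total sheath only
  s2 <- tiny_stock(area = 200, built = 1950)
  out2 <- renovation_step(s2, renovation_policy(0.045, 30,
                          c(total_sheath = 1)), t = 2010)
  expect_equal(it_filter(out2, list(Renovation = "total_sheath"))$Result, 9)
  expect_error(renovation_policy(1.2, 30, default_shares), "rate")
  expect_error(renovation_policy(0.03, 30, c(windows = 0.5)), "sum to 1")
})

test_that("area is conserved under renovation for randomized stocks", {
  set.seed(7)
  for (i in 1:100) {
    s <- random_stock()
    rate <- runif(1, 0, 0.2)
    pol <- renovation_policy(rate, sample(c(10, 30, 50), 1), default_shares)
    out <- renovation_step(s, pol, t = sample(2000:2050, 1))
    expect_equal(sum(out$Result), sum(s$Result), tolerance = 1e-12)
    expect_true(all(out$Result >= 0))
  }
})

test_that("evolution matches closed forms for construction and conservation", {
  s <- tiny_stock(area = 1000, built = 1960)
  pol0 <- renovation_policy(0, 30, default_shares)
  # zero construction, zero renovation: constant totals
  st <- evolve_stock(s, NULL, pol0, 2010:2020)
  tot <- tapply(st$Result, st$Time, sum)
  expect_true(all(abs(tot - 1000) < 1e-9))
  # constant construction c for T years: A0 + c*T
  plan <- construction_plan(
    data.frame(Time = 2011:2020, Building = "residential",
               Heating = "district", Result = 50))
  st2 <- evolve_stock(s, plan, pol0, 2010:2020)
  tot2 <- tapply(st2$Result, st2$Time, sum)
  expect_equal(as.numeric(tot2), 1000 + 50 * (0:10))
  # plan gaps are rejected
  bad <- construction_plan(
    data.frame(Time = c(2011, 2013), Building = "residential",
               Heating = "district", Result = 50))
  expect_error(evolve_stock(s, bad, pol0, 2010:2020), "gaps")
})

test_that("unrenovated fraction decays geometrically on a static stock", {
  s <- tiny_stock(area = 1e6, built = 1950)
  rate <- 0.03
  pol <- renovation_policy(rate, 30, default_shares)
  k <- 40
  st <- evolve_stock(s, NULL, pol, 2010:(2010 + k))
  df <- as.data.frame(st)
  for (kk in c(1, 10, 40)) {
    un <- sum(df$Result[df$Time == 2010 + kk & df$Renovation == "none"])
    expect_equal(un / 1e6, (1 - rate)^kk, tolerance = 1e-9)
  }
  # spec'd closed-form share after 40 years of 3 %/a
  expect_equal(renovated_share(st, 2050), 1 - 0.97^40, tolerance = 1e-9)
  expect_equal(renovated_share(st, 2050), 0.7, tolerance = 0.01)
})

test_that("renovated share is 0 for untouched old stock and 1 when complete", {
  s <- tiny_stock(area = 1000, built = 1960)
  st <- evolve_stock(s, NULL, renovation_policy(0, 30, default_shares),
                     2010:2012)
  expect_equal(renovated_share(st, 2012), 0)
  s1 <- tiny_stock(area = 1000, built = 1960, renovation = "total_sheath")
  st1 <- evolve_stock(s1, NULL, renovation_policy(0, 30, default_shares),
                      2010:2012)
  expect_equal(renovated_share(st1, 2012), 1)
})

test_that("higher renovation rate gives pointwise higher renovated share", {
  s <- tiny_stock(area = 1e5, built = 1950)
  shares_lo <- vapply(2011:2040, function(t)
    renovated_share(evolve_stock(s, NULL,
      renovation_policy(0.01, 30, default_shares), 2010:t), t), numeric(1))
  shares_hi <- vapply(2011:2040, function(t)
    renovated_share(evolve_stock(s, NULL,
      renovation_policy(0.03, 30, default_shares), 2010:t), t), numeric(1))
  expect_true(all(shares_hi >= shares_lo))
  expect_true(all(diff(shares_lo) >= -1e-12))  # non-decreasing in time
})
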