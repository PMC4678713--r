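base_demand <- function() {
  data.frame(Building = "residential", Built = 1960, Result = 150)
}

test_that("post-renovation demand subtracts savings with a floor", {
  spec <- demand_spec(base_demand(),
                      savings = c(windows = 30, total_sheath = 100))
  d <- post_renovation_demand(spec)
  expect_equal(it_filter(d, list(Renovation = "windows"))$Result, 120)
  expect_equal(it_filter(d, list(Renovation = "total_sheath"))$Result, 50)
  expect_equal(it_filter(d, list(Renovation = "none"))$Result, 150)
  # zero saving leaves demand unchanged
  d0 <- post_renovation_demand(demand_spec(base_demand(),
                                           savings = c(windows = 0)))
  expect_equal(it_filter(d0, list(Renovation = "windows"))$Result, 150)
  # saving > demand: floored, or an error without a floor
  spec2 <- demand_spec(base_demand(), savings = c(total_sheath = 140),
                       floor = 20)
  expect_equal(it_filter(post_renovation_demand(spec2),
                         list(Renovation = "total_sheath"))$Result, 20)
  spec3 <- demand_spec(base_demand(), savings = c(total_sheath = 160),
                       floor = NULL)
  expect_error(post_renovation_demand(spec3), "floor")
})

test_that("heat demand is area times specific demand in GWh", {
  st <- evolve_stock(tiny_stock(area = 1e6, built = 1960), NULL,
                     renovation_policy(0, 30, default_shares), 2010:2011)
  dem <- post_renovation_demand(demand_spec(base_demand(),
                                            savings = c(windows = 30)))
  h <- heat_demand(st, dem)
  expect_equal(it_unit(h), "GWh/a")
  expect_equal(it_filter(h, list(Time = 2010))$Result, 150)
  # two strata sum: 1e6 m2 @ 150 + 0.5e6 m2 @ 100 = 200 GWh
  s2 <- indexed_table(
    data.frame(Time = 2010, Built = c(1960, 1990), Building = "residential",
               Heating = "district", Renovation = "none",
               Result = c(1e6, 0.5e6)), unit = "m2")
  d2 <- indexed_table(
    data.frame(Building = "residential", Built = c(1960, 1990),
               Renovation = "none", Result = c(150, 100)), unit = "kWh/m2/a")
  expect_equal(heat_demand(s2, d2)$Result, 200)
  # linearity in floor area
  s3 <- it_apply(s2, function(v) 3 * v)
  expect_equal(heat_demand(s3, d2)$Result, 600)
  # uncovered stratum errors with the missing key
  d3 <- indexed_table(
    data.frame(Building = "residential", Built = 1960, Renovation = "none",
               Result = 150), unit = "kWh/m2/a")
  expect_error(heat_demand(s2, d3), "1990")
})

test_that("deeper renovation never increases demand given monotone savings", {
  spec <- demand_spec(
    expand.grid(Building = c("residential", "service"),
                Built = c(1950, 1970, 1990), stringsAsFactors = FALSE) |>
      transform(Result = c(220, 200, 190, 170, 150, 130)),
    savings = c(windows = 30, windows_sheath_tech = 65, total_sheath = 100))
  d <- as.data.frame(post_renovation_demand(spec))
  wide <- reshape(d, idvar = c("Building", "Built"), timevar = "Renovation",
                  direction = "wide")
  expect_true(all(wide$Result.windows <= wide$Result.none))
  expect_true(all(wide$Result.windows_sheath_tech <= wide$Result.windows))
  expect_true(all(wide$Result.total_sheath <=
                    wide$Result.windows_sheath_tech))
})

heat_100 <- function() {
  indexed_table(data.frame(Time = 2010, Heating = "district", Result = 100),
                unit = "GWh/a", name = "heat")
}

test_that("fuel use splits heat by mix shares and efficiency", {
  mix1 <- fuel_mix(data.frame(Heating = "district", Fuel = "peat",
                              Time = 2010, Result = 1))
  eff1 <- conversion_efficiency(data.frame(Heating = "district", Result = 1))
  f <- fuel_use(heat_100(), mix1, eff1)
  expect_equal(f$Result, 100000)
  expect_equal(it_unit(f), "MWh/a")
  # the cogeneration-plant mix: 84/12/4
  mix2 <- fuel_mix(data.frame(Heating = "district",
                              Fuel = c("peat", "oil", "biomass"),
                              Time = 2010, Result = c(0.84, 0.12, 0.04)))
  f2 <- as.data.frame(fuel_use(heat_100(), mix2, eff1))
  expect_equal(f2$Result[match(c("peat", "oil", "biomass"), f2$Fuel)],
               c(84000, 12000, 4000))
  # efficiency 1.1 raises fuel input 10 % above delivered heat
  eff2 <- conversion_efficiency(data.frame(Heating = "district",
                                           Result = 1.1))
  expect_equal(sum(fuel_use(heat_100(), mix2, eff2)$Result), 110000)
  # invalid shares rejected
  expect_error(fuel_mix(data.frame(Heating = "district",
                                   Fuel = c("peat", "oil"), Time = 2010,
                                   Result = c(0.8, 0.1))), "sum to 1")
})

test_that("emissions multiply fuel use by factors; biogenic wood is fossil-free", {
  fuel <- indexed_table(
    data.frame(Time = 2010, Heating = "district",
               Fuel = c("peat", "wood"), Result = c(100000, 10000)),
    unit = "MWh/a", name = "fuel")
  fac <- emission_factor_set(data.frame(
    Fuel = rep(c("peat", "wood"), each = 3),
    Pollutant = rep(c("CO2_fossil", "CO2_total", "PM2.5"), 2),
    Result = c(380, 380, 0.02, 0, 420, 0.03)))
  em <- as.data.frame(emissions_from_fuel(fuel, fac))
  get <- function(f, p) em$Result[em$Fuel == f & em$Pollutant == p]
  expect_equal(get("peat", "CO2_fossil"), 38000)
  expect_equal(get("wood", "CO2_fossil"), 0)
  expect_equal(get("wood", "CO2_total"), 4200)
  # fossil factor above total is rejected at construction
  expect_error(emission_factor_set(data.frame(
    Fuel = "x", Pollutant = c("CO2_fossil", "CO2_total"),
    Result = c(500, 400))), "exceeds")
  # missing factor errors
  fuel2 <- indexed_table(data.frame(Time = 2010, Heating = "district",
                                    Fuel = "coal", Result = 1),
                         unit = "MWh/a")
  expect_error(emissions_from_fuel(fuel2, fac), "coal")
})

test_that("emissions are linear in heat demand at fixed mix and factors", {
  mix <- fuel_mix(data.frame(Heating = "district",
                             Fuel = c("peat", "wood"), Time = 2010,
                             Result = c(0.6, 0.4)))
  eff <- conversion_efficiency(data.frame(Heating = "district", Result = 1.1))
  fac <- emission_factor_set(data.frame(
    Fuel = rep(c("peat", "wood"), each = 3),
    Pollutant = rep(c("CO2_fossil", "CO2_total", "PM2.5"), 2),
    Result = c(380, 380, 0.02, 0, 420, 0.03)))
  e1 <- emissions_from_fuel(fuel_use(heat_100(), mix, eff), fac)
  h3 <- it_apply(heat_100(), function(v) 3 * v)
  e3 <- emissions_from_fuel(fuel_use(h3, mix, eff), fac)
  expect_tables_equal(it_apply(e1, function(v) 3 * v), e3, tol = 1e-12)
  # CO2_fossil <= CO2_total rowwise
  df <- as.data.frame(e3)
  foss <- df[df$Pollutant == "CO2_fossil", ]
  tot <- df[df$Pollutant == "CO2_total", ]
  m <- merge(foss, tot, by = c("Time", "Heating", "Fuel"))
  expect_true(all(m$Result.x <= m$Result.y + 1e-12))
})

test_that("the peat-to-wood mix change cuts fossil CO2, total CO2 barely moves", {
  mix_bau <- fuel_mix(data.frame(
    Heating = "district", Fuel = c("peat", "heavy_oil", "wood"), Time = 2010,
    Result = c(0.84, 0.12, 0.04)))
  mix_pol <- fuel_mix(data.frame(
    Heating = "district", Fuel = c("peat", "heavy_oil", "wood"), Time = 2010,
    Result = c(0.49, 0.01, 0.50)))
  fac <- emission_factor_set(data.frame(
    Fuel = rep(c("peat", "heavy_oil", "wood"), each = 2),
    Pollutant = rep(c("CO2_fossil", "CO2_total"), 3),
    Result = c(380, 380, 280, 280, 0, 420)))
  d <- as.data.frame(fuel_policy_delta(mix_bau, mix_pol, heat_100(), fac))
  dfoss <- d$Result[d$Pollutant == "CO2_fossil"]
  dtot <- d$Result[d$Pollutant == "CO2_total"]
  expect_lt(dfoss, 0)
  # hand mix arithmetic: per-MWh factors 352.8 -> 189 (fossil), 369.6 -> 399
  expect_equal(dfoss, (189 - 352.8) * 100000 / 1000, tolerance = 1e-9)
  expect_equal(dtot, (399 - 369.6) * 100000 / 1000, tolerance = 1e-9)
  # identical mixes give zero delta
  d0 <- fuel_policy_delta(mix_bau, mix_bau, heat_100(), fac)
  expect_true(all(abs(d0$Result) < 1e-9))
})

test_that("mix interpolation is linear between anchors and constant outside", {
  mix <- fuel_mix(data.frame(
    Heating = "district", Fuel = rep(c("peat", "wood"), each = 2),
    Time = rep(c(2010, 2020), 2), Result = c(0.8, 0.4, 0.2, 0.6)))
  m <- as.data.frame(mix_at_years(mix, c(2005, 2015, 2025)))
  peat <- m$Result[m$Fuel == "peat"][order(m$Time[m$Fuel == "peat"])]
  expect_equal(peat, c(0.8, 0.6, 0.4))
  wood <- m$Result[m$Fuel == "wood"][order(m$Time[m$Fuel == "wood"])]
  expect_equal(peat + wood, c(1, 1, 1))
})
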