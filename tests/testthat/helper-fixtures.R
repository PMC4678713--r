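# Small fixtures built in code, shared across test files.

it_tab <- function(..., unit = "u", name = "t") {
  indexed_table(data.frame(...), unit = unit, name = name)
}

# single-stratum stock: one era, one type, one heating system
tiny_stock <- function(area = 1000, built = 1960, heating = "district",
                       building = "residential", renovation = "none") {
  indexed_table(
    data.frame(Built = built, Building = building, Heating = heating,
               Renovation = renovation, Result = area),
    unit = "m2", name = "stock_initial")
}

# a random multi-stratum single-year stock for property tests
random_stock <- function(n_era = 3, n_heat = 2) {
  eras <- sample(seq(1920, 2000, 10), n_era)
  g <- expand.grid(Built = eras, Building = c("residential", "service"),
                   Heating = paste0("h", seq_len(n_heat)),
                   Renovation = "none", stringsAsFactors = FALSE)
  g$Result <- stats::runif(nrow(g), 0, 1e5)
  indexed_table(g, unit = "m2", name = "stock_initial")
}

default_shares <- c(windows = 0.4, windows_sheath_tech = 0.4,
                    total_sheath = 0.2)

tiny_hp <- function(...) {
  args <- utils::modifyList(
    list(population = 1e5, mortality = 0.01, breathing_rate = 13,
         intake_fraction = c(district = 1e-5), rr10 = 1.062,
         yll_per_death = 10),
    list(...))
  do.call(health_parameters, args)
}

expect_tables_equal <- function(a, b, tol = 1e-12) {
  idx <- index_names(a)
  expect_setequal(idx, index_names(b))
  da <- as.data.frame(a)
  db <- as.data.frame(b)
  da <- da[do.call(order, da[idx]), , drop = FALSE]
  db <- db[do.call(order, db[c(idx)]), , drop = FALSE]
  expect_equal(nrow(da), nrow(db))
  for (cl in idx) expect_equal(as.character(da[[cl]]), as.character(db[[cl]]))
  expect_equal(da$Result, db$Result, tolerance = tol)
}
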