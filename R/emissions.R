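#' Fuel mix of heating-energy production
#'
#' Shares of fuel input per heating type, with `Time` anchor years between
#' which shares are interpolated linearly (constant outside the anchor range).
#' Shares must sum to 1 within each (`Heating`, `Time`) group — and within
#' each scenario slice once decisions are applied.
#'
#' @param df data frame with `Heating`, `Fuel`, `Time`, `Result` (share).
#' @return Indexed table of class `itable` (dimensionless shares).
#' @export
fuel_mix <- function(df) {
  tab <- indexed_table(df, unit = "fraction", name = "fuel_mix")
  need <- c("Heating", "Fuel", "Time")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("fuel mix lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  check_mix_shares(tab)
  tab
}

check_mix_shares <- function(tab) {
  df <- as.data.frame(tab)
  grp <- c("Heating", "Time", intersect(c(scenario_index_of(tab), "Iteration"),
                                        names(df)))
  key <- do.call(paste, c(df[grp], sep = "\r"))
  s <- tapply(df$Result, key, sum)
  bad <- names(s)[abs(s - 1) > 1e-9]
  if (length(bad)) {
    stop("fuel-mix shares do not sum to 1 for (",
         paste(grp, collapse = ", "), ") = (", gsub("\r", ", ", bad[1L]),
         "): sum = ", format(s[bad[1L]]), call. = FALSE)
  }
  invisible(tab)
}

#' Interpolate fuel-mix anchors to a set of years
#'
#' Linear interpolation of each (`Heating`, `Fuel`) share between its `Time`
#' anchors, constant before the first and after the last anchor. Shares are
#' re-validated after interpolation (linear interpolation preserves the
#' sum-to-one constraint).
#'
#' @param mix a [fuel_mix()] table (possibly carrying decision indices).
#' @param years integer vector of target years.
#' @return Fuel-mix table with `Time` running over `years`.
#' @export
mix_at_years <- function(mix, years) {
  stopifnot(is_indexed_table(mix))
  df <- as.data.frame(mix)
  grp <- setdiff(names(df), c("Time", "Result"))
  key <- do.call(paste, c(df[grp], sep = "\r"))
  out <- do.call(rbind, lapply(split(df, key), function(g) {
    g <- g[order(g$Time), , drop = FALSE]
    v <- if (nrow(g) == 1L) rep(g$Result, length(years)) else
      stats::approx(g$Time, g$Result, xout = years, rule = 2)$y
    r <- g[rep(1L, length(years)), grp, drop = FALSE]
    r$Time <- years
    r$Result <- v
    r
  }))
  tab <- it_new(out, unit = it_unit(mix), name = it_name(mix),
                decisions = attr(mix, "decisions"))
  check_mix_shares(tab)
  tab
}

#' Emission factors per fuel and pollutant
#'
#' Factors in kg emitted per MWh of fuel input, for the pollutants
#' `CO2_fossil` (regulated "official" CO2: peat counts as fossil, wood as
#' zero), `CO2_total` (including biogenic stack CO2) and `PM2.5`. For every
#' fuel the fossil factor may not exceed the total factor.
#'
#' @param df data frame with `Fuel`, `Pollutant`, `Result` (kg/MWh).
#' @return Indexed table of class `itable`.
#' @export
emission_factor_set <- function(df) {
  tab <- indexed_table(df, unit = "kg/MWh", name = "emission_factors")
  miss <- setdiff(c("Fuel", "Pollutant"), names(tab))
  if (length(miss)) stop("emission factors lack column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(tab$Result < 0)) stop("emission factors must be >= 0", call. = FALSE)
  d <- as.data.frame(tab)
  foss <- d[d$Pollutant == "CO2_fossil", c("Fuel", "Result")]
  tot <- d[d$Pollutant == "CO2_total", c("Fuel", "Result")]
  m <- merge(foss, tot, by = "Fuel", suffixes = c(".foss", ".tot"))
  bad <- m$Fuel[m$Result.foss > m$Result.tot + 1e-9]
  if (length(bad)) {
    stop("CO2_fossil exceeds CO2_total for fuel(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Fuel-to-heat conversion efficiency
#'
#' MWh of fuel input required per MWh of heat delivered, per heating type
#' (>= 1 for ordinary boilers and network losses; for the cogeneration plant
#' it is the heat-allocation factor). All combustion emissions of district
#' heat production are attributed to delivered heat; compensating electricity
#' bought from outside the city is out of the system boundary.
#'
#' @param df data frame with `Heating`, `Result` (MWh fuel / MWh heat, > 0).
#' @return Indexed table of class `itable`.
#' @export
conversion_efficiency <- function(df) {
  tab <- indexed_table(df, unit = "MWh/MWh", name = "efficiency")
  if (!"Heating" %in% names(tab)) stop("efficiency needs a Heating index",
                                       call. = FALSE)
  if (any(tab$Result <= 0)) stop("efficiency must be > 0", call. = FALSE)
  tab
}

#' Fuel use by heating type and fuel
#'
#' `fuel MWh/a = heat GWh/a × 1000 × efficiency × share`.
#'
#' @param heat heat-demand table (GWh/a) by (`Time`, `Heating`).
#' @param mix fuel-mix table whose `Time` values cover the heat years (use
#'   [mix_at_years()] to interpolate anchors first).
#' @param eff a [conversion_efficiency()] table.
#' @return Indexed table of fuel input in MWh/a by (`Time`, `Heating`,
#'   `Fuel`) plus any scenario / `Iteration` indices.
#' @export
fuel_use <- function(heat, mix, eff) {
  stopifnot(is_indexed_table(heat), is_indexed_table(mix),
            is_indexed_table(eff))
  missing_h <- setdiff(unique(heat$Heating), unique(mix$Heating))
  if (length(missing_h)) {
    stop("fuel mix does not cover heating type(s): ",
         paste(missing_h, collapse = ", "), call. = FALSE)
  }
  missing_e <- setdiff(unique(heat$Heating), unique(eff$Heating))
  if (length(missing_e)) {
    stop("efficiency does not cover heating type(s): ",
         paste(missing_e, collapse = ", "), call. = FALSE)
  }
  check_mix_shares(mix)
  out <- it_binary(it_binary(it_apply(heat, function(v) v * 1000,
                                      unit = "MWh/a"), eff, "*"), mix, "*")
  it_new(as.data.frame(out), unit = "MWh/a", name = "fuel_use",
         decisions = attr(out, "decisions"))
}

#' Emissions from fuel use
#'
#' `tonnes/a = MWh/a × kg/MWh / 1000`, per (`Time`, `Heating`, `Fuel`,
#' `Pollutant`).
#'
#' @param fuel fuel-use table (MWh/a) with a `Fuel` index.
#' @param factors an [emission_factor_set()].
#' @return Indexed table of emissions in t/a.
#' @export
emissions_from_fuel <- function(fuel, factors) {
  stopifnot(is_indexed_table(fuel), is_indexed_table(factors))
  missing_f <- setdiff(unique(fuel$Fuel), unique(factors$Fuel))
  if (length(missing_f)) {
    stop("emission factors missing for fuel(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  out <- it_binary(fuel, factors, "*")
  out <- it_apply(out, function(v) v / 1000, unit = "t/a")
  it_new(as.data.frame(out), unit = "t/a", name = "emissions",
         decisions = attr(out, "decisions"))
}

#' Emission change of a fuel-mix policy
#'
#' Difference in annual emissions, policy minus business-as-usual, for the
#' same heat demand, conversion efficiency and emission factors.
#'
#' @param mix_bau,mix_policy fuel-mix tables (validated, same coverage).
#' @param heat heat-demand table (GWh/a).
#' @param factors an [emission_factor_set()].
#' @param eff a [conversion_efficiency()] table; defaults to 1 for all heating
#'   types in `heat`.
#' @return Indexed table of emission differences (t/a) by (`Time`,
#'   `Pollutant`); negative values are reductions.
#' @export
fuel_policy_delta <- function(mix_bau, mix_policy, heat, factors, eff = NULL) {
  if (is.null(eff)) {
    eff <- conversion_efficiency(data.frame(Heating = unique(heat$Heating),
                                            Result = 1))
  }
  years <- unique(heat$Time)
  e_bau <- emissions_from_fuel(fuel_use(heat, mix_at_years(mix_bau, years),
                                        eff), factors)
  e_pol <- emissions_from_fuel(fuel_use(heat, mix_at_years(mix_policy, years),
                                        eff), factors)
  keep <- intersect(c("Time", "Pollutant"), names(e_bau))
  d <- it_binary(agg_keep_iter(e_pol, keep), agg_keep_iter(e_bau, keep), "-")
  it_new(as.data.frame(d), unit = "t/a", name = "emission_delta",
         decisions = attr(d, "decisions"))
}
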