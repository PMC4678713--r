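#' Population and health-impact parameters
#'
#' Parameters of the intake-fraction exposure model and the mortality
#' exposure-response chain. The intake fraction (iF) is the fraction of
#' emitted pollutant mass eventually inhaled by the exposed population; it is
#' keyed by emission-source archetype — here the heating type, distinguishing
#' high-stack plants (district heat) from ground-level residential sources —
#' following the intake-fraction framework commonly used for PM2.5.
#'
#' @param population exposed population (persons, > 0).
#' @param mortality background mortality rate (deaths/person/year, > 0).
#' @param breathing_rate nominal breathing rate (m³/person/day, > 0;
#'   default 13).
#' @param intake_fraction named numeric vector of intake fractions per heating
#'   type (dimensionless, each in (0, 1)), or a single unnamed value applied
#'   to all sources.
#' @param rr10 relative risk of all-cause mortality per 10 µg/m³ of long-term
#'   PM2.5 (>= 1).
#' @param c0 counterfactual concentration (µg/m³, default 0: the impact of the
#'   marginal source).
#' @param yll_per_death years of life lost per premature death (> 0); the YLD
#'   component of the DALY is zero by design, so DALY = deaths × YLL.
#' @param erf_form `"loglinear"` (default) or `"linear"` exposure-response
#'   shape; the linear form is provided for cross-checks.
#' @return A `health_parameters` list.
#' @export
health_parameters <- function(population, mortality, breathing_rate = 13,
                              intake_fraction, rr10, c0 = 0, yll_per_death,
                              erf_form = c("loglinear", "linear")) {
  erf_form <- match.arg(erf_form)
  if (population <= 0) stop("population must be > 0", call. = FALSE)
  if (mortality <= 0) stop("mortality must be > 0", call. = FALSE)
  if (breathing_rate <= 0) stop("breathing_rate must be > 0", call. = FALSE)
  if (any(intake_fraction <= 0) || any(intake_fraction >= 1)) {
    stop("intake fractions must lie in (0, 1)", call. = FALSE)
  }
  if (rr10 < 1) stop("rr10 must be >= 1", call. = FALSE)
  if (yll_per_death <= 0) stop("yll_per_death must be > 0", call. = FALSE)
  structure(list(population = population, mortality = mortality,
                 breathing_rate = breathing_rate,
                 intake_fraction = intake_fraction, rr10 = rr10, c0 = c0,
                 yll_per_death = yll_per_death, erf_form = erf_form),
            class = "health_parameters")
}

#' Population-average exposure from annual emissions
#'
#' Converts an annual emission to the population-average outdoor
#' concentration increment via the intake fraction:
#' `dC = E × iF / (P × BR × 365.25)` with `E` in µg/a (t/a × 1e12) and the
#' denominator the population's annual breathed volume in m³.
#'
#' @param emission annual emission, t/a (vectorized).
#' @param hp a [health_parameters()] object.
#' @param intake_fraction optional override of the intake fraction (single
#'   value); by default the first (or only) entry of `hp$intake_fraction`.
#' @return Concentration increment in µg/m³.
#' @export
exposure_concentration <- function(emission, hp, intake_fraction = NULL) {
  stopifnot(inherits(hp, "health_parameters"))
  if (any(emission < 0)) stop("emission must be >= 0", call. = FALSE)
  iF <- if (is.null(intake_fraction)) unname(hp$intake_fraction[1L]) else
    intake_fraction
  emission * 1e12 * iF / (hp$population * hp$breathing_rate * 365.25)
}

#' Relative risk at a concentration increment
#'
#' Log-linear form `RR = exp(log(rr10) × (dC − c0) / 10)`; linear form
#' `RR = 1 + (rr10 − 1) × (dC − c0) / 10` (both floored at 1 below the
#' counterfactual).
#'
#' @param delta_c concentration increment, µg/m³ (vectorized).
#' @param hp a [health_parameters()] object.
#' @return Relative risk (>= 1).
#' @export
relative_risk <- function(delta_c, hp) {
  stopifnot(inherits(hp, "health_parameters"))
  if (any(delta_c < 0)) stop("delta_c must be >= 0", call. = FALSE)
  x <- pmax(delta_c - hp$c0, 0) / 10
  if (hp$erf_form == "loglinear") exp(log(hp$rr10) * x) else
    1 + (hp$rr10 - 1) * x
}

#' Attributable premature deaths per year
#'
#' Population attributable fraction form:
#' `deaths = P × M × (RR − 1) / RR`.
#'
#' @param rr relative risk (>= 1, vectorized).
#' @param hp a [health_parameters()] object.
#' @return Premature deaths per year.
#' @export
attributable_deaths <- function(rr, hp) {
  stopifnot(inherits(hp, "health_parameters"))
  if (any(rr < 1)) stop("rr must be >= 1", call. = FALSE)
  hp$population * hp$mortality * (rr - 1) / rr
}

#' Disease burden of premature mortality
#'
#' `DALY/a = deaths/a × YLL per death`; the years-lived-with-disability
#' component is zero by design (mortality is the only endpoint).
#'
#' @param deaths premature deaths per year (vectorized).
#' @param hp a [health_parameters()] object.
#' @return DALY per year.
#' @export
burden_daly <- function(deaths, hp) {
  stopifnot(inherits(hp, "health_parameters"))
  if (any(deaths < 0)) stop("deaths must be >= 0", call. = FALSE)
  deaths * hp$yll_per_death
}

#' Full exposure-to-burden chain on an emission table
#'
#' Converts a PM2.5 emission table (t/a by `Time` and `Heating`, plus any
#' scenario / `Iteration` indices) into population exposure, attributable
#' deaths and DALYs. Per-source concentration increments (intake fraction by
#' heating type) are summed before the exposure-response step, since
#' concentrations add. Uncertain parameters may be passed as indexed tables
#' carrying an `Iteration` index via `overrides`.
#'
#' @param pm PM2.5 emission table in t/a with at least a `Time` index; a
#'   `Heating` index selects per-source intake fractions.
#' @param hp a [health_parameters()] object.
#' @param overrides optional named list of indexed tables (or scalars)
#'   overriding `rr10`, `intake_fraction` or `mortality` — used by the
#'   Monte-Carlo engine to inject sampled parameter values.
#' @return A list of indexed tables: `delta_c` (µg/m³), `deaths` (1/a),
#'   `daly` (DALY/a), all by `Time` plus scenario / `Iteration` indices.
#' @export
health_burden <- function(pm, hp, overrides = list()) {
  stopifnot(is_indexed_table(pm), inherits(hp, "health_parameters"))
  ov <- function(nm, default) {
    v <- overrides[[nm]]
    if (is.null(v)) default else v
  }
  # intake fraction per source (Heating archetype)
  if (!is.null(overrides$intake_fraction)) {
    if_tab <- as_itable(overrides$intake_fraction, unit = "", name = "iF")
  } else if ("Heating" %in% names(pm) && !is.null(names(hp$intake_fraction))) {
    miss <- setdiff(unique(pm$Heating), names(hp$intake_fraction))
    if (length(miss)) {
      stop("no intake fraction for heating type(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    if_tab <- indexed_table(
      data.frame(Heating = names(hp$intake_fraction),
                 Result = unname(hp$intake_fraction)),
      unit = "", name = "iF")
  } else {
    if_tab <- as_itable(unname(hp$intake_fraction[1L]), name = "iF")
  }
  denom <- hp$population * hp$breathing_rate * 365.25
  dc_src <- it_apply(it_binary(pm, if_tab, "*"),
                     function(v) v * 1e12 / denom, unit = "ug/m3")
  dc <- agg_keep_iter(dc_src, keep = intersect("Time", names(dc_src)))
  dc <- it_new(as.data.frame(dc), unit = "ug/m3", name = "delta_c",
               decisions = attr(dc, "decisions"))
  rr10_t <- as_itable(ov("rr10", hp$rr10), name = "rr10")
  x <- it_apply(dc, function(v) pmax(v - hp$c0, 0) / 10, unit = "")
  rr <- if (hp$erf_form == "loglinear") {
    it_apply(it_binary(x, it_apply(rr10_t, log), "*"), exp, unit = "")
  } else {
    it_apply(it_binary(x, it_binary(rr10_t, 1, "-"), "*"),
             function(v) 1 + v, unit = "")
  }
  paf <- it_apply(rr, function(v) (v - 1) / v, unit = "")
  mort <- as_itable(ov("mortality", hp$mortality), name = "mortality")
  deaths <- it_binary(it_binary(paf, mort, "*"), hp$population, "*")
  deaths <- it_new(as.data.frame(deaths), unit = "1/a", name = "deaths",
                   decisions = attr(deaths, "decisions"))
  daly <- it_apply(deaths, function(v) v * hp$yll_per_death, unit = "DALY/a")
  daly <- it_new(as.data.frame(daly), unit = "DALY/a", name = "daly",
                 decisions = attr(daly, "decisions"))
  list(delta_c = dc, deaths = deaths, daly = daly)
}
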