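#' Validate a model input bundle
#'
#' A bundle is a named list holding every input of the full chain:
#' `stock_initial`, `construction`, `renovation_rate`, `renovation_shares`,
#' `demand`, `fuel_mix`, `efficiency`, `emission_factors` (indexed tables),
#' `health` ([health_parameters()]), `weights` (monetization), `horizon`
#' (integer years), `age_threshold`, and optionally `rate_base` and
#' `decisions` / `dists`. Cross-table consistency (demand covering all stock
#' strata, factors covering all fuels, mixes summing to one) is checked here
#' so a broken bundle fails before any computation.
#'
#' @param bundle named list as above.
#' @return The bundle, invisibly, if valid; otherwise an error.
#' @export
validate_bundle <- function(bundle) {
  need <- c("stock_initial", "construction", "renovation_rate",
            "renovation_shares", "demand", "fuel_mix", "efficiency",
            "emission_factors", "health", "weights", "horizon")
  miss <- setdiff(need, names(bundle))
  if (length(miss)) stop("bundle lacks element(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  for (nm in c("stock_initial", "renovation_rate", "renovation_shares",
               "demand", "fuel_mix", "efficiency", "emission_factors")) {
    if (!is_indexed_table(bundle[[nm]])) {
      stop("bundle element '", nm, "' is not an indexed table", call. = FALSE)
    }
  }
  if (!is.null(bundle$construction) && !is_indexed_table(bundle$construction)) {
    stop("bundle element 'construction' is not an indexed table",
         call. = FALSE)
  }
  if (!inherits(bundle$health, "health_parameters")) {
    stop("bundle element 'health' must be health_parameters()", call. = FALSE)
  }
  if (any(bundle$stock_initial$Result < 0)) {
    stop("negative floor area in stock_initial", call. = FALSE)
  }
  if (abs(sum(bundle$renovation_shares$Result) - 1) > 1e-9) {
    stop("renovation_shares must sum to 1", call. = FALSE)
  }
  check_mix_shares(bundle$fuel_mix)
  # demand must cover every stratum of the initial stock
  shared <- intersect(index_names(bundle$stock_initial),
                      index_names(bundle$demand))
  ks <- unique(do.call(paste, c(as.data.frame(bundle$stock_initial)[shared],
                                sep = "\r")))
  kd <- unique(do.call(paste, c(as.data.frame(bundle$demand)[shared],
                                sep = "\r")))
  if (length(setdiff(ks, kd))) {
    stop("demand does not cover all initial stock strata", call. = FALSE)
  }
  heats <- unique(bundle$stock_initial$Heating)
  if (length(setdiff(heats, unique(bundle$fuel_mix$Heating)))) {
    stop("fuel_mix does not cover all heating types", call. = FALSE)
  }
  if (length(setdiff(heats, unique(bundle$efficiency$Heating)))) {
    stop("efficiency does not cover all heating types", call. = FALSE)
  }
  fuels <- unique(bundle$fuel_mix$Fuel)
  if (length(setdiff(fuels, unique(bundle$emission_factors$Fuel)))) {
    stop("emission_factors do not cover all fuels", call. = FALSE)
  }
  invisible(bundle)
}

bundle_table_names <- c("stock_initial", "construction", "renovation_rate",
                        "renovation_shares", "demand", "fuel_mix",
                        "efficiency", "emission_factors")

# scenario combinations present in the renovation policy tables; these two
# enter the annual stock recursion through scalars, so their decision levels
# are expanded by an explicit loop rather than through table joins
renovation_scenarios <- function(rate_tab, shares_tab) {
  dcols <- union(scenario_index_of(rate_tab), scenario_index_of(shares_tab))
  if (!length(dcols)) return(data.frame(row.names = 1L))
  levs <- lapply(dcols, function(d) {
    unique(c(if (d %in% names(rate_tab)) unique(rate_tab[[d]]),
             if (d %in% names(shares_tab)) unique(shares_tab[[d]])))
  })
  names(levs) <- dcols
  expand.grid(levs, stringsAsFactors = FALSE)
}

slice_scalar <- function(tab, combo, what) {
  sel <- as.list(combo[intersect(names(combo), names(tab))])
  s <- if (length(sel)) it_filter(tab, sel) else tab
  if (nrow(s) != 1L) {
    stop(what, " must reduce to a single value per scenario (got ", nrow(s),
         " rows)", call. = FALSE)
  }
  s$Result
}

slice_shares <- function(tab, combo) {
  sel <- as.list(combo[intersect(names(combo), names(tab))])
  s <- if (length(sel)) it_filter(tab, sel) else tab
  stats::setNames(s$Result, s$Renovation)
}

#' Run the full building-stock impact model
#'
#' Executes the chain stock dynamics -> heat demand -> fuel use -> emissions
#' -> exposure -> premature deaths / DALY, expanding externally declared
#' policies into scenario indices and optionally propagating input
#' uncertainty by Monte Carlo. In `"deterministic"` mode every declared
#' distribution is collapsed to its median and the model runs once; in
#' `"monte_carlo"` mode sampled inputs carry an `Iteration` index that flows
#' through every table operation into the outputs.
#'
#' Distributions may not target `renovation_rate` or `renovation_shares`:
#' those enter the annual stock recursion nonlinearly and are policy levers
#' rather than sampled quantities here.
#'
#' @param bundle input bundle, see [validate_bundle()].
#' @param decisions a [decision_table()] or `NULL`; defaults to
#'   `bundle$decisions`.
#' @param dists list of [input_distribution()]; defaults to `bundle$dists`.
#' @param mode `"deterministic"` or `"monte_carlo"`.
#' @param n_iter Monte-Carlo iterations (default 1000, the conventional run
#'   size for the importance analysis).
#' @param seed integer seed, mandatory in Monte-Carlo mode.
#' @return List with indexed tables `stock` (m²), `heat` (GWh/a), `fuel`
#'   (MWh/a), `emissions` (t/a), `delta_c` (µg/m³), `deaths` (1/a), `daly`
#'   (DALY/a), `co2_fossil` and `co2_total` (t/a by Time), `value` (€/a,
#'   summed over the horizon), plus `draws`, `medians`, `mode` and `seed`.
#' @export
run_model <- function(bundle, decisions = NULL, dists = NULL,
                      mode = c("deterministic", "monte_carlo"),
                      n_iter = 1000, seed = NULL) {
  mode <- match.arg(mode)
  validate_bundle(bundle)
  if (is.null(decisions)) decisions <- bundle$decisions
  if (is.null(dists)) dists <- bundle$dists
  dists <- dists %||% list()
  hp <- bundle$health
  tables <- bundle[intersect(bundle_table_names, names(bundle))]
  tables <- apply_decisions(tables, decisions)

  overrides <- list()
  draws <- list()
  medians <- numeric()
  if (length(dists)) {
    bad <- vapply(dists, function(d)
      !is.null(d$target) &&
        d$target %in% c("renovation_rate", "renovation_shares"), logical(1L))
    if (any(bad)) {
      stop("distributions may not target the renovation policy tables ",
           "(nonlinear in the stock recursion); vary them as decisions",
           call. = FALSE)
    }
  }
  if (mode == "deterministic") {
    ap <- apply_medians(tables, dists)
    tables <- ap$inputs
    medians <- ap$medians
    for (d in dists) {
      if (!is.null(d$target) && d$target %in% health_param_targets) {
        m <- medians[d$name]
        hp[[d$target]] <- if (d$kind != "scale") {
          m * (hp[[d$target]]^0)  # keep archetype names for intake_fraction
        } else if (d$target == "rr10") {
          # for the ERF, "scale" multiplies the log-linear slope, keeping the
          # relative risk on the >= 1 branch for any positive draw
          hp$rr10^m
        } else {
          hp[[d$target]] * m
        }
      }
    }
  } else {
    if (is.null(seed)) stop("seed is mandatory in monte_carlo mode",
                            call. = FALSE)
    sm <- sample_inputs(tables, dists, n_iter = n_iter, seed = seed)
    tables <- sm$inputs
    draws <- sm$draws
    for (d in dists) {
      if (is.null(d$target) || !d$target %in% health_param_targets) next
      dt <- draws[[d$name]]
      if (d$target == "intake_fraction") {
        base <- if (!is.null(names(hp$intake_fraction))) {
          indexed_table(data.frame(Heating = names(hp$intake_fraction),
                                   Result = unname(hp$intake_fraction)),
                        unit = "", name = "iF")
        } else as_itable(unname(hp$intake_fraction[1L]), name = "iF")
        overrides$intake_fraction <- if (d$kind == "scale")
          it_binary(base, dt, "*") else dt
      } else if (d$target == "rr10") {
        overrides$rr10 <- if (d$kind == "scale")
          it_apply(dt, function(v) hp$rr10^v) else dt
      } else {
        overrides[[d$target]] <- if (d$kind == "scale")
          it_apply(dt, function(v) v * hp[[d$target]]) else dt
      }
    }
  }

  horizon <- as.integer(bundle$horizon)
  age_thr <- bundle$age_threshold %||% 30
  rate_base <- bundle$rate_base %||% "unrenovated"
  combos <- renovation_scenarios(tables$renovation_rate,
                                 tables$renovation_shares)
  evolve_one <- function(combo) {
    rate <- slice_scalar(tables$renovation_rate, combo, "renovation_rate")
    shares <- slice_shares(tables$renovation_shares, combo)
    pol <- renovation_policy(rate, age_threshold = age_thr,
                             depth_shares = shares, rate_base = rate_base)
    evolve_stock(tables$stock_initial, tables$construction, pol, horizon)
  }
  if (nrow(combos) == 0L || ncol(combos) == 0L) {
    stock <- evolve_one(combos[1L, , drop = FALSE])
  } else {
    parts <- lapply(seq_len(nrow(combos)), function(i) {
      st <- evolve_one(combos[i, , drop = FALSE])
      df <- as.data.frame(st)
      for (d in names(combos)) df[[d]] <- combos[[d]][i]
      df
    })
    dec_all <- union(names(combos),
                     attr(tables$stock_initial, "decisions") %||% character())
    stock <- it_new(do.call(rbind, parts), unit = "m2", name = "stock",
                    decisions = union(dec_all,
                                      attr(tables$construction, "decisions")
                                      %||% character()))
  }

  heat <- heat_demand(stock, tables$demand)
  mix <- mix_at_years(tables$fuel_mix, horizon)
  fuel <- fuel_use(heat, mix, tables$efficiency)
  em <- emissions_from_fuel(fuel, tables$emission_factors)

  pm <- it_filter(em, list(Pollutant = "PM2.5"), drop = TRUE)
  pm <- agg_keep_iter(pm, keep = intersect(c("Time", "Heating"), names(pm)))
  burden <- health_burden(pm, hp, overrides = overrides)

  co2f <- agg_keep_iter(it_filter(em, list(Pollutant = "CO2_fossil"),
                                  drop = TRUE), keep = "Time")
  co2t <- agg_keep_iter(it_filter(em, list(Pollutant = "CO2_total"),
                                  drop = TRUE), keep = "Time")
  co2_sum <- agg_keep_iter(co2f)
  daly_sum <- agg_keep_iter(burden$daly)
  value <- monetize(co2_sum, daly_sum, bundle$weights)

  list(stock = stock, heat = heat, fuel = fuel, emissions = em,
       delta_c = burden$delta_c, deaths = burden$deaths, daly = burden$daly,
       co2_fossil = co2f, co2_total = co2t, value = value, draws = draws,
       medians = medians, mode = mode, seed = seed,
       n_iter = if (mode == "monte_carlo") n_iter else 1L)
}
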