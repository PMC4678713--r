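#' Specific heating-energy demand specification
#'
#' Couples the unrenovated specific demand (kWh/m²/a by building type and
#' construction era) with per-depth renovation savings. Renovation reduces the
#' specific demand by the depth's saving, floored at a configurable minimum so
#' deep renovation of an already efficient building cannot produce a negative
#' demand.
#'
#' @param base data frame or indexed table with indices `Building`, `Built`
#'   and a `Result` column of unrenovated specific demand (kWh/m²/a, > 0).
#' @param savings named numeric vector of savings (kWh/m²/a, >= 0) per
#'   renovation depth, e.g. `c(windows = 30, windows_sheath_tech = 65,
#'   total_sheath = 100)`.
#' @param floor minimum post-renovation specific demand (kWh/m²/a). Set to
#'   `NULL` to disable flooring, in which case a saving exceeding the base
#'   demand is an error.
#' @return A `demand_spec` list.
#' @export
demand_spec <- function(base, savings, floor = 20) {
  if (!is_indexed_table(base)) {
    base <- indexed_table(base, unit = "kWh/m2/a", name = "demand")
  }
  if (any(base$Result <= 0)) stop("specific demand must be > 0", call. = FALSE)
  if (any(savings < 0)) stop("savings must be >= 0", call. = FALSE)
  if (is.null(names(savings)) || any(!nzchar(names(savings)))) {
    stop("savings must be named by renovation depth", call. = FALSE)
  }
  structure(list(base = base, savings = savings, floor = floor),
            class = "demand_spec")
}

#' Specific demand across renovation states
#'
#' Expands a [demand_spec()] into a full table over the `Renovation` index:
#' the `"none"` state keeps the base demand and each renovated state subtracts
#' its depth's saving (floored at `spec$floor`).
#'
#' @param spec a [demand_spec()].
#' @return Indexed table over (`Building`, `Built`, `Renovation`) in kWh/m²/a.
#' @export
post_renovation_demand <- function(spec) {
  stopifnot(inherits(spec, "demand_spec"))
  base <- as.data.frame(spec$base)
  states <- c(none = 0, spec$savings)
  out <- do.call(rbind, lapply(names(states), function(st) {
    d <- base
    d$Renovation <- st
    d$Result <- d$Result - states[[st]]
    d
  }))
  if (is.null(spec$floor)) {
    if (any(out$Result <= 0)) {
      stop("renovation saving exceeds base demand and no floor is set",
           call. = FALSE)
    }
  } else {
    out$Result <- pmax(out$Result, spec$floor)
  }
  it_new(out, unit = it_unit(spec$base), name = "demand",
         decisions = attr(spec$base, "decisions"))
}

#' Heating-energy demand of the building stock
#'
#' Multiplies floor area by specific demand over matching strata and
#' aggregates to annual totals per heating type: the model covers heating
#' energy only (non-heating electricity is out of scope by construction).
#'
#' @param stock building-stock table (m²) indexed at least by `Time`,
#'   `Building`, `Built`, `Renovation`, `Heating`.
#' @param demand specific-demand table (kWh/m²/a) over (`Building`, `Built`,
#'   `Renovation`), e.g. from [post_renovation_demand()].
#' @return Indexed table of heat demand in GWh/a by (`Time`, `Heating`) plus
#'   any scenario / `Iteration` indices present.
#' @export
heat_demand <- function(stock, demand) {
  stopifnot(is_indexed_table(stock), is_indexed_table(demand))
  shared <- intersect(index_names(stock), index_names(demand))
  shared <- setdiff(shared, c("Iteration", scenario_index_of(stock),
                              scenario_index_of(demand)))
  if (!length(shared)) stop("stock and demand share no strata indices",
                            call. = FALSE)
  ks <- unique(do.call(paste, c(as.data.frame(stock)[shared], sep = "\r")))
  kd <- unique(do.call(paste, c(as.data.frame(demand)[shared], sep = "\r")))
  missing_k <- setdiff(ks, kd)
  if (length(missing_k)) {
    stop("demand spec does not cover ", length(missing_k),
         " stock stratum/strata over (", paste(shared, collapse = ", "),
         "), e.g. (", gsub("\r", ", ", missing_k[1L]), ")", call. = FALSE)
  }
  e <- it_binary(stock, demand, "*")  # m2 * kWh/m2/a = kWh/a
  e <- it_apply(e, function(v) v / 1e6, unit = "GWh/a")
  out <- agg_keep_iter(e, keep = intersect(c("Time", "Heating"), names(e)))
  it_new(as.data.frame(out), unit = "GWh/a", name = "heat_demand",
         decisions = attr(out, "decisions"))
}
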