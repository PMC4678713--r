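#' Renovation policy parameters
#'
#' Age-gated renovation: each year a fraction `rate` of the currently
#' unrenovated floor area older than `age_threshold` years is renovated, and
#' the renovated area is split across renovation depths by `depth_shares`.
#' The depth states follow the standard ladder: window replacement only
#' (`windows`), windows plus sheath sealing and technical systems
#' (`windows_sheath_tech`), and total sheath reform (`total_sheath`).
#'
#' @param rate fraction of eligible floor area renovated per year, in `[0, 1]`.
#' @param age_threshold building age (years, from era start) above which a
#'   building becomes eligible; default 30.
#' @param depth_shares named numeric vector over renovated states, summing
#'   to 1.
#' @param rate_base `"unrenovated"` (default: the rate applies to still
#'   unrenovated over-threshold area) or `"all"` (rate applies to all
#'   over-threshold area, so the annual renovated amount stays constant while
#'   eligible area lasts).
#' @return A `renovation_policy` list.
#' @export
renovation_policy <- function(rate, age_threshold = 30,
                              depth_shares = c(windows = 0.4,
                                               windows_sheath_tech = 0.4,
                                               total_sheath = 0.2),
                              rate_base = c("unrenovated", "all")) {
  rate_base <- match.arg(rate_base)
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate)) {
    stop("rate must be a single number", call. = FALSE)
  }
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]", call. = FALSE)
  if (abs(sum(depth_shares) - 1) > 1e-9) {
    stop("depth_shares must sum to 1", call. = FALSE)
  }
  if (any(depth_shares < 0)) stop("depth_shares must be >= 0", call. = FALSE)
  if (is.null(names(depth_shares)) || any(!nzchar(names(depth_shares)))) {
    stop("depth_shares must be named by renovation state", call. = FALSE)
  }
  structure(list(rate = rate, age_threshold = age_threshold,
                 depth_shares = depth_shares, rate_base = rate_base),
            class = "renovation_policy")
}

stock_index_cols <- function(stock) {
  setdiff(index_names(stock), "Time")
}

#' Floor area eligible for renovation
#'
#' Returns the floor area at year `t` that is still unrenovated
#' (`Renovation == "none"`) and strictly older than the age threshold,
#' measured from the era (`Built`) start year.
#'
#' @param stock_at_t building-stock table for a single year (a `Time` column,
#'   if present, must be single-valued).
#' @param t evaluation year.
#' @param age_threshold age gate in years (default 30).
#' @return Indexed table of eligible floor area (possibly zero rows).
#' @export
eligible_area <- function(stock_at_t, t, age_threshold = 30) {
  stopifnot(is_indexed_table(stock_at_t))
  df <- as.data.frame(stock_at_t)
  if ("Time" %in% names(df)) {
    df <- df[df$Time == t, , drop = FALSE]
    if (!nrow(df)) stop("no stock rows at Time=", t, call. = FALSE)
  }
  keep <- df$Renovation == "none" & (t - df$Built) > age_threshold
  it_new(df[keep, , drop = FALSE], unit = it_unit(stock_at_t),
         name = "eligible_area", decisions = attr(stock_at_t, "decisions"))
}

#' One annual renovation transition
#'
#' Moves `rate` times the eligible floor area out of `Renovation == "none"`
#' into the renovated states in the proportions of the policy's
#' `depth_shares`. Total floor area is conserved exactly. Renovated area does
#' not re-enter eligibility.
#'
#' @param stock_at_t single-year building-stock table with a `Renovation`
#'   index.
#' @param policy a [renovation_policy()].
#' @param t evaluation year; defaults to the single `Time` value if present.
#' @return Stock table of the same year after the transition.
#' @export
renovation_step <- function(stock_at_t, policy, t = NULL) {
  stopifnot(is_indexed_table(stock_at_t), inherits(policy, "renovation_policy"))
  df <- as.data.frame(stock_at_t)
  if (is.null(t)) {
    if (!"Time" %in% names(df)) stop("t is required when stock has no Time",
                                     call. = FALSE)
    t <- unique(df$Time)
    if (length(t) != 1L) stop("stock_at_t spans several years", call. = FALSE)
  }
  if (policy$rate == 0) return(stock_at_t)
  elig <- df$Renovation == "none" & (t - df$Built) > policy$age_threshold
  if (!any(elig)) return(stock_at_t)
  if (policy$rate_base == "unrenovated") {
    moved <- policy$rate * df$Result[elig]
  } else {
    # rate applies to all over-threshold area of the same stratum (renovated
    # or not), capped at what is still unrenovated
    strat <- setdiff(index_names(stock_at_t), c("Renovation"))
    key_all <- do.call(paste, c(df[strat], sep = "\r"))
    over <- (t - df$Built) > policy$age_threshold
    base <- tapply(df$Result[over], key_all[over], sum)
    moved <- pmin(policy$rate * as.numeric(base[key_all[elig]]),
                  df$Result[elig])
  }
  out <- df
  out$Result[elig] <- out$Result[elig] - moved
  add <- do.call(rbind, lapply(names(policy$depth_shares), function(st) {
    a <- df[elig, , drop = FALSE]
    a$Renovation <- st
    a$Result <- moved * policy$depth_shares[[st]]
    a
  }))
  out <- rbind(out, add)
  # merge duplicate strata created by moving area into existing states
  idx <- index_names(stock_at_t)
  agg <- stats::aggregate(out["Result"], by = out[idx], FUN = sum)
  it_new(agg, unit = it_unit(stock_at_t), name = it_name(stock_at_t),
         decisions = attr(stock_at_t, "decisions"))
}

#' Per-year new-construction plan
#'
#' @param df data frame with `Time`, `Building`, `Heating` and `Result`
#'   (m²/year of new floor area); extra index columns are carried along.
#' @return Indexed table of class `itable` in m²/a.
#' @export
construction_plan <- function(df) {
  tab <- indexed_table(df, unit = "m2/a", name = "construction")
  if (any(tab$Result < 0)) stop("construction must be non-negative",
                                call. = FALSE)
  if (!"Time" %in% names(tab)) stop("construction plan needs a Time index",
                                    call. = FALSE)
  tab
}

#' Evolve the building stock through time
#'
#' Annual loop: carry forward the previous year's stock, add the year's new
#' construction (entering unrenovated, `Built` set to the year's decade era),
#' optionally demolish a uniform fraction, then apply the renovation
#' transition. The initial stock is taken to be the state at the first horizon
#' year and is emitted unchanged for that year.
#'
#' @param initial building-stock table at the first horizon year (no `Time`
#'   column, or single-valued).
#' @param plan a [construction_plan()] covering every horizon year after the
#'   first, or `NULL` for no construction.
#' @param policy a [renovation_policy()].
#' @param horizon integer vector of consecutive years.
#' @param demolition_rate uniform fraction of floor area demolished per year
#'   (default 0; demolition is not part of the standard model and is exposed
#'   only as an optional input).
#' @return Stock table indexed by `Time` over the whole horizon.
#' @export
evolve_stock <- function(initial, plan, policy, horizon, demolition_rate = 0) {
  stopifnot(is_indexed_table(initial), inherits(policy, "renovation_policy"))
  horizon <- as.integer(horizon)
  if (any(diff(horizon) != 1L)) stop("horizon must be consecutive years",
                                     call. = FALSE)
  cur <- as.data.frame(initial)
  if ("Time" %in% names(cur)) {
    if (length(unique(cur$Time)) > 1L) {
      stop("initial stock must be a single year", call. = FALSE)
    }
    if (unique(cur$Time) > horizon[1L]) {
      stop("horizon starts before the initial stock year", call. = FALSE)
    }
    cur$Time <- NULL
  }
  if (!is.null(plan)) {
    missing_y <- setdiff(horizon[-1L], unique(plan$Time))
    if (length(missing_y)) {
      stop("construction plan has gaps at year(s): ",
           paste(missing_y, collapse = ", "), call. = FALSE)
    }
  }
  dec <- union(attr(initial, "decisions") %||% character(),
               if (!is.null(plan)) attr(plan, "decisions") %||% character())
  unit <- it_unit(initial)
  # broadcast the initial stock over plan-only index columns (e.g. Iteration
  # or a decision index carried by the construction plan)
  if (!is.null(plan)) {
    extra <- setdiff(setdiff(names(plan), "Result"), c(names(cur), "Time"))
    for (cl in extra) {
      vals <- unique(as.data.frame(plan)[[cl]])
      cur <- merge(cur, stats::setNames(data.frame(v = vals), cl), by = NULL)
    }
  }
  out <- vector("list", length(horizon))
  cur_it <- it_new(cur, unit, "stock", dec)
  out[[1L]] <- cbind(Time = horizon[1L], as.data.frame(cur_it))
  for (k in seq_along(horizon)[-1L]) {
    t <- horizon[k]
    df <- as.data.frame(cur_it)
    if (demolition_rate > 0) df$Result <- df$Result * (1 - demolition_rate)
    if (!is.null(plan)) {
      new <- as.data.frame(plan)[plan$Time == t, , drop = FALSE]
      new$Time <- NULL
      if (nrow(new)) {
        new$Built <- (t %/% 10L) * 10L
        new$Renovation <- "none"
        for (cl in setdiff(names(df), names(new))) {
          # broadcast construction over stock-only index columns (e.g. an
          # Iteration index carried only by the initial stock)
          new <- merge(new,
                       stats::setNames(data.frame(v = unique(df[[cl]])), cl),
                       by = NULL)
        }
        extra_new <- setdiff(names(new), names(df))
        if (length(extra_new)) {
          stop("construction plan carries index column(s) absent from the ",
               "stock: ", paste(extra_new, collapse = ", "), call. = FALSE)
        }
        df <- rbind(df[names(df)], new[names(df)])
        idx <- setdiff(names(df), "Result")
        df <- stats::aggregate(df["Result"], by = df[idx], FUN = sum)
      }
    }
    cur_it <- renovation_step(it_new(df, unit, "stock", dec), policy, t = t)
    out[[k]] <- cbind(Time = t, as.data.frame(cur_it))
  }
  res <- do.call(rbind, out)
  if ("Renovation" %in% names(res)) {
    # drop empty renovated strata to keep tables compact; unrenovated rows are
    # kept even at zero area so strata never vanish from the index
    res <- res[res$Result > 0 | res$Renovation == "none", , drop = FALSE]
  }
  it_new(res, unit = unit, name = "stock", decisions = dec)
}

#' Share of energy-efficient floor space
#'
#' The fraction of floor area at year `t` that is either renovated
#' (`Renovation != "none"`) or built to modern standards (era at or after
#' `efficient_from`), mirroring the convention that new construction counts
#' toward the energy-efficient share.
#'
#' @param stock stock table indexed by `Time`.
#' @param t year.
#' @param efficient_from era start year from which new builds count as
#'   efficient (default 2010).
#' @return Fraction in `[0, 1]` (a named vector over scenario combinations if
#'   the stock carries decision indices).
#' @export
renovated_share <- function(stock, t, efficient_from = 2010) {
  stopifnot(is_indexed_table(stock))
  df <- as.data.frame(stock)
  df <- df[df$Time == t, , drop = FALSE]
  if (!nrow(df)) stop("no stock rows at Time=", t, call. = FALSE)
  dec <- scenario_index_of(stock)
  eff <- df$Renovation != "none" | df$Built >= efficient_from
  if (!length(dec)) {
    tot <- sum(df$Result)
    if (tot <= 0) stop("zero total floor area at Time=", t, call. = FALSE)
    return(sum(df$Result[eff]) / tot)
  }
  key <- do.call(paste, c(df[dec], sep = " / "))
  tot <- tapply(df$Result, key, sum)
  if (any(tot <= 0)) stop("zero total floor area at Time=", t, call. = FALSE)
  effsum <- tapply(ifelse(eff, df$Result, 0), key, sum)
  as.numeric(effsum / tot) |> stats::setNames(names(tot))
}
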