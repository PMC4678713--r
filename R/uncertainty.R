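#' Declare an uncertain model input
#'
#' A distribution attached to a model input: either a named table of the input
#' bundle (with an optional cell selector), one of the scalar health
#' parameters (`"rr10"`, `"intake_fraction"`, `"mortality"`), or no target at
#' all (`target = NULL`), in which case the draws are recorded but do not
#' enter the model — useful as a null reference in importance analysis.
#'
#' One value is drawn per Monte-Carlo iteration and applied to every
#' selector-matched cell, i.e. the distribution describes a shared
#' (systematic) uncertainty of the targeted quantity, which is what a
#' rank-correlation importance analysis ranks.
#'
#' @param name variable name used in importance output.
#' @param dist one of `"point"`, `"normal"`, `"lognormal"`, `"uniform"`,
#'   `"triangular"`.
#' @param params named numeric vector of parameters: `point`: `value`;
#'   `normal`: `mean`, `sd`; `lognormal`: `meanlog`, `sdlog`; `uniform`:
#'   `min`, `max`; `triangular`: `min`, `mode`, `max`.
#' @param target name of the targeted bundle table or health parameter, or
#'   `NULL`.
#' @param selector named list restricting which rows of a targeted table are
#'   affected (default: all).
#' @param kind `"scale"` (draw multiplies the baseline cell values) or
#'   `"replace"` (draw replaces them).
#' @param lower,upper optional truncation bounds (applied in quantile space,
#'   so truncated draws keep the distribution's shape).
#' @return An `input_distribution` list.
#' @export
input_distribution <- function(name, dist, params, target = NULL,
                               selector = NULL, kind = c("scale", "replace"),
                               lower = -Inf, upper = Inf) {
  kind <- match.arg(kind)
  dist <- match.arg(dist, c("point", "normal", "lognormal", "uniform",
                            "triangular"))
  need <- switch(dist, point = "value", normal = c("mean", "sd"),
                 lognormal = c("meanlog", "sdlog"), uniform = c("min", "max"),
                 triangular = c("min", "mode", "max"))
  miss <- setdiff(need, names(params))
  if (length(miss)) {
    stop("distribution '", name, "' (", dist, ") lacks parameter(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  p <- as.list(params[need])
  if (dist == "normal" && p$sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (dist == "lognormal" && p$sdlog < 0) stop("sdlog must be >= 0",
                                               call. = FALSE)
  if (dist == "uniform" && p$max < p$min) stop("max < min", call. = FALSE)
  if (dist == "triangular" &&
      (p$mode < p$min || p$mode > p$max || p$max <= p$min)) {
    stop("triangular requires min <= mode <= max, min < max", call. = FALSE)
  }
  if (lower >= upper) stop("lower must be < upper", call. = FALSE)
  structure(list(name = name, dist = dist, params = p, target = target,
                 selector = selector, kind = kind, lower = lower,
                 upper = upper),
            class = "input_distribution")
}

# quantile function of the (untruncated) distribution
dist_quantile <- function(d, p) {
  with(d$params, switch(d$dist,
    point = rep(value, length(p)),
    normal = stats::qnorm(p, mean, sd),
    lognormal = stats::qlnorm(p, meanlog, sdlog),
    uniform = stats::qunif(p, min, max),
    triangular = qtriangular(p, min, mode, max)))
}

# CDF, needed to truncate in quantile space
dist_cdf <- function(d, q) {
  with(d$params, switch(d$dist,
    point = as.numeric(q >= value),
    normal = stats::pnorm(q, mean, sd),
    lognormal = stats::plnorm(q, meanlog, sdlog),
    uniform = stats::punif(q, min, max),
    triangular = ptriangular(q, min, mode, max)))
}

qtriangular <- function(p, a, m, b) {
  pc <- (m - a) / (b - a)
  ifelse(p <= pc, a + sqrt(p * (b - a) * (m - a)),
         b - sqrt((1 - p) * (b - a) * (b - m)))
}

ptriangular <- function(q, a, m, b) {
  out <- numeric(length(q))
  q <- pmin(pmax(q, a), b)
  lo <- q <= m
  out[lo] <- (q[lo] - a)^2 / ((b - a) * (m - a + (m == a)))
  out[!lo] <- 1 - (b - q[!lo])^2 / ((b - a) * (b - m + (b == m)))
  out
}

trunc_p_range <- function(d) {
  c(if (is.finite(d$lower)) dist_cdf(d, d$lower) else 0,
    if (is.finite(d$upper)) dist_cdf(d, d$upper) else 1)
}

#' @rdname input_distribution
#' @param d an `input_distribution`.
#' @param n number of draws.
#' @export
dist_sample <- function(d, n) {
  if (d$dist == "point") return(rep(d$params$value, n))
  pr <- trunc_p_range(d)
  u <- stats::runif(n, pr[1L], pr[2L])
  dist_quantile(d, u)
}

#' @rdname input_distribution
#' @export
dist_median <- function(d) {
  if (d$dist == "point") return(d$params$value)
  pr <- trunc_p_range(d)
  dist_quantile(d, mean(pr))
}

health_param_targets <- c("rr10", "intake_fraction", "mortality")

apply_draw_to_table <- function(tab, d, draws_tab) {
  m <- selector_match(tab, d$selector)
  if (!any(m)) {
    stop("distribution '", d$name, "': selector matches no rows of '",
         d$target, "'", call. = FALSE)
  }
  df <- as.data.frame(tab)
  matched <- it_new(df[m, , drop = FALSE], it_unit(tab), it_name(tab),
                    attr(tab, "decisions"))
  if (d$kind == "scale") {
    matched <- it_binary(matched, draws_tab, "*")
  } else {
    grid <- merge(df[m, setdiff(names(df), "Result"), drop = FALSE],
                  as.data.frame(draws_tab), by = NULL)
    matched <- it_new(grid, it_unit(tab), it_name(tab),
                      attr(tab, "decisions"))
  }
  rest <- df[!m, , drop = FALSE]
  if (nrow(rest)) {
    if (!"Iteration" %in% names(rest)) {
      rest <- merge(rest, data.frame(Iteration = unique(draws_tab$Iteration)),
                    by = NULL)
    }
    out <- rbind(as.data.frame(matched)[names(rest)], rest)
  } else {
    out <- as.data.frame(matched)
  }
  it_new(out, it_unit(tab), it_name(tab), attr(tab, "decisions"))
}

#' Sample uncertain inputs into Monte-Carlo iterations
#'
#' Draws `n_iter` values from every declared distribution (one shared draw per
#' iteration per distribution) and attaches them to the targeted tables, which
#' gain an `Iteration` index. A fixed seed makes the draws bit-identical
#' across calls.
#'
#' @param inputs named list of indexed tables (the model input bundle; health
#'   parameter targets are left to [run_model()]).
#' @param dists list of [input_distribution()] objects.
#' @param n_iter number of iterations (>= 1).
#' @param seed integer RNG seed.
#' @return List with `inputs` (tables, targeted ones carrying `Iteration`) and
#'   `draws` (named list of `Iteration`-indexed draw tables, one per
#'   distribution — including untargeted and health-parameter ones).
#' @export
sample_inputs <- function(inputs, dists, n_iter, seed) {
  stopifnot(n_iter >= 1)
  if (!length(dists)) return(list(inputs = inputs, draws = list()))
  set.seed(as.integer(seed))
  draws <- list()
  for (d in dists) {
    stopifnot(inherits(d, "input_distribution"))
    v <- dist_sample(d, n_iter)
    dt <- indexed_table(data.frame(Iteration = seq_len(n_iter), Result = v),
                        unit = "", name = d$name)
    draws[[d$name]] <- dt
    if (is.null(d$target) || d$target %in% health_param_targets) next
    if (!d$target %in% names(inputs)) {
      stop("distribution '", d$name, "' targets unknown table '", d$target,
           "'", call. = FALSE)
    }
    inputs[[d$target]] <- apply_draw_to_table(inputs[[d$target]], d, dt)
  }
  list(inputs = inputs, draws = draws)
}

#' Replace distributions by their medians (deterministic mode)
#'
#' @param inputs named list of indexed tables.
#' @param dists list of [input_distribution()] objects.
#' @return List with `inputs` (medians applied) and `medians` (named numeric).
#' @export
apply_medians <- function(inputs, dists) {
  med <- numeric()
  for (d in dists) {
    m <- dist_median(d)
    med[d$name] <- m
    if (is.null(d$target) || d$target %in% health_param_targets) next
    if (!d$target %in% names(inputs)) {
      stop("distribution '", d$name, "' targets unknown table '", d$target,
           "'", call. = FALSE)
    }
    tab <- inputs[[d$target]]
    sel <- selector_match(tab, d$selector)
    if (!any(sel)) {
      stop("distribution '", d$name, "': selector matches no rows of '",
           d$target, "'", call. = FALSE)
    }
    df <- as.data.frame(tab)
    df$Result[sel] <- if (d$kind == "scale") df$Result[sel] * m else m
    inputs[[d$target]] <- it_new(df, it_unit(tab), it_name(tab),
                                 attr(tab, "decisions"))
  }
  list(inputs = inputs, medians = med)
}

#' Monetized combination of climate and health impacts
#'
#' `value €/a = eur_per_t_co2 × CO2 t/a + eur_per_daly × DALY/a`, the nominal
#' valuation used to put emissions and disease burden on one scale for
#' importance analysis.
#'
#' @param co2 annual CO2 emissions (t/a), numeric or indexed table.
#' @param daly annual disease burden (DALY/a), numeric or indexed table.
#' @param weights named list or vector with `eur_per_t_co2` and
#'   `eur_per_daly` (defaults 15 and 50000).
#' @return €/a, of the same shape as the inputs (table in, table out).
#' @export
monetize <- function(co2, daly, weights = list(eur_per_t_co2 = 15,
                                               eur_per_daly = 50000)) {
  w1 <- weights[["eur_per_t_co2"]]
  w2 <- weights[["eur_per_daly"]]
  if (w1 < 0 || w2 < 0) stop("monetization weights must be >= 0",
                             call. = FALSE)
  if (!is_indexed_table(co2) && !is_indexed_table(daly)) {
    return(w1 * co2 + w2 * daly)
  }
  a <- it_apply(as_itable(co2, "t/a", "co2"), function(v) v * w1,
                unit = "EUR/a")
  b <- it_apply(as_itable(daly, "DALY/a", "daly"), function(v) v * w2,
                unit = "EUR/a")
  out <- it_binary(a, b, "+")
  it_new(as.data.frame(out), unit = "EUR/a", name = "monetized",
         decisions = attr(out, "decisions"))
}

#' Incremental (policy-minus-BAU) values per iteration
#'
#' Subtracts the BAU scenario slice from every other decision-option
#' combination, matching on all remaining indices (including `Iteration`).
#' At the BAU combination itself the increments are identically zero.
#'
#' @param value indexed table carrying at least one decision index.
#' @param bau named character vector/list giving the reference option per
#'   decision (default: `"BAU"` for every decision index).
#' @return Indexed table of increments with the same indices as `value`.
#' @export
incremental_values <- function(value, bau = NULL) {
  dec <- scenario_index_of(value)
  if (!length(dec)) stop("value carries no decision index", call. = FALSE)
  if (is.null(bau)) bau <- stats::setNames(rep("BAU", length(dec)), dec)
  ref <- it_filter(value, as.list(bau))
  if (!nrow(ref)) stop("no rows match the BAU combination", call. = FALSE)
  ref_df <- as.data.frame(ref)[, setdiff(names(ref), dec), drop = FALSE]
  ref_it <- it_new(ref_df, it_unit(value), "bau_reference")
  out <- it_binary(value, ref_it, "-")
  it_new(as.data.frame(out), unit = it_unit(value), name = "incremental",
         decisions = attr(value, "decisions"))
}

#' Rank-correlation importance of uncertain inputs
#'
#' For every sampled input and every decision-option combination, the absolute
#' Spearman (or Kendall) rank correlation between the input draws and the
#' monetized outcome across Monte-Carlo iterations. In `"incremental"` mode
#' the BAU combination is first subtracted per iteration, so the correlation
#' measures influence on the policy *effect* rather than on the absolute
#' level; at the BAU combination itself the increments are identically zero
#' and the correlation is undefined (reported as `NA`, not 0 — likewise for
#' any zero-variance input).
#'
#' @param draws named list of `Iteration`-indexed draw tables (from
#'   [sample_inputs()] or `run_model()$draws`).
#' @param value monetized outcome table with an `Iteration` index, one value
#'   per iteration per decision-option combination.
#' @param mode `"absolute"` or `"incremental"`.
#' @param bau reference options for incremental mode (see
#'   [incremental_values()]).
#' @param method `"spearman"` (default) or `"kendall"`.
#' @return Data frame with columns `variable`, `mode`, `combination`,
#'   `rho` (absolute rank correlation, `NA` when undefined).
#' @export
importance <- function(draws, value, mode = c("absolute", "incremental"),
                       bau = NULL, method = c("spearman", "kendall")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  stopifnot(is_indexed_table(value), "Iteration" %in% names(value))
  if (mode == "incremental") value <- incremental_values(value, bau)
  dec <- scenario_index_of(value)
  extra <- setdiff(index_names(value), c("Iteration", dec))
  if (length(extra)) {
    stop("outcome must have one value per iteration per combination; ",
         "aggregate over ", paste(extra, collapse = ", "), " first",
         call. = FALSE)
  }
  df <- as.data.frame(value)
  combo <- if (length(dec)) do.call(paste, c(df[dec], sep = " / ")) else
    rep("(all)", nrow(df))
  out <- list()
  for (nm in names(draws)) {
    dd <- as.data.frame(draws[[nm]])
    x <- dd$Result[order(dd$Iteration)]
    for (cb in unique(combo)) {
      sub <- df[combo == cb, , drop = FALSE]
      y <- sub$Result[order(sub$Iteration)]
      if (length(y) != length(x)) {
        stop("iteration counts differ between draws '", nm,
             "' and the outcome", call. = FALSE)
      }
      rho <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
        abs(stats::cor(x, y, method = method))
      out[[length(out) + 1L]] <- data.frame(variable = nm, mode = mode,
                                            combination = cb, rho = rho)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise importance results as min-max ranges per variable
#'
#' @param imp data frame from [importance()] (possibly both modes bound
#'   together).
#' @return Data frame with one row per (`variable`, `mode`): `rho_min`,
#'   `rho_max` over decision-option combinations (NAs removed).
#' @export
importance_ranges <- function(imp) {
  sp <- split(imp, list(imp$variable, imp$mode), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) {
    r <- g$rho[!is.na(g$rho)]
    data.frame(variable = g$variable[1L], mode = g$mode[1L],
               rho_min = if (length(r)) min(r) else NA_real_,
               rho_max = if (length(r)) max(r) else NA_real_)
  }))
  out <- out[order(out$mode, -out$rho_max), , drop = FALSE]
  rownames(out) <- NULL
  out
}
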