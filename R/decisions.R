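#' Externally defined policy (decision) tables
#'
#' The core model contains no policies. Policies are declared in a decision
#' table outside the model; when a run starts, every targeted input table is
#' expanded along a new index column named after the decision, with a
#' `"BAU"` (business-as-usual) level reproducing the untouched input and one
#' level per policy option applying the declared change to selector-matched
#' rows. Downstream outputs then automatically carry the full factorial of all
#' decision options as scenario indices.
#'
#' @param decision character, decision names (e.g. `"Renovation"`).
#' @param option character, option names within each decision. `"BAU"` is
#'   always present implicitly and must not be declared with a change.
#' @param target character, name of the input table the row modifies.
#' @param selector list column (or `"col=value;col=value"` strings) restricting
#'   which rows of the target the change applies to; multiple accepted values
#'   for one column are separated by `|`. `NULL`/`""` matches all rows.
#' @param change one of `"multiply"`, `"add"`, `"replace"`.
#' @param value numeric magnitude of the change.
#' @return A `decision_table` data frame.
#' @examples
#' decision_table(
#'   decision = "Fuel", option = "Biofuel", target = "fuel_mix",
#'   selector = "Fuel=peat", change = "replace", value = 0.49
#' )
#' @export
decision_table <- function(decision, option, target, selector, change, value) {
  if (missing(decision)) {
    df <- data.frame(decision = character(), option = character(),
                     target = character(), change = character(),
                     value = numeric())
    df$selector <- list()
    class(df) <- c("decision_table", "data.frame")
    return(df)
  }
  n <- max(length(decision), length(option), length(target), length(change),
           length(value))
  if (is.character(selector)) selector <- lapply(selector, parse_selector)
  if (!is.list(selector)) selector <- list(selector)
  df <- data.frame(decision = rep_len(as.character(decision), n),
                   option = rep_len(as.character(option), n),
                   target = rep_len(as.character(target), n),
                   change = rep_len(as.character(change), n),
                   value = rep_len(as.numeric(value), n))
  df$selector <- rep_len(selector, n)
  bad <- setdiff(df$change, c("multiply", "add", "replace"))
  if (length(bad)) {
    stop("unknown change type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(df$option == "BAU")) {
    stop("'BAU' is implicit (no change) and must not appear as an option row",
         call. = FALSE)
  }
  class(df) <- c("decision_table", "data.frame")
  df
}

# "col=a|b;col2=x" -> list(col = c("a","b"), col2 = "x")
parse_selector <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(s)) return(NULL)
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed selector: '", p, "'", call. = FALSE)
    vals <- strsplit(kv[2L], "|", fixed = TRUE)[[1L]]
    nums <- suppressWarnings(as.numeric(vals))
    out[[trimws(kv[1L])]] <- if (!anyNA(nums)) nums else trimws(vals)
  }
  out
}

deparse_selector <- function(sel) {
  if (is.null(sel) || !length(sel)) return("")
  paste(vapply(names(sel), function(k)
    paste0(k, "=", paste(sel[[k]], collapse = "|")), character(1L)),
    collapse = ";")
}

#' Expand policy decisions into scenario indices on model inputs
#'
#' Applies a [decision_table()] to a named list of input tables. Each targeted
#' table is duplicated along a new index column per decision; the `"BAU"` level
#' reproduces the input exactly, and each option level applies its changes to
#' selector-matched rows (in decision-table row order, so `multiply`/`add` do
#' not commute with a later `replace`). A selector that matches no rows is an
#' error: a silently inert policy is a modelling hazard.
#'
#' @param model_inputs named list of indexed tables.
#' @param decisions a [decision_table()] (or `NULL` / empty for a plain run).
#' @return The input list with targeted tables expanded; untargeted tables are
#'   returned unchanged.
#' @export
apply_decisions <- function(model_inputs, decisions) {
  stopifnot(is.list(model_inputs))
  if (is.null(decisions) || nrow(decisions) == 0L) return(model_inputs)
  missing_t <- setdiff(unique(decisions$target), names(model_inputs))
  if (length(missing_t)) {
    stop("decision target table(s) not found: ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  }
  for (d in unique(decisions$decision)) {
    rows_d <- decisions[decisions$decision == d, , drop = FALSE]
    levels_d <- c("BAU", unique(rows_d$option))
    for (tname in unique(rows_d$target)) {
      tab <- model_inputs[[tname]]
      if (!is_indexed_table(tab)) {
        stop("decision target '", tname, "' is not an indexed table",
             call. = FALSE)
      }
      if (d %in% names(tab)) {
        stop("table '", tname, "' already carries a '", d, "' index",
             call. = FALSE)
      }
      slices <- lapply(levels_d, function(o) {
        df <- as.data.frame(tab)
        rr <- rows_d[rows_d$option == o & rows_d$target == tname, ,
                     drop = FALSE]
        for (i in seq_len(nrow(rr))) {
          m <- selector_match(tab, rr$selector[[i]])
          if (!any(m)) {
            stop("decision '", d, "' option '", o, "': selector '",
                 deparse_selector(rr$selector[[i]]),
                 "' matches no rows of '", tname, "'", call. = FALSE)
          }
          df$Result[m] <- switch(rr$change[i],
            multiply = df$Result[m] * rr$value[i],
            add      = df$Result[m] + rr$value[i],
            replace  = rr$value[i])
        }
        df[[d]] <- o
        df
      })
      out <- do.call(rbind, slices)
      model_inputs[[tname]] <- it_new(
        out, unit = it_unit(tab), name = tname,
        decisions = union(attr(tab, "decisions"), d))
    }
  }
  model_inputs
}
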