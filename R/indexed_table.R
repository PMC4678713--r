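#' Long-format indexed value tables
#'
#' The universal interchange type of the model: a data frame whose columns are
#' named index columns (categorical or integer-year) plus a numeric `Result`
#' column, carrying a free-text unit and a name as attributes. Two index names
#' are reserved: `Iteration` (Monte-Carlo sample id, integers `1..N`) and one
#' column per declared policy decision (the "scenario index", tracked in the
#' `decisions` attribute).
#'
#' @param data data frame containing a numeric `Result` column; every other
#'   column is treated as an index column.
#' @param unit non-empty unit string, e.g. `"m2"`, `"GWh/a"`.
#' @param name identifier used in messages and file output.
#' @param decisions character vector naming which index columns are scenario
#'   (decision) indices.
#' @return An object of class `itable` (inherits from `data.frame`).
#' @examples
#' indexed_table(data.frame(Time = 2010:2012, Result = c(1, 2, 3)), unit = "m2")
#' @export
indexed_table <- function(data, unit, name = "table", decisions = character()) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"Result" %in% names(data)) {
    stop("table '", name, "': no 'Result' column", call. = FALSE)
  }
  if (!is.numeric(data$Result)) {
    stop("table '", name, "': 'Result' must be numeric", call. = FALSE)
  }
  if (anyNA(data$Result) || any(!is.finite(data$Result))) {
    stop("table '", name, "': 'Result' contains non-finite values", call. = FALSE)
  }
  if (!is.character(unit) || length(unit) != 1L || is.na(unit)) {
    stop("table '", name, "': unit must be a single string", call. = FALSE)
  }
  idx <- setdiff(names(data), "Result")
  data <- data[, c(idx, "Result"), drop = FALSE]
  if (length(idx)) {
    key <- do.call(paste, c(data[idx], sep = "\r"))
    if (anyDuplicated(key)) {
      dup <- data[duplicated(key), idx, drop = FALSE][1L, , drop = FALSE]
      stop("table '", name, "': duplicate index tuple, e.g. (",
           paste(names(dup), unlist(dup), sep = "=", collapse = ", "), ")",
           call. = FALSE)
    }
    if ("Iteration" %in% idx && !is.numeric(data$Iteration)) {
      stop("table '", name, "': 'Iteration' must be integer-valued", call. = FALSE)
    }
  }
  decisions <- intersect(decisions, idx)
  rownames(data) <- NULL
  structure(data, unit = unit, table_name = name, decisions = decisions,
            class = c("itable", "data.frame"))
}

#' @rdname indexed_table
#' @param x object to test or query.
#' @export
is_indexed_table <- function(x) inherits(x, "itable")

#' @rdname indexed_table
#' @export
index_names <- function(x) setdiff(names(x), "Result")

#' @rdname indexed_table
#' @export
it_unit <- function(x) attr(x, "unit", exact = TRUE) %||% ""

#' @rdname indexed_table
#' @export
it_name <- function(x) attr(x, "table_name", exact = TRUE) %||% "table"

`%||%` <- function(a, b) if (is.null(a)) b else a

# rebuild an itable without re-running full validation paths that constructors
# already guarantee; still routes through indexed_table() for safety.
it_new <- function(data, unit, name, decisions = character()) {
  indexed_table(data, unit = unit, name = name, decisions = decisions)
}

#' @export
print.itable <- function(x, ...) {
  cat(sprintf("<itable '%s'> %d row(s), unit: %s\n", it_name(x), nrow(x),
              it_unit(x)))
  idx <- index_names(x)
  if (length(idx)) cat("indices:", paste(idx, collapse = ", "), "\n")
  dec <- scenario_index_of(x)
  if (length(dec)) cat("decisions:", paste(dec, collapse = ", "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

as_itable <- function(x, unit = "", name = "scalar") {
  if (is_indexed_table(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) {
    return(indexed_table(data.frame(Result = as.numeric(x)), unit = unit,
                         name = name))
  }
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to an indexed table", call. = FALSE)
}

combine_units <- function(ua, ub, op) {
  if (op %in% c("+", "-")) {
    if (nzchar(ua) && nzchar(ub) && ua != ub) {
      warning("adding tables with different units: '", ua, "' vs '", ub, "'",
              call. = FALSE)
    }
    return(if (nzchar(ua)) ua else ub)
  }
  if (op == "*") {
    if (!nzchar(ua)) return(ub)
    if (!nzchar(ub)) return(ua)
    return(paste0(ua, "*", ub))
  }
  # division
  if (!nzchar(ub)) return(ua)
  if (ua == ub) return("")
  paste0(if (nzchar(ua)) ua else "1", "/", ub)
}

#' Index-aligned binary arithmetic on indexed tables
#'
#' Rows are matched by an inner join on the index columns the two tables share;
#' index columns present in only one table broadcast over the other. The result
#' is indexed by the union of index columns. Rows dropped by the join are
#' reported via a message. The usual arithmetic operators (`+`, `-`, `*`, `/`)
#' dispatch here for `itable` operands; bare numeric scalars are promoted to
#' index-free tables.
#'
#' @param a,b indexed tables (or single numbers).
#' @param op one of `"+"`, `"-"`, `"*"`, `"/"`.
#' @return An indexed table indexed by the union of the operands' indices.
#' @export
it_binary <- function(a, b, op) {
  stopifnot(op %in% c("+", "-", "*", "/"))
  a <- as_itable(a)
  b <- as_itable(b)
  shared <- intersect(index_names(a), index_names(b))
  da <- as.data.frame(a)
  db <- as.data.frame(b)
  names(db)[names(db) == "Result"] <- "Result.b"
  names(da)[names(da) == "Result"] <- "Result.a"
  if (length(shared)) {
    m <- merge(da, db, by = shared)
    if (nrow(m) == 0L) {
      bad <- shared[vapply(shared, function(cl)
        length(intersect(unique(da[[cl]]), unique(db[[cl]]))) == 0L, logical(1L))]
      stop("no overlapping index values between '", it_name(a), "' and '",
           it_name(b), "' on shared index ",
           paste(if (length(bad)) bad else shared, collapse = ", "),
           call. = FALSE)
    }
    # count input rows that found no partner (per table)
    ka <- do.call(paste, c(da[shared], sep = "\r"))
    kb <- do.call(paste, c(db[shared], sep = "\r"))
    n_drop <- sum(!(ka %in% kb)) + sum(!(kb %in% ka))
    if (n_drop > 0L) {
      message("it_binary: dropped ", n_drop, " unmatched row(s) joining '",
              it_name(a), "' and '", it_name(b), "'")
    }
  } else {
    m <- merge(da, db, by = NULL)  # cartesian broadcast
  }
  m$Result <- switch(op,
    "+" = m$Result.a + m$Result.b,
    "-" = m$Result.a - m$Result.b,
    "*" = m$Result.a * m$Result.b,
    "/" = m$Result.a / m$Result.b)
  if (any(!is.finite(m$Result))) {
    stop("non-finite result in '", it_name(a), "' ", op, " '", it_name(b),
         "' (division by zero?)", call. = FALSE)
  }
  m$Result.a <- NULL
  m$Result.b <- NULL
  dec <- union(attr(a, "decisions"), attr(b, "decisions"))
  it_new(m, unit = combine_units(it_unit(a), it_unit(b), op),
         name = paste0(it_name(a), op, it_name(b)), decisions = dec)
}

#' @export
Ops.itable <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "*", "/")) {
    stop("operator '", .Generic, "' is not defined for indexed tables",
         call. = FALSE)
  }
  if (missing(e2)) {  # unary +/-
    r <- e1
    if (.Generic == "-") r$Result <- -r$Result
    return(it_new(as.data.frame(r), it_unit(e1), it_name(e1),
                  attr(e1, "decisions")))
  }
  it_binary(e1, e2, .Generic)
}

#' Aggregate an indexed table over dropped indices
#'
#' Sums (or averages) `Result` over every index column not listed in `keep`.
#' Scenario (decision) indices are never dropped: they are retained
#' automatically even when absent from `keep`. Dropping the `Iteration` index
#' collapses Monte-Carlo samples and therefore requires the explicit
#' `drop_iteration` flag.
#'
#' @param x indexed table.
#' @param keep character vector of index names to keep (may be empty for a
#'   grand total).
#' @param how `"sum"` or `"mean"`.
#' @param drop_iteration set `TRUE` to explicitly allow collapsing the
#'   `Iteration` index.
#' @return Indexed table with indices `keep` (plus retained reserved indices).
#' @export
it_aggregate <- function(x, keep = character(), how = c("sum", "mean"),
                         drop_iteration = FALSE) {
  how <- match.arg(how)
  stopifnot(is_indexed_table(x))
  idx <- index_names(x)
  if (length(setdiff(keep, idx))) {
    stop("unknown index name(s): ", paste(setdiff(keep, idx), collapse = ", "),
         call. = FALSE)
  }
  keep <- union(keep, scenario_index_of(x))
  if ("Iteration" %in% idx && !"Iteration" %in% keep) {
    if (!drop_iteration) {
      stop("aggregating over 'Iteration' requires drop_iteration = TRUE",
           call. = FALSE)
    }
  } else {
    keep <- union(keep, intersect("Iteration", idx))
  }
  keep <- idx[idx %in% keep]  # preserve column order
  df <- as.data.frame(x)
  fn <- if (how == "sum") sum else mean
  if (!length(keep)) {
    out <- data.frame(Result = fn(df$Result))
  } else {
    out <- stats::aggregate(df["Result"], by = df[keep], FUN = fn)
  }
  it_new(out, unit = it_unit(x), name = it_name(x),
         decisions = attr(x, "decisions"))
}

# aggregate while always retaining an Iteration index if present; the
# pipeline's internal call sites use this so Monte-Carlo samples survive
agg_keep_iter <- function(x, keep = character(), how = "sum") {
  it_aggregate(x, union(keep, intersect("Iteration", names(x))), how = how)
}

#' Transform the value column of an indexed table
#'
#' @param x indexed table.
#' @param f vectorized function applied to `Result`.
#' @param unit unit string of the transformed quantity (defaults to `x`'s).
#' @return Indexed table with identical indices.
#' @export
it_apply <- function(x, f, unit = it_unit(x)) {
  stopifnot(is_indexed_table(x))
  df <- as.data.frame(x)
  df$Result <- f(df$Result)
  it_new(df, unit = unit, name = it_name(x), decisions = attr(x, "decisions"))
}

#' Filter an indexed table by index values
#'
#' @param x indexed table.
#' @param selector named list mapping index columns to kept value sets.
#' @param drop drop selector columns that become single-valued? (default keeps
#'   all columns).
#' @return Indexed table restricted to matching rows.
#' @export
it_filter <- function(x, selector, drop = FALSE) {
  stopifnot(is_indexed_table(x))
  m <- selector_match(x, selector)
  df <- as.data.frame(x)[m, , drop = FALSE]
  if (drop) df <- df[, setdiff(names(df), names(selector)), drop = FALSE]
  it_new(df, unit = it_unit(x), name = it_name(x),
         decisions = attr(x, "decisions"))
}

selector_match <- function(tab, selector) {
  if (is.null(selector) || !length(selector)) return(rep(TRUE, nrow(tab)))
  bad <- setdiff(names(selector), index_names(tab))
  if (length(bad)) {
    stop("selector column(s) not among indices of '", it_name(tab), "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- rep(TRUE, nrow(tab))
  for (cl in names(selector)) {
    m <- m & (tab[[cl]] %in% selector[[cl]])
  }
  m
}

#' Which scenario (decision) indices does an output carry?
#'
#' Policies declared outside the core model appear in every downstream output
#' as extra index columns, one per decision; this returns their names (empty
#' for a plain, no-policy run).
#'
#' @param output indexed table.
#' @return Character vector of decision index names (possibly empty).
#' @export
scenario_index_of <- function(output) {
  intersect(attr(output, "decisions", exact = TRUE) %||% character(),
            names(output))
}
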