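#' Read and write indexed tables as CSV with a JSON sidecar
#'
#' The CSV dialect is UTF-8 with a header row, index columns first and the
#' value column `Result` last. A sidecar `<path>.json` records the table
#' name, unit, index declaration and decision indices, so a round trip
#' preserves the full object.
#'
#' @param x indexed table.
#' @param path CSV file path.
#' @return `write_indexed_table` returns `path` invisibly;
#'   `read_indexed_table` returns the table.
#' @export
write_indexed_table <- function(x, path) {
  stopifnot(is_indexed_table(x))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  meta <- list(name = it_name(x), unit = it_unit(x),
               indices = index_names(x), decisions = scenario_index_of(x))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_indexed_table
#' @param declared_indices optional character vector; when given, the file
#'   header must contain exactly these index columns.
#' @param unit unit override when no sidecar exists.
#' @export
read_indexed_table <- function(path, declared_indices = NULL, unit = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"Result" %in% names(df)) {
    stop(path, ": no 'Result' column", call. = FALSE)
  }
  if (!is.numeric(df$Result)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$Result))))
    stop(path, ": non-numeric Result in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else
    list()
  idx <- setdiff(names(df), "Result")
  if (!is.null(declared_indices) && !setequal(idx, declared_indices)) {
    stop(path, ": header indices (", paste(idx, collapse = ", "),
         ") do not match declaration (",
         paste(declared_indices, collapse = ", "), ")", call. = FALSE)
  }
  key <- if (length(idx)) do.call(paste, c(df[idx], sep = "\r")) else
    character()
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop(path, ": duplicate index tuple(s) in row(s) ",
         paste(utils::head(rows, 6L), collapse = ", "), call. = FALSE)
  }
  indexed_table(df,
                unit = unit %||% (meta$unit %||% ""),
                name = meta$name %||%
                  tools::file_path_sans_ext(basename(path)),
                decisions = unlist(meta$decisions) %||% character())
}

#' Read a policy decision table from CSV
#'
#' Expected columns: `Decision`, `Option`, `Target`, `Selector`, `Change`,
#' `Value`; selectors are encoded `col=value;col=value` with `|` separating
#' alternative values.
#'
#' @param path CSV file path.
#' @return A [decision_table()].
#' @export
read_decision_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("Decision", "Option", "Target", "Selector", "Change", "Value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(path, ": missing column(s) ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!nrow(df)) return(decision_table())
  decision_table(decision = df$Decision, option = df$Option,
                 target = df$Target, selector = as.character(df$Selector),
                 change = tolower(df$Change), value = df$Value)
}

#' @rdname read_decision_table
#' @param x a [decision_table()].
#' @export
write_decision_table <- function(x, path) {
  df <- data.frame(Decision = x$decision, Option = x$option,
                   Target = x$target,
                   Selector = vapply(x$selector, deparse_selector,
                                     character(1L)),
                   Change = x$change, Value = x$value)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a full input bundle as a directory of text files
#'
#' Tables go to CSV + JSON sidecars, the health parameters, monetization
#' weights, horizon and distribution declarations to a single `config.yaml`.
#'
#' @param bundle validated input bundle.
#' @param dir directory (created if missing).
#' @return `write_bundle` returns `dir` invisibly; `read_bundle` a bundle.
#' @export
write_bundle <- function(bundle, dir) {
  validate_bundle(bundle)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in intersect(bundle_table_names, names(bundle))) {
    write_indexed_table(bundle[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  if (!is.null(bundle$decisions)) {
    write_decision_table(bundle$decisions, file.path(dir, "decisions.csv"))
  }
  hp <- bundle$health
  cfg <- list(
    health = list(population = hp$population, mortality = hp$mortality,
                  breathing_rate = hp$breathing_rate,
                  intake_fraction = as.list(hp$intake_fraction),
                  rr10 = hp$rr10, c0 = hp$c0,
                  yll_per_death = hp$yll_per_death, erf_form = hp$erf_form),
    weights = bundle$weights,
    horizon = list(start = min(bundle$horizon), end = max(bundle$horizon)),
    age_threshold = bundle$age_threshold %||% 30,
    dists = lapply(bundle$dists %||% list(), function(d) {
      list(name = d$name, dist = d$dist, params = as.list(d$params),
           target = d$target, selector = d$selector, kind = d$kind,
           lower = if (is.finite(d$lower)) d$lower else NULL,
           upper = if (is.finite(d$upper)) d$upper else NULL)
    }))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  cfg_path <- file.path(dir, "config.yaml")
  if (!file.exists(cfg_path)) stop("no config.yaml in ", dir, call. = FALSE)
  cfg <- yaml::read_yaml(cfg_path)
  bundle <- list()
  for (nm in bundle_table_names) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(p)) stop("missing input table: ", p, call. = FALSE)
    bundle[[nm]] <- read_indexed_table(p)
  }
  dpath <- file.path(dir, "decisions.csv")
  if (file.exists(dpath)) bundle$decisions <- read_decision_table(dpath)
  h <- cfg$health
  bundle$health <- health_parameters(
    population = h$population, mortality = h$mortality,
    breathing_rate = h$breathing_rate,
    intake_fraction = unlist(h$intake_fraction),
    rr10 = h$rr10, c0 = h$c0 %||% 0, yll_per_death = h$yll_per_death,
    erf_form = h$erf_form %||% "loglinear")
  bundle$weights <- cfg$weights
  bundle$horizon <- seq(cfg$horizon$start, cfg$horizon$end)
  bundle$age_threshold <- cfg$age_threshold %||% 30
  bundle$dists <- lapply(cfg$dists %||% list(), function(d) {
    input_distribution(name = d$name, dist = d$dist,
                       params = unlist(d$params), target = d$target,
                       selector = d$selector, kind = d$kind %||% "scale",
                       lower = d$lower %||% -Inf, upper = d$upper %||% Inf)
  })
  validate_bundle(bundle)
  bundle
}

#' Scenario comparison report
#'
#' Renders the disease burden per year and decision-option combination —
#' the standard policy-comparison layout — plus per-pollutant emission
#' trajectories, as plain data frames (written as CSV and a small markdown
#' summary by the command-line interface).
#'
#' @param outputs result list from [run_model()].
#' @param years years to tabulate (default: all in the output).
#' @return List with data frames `burden` (one row per year x combination)
#'   and `emissions` (per year x pollutant totals); both empty with a notice
#'   attribute if the outputs are empty.
#' @export
report_outputs <- function(outputs, years = NULL) {
  daly <- outputs$daly
  if (is.null(daly) || nrow(daly) == 0L) {
    out <- list(burden = data.frame(), emissions = data.frame())
    attr(out, "notice") <- "empty outputs: nothing to report"
    return(out)
  }
  if ("Iteration" %in% names(daly)) {
    daly <- it_aggregate(daly, keep = setdiff(index_names(daly), "Iteration"),
                         how = "mean", drop_iteration = TRUE)
  }
  df <- as.data.frame(daly)
  if (!is.null(years)) df <- df[df$Time %in% years, , drop = FALSE]
  dec <- scenario_index_of(daly)
  names(df)[names(df) == "Result"] <- "DALY_per_a"
  df <- df[do.call(order, df[c("Time", dec)]), , drop = FALSE]
  rownames(df) <- NULL
  em <- outputs$emissions
  keep <- intersect(c("Time", "Pollutant"), names(em))
  if ("Iteration" %in% names(em)) {
    em <- it_aggregate(em, keep = keep, how = "mean", drop_iteration = TRUE)
  } else {
    em <- it_aggregate(em, keep = keep)
  }
  emdf <- as.data.frame(em)
  if (!is.null(years)) emdf <- emdf[emdf$Time %in% years, , drop = FALSE]
  names(emdf)[names(emdf) == "Result"] <- "tonnes_per_a"
  rownames(emdf) <- NULL
  list(burden = df, emissions = emdf)
}

#' Run manifest
#'
#' A JSON record sufficient to reproduce a run: input directory content hash,
#' mode, seed, iteration count and package/R versions.
#'
#' @param dir input bundle directory.
#' @param mode,seed,n_iter run settings.
#' @param out_path where to write the manifest JSON.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(dir, mode, seed, n_iter, out_path) {
  files <- sort(list.files(dir, full.names = TRUE, recursive = TRUE))
  hash <- vapply(files, function(f)
    unname(tools::md5sum(f)), character(1L))
  man <- list(inputs = stats::setNames(as.list(unname(hash)),
                                       basename(files)),
              mode = mode, seed = seed, n_iter = n_iter,
              r_version = as.character(getRversion()),
              package_version = as.character(
                utils::packageVersion("heatburden")),
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, out_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}
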