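# CSV dialect, pipeline orchestration and JSON reports.
#
# The on-disk table format is deliberately plain: comma-separated, decimal
# point, UTF-8, one header row. Concentration columns are micromolar
# throughout; `units` on ingest converts nM or M columns.

VELOCITY_COLS <- c("substrate_uM", "inhibitor_uM", "replicate", "velocity")

#' Read and write velocity tables as CSV
#'
#' `read_velocity_csv()` reads a long-format velocity table with mandatory
#' columns `substrate_uM`, `inhibitor_uM`, `replicate`, `velocity` and an
#' optional `inhibitor2_uM`; unknown columns are preserved. A missing
#' mandatory column raises a schema error naming it; a non-numeric cell
#' raises a parse error naming the row. `write_velocity_csv()` writes a
#' table such that a read-back reproduces it.
#'
#' @param path File path.
#' @param units Unit of the concentration columns in the file: `"uM"`
#'   (default), `"nM"` or `"M"`; values are converted to uM on ingest.
#' @param table A velocity table (data frame).
#' @return `read_velocity_csv()` returns a `velocity_table` data frame;
#'   `write_velocity_csv()` returns `path` invisibly.
#' @export
read_velocity_csv <- function(path, units = c("uM", "nM", "M")) {
  units <- match.arg(units)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(VELOCITY_COLS, names(raw))
  if (length(missing_cols))
    stop_inhibkin(paste0("missing mandatory column(s): ",
                         paste(missing_cols, collapse = ", ")), "schema_error")
  num_cols <- intersect(c(VELOCITY_COLS, "inhibitor2_uM"), names(raw))
  for (cl in num_cols) {
    vals <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(vals) & !is.na(raw[[cl]]) & nzchar(trimws(raw[[cl]])))
    if (length(bad))
      stop_inhibkin(sprintf("non-numeric value '%s' in column '%s', data row %d",
                            raw[[cl]][bad[1]], cl, bad[1]), "parse_error")
    raw[[cl]] <- vals
  }
  extra <- setdiff(names(raw), num_cols)
  for (cl in extra)
    raw[[cl]] <- utils::type.convert(raw[[cl]], as.is = TRUE)
  scale <- switch(units, uM = 1, nM = 1e-3, M = 1e6)
  for (cl in intersect(c("substrate_uM", "inhibitor_uM", "inhibitor2_uM"),
                       names(raw)))
    raw[[cl]] <- raw[[cl]] * scale
  structure(raw, class = c("velocity_table", "data.frame"), source = path)
}

#' @rdname read_velocity_csv
#' @export
write_velocity_csv <- function(table, path) {
  if (!is.data.frame(table))
    stop_inhibkin("'table' must be a data frame", "schema_error")
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Strip S3 baggage so a fit serialises to plain JSON.
report_fit <- function(f) {
  if (inherits(f, "mixed_inhibition_fit"))
    list(model = f$model_label,
         Km = f$mm$Km, Vmax = f$mm$Vmax,
         Ki = f$inhib$Ki, alpha = f$inhib$alpha,
         se = as.list(f$se), rss = f$rss, aic = f$aic, n_obs = f$n_obs)
  else if (inherits(f, "potency_fit"))
    list(bottom_mode = f$bottom_mode,
         pIC50 = f$params$pIC50, ic50_uM = f$ic50_uM,
         hill_slope = f$params$hill_slope,
         top = f$params$top, bottom = f$params$bottom,
         se = as.list(f$se), rss = f$rss, aic = f$aic, n_obs = f$n_obs)
  else f
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analysis stages in the usual order -- potency,
#' inhibition kinetics with model selection, Dixon median-intersection Ki,
#' and two-inhibitor exclusivity -- on either an input CSV or a simulated
#' dataset, and returns (optionally writes) a JSON-serialisable report.
#'
#' @param config A list with entries:
#'   * `input`: path to a velocity CSV, or
#'   * `simulation`: a [simulation_config()] (one of the two is required);
#'   * `analyses`: character subset of `c("potency", "kinetics", "dixon",
#'     "exclusivity")`;
#'   * `potency_params`: [potency_params()] used when `"potency"` is
#'     requested on simulated data (a concentration-response table is
#'     generated from the same simulation settings);
#'   * `out`: optional path for the JSON report.
#'   Alternatively a path to a YAML file with the same structure (requires
#'   the yaml package).
#' @return An `analysis_report` list: provenance, per-stage results,
#'   package version, configuration echo and timestamp.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_inhibkin("reading a YAML config requires the 'yaml' package",
                    "config_error")
    cfg <- yaml::read_yaml(config)
    if (!is.null(cfg$simulation))
      cfg$simulation <- do.call(simulation_config, cfg$simulation)
    if (!is.null(cfg$potency_params))
      cfg$potency_params <- do.call(potency_params, cfg$potency_params)
    config <- cfg
  }
  if (!is.list(config))
    stop_inhibkin("'config' must be a list or a YAML path", "config_error")
  analyses <- config$analyses %||% c("kinetics", "dixon")
  bad <- setdiff(analyses, c("potency", "kinetics", "dixon", "exclusivity"))
  if (length(bad))
    stop_inhibkin(paste0("unknown analysis stage(s): ",
                         paste(bad, collapse = ", ")), "config_error")

  if (!is.null(config$input)) {
    table <- read_velocity_csv(config$input)
    provenance <- list(type = "file", path = config$input)
  } else if (!is.null(config$simulation)) {
    table <- simulate_velocity_table(config$simulation)
    provenance <- list(type = "simulation",
                       seed = config$simulation$seed,
                       model = config$simulation$model)
  } else {
    stop_inhibkin("config needs either 'input' or 'simulation'", "config_error")
  }

  results <- list()

  if ("potency" %in% analyses) {
    if (!is.null(config$simulation) && !is.null(config$potency_params)) {
      cr <- simulate_conc_response(config$simulation, config$potency_params)
    } else if (all(c("inhibitor_uM", "response") %in% names(table))) {
      cr <- table
    } else {
      stop_inhibkin(
        "potency stage needs a response table or simulated potency parameters",
        "config_error")
    }
    results$potency <- report_fit(fit_potency(cr))
  }

  if (any(c("kinetics", "dixon") %in% analyses) &&
      length(unique(table$substrate_uM)) < 2L)
    stop_inhibkin("kinetics/Dixon stages need multi-substrate data",
                  "config_error")

  if ("kinetics" %in% analyses) {
    cmp <- fit_inhibition_kinetics(table)
    results$kinetics <- list(
      selected = cmp$candidates[[cmp$selected]]$model_label,
      delta_aic = cmp$delta_aic,
      fits = lapply(cmp$candidates, report_fit))
  }

  if ("dixon" %in% analyses) {
    fam <- build_dixon_family(table)
    xs <- pairwise_intersections(fam)
    ki <- median_intersection_ki(xs)
    results$dixon <- list(
      n_lines = length(fam$lines),
      n_intersections = nrow(xs$pairs),
      n_excluded = nrow(xs$excluded_pairs),
      ki_uM = ki$ki, median_y = ki$median_y)
  }

  if ("exclusivity" %in% analyses) {
    if (!"inhibitor2_uM" %in% names(table))
      stop_inhibkin("exclusivity stage needs a two-inhibitor table ('inhibitor2_uM')",
                    "config_error")
    ex <- exclusivity_analysis(table)
    results$exclusivity <- list(
      verdict = ex$verdict,
      p_value = ex$statistic$p_value,
      delta_aic = ex$statistic$delta_aic,
      slopes = ex$free_slope_fit$slopes,
      common_slope = ex$common_slope_fit$slope)
  }

  report <- list(
    provenance = provenance,
    results = results,
    version = as.character(utils::packageVersion("inhibkin")),
    config = list(analyses = analyses),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  class(report) <- "analysis_report"
  if (!is.null(config$out)) {
    jsonlite::write_json(unclass(report), config$out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report (", x$timestamp, ")\n", sep = "")
  cat("  input:", x$provenance$type, "\n")
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat("  ", nm, ": ", sep = "")
    if (nm == "kinetics") cat("selected", r$selected, "model\n")
    else if (nm == "dixon")
      cat(sprintf("Ki = %.3g uM from %d intersections\n", r$ki_uM,
                  r$n_intersections))
    else if (nm == "exclusivity") cat("verdict", r$verdict, "\n")
    else if (nm == "potency")
      cat(sprintf("pIC50 = %.3g (IC50 = %.3g uM)\n", r$pIC50, r$ic50_uM))
  }
  invisible(x)
}
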