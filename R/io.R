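# CSV dialects, result-record serialization and the simulate -> fit ->
# report pipeline. Matrix CSVs carry the wavelength grid in the first column
# and one data column per concentration (header = mM) or time point
# (header = s). pH traces are time_s/pH columns with '#'-prefixed event
# markers. Panels are long-format CSV.

write_matrix_csv <- function(wavelengths_nm, headers, mat, path) {
  df <- data.frame(wavelength_nm = wavelengths_nm, mat)
  names(df) <- c("wavelength_nm", format(headers, scientific = TRUE,
                                         trim = TRUE, digits = 15))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a titration series to CSV
#'
#' First column `wavelength_nm`; one column per concentration with the
#' concentration in mM as header.
#'
#' @param series a [spectrum_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "spectrum_series"))
  write_matrix_csv(series$wavelengths_nm, series$concentrations_mM,
                   series$absorbance, path)
}

#' Write a transient dataset to CSV
#'
#' First column `wavelength_nm`; one column per time point with the time in
#' seconds as header.
#'
#' @param data a [transient_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transient_csv <- function(data, path) {
  stopifnot(inherits(data, "transient_dataset"))
  write_matrix_csv(data$wavelengths_nm, data$times_s, data$deltaA, path)
}

#' Read a titration or transient matrix CSV
#'
#' Parses the dialect written by [write_titration_csv()] /
#' [write_transient_csv()]: numeric header values (concentrations in mM or
#' times in s), numeric cells, no missing values. Duplicate header values,
#' ragged rows and non-numeric cells are errors naming the offending
#' row/column; out-of-order grids are re-sorted with a warning. CRLF files
#' parse identically to LF.
#'
#' @param path CSV file.
#' @param kind `"titration"` or `"transient"`.
#' @return a [spectrum_series()] or [transient_dataset()].
#' @export
read_matrix_csv <- function(path, kind = c("titration", "transient")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("matrix CSV needs a header and data rows", call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 2) stop("matrix CSV needs at least one data column", call. = FALSE)
  vals <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(vals)) {
    stop(sprintf("non-numeric header in column %d: '%s'",
                 which(is.na(vals))[1] + 1, header[-1][which(is.na(vals))[1]]),
         call. = FALSE)
  }
  if (anyDuplicated(vals)) {
    stop(sprintf("duplicated header value in column %d",
                 which(duplicated(vals))[1] + 1), call. = FALSE)
  }
  rows <- strsplit(lines[-1], ",", fixed = TRUE)
  nc <- length(header)
  bad <- which(lengths(rows) != nc)
  if (length(bad)) {
    stop(sprintf("ragged row %d: expected %d fields, found %d",
                 bad[1] + 1, nc, lengths(rows)[bad[1]]), call. = FALSE)
  }
  num <- suppressWarnings(
    matrix(as.numeric(unlist(rows)), nrow = length(rows), ncol = nc,
           byrow = TRUE)
  )
  if (anyNA(num)) {
    at <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d, column %d", at[1] + 1, at[2]),
         call. = FALSE)
  }
  wl <- num[, 1]
  mat <- num[, -1, drop = FALSE]
  if (is.unsorted(wl, strictly = TRUE)) {
    warning("wavelength grid not ascending; re-sorting", call. = FALSE)
    o <- order(wl)
    wl <- wl[o]; mat <- mat[o, , drop = FALSE]
  }
  if (is.unsorted(vals, strictly = TRUE)) {
    warning("column grid not ascending; re-sorting", call. = FALSE)
    o <- order(vals)
    vals <- vals[o]; mat <- mat[, o, drop = FALSE]
  }
  if (kind == "titration") {
    spectrum_series(wl, vals, mat)
  } else {
    transient_dataset(wl, vals, mat)
  }
}

#' Write a pH trace to CSV
#'
#' Columns `time_s`, `pH`, preceded by `#`-prefixed light-on/light-off
#' marker lines.
#'
#' @param trace a [ph_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ph_csv <- function(trace, path) {
  stopifnot(inherits(trace, "ph_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# light_on_s: %.15g", trace$light_on_s),
               sprintf("# light_off_s: %.15g", trace$light_off_s),
               "time_s,pH"), con)
  writeLines(sprintf("%.15g,%.15g", trace$times_s, trace$pH), con)
  invisible(path)
}

#' Read a pH trace CSV written by [write_ph_csv()]
#'
#' @param path CSV file with `# light_on_s:` / `# light_off_s:` markers.
#' @return a [ph_trace()].
#' @export
read_ph_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  markers <- grep("^#", lines, value = TRUE)
  get_marker <- function(name) {
    hit <- grep(paste0("^#\\s*", name, ":"), markers, value = TRUE)
    if (!length(hit)) stop(sprintf("missing marker '%s'", name), call. = FALSE)
    as.numeric(sub(".*:", "", hit[1]))
  }
  body <- utils::read.csv(text = paste(grep("^#", lines, invert = TRUE,
                                            value = TRUE), collapse = "\n"))
  ph_trace(body$time_s, body$pH, get_marker("light_on_s"),
           get_marker("light_off_s"))
}

#' Write a mutant panel to long-format CSV
#'
#' Columns `mutant`, `anion`, `replicate`, `slope`, `expression`.
#'
#' @param panel a [mutant_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  panel <- mutant_panel(panel)
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format mutant panel CSV
#'
#' @param path CSV written by [write_panel_csv()].
#' @return a [mutant_panel()].
#' @export
read_panel_csv <- function(path) {
  mutant_panel(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Build a result record for one pipeline stage
#'
#' @param stage stage name.
#' @param inputs named character vector/list of input file paths; stored
#'   with their md5 digests.
#' @param parameters list echoed verbatim.
#' @param outputs stage-specific payload (must be JSON-serializable).
#' @param seed seed used by the stage (or `NULL`).
#' @return object of class `result_record`.
#' @export
result_record <- function(stage, inputs = list(), parameters = list(),
                          outputs = list(), seed = NULL) {
  digests <- lapply(inputs, function(p) {
    if (is.character(p) && file.exists(p)) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    } else {
      list(path = as.character(p), md5 = NA_character_)
    }
  })
  structure(
    list(stage = stage, inputs = digests, parameters = parameters,
         outputs = outputs, seed = seed,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "result_record"
  )
}

#' Serialize a result record (or any fit result) to JSON
#'
#' @param record a `result_record` or plain list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(record, path) {
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a result record JSON
#'
#' @param path JSON file written by [write_result_json()].
#' @return list (class `result_record` when the stage field is present).
#' @export
read_result_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(rec$stage)) class(rec) <- "result_record"
  rec
}

#' Validate a result record against the shipped schema description
#'
#' The schema (inst/extdata/result_record_schema.json) lists the required
#' fields and their types.
#'
#' @param record a `result_record` (or list read from JSON).
#' @return `TRUE` invisibly, or an error naming the missing field.
#' @export
validate_record <- function(record) {
  schema <- jsonlite::read_json(
    system.file("extdata", "result_record_schema.json", package = "halopump",
                mustWork = TRUE),
    simplifyVector = TRUE
  )
  for (field in schema$required) {
    if (is.null(record[[field]])) {
      stop(sprintf("result record is missing required field '%s'", field),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

summary_of_fit <- function(fit) {
  if (inherits(fit, "hill_fit")) {
    out <- list(model_kind = fit$model_kind, rss = fit$rss, aicc = fit$aicc,
                converged = fit$converged)
    if (fit$model_kind == "one_site") {
      out$Kd_mM <- fit$Kd_mM
    } else {
      out$Kd1_mM <- fit$Kd1_mM
      out$Kd2_mM <- fit$Kd2_mM
      out$Vmax1 <- fit$Vmax1
    }
    out
  } else if (inherits(fit, "global_fit")) {
    list(tau_s = fit$scheme$tau_s, labels = fit$scheme$labels, rss = fit$rss,
         converged = fit$converged, degenerate = fit$degenerate)
  } else {
    unclass(fit)
  }
}

#' Run a declarative simulate -> fit -> report pipeline
#'
#' The config (YAML file or equivalent list) declares datasets, each with a
#' scenario (catalog `name` or inline definition), an `analysis` kind and an
#' optional `seed` override. Each dataset is simulated, written as CSV,
#' analyzed, and summarized in a JSON result record. Deterministic for fixed
#' seeds.
#'
#' @param config path to a YAML pipeline config, or the equivalent list. Top
#'   level: `datasets`, a list of entries with fields `name`,
#'   `scenario` (catalog name) or `scenario_file`, `analysis`
#'   (`"binding"`, `"photocycle"` or `"transport-panel"`), optional `seed`
#'   and analysis options (`n_exp`, `model`).
#' @param out_dir output directory (created if needed).
#' @return named list of `result_record`s, invisibly; records and CSVs are
#'   written under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$datasets) || !length(cfg$datasets)) {
    stop("pipeline config must declare at least one dataset", call. = FALSE)
  }
  # Validate every scenario before any compute
  specs <- lapply(cfg$datasets, function(ds) {
    if (is.null(ds$name)) stop("dataset entry without a name", call. = FALSE)
    sc <- if (!is.null(ds$scenario_file)) {
      read_scenario(ds$scenario_file)
    } else if (!is.null(ds$scenario)) {
      scenario(ds$scenario)
    } else {
      stop(sprintf("dataset '%s': no scenario given", ds$name), call. = FALSE)
    }
    if (!is.null(ds$seed)) sc <- scenario_modify(sc, seed = ds$seed)
    list(ds = ds, sc = sc)
  })
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- list()
  for (spec in specs) {
    ds <- spec$ds
    sc <- spec$sc
    rec <- tryCatch(
      run_pipeline_stage(ds, sc, out_dir),
      error = function(e) {
        stop(sprintf("pipeline stage '%s' failed: %s", ds$name,
                     conditionMessage(e)), call. = FALSE)
      }
    )
    records[[ds$name]] <- rec
    write_result_json(rec, file.path(out_dir, paste0(ds$name, ".json")))
  }
  invisible(records)
}

run_pipeline_stage <- function(ds, sc, out_dir) {
  analysis <- if (is.null(ds$analysis)) {
    switch(class(sc)[1],
           titration_scenario = "binding",
           photocycle_scenario = "photocycle",
           panel_scenario = "transport-panel",
           transport_scenario = "transport-trace")
  } else ds$analysis
  csv <- file.path(out_dir, paste0(ds$name, ".csv"))
  if (analysis == "binding") {
    series <- gen_titration(sc)
    write_titration_csv(series, csv)
    curve <- extract_curve(series)
    fit <- switch(if (is.null(ds$model)) "auto" else ds$model,
                  auto = select_model(curve),
                  one = fit_one_site(curve),
                  two = fit_two_site(curve))
    outputs <- c(summary_of_fit(fit),
                 list(peak_wavelength_nm = curve$peak_wavelength_nm,
                      shift = classify_shift(difference_spectra(series),
                                             series$wavelengths_nm)))
  } else if (analysis == "photocycle") {
    data <- gen_transient(sc)
    write_transient_csv(data, csv)
    n_exp <- if (is.null(ds$n_exp)) length(sc$tau_s) else ds$n_exp
    fit <- assign_intermediates(fit_global(data, n_exp))
    o <- detect_o_accumulation(fit)
    outputs <- c(summary_of_fit(fit),
                 list(o_accumulating = o$accumulating, o_score = o$score))
  } else if (analysis == "transport-panel") {
    panel <- gen_mutant_panel(sc)
    write_panel_csv(panel, csv)
    corr <- correlate_anions(panel)
    outputs <- list(normalized = normalize_panel(panel),
                    correlation = unclass(corr))
  } else if (analysis == "transport-trace") {
    trace <- gen_ph_trace(sc)
    write_ph_csv(trace, csv)
    act <- initial_slope(trace)
    outputs <- unclass(act)
  } else {
    stop(sprintf("unknown analysis kind '%s'", analysis), call. = FALSE)
  }
  result_record(
    stage = analysis,
    inputs = list(data = csv),
    parameters = list(scenario = if (!is.null(ds$scenario)) ds$scenario else
      class(sc)[1]),
    outputs = outputs,
    seed = sc$seed
  )
}
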