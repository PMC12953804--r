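minute_csv_header <- c("minute", "MAP", "ICP", "CPP", "PbtO2", "AMP",
                       "PRx", "PAx", "RAC", "RAP")

#' Read / write a minute-by-minute patient CSV
#'
#' The canonical per-patient exchange format: header exactly
#' `minute,MAP,ICP,CPP,PbtO2,AMP,PRx,PAx,RAC,RAP`, `minute` a 0-based
#' integer, missing values as empty fields. Reading validates the header
#' and rejects extra or misnamed columns by name; write-then-read
#' round-trips exactly.
#'
#' @param path File path.
#' @return `load_minute_csv()` returns the minute tibble.
#' @export
load_minute_csv <- function(path) {
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  extra <- setdiff(header, minute_csv_header)
  missing_cols <- setdiff(minute_csv_header, header)
  if (length(extra) || length(missing_cols)) {
    stopf("minute CSV header mismatch in %s:%s%s", basename(path),
          if (length(missing_cols))
            sprintf(" missing column(s) %s.",
                    paste(missing_cols, collapse = ", ")) else "",
          if (length(extra))
            sprintf(" unexpected column(s) %s.",
                    paste(extra, collapse = ", ")) else "")
  }
  out <- readr::read_csv(
    path,
    col_types = readr::cols(minute = readr::col_integer(),
                            .default = readr::col_double()),
    na = c("", "NA"), show_col_types = FALSE)
  problems <- readr::problems(out)
  if (nrow(problems)) {
    stopf("malformed minute CSV %s: first problem at line %d (%s)",
          basename(path), problems$row[1], problems$expected[1])
  }
  if (nrow(out) == 0L) warning(sprintf("minute CSV %s has no data rows",
                                       basename(path)), call. = FALSE)
  out[minute_csv_header]
}

#' @rdname load_minute_csv
#' @param table Minute tibble as produced by [derive_minute_record()].
#' @export
write_minute_csv <- function(table, path) {
  if (!all(minute_csv_header %in% names(table))) {
    stopf("`table` must carry the minute-record columns")
  }
  readr::write_csv(table[minute_csv_header], path, na = "")
  invisible(path)
}

#' Configuration of a benchmark run
#'
#' Validates and freezes every knob of the resolution-sweep experiment
#' before any work starts.
#'
#' @param cohort Either a named list of minute tibbles (one per patient) or
#'   a synthetic-cohort spec: `list(n_patients =, duration =, ...)` with
#'   `...` forwarded to [sim_config()] via [simulate_cohort()].
#' @param signals Subset of [signal_names()].
#' @param resolutions Subset of [resolution_ladder()], in minutes.
#' @param methods Subset of `c("one_step", "blocked", "tss")`.
#' @param types Subset of `c("point", "interval")`; the blocked method is
#'   point-only and silently contributes no interval rows.
#' @param p_range,d_range,q_range ARIMA order grid (defaults: the full
#'   grid, `p` 1..10, `d` 0..2, `q` 0..10).
#' @param horizon Interval-forecast length (default 5).
#' @param level Prediction-interval coverage (default 0.95).
#' @param n_folds Number of folds / splits (default 5).
#' @param min_points Minimum series length (after reduction and gap
#'   handling, longest segment) for a (signal, resolution) cell to be
#'   analysed; shorter series are skipped with a logged reason
#'   (default 30).
#' @param seed Master seed for synthetic cohorts.
#' @param out_dir Optional output directory; when set, `metrics.csv`,
#'   `summary_<method>_<type>.csv`, `diagnostics.csv` and `manifest.json`
#'   are written there (plus `traces/` when `save_traces`).
#' @param save_traces Write per-cell prediction traces as CSV.
#' @return A validated `run_config` object.
#' @export
run_config <- function(cohort,
                       signals = signal_names(),
                       resolutions = resolution_ladder(),
                       methods = c("one_step", "blocked", "tss"),
                       types = c("point", "interval"),
                       p_range = 1:10, d_range = 0:2, q_range = 0:10,
                       horizon = 5L, level = 0.95, n_folds = 5L,
                       min_points = 30L, seed = 1L, out_dir = NULL,
                       save_traces = FALSE) {
  if (!all(signals %in% signal_names())) {
    stopf("unknown signal(s): %s",
          paste(setdiff(signals, signal_names()), collapse = ", "))
  }
  if (!all(resolutions %in% resolution_ladder())) {
    stopf("resolution(s) %s not on the supported ladder (%s)",
          paste(setdiff(resolutions, resolution_ladder()), collapse = ", "),
          paste(resolution_ladder(), collapse = ", "))
  }
  if (!all(methods %in% c("one_step", "blocked", "tss"))) {
    stopf("unknown method(s): %s",
          paste(setdiff(methods, c("one_step", "blocked", "tss")),
                collapse = ", "))
  }
  if (!all(types %in% c("point", "interval"))) {
    stopf("unknown prediction type(s): %s",
          paste(setdiff(types, c("point", "interval")), collapse = ", "))
  }
  if (!all(p_range %in% 1:10) || !all(d_range %in% 0:2) ||
      !all(q_range %in% 0:10)) {
    stopf("order grid outside the supported bounds (p 1..10, d 0..2, q 0..10)")
  }
  if (horizon < 1L) stopf("`horizon` must be >= 1")
  if (level <= 0 || level >= 1) stopf("`level` must be in (0, 1)")
  synthetic <- !is.null(cohort$n_patients)
  if (!synthetic) {
    if (!is.list(cohort) || !length(cohort) ||
        !all(purrr::map_lgl(cohort, is.data.frame))) {
      stopf("`cohort` must be a named list of minute tibbles or a synthetic spec with `n_patients`")
    }
    if (is.null(names(cohort)) || any(names(cohort) == "")) {
      names(cohort) <- sprintf("P%03d", seq_along(cohort))
    }
  }
  structure(
    list(cohort = cohort, synthetic = synthetic, signals = signals,
         resolutions = as.integer(resolutions), methods = methods,
         types = types, p_range = as.integer(p_range),
         d_range = as.integer(d_range), q_range = as.integer(q_range),
         horizon = as.integer(horizon), level = level,
         n_folds = as.integer(n_folds), min_points = as.integer(min_points),
         seed = as.integer(seed), out_dir = out_dir,
         save_traces = isTRUE(save_traces)),
    class = "run_config")
}

#' Run the full resolution-sweep forecasting benchmark
#'
#' For every patient x signal x resolution x method x prediction type:
#' reduce the minute series to the working resolution, apply the gap rules,
#' model the longest contiguous segment, run the cross-validated ARIMA
#' prediction, and collect MAE/RMSE/R-squared/CI-spread metric rows, plus
#' ADF/KPSS diagnostics per cell. Failures are isolated per cell and
#' logged; the run aborts only on configuration errors. Identical config +
#' seed reruns are byte-identical.
#'
#' @param config A [run_config()].
#' @return A `benchmark_result`: list with `metrics` (per-cell rows),
#'   `summary` (cohort aggregation), `diagnostics`, `skipped`, `log`,
#'   `traces` (when requested) and the `config`. Files are written when
#'   `out_dir` is set.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  minutes <- if (config$synthetic) {
    spec <- config$cohort
    args <- spec[setdiff(names(spec), c("n_patients", "duration"))]
    records <- do.call(simulate_cohort,
                       c(list(n_patients = spec$n_patients,
                              duration = spec$duration %||% 720,
                              seed = config$seed), args))
    purrr::map(records, derive_minute_record)
  } else {
    config$cohort
  }
  t_cohort <- proc.time()[["elapsed"]] - t0

  metric_rows <- list()
  diag_rows <- list()
  skip_rows <- list()
  log_rows <- list()
  traces <- list()

  for (pid in names(minutes)) {
    tbl <- minutes[[pid]]
    for (sig in config$signals) {
      minute_values <- tbl[[sig]]
      for (res in config$resolutions) {
        series <- reduce_resolution(minute_values, res, signal_name = sig) |>
          handle_gaps()
        seg <- longest_segment(series)
        cell <- sprintf("%s/%s/%dmin", pid, sig, res)
        if (length(seg) < config$min_points) {
          skip_rows[[length(skip_rows) + 1L]] <- tibble::tibble(
            patient_id = pid, signal = sig, resolution = res,
            n_points = length(seg),
            reason = sprintf("longest segment %d < min_points %d",
                             length(seg), config$min_points))
          next
        }
        if (length(seg) >= 20 && var(seg) > 0) {
          diag_rows[[length(diag_rows) + 1L]] <- dplyr::bind_cols(
            tibble::tibble(patient_id = pid, signal = sig,
                           resolution = res),
            stationarity_report(seg))
        }
        for (method in config$methods) {
          for (type in config$types) {
            if (type == "interval" && method == "blocked") next
            run <- tryCatch({
              tr <- if (type == "point") {
                plan <- switch(method,
                  one_step = one_step_folds(length(seg),
                                            n_folds = config$n_folds),
                  blocked = blocked_folds(length(seg),
                                          n_folds = config$n_folds),
                  tss = tss_folds(length(seg), n_splits = config$n_folds))
                run_point_cv(seg, plan, config$p_range, config$d_range,
                             config$q_range)
              } else {
                run_interval_cv(seg, method = method,
                                horizon = config$horizon,
                                level = config$level,
                                n_folds = config$n_folds,
                                p_range = config$p_range,
                                d_range = config$d_range,
                                q_range = config$q_range)
              }
              tr
            }, error = function(e) e)
            if (inherits(run, "error")) {
              log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
                cell = cell, method = method, type = type,
                message = conditionMessage(run))
              next
            }
            metric_rows[[length(metric_rows) + 1L]] <- dplyr::bind_cols(
              tibble::tibble(patient_id = pid, signal = sig,
                             resolution = res, method = method,
                             prediction_type = type),
              evaluate_trace(run),
              tibble::tibble(
                train_seconds = attr(run, "train_seconds"),
                test_seconds = attr(run, "test_seconds")))
            if (config$save_traces) {
              traces[[sprintf("%s_%s_%s", cell, method, type)]] <- run
            }
          }
        }
      }
    }
  }

  metrics <- dplyr::bind_rows(metric_rows)
  summary <- summarize_cohort(metrics)
  diagnostics <- dplyr::bind_rows(diag_rows)
  skipped <- dplyr::bind_rows(skip_rows)
  log <- dplyr::bind_rows(log_rows)

  result <- structure(
    list(metrics = metrics, summary = summary, diagnostics = diagnostics,
         skipped = skipped, log = log,
         traces = if (config$save_traces) traces else NULL,
         config = config,
         elapsed = c(cohort = t_cohort,
                     total = proc.time()[["elapsed"]] - t0)),
    class = "benchmark_result")

  if (!is.null(config$out_dir)) write_benchmark(result, config$out_dir)
  result
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(
    "<benchmark_result> %d metric rows (%d skipped cells, %d failures) in %.1f s\n",
    nrow(x$metrics), nrow(x$skipped), nrow(x$log), x$elapsed[["total"]]))
  invisible(x)
}

write_benchmark <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # timing columns are wall-clock and go to timings.csv; metrics.csv stays
  # byte-identical across same-seed reruns
  readr::write_csv(
    dplyr::select(result$metrics, -dplyr::any_of(c("train_seconds",
                                                   "test_seconds"))),
    file.path(out_dir, "metrics.csv"), na = "")
  if (nrow(result$metrics)) {
    readr::write_csv(
      dplyr::select(result$metrics, dplyr::all_of(c(
        "patient_id", "signal", "resolution", "method", "prediction_type",
        "train_seconds", "test_seconds"))),
      file.path(out_dir, "timings.csv"), na = "")
  }
  if (nrow(result$diagnostics)) {
    readr::write_csv(result$diagnostics,
                     file.path(out_dir, "diagnostics.csv"), na = "")
  }
  for (m in unique(result$summary$method)) {
    for (ty in unique(result$summary$prediction_type[
      result$summary$method == m])) {
      readr::write_csv(summary_table(result$summary, m, ty),
                       file.path(out_dir,
                                 sprintf("summary_%s_%s.csv", m, ty)),
                       na = "")
    }
  }
  if (!is.null(result$traces)) {
    tdir <- file.path(out_dir, "traces")
    dir.create(tdir, showWarnings = FALSE)
    for (nm in names(result$traces)) {
      readr::write_csv(result$traces[[nm]],
                       file.path(tdir, paste0(gsub("/", "_", nm), ".csv")),
                       na = "")
    }
  }
  cfg <- result$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("neurocast")),
    seed = cfg$seed,
    synthetic_cohort = cfg$synthetic,
    cohort_spec = if (cfg$synthetic) cfg$cohort else
      list(n_patients = length(cfg$cohort)),
    signals = cfg$signals, resolutions = cfg$resolutions,
    methods = cfg$methods, types = cfg$types,
    grid = list(p = cfg$p_range, d = cfg$d_range, q = cfg$q_range),
    horizon = cfg$horizon, level = cfg$level, n_folds = cfg$n_folds,
    min_points = cfg$min_points,
    elapsed_seconds = as.list(result$elapsed))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
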