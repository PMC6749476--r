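#' Pipeline run configuration
#'
#' Bundles all stage settings under one top-level seed. Per-stage seeds are
#' derived deterministically via [derive_seed()], so any stage can be re-run
#' in isolation and an identical configuration always yields identical
#' outputs.
#'
#' @param seed Top-level integer seed (always present; default 1).
#' @param synth A [synth_config()] for the simulate stage, or `NULL` to read
#'   trial CSVs from `input_dir` instead. The default simulates 36 streams of
#'   which 9 carry faulty blocks, so the QC stage retains 27. The synth seed
#'   is re-derived from `seed`.
#' @param input_dir Directory of trial CSVs (used when `synth` is `NULL`).
#' @param signals Either `NULL` to run the four-criterion selection, or a
#'   character vector forcing the model inputs (selection stage skipped).
#' @param availability_threshold,r_threshold,relevance_floor Selection
#'   thresholds, see [select_inputs()].
#' @param n_repeats,n_validation Cross-validation shape.
#' @param outlier_limit Per-pair absolute error bound, mg/dL.
#' @param ega_methods Error-grid analyses to run.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       synth = synth_config(n_streams = 36,
                                            n_faulty_streams = 9),
                       input_dir = NULL,
                       signals = NULL,
                       availability_threshold = 70,
                       r_threshold = 0.85,
                       relevance_floor = 0.05,
                       n_repeats = 20,
                       n_validation = 9,
                       outlier_limit = 100,
                       ega_methods = c("clarke", "parkes", "iso")) {
  stopifnot(availability_threshold >= 0, availability_threshold <= 100,
            r_threshold > 0, r_threshold <= 1, relevance_floor >= 0,
            n_repeats >= 1, n_validation >= 1)
  if (is.null(synth) && is.null(input_dir))
    stop("either a synth config or an input_dir is required")
  if (!is.null(synth)) {
    stopifnot(inherits(synth, "synth_config"))
    synth$seed <- derive_seed(seed, "simulate")
  }
  structure(list(seed = as.integer(seed), synth = synth,
                 input_dir = input_dir, signals = signals,
                 availability_threshold = availability_threshold,
                 r_threshold = r_threshold, relevance_floor = relevance_floor,
                 n_repeats = n_repeats, n_validation = n_validation,
                 outlier_limit = outlier_limit, ega_methods = ega_methods),
            class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file mirrors the [run_config()] (and nested [synth_config()])
#' arguments field by field; unknown fields are an error.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(raw$synth)) {
    for (fld in c("true_coefficients", "availability"))
      if (!is.null(raw$synth[[fld]])) raw$synth[[fld]] <- unlist(raw$synth[[fld]])
    raw$synth <- do.call(synth_config, raw$synth)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

write_csv_plain <- function(df, path) {
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Run the full correction pipeline
#'
#' Simulate (or ingest) -> quality control -> baseline removal -> input
#' selection -> model fit -> leave-nine-out cross-validation -> error-grid
#' report, writing every stage artifact plus a manifest into `out_dir`.
#' The run is fully determined by the configuration: the same config written
#' twice produces byte-identical outputs.
#'
#' Artifacts: `streams/*.csv` (simulated trials), `qc_log.csv`,
#' `baselines.csv`, `availability.csv`, `elimination_trace.json`,
#' `model.json` (fit on all retained data), `crossval_summary.csv`,
#' `crossval_per_repeat.csv`, `mard_table.csv`, `ega_<method>.csv`,
#' `manifest.json`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results (`streams`,
#'   `qc`, `baselines`, `trace`, `model`, `report`, `ega`, `manifest`).
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- simulate or ingest ---------------------------------------------------
  if (!is.null(config$synth)) {
    streams <- generate_cohort(config$synth)
    sdir <- file.path(out_dir, "streams")
    dir.create(sdir, showWarnings = FALSE)
    for (s in streams) write_trial(s, file.path(sdir, paste0(s$stream_id, ".csv")))
  } else {
    files <- sort(list.files(config$input_dir, pattern = "\\.csv$",
                             full.names = TRUE))
    if (!length(files))
      stop("ingest stage: no trial CSVs found in ", config$input_dir)
    streams <- lapply(files, read_trial)
  }

  # --- quality control ------------------------------------------------------
  qc <- qc_filter(streams)
  write_csv_plain(if (nrow(qc$log)) qc$log else
    data.frame(stream_id = character(0), reason = character(0)),
    file.path(out_dir, "qc_log.csv"))
  retained <- qc$retained
  if (!length(retained)) stop("qc stage: no streams retained")

  # --- preprocessing --------------------------------------------------------
  baselines <- baseline_table(retained)
  write_csv_plain(transform(baselines, baseline = fmt_num(baseline)),
                  file.path(out_dir, "baselines.csv"))
  prepped <- lapply(retained, remove_baseline, baselines = baselines)
  avail <- pooled_availability(prepped)
  write_csv_plain(data.frame(signal = names(avail),
                             availability_pct = sprintf("%.4f", avail)),
                  file.path(out_dir, "availability.csv"))

  # --- input selection ------------------------------------------------------
  if (is.null(config$signals)) {
    trace <- select_inputs(prepped,
                           availability_threshold = config$availability_threshold,
                           r_threshold = config$r_threshold,
                           relevance_floor = config$relevance_floor,
                           n_repeats = config$n_repeats,
                           n_validation = config$n_validation,
                           seed = derive_seed(config$seed, "select"),
                           outlier_limit = config$outlier_limit)
    signals <- trace$surviving
    write_trace(trace, file.path(out_dir, "elimination_trace.json"))
  } else {
    trace <- NULL
    signals <- config$signals
  }

  # --- model fit on all retained data --------------------------------------
  pairs <- do.call(rbind, lapply(prepped, pair_with_reference,
                                 outlier_limit = config$outlier_limit))
  cc <- stats::complete.cases(pairs[signals])
  model <- fit_zero_intercept(as.matrix(pairs[cc, signals, drop = FALSE]),
                              pairs$error[cc])
  write_model(model, file.path(out_dir, "model.json"))

  # --- cross-validation -----------------------------------------------------
  report <- crossvalidate(prepped, signals,
                          n_repeats = config$n_repeats,
                          n_validation = config$n_validation,
                          seed = derive_seed(config$seed, "crossvalidate"),
                          outlier_limit = config$outlier_limit)
  s <- report$summary
  write_csv_plain(data.frame(metric = names(s), value = sprintf("%.6f", s)),
                  file.path(out_dir, "crossval_summary.csv"))
  pr <- report$per_repeat
  pr[-1] <- lapply(pr[-1], function(x) sprintf("%.6f", x))
  write_csv_plain(pr, file.path(out_dir, "crossval_per_repeat.csv"))
  mard_tab <- data.frame(
    metric = c("MARD exercise", "MARD rest", "MARD total", "CV"),
    original_cgm = sprintf("%.2f", c(s["mard_exercise_cgm"], s["mard_rest_cgm"],
                                     s["mard_total_cgm"], s["cv_cgm"])),
    enhanced_cgm = sprintf("%.2f", c(s["mard_exercise_ecgm"], s["mard_rest_ecgm"],
                                     s["mard_total_ecgm"], s["cv_ecgm"])),
    p_value = sprintf("%.4g", report$p_values[c("mard_exercise", "mard_rest",
                                                "mard_total", "cv")]))
  write_csv_plain(mard_tab, file.path(out_dir, "mard_table.csv"))

  # --- error-grid analysis --------------------------------------------------
  ega <- lapply(config$ega_methods, function(m) zone_summary(report$pairs, m))
  names(ega) <- config$ega_methods
  for (m in config$ega_methods)
    write_csv_plain(ega[[m]], file.path(out_dir, paste0("ega_", m, ".csv")))

  # --- manifest -------------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE, null = "null")
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE), "manifest.json"))
  manifest <- list(
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    model_inputs = signals,
    n_streams_in = length(streams),
    n_streams_retained = length(retained),
    files = data.frame(file = files,
                       md5 = unname(tools::md5sum(file.path(out_dir, files)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(streams = streams, qc = qc, baselines = baselines,
                 availability = avail, trace = trace, model = model,
                 report = report, ega = ega, manifest = manifest,
                 signals = signals))
}
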