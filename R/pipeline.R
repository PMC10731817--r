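#' Analyze a COP recording end to end
#'
#' Runs the full chain on an in-memory recording: preprocessing, parameter
#' battery, anthropometric normalization, fidgety-movement classification and
#' MOS-R estimation. A MOS-R domain error (e.g. negative velocity skewness,
#' whose logarithm is undefined) degrades to a report without an estimate and
#' with the reason flagged; the classification is still emitted.
#'
#' @param rec A [cop_recording()].
#' @param cfg A [preprocess_config()].
#' @param scheme Normalization scheme (see [normalize_parameters()]).
#' @param fm_model An [fm_logistic_model()].
#' @param mosr_model A [mosr_linear_model()].
#' @param apen_cfg An [apen_config()].
#' @return An object of class `analysis_report`.
#' @export
analyze_recording <- function(rec, cfg = preprocess_config(),
                              scheme = "height_weight",
                              fm_model = fm_logistic_model(),
                              mosr_model = mosr_linear_model(),
                              apen_cfg = apen_config()) {
  p <- preprocess(rec, cfg)
  raw_params <- compute_parameters(p, apen_cfg)
  norm_params <- normalize_parameters(raw_params, scheme)
  classification <- fm_classify(norm_params, fm_model)
  v <- norm_params$values
  mosr <- tryCatch(
    c(mosr_predict(v[["instantaneous_velocity_std_R"]],
                   v[["instantaneous_velocity_skewness_R"]],
                   v[["approximate_entropy_R"]], mosr_model),
      list(flag = NA_character_)),
    error = function(e) list(log_prediction = NA_real_,
                             mosr_estimate = NA_real_, clamped = FALSE,
                             flag = conditionMessage(e)))
  structure(
    list(subject = rec$subject,
         preprocessing = list(n_analyzed = p$n_analyzed, fs = p$fs,
                              valid_fraction = p$valid_fraction,
                              cutoff = cfg$cutoff, order = cfg$order,
                              zero_phase = cfg$zero_phase,
                              trim_lead = cfg$trim_lead,
                              analysis_window = cfg$analysis_window),
         parameters_raw = raw_params,
         parameters = norm_params,
         normalization_scheme = scheme,
         classification = classification,
         mosr = mosr,
         model = list(fm = unclass(fm_model), mosr = unclass(mosr_model)),
         version = as.character(utils::packageVersion("infantsway"))),
    class = "analysis_report"
  )
}

#' Analyze a recording from a force-plate export file
#'
#' Reads the file ([read_forceplate_csv()]), converts forces to COP when
#' needed ([cop_from_forces()]), and delegates to [analyze_recording()].
#'
#' @param path Input file path.
#' @param dialect `"cop"` or `"forces"`.
#' @param subject A [subject_meta()] with the infant's anthropometrics.
#' @param fs_declared Declared sampling rate (Hz).
#' @param plate_offset_z,fz_min Passed to [cop_from_forces()] for the
#'   `"forces"` dialect.
#' @inheritParams analyze_recording
#' @return An object of class `analysis_report`.
#' @export
run_analysis <- function(path, dialect = c("cop", "forces"),
                         subject = subject_meta(), fs_declared = 50,
                         plate_offset_z = 0, fz_min = 1,
                         cfg = preprocess_config(), scheme = "height_weight",
                         fm_model = fm_logistic_model(),
                         mosr_model = mosr_linear_model(),
                         apen_cfg = apen_config()) {
  dialect <- match.arg(dialect)
  rec <- read_forceplate_csv(path, dialect, fs_declared, subject)
  if (dialect == "forces") rec <- cop_from_forces(rec, plate_offset_z, fz_min)
  analyze_recording(rec, cfg, scheme, fm_model, mosr_model, apen_cfg)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("== COP analysis report (infantsway %s) ==\n", x$version))
  print(x$subject)
  cat(sprintf("analyzed %d samples at %g Hz; filter: order %d, %g Hz low-pass%s\n",
              x$preprocessing$n_analyzed, x$preprocessing$fs,
              x$preprocessing$order, x$preprocessing$cutoff,
              if (x$preprocessing$zero_phase) " (zero-phase)" else ""))
  cat(sprintf("normalization: %s\n", x$normalization_scheme))
  v <- x$parameters$values
  cat(sprintf("IV R (Std) = %.4f, IV R (Skew) = %.4f, ApEn R = %.4f\n",
              v[["instantaneous_velocity_std_R"]],
              v[["instantaneous_velocity_skewness_R"]],
              v[["approximate_entropy_R"]]))
  print(x$classification)
  if (is.na(x$mosr$mosr_estimate)) {
    cat(sprintf("MOS-R estimate unavailable: %s\n", x$mosr$flag))
  } else {
    cat(sprintf("MOS-R estimate = %.1f%s\n", x$mosr$mosr_estimate,
                if (isTRUE(x$mosr$clamped)) " (clamped to legal range)" else ""))
  }
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' @param report An `analysis_report`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  payload <- list(
    subject = unclass(report$subject),
    preprocessing = report$preprocessing,
    normalization_scheme = report$normalization_scheme,
    parameters_raw = as.list(report$parameters_raw$values),
    parameters_normalized = as.list(report$parameters$values),
    units = as.list(report$parameters$units),
    classification = unclass(report$classification),
    mosr = report$mosr,
    model = report$model,
    version = report$version
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Batch analysis of a simulated or recorded cohort
#'
#' Applies [analyze_recording()] to every recording and assembles a
#' per-recording summary table (predictors, probability, label, MOS-R).
#'
#' @param recordings List of [cop_recording()] objects.
#' @param ... Passed to [analyze_recording()].
#' @return List with `reports` (list of `analysis_report`) and `summary`
#'   (data frame, one row per recording).
#' @export
analyze_cohort <- function(recordings, ...) {
  reports <- lapply(recordings, analyze_recording, ...)
  summary <- do.call(rbind, lapply(reports, function(r) {
    v <- r$parameters$values
    data.frame(
      id = r$subject$id,
      iv_std_R = v[["instantaneous_velocity_std_R"]],
      iv_skew_R = v[["instantaneous_velocity_skewness_R"]],
      apen_R = v[["approximate_entropy_R"]],
      probability = r$classification$probability,
      label = r$classification$label,
      mosr_estimate = r$mosr$mosr_estimate,
      row.names = NULL)
  }))
  list(reports = reports, summary = summary)
}
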