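#' Preprocessing configuration
#'
#' Defaults reproduce the published processing chain: 50 Hz sampling, a
#' fourth-order 10 Hz low-pass Butterworth filter, the first 10 s discarded
#' as acclimation time, and the last 170 s retained for analysis.
#'
#' @param expected_fs Expected sampling rate (Hz).
#' @param cutoff Low-pass cutoff (Hz), must be below Nyquist.
#' @param order Butterworth filter order.
#' @param trim_lead Acclimation time discarded from the start (s).
#' @param analysis_window Analysis window length (s), taken from the end.
#' @param zero_phase Apply the filter forward and backward (no phase lag)?
#' @param allow_short Keep everything after `trim_lead` when the recording is
#'   shorter than `trim_lead + analysis_window` instead of erroring.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(expected_fs = 50, cutoff = 10, order = 4,
                              trim_lead = 10, analysis_window = 170,
                              zero_phase = TRUE, allow_short = FALSE) {
  if (cutoff >= expected_fs / 2) {
    stop("parameter error: cutoff must be below the Nyquist frequency",
         call. = FALSE)
  }
  if (trim_lead < 0) stop("trim_lead must be >= 0", call. = FALSE)
  if (analysis_window <= 0) stop("analysis_window must be > 0", call. = FALSE)
  structure(
    list(expected_fs = expected_fs, cutoff = cutoff, order = as.integer(order),
         trim_lead = trim_lead, analysis_window = analysis_window,
         zero_phase = isTRUE(zero_phase), allow_short = isTRUE(allow_short)),
    class = "preprocess_config"
  )
}

#' Butterworth low-pass filter
#'
#' Applies a digital Butterworth low-pass design (bilinear transform). With
#' `zero_phase = TRUE` the filter runs forward and backward over the series
#' extended at both ends by odd (point-reflected) padding, giving zero phase
#' lag and the squared magnitude response; otherwise a single causal pass is
#' used. Output length always equals input length and the DC gain is 1.
#'
#' @param series Numeric vector sampled uniformly at `fs`.
#' @param fs Sampling rate (Hz).
#' @param cutoff Cutoff frequency (Hz), below Nyquist.
#' @param order Filter order.
#' @param zero_phase Forward-backward application (default `TRUE`).
#' @return Filtered numeric vector, same length as `series`.
#' @export
butterworth_lowpass <- function(series, fs, cutoff = 10, order = 4,
                                zero_phase = TRUE) {
  n <- length(series)
  if (n <= 3L * order) {
    stop(sprintf("length error: need more than %d samples for order %d",
                 3L * order, order), call. = FALSE)
  }
  if (cutoff >= fs / 2) {
    stop("parameter error: cutoff must be below the Nyquist frequency",
         call. = FALSE)
  }
  ba <- signal::butter(order, cutoff / (fs / 2), type = "low")
  b <- ba$b; a <- ba$a
  # pad long enough that the startup transient of the slowest pole decays
  # below double precision before the retained window begins
  maxpole <- max(Mod(polyroot(rev(a))))
  pad <- if (maxpole < 1 && maxpole > 0) ceiling(log(1e-14) / log(maxpole)) else 50L
  pad <- min(n - 1L, max(pad, 3L * (length(a) - 1L)))
  if (zero_phase) {
    ext <- c(2 * series[1] - series[(pad + 1):2],
             series,
             2 * series[n] - series[(n - 1):(n - pad)])
    fwd <- as.numeric(signal::filter(b, a, ext))
    bwd <- rev(as.numeric(signal::filter(b, a, rev(fwd))))
    bwd[(pad + 1):(pad + n)]
  } else {
    ext <- c(2 * series[1] - series[(pad + 1):2], series)
    out <- as.numeric(signal::filter(b, a, ext))
    out[(pad + 1):(pad + n)]
  }
}

#' Trim a recording to the analysis window
#'
#' Keeps the last `analysis_window` seconds, discarding at least the leading
#' `trim_lead` seconds of acclimation. With the defaults (10 s lead, 170 s
#' window) a 180 s recording at 50 Hz yields exactly 8500 samples.
#'
#' @param rec A [cop_recording()].
#' @param cfg A [preprocess_config()].
#' @return A [cop_recording()] containing the trimmed series.
#' @export
trim_to_analysis_window <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "cop_recording"))
  n <- length(rec$x)
  need <- round((cfg$trim_lead + cfg$analysis_window) * rec$fs)
  n_keep <- round(cfg$analysis_window * rec$fs)
  if (n < need) {
    if (!cfg$allow_short) {
      stop(sprintf(
        "duration error: recording is %.2f s but %.2f s required (trim %g s + window %g s)",
        n / rec$fs, need / rec$fs, cfg$trim_lead, cfg$analysis_window),
        call. = FALSE)
    }
    start <- round(cfg$trim_lead * rec$fs) + 1L
    if (start > n) stop("duration error: nothing left after trim_lead",
                        call. = FALSE)
    idx <- start:n
  } else {
    idx <- (n - n_keep + 1L):n
  }
  cop_recording(rec$fs, rec$x[idx], rec$y[idx],
                valid_mask = rec$valid_mask[idx], subject = rec$subject)
}

#' Preprocess a COP recording
#'
#' Full preprocessing chain: sampling-rate check, low-pass filtering of the
#' whole recording (so startup transients fall in the discarded acclimation
#' lead), trimming to the analysis window, mean-centering, and computation of
#' the resultant displacement series
#' \eqn{r_i = \sqrt{(x_i-\bar x)^2 + (y_i-\bar y)^2}}.
#'
#' @param rec A [cop_recording()].
#' @param cfg A [preprocess_config()].
#' @return An object of class `processed_cop` with fields `fs`, `x`, `y`
#'   (filtered, trimmed), `x_c`, `y_c` (mean-centered), `r_disp`
#'   (resultant displacement from the window-mean COP), `subject`,
#'   `n_analyzed`, `valid_fraction` and `config`.
#' @export
preprocess <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "cop_recording"))
  if (abs(rec$fs - cfg$expected_fs) / cfg$expected_fs > 0.01) {
    stop(sprintf(
      "sampling-rate error: recording fs %.4g Hz differs from expected %.4g Hz by more than 1%%",
      rec$fs, cfg$expected_fs), call. = FALSE)
  }
  fx <- butterworth_lowpass(rec$x, rec$fs, cfg$cutoff, cfg$order, cfg$zero_phase)
  fy <- butterworth_lowpass(rec$y, rec$fs, cfg$cutoff, cfg$order, cfg$zero_phase)
  filtered <- cop_recording(rec$fs, fx, fy, valid_mask = rec$valid_mask,
                            subject = rec$subject)
  trimmed <- trim_to_analysis_window(filtered, cfg)
  x_c <- trimmed$x - mean(trimmed$x)
  y_c <- trimmed$y - mean(trimmed$y)
  structure(
    list(fs = trimmed$fs, x = trimmed$x, y = trimmed$y,
         x_c = x_c, y_c = y_c,
         r_disp = sqrt(x_c^2 + y_c^2),
         subject = rec$subject,
         n_analyzed = length(trimmed$x),
         valid_fraction = mean(trimmed$valid_mask),
         config = cfg),
    class = "processed_cop"
  )
}

#' @export
print.processed_cop <- function(x, ...) {
  cat(sprintf(
    "<processed_cop> %d samples at %g Hz (%.1f s window), filter: order %d, %g Hz low-pass%s\n",
    x$n_analyzed, x$fs, x$n_analyzed / x$fs, x$config$order, x$config$cutoff,
    if (x$config$zero_phase) " (zero-phase)" else ""))
  invisible(x)
}
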