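#' Subject metadata
#'
#' Anthropometrics and labels attached to a recording. Height and weight are
#' the infant's *current* (measurement-day) values; they drive parameter
#' normalization.
#'
#' @param id Opaque subject identifier (coerced to character).
#' @param height Current height in cm, or `NA`.
#' @param weight Current weight in g, or `NA`.
#' @param post_term_age Post-term age in weeks (optional).
#' @param group_label One of `"normal_FM"`, `"absent_FM"`, `"unknown"`.
#' @return An object of class `subject_meta`.
#' @export
subject_meta <- function(id = "anonymous", height = NA_real_, weight = NA_real_,
                         post_term_age = NA_real_, group_label = "unknown") {
  group_label <- match.arg(group_label, c("unknown", "normal_FM", "absent_FM"))
  height <- as.numeric(height)
  weight <- as.numeric(weight)
  if (!is.na(height) && height <= 0) stop("subject height must be > 0 cm", call. = FALSE)
  if (!is.na(weight) && weight <= 0) stop("subject weight must be > 0 g", call. = FALSE)
  structure(
    list(id = as.character(id), height = height, weight = weight,
         post_term_age = as.numeric(post_term_age), group_label = group_label),
    class = "subject_meta"
  )
}

#' @export
print.subject_meta <- function(x, ...) {
  cat(sprintf("<subject %s> height: %s cm, weight: %s g, group: %s\n",
              x$id, format(x$height), format(x$weight), x$group_label))
  invisible(x)
}

#' Raw force-plate recording
#'
#' Six-channel force/moment time series as exported by a force plate:
#' forces in N, moments in N*m, all channels sampled synchronously.
#'
#' @param fs Sampling rate in Hz (> 0).
#' @param Fx,Fy,Fz Force channels (N).
#' @param Mx,My,Mz Moment channels (N*m).
#' @param subject A [subject_meta()].
#' @return An object of class `raw_force_recording`.
#' @export
raw_force_recording <- function(fs, Fx, Fy, Fz, Mx, My, Mz,
                                subject = subject_meta()) {
  fs <- as.numeric(fs)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  n <- length(Fx)
  chans <- list(Fx = Fx, Fy = Fy, Fz = Fz, Mx = Mx, My = My, Mz = Mz)
  if (n < 1L) stop("force channels must have length >= 1", call. = FALSE)
  lens <- vapply(chans, length, integer(1))
  if (any(lens != n)) {
    stop("all six force/moment channels must have equal length", call. = FALSE)
  }
  structure(
    c(list(fs = fs), lapply(chans, as.numeric), list(subject = subject)),
    class = "raw_force_recording"
  )
}

#' Center-of-pressure recording
#'
#' COP coordinate time series in mm: `x` is medial-lateral, `y` is
#' caudo-cephalic (the infant lies supine with the cranial-caudal axis along
#' the plate's long axis). `valid_mask` flags samples backed by sufficient
#' vertical load; invalid samples carry the last valid COP.
#'
#' @param fs Sampling rate in Hz (> 0).
#' @param x Medial-lateral COP series (mm).
#' @param y Caudo-cephalic COP series (mm).
#' @param valid_mask Logical per-sample validity flags (default all `TRUE`).
#' @param subject A [subject_meta()].
#' @return An object of class `cop_recording`.
#' @export
cop_recording <- function(fs, x, y, valid_mask = NULL,
                          subject = subject_meta()) {
  fs <- as.numeric(fs)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  if (length(x) != length(y)) {
    stop("x and y COP series must have equal length", call. = FALSE)
  }
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, length(x))
  if (length(valid_mask) != length(x)) {
    stop("valid_mask must match the series length", call. = FALSE)
  }
  structure(
    list(fs = fs, x = as.numeric(x), y = as.numeric(y),
         valid_mask = as.logical(valid_mask), subject = subject),
    class = "cop_recording"
  )
}

#' @export
print.cop_recording <- function(x, ...) {
  cat(sprintf("<cop_recording> %d samples at %g Hz (%.1f s), %.1f%% valid\n",
              length(x$x), x$fs, length(x$x) / x$fs,
              100 * mean(x$valid_mask)))
  print(x$subject)
  invisible(x)
}

#' @export
print.raw_force_recording <- function(x, ...) {
  cat(sprintf("<raw_force_recording> %d samples at %g Hz (%.1f s)\n",
              length(x$Fx), x$fs, length(x$Fx) / x$fs))
  print(x$subject)
  invisible(x)
}
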