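#' Read a force-plate export
#'
#' Reads delimited text exports in one of two dialects: `"forces"` with
#' columns `time,Fx,Fy,Fz,Mx,My,Mz` (N and N*m) or `"cop"` with columns
#' `time,copx,copy` (mm). The delimiter is auto-detected among comma, tab and
#' semicolon. The sampling rate is inferred from the median time step and
#' cross-checked against `fs_declared` within 1% relative tolerance.
#'
#' @param path Path to the delimited text file.
#' @param dialect `"forces"` or `"cop"`.
#' @param fs_declared Declared sampling rate (Hz).
#' @param subject A [subject_meta()] to attach.
#' @return A [raw_force_recording()] (`dialect = "forces"`) or a
#'   [cop_recording()] (`dialect = "cop"`).
#' @export
read_forceplate_csv <- function(path, dialect = c("cop", "forces"),
                                fs_declared = 50, subject = subject_meta()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_delimiter(path)
  df <- utils::read.csv(path, sep = sep, header = TRUE,
                        check.names = TRUE, strip.white = TRUE)
  names(df) <- tolower(names(df))
  required <- if (dialect == "forces") {
    c("time", "fx", "fy", "fz", "mx", "my", "mz")
  } else {
    c("time", "copx", "copy")
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("format error: missing column(s) %s for dialect '%s'",
                 paste(missing_cols, collapse = ", "), dialect), call. = FALSE)
  }
  for (col in required) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(v <- as.numeric(as.character(v)))
      if (anyNA(v)) {
        stop(sprintf("format error: column '%s' is not numeric", col),
             call. = FALSE)
      }
      df[[col]] <- v
    }
  }
  fs <- infer_fs(df$time)
  if (!is.na(fs_declared)) {
    if (abs(fs - fs_declared) / fs_declared > 0.01) {
      stop(sprintf(
        "sampling-rate error: inferred %.4g Hz from the time column but %.4g Hz declared",
        fs, fs_declared), call. = FALSE)
    }
    fs <- fs_declared
  }
  if (dialect == "forces") {
    raw_force_recording(fs, df$fx, df$fy, df$fz, df$mx, df$my, df$mz,
                        subject = subject)
  } else {
    cop_recording(fs, df$copx, df$copy, subject = subject)
  }
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- c(
    "," = lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))),
    "\t" = lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))),
    ";" = lengths(regmatches(header, gregexpr(";", header, fixed = TRUE)))
  )
  if (all(counts == 0)) {
    stop("format error: no comma/tab/semicolon delimiter found in header",
         call. = FALSE)
  }
  names(counts)[which.max(counts)]
}

infer_fs <- function(time) {
  if (length(time) < 2L) stop("need >= 2 samples to infer sampling rate",
                              call. = FALSE)
  dt <- stats::median(diff(time))
  if (!is.finite(dt) || dt <= 0) {
    stop("sampling-rate error: non-increasing time column", call. = FALSE)
  }
  1 / dt
}

#' Compute COP coordinates from raw force/moment channels
#'
#' Standard force-plate mechanics for a plate whose measurement origin sits
#' `plate_offset_z` metres below the contact surface:
#' \deqn{COP_x = -(M_y + F_x z_0)/F_z, \quad COP_y = (M_x - F_y z_0)/F_z,}
#' converted to mm. Samples with \eqn{|F_z|} below `fz_min` are flagged
#' invalid and the COP is held at the last valid value (the leading run of
#' invalid samples is back-filled from the first valid one) rather than
#' interpolated, so no motion is invented.
#'
#' @param rec A [raw_force_recording()].
#' @param plate_offset_z Vertical offset between plate surface and
#'   measurement origin (m, >= 0). Default 0.
#' @param fz_min Minimum |Fz| (N) for a sample to be considered loaded.
#' @return A [cop_recording()] with `valid_mask` set.
#' @export
cop_from_forces <- function(rec, plate_offset_z = 0, fz_min = 1) {
  stopifnot(inherits(rec, "raw_force_recording"))
  if (plate_offset_z < 0) stop("plate_offset_z must be >= 0", call. = FALSE)
  if (fz_min <= 0) stop("fz_min must be > 0", call. = FALSE)
  valid <- abs(rec$Fz) >= fz_min
  if (!any(valid)) {
    stop("empty-signal error: no sample has |Fz| >= fz_min", call. = FALSE)
  }
  # metres -> mm
  x <- -(rec$My + rec$Fx * plate_offset_z) / rec$Fz * 1000
  y <- (rec$Mx - rec$Fy * plate_offset_z) / rec$Fz * 1000
  x <- hold_last_valid(x, valid)
  y <- hold_last_valid(y, valid)
  cop_recording(rec$fs, x, y, valid_mask = valid, subject = rec$subject)
}

# Carry the last valid value forward; back-fill a leading invalid run.
hold_last_valid <- function(v, valid) {
  if (all(valid)) return(v)
  idx <- seq_along(v)
  valid_idx <- idx[valid]
  # index of the most recent valid sample at or before each position
  last <- findInterval(idx, valid_idx)
  last[last == 0L] <- 1L            # leading invalid run <- first valid value
  v[valid_idx[last]]
}

#' Write a parameter table
#'
#' One row per recording, one column per (parameter, direction) pair in the
#' frozen battery order, written at full floating precision so a read-back
#' reproduces the values bit-for-bit.
#'
#' @param params A `cop_parameters` object or a list of them.
#' @param path Output file path (CSV).
#' @return Invisibly, the data frame written.
#' @export
write_parameter_table <- function(params, path) {
  if (inherits(params, "cop_parameters")) params <- list(params)
  if (!length(params)) stop("empty parameter list", call. = FALSE)
  stopifnot(all(vapply(params, inherits, logical(1), "cop_parameters")))
  keys <- parameter_battery_keys()
  rows <- lapply(params, function(p) {
    vals <- p$values[keys]
    c(list(id = p$subject$id,
           normalized = p$normalized,
           scheme = p$scheme),
      as.list(vals))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  names(df) <- c("id", "normalized", "scheme", keys)
  # full precision: format numerics with 17 significant digits
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Write a COP recording in the "cop" CSV dialect
#'
#' Emits `time,copx,copy` at full precision, readable back with
#' [read_forceplate_csv()] (`dialect = "cop"`). This is also how simulated
#' recordings are materialized as fixtures.
#'
#' @param rec A [cop_recording()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cop_csv <- function(rec, path) {
  stopifnot(inherits(rec, "cop_recording"))
  n <- length(rec$x)
  time <- (seq_len(n) - 1) / rec$fs
  lines <- c("time,copx,copy",
             sprintf("%.17g,%.17g,%.17g", time, rec$x, rec$y))
  writeLines(lines, path)
  invisible(path)
}

#' Read back a parameter table written by [write_parameter_table()]
#'
#' @param path Path to the CSV file.
#' @return A data frame with one row per recording.
#' @export
read_parameter_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, check.names = FALSE)
}
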