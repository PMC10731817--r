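#' Approximate entropy configuration
#'
#' @param m Embedding dimension (default 2).
#' @param r_factor Tolerance as a fraction of the series standard deviation
#'   (default 0.2). These are the de facto standard settings for
#'   physiological time series.
#' @return An object of class `apen_config`.
#' @export
apen_config <- function(m = 2, r_factor = 0.2) {
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  if (r_factor <= 0) stop("r_factor must be > 0", call. = FALSE)
  structure(list(m = m, r_factor = r_factor), class = "apen_config")
}

#' Approximate entropy
#'
#' Pincus' ApEn(m, r, N) regularity statistic with Chebyshev distance and
#' self-matches included:
#' \deqn{ApEn = \Phi^m(r) - \Phi^{m+1}(r), \quad
#'       \Phi^k(r) = \frac{1}{N-k+1}\sum_i \ln C_i^k(r),}
#' where \eqn{C_i^k(r)} is the fraction of length-\eqn{k} templates within
#' tolerance \eqn{r} of template \eqn{i}. The tolerance is
#' `r_factor * sd(series)`; a zero-variance series has ApEn defined as 0.
#' Larger values indicate a less predictable, more irregular series.
#'
#' @param series Numeric vector, length at least `10 * (m + 1)`.
#' @param cfg An [apen_config()].
#' @return Non-negative ApEn value.
#' @export
approximate_entropy <- function(series, cfg = apen_config()) {
  n <- length(series)
  if (n < 10L * (cfg$m + 1L)) {
    stop(sprintf("length error: need at least %d samples for m = %d",
                 10L * (cfg$m + 1L), cfg$m), call. = FALSE)
  }
  s <- stats::sd(series)
  if (!is.finite(s) || s == 0) return(0)
  .apen_cpp(as.numeric(series), cfg$m, cfg$r_factor * s)
}

#' Instantaneous COP velocity
#'
#' Forward-difference velocities \eqn{v_i = (x_{i+1} - x_i) f_s} per axis
#' (length N-1) and the resultant speed
#' \eqn{v_{R,i} = \sqrt{v_{x,i}^2 + v_{y,i}^2}}, i.e. the magnitude of the
#' planar velocity vector. With this convention the mean resultant speed
#' times the window duration telescopes exactly to the planar path length.
#'
#' @param p A `processed_cop` object from [preprocess()].
#' @return List with numeric vectors `vx`, `vy`, `vr` (mm/s).
#' @export
instantaneous_velocity <- function(p) {
  stopifnot(inherits(p, "processed_cop"))
  if (length(p$x) < 2L) stop("length error: need >= 2 samples", call. = FALSE)
  vx <- diff(p$x) * p$fs
  vy <- diff(p$y) * p$fs
  list(vx = vx, vy = vy, vr = sqrt(vx^2 + vy^2))
}

#' Summary statistics of a velocity series
#'
#' @param v Numeric velocity series (length >= 2; skewness needs >= 3 and is
#'   `NA` for a 2-sample series).
#' @return List with `std` (sample SD, denominator N-1), `rms`
#'   (root-mean-square), `skewness` (adjusted Fisher-Pearson; 0 for a
#'   zero-variance series) and `range` (max - min).
#' @export
velocity_stats <- function(v) {
  n <- length(v)
  if (n < 2L) stop("length error: need >= 2 values", call. = FALSE)
  list(std = stats::sd(v),
       rms = sqrt(mean(v^2)),
       skewness = if (n >= 3L) sample_skewness(v) else NA_real_,
       range = max(v) - min(v))
}

# Adjusted Fisher-Pearson sample skewness; 0 when the series has no variance.
sample_skewness <- function(v) {
  n <- length(v)
  d <- v - mean(v)
  m2 <- mean(d^2)
  if (m2 == 0) return(0)
  g1 <- mean(d^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Path-length and displacement metrics
#'
#' Total distance per axis is the summed absolute first difference; the
#' resultant total distance is the planar path length
#' \eqn{\sum_i \sqrt{\Delta x_i^2 + \Delta y_i^2}}. Instantaneous distance
#' RMS is the root-mean-square of the centered series (of `r_disp` for the
#' resultant); average distance is the mean resultant displacement from the
#' window-mean COP.
#'
#' @param p A `processed_cop` object.
#' @return List with `total_distance` (named X/Y/R, mm),
#'   `instantaneous_distance_rms` (named X/Y/R, mm) and `average_distance`
#'   (mm).
#' @export
path_metrics <- function(p) {
  stopifnot(inherits(p, "processed_cop"))
  if (length(p$x) < 2L) stop("length error: need >= 2 samples", call. = FALSE)
  dx <- diff(p$x); dy <- diff(p$y)
  list(
    total_distance = c(X = sum(abs(dx)), Y = sum(abs(dy)),
                       R = sum(sqrt(dx^2 + dy^2))),
    instantaneous_distance_rms = c(X = sqrt(mean(p$x_c^2)),
                                   Y = sqrt(mean(p$y_c^2)),
                                   R = sqrt(mean(p$r_disp^2))),
    average_distance = mean(p$r_disp)
  )
}

#' Prediction ellipse of the COP scatter
#'
#' Ellipse expected to contain `level` of the COP samples, from the 2x2
#' sample covariance \eqn{\Sigma} of the centered coordinates:
#' area \eqn{= \pi \chi^2_2(level) \sqrt{\det \Sigma}}, axis lengths
#' \eqn{2\sqrt{\chi^2_2(level)\,\lambda_i}} for eigenvalues \eqn{\lambda_i},
#' orientation the angle of the leading eigenvector. A degenerate
#' (rank-deficient) covariance yields area 0 with `degenerate = TRUE` rather
#' than an error.
#'
#' @param p A `processed_cop` object (or any list with `x_c`, `y_c`).
#' @param level Coverage probability (default 0.95, for which
#'   \eqn{\chi^2_2 = 5.991}).
#' @return List with `area` (mm^2), `major_axis`, `minor_axis` (mm, full
#'   lengths), `orientation` (rad, in (-pi/2, pi/2]), `degenerate` flag.
#' @export
confidence_ellipse <- function(p, level = 0.95) {
  x <- p$x_c; y <- p$y_c
  if (length(x) < 3L) stop("length error: need >= 3 points", call. = FALSE)
  S <- stats::var(cbind(x, y))
  k <- stats::qchisq(level, df = 2)
  detS <- S[1, 1] * S[2, 2] - S[1, 2]^2
  eg <- eigen(S, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  v1 <- eg$vectors[, 1]
  ang <- atan2(v1[2], v1[1])
  # fold into (-pi/2, pi/2]: an ellipse axis has no sign
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  degenerate <- !(detS > 0) || lam[2] <= 0
  list(
    area = if (degenerate) 0 else pi * k * sqrt(detS),
    major_axis = 2 * sqrt(k * lam[1]),
    minor_axis = 2 * sqrt(k * lam[2]),
    orientation = ang,
    degenerate = degenerate
  )
}

# Frozen battery order: this is the stable column order of parameter tables.
parameter_battery_keys <- function() {
  stat_params <- c("instantaneous_velocity_std", "instantaneous_velocity_rms",
                   "instantaneous_velocity_skewness", "velocity_range",
                   "total_distance", "instantaneous_distance_rms")
  c(as.vector(t(outer(stat_params, c("X", "Y", "R"), paste, sep = "_"))),
    "average_distance_R",
    "ellipse_area_R", "ellipse_major_axis_R", "ellipse_minor_axis_R",
    "ellipse_orientation_R",
    paste("approximate_entropy", c("X", "Y", "R"), sep = "_"))
}

# Unit for each battery key; "1" marks a dimensionless parameter that
# normalization must never rescale.
parameter_units <- function() {
  keys <- parameter_battery_keys()
  units <- ifelse(grepl("^instantaneous_velocity_skewness|^approximate_entropy", keys), "1",
           ifelse(grepl("^ellipse_orientation", keys), "rad",
           ifelse(grepl("^ellipse_area", keys), "mm^2",
           ifelse(grepl("velocity", keys), "mm/s", "mm"))))
  stats::setNames(units, keys)
}

#' Compute the full COP movement-parameter battery
#'
#' Fills every parameter of the battery for the medial-lateral (X),
#' caudo-cephalic (Y) and resultant (R) directions: velocity statistics
#' (SD, RMS, skewness, range), path metrics (total distance, instantaneous
#' distance RMS, average distance), the 95% prediction ellipse, and
#' approximate entropy of the centered series and the resultant
#' displacement.
#'
#' @param p A `processed_cop` object.
#' @param apen_cfg An [apen_config()].
#' @return An object of class `cop_parameters` with fields `values` (named
#'   numeric in the frozen battery order), `units`, `normalized` (FALSE),
#'   `scheme` ("none") and `subject`.
#' @export
compute_parameters <- function(p, apen_cfg = apen_config()) {
  stopifnot(inherits(p, "processed_cop"))
  vel <- instantaneous_velocity(p)
  sx <- velocity_stats(vel$vx); sy <- velocity_stats(vel$vy)
  sr <- velocity_stats(vel$vr)
  pm <- path_metrics(p)
  el <- confidence_ellipse(p, level = 0.95)

  vals <- c(
    instantaneous_velocity_std_X = sx$std,
    instantaneous_velocity_std_Y = sy$std,
    instantaneous_velocity_std_R = sr$std,
    instantaneous_velocity_rms_X = sx$rms,
    instantaneous_velocity_rms_Y = sy$rms,
    instantaneous_velocity_rms_R = sr$rms,
    instantaneous_velocity_skewness_X = sx$skewness,
    instantaneous_velocity_skewness_Y = sy$skewness,
    instantaneous_velocity_skewness_R = sr$skewness,
    velocity_range_X = sx$range,
    velocity_range_Y = sy$range,
    velocity_range_R = sr$range,
    total_distance_X = pm$total_distance[["X"]],
    total_distance_Y = pm$total_distance[["Y"]],
    total_distance_R = pm$total_distance[["R"]],
    instantaneous_distance_rms_X = pm$instantaneous_distance_rms[["X"]],
    instantaneous_distance_rms_Y = pm$instantaneous_distance_rms[["Y"]],
    instantaneous_distance_rms_R = pm$instantaneous_distance_rms[["R"]],
    average_distance_R = pm$average_distance,
    ellipse_area_R = el$area,
    ellipse_major_axis_R = el$major_axis,
    ellipse_minor_axis_R = el$minor_axis,
    ellipse_orientation_R = el$orientation,
    approximate_entropy_X = approximate_entropy(p$x_c, apen_cfg),
    approximate_entropy_Y = approximate_entropy(p$y_c, apen_cfg),
    approximate_entropy_R = approximate_entropy(p$r_disp, apen_cfg)
  )
  vals <- vals[parameter_battery_keys()]
  structure(
    list(values = vals, units = parameter_units(), normalized = FALSE,
         scheme = "none", subject = p$subject),
    class = "cop_parameters"
  )
}

#' @export
print.cop_parameters <- function(x, ...) {
  cat(sprintf("<cop_parameters> subject %s, normalized: %s (scheme: %s)\n",
              x$subject$id, x$normalized, x$scheme))
  df <- data.frame(parameter = names(x$values), value = unname(x$values),
                   unit = unname(x$units[names(x$values)]))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Anthropometric normalization of COP parameters
#'
#' Divides every length-dimensioned parameter by the infant's current height
#' (cm) and/or weight (kg): parameters in mm or mm/s are divided once per
#' factor, areas (mm^2) twice. Dimensionless parameters (velocity skewness,
#' approximate entropy) and the ellipse orientation are never rescaled. The
#' default scheme uses both height and weight because both differ
#' systematically between clinical groups.
#'
#' @param params A `cop_parameters` object.
#' @param scheme One of `"none"`, `"height"`, `"weight"`, `"height_weight"`.
#' @return The normalized `cop_parameters` (with `normalized = TRUE` and the
#'   scheme recorded).
#' @export
normalize_parameters <- function(params,
                                 scheme = c("height_weight", "height",
                                            "weight", "none")) {
  stopifnot(inherits(params, "cop_parameters"))
  scheme <- match.arg(scheme)
  subj <- params$subject
  divisor <- 1
  if (scheme %in% c("height", "height_weight")) {
    if (is.na(subj$height)) {
      stop("normalization error: subject height is missing", call. = FALSE)
    }
    divisor <- divisor * subj$height
  }
  if (scheme %in% c("weight", "height_weight")) {
    if (is.na(subj$weight)) {
      stop("normalization error: subject weight is missing", call. = FALSE)
    }
    divisor <- divisor * subj$weight / 1000   # g -> kg
  }
  vals <- params$values
  units <- params$units[names(vals)]
  pow <- ifelse(units %in% c("mm", "mm/s"), 1, ifelse(units == "mm^2", 2, 0))
  params$values <- vals / divisor^pow
  params$normalized <- TRUE
  params$scheme <- scheme
  params
}
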