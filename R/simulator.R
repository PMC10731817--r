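#' Simulation configuration
#'
#' Synthetic supine COP recordings come in two regimes that mirror the
#' clinically discriminative contrasts: `"normal"` (fidgety movements
#' present) has high velocity variability and low broadband complexity,
#' `"absent"` has reduced velocity variability and a larger broadband
#' (irregular) component. Movement energy is confined below 3 Hz, the upper
#' bound of infant spontaneous-movement frequency.
#'
#' @param regime `"normal"` or `"absent"`.
#' @param fs Sampling rate (Hz, default 50).
#' @param duration Recording length (s, default 180).
#' @param seed Integer seed; the recording is fully deterministic given it.
#' @param band Movement frequency band (Hz, default `c(0.1, 3)`).
#' @param base_amplitude Carrier sway amplitude (mm, default 15).
#' @param velocity_variability_gain Depth multiplier of the slow amplitude
#'   envelope; regime default: normal 1.0, absent 0.35.
#' @param complexity_gain Broadband-noise mix weight; regime default:
#'   normal 0.2, absent 0.6.
#' @param n_recordings Cohort size used by [simulate_cohort()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(regime = c("normal", "absent"), fs = 50,
                              duration = 180, seed = 1, band = c(0.1, 3),
                              base_amplitude = 15,
                              velocity_variability_gain = NULL,
                              complexity_gain = NULL, n_recordings = 1) {
  regime <- match.arg(regime)
  if (band[2] >= fs / 2) stop("band upper edge must be below Nyquist",
                              call. = FALSE)
  if (band[1] <= 0 || band[1] >= band[2]) stop("invalid band", call. = FALSE)
  n <- duration * fs
  if (abs(n - round(n)) > 1e-9) stop("duration * fs must be integral",
                                     call. = FALSE)
  if (is.null(velocity_variability_gain)) {
    velocity_variability_gain <- if (regime == "normal") 1.0 else 0.35
  }
  if (is.null(complexity_gain)) {
    complexity_gain <- if (regime == "normal") 0.2 else 0.6
  }
  if (velocity_variability_gain < 0 || complexity_gain < 0) {
    stop("gains must be >= 0", call. = FALSE)
  }
  structure(
    list(regime = regime, fs = fs, duration = duration, seed = as.integer(seed),
         band = band, base_amplitude = base_amplitude,
         velocity_variability_gain = velocity_variability_gain,
         complexity_gain = complexity_gain,
         n_recordings = as.integer(n_recordings)),
    class = "simulation_config"
  )
}

# Band-limited Gaussian noise by frequency-domain synthesis: complex Gaussian
# coefficients on [band_lo, band_hi] with flat amplitude up to 1 Hz and 1/f
# amplitude decay above (infant movement spectra decay with frequency), zero
# outside the band, inverse FFT, unit-SD scaling. All movement energy is in
# the band by construction.
band_limited_noise <- function(n, fs, band) {
  freqs <- (0:(n %/% 2)) * fs / n
  amp <- ifelse(freqs >= band[1] & freqs <= band[2],
                ifelse(freqs <= 1, 1, 1 / freqs), 0)
  half <- complex(real = stats::rnorm(length(freqs)),
                  imaginary = stats::rnorm(length(freqs))) * amp
  half[1] <- 0                                 # no DC
  spec <- c(half, Conj(rev(half[2:(n - length(half) + 1)])))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Slow random amplitude modulation: a handful of sinusoids with frequencies
# in [0.05, 0.2] Hz and random phases, normalized to unit SD.
slow_modulator <- function(t, k = 6) {
  f <- stats::runif(k, 0.05, 0.2)
  a <- stats::runif(k, 0.5, 1)
  ph <- stats::runif(k, 0, 2 * pi)
  m <- rowSums(vapply(seq_len(k),
                      function(i) a[i] * sin(2 * pi * f[i] * t + ph[i]),
                      numeric(length(t))))
  m / stats::sd(m)
}

# Amplitude of the broadband (white) complexity component at unit
# complexity_gain, in mm. Kept small relative to the 15 mm carrier so the
# noise perturbs regularity without dominating the sway.
BROADBAND_SD_MM <- 1.5

#' Simulate a supine COP recording
#'
#' Per axis the signal is
#' `base_amplitude * envelope(t) * bandlimited(t) + complexity_gain * broadband(t)`
#' plus a constant axis offset: `bandlimited` is seeded Gaussian noise
#' synthesized in the movement band, `envelope` is a slow (0.05-0.2 Hz)
#' log-scale amplitude modulation whose depth scales with
#' `velocity_variability_gain`, and `broadband` is low-amplitude white noise.
#' Subject anthropometrics are drawn from plausible infant ranges
#' (height 55-68 cm, weight 4500-8000 g). Fully deterministic given
#' `cfg$seed`; the caller's RNG state is left untouched.
#'
#' @param cfg A [simulation_config()].
#' @param id Subject identifier (default derived from regime and seed).
#' @return A [cop_recording()] of `duration * fs` samples.
#' @export
simulate_cop_recording <- function(cfg, id = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.null(id)) id <- sprintf("sim_%s_%d", cfg$regime, cfg$seed)
  with_preserved_rng({
    set.seed(cfg$seed)
    n <- round(cfg$duration * cfg$fs)
    t <- (seq_len(n) - 1) / cfg$fs
    depth <- 0.5 * cfg$velocity_variability_gain
    axis_signal <- function() {
      carrier <- band_limited_noise(n, cfg$fs, cfg$band)
      env <- exp(depth * slow_modulator(t))
      offset <- stats::runif(1, -10, 10)
      cfg$base_amplitude * env * carrier +
        cfg$complexity_gain * BROADBAND_SD_MM * stats::rnorm(n) + offset
    }
    x <- axis_signal()
    y <- axis_signal()
    subj <- subject_meta(
      id = id,
      height = stats::runif(1, 55, 68),
      weight = stats::runif(1, 4500, 8000),
      group_label = if (cfg$regime == "normal") "normal_FM" else "absent_FM")
    cop_recording(cfg$fs, x, y, subject = subj)
  })
}

#' Simulate a labelled cohort of COP recordings
#'
#' Independent recordings with per-recording seeds derived from a master
#' seed, so the whole cohort is reproducible from a single integer. Infants
#' within a clinical group are not identical: each recording's envelope
#' depth, complexity mix and carrier amplitude are drawn around the regime
#' defaults with a multiplicative lognormal spread of coefficient of
#' variation `heterogeneity`, so the groups overlap the way clinical cohorts
#' do rather than forming two point masses.
#'
#' @param n_normal,n_absent Group sizes (total >= 2).
#' @param seed Master seed.
#' @param heterogeneity Log-scale SD of the per-infant gain and amplitude
#'   jitter (default 0.3; 0 gives identical regime parameters for all).
#' @param ... Further arguments passed to [simulation_config()] (e.g.
#'   `duration`, `base_amplitude`).
#' @return List with `recordings` (list of [cop_recording()]), `labels`
#'   (character, `"normal_FM"`/`"absent_FM"`) and `seeds` (per-recording).
#' @export
simulate_cohort <- function(n_normal, n_absent, seed = 1, heterogeneity = 0.3,
                            ...) {
  if (n_normal + n_absent < 2) stop("cohort must have >= 2 recordings",
                                    call. = FALSE)
  regimes <- c(rep("normal", n_normal), rep("absent", n_absent))
  n <- length(regimes)
  draws <- with_preserved_rng({
    set.seed(seed)
    list(seeds = sample.int(.Machine$integer.max - 1L, n),
         jitter = matrix(exp(stats::rnorm(3 * n, 0, heterogeneity)),
                         ncol = 3))
  })
  recordings <- lapply(seq_len(n), function(i) {
    base <- simulation_config(regime = regimes[i], seed = draws$seeds[i], ...)
    cfg <- simulation_config(
      regime = regimes[i], seed = draws$seeds[i],
      fs = base$fs, duration = base$duration, band = base$band,
      base_amplitude = base$base_amplitude * draws$jitter[i, 1],
      velocity_variability_gain =
        base$velocity_variability_gain * draws$jitter[i, 2],
      complexity_gain = base$complexity_gain * draws$jitter[i, 3])
    simulate_cop_recording(cfg, id = sprintf("sim_%s_%03d", regimes[i], i))
  })
  list(recordings = recordings,
       labels = ifelse(regimes == "normal", "normal_FM", "absent_FM"),
       seeds = draws$seeds)
}

# Evaluate an expression with the caller's .Random.seed saved and restored.
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}
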