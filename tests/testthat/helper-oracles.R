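# Independent brute-force oracles, kept deliberately naive.

# Pincus ApEn by direct O(N^2) template counting (Chebyshev distance,
# self-matches included).
naive_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(k) {
    nk <- n - k + 1
    logC <- numeric(nk)
    for (i in seq_len(nk)) {
      cnt <- 0
      for (j in seq_len(nk)) {
        if (max(abs(x[i:(i + k - 1)] - x[j:(j + k - 1)])) <= r) cnt <- cnt + 1
      }
      logC[i] <- log(cnt / nk)
    }
    mean(logC)
  }
  phi(m) - phi(m + 1)
}

# Adjusted Fisher-Pearson sample skewness from the textbook formula.
naive_skewness <- function(v) {
  n <- length(v)
  xb <- sum(v) / n
  m2 <- sum((v - xb)^2) / n
  m3 <- sum((v - xb)^3) / n
  (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
}

# Clopper-Pearson bounds by grid inversion of the binomial tails.
grid_clopper_pearson <- function(s, n, level = 0.95, step = 1e-6) {
  alpha <- 1 - level
  p <- seq(step, 1 - step, by = step)
  lower <- if (s == 0) 0 else {
    ok <- p[pbinom(s - 1, n, p, lower.tail = FALSE) >= alpha / 2]
    min(ok)
  }
  upper <- if (s == n) 1 else {
    ok <- p[pbinom(s, n, p) >= alpha / 2]
    max(ok)
  }
  c(lower = lower, upper = upper)
}

# Analytic magnitude response of a digital (bilinear) Butterworth low-pass.
butter_digital_gain <- function(f, fs, cutoff, order) {
  1 / sqrt(1 + (tan(pi * f / fs) / tan(pi * cutoff / fs))^(2 * order))
}

# Fraction of periodogram power at or below f_max (excluding DC).
power_fraction_below <- function(x, fs, f_max) {
  n <- length(x)
  x <- x - mean(x)
  pw <- Mod(fft(x))^2
  k <- 2:(n %/% 2)                     # positive frequencies, no DC
  freqs <- (k - 1) * fs / n
  sum(pw[k][freqs <= f_max]) / sum(pw[k])
}

# Fit amplitude of a known-frequency sinusoid by least squares.
fitted_amplitude <- function(y, t, f) {
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  cf <- qr.solve(X, y - mean(y))
  sqrt(sum(cf^2))
}

make_sine_recording <- function(fs = 50, duration = 180, f = 1, amp = 15,
                                subject = subject_meta(height = 62, weight = 6000)) {
  t <- (seq_len(fs * duration) - 1) / fs
  cop_recording(fs, amp * sin(2 * pi * f * t), amp * cos(2 * pi * f * t),
                subject = subject)
}

write_cop_fixture <- function(x, y, dt = 0.02, path = tempfile(fileext = ".csv")) {
  time <- (seq_along(x) - 1) * dt
  writeLines(c("time,copx,copy", sprintf("%.10g,%.10g,%.10g", time, x, y)),
             path)
  path
}
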