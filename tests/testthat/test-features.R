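processed_from_xy <- function(x, y, fs = 50) {
  # bypass filtering/trimming to probe the feature math directly
  x_c <- x - mean(x); y_c <- y - mean(y)
  structure(list(fs = fs, x = x, y = y, x_c = x_c, y_c = y_c,
                 r_disp = sqrt(x_c^2 + y_c^2),
                 subject = subject_meta(height = 62, weight = 6000),
                 n_analyzed = length(x), valid_fraction = 1,
                 config = preprocess_config()),
            class = "processed_cop")
}

test_that("instantaneous velocity is the forward difference times fs", {
  p <- processed_from_xy(c(0, 1, 2, 3), rep(0, 4))
  v <- instantaneous_velocity(p)
  expect_equal(v$vx, c(50, 50, 50))
  expect_equal(v$vr, c(50, 50, 50))

  pc <- processed_from_xy(rep(2, 10), rep(5, 10))
  expect_true(all(instantaneous_velocity(pc)$vr == 0))

  set.seed(21)
  x <- rnorm(100); y <- rnorm(100)
  v2 <- instantaneous_velocity(processed_from_xy(x, y))
  expect_equal(v2$vx, (x[-1] - x[-100]) * 50)
  expect_equal(v2$vr, sqrt(v2$vx^2 + v2$vy^2))
})

test_that("velocity statistics match direct formula evaluation", {
  s <- velocity_stats(c(50, 50, 50))
  expect_equal(s$std, 0)
  expect_equal(s$rms, 50)
  expect_equal(s$skewness, 0)   # zero-variance convention
  expect_equal(s$range, 0)

  v <- c(1, 2, 3, 10)
  s2 <- velocity_stats(v)
  expect_equal(s2$std, sqrt(sum((v - mean(v))^2) / 3))
  expect_equal(s2$rms, sqrt(mean(v^2)))
  expect_equal(s2$skewness, naive_skewness(v))
  expect_equal(s2$range, 9)

  # scale equivariance: std/rms/range scale, skewness does not
  s3 <- velocity_stats(3.7 * v)
  expect_equal(s3$std, 3.7 * s2$std)
  expect_equal(s3$rms, 3.7 * s2$rms)
  expect_equal(s3$range, 3.7 * s2$range)
  expect_equal(s3$skewness, s2$skewness)

  expect_error(velocity_stats(5), "length error")
})

test_that("path metrics match brute-force summation", {
  # straight path (0,0) -> (3,4) in collinear steps
  steps <- seq(0, 1, length.out = 11)
  p <- processed_from_xy(3 * steps, 4 * steps)
  pm <- path_metrics(p)
  expect_equal(pm$total_distance[["R"]], 5)

  pc <- processed_from_xy(rep(1, 5), rep(1, 5))
  pmc <- path_metrics(pc)
  expect_equal(unname(pmc$total_distance), c(0, 0, 0))
  expect_equal(pmc$average_distance, 0)

  set.seed(13)
  x <- cumsum(rnorm(100)); y <- cumsum(rnorm(100))
  p2 <- processed_from_xy(x, y)
  pm2 <- path_metrics(p2)
  td_r <- 0; td_x <- 0
  for (i in 1:99) {
    td_x <- td_x + abs(x[i + 1] - x[i])
    td_r <- td_r + sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
  }
  expect_equal(pm2$total_distance[["X"]], td_x)
  expect_equal(pm2$total_distance[["R"]], td_r)
  expect_equal(pm2$instantaneous_distance_rms[["X"]],
               sqrt(mean((x - mean(x))^2)))
  # quadratic mean dominates arithmetic mean
  expect_gte(pm2$instantaneous_distance_rms[["R"]], pm2$average_distance)
})

test_that("prediction ellipse matches the closed form", {
  same <- processed_from_xy(rep(1, 10), rep(2, 10))
  el0 <- confidence_ellipse(same)
  expect_equal(el0$area, 0)
  expect_true(el0$degenerate)

  set.seed(99)
  n <- 10000
  p <- processed_from_xy(rnorm(n), rnorm(n))
  el <- confidence_ellipse(p)
  expect_equal(el$area, pi * qchisq(0.95, 2), tolerance = 0.05)
  expect_false(el$degenerate)

  p2 <- processed_from_xy(2 * p$x, 2 * p$y)
  expect_equal(confidence_ellipse(p2)$area, 4 * el$area)

  # anisotropic case: axes follow the covariance eigenstructure
  set.seed(100)
  x <- rnorm(5000, sd = 3); y <- 0.5 * x + rnorm(5000, sd = 1)
  pa <- processed_from_xy(x, y)
  ela <- confidence_ellipse(pa)
  S <- var(cbind(pa$x_c, pa$y_c))
  ev <- eigen(S)$values
  expect_equal(ela$major_axis, 2 * sqrt(qchisq(0.95, 2) * ev[1]))
  expect_equal(ela$minor_axis, 2 * sqrt(qchisq(0.95, 2) * ev[2]))
  expect_equal(ela$area, pi * qchisq(0.95, 2) * sqrt(det(S)))
  expect_true(ela$orientation > -pi / 2 && ela$orientation <= pi / 2)
})

test_that("approximate entropy agrees with the naive oracle and pracma", {
  expect_equal(approximate_entropy(rep(4, 100)), 0)

  x <- rep(c(1, 2, 3), 10)
  r <- 0.5 * sd(x)
  expect_lt(abs(approximate_entropy(x, apen_config(m = 2, r_factor = 0.5)) -
                  naive_apen(x, 2, r)), 1e-12)

  set.seed(31)
  noise <- runif(1000)
  tone <- sin(2 * pi * (1:1000) / 50)
  expect_gt(approximate_entropy(noise), approximate_entropy(tone))

  # independent library cross-check on a moderate series
  set.seed(32)
  z <- as.numeric(arima.sim(list(ar = 0.6), 200))
  expect_equal(approximate_entropy(z),
               pracma::approx_entropy(z, edim = 2, r = 0.2 * sd(z)),
               tolerance = 1e-10)

  expect_error(approximate_entropy(rnorm(20)), "length error")
})

test_that("the battery is complete, deterministic, and matches analytic path length", {
  rec <- make_sine_recording(f = 1, amp = 15)
  p <- preprocess(rec)
  params <- compute_parameters(p)
  expect_identical(names(params$values), parameter_battery_keys())
  expect_true(all(is.finite(params$values)))
  expect_false(params$normalized)

  params2 <- compute_parameters(preprocess(make_sine_recording(f = 1, amp = 15)))
  expect_identical(params$values, params2$values)

  # analytic arc-length oracle for the trimmed circular sweep
  # (the 170 s window is the last 8500 of 9000 samples)
  fs <- 50; t <- (0:8999) / fs
  tw <- t[501:9000]
  xa <- 15 * sin(2 * pi * tw); ya <- 15 * cos(2 * pi * tw)
  oracle <- sum(sqrt(diff(xa)^2 + diff(ya)^2))
  expect_equal(params$values[["total_distance_R"]], oracle, tolerance = 1e-3)
})

test_that("normalization rescales length-dimensioned parameters only", {
  rec <- simulate_cop_recording(simulation_config("normal", seed = 17,
                                                  duration = 40))
  cfg <- preprocess_config(trim_lead = 5, analysis_window = 30)
  params <- compute_parameters(preprocess(rec, cfg))
  h <- rec$subject$height; w_kg <- rec$subject$weight / 1000

  nn <- normalize_parameters(params, "none")
  expect_identical(nn$values, params$values)
  expect_true(nn$normalized)

  nh <- normalize_parameters(params, "height")
  expect_equal(nh$values[["total_distance_R"]],
               params$values[["total_distance_R"]] / h)
  expect_equal(nh$values[["ellipse_area_R"]],
               params$values[["ellipse_area_R"]] / h^2)
  expect_identical(nh$values[["approximate_entropy_R"]],
                   params$values[["approximate_entropy_R"]])
  expect_identical(nh$values[["instantaneous_velocity_skewness_R"]],
                   params$values[["instantaneous_velocity_skewness_R"]])

  nhw <- normalize_parameters(params, "height_weight")
  expect_equal(nhw$values[["instantaneous_velocity_std_R"]],
               params$values[["instantaneous_velocity_std_R"]] / (h * w_kg))

  params$subject <- subject_meta()
  expect_error(normalize_parameters(params, "height"), "height is missing")
  expect_error(normalize_parameters(params, "weight"), "weight is missing")

  # worked division example: 500 mm at 62 cm
  p2 <- params
  p2$subject <- subject_meta(height = 62, weight = 6000)
  p2$values[["total_distance_R"]] <- 500
  expect_equal(normalize_parameters(p2, "height")$values[["total_distance_R"]],
               500 / 62)
})
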