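test_that("the published logistic equation evaluates and orders correctly", {
  m <- fm_logistic_model()
  expect_equal(fm_probability(0, 0, m), 1 / (1 + exp(3.354)))
  expect_equal(round(fm_probability(0, 0, m), 4), 0.0338)

  # monotone with the printed signs
  p0 <- fm_probability(100, 1, m)
  expect_lt(fm_probability(150, 1, m), p0)
  expect_gt(fm_probability(100, 2, m), p0)
  # logistic limit
  expect_gt(fm_probability(100, 1e4, m), 1 - 1e-10)

  expect_error(fm_probability(NA, 1, m), "domain error")
  expect_error(fm_probability(Inf, 1, m), "domain error")
})

test_that("odds ratios and Wald bounds reproduce the printed table", {
  or <- odds_ratios(fm_logistic_model())
  expect_equal(round(or$odds_ratio, 3), c(0.990, 2.447))
  expect_lt(abs(or$lower[2] - 1.376), 0.002)
  expect_lt(abs(or$upper[2] - 4.353), 0.002)
  expect_lt(abs(or$lower[1] - 0.981), 0.002)
  expect_lt(abs(or$upper[1] - 0.999), 0.002)
})

make_params <- function(iv, apen, skew = 0.5, normalized = TRUE) {
  keys <- parameter_battery_keys()
  vals <- stats::setNames(rep(1, length(keys)), keys)
  vals[["instantaneous_velocity_std_R"]] <- iv
  vals[["approximate_entropy_R"]] <- apen
  vals[["instantaneous_velocity_skewness_R"]] <- skew
  structure(list(values = vals, units = parameter_units(),
                 normalized = normalized,
                 scheme = if (normalized) "height_weight" else "none",
                 subject = subject_meta()),
            class = "cop_parameters")
}

test_that("classification applies the 0.15 threshold with ties as absent", {
  m <- fm_logistic_model()
  # invert the logistic for a target probability at fixed apen = 1
  iv_for <- function(p) (log(p / (1 - p)) - m$beta0 - m$beta_apen) / m$beta_iv
  out_hi <- fm_classify(make_params(iv_for(0.16), 1), m)
  expect_equal(out_hi$label, "absent_FM")
  expect_equal(out_hi$probability, 0.16)
  out_lo <- fm_classify(make_params(iv_for(0.14), 1), m)
  expect_equal(out_lo$label, "normal_FM")
  # tie rule: P exactly at the threshold classifies as absent
  params <- make_params(iv_for(0.15), 1)
  p_tie <- fm_probability(params$values[["instantaneous_velocity_std_R"]], 1, m)
  m_tie <- fm_logistic_model(threshold = p_tie)
  expect_equal(fm_classify(params, m_tie)$label, "absent_FM")

  expect_warning(fm_classify(make_params(10, 1, normalized = FALSE), m),
                 "not normalized")
  bad <- make_params(1, 1)
  bad$values <- bad$values[setdiff(names(bad$values), "approximate_entropy_R")]
  expect_error(fm_classify(bad, m), "approximate_entropy_R")
})

test_that("MOS-R prediction follows the printed equation in base 10", {
  m <- mosr_linear_model()
  out <- mosr_predict(1, 1, 1, m)
  expect_equal(out$log_prediction, 1.294)
  expect_equal(out$mosr_estimate, 10^1.294)
  expect_false(out$clamped)

  # monotone in iv_std (coefficient +0.172)
  expect_gt(mosr_predict(2, 1, 1, m)$log_prediction, out$log_prediction)
  # decreasing in skewness and entropy
  expect_lt(mosr_predict(1, 2, 1, m)$log_prediction, out$log_prediction)
  expect_lt(mosr_predict(1, 1, 2, m)$log_prediction, out$log_prediction)

  big <- mosr_predict(1e6, 1, 1, m)
  expect_equal(big$mosr_estimate, 28)
  expect_true(big$clamped)
  tiny <- mosr_predict(1e-6, 1e6, 1e6, m)
  expect_equal(tiny$mosr_estimate, 5)

  expect_error(mosr_predict(1, -0.2, 1, m), "instantaneous_velocity_skewness_R")
  # a configured positive shift rescues non-positive predictors
  shifted <- mosr_predict(1, -0.2, 1, m, shift = 1)
  expect_true(is.finite(shifted$mosr_estimate))

  # under natural log the all-ones prediction (e^1.294 = 3.65) falls below
  # the legal minimum and is clamped -- the reason base 10 is the default
  nat <- mosr_linear_model(log_base = exp(1))
  out_nat <- mosr_predict(1, 1, 1, nat)
  expect_equal(out_nat$log_prediction, 1.294)
  expect_equal(out_nat$mosr_estimate, 5)
  expect_true(out_nat$clamped)
})

test_that("predictor screening applies relevance then collinearity rules", {
  set.seed(41)
  n <- 120
  latent <- rnorm(n)
  y <- ifelse(latent + rnorm(n, sd = 0.8) > 0.8, "absent_FM", "normal_FM")
  tab <- data.frame(
    strong = latent + rnorm(n, sd = 0.5),
    weak = rnorm(n),                       # irrelevant
    dup = NA
  )
  tab$dup <- tab$strong                     # perfect collinearity
  kept <- select_candidate_predictors(tab, y)
  expect_true("strong" %in% kept || "dup" %in% kept)
  expect_false(all(c("strong", "dup") %in% kept))
  expect_false("weak" %in% kept)

  # hand-oracle: exhaustive application of the two rules
  yy <- as.numeric(y == "absent_FM")
  rel <- sapply(tab, function(v) cor(v, yy))
  pv <- sapply(tab, function(v) cor.test(v, yy)$p.value)
  surv <- names(tab)[abs(rel) > 0.25 & pv < 0.05]
  ord <- surv[order(-abs(rel[surv]))]
  hand <- character(0)
  for (cand in ord) {
    if (!any(sapply(hand, function(k)
      abs(cor(tab[[cand]], tab[[k]], method = "spearman")) > 0.7))) {
      hand <- c(hand, cand)
    }
  }
  expect_identical(as.character(kept), hand)

  none <- data.frame(a = rnorm(50), b = rnorm(50))
  expect_length(select_candidate_predictors(none, rbinom(50, 1, 0.5)), 0)
  expect_error(select_candidate_predictors(tab, rep(1, n)),
               "degenerate-outcome")
})

test_that("logistic refit recovers parameters and reports fit statistics", {
  set.seed(71)
  n <- 2000
  truth <- fm_logistic_model()
  tab <- data.frame(
    instantaneous_velocity_std_R = runif(n, 0, 300),
    approximate_entropy_R = runif(n, 0, 2.5)
  )
  p <- fm_probability(tab$instantaneous_velocity_std_R,
                      tab$approximate_entropy_R, truth)
  labels <- ifelse(runif(n) < p, "absent_FM", "normal_FM")
  fit <- refit_logistic(tab, labels,
                        c("instantaneous_velocity_std_R",
                          "approximate_entropy_R"))
  expect_true(fit$converged)
  cf <- fit$coefficients; se <- fit$se
  expect_lt(abs(cf[["(Intercept)"]] - truth$beta0),
            3 * se[["(Intercept)"]])
  expect_lt(abs(cf[["instantaneous_velocity_std_R"]] - truth$beta_iv),
            3 * se[["instantaneous_velocity_std_R"]])
  expect_lt(abs(cf[["approximate_entropy_R"]] - truth$beta_apen),
            3 * se[["approximate_entropy_R"]])
  expect_s3_class(fit$model, "fm_logistic_model")
  expect_gt(fit$model_chisq, 0)

  # labels independent of features: near-null fit
  set.seed(72)
  tab0 <- data.frame(a = rnorm(500), b = rnorm(500))
  y0 <- rbinom(500, 1, 0.3)
  fit0 <- refit_logistic(tab0, y0, c("a", "b"))
  expect_lt(fit0$nagelkerke_r2, 0.05)
  expect_gt(fit0$chisq_p, 0.001)

  sep <- data.frame(v = c(rep(0, 10), rep(10, 10)))
  ysep <- c(rep("normal_FM", 10), rep("absent_FM", 10))
  expect_error(refit_logistic(sep, ysep, "v"), "separation error")
})

test_that("Hosmer-Lemeshow matches a hand-computed case and is calibrated", {
  # two-group hand oracle
  p <- c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9)
  y <- c(0, 0, 1, 0, 1, 0, 1, 1)
  hl <- hosmer_lemeshow(p, y, groups = 2)
  e1 <- sum(p[1:4]); o1 <- 1; n1 <- 4
  e2 <- sum(p[5:8]); o2 <- 3; n2 <- 4
  hand <- (o1 - e1)^2 / (e1 * (1 - e1 / n1)) +
    (o2 - e2)^2 / (e2 * (1 - e2 / n2))
  expect_equal(hl$statistic, hand)
  expect_equal(hl$df, 0L)

  # equal probabilities with matching group rates -> statistic 0
  p0 <- rep(0.3, 100)
  y0 <- rep(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), 10)
  hl0 <- hosmer_lemeshow(p0, y0, groups = 10)
  expect_lt(hl0$statistic, 1e-9)

  # calibrated probabilities: statistic near its df, p not extreme
  set.seed(81)
  pc <- runif(2000, 0.05, 0.95)
  yc <- rbinom(2000, 1, pc)
  hlc <- hosmer_lemeshow(pc, yc)
  expect_equal(hlc$df, 8L)
  expect_gt(hlc$p_value, 0.001)
  expect_lt(hlc$statistic, 35)

  expect_error(hosmer_lemeshow(runif(10), rbinom(10, 1, 0.5), groups = 10),
               "need n >=")
  expect_error(hosmer_lemeshow(c(0, runif(39)), rbinom(40, 1, 0.5), 2),
               "in \\(0, 1\\)")
})

test_that("model files round-trip through JSON", {
  fm <- fm_logistic_model()
  path <- tempfile(fileext = ".json")
  write_model_json(fm, path)
  back <- read_model_json(path)
  expect_equal(back[names(back) != "se"], fm[names(fm) != "se"])
  expect_equal(unname(back$se), unname(fm$se))

  mosr <- mosr_linear_model()
  path2 <- tempfile(fileext = ".json")
  write_model_json(mosr, path2)
  expect_equal(read_model_json(path2), mosr)

  # the shipped model files equal the in-code defaults
  shipped <- read_model_json(system.file("extdata", "fm_model.json",
                                         package = "infantsway"))
  expect_equal(shipped$beta_apen, fm$beta_apen)
  expect_equal(shipped$threshold, fm$threshold)
})
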