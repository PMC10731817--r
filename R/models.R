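#' Published logistic model for absent fidgety movements
#'
#' The binary logistic classifier that predicts absent fidgety movements
#' (FMs) from two resultant-direction COP parameters:
#' \deqn{P(absent) = \frac{1}{1 + e^{-(\beta_0 + \beta_{iv} IV_{std,R} +
#'   \beta_{ApEn} ApEn_R)}}}
#' with published coefficients \eqn{\beta_0 = -3.354},
#' \eqn{\beta_{iv} = -0.010} (instantaneous velocity R, SD) and
#' \eqn{\beta_{ApEn} = 0.895} (approximate entropy R), classification
#' threshold 0.15. Standard errors are retained so the implied odds ratios
#' and their Wald confidence bounds can be reproduced.
#'
#' @param beta0 Intercept.
#' @param beta_iv Coefficient of normalized instantaneous velocity R (SD).
#' @param beta_apen Coefficient of approximate entropy R.
#' @param threshold Classification cutoff on P(absent), in (0, 1).
#' @param se Named numeric standard errors (`iv`, `apen`, `intercept`).
#' @return An object of class `fm_logistic_model`.
#' @export
fm_logistic_model <- function(beta0 = -3.354, beta_iv = -0.010,
                              beta_apen = 0.895, threshold = 0.15,
                              se = c(iv = 0.005, apen = 0.294,
                                     intercept = 1.336)) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(beta0 = beta0, beta_iv = beta_iv, beta_apen = beta_apen,
         threshold = threshold, se = se),
    class = "fm_logistic_model"
  )
}

#' @export
print.fm_logistic_model <- function(x, ...) {
  cat(sprintf(
    "<fm_logistic_model> logit P(absent FM) = %.4g + %.4g * IV_std_R + %.4g * ApEn_R, threshold %.3g\n",
    x$beta0, x$beta_iv, x$beta_apen, x$threshold))
  invisible(x)
}

#' Odds ratios implied by a logistic model
#'
#' @param model An [fm_logistic_model()].
#' @param level Confidence level for the Wald bounds (default 0.95).
#' @return Data frame with predictor, coefficient, odds ratio and Wald
#'   confidence bounds `exp(B +/- z * SE)`.
#' @export
odds_ratios <- function(model, level = 0.95) {
  stopifnot(inherits(model, "fm_logistic_model"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- c(iv = model$beta_iv, apen = model$beta_apen)
  se <- model$se[c("iv", "apen")]
  data.frame(
    predictor = c("instantaneous_velocity_std_R", "approximate_entropy_R"),
    coefficient = unname(b),
    odds_ratio = unname(exp(b)),
    lower = unname(exp(b - z * se)),
    upper = unname(exp(b + z * se)),
    row.names = NULL
  )
}

#' Probability of absent fidgety movements
#'
#' Evaluates the published logistic equation. Strictly decreasing in the
#' velocity-variability predictor and strictly increasing in the approximate
#' entropy predictor.
#'
#' @param iv_std_R Normalized instantaneous velocity R (SD).
#' @param apen_R Approximate entropy R.
#' @param model An [fm_logistic_model()].
#' @return P(absent FMs), in (0, 1). Vectorized over the predictors.
#' @export
fm_probability <- function(iv_std_R, apen_R, model = fm_logistic_model()) {
  if (any(!is.finite(iv_std_R)) || any(!is.finite(apen_R))) {
    stop("domain error: predictors must be finite", call. = FALSE)
  }
  eta <- model$beta0 + model$beta_iv * iv_std_R + model$beta_apen * apen_R
  1 / (1 + exp(-eta))
}

#' Classify a recording's fidgety-movement status
#'
#' Applies [fm_probability()] to the resultant-direction predictors of a
#' parameter set and thresholds the result. A probability exactly at the
#' threshold classifies as `absent_FM` (a screening context favors
#' sensitivity). If the parameters are not normalized, a warning is issued
#' and recorded in the outcome.
#'
#' @param params A `cop_parameters` object containing
#'   `instantaneous_velocity_std_R` and `approximate_entropy_R`.
#' @param model An [fm_logistic_model()].
#' @return A list of class `fm_classification` with `probability`, `label`
#'   (`"absent_FM"` or `"normal_FM"`), `threshold` and `predictors_used`
#'   (values, normalization flag, scheme).
#' @export
fm_classify <- function(params, model = fm_logistic_model()) {
  stopifnot(inherits(params, "cop_parameters"))
  needed <- c("instantaneous_velocity_std_R", "approximate_entropy_R")
  missing_keys <- setdiff(needed, names(params$values))
  if (length(missing_keys)) {
    stop("key error: missing predictor ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  if (!isTRUE(params$normalized)) {
    warning("parameters are not normalized; the published coefficients assume normalized predictors",
            call. = FALSE)
  }
  iv <- params$values[["instantaneous_velocity_std_R"]]
  ap <- params$values[["approximate_entropy_R"]]
  p <- fm_probability(iv, ap, model)
  structure(
    list(probability = p,
         label = if (p >= model$threshold) "absent_FM" else "normal_FM",
         threshold = model$threshold,
         predictors_used = list(instantaneous_velocity_std_R = iv,
                                approximate_entropy_R = ap,
                                normalized = params$normalized,
                                scheme = params$scheme)),
    class = "fm_classification"
  )
}

#' @export
print.fm_classification <- function(x, ...) {
  cat(sprintf("<fm_classification> P(absent FM) = %.4f -> %s (threshold %.3g)\n",
              x$probability, x$label, x$threshold))
  invisible(x)
}

#' Published log-linear model for the MOS-R total score
#'
#' Predicts the Motor Optimality Score-Revised (range 5-28) via
#' \deqn{\log MOS\!-\!R = 1.294 + 0.172 \log IV_{std,R}
#'   - 0.219 \log IV_{skew,R} - 0.265 \log ApEn_R.}
#' Base-10 logarithms are used: the published intercept then places the
#' all-ones prediction (\eqn{10^{1.294} \approx 19.7}) inside the legal MOS-R
#' range, which natural logarithms cannot.
#'
#' @param a0,a_iv_std,a_iv_skew,a_apen Regression coefficients.
#' @param log_base Logarithm base (default 10; set `exp(1)` for natural log).
#' @param score_range Legal MOS-R range used for clamping.
#' @return An object of class `mosr_linear_model`.
#' @export
mosr_linear_model <- function(a0 = 1.294, a_iv_std = 0.172,
                              a_iv_skew = -0.219, a_apen = -0.265,
                              log_base = 10, score_range = c(5, 28)) {
  structure(
    list(a0 = a0, a_iv_std = a_iv_std, a_iv_skew = a_iv_skew,
         a_apen = a_apen, log_base = log_base, score_range = score_range),
    class = "mosr_linear_model"
  )
}

#' Predict the MOS-R total score
#'
#' All three predictors enter as logarithms and must be strictly positive; a
#' non-positive value (e.g. a negative velocity skewness) raises a domain
#' error naming the predictor unless a positive `shift` is supplied, in which
#' case `shift` is added to every predictor before the logarithm. The score
#' estimate is the back-transformed prediction clamped to the legal MOS-R
#' range.
#'
#' @param iv_std_R Normalized instantaneous velocity R (SD), > 0.
#' @param iv_skew_R Instantaneous velocity R skewness, > 0.
#' @param apen_R Approximate entropy R, > 0.
#' @param model A [mosr_linear_model()].
#' @param shift Optional positive shift added to each predictor before the
#'   logarithm (off by default).
#' @return List with `log_prediction`, `mosr_estimate` (clamped to
#'   `score_range`) and `clamped` flag.
#' @export
mosr_predict <- function(iv_std_R, iv_skew_R, apen_R,
                         model = mosr_linear_model(), shift = 0) {
  preds <- c(instantaneous_velocity_std_R = iv_std_R,
             instantaneous_velocity_skewness_R = iv_skew_R,
             approximate_entropy_R = apen_R) + shift
  if (any(!is.finite(preds))) {
    stop("domain error: predictors must be finite", call. = FALSE)
  }
  bad <- names(preds)[preds <= 0]
  if (length(bad)) {
    stop("domain error: non-positive predictor ", paste(bad, collapse = ", "),
         " (logarithm required)", call. = FALSE)
  }
  lg <- function(v) log(v, base = model$log_base)
  log_pred <- model$a0 + model$a_iv_std * lg(preds[[1]]) +
    model$a_iv_skew * lg(preds[[2]]) + model$a_apen * lg(preds[[3]])
  raw <- model$log_base^log_pred
  est <- min(max(raw, model$score_range[1]), model$score_range[2])
  list(log_prediction = log_pred, mosr_estimate = est,
       clamped = !identical(raw, est))
}

#' Screen candidate predictors by relevance and collinearity
#'
#' Two-step screening: (1) keep parameters whose correlation with the
#' outcome exceeds `relevance_cutoff` in absolute value with p < 0.05
#' (point-biserial, i.e. Pearson against a 0/1 indicator, for a dichotomous
#' outcome; rank correlation by default otherwise); (2) scan the survivors
#' in descending absolute outcome correlation and drop any candidate whose
#' absolute correlation with an already-kept predictor exceeds
#' `collinearity_cutoff`.
#'
#' @param feature_table Data frame of numeric parameter columns, one row per
#'   recording.
#' @param outcome Dichotomous (factor/character/logical or 0/1) or numeric
#'   outcome, one value per row.
#' @param relevance_cutoff Minimum absolute outcome correlation (default
#'   0.25).
#' @param collinearity_cutoff Maximum absolute between-predictor correlation
#'   (default 0.70).
#' @param method Correlation among numeric variables: `"spearman"` (default)
#'   or `"pearson"`.
#' @return Character vector of kept predictor names, ordered by decreasing
#'   absolute outcome correlation, with the correlations as the
#'   `"outcome_correlation"` attribute.
#' @export
select_candidate_predictors <- function(feature_table, outcome,
                                        relevance_cutoff = 0.25,
                                        collinearity_cutoff = 0.70,
                                        method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (nrow(feature_table) < 3L) stop("need >= 3 recordings", call. = FALSE)
  if (length(outcome) != nrow(feature_table)) {
    stop("outcome length must match the number of rows", call. = FALSE)
  }
  dichotomous <- !is.numeric(outcome) || length(unique(outcome)) == 2L
  y <- if (is.numeric(outcome)) outcome else as.numeric(factor(outcome)) - 1
  if (stats::var(y) == 0) stop("degenerate-outcome error: outcome is constant",
                               call. = FALSE)
  cols <- names(feature_table)[vapply(feature_table, is.numeric, logical(1))]
  rel <- vapply(cols, function(cl) {
    v <- feature_table[[cl]]
    if (stats::sd(v) == 0) return(c(r = 0, p = 1))
    ct <- suppressWarnings(stats::cor.test(
      v, y, method = if (dichotomous) "pearson" else method, exact = FALSE))
    c(r = unname(ct$estimate), p = ct$p.value)
  }, numeric(2))
  keep1 <- cols[abs(rel["r", ]) > relevance_cutoff & rel["p", ] < 0.05]
  if (!length(keep1)) {
    return(structure(character(0), outcome_correlation = numeric(0)))
  }
  ord <- keep1[order(-abs(rel["r", keep1]))]
  kept <- character(0)
  for (cand in ord) {
    collinear <- FALSE
    for (k in kept) {
      rr <- suppressWarnings(stats::cor(feature_table[[cand]],
                                        feature_table[[k]], method = method))
      if (is.finite(rr) && abs(rr) > collinearity_cutoff) {
        collinear <- TRUE; break
      }
    }
    if (!collinear) kept <- c(kept, cand)
  }
  structure(kept, outcome_correlation = stats::setNames(rel["r", kept], kept))
}

#' Refit the fidgety-movement logistic model
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()],
#' convergence tolerance 1e-8, at most 100 iterations) of absent-FM status
#' on selected parameters, reporting the likelihood-ratio model chi-square
#' \eqn{-2(LL_0 - LL_1)} and Nagelkerke's rescaled pseudo-R-squared.
#'
#' @param feature_table Data frame of numeric parameter columns.
#' @param labels Outcome labels; `"absent_FM"` (or 1/TRUE) is the positive
#'   class.
#' @param predictors Character vector of column names to enter.
#' @return List with `coefficients`, `se`, `model_chisq`, `chisq_df`,
#'   `chisq_p`, `nagelkerke_r2`, `n`, `converged`, `iterations`, the fitted
#'   `glm` object (`fit`) and, when the predictors are exactly the published
#'   pair, an equivalent [fm_logistic_model()] under `model`.
#' @export
refit_logistic <- function(feature_table, labels, predictors) {
  y <- as_absent_indicator(labels)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  n <- length(y)
  if (n <= length(predictors) + 1L) {
    stop("need n > number of predictors + 1", call. = FALSE)
  }
  missing_cols <- setdiff(predictors, names(feature_table))
  if (length(missing_cols)) {
    stop("key error: missing predictor ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- feature_table[, predictors, drop = FALSE]
  dat$.y <- y
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) {
    stop(sprintf("convergence error: IRLS did not converge in %d iterations",
                 fit$iter), call. = FALSE)
  }
  mu <- stats::fitted(fit)
  if (all(abs(mu - y) < 1e-6)) {
    stop("separation error: outcome is perfectly separated by the predictors",
         call. = FALSE)
  }
  dev1 <- fit$deviance
  dev0 <- fit$null.deviance
  chisq <- dev0 - dev1
  df <- length(predictors)
  # Nagelkerke: Cox-Snell rescaled by its maximum
  cox_snell <- 1 - exp((dev1 - dev0) / n)
  max_cs <- 1 - exp(-dev0 / n)
  nagelkerke <- if (max_cs > 0) cox_snell / max_cs else 0
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  out <- list(coefficients = cf, se = se,
              model_chisq = chisq, chisq_df = df,
              chisq_p = stats::pchisq(chisq, df, lower.tail = FALSE),
              nagelkerke_r2 = nagelkerke, n = n,
              converged = fit$converged, iterations = fit$iter, fit = fit)
  pub <- c("instantaneous_velocity_std_R", "approximate_entropy_R")
  if (identical(sort(predictors), sort(pub))) {
    out$model <- fm_logistic_model(
      beta0 = unname(cf["(Intercept)"]),
      beta_iv = unname(cf["instantaneous_velocity_std_R"]),
      beta_apen = unname(cf["approximate_entropy_R"]),
      se = c(iv = unname(se["instantaneous_velocity_std_R"]),
             apen = unname(se["approximate_entropy_R"]),
             intercept = unname(se["(Intercept)"])))
  }
  out
}

as_absent_indicator <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1",
                                        call. = FALSE)
    return(as.integer(labels))
  }
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("absent_FM", "normal_FM"))
  if (length(bad)) {
    stop("labels must be 'absent_FM' or 'normal_FM', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  as.integer(labels == "absent_FM")
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups observations into `groups` risk strata by predicted probability
#' (stable ordering for ties) and computes
#' \deqn{HL = \sum_g \frac{(O_g - E_g)^2}{E_g (1 - E_g / n_g)}}
#' which sums the standard \eqn{(O-E)^2/E} contributions over both outcome
#' levels; df = groups - 2, p-value from the upper chi-square tail. Groups
#' whose expected count is zero are merged with their neighbor and the merge
#' is recorded.
#'
#' @param probabilities Predicted probabilities in (0, 1).
#' @param labels Outcome labels (positive class as in [refit_logistic()]).
#' @param groups Number of risk strata (default 10, "deciles of risk").
#' @return List with `statistic`, `df`, `p_value`, `groups_used`,
#'   `collapsed` (number of merges) and the per-group `table`.
#' @export
hosmer_lemeshow <- function(probabilities, labels, groups = 10) {
  y <- as_absent_indicator(labels)
  n <- length(y)
  if (length(probabilities) != n) stop("length mismatch", call. = FALSE)
  if (n < 2L * groups) stop(sprintf("need n >= %d for %d groups", 2L * groups,
                                    groups), call. = FALSE)
  if (any(probabilities <= 0 | probabilities >= 1)) {
    stop("probabilities must be in (0, 1)", call. = FALSE)
  }
  ord <- order(probabilities)          # stable for ties
  p <- probabilities[ord]; yy <- y[ord]
  bounds <- round(seq(0, n, length.out = groups + 1))
  grp <- findInterval(seq_len(n), bounds[-1] + 0.5) + 1L
  tab <- data.frame(
    n = as.vector(tapply(yy, grp, length)),
    observed = as.vector(tapply(yy, grp, sum)),
    expected = as.vector(tapply(p, grp, sum))
  )
  # merge groups with degenerate expectation into the previous one
  collapsed <- 0L
  i <- 1L
  while (i <= nrow(tab)) {
    e <- tab$expected[i]
    if ((e <= 0 || e >= tab$n[i]) && nrow(tab) > 1L) {
      j <- if (i == 1L) 2L else i - 1L
      tab$n[j] <- tab$n[j] + tab$n[i]
      tab$observed[j] <- tab$observed[j] + tab$observed[i]
      tab$expected[j] <- tab$expected[j] + tab$expected[i]
      tab <- tab[-i, , drop = FALSE]
      collapsed <- collapsed + 1L
      i <- 1L
    } else i <- i + 1L
  }
  stat <- sum((tab$observed - tab$expected)^2 /
                (tab$expected * (1 - tab$expected / tab$n)))
  g <- nrow(tab)
  df <- g - 2L
  list(statistic = stat, df = df,
       p_value = if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE)
                 else NA_real_,
       groups_used = g, collapsed = collapsed, table = tab)
}

#' Write or read a prediction-model file
#'
#' Models ship as versioned human-readable JSON so a CLI run can be pointed
#' at a refitted model with the same schema.
#'
#' @param model An [fm_logistic_model()] or [mosr_linear_model()].
#' @param path File path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns the reconstructed model object.
#' @export
write_model_json <- function(model, path) {
  kind <- if (inherits(model, "fm_logistic_model")) "fm_logistic"
          else if (inherits(model, "mosr_linear_model")) "mosr_linear"
          else stop("unsupported model class", call. = FALSE)
  payload <- c(list(kind = kind, schema_version = 1L), unclass(model))
  payload$fit <- NULL
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$kind)) stop("model file lacks a 'kind' field", call. = FALSE)
  switch(obj$kind,
    fm_logistic = fm_logistic_model(
      beta0 = obj$beta0, beta_iv = obj$beta_iv, beta_apen = obj$beta_apen,
      threshold = obj$threshold, se = unlist(obj$se)),
    mosr_linear = mosr_linear_model(
      a0 = obj$a0, a_iv_std = obj$a_iv_std, a_iv_skew = obj$a_iv_skew,
      a_apen = obj$a_apen, log_base = obj$log_base,
      score_range = unlist(obj$score_range)),
    stop("unknown model kind: ", obj$kind, call. = FALSE)
  )
}
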