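#' Confusion matrix for fidgety-movement classification
#'
#' Counts with `absent_FM` as the positive class.
#'
#' @param predicted,actual Label vectors (`"absent_FM"` / `"normal_FM"`, or
#'   logical/0-1 indicators of the positive class), equal length.
#' @return An object of class `confusion_matrix` with integer fields `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
confusion_matrix <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("shape error: predicted and actual must have equal length",
         call. = FALSE)
  }
  if (!length(predicted)) stop("shape error: empty label vectors",
                               call. = FALSE)
  p <- as_absent_indicator(predicted)
  a <- as_absent_indicator(actual)
  structure(
    list(tp = sum(p == 1 & a == 1), fp = sum(p == 1 & a == 0),
         tn = sum(p == 0 & a == 0), fn = sum(p == 0 & a == 1)),
    class = "confusion_matrix"
  )
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts (positive class =
#'   absent FMs).
#' @return An object of class `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) < 1) stop("total count must be >= 1", call. = FALSE)
  structure(lapply(as.list(counts), as.integer), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fp=%d tn=%d fn=%d (positive = absent_FM)\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Exact interval by inversion of the binomial tails, in Beta quantile form:
#' lower = \eqn{B^{-1}(\alpha/2;\, s,\, n-s+1)} (0 when s = 0),
#' upper = \eqn{B^{-1}(1-\alpha/2;\, s+1,\, n-s)} (1 when s = n). The exact
#' method is conservative: coverage is at least nominal.
#'
#' @param successes Number of successes (0 <= successes <= n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @return An object of class `proportion_ci` with `estimate`, `lower`,
#'   `upper`, `level`, `method`.
#' @export
clopper_pearson <- function(successes, n, level = 0.95) {
  if (n < 1 || successes < 0 || successes > n ||
      successes != round(successes) || n != round(n)) {
    stop("domain error: need integer 0 <= successes <= n, n >= 1",
         call. = FALSE)
  }
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  structure(
    list(estimate = successes / n, lower = lower, upper = upper,
         level = level, method = "Clopper-Pearson"),
    class = "proportion_ci"
  )
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%.3f (%g%% CI: %.3f-%.3f, %s)\n", x$estimate, 100 * x$level,
              x$lower, x$upper, x$method))
  invisible(x)
}

#' Diagnostic-accuracy metrics with exact confidence intervals
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), accuracy (tp+tn)/total,
#' PPV tp/(tp+fp) and NPV tn/(tn+fn), each with an exact Clopper-Pearson
#' interval. A metric whose denominator is zero is reported as `NA` with an
#' `undefined` flag rather than raising an error.
#'
#' @param cm A `confusion_matrix`.
#' @param level Confidence level (default 0.95).
#' @return A list of class `diagnostic_metrics`: one element per metric, each
#'   holding `estimate`, `lower`, `upper`, `successes`, `n`, `undefined`.
#' @export
diagnostic_metrics <- function(cm, level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  defs <- list(
    sensitivity = c(cm$tp, cm$tp + cm$fn),
    specificity = c(cm$tn, cm$tn + cm$fp),
    accuracy = c(cm$tp + cm$tn, total),
    ppv = c(cm$tp, cm$tp + cm$fp),
    npv = c(cm$tn, cm$tn + cm$fn)
  )
  out <- lapply(defs, function(sn) {
    if (sn[2] == 0) {
      return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                  successes = sn[1], n = sn[2], undefined = TRUE))
    }
    ci <- clopper_pearson(sn[1], sn[2], level)
    list(estimate = ci$estimate, lower = ci$lower, upper = ci$upper,
         successes = sn[1], n = sn[2], undefined = FALSE)
  })
  structure(out, class = "diagnostic_metrics", level = level)
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  for (nm in names(x)) {
    m <- x[[nm]]
    if (m$undefined) {
      cat(sprintf("%-12s undefined (denominator 0)\n", nm))
    } else {
      cat(sprintf("%-12s %d%% (%g%% CI: %d-%d)  [%d/%d]\n", nm,
                  round_half_up(100 * m$estimate),
                  100 * attr(x, "level"),
                  round_half_up(100 * m$lower), round_half_up(100 * m$upper),
                  m$successes, m$n))
    }
  }
  invisible(x)
}

# Half-up rounding to integer percent, the display convention of clinical
# accuracy reports (base round() is half-to-even).
round_half_up <- function(x) floor(x + 0.5)
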