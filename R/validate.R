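#' Validate back-transformed BMI predictions against measurements
#'
#' Method-agreement check of predicted BMI (pBMI) against measured BMI:
#' OLS of measured on predicted with a test of `H0: slope = 1` (single
#' linear restriction; F with 1 numerator df, identical to the squared t),
#' a paired t-test of the mean difference against 0, Pearson correlation,
#' and a CUSUM check that the measured-predicted relation is itself linear.
#' A slope of 1 and intercept of 0 indicate unbiased prediction.
#'
#' @param bmi_measured,bmi_predicted equal-length numeric vectors, n >= 10.
#' @param alpha level for the two-sided tests and the CUSUM check.
#' @param cusum_sims permutation draws for the CUSUM null.
#' @param seed seed for the CUSUM permutation null.
#' @return object of class `validation_result` with fields `slope`,
#'   `intercept`, `slope_test_stat` (F), `slope_test_p`, `paired_diff_mean`,
#'   `paired_t_p`, `pearson_r`, `r_squared`, `cusum_linear_ok`, `n`,
#'   `alpha`.
#' @export
validate_predictions <- function(bmi_measured, bmi_predicted, alpha = 0.05,
                                 cusum_sims = 2000, seed = NULL) {
  if (length(bmi_measured) != length(bmi_predicted))
    stop("measured and predicted vectors differ in length", call. = FALSE)
  n <- length(bmi_measured)
  if (n < 10) stop("need n >= 10 for validation", call. = FALSE)
  check_scalar(alpha, "alpha", lower = 0, upper = 1)
  if (stats::sd(bmi_predicted) == 0)
    stop("zero variance in predictions: slope undefined", call. = FALSE)

  fit <- stats::lm(bmi_measured ~ bmi_predicted)
  sm <- suppressWarnings(summary(fit)) # silence 'essentially perfect fit'
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  se_slope <- sm$coefficients[2, 2]
  if (se_slope <= 1e-10 * max(abs(slope), 1)) { # numerically exact affine fit
    exact_one <- abs(slope - 1) <= 1e-8
    fstat <- if (exact_one) 0 else Inf
    slope_p <- if (exact_one) 1 else 0
  } else {
    tstat <- (slope - 1) / se_slope
    fstat <- tstat^2
    slope_p <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  }

  d <- bmi_measured - bmi_predicted
  if (stats::sd(d) <= 1e-12 * max(stats::sd(bmi_measured), 1)) {
    paired_p <- if (abs(mean(d)) <= 1e-10) 1 else 0
  } else {
    paired_p <- stats::t.test(d)$p.value
  }

  cus <- cusum_linearity_test(bmi_predicted, bmi_measured, alpha = alpha,
                              n_sims = cusum_sims, seed = seed)

  structure(list(slope = slope, intercept = intercept,
                 slope_test_stat = fstat, slope_test_p = slope_p,
                 paired_diff_mean = mean(d), paired_t_p = paired_p,
                 pearson_r = stats::cor(bmi_measured, bmi_predicted),
                 r_squared = sm$r.squared,
                 cusum_linear_ok = !cus$reject_linearity,
                 n = n, alpha = alpha),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("Measured-on-predicted BMI validation\n")
  cat(sprintf("  BMI = %.4f x pBMI %+.4f  (R2 = %.4f, r = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$pearson_r, x$n))
  cat(sprintf("  slope = 1: F(1, %d) = %.3f, p = %.3f\n",
              x$n - 2, x$slope_test_stat, x$slope_test_p))
  cat(sprintf("  paired mean difference = %.4f kg/m2, p = %.3f\n",
              x$paired_diff_mean, x$paired_t_p))
  cat(sprintf("  CUSUM linear association: %s\n",
              if (x$cusum_linear_ok) "ok" else "rejected"))
  invisible(x)
}
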