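#' Fit a log-scale polynomial adiposity model
#'
#' Regresses `ln(BMI)` on raw polynomial terms of BF% by ordinary least
#' squares for every degree `1..max_degree` and keeps the degree with the
#' highest *adjusted* R^2.  (Plain R^2 is monotone in degree, so selection
#' uses the adjusted version while the plain value is what gets reported --
#' the convention in the body-composition literature this mirrors.)  The
#' natural log is used throughout; predictions back-transform with `exp`.
#'
#' @param bf_pct body-fat percentages (predictor).
#' @param bmi positive BMI values (response), same length.
#' @param max_degree largest polynomial degree considered (1..3).
#' @param degree force this exact degree instead of selecting by adjusted
#'   R^2 (e.g. for parameter-recovery studies); default `NULL` selects.
#' @return an object of class `adiposity_model`: `coeffs` (c0..c_degree),
#'   `degree`, `r_squared` (plain), `adj_r_squared`, `resid_sd` (residual SD
#'   in ln-units), `n_fit`, `bf_range_fit`.
#' @export
#' @examples
#' x <- seq(6, 30, length.out = 50)
#' m <- fit_log_polynomial(x, exp(3.2 - 0.02 * x + 0.001 * x^2))
#' m$degree # 2
fit_log_polynomial <- function(bf_pct, bmi, max_degree = 3, degree = NULL) {
  if (!is.null(degree)) {
    check_scalar(degree, "degree", lower = 1, upper = 3,
                 strict = c(FALSE, FALSE))
    max_degree <- as.integer(degree)
  }
  if (length(bf_pct) != length(bmi))
    stop("'bf_pct' and 'bmi' differ in length", call. = FALSE)
  check_scalar(max_degree, "max_degree", lower = 1, upper = 3,
               strict = c(FALSE, FALSE))
  max_degree <- as.integer(max_degree)
  n <- length(bmi)
  if (n <= max_degree + 2)
    stop(sprintf("need n > max_degree + 2 observations (have %d)", n),
         call. = FALSE)
  if (any(!is.finite(bf_pct)) || any(!is.finite(bmi)))
    stop("non-finite values in input", call. = FALSE)
  if (any(bmi <= 0)) stop("all 'bmi' values must be positive", call. = FALSE)
  if (length(unique(bf_pct)) <= max_degree)
    stop("'bf_pct' has too few distinct values (collinear predictor)",
         call. = FALSE)

  ln_bmi <- log(bmi)
  # constant response: R^2 is 0/0 and summary.lm returns rounding noise;
  # define the fit as the flat degree-1 line with nothing explained
  if (stats::sd(ln_bmi) <= 1e-12 * max(abs(mean(ln_bmi)), 1)) {
    coeffs <- c(c0 = mean(ln_bmi), c1 = 0)
    return(structure(list(coeffs = coeffs, degree = 1L, r_squared = 0,
                          adj_r_squared = 0, resid_sd = 0, n_fit = n,
                          bf_range_fit = range(bf_pct)),
                     class = "adiposity_model"))
  }
  degrees <- if (is.null(degree)) seq_len(max_degree) else as.integer(degree)
  fits <- lapply(degrees, function(d) {
    X <- stats::poly(bf_pct, degree = d, raw = TRUE)
    fit <- stats::lm(ln_bmi ~ X)
    sm <- suppressWarnings(summary(fit)) # silence 'essentially perfect fit'
    list(degree = d, coeffs = unname(stats::coef(fit)),
         r2 = sm$r.squared, ar2 = sm$adj.r.squared, sigma = sm$sigma)
  })
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "ar2"))]]
  coeffs <- best$coeffs
  names(coeffs) <- paste0("c", seq_along(coeffs) - 1L)
  model <- list(coeffs = coeffs, degree = best$degree,
                r_squared = best$r2, adj_r_squared = best$ar2,
                resid_sd = best$sigma, n_fit = n,
                bf_range_fit = range(bf_pct))
  class(model) <- "adiposity_model"
  model
}

# Build an adiposity_model from known coefficients (no data behind it);
# used for closed-form work and in tests.  bf_range defaults wide open.
#' Construct an adiposity model from known coefficients
#'
#' Wraps a coefficient vector `(c0, c1, ...)` of `ln BMI = c0 + c1 x + ...`
#' into an `adiposity_model` without fitting, e.g. to evaluate a published
#' or pre-calibrated curve.
#'
#' @param coeffs numeric vector of polynomial coefficients, intercept first.
#' @param bf_range_fit BF% interval the curve is considered supported on.
#' @return an `adiposity_model`.
#' @export
adiposity_model <- function(coeffs, bf_range_fit = c(5, 35)) {
  if (!is.numeric(coeffs) || length(coeffs) < 2L || length(coeffs) > 4L ||
      any(!is.finite(coeffs)))
    stop("'coeffs' must be 2-4 finite numbers (intercept first)",
         call. = FALSE)
  stopifnot(is.numeric(bf_range_fit), length(bf_range_fit) == 2L,
            bf_range_fit[1] < bf_range_fit[2])
  coeffs <- as.numeric(coeffs)
  names(coeffs) <- paste0("c", seq_along(coeffs) - 1L)
  structure(list(coeffs = coeffs, degree = length(coeffs) - 1L,
                 r_squared = NA_real_, adj_r_squared = NA_real_,
                 resid_sd = NA_real_, n_fit = 0L,
                 bf_range_fit = as.numeric(bf_range_fit)),
            class = "adiposity_model")
}

eval_log_poly <- function(model, x) {
  cf <- model$coeffs
  out <- rep(cf[[1]], length(x))
  for (k in seq_along(cf)[-1]) out <- out + cf[[k]] * x^(k - 1L)
  out
}

#' Predicted BMI from an adiposity model
#'
#' Evaluates the fitted log-scale polynomial at `bf_pct` and
#' back-transforms: `pBMI = exp(c0 + c1 x + ...)`.  Requests outside the
#' fitted BF% range raise a warning; beyond `guard` percentage points past
#' the range the warning flags heavy extrapolation (the result is still
#' returned -- never silently, never as an error).
#'
#' @param model an `adiposity_model`.
#' @param bf_pct BF% values at which to predict.
#' @param guard extrapolation guard in BF percentage points (default 2).
#' @return positive numeric vector of predicted BMI (kg/m^2).
#' @export
predict_bmi <- function(model, bf_pct, guard = 2) {
  stopifnot(inherits(model, "adiposity_model"))
  if (!is.numeric(bf_pct) || any(!is.finite(bf_pct)))
    stop("'bf_pct' must be finite numeric", call. = FALSE)
  rng <- model$bf_range_fit
  out_rng <- bf_pct < rng[1] | bf_pct > rng[2]
  out_guard <- bf_pct < rng[1] - guard | bf_pct > rng[2] + guard
  if (any(out_guard))
    warning(sprintf(
      "%d value(s) more than %g BF%% points outside the fitted range [%.2f, %.2f]: heavy extrapolation",
      sum(out_guard), guard, rng[1], rng[2]))
  else if (any(out_rng))
    warning(sprintf(
      "%d value(s) outside the fitted BF%% range [%.2f, %.2f] (within the %g-point guard)",
      sum(out_rng), rng[1], rng[2], guard))
  exp(eval_log_poly(model, bf_pct))
}

#' @export
print.adiposity_model <- function(x, ...) {
  terms <- c("", " BF%", " BF%^2", " BF%^3")[seq_along(x$coeffs)]
  eq <- paste(sprintf("%+.6g%s", x$coeffs, terms), collapse = " ")
  cat("Log-polynomial adiposity model\n")
  cat("  ln BMI =", sub("^\\+", "", eq), "\n")
  cat(sprintf("  degree %d, n = %d, R2 = %.4f (adj %.4f), resid SD = %.4f\n",
              x$degree, x$n_fit, x$r_squared, x$adj_r_squared, x$resid_sd))
  cat(sprintf("  fitted BF%% range: [%.2f, %.2f]\n",
              x$bf_range_fit[1], x$bf_range_fit[2]))
  invisible(x)
}
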