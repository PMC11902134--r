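#' Configuration for the synthetic athlete-cohort generator
#'
#' Describes the joint distribution of a cohort of young adult male athletes:
#' a right-skewed body-fat percentage (BF%) marginal, a log-quadratic
#' BMI--BF% relation with normal errors on the log scale, and independent
#' height and age marginals.  Defaults describe a reference population of
#' n = 622 Caucasian male athletes (BF% 13.1 +/- 3.4, height 182.8 +/- 9.2 cm,
#' age 25.7 +/- 4.7 y, lean-mass fraction 82.8 +/- 3.2%) whose log-quadratic
#' curve passes through BMI 24.1 at BF% 13.1, BMI 28.2 at BF% 21 and BMI 33.7
#' at BF% 26 (the three anchors used for cut-off derivation; see
#' `scripts/calibration.R` in the source tree for the solve).
#'
#' BF% is drawn from a gamma distribution with its origin shifted to `bf_min`
#' and shape/scale matched to (`bf_mean`, `bf_sd`) by moments, redrawn when
#' outside `[bf_min, bf_max]`.  A shifted gamma is used because BF% in lean
#' athletes is bounded below physiologically and right-skewed; a normal
#' marginal would put mass at impossible BF% values.
#'
#' @param n_subjects number of athletes (>= 10).
#' @param seed integer RNG seed; identical config + seed gives a
#'   bit-identical cohort.
#' @param bf_mean,bf_sd target BF% mean and SD (percent).
#' @param bf_min,bf_max physiological truncation bounds for BF% (percent).
#' @param height_mean,height_sd height marginal (cm).
#' @param age_mean,age_sd age marginal (years); ages below 20 are redrawn
#'   (cohort inclusion criterion).
#' @param lm_frac_mean,lm_frac_sd lean-mass fraction of body weight
#'   (proportion); values with `lm_frac + bf_pct/100 >= 1` are redrawn so the
#'   bone-mineral remainder stays positive.
#' @param ln_coeffs numeric triple `(c0, c1, c2)` of the generating
#'   log-quadratic: `ln BMI = c0 + c1 BF% + c2 BF%^2 + eps`.
#' @param resid_sd SD of `eps` in ln-units.  The default 0.057 is calibrated
#'   (once, by simulation) so that refitting the quadratic on default cohorts
#'   returns R^2 of about 0.445.
#' @return an object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_subjects = 622,
                          seed = 1L,
                          bf_mean = 13.1, bf_sd = 3.4,
                          bf_min = 5, bf_max = 35,
                          height_mean = 182.8, height_sd = 9.2,
                          age_mean = 25.7, age_sd = 4.7,
                          lm_frac_mean = 0.828, lm_frac_sd = 0.032,
                          ln_coeffs = c(3.25751869715676,
                                        -0.02174057985959,
                                        0.00122076067537),
                          resid_sd = 0.057) {
  check_scalar(n_subjects, "n_subjects", lower = 10, strict = c(FALSE, TRUE))
  check_scalar(seed, "seed")
  check_scalar(bf_sd, "bf_sd", lower = 0)
  check_scalar(height_sd, "height_sd", lower = 0)
  check_scalar(age_sd, "age_sd", lower = 0)
  check_scalar(lm_frac_sd, "lm_frac_sd", lower = 0)
  check_scalar(resid_sd, "resid_sd", lower = 0, strict = c(FALSE, TRUE))
  if (!(bf_min < bf_mean && bf_mean < bf_max))
    stop("'bf_min < bf_mean < bf_max' is required", call. = FALSE)
  if (!is.numeric(ln_coeffs) || length(ln_coeffs) != 3L ||
      any(!is.finite(ln_coeffs)))
    stop("'ln_coeffs' must be a finite numeric triple (c0, c1, c2)",
         call. = FALSE)
  cfg <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
              bf_mean = bf_mean, bf_sd = bf_sd,
              bf_min = bf_min, bf_max = bf_max,
              height_mean = height_mean, height_sd = height_sd,
              age_mean = age_mean, age_sd = age_sd,
              lm_frac_mean = lm_frac_mean, lm_frac_sd = lm_frac_sd,
              ln_coeffs = as.numeric(ln_coeffs), resid_sd = resid_sd)
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic athlete cohort configuration\n")
  cat(sprintf("  n = %d, seed = %d\n", x$n_subjects, x$seed))
  cat(sprintf("  BF%%: %.1f +/- %.1f (shifted gamma on [%.0f, %.0f])\n",
              x$bf_mean, x$bf_sd, x$bf_min, x$bf_max))
  cat(sprintf("  ln BMI = %.4f + %.4f BF%% + %.6f BF%%^2 + N(0, %.3f)\n",
              x$ln_coeffs[1], x$ln_coeffs[2], x$ln_coeffs[3], x$resid_sd))
  invisible(x)
}

# Shifted-gamma shape/scale implied by the BF% moments.
bf_gamma_params <- function(cfg) {
  m <- cfg$bf_mean - cfg$bf_min
  list(shape = (m / cfg$bf_sd)^2, scale = cfg$bf_sd^2 / m)
}

cohort_columns <- c("age", "weight_kg", "height_cm", "bmi",
                    "lean_mass_kg", "fat_mass_kg", "bf_pct")

#' Generate a synthetic athlete cohort
#'
#' Draws `n_subjects` athletes from the joint distribution described by a
#' [cohort_config()].  BF% is drawn first, then `ln BMI` from the generating
#' log-quadratic plus normal noise, then height; weight follows from BMI and
#' height, fat mass from BF% and weight, and lean mass from an independently
#' drawn lean-mass fraction (the remainder is bone mineral).  Records
#' violating the cohort inclusion criteria (age >= 20 y, BMI >= 20 kg/m^2)
#' or the BF% bounds are redrawn rather than clipped, so no probability mass
#' piles up at the boundaries.
#'
#' @param config a [cohort_config()].
#' @return a `data.frame` of class `athlete_cohort` with columns
#'   `age`, `weight_kg`, `height_cm`, `bmi`, `lean_mass_kg`, `fat_mass_kg`,
#'   `bf_pct`, one row per athlete.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 50, seed = 7))
#' summary(coh$bf_pct)
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("'config' must be created by cohort_config()", call. = FALSE)
  gp <- bf_gamma_params(config)
  cf <- config$ln_coeffs
  n <- config$n_subjects

  with_seed(config$seed, {
    acc <- vector("list", 0L)
    got <- 0L
    while (got < n) {
      nb <- max(64L, ceiling((n - got) * 1.4))
      bf <- config$bf_min + stats::rgamma(nb, shape = gp$shape,
                                          scale = gp$scale)
      ln_bmi <- cf[1] + cf[2] * bf + cf[3] * bf^2 +
        stats::rnorm(nb, 0, config$resid_sd)
      bmi <- exp(ln_bmi)
      height <- stats::rnorm(nb, config$height_mean, config$height_sd)
      age <- stats::rnorm(nb, config$age_mean, config$age_sd)
      keep <- bf >= config$bf_min & bf <= config$bf_max &
        bmi >= 20 & age >= 20 & height > 0
      if (!any(keep)) next
      bf <- bf[keep]; bmi <- bmi[keep]
      height <- height[keep]; age <- age[keep]
      nk <- length(bf)
      # lean fraction: normal truncated above at the fraction left after fat
      # (inverse-CDF draw), so fat + lean <= weight and bone mineral >= 0.
      # At high BF% the admissible upper tail is tiny; truncation is exact
      # and loop-free where rejection sampling would effectively hang.
      ub <- stats::pnorm(1 - bf / 100, config$lm_frac_mean,
                         config$lm_frac_sd)
      lb <- stats::pnorm(0, config$lm_frac_mean, config$lm_frac_sd)
      u <- lb + stats::runif(nk) * (ub - lb)
      lmf <- stats::qnorm(u, config$lm_frac_mean, config$lm_frac_sd)
      lmf <- pmin(lmf, 1 - bf / 100) # guard against qnorm rounding at u ~ ub
      weight <- bmi * (height / 100)^2
      batch <- data.frame(age = age, weight_kg = weight, height_cm = height,
                          bmi = bmi, lean_mass_kg = lmf * weight,
                          fat_mass_kg = bf / 100 * weight, bf_pct = bf)
      acc[[length(acc) + 1L]] <- batch
      got <- got + nk
    }
    out <- do.call(rbind, acc)[seq_len(n), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("athlete_cohort", "data.frame")
    out
  })
}

# Per-row invariant checks shared by read_cohort()/write_cohort().
# Returns a character vector of row-indexed problems (empty when clean).
cohort_problems <- function(df, bmi_tol = 0.05, fat_tol = 0.1) {
  probs <- character(0)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    bad <- function(msg) probs[[length(probs) + 1L]] <<-
        sprintf("row %d: %s", i, msg)
    if (any(!is.finite(unlist(r[cohort_columns]))))
      { bad("non-finite value"); next }
    if (r$bf_pct <= 0 || r$bf_pct >= 100)
      bad(sprintf("bf_pct = %g must be in (0, 100)", r$bf_pct))
    if (r$height_cm <= 0) bad("height_cm must be positive")
    if (r$weight_kg <= 0) bad("weight_kg must be positive")
    if (abs(r$bmi - r$weight_kg / (r$height_cm / 100)^2) > bmi_tol)
      bad(sprintf("bmi = %g inconsistent with weight/height^2 = %g",
                  r$bmi, r$weight_kg / (r$height_cm / 100)^2))
    if (abs(r$fat_mass_kg - r$bf_pct / 100 * r$weight_kg) > fat_tol)
      bad(sprintf("fat_mass_kg = %g inconsistent with bf_pct/100 * weight = %g",
                  r$fat_mass_kg, r$bf_pct / 100 * r$weight_kg))
    if (r$lean_mass_kg + r$fat_mass_kg > r$weight_kg + fat_tol)
      bad("lean + fat mass exceeds body weight")
    if (r$bmi < 20) bad(sprintf("bmi = %g below inclusion minimum 20", r$bmi))
    if (r$age < 20) bad(sprintf("age = %g below inclusion minimum 20", r$age))
  }
  probs
}

validate_cohort <- function(df, context = "cohort") {
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols))
    stop(sprintf("%s is missing column(s): %s", context,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0L)
    stop(sprintf("%s contains no data rows", context), call. = FALSE)
  for (cl in cohort_columns)
    if (!is.numeric(df[[cl]]))
      stop(sprintf("%s column '%s' is not numeric", context, cl),
           call. = FALSE)
  probs <- cohort_problems(df)
  if (length(probs))
    stop(sprintf("%s has invalid records:\n  %s", context,
                 paste(probs, collapse = "\n  ")), call. = FALSE)
  df <- df[, cohort_columns]
  class(df) <- c("athlete_cohort", "data.frame")
  df
}

#' Read / write an athlete cohort CSV
#'
#' The on-disk format is a UTF-8 CSV with header
#' `age,weight_kg,height_cm,bmi,lean_mass_kg,fat_mass_kg,bf_pct` and dot
#' decimal separator.  Reading validates every row against the record
#' invariants (BMI consistent with weight/height, fat mass consistent with
#' BF%, inclusion criteria age >= 20 and BMI >= 20) and fails with
#' row-indexed messages on violation.
#'
#' @param path file path.
#' @return `read_cohort()` returns an `athlete_cohort` data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cohort file '%s' does not exist", path), call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("cannot parse '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  validate_cohort(df, context = sprintf("'%s'", path))
}

#' @rdname read_cohort
#' @param records an `athlete_cohort` data frame (or anything with the seven
#'   cohort columns).
#' @return `write_cohort()` invisibly returns `path`.
#' @export
write_cohort <- function(records, path) {
  records <- validate_cohort(as.data.frame(records), context = "'records'")
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
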