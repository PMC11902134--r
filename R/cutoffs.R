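#' Derive population-specific BMI cut-offs from an adiposity model
#'
#' Substitutes the BF% thresholds of `bands` into the fitted log-polynomial
#' and back-transforms: `cutoff = exp(c0 + c1 t + c2 t^2)` at `t =`
#' overweight / obesity BF%.  Cut-offs are rounded half-up to `rounding`
#' decimals for reporting; the unrounded values and the inputs that produced
#' them are kept in the `provenance` attribute.
#'
#' @param model an `adiposity_model` (fitted or constructed).
#' @param bands a [bf_bands()] object with the BF% thresholds.
#' @param rounding decimal places for the published cut-offs (default 1).
#' @return a [cutoff_set()] named `"derived"`, with attribute `provenance`
#'   (list: `bands`, `coeffs`, `degree`, `unrounded`).
#' @export
#' @examples
#' m <- adiposity_model(c(3.2, -0.02, 0.001))
#' derive_cutoffs(m, bf_bands(21, 26), rounding = 2)
derive_cutoffs <- function(model, bands = bf_bands(), rounding = 1) {
  stopifnot(inherits(model, "adiposity_model"), inherits(bands, "bf_bands"))
  check_scalar(rounding, "rounding", lower = 0, upper = 10,
               strict = c(FALSE, FALSE))
  at <- c(bands$overweight_bf, bands$obesity_bf)
  raw <- predict_bmi(model, at)
  if (raw[2] <= raw[1])
    stop(sprintf(paste0("model is not increasing over the band interval: ",
                        "obesity cut-off %.3f <= overweight cut-off %.3f"),
                 raw[2], raw[1]), call. = FALSE)
  cut <- round_half_up(raw, rounding)
  out <- cutoff_set("derived", cut[1], cut[2])
  attr(out, "provenance") <- list(bands = unclass(bands),
                                  coeffs = model$coeffs,
                                  degree = model$degree,
                                  unrounded = raw)
  out
}

#' Invert an adiposity model: BF% attaining a given BMI
#'
#' Solves `ln(bmi) = c0 + c1 x + c2 x^2` for `x` on the physiologic branch:
#' among real roots, the one inside the fitted BF% range (extended by
#' `guard`) is returned; if both roots fall inside, the one on the rising
#' limb of the curve (derivative > 0) is chosen, since adiposity cut-offs
#' live where BMI increases with BF%.
#'
#' @param model an `adiposity_model` of degree 1 or 2.
#' @param bmi positive BMI value(s) to invert.
#' @param guard BF%-point extension of the admissible root range.
#' @return BF% value(s) attaining `bmi` on the model curve.
#' @export
bmi_to_bf <- function(model, bmi, guard = 2) {
  stopifnot(inherits(model, "adiposity_model"))
  if (!is.numeric(bmi) || any(!is.finite(bmi)) || any(bmi <= 0))
    stop("'bmi' must be positive finite numeric", call. = FALSE)
  if (model$degree > 2)
    stop("inversion implemented for degree <= 2 models only", call. = FALSE)
  lo <- model$bf_range_fit[1] - guard
  hi <- model$bf_range_fit[2] + guard
  cf <- model$coeffs

  invert_one <- function(b) {
    target <- log(b)
    if (model$degree == 1L) {
      if (cf[["c1"]] == 0)
        stop("constant model cannot be inverted", call. = FALSE)
      roots <- (target - cf[["c0"]]) / cf[["c1"]]
    } else {
      disc <- cf[["c1"]]^2 - 4 * cf[["c2"]] * (cf[["c0"]] - target)
      if (cf[["c2"]] == 0) {
        roots <- (target - cf[["c0"]]) / cf[["c1"]]
      } else if (disc < 0) {
        stop(sprintf("BMI %.3f is not attained by the model (no real root)",
                     b), call. = FALSE)
      } else {
        roots <- (-cf[["c1"]] + c(-1, 1) * sqrt(disc)) / (2 * cf[["c2"]])
      }
    }
    inside <- roots[roots >= lo & roots <= hi]
    if (length(inside) == 0L)
      stop(sprintf(paste0("no root for BMI %.3f inside the admissible BF%% ",
                          "range [%.2f, %.2f]"), b, lo, hi), call. = FALSE)
    if (length(inside) == 1L) return(inside)
    slope <- cf[["c1"]] + 2 * cf[["c2"]] * inside
    rising <- inside[slope > 0]
    if (length(rising)) rising[1] else inside[which.max(slope)]
  }
  vapply(bmi, invert_one, numeric(1))
}
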