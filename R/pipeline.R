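#' Full BMI cut-off recalibration analysis on a cohort
#'
#' Orchestrates the complete workflow on one cohort: (1) classify every
#' athlete by BF% (reference) and by BMI under the incumbent cut-offs, and
#' cross-tabulate; (2) CUSUM test of BMI--BF% linearity; (3) fit the
#' log-polynomial adiposity model; (4) validate back-transformed predictions
#' against measured BMI; (5) derive recalibrated BMI cut-offs by substituting
#' the BF% bands; (6) re-classify under the derived cut-offs and
#' cross-tabulate again.  Any stage failure is re-raised with the stage name
#' prefixed.
#'
#' @param cohort an `athlete_cohort` data frame or a path to a cohort CSV
#'   (see [read_cohort()]).
#' @param incumbent_cutoffs the BMI cut-off set under evaluation (default
#'   [who_cutoffs()]).
#' @param bands BF% reference bands (default Gallagher, [bf_bands()]).
#' @param alpha level for all tests.
#' @param max_degree largest polynomial degree considered.
#' @param cusum_sims permutation draws for each CUSUM null.
#' @param seed seed governing the two CUSUM nulls (recorded in the report;
#'   the whole report is reproducible from it).
#' @param rounding decimals for the derived cut-offs.
#' @return an object of class `analysis_report`: `settings`, `n`,
#'   `contingency_incumbent`, `cusum`, `model`, `validation`, `cutoffs`
#'   (with unrounded provenance), `contingency_derived`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 200, seed = 3))
#' rep <- run_full_analysis(coh, cusum_sims = 200)
#' c(rep$contingency_incumbent$kappa, rep$contingency_derived$kappa)
run_full_analysis <- function(cohort,
                              incumbent_cutoffs = who_cutoffs(),
                              bands = bf_bands(),
                              alpha = 0.05, max_degree = 3,
                              cusum_sims = 2000, seed = 1L,
                              rounding = 1) {
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))

  coh <- stage("read_cohort",
               if (is.character(cohort)) read_cohort(cohort)
               else validate_cohort(as.data.frame(cohort)))

  cls_bf <- stage("classification", classify_bf(coh$bf_pct, bands))
  cls_inc <- stage("classification",
                   classify_bmi(coh$bmi, incumbent_cutoffs))
  ct_inc <- stage("classification",
                  cross_tabulate(cls_inc, cls_bf, collapse = TRUE))

  cus <- stage("linearity_test",
               cusum_linearity_test(coh$bf_pct, coh$bmi, alpha = alpha,
                                    n_sims = cusum_sims, seed = seed))

  model <- stage("model_building",
                 fit_log_polynomial(coh$bf_pct, coh$bmi,
                                    max_degree = max_degree))

  val <- stage("model_validation", {
    pred <- predict_bmi(model, coh$bf_pct)
    validate_predictions(coh$bmi, pred, alpha = alpha,
                         cusum_sims = cusum_sims, seed = seed + 1L)
  })

  cuts <- stage("cutoff_derivation",
                derive_cutoffs(model, bands, rounding = rounding))

  ct_der <- stage("reclassification",
                  cross_tabulate(classify_bmi(coh$bmi, cuts), cls_bf,
                                 collapse = TRUE))

  structure(list(
    settings = list(seed = as.integer(seed), alpha = alpha,
                    cusum_sims = as.integer(cusum_sims),
                    max_degree = as.integer(max_degree),
                    rounding = rounding,
                    bands = unclass(bands),
                    incumbent_cutoffs = unclass(incumbent_cutoffs)),
    n = nrow(coh),
    contingency_incumbent = ct_inc,
    cusum = cus,
    model = model,
    validation = val,
    cutoffs = cuts,
    contingency_derived = ct_der), class = "analysis_report")
}

# Flatten the report into plain lists/vectors for JSON serialisation.
report_to_list <- function(report) {
  strip <- function(x) {
    if (inherits(x, "cutoff_set")) {
      prov <- attr(x, "provenance")
      x <- unclass(x)
      if (!is.null(prov)) x$provenance <- strip(prov)
      return(lapply(x, strip))
    }
    if (is.table(x) || is.matrix(x)) {
      m <- unclass(as.matrix(x)); attr(m, "dimnames") <- dimnames(x)
      return(m)
    }
    if (is.list(x)) return(lapply(unclass(x), strip))
    if (is.factor(x)) return(as.character(x))
    x
  }
  strip(unclass(report))
}

#' Write an analysis report as JSON
#'
#' Serialises an `analysis_report` (or any nested result object of this
#' package) to pretty-printed JSON with enough digits for lossless reading.
#'
#' @param report an `analysis_report` from [run_full_analysis()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("BMI cut-off recalibration report (n = %d)\n", x$n))
  cat(sprintf("\n-- incumbent cut-offs (%s) vs BF%% reference --\n",
              x$settings$incumbent_cutoffs$name))
  print(x$contingency_incumbent)
  cat("\n-- BMI~BF% linearity --\n"); print(x$cusum)
  cat("\n-- fitted model --\n"); print(x$model)
  cat("\n-- validation --\n"); print(x$validation)
  cat("\n-- derived cut-offs --\n"); print(x$cutoffs)
  cat("\n-- derived cut-offs vs BF% reference --\n")
  print(x$contingency_derived)
  invisible(x)
}
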