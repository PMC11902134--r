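#' Weight-status category sets
#'
#' `bf_bands()` holds the body-fat-percentage thresholds of the Gallagher
#' classification for young adult males (overweight at BF% >= 21, obesity at
#' BF% >= 26).  `cutoff_set()` holds named BMI thresholds; `who_cutoffs()`
#' is the WHO adult set (overweight at BMI >= 25 kg/m^2, obesity at >= 30).
#' All thresholds are inclusive upward: a value exactly on a threshold goes
#' to the higher category.
#'
#' @param overweight_bf,obesity_bf BF% thresholds, `0 < overweight < obesity
#'   < 100`.
#' @return an object of class `bf_bands` / `cutoff_set`.
#' @export
bf_bands <- function(overweight_bf = 21, obesity_bf = 26) {
  check_scalar(overweight_bf, "overweight_bf", lower = 0, upper = 100)
  check_scalar(obesity_bf, "obesity_bf", lower = 0, upper = 100)
  if (overweight_bf >= obesity_bf)
    stop("'overweight_bf' must be below 'obesity_bf'", call. = FALSE)
  structure(list(overweight_bf = overweight_bf, obesity_bf = obesity_bf),
            class = "bf_bands")
}

#' @rdname bf_bands
#' @param name label for the cut-off set.
#' @param overweight_bmi,obesity_bmi BMI thresholds in kg/m^2,
#'   `0 < overweight < obesity`.
#' @export
cutoff_set <- function(name, overweight_bmi, obesity_bmi) {
  stopifnot(is.character(name), length(name) == 1L)
  check_scalar(overweight_bmi, "overweight_bmi", lower = 0)
  check_scalar(obesity_bmi, "obesity_bmi", lower = 0)
  if (overweight_bmi >= obesity_bmi)
    stop("'overweight_bmi' must be below 'obesity_bmi'", call. = FALSE)
  structure(list(name = name, overweight_bmi = overweight_bmi,
                 obesity_bmi = obesity_bmi), class = "cutoff_set")
}

#' @rdname bf_bands
#' @export
who_cutoffs <- function() cutoff_set("WHO", 25, 30)

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf("BMI cut-offs '%s': overweight >= %.4g, obesity >= %.4g kg/m2\n",
              x$name, x$overweight_bmi, x$obesity_bmi))
  invisible(x)
}

weight_levels <- c("normal", "overweight", "obesity")
collapsed_levels <- c("normal", "overweight_obesity")

three_way <- function(x, lo, hi) {
  factor(weight_levels[1L + (x >= lo) + (x >= hi)],
         levels = weight_levels, ordered = TRUE)
}

#' Classify subjects by body-fat percentage or BMI
#'
#' Three-way weight-status classification (`normal` / `overweight` /
#' `obesity`) with thresholds inclusive upward.
#'
#' @param bf_pct numeric vector of body-fat percentages, each in (0, 100).
#' @param bands a [bf_bands()] object.
#' @return an ordered factor with levels `normal < overweight < obesity`.
#' @export
#' @examples
#' classify_bf(c(20.9, 21, 26))
#' classify_bmi(c(24.9, 25, 30), who_cutoffs())
classify_bf <- function(bf_pct, bands = bf_bands()) {
  stopifnot(inherits(bands, "bf_bands"))
  if (!is.numeric(bf_pct) || any(!is.finite(bf_pct)))
    stop("'bf_pct' must be finite numeric", call. = FALSE)
  if (any(bf_pct <= 0 | bf_pct >= 100))
    stop("'bf_pct' values must lie in (0, 100)", call. = FALSE)
  three_way(bf_pct, bands$overweight_bf, bands$obesity_bf)
}

#' @rdname classify_bf
#' @param bmi numeric vector of BMI values (kg/m^2), each positive.
#' @param cutoffs a [cutoff_set()].
#' @export
classify_bmi <- function(bmi, cutoffs = who_cutoffs()) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  if (!is.numeric(bmi) || any(!is.finite(bmi)))
    stop("'bmi' must be finite numeric", call. = FALSE)
  if (any(bmi <= 0))
    stop("'bmi' values must be positive", call. = FALSE)
  three_way(bmi, cutoffs$overweight_bmi, cutoffs$obesity_bmi)
}

collapse_categories <- function(x) {
  factor(ifelse(as.character(x) == "normal", "normal", "overweight_obesity"),
         levels = collapsed_levels, ordered = TRUE)
}

#' Unweighted Cohen's kappa from a square contingency table
#'
#' `kappa = (Po - Pe) / (1 - Pe)` with observed agreement `Po` the diagonal
#' proportion and chance agreement `Pe = sum(row_i * col_i) / n^2`.  When
#' `Pe = 1` (all mass in one cell) kappa is undefined and `NA` is returned
#' with a warning.
#'
#' @param table square matrix of non-negative counts, rows = classifier A,
#'   columns = classifier B.
#' @return kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
#' @examples
#' cohen_kappa(matrix(c(449, 149, 2, 22), 2)) # 0.169
cohen_kappa <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) != ncol(tab))
    stop("'table' must be square", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("'table' must hold non-negative integer counts", call. = FALSE)
  n <- sum(tab)
  if (n == 0) stop("'table' is all zero", call. = FALSE)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) {
    warning("chance agreement Pe = 1: kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Pearson chi-squared test of independence (no continuity correction)
#'
#' Classic `sum((O - E)^2 / E)` on an r x c count table, with
#' `df = (r-1)(c-1)` and an upper-tail chi-squared p-value.  No Yates
#' correction is applied (the convention used for the published agreement
#' tables this package reproduces).
#'
#' @param table matrix of non-negative counts with positive margins.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_squared_independence(matrix(c(449, 149, 2, 22), 2))$statistic # 51.575
chi_squared_independence <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- sum(tab)
  if (n == 0) stop("'table' is all zero", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected == 0))
    stop("degenerate table: expected count of zero (empty margin)",
         call. = FALSE)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Capture and false-positive rates of a 2x2 agreement table
#'
#' With rows = index classifier (e.g. a BMI rule) and columns = reference
#' classifier (BF%), both ordered (negative, positive): the capture rate is
#' the percentage of reference positives also called positive by the index
#' rule; the false-positive rate is the percentage of reference normals the
#' index rule calls positive.
#'
#' @param table 2x2 count matrix.
#' @return list with `capture_rate` and `false_positive_rate` (percent, full
#'   precision; `NA` with a warning when a reference column is empty).
#' @export
#' @examples
#' agreement_rates(matrix(c(449, 149, 2, 22), 2)) # capture 91.7, fp 24.9
agreement_rates <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("'table' must be 2x2", call. = FALSE)
  pos_total <- sum(tab[, 2]); neg_total <- sum(tab[, 1])
  cap <- if (pos_total > 0) tab[2, 2] / pos_total * 100 else {
    warning("no reference positives: capture rate undefined"); NA_real_ }
  fpr <- if (neg_total > 0) tab[2, 1] / neg_total * 100 else {
    warning("no reference normals: false-positive rate undefined"); NA_real_ }
  list(capture_rate = cap, false_positive_rate = fpr)
}

#' Landis-Koch verbal label for a kappa value
#'
#' Bands: `<= 0` poor, `(0, 0.20]` slight, `(0.20, 0.40]` fair,
#' `(0.40, 0.60]` moderate, `(0.60, 0.80]` substantial, `(0.80, 1]` almost
#' perfect.
#'
#' @param kappa numeric vector in `[-1, 1]`.
#' @return character vector of band labels.
#' @export
#' @examples
#' kappa_label(c(0.169, 0.522)) # "slight", "moderate"
kappa_label <- function(kappa) {
  if (!is.numeric(kappa) || any(!is.finite(kappa)) ||
      any(kappa < -1 | kappa > 1))
    stop("'kappa' must lie in [-1, 1]", call. = FALSE)
  as.character(cut(kappa, breaks = c(-1, 0, 0.2, 0.4, 0.6, 0.8, 1),
                   labels = c("poor", "slight", "fair", "moderate",
                              "substantial", "almost perfect"),
                   include.lowest = TRUE, right = TRUE))
}

#' Cross-tabulate two weight-status classifications with agreement statistics
#'
#' Tabulates paired category calls (rows = `categories_a`, the index
#' classifier; columns = `categories_b`, the reference) and attaches
#' unweighted Cohen's kappa, the uncorrected chi-squared test of
#' independence, observed/expected agreement, and -- from the table collapsed
#' to normal vs overweight-or-obesity -- the capture and false-positive
#' rates.
#'
#' @param categories_a,categories_b equal-length factors or character vectors
#'   of weight categories (as returned by [classify_bmi()] /
#'   [classify_bf()]).
#' @param collapse merge overweight and obesity into one positive class
#'   before tabulation (the layout used in published 2x2 agreement tables).
#' @return an object of class `contingency_result`.
#' @export
cross_tabulate <- function(categories_a, categories_b, collapse = FALSE) {
  if (length(categories_a) != length(categories_b))
    stop("category sequences differ in length", call. = FALSE)
  if (length(categories_a) == 0L)
    stop("empty category sequences", call. = FALSE)
  lev <- if (collapse) collapsed_levels else weight_levels
  norm <- function(x) {
    x <- if (collapse) collapse_categories(x) else
      factor(as.character(x), levels = weight_levels, ordered = TRUE)
    if (any(is.na(x)))
      stop("unknown category label in input", call. = FALSE)
    x
  }
  a <- norm(categories_a); b <- norm(categories_b)
  tab <- table(a = a, b = b)
  tab_m <- matrix(as.integer(tab), nrow = length(lev),
                  dimnames = list(a = lev, b = lev))
  n <- sum(tab_m)
  po <- sum(diag(tab_m)) / n
  pe <- sum(rowSums(tab_m) * colSums(tab_m)) / n^2
  kap <- cohen_kappa(tab_m)
  # chi-squared needs populated margins; categories absent from both
  # classifiers are dropped first, and a table with nothing left to test
  # (all mass in one row or column) gets NA rather than an error
  nz_r <- rowSums(tab_m) > 0
  nz_c <- colSums(tab_m) > 0
  chi <- if (sum(nz_r) >= 2 && sum(nz_c) >= 2)
    chi_squared_independence(tab_m[nz_r, nz_c, drop = FALSE])
  else list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
  tab2 <- if (collapse) tab_m else {
    cm <- matrix(0L, 2, 2, dimnames = list(a = collapsed_levels,
                                           b = collapsed_levels))
    cm[1, 1] <- tab_m[1, 1]
    cm[1, 2] <- sum(tab_m[1, 2:3]); cm[2, 1] <- sum(tab_m[2:3, 1])
    cm[2, 2] <- sum(tab_m[2:3, 2:3])
    cm
  }
  rates <- agreement_rates(tab2)
  structure(list(table = tab_m, n = n,
                 kappa = kap,
                 kappa_label = if (is.na(kap)) NA_character_ else
                   kappa_label(kap),
                 chi2 = chi$statistic, chi2_df = chi$df,
                 chi2_p = chi$p_value,
                 observed_agreement = po, expected_agreement = pe,
                 capture_rate = rates$capture_rate,
                 false_positive_rate = rates$false_positive_rate),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, digits = 3, ...) {
  cat(sprintf("Agreement analysis (n = %d)\n", x$n))
  print(x$table)
  cat(sprintf("kappa = %.3f (%s); chi2 = %.3f, df = %d, p = %.3g\n",
              x$kappa, x$kappa_label, x$chi2, x$chi2_df, x$chi2_p))
  cat(sprintf("capture rate = %.1f%%, false-positive rate = %.1f%%\n",
              round_half_up(x$capture_rate, 1),
              round_half_up(x$false_positive_rate, 1)))
  invisible(x)
}
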