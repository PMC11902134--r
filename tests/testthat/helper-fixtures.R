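# Shared fixtures: published agreement tables and small helpers.
# Table orientation everywhere: rows = BMI-based classifier, columns = BF%
# reference, both ordered (normal, overweight-or-obesity).

table_who <- matrix(c(449, 149, 2, 22), nrow = 2,
                    dimnames = list(a = c("normal", "overweight_obesity"),
                                    b = c("normal", "overweight_obesity")))
table_new <- matrix(c(574, 24, 6, 18), nrow = 2,
                    dimnames = dimnames(table_who))

# Brute-force kappa oracle: expand the table into paired label vectors and
# sum observed / chance agreement explicitly over the label set.  Kept free
# of the closed form used by cohen_kappa().
oracle_kappa <- function(tab) {
  labs <- seq_len(nrow(tab))
  a <- rep(rep(labs, ncol(tab)), times = as.vector(tab))
  b <- rep(rep(labs, each = nrow(tab)), times = as.vector(tab))
  po <- mean(a == b)
  pe <- sum(vapply(labs, function(l) mean(a == l) * mean(b == l), 0))
  (po - pe) / (1 - pe)
}

# Random non-degenerate square count table with n <= n_max.
random_table <- function(dim = 3, n_max = 50) {
  repeat {
    tab <- matrix(stats::rpois(dim * dim, lambda = n_max / dim^2), dim)
    if (sum(tab) > 0 && all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      return(tab)
  }
}

# Paired category vectors realizing a given collapsed 2x2 table.
labels_from_table <- function(tab) {
  lev <- c("normal", "overweight_obesity")
  a <- rep(rep(lev, 2), times = as.vector(tab))
  b <- rep(rep(lev, each = 2), times = as.vector(tab))
  list(a = a, b = b)
}

small_cohort <- function(n = 50, seed = 1)
  generate_cohort(cohort_config(n_subjects = n, seed = seed))
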