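test_that("BF% and BMI classification use inclusive-upward thresholds", {
  expect_equal(as.character(classify_bf(c(20.9, 21, 25.9, 26, 5.1))),
               c("normal", "overweight", "overweight", "obesity", "normal"))
  expect_equal(as.character(classify_bmi(c(24.9, 25, 29.9, 30), who_cutoffs())),
               c("normal", "overweight", "overweight", "obesity"))
  derived <- cutoff_set("derived", 28.2, 33.7)
  expect_equal(as.character(classify_bmi(c(28.2, 33.7, 28.1), derived)),
               c("overweight", "obesity", "normal"))
  expect_error(classify_bf(101), "0, 100")
  expect_error(classify_bf(0), "0, 100")
  expect_error(classify_bmi(-1), "positive")
  expect_error(cutoff_set("x", 30, 25), "below")
  expect_error(bf_bands(26, 21), "below")
})

test_that("classify_bmi is monotone in BMI", {
  set.seed(42)
  for (i in 1:20) {
    bmi <- sort(runif(100, 18, 45))
    cats <- classify_bmi(bmi, who_cutoffs())
    expect_true(all(diff(as.integer(cats)) >= 0))
  }
})

test_that("cross_tabulate reproduces published marginals and cells", {
  lv <- labels_from_table(table_who)
  ct <- cross_tabulate(lv$a, lv$b, collapse = TRUE)
  expect_equal(ct$n, 622)
  expect_equal(unname(as.vector(ct$table)), c(449, 149, 2, 22))
  expect_equal(unname(rowSums(ct$table)), c(451, 171))
  expect_equal(unname(colSums(ct$table)), c(598, 24))

  lv3 <- labels_from_table(table_new)
  ct3 <- cross_tabulate(lv3$a, lv3$b, collapse = TRUE)
  expect_equal(unname(as.vector(ct3$table)), c(574, 24, 6, 18))
  expect_equal(ct3$n, 622)

  # self-agreement: all off-diagonal cells zero
  cats <- classify_bf(small_cohort(80, 4)$bf_pct)
  ct_self <- suppressWarnings(cross_tabulate(cats, cats))
  expect_equal(sum(ct_self$table) - sum(diag(ct_self$table)), 0)

  expect_error(cross_tabulate(c("normal"), character(0)), "length")
  expect_error(cross_tabulate(character(0), character(0)), "empty")
})

test_that("collapsing preserves n and the normal margins", {
  set.seed(7)
  for (i in 1:10) {
    a <- sample(c("normal", "overweight", "obesity"), 60, replace = TRUE)
    b <- sample(c("normal", "overweight", "obesity"), 60, replace = TRUE)
    t3 <- cross_tabulate(a, b, collapse = FALSE)
    t2 <- cross_tabulate(a, b, collapse = TRUE)
    expect_equal(t2$n, t3$n)
    expect_equal(t2$table[1, 1], t3$table[1, 1])
    expect_equal(unname(rowSums(t2$table)[1]), unname(rowSums(t3$table)[1]))
    expect_equal(unname(colSums(t2$table)[1]), unname(colSums(t3$table)[1]))
  }
})

test_that("cohen_kappa matches the brute-force oracle on random tables", {
  set.seed(123)
  for (i in 1:50) {
    tab <- random_table(dim = sample(2:3, 1), n_max = 50)
    expect_equal(cohen_kappa(tab), oracle_kappa(tab), tolerance = 1e-12)
  }
})

test_that("cohen_kappa handles agreement extremes and degenerate input", {
  expect_equal(cohen_kappa(diag(c(5, 9, 2))), 1)
  # cells equal to expected counts: chance-level agreement
  chance <- outer(c(10, 20), c(6, 4)) / 10
  expect_equal(cohen_kappa(chance), 0)
  expect_error(cohen_kappa(matrix(1:6, 2)), "square")
  expect_error(cohen_kappa(matrix(0, 2, 2)), "zero")
  expect_warning(k <- cohen_kappa(matrix(c(5, 0, 0, 0), 2)), "undefined")
  expect_true(is.na(k))
})

test_that("chi-squared matches stats::chisq.test without correction", {
  set.seed(99)
  for (i in 1:30) {
    tab <- random_table(dim = sample(2:3, 1), n_max = 200)
    ours <- chi_squared_independence(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("chi-squared is symmetric under transposition and exact at independence", {
  set.seed(5)
  for (i in 1:20) {
    tab <- random_table()
    expect_equal(chi_squared_independence(tab)$statistic,
                 chi_squared_independence(t(tab))$statistic,
                 tolerance = 1e-12)
  }
  expect_equal(chi_squared_independence(matrix(10, 2, 2))$statistic, 0)
  expect_error(chi_squared_independence(matrix(c(1, 1, 0, 0), 2,
                                               byrow = TRUE)),
               "degenerate")
})

test_that("agreement_rates recovers published capture / false-positive rates", {
  r_who <- agreement_rates(table_who)
  expect_equal(round_half_up(r_who$capture_rate, 1), 91.7)
  expect_equal(round_half_up(r_who$false_positive_rate, 1), 24.9)
  r_new <- agreement_rates(table_new)
  expect_equal(round_half_up(r_new$capture_rate, 1), 75.0)
  expect_equal(round_half_up(r_new$false_positive_rate, 1), 4.0)

  diag_tab <- diag(c(30, 12))
  r_diag <- agreement_rates(diag_tab)
  expect_equal(r_diag$capture_rate, 100)
  expect_equal(r_diag$false_positive_rate, 0)

  expect_warning(r0 <- agreement_rates(matrix(c(3, 1, 0, 0), 2)),
                 "undefined")
  expect_true(is.na(r0$capture_rate))
})

test_that("kappa_label implements the Landis-Koch bands with closed upper ends", {
  expect_equal(kappa_label(c(0.169, 0.522, 1, -0.3, 0)),
               c("slight", "moderate", "almost perfect", "poor", "poor"))
  expect_equal(kappa_label(c(0.20, 0.21, 0.40, 0.60, 0.80, 0.81)),
               c("slight", "fair", "fair", "moderate", "substantial",
                 "almost perfect"))
  expect_error(kappa_label(1.2), "\\[-1, 1\\]")
})
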