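test_that("exact Friedman p equals exhaustive within-row permutation", {
  set.seed(17)
  for (i in 1:6) {
    n <- sample(3:6, 1)
    X <- matrix(round(rexp(n * 3, 1 / 10), 1), n, 3)
    X[sample(length(X), 2)] <- 0  # zero areas induce within-row ties
    res <- friedman_area_test(table_of(X), c("A", "B", "C"))
    expect_equal(res$p.value, brute_friedman_p(X), tolerance = 1e-12)
    expect_equal(res$df, 2)
  }
})

test_that("chi-square Friedman approximation tracks the exact p at cohort size", {
  set.seed(23)
  for (i in 1:3) {
    n <- 30
    X <- matrix(rexp(n * 3, 1 / 10), n, 3)
    X[, 1] <- X[, 1] + 3
    tab <- table_of(X)
    p_exact <- friedman_area_test(tab, c("A", "B", "C"), mode = "exact")$p.value
    p_chi <- friedman_area_test(tab, c("A", "B", "C"), mode = "approx")$p.value
    # the chi-square approximation is only good to a few percent in the
    # mid-p regime even at cohort size, which is why exact is the default
    expect_lt(abs(p_chi - p_exact), 0.05)
  }
})

test_that("fully tied tables give chi2 = 0 and p = 1", {
  X <- matrix(5, 4, 3)
  res <- friedman_area_test(table_of(X), c("A", "B", "C"))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
})

test_that("Friedman requires complete rows and >= 2 conditions", {
  tab <- table_of(matrix(1:9, 3, 3))
  expect_error(friedman_area_test(tab, c("A")), class = "qsf_stats_error")
  tab$B[2] <- NA
  expect_error(friedman_area_test(tab, c("A", "B", "C")),
               "incomplete", class = "qsf_stats_error")
})

test_that("tie-free Friedman chi-square matches stats::friedman.test", {
  set.seed(31)
  X <- matrix(rnorm(12 * 3), 12, 3)  # continuous: no ties
  res <- friedman_area_test(table_of(abs(X)), c("A", "B", "C"), mode = "approx")
  ref <- friedman.test(abs(X))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p.value, ref$p.value)
})

test_that("exact Wilcoxon signed-rank p equals 2^n sign-flip enumeration", {
  set.seed(12)
  for (i in 1:8) {
    n <- sample(6:10, 1)
    x <- round(rexp(n, 1 / 10), 2)
    y <- round(pmax(0, x * runif(n, 0.2, 1.4) - 1), 2)
    d <- x - y
    if (any(d == 0) || anyDuplicated(abs(d[d != 0]))) next  # exact mode wants no ties
    res <- wilcoxon_signed_rank(x, y)
    expect_equal(res$p.value, brute_wilcoxon_p(d), tolerance = 1e-12)
  }
  # fixed n = 8 case so the oracle is always exercised
  x <- c(11.3, 4.2, 9.8, 15.1, 7.7, 3.3, 12.9, 6.4)
  y <- c(2.1, 3.9, 1.2, 10.0, 8.8, 0.0, 4.4, 6.0)
  expect_equal(wilcoxon_signed_rank(x, y)$p.value,
               brute_wilcoxon_p(x - y), tolerance = 1e-12)
})

test_that("degenerate and tied Wilcoxon inputs follow the zero-drop policy", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_warning(res <- wilcoxon_signed_rank(x, x), "zero")
  expect_equal(res$p.value, 1)
  expect_equal(res$n_effective, 0L)

  # ties in |d| force the normal approximation
  y <- x + c(2, -2, 2, -2, 2, 2)
  res2 <- wilcoxon_signed_rank(x, y)
  expect_match(res2$method, "approx")
  expect_error(wilcoxon_signed_rank(1:3, 1:2), class = "qsf_stats_error")
})

test_that("compare_conditions runs Friedman then Bonferroni pairwise tests", {
  tab <- synthetic_cohort_table()
  res <- compare_conditions(tab, c("FI", "TCCI", "CADCAM"))
  expect_equal(res$k, 3L)
  expect_equal(res$n, 60L)
  expect_equal(res$alpha_pairwise, 0.05 / 3, tolerance = 1e-12)
  expect_equal(round(res$alpha_pairwise, 7), 0.0166667)
  expect_equal(nrow(res$pairwise), 3L)
  # strong offloading: both custom conditions differ from flat
  fi_rows <- res$pairwise$condition1 == "FI"
  expect_true(all(res$pairwise$significant[fi_rows]))
  expect_true(all(res$pairwise$mean_difference_cm2[fi_rows] > 0))
  # mean differences are plain column-mean differences
  expect_equal(res$pairwise$mean_difference_cm2[1],
               mean(tab$FI) - mean(tab$TCCI))
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$friedman_df, 2)
})

test_that("identical conditions yield p = 1 and shift recovers exactly", {
  X <- cbind(c(5, 8, 2, 9, 4), c(5, 8, 2, 9, 4), c(8, 11, 5, 12, 7))
  tab <- table_of(X)
  res <- suppressWarnings(compare_conditions(tab, c("A", "B", "C")))
  ab <- res$pairwise[res$pairwise$condition1 == "A" &
                       res$pairwise$condition2 == "B", ]
  expect_equal(ab$p.value, 1)
  expect_equal(ab$mean_difference_cm2, 0)
  # uniform -3 shift: mean difference is exactly 3 for (shifted, original)
  ca <- res$pairwise[res$pairwise$condition1 == "A" &
                       res$pairwise$condition2 == "C", ]
  expect_equal(ca$mean_difference_cm2, -3)
})

test_that("compare_conditions is invariant to row order", {
  tab <- synthetic_cohort_table()
  shuf <- tab[sample(nrow(tab)), ]
  a <- compare_conditions(tab, c("FI", "TCCI", "CADCAM"))
  b <- compare_conditions(as_area_table(shuf), c("FI", "TCCI", "CADCAM"))
  expect_equal(a$friedman$p.value, b$friedman$p.value)
  expect_equal(a$pairwise, b$pairwise)
})

test_that("optimal-case counting partitions the cohort", {
  tab <- as_area_table(data.frame(subject = 1:4, side = "l",
                                  X = c(0, 1.25, 0, 4.5)))
  expect_equal(count_optimal(tab, "X"), 2L)
  expect_error(count_optimal(tab, "Y"), class = "qsf_stats_error")

  cohort <- synthetic_cohort_table()
  for (cc in c("FI", "TCCI", "CADCAM")) {
    n_opt <- count_optimal(cohort, cc)
    expect_equal(n_opt + sum(cohort[[cc]] > 0), nrow(cohort))
  }
})

test_that("descriptives match closed forms", {
  tab <- as_area_table(data.frame(subject = 1:2, side = "l", A = c(2, 4)))
  d <- area_descriptives(tab)
  expect_equal(d$mean, 3)
  expect_equal(d$sd, sqrt(2))
  expect_equal(d$sd, 1.414, tolerance = 1e-3)
  expect_equal(d$median, 3)
  expect_equal(d$max, 4)

  one <- as_area_table(data.frame(subject = 1, side = "l", A = 7))
  d1 <- area_descriptives(one)
  expect_equal(d1$mean, 7)
  expect_equal(d1$median, 7)
  expect_equal(d1$max, 7)
  expect_true(is.na(d1$sd))
})
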