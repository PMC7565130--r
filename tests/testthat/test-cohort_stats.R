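test_that("odds ratios and Woolf intervals reproduce the published univariable rows", {
  ts <- odds_ratio(20, 33, 2, 27)                  # lower T stage
  expect_equal(round(ts$or, 2), 8.18)
  expect_equal(round(ts$ci, 2), c(1.75, 38.16))
  expect_equal(round(odds_ratio(20, 46, 2, 14)$or, 2), 3.04)   # anatomic stage
  expect_equal(round(odds_ratio(11, 28, 8, 30)$or, 2), 1.47)   # grade 3
  expect_equal(round(odds_ratio(9, 35, 8, 25)$or, 2), 0.80)    # Ki-67 high
  er <- odds_ratio(18, 37, 4, 23)                  # ER negative
  expect_equal(round(er$or, 2), 2.80)
  expect_equal(round(er$ci, 2), c(0.84, 9.31))
  expect_equal(odds_ratio(1, 1, 1, 1)$or, 1)
})

test_that("zero cells require the flagged continuity correction", {
  expect_error(odds_ratio(5, 0, 3, 7), "zero cell")
  fixed <- odds_ratio(5, 0, 3, 7, correction = TRUE)
  expect_true(fixed$corrected)
  expect_equal(fixed$or, (5.5 * 7.5) / (0.5 * 3.5))
})

test_that("Pearson chi-square equals the brute-force O-E summation", {
  tab <- matrix(c(10, 6, 12, 29), 2)               # dual vs single HER2 blockade
  got <- pearson_chi2(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$statistic, sum((tab - E)^2 / E))
  expect_equal(got$df, 1)
  expect_lt(got$p, 0.05)
  expect_equal(round(got$p, 3), 0.021)             # printed significance
  same <- matrix(c(10, 20, 5, 10), 2)              # identical row distributions
  expect_equal(pearson_chi2(same)$statistic, 0)
  expect_equal(pearson_chi2(same)$p, 1)
  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2)), "margins")
})

test_that("Fisher enumeration matches stats::fisher.test", {
  t1 <- matrix(c(1, 9, 9, 1), 2)
  expect_equal(fisher_exact(t1), fisher.test(t1)$p.value, tolerance = 1e-10)
  # the NAC-regimen 2x3 comparison printed as p = 0.279
  t2 <- matrix(c(16, 41, 6, 12, 0, 7), 2)
  expect_equal(fisher_exact(t2), fisher.test(t2)$p.value, tolerance = 1e-10)
  expect_equal(round(fisher_exact(t2), 3), 0.279)
  expect_equal(fisher_exact(matrix(c(3, 3, 5, 5), 2)), 1)
  expect_equal(fisher_exact(matrix(2, 2, 3)), 1)
  expect_error(fisher_exact(matrix(1, 2, 6)), "too large")
})

test_that("Fisher enumeration probabilities sum to 1 over the margin-fixed space", {
  tab <- matrix(c(4, 2, 3, 6, 1, 5), 2)
  cm <- colSums(tab); r1 <- sum(tab[1, ])
  rows <- petcsc:::.enumerate_rows(cm, r1)
  p <- vapply(rows, function(r) exp(sum(lchoose(cm, r)) - lchoose(sum(cm), r1)),
              numeric(1))
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("univariable logistic OR equals the cross-product OR", {
  # the 2x2 identity on the published T-stage cells
  x <- rep(c(TRUE, TRUE, FALSE, FALSE), c(20, 33, 2, 27))
  y <- rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 33, 2, 27))
  fit <- logistic_fit(data.frame(x = x), y)
  expect_equal(fit$table$or[2], 8.1818, tolerance = 1e-4)
  # and on random tables
  set.seed(13)
  for (rep in 1:10) {
    cells <- rpois(4, 15) + 1
    x <- rep(c(TRUE, TRUE, FALSE, FALSE), cells)
    y <- rep(c(TRUE, FALSE, TRUE, FALSE), cells)
    fit <- logistic_fit(data.frame(x = x), y)
    expect_equal(fit$table$or[2],
                 (cells[1] * cells[4]) / (cells[2] * cells[3]),
                 tolerance = 1e-6)
  }
})

test_that("logistic fit recovers a known coefficient at n = 2000", {
  set.seed(17)
  n <- 2000
  mtv <- rlnorm(n, log(1.5), 0.6)
  eta <- 1.5 - 2.0 * mtv
  y <- rbinom(n, 1, plogis(eta)) == 1
  fit <- logistic_fit(data.frame(mtv_csc = mtv), y)
  expect_true(fit$converged)
  expect_equal(fit$table$estimate[2], -2.0, tolerance = 0.15)
  expect_equal(fit$n_used, n)
})

test_that("logistic preconditions and separation are reported", {
  expect_error(logistic_fit(data.frame(x = rnorm(10)), rep(TRUE, 10)), "constant")
  # complete separation: x perfectly splits the outcome
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c(FALSE, TRUE), each = 20)
  expect_warning(fit <- logistic_fit(data.frame(x = x), y), "separation")
  expect_false(fit$converged)
  expect_true(fit$separation)
})

test_that("missing covariates are dropped per-analysis (complete cases)", {
  x <- c(rnorm(30), NA, NA, NA)
  y <- rep(c(TRUE, FALSE), length.out = 33)
  fit <- logistic_fit(data.frame(x = x), y)
  expect_equal(fit$n_used, 30)
})

test_that("univariable_or_table applies the published encodings", {
  # reconstruct a cohort matching the published 2x2 cells for T stage and ER
  n <- 82
  cohort <- data.frame(
    t_stage = rep(c("T1-2", "T3-4"), c(53, 29)),
    pcr = c(rep(c(TRUE, FALSE), c(20, 33)), rep(c(TRUE, FALSE), c(2, 27))),
    anatomic_stage = rep("IIA-IIIA", n), grade = rep(NA_real_, n),
    ki67_pct = rep(NA_real_, n), er_status = rep("positive", n))
  cohort$er_status[c(1:18, 21:53, 56:59)] <- "negative"  # 18 pCR + 37 residual
  expect_equal(sum(cohort$er_status == "negative" & cohort$pcr), 18)
  expect_equal(sum(cohort$er_status == "negative" & !cohort$pcr), 37)
  out <- univariable_or_table(cohort)
  expect_equal(round(out$or[out$predictor == "t_stage"], 2), 8.18)
  expect_equal(out$a[out$predictor == "t_stage"], 20)
  expect_equal(out$d[out$predictor == "t_stage"], 27)
  expect_equal(round(out$or[out$predictor == "er_negative"], 2), 2.80)
  # grade and Ki-67 are all-missing here: their rows are absent or degenerate
  expect_true(all(is.finite(out$or[out$predictor %in% c("t_stage", "er_negative")])))
})
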