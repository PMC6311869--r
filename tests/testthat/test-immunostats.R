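# Derived statistics: TCES, pooled t-tests, Bonferroni, ratios, formulas.

test_that("TCES evaluates its defining ratio", {
  expect_equal(compute_tces(tces_inputs(0, 0, 0, 0, 10, 10)), 0)
  expect_equal(compute_tces(tces_inputs(50, 50, 50, 50, 10, 10)), 10)
  expect_error(compute_tces(tces_inputs(10, 10, 10, 10, 0, 0)),
               "undefined TCES")
  expect_error(tces_inputs(120, 0, 0, 0, 10, 10), "\\[0, 100\\]")
})

test_that("TCES respects its upper bound 400/(pctCTL+pctTh)", {
  withr::with_seed(31, for (i in 1:25) {
    v <- runif(4, 0, 100)
    ctl <- runif(1, 0.5, 60); th <- runif(1, 0.5, 60)
    s <- compute_tces(tces_inputs(v[1], v[2], v[3], v[4], ctl, th))
    expect_lte(s, 400 / (ctl + th))
    expect_gte(s, 0)
  })
})

test_that("pooled t-test reproduces published rows from summary statistics", {
  # Tregs row, tumor-bearing vs sham
  tt <- pooled_t_test_summary(group_summary(21.09, 5.12, 5),
                              group_summary(7.25, 0.23, 4))
  expect_equal(tt$df, 7)
  expect_equal(signif(tt$p, 2), 0.0011)
  # Nos2+ macrophages row
  tt <- pooled_t_test_summary(group_summary(97.99, 1.62, 5),
                              group_summary(16.56, 10.19, 4))
  expect_equal(signif(tt$p, 2), 4.2e-07)
})

test_that("degenerate and identical inputs follow the stated conventions", {
  same <- group_summary(5, 1, 4)
  tt <- pooled_t_test_summary(same, same)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  # zero pooled variance
  expect_equal(pooled_t_test_summary(group_summary(1, 0, 4),
                                     group_summary(1, 0, 3))$p, 1)
  expect_equal(pooled_t_test_summary(group_summary(1, 0, 4),
                                     group_summary(2, 0, 3))$p, 0)
  expect_equal(pooled_t_test_raw(c(0, 0, 0, 0), c(1, 1, 1, 1))$p, 0)
  expect_equal(pooled_t_test_raw(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(pooled_t_test_summary(group_summary(1, 0, 1),
                                     group_summary(2, 0, 1)),
               "inference error")
  expect_error(pooled_t_test_raw(1, c(1, 2)), "inference error")
})

test_that("swapping groups negates t and preserves p; p falls with |diff|", {
  a <- group_summary(10, 2, 5); b <- group_summary(7, 3, 6)
  ab <- pooled_t_test_summary(a, b)
  ba <- pooled_t_test_summary(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
  p_prev <- 1
  for (d in c(0, 1, 2, 4, 8)) {
    p <- pooled_t_test_summary(group_summary(10 + d, 2, 5),
                               group_summary(10, 2, 5))$p
    expect_lte(p, p_prev)
    p_prev <- p
  }
})

test_that("raw and summary forms agree to machine precision, and with t.test", {
  withr::with_seed(5, for (i in 1:10) {
    a <- rnorm(sample(3:8, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1))
    raw <- pooled_t_test_raw(a, b)
    smry <- pooled_t_test_summary(summarize_values(a), summarize_values(b))
    expect_identical(raw, smry)
    oracle <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(raw$t, unname(oracle$statistic))
    expect_equal(raw$df, unname(oracle$parameter))
    expect_equal(raw$p, oracle$p.value)
  })
})

test_that("Bonferroni thresholds match the published per-comparison alphas", {
  expect_equal(bonferroni_threshold(6), 0.05 / 6)
  expect_equal(signif(bonferroni_threshold(6), 2), 0.0083)
  expect_equal(signif(bonferroni_threshold(7), 3), 0.00714)
  expect_equal(bonferroni_threshold(5), 0.01)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_error(bonferroni_threshold(0), "positive")
  alphas <- vapply(1:10, bonferroni_threshold, numeric(1L))
  expect_true(all(diff(alphas) < 0))
})

test_that("M1:M2 ratio follows its decided form", {
  expect_equal(m1m2_ratio(macrophage_profile(10, 10, 15, 5)), 1)
  tf <- m1m2_ratio(macrophage_profile(pct_Tgm2 = 18.58, pct_Arg1 = 0.3,
                                      pct_Cxcl9 = 18.28, pct_Nos2 = 97.99))
  expect_equal(tf, 116.27 / 18.88)
  expect_equal(m1m2_ratio(macrophage_profile(5, 5, 0, 0)), 0)
  expect_error(m1m2_ratio(macrophage_profile(0, 0, 10, 10)),
               "undefined M1:M2")
})

test_that("tumor volume and dose formulas are exact", {
  expect_equal(tumor_volume(1, 1), 0.5)
  expect_equal(tumor_volume(2, 1.3), 1.69)
  expect_equal(tumor_volume(3, 2 * 0.7), 4 * tumor_volume(3, 0.7))
  expect_error(tumor_volume(0, 1), "positive")
  expect_equal(dose_micrograms(0.020, 1), 20)
  expect_equal(dose_micrograms(0.020, 10), 200)
  expect_equal(dose_micrograms(0.5, 0), 0)
  expect_error(dose_micrograms(0, 1), "positive")
})

test_that("printed p-value regression flags exactly the known residual rows", {
  reg <- reproduce_printed_tables()
  expect_equal(nrow(reg), 38)
  flagged <- reg[!reg$reproduced, c("table", "population")]
  expect_equal(
    paste(flagged$table, flagged$population),
    c("table2 MLCs", "table4 CTLs", "table6 Tgm2+ macrophages",
      "table6 Arg1+ macrophages", "table6 Cxcl9+ macrophages"))
  # the recomputed significance pattern matches every printed star anyway
  expect_identical(reg$significant, reg$starred)
})

test_that("compare_panels reports mismatched population sets", {
  a <- data.frame(population = c("x", "y"), mean = 1:2, sd = 1, n = 4)
  b <- data.frame(population = c("x", "z"), mean = 1:2, sd = 1, n = 4)
  expect_error(compare_panels(a, b), "only in A: \\{y\\}.*only in B: \\{z\\}")
})

test_that("compare_panels flags exactly the published significant rows", {
  tabs <- printed_tables()
  run <- function(nm) {
    tb <- tabs[[nm]]
    a <- data.frame(population = tb$rows$population, mean = tb$rows$mean_a,
                    sd = tb$rows$sd_a, n = tb$n_a)
    b <- data.frame(population = tb$rows$population, mean = tb$rows$mean_b,
                    sd = tb$rows$sd_b, n = tb$n_b)
    compare_panels(a, b, family_size = tb$family_size)
  }
  t5 <- run("table5")
  expect_setequal(t5$population[t5$significant],
                  c("NK cells", "Tregs", "TCES"))
  t8 <- run("table8")
  expect_setequal(t8$population[t8$significant],
                  c("Monocytes/macrophages", "Tgm2+ macrophages",
                    "Cxcl9+ macrophages", "Nos2+ macrophages"))
  expect_equal(unique(t8$corrected_alpha), 0.05 / 7)
})
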