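test_that("identical methods give zero difference and p = 1", {
  set.seed(1)
  rec <- balanced_records(12, method_effect = 0, sd_noise = 0)
  out <- compare_factor(rec, "A", "method")
  expect_equal(out$estimate, 0)
  expect_equal(out$p_value, 1)
})

test_that("a constant offset is recovered exactly without noise", {
  set.seed(2)
  rec <- balanced_records(15, method_effect = 1.0, sd_noise = 0)
  out <- compare_factor(rec, "A", "method")
  expect_equal(out$estimate, 1.0, tolerance = 1e-9)
  expect_lt(out$p_value, 1e-6)
})

test_that("balanced mixed-model contrast equals the paired closed form", {
  set.seed(3)
  for (i in 1:20) {
    rec <- balanced_records(20, method_effect = runif(1, -1, 1),
                            observer_effect = runif(1, -1, 1),
                            sd_noise = 0.4)
    out <- compare_factor(rec, "A", "method")
    ## independent oracle: paired t-test on lesion-level means
    lm_ <- tapply(rec$A, list(rec$lesion_id, rec$method), mean)
    tt <- t.test(lm_[, "patho"], lm_[, "mri"], paired = TRUE)
    expect_lt(abs(out$estimate - unname(tt$estimate)), 1e-6)
    expect_lt(abs(out$p_value - tt$p.value), 1e-6)
    expect_equal(out$df, 19)
  }
})

test_that("p-values are invariant under relabelling of methods", {
  set.seed(4)
  rec <- balanced_records(18, method_effect = 0.4)
  swapped <- rec
  swapped$method <- ifelse(rec$method == "mri", "zpatho", "amri")
  a <- compare_factor(rec, "A", "method")
  b <- compare_factor(swapped, "A", "method")
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
  expect_equal(abs(a$estimate), abs(b$estimate), tolerance = 1e-9)
})

test_that("lesions missing one level are dropped pairwise", {
  set.seed(5)
  rec <- balanced_records(10, method_effect = 0.5)
  rec <- rec[!(rec$lesion_id <= 2 & rec$method == "mri"), ]
  out <- compare_factor(rec, "A", "method")
  expect_equal(out$n_lesions, 8)
})

test_that("degenerate factors are rejected", {
  set.seed(6)
  rec <- balanced_records(5)
  expect_error(compare_factor(rec[rec$method == "mri", ], "A", "method"),
               "fewer than 2")
  expect_error(compare_factor(rec, "Z", "method"), "lack column")
})

test_that("inter-observer differences are detected, intra-observer are not", {
  set.seed(7)
  ## emulate a ~1.1 mm systematic gap between observers on width
  rec <- balanced_records(99, observer_effect = 1.1, sd_noise = 0.3)
  names(rec)[names(rec) == "A"] <- "B"
  inter <- observer_variability(rec, "B", "inter")
  expect_equal(inter$estimate, 1.1, tolerance = 0.15)
  expect_lt(inter$p_value, 0.05)
  intra <- observer_variability(rec, "B", "intra")
  expect_equal(nrow(intra), 2)
  expect_equal(intra$sd_within, rep(0.3, 2), tolerance = 0.35)
  expect_true(all(intra$p_repeat > 0.001))  # no systematic repeat effect
  ## no repeat noise at all: within-observer SD collapses to zero
  rec0 <- balanced_records(10, sd_noise = 0)
  names(rec0)[names(rec0) == "A"] <- "B"
  intra0 <- observer_variability(rec0, "B", "intra")
  expect_equal(intra0$sd_within, c(0, 0))
  expect_error(
    observer_variability(rec0[rec0$observer_id == 1, ], "B", "inter"),
    "2 observers")
})

test_that("recognition chi-square matches hand arithmetic", {
  even <- recognition_test(50, 100, 50, 100)
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  ## 92/99 vs 98/99: expected cells 95/95/4/4 -> 2*(9/95) + 2*(9/4)
  r <- recognition_test(92, 99, 98, 99)
  expect_equal(r$statistic, 2 * 9 / 95 + 2 * 9 / 4, tolerance = 1e-9)
  expect_equal(r$statistic, 4.689, tolerance = 1e-3)
  ## 0/10 vs 10/10: expected 5 everywhere -> chi2 = 4 * 5 = 20
  x <- recognition_test(0, 10, 10, 10)
  expect_equal(x$statistic, 20)
  ## Yates correction is available behind a flag
  ry <- recognition_test(92, 99, 98, 99, correct = TRUE)
  expect_lt(ry$statistic, r$statistic)
  expect_error(recognition_test(12, 10, 5, 10), "impossible")
})

test_that("summaries report lesion-level and raw moments", {
  rec <- data.frame(lesion_id = 1L, method = "mri", observer_id = 1L,
                    repeat_index = 1L, A = 7.5)
  s1 <- summarize_measurements(rec, "A")
  expect_equal(s1$mean, c(7.5, 7.5))
  expect_equal(s1$sd, c(0, 0))       # single record: SD reported as 0
  expect_true(all(s1$n_flag))        # ...with the n = 1 flag set
  rec2 <- rbind(rec, rec)
  rec2$repeat_index <- 1:2
  s2 <- summarize_measurements(rec2, "A")
  expect_equal(s2$sd[s2$level == "raw"], 0)  # identical records: SD 0
  ## cohort draw recovers its target mean within sampling error
  set.seed(8)
  rec3 <- balanced_records(99, sd_lesion = 2.8, sd_noise = 0.3)
  s3 <- summarize_measurements(rec3, "A")
  lesion_mri <- s3[s3$method == "mri" & s3$level == "lesion", ]
  expect_lt(abs(lesion_mri$mean - 9), 2 * 2.8 / sqrt(99))
})
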