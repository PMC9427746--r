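test_that("degenerate bootstrap inputs give the documented results", {
  r <- bca_bootstrap_test(rep(2.5, 10), n_boot = 1000, seed = 1)
  expect_equal(r$ci_low, 2.5)
  expect_equal(r$ci_high, 2.5)
  expect_equal(r$p_value, 1 / 1000)
  r0 <- bca_bootstrap_test(rep(0, 10), n_boot = 1000, seed = 1)
  expect_equal(r0$p_value, 1)
  expect_error(bca_bootstrap_test(c(1, 2), n_boot = 1000), "at least 3")
  expect_error(bca_bootstrap_test(rnorm(10), n_boot = 10), "n_boot")
})

test_that("symmetric zero-mean data are clearly non-significant", {
  x <- rep(c(1, -1), 13) # n = 26, mean 0
  r <- bca_bootstrap_test(x, n_boot = 2000, seed = 4)
  expect_gt(r$p_value, 0.5)
  expect_lt(r$ci_low, 0)
  expect_gt(r$ci_high, 0)
  expect_lt(abs(r$bias_correction_z0), 0.1)
  expect_equal(r$acceleration_a, 0) # exact: jackknife values are symmetric
})

test_that("BCa reduces to the percentile interval when z0 = a = 0", {
  x <- rep(c(1, -1), 13)
  r <- bca_bootstrap_test(x, n_boot = 4000, seed = 9, keep_boot = TRUE)
  perc <- unname(stats::quantile(r$boot_means, c(0.025, 0.975), type = 1))
  # z0 is near (not exactly) 0, so allow a few order statistics of slack
  expect_equal(r$ci_low, perc[1], tolerance = 0.08)
  expect_equal(r$ci_high, perc[2], tolerance = 0.08)
})

test_that("clearly shifted data are significant with a sane interval", {
  withr::with_seed(5, x <- rnorm(26, mean = 1, sd = 0.5))
  r <- bca_bootstrap_test(x, n_boot = 2000, seed = 2)
  expect_lt(r$p_value, 0.01)
  expect_gt(r$ci_low, 0)
  expect_true(r$ci_low <= r$observed_stat && r$observed_stat <= r$ci_high)
  # p-value honors its floor and the CI honors its level
  expect_gte(r$p_value, 1 / 2000)
})

test_that("bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, family = 4), 0.04)
  expect_equal(bonferroni_adjust(0.5, family = 4), 1.0)
  expect_identical(bonferroni_adjust(numeric(0)), numeric(0))
  expect_equal(bonferroni_adjust(c(0.02, 0.5)), c(0.04, 1))
  expect_error(bonferroni_adjust(1.2), "p-values")
})

test_that("ROI aggregation averages cells and validates coverage", {
  layout <- default_roi_layout()
  peaks <- data.frame(channel = layout$channel, target_freq = 1.5625,
                      snr = 2, d = 0.7)
  agg <- roi_aggregate(peaks, layout)
  expect_equal(nrow(agg), 9)
  expect_true(all(agg$d == 0.7))
  expect_equal(sum(agg$n_channels), 64)

  # a posterior gradient in d shows up in the anteriority means
  mont <- default_montage()
  w <- mont$row[match(layout$channel, mont$channel)]
  peaks$d <- w
  agg2 <- roi_aggregate(peaks, layout)
  post <- mean(agg2$d[agg2$anteriority == "posterior"])
  front <- mean(agg2$d[agg2$anteriority == "frontal"])
  expect_gt(post, front)

  # unmapped channels are excluded but counted
  peaks3 <- rbind(peaks, data.frame(channel = "EXG1", target_freq = 1.5625,
                                    snr = 1, d = 0))
  agg3 <- roi_aggregate(peaks3, layout)
  expect_equal(attr(agg3, "n_unmapped"), 1)
  # an empty requested cell errors with its name
  expect_error(roi_aggregate(peaks[peaks$channel != "Fpz", ][1:10, ], layout),
               "empty ROI cell")
})

test_that("peak correlations match hand-computed cases", {
  a <- c(1, -1, 1, -1); b <- c(1, 1, -1, -1)
  expect_equal(peak_correlation(a, b)$r, 0)
  self <- peak_correlation(c(1, 2, 3, 5), c(1, 2, 3, 5))
  expect_equal(self$r, 1)
  expect_equal(self$r_squared, 1)
  expect_error(peak_correlation(1:2, 1:2), "at least 3")
  expect_error(peak_correlation(1:3, 1:4), "equal length")
  flagged <- peak_correlation(c(1, 1, 1), c(1, 2, 3))
  expect_false(flagged$defined)
  expect_true(is.na(flagged$r))
  # p agrees with the t-distribution reference
  withr::with_seed(3, {x <- rnorm(12); y <- x + rnorm(12)})
  expect_equal(peak_correlation(x, y)$p, stats::cor.test(x, y)$p.value,
               tolerance = 1e-12)
})

test_that("d-prime uses the log-linear correction and is antisymmetric", {
  expect_equal(dprime(5, 5, 5, 5)$dprime, 0)
  r <- dprime(8, 0, 0, 22)
  expect_equal(r$dprime, stats::qnorm(8.5 / 9) - stats::qnorm(0.5 / 23))
  expect_true(is.finite(r$dprime))
  expect_equal(dprime(8, 2, 3, 19)$dprime, -dprime(3, 19, 8, 2)$dprime)
  expect_error(dprime(0, 0, 3, 7), "at least one")
})
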