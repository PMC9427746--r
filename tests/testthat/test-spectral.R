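test_that("target frequencies land on the canonical bins", {
  expect_identical(target_bin(0.78125, 14.08), 11L)
  expect_identical(target_bin(1.5625, 14.08), 22L)
  expect_identical(target_bin(3.125, 14.08), 44L)
  err <- tryCatch(target_bin(1.0, 14.08), error = function(e) conditionMessage(e))
  expect_match(err, "off the")
  expect_match(err, "bin") # names the nearest bin
})

test_that("evoked power concentrates an integer-cycle sinusoid on one bin", {
  es <- sine_epochs(1, freq = CANON$half, amp = 1)
  spec <- evoked_power(es)
  b <- target_bin(CANON$half, CANON$epoch_len_s) + 1
  expect_equal(unname(spec$power[1, b]), 1 / 4, tolerance = 1e-9) # A^2/4 two-sided
  expect_lt(max(spec$power[1, -b]) / spec$power[1, b], 1e-10)
  expect_equal(spec$freqs[2], 1 / 14.08)
  expect_error(evoked_power(epoch_set(array(0, c(0, 1, 8)), 250, "a")), "empty")
})

test_that("trial averaging keeps fixed-phase and cancels random-phase power", {
  b <- target_bin(CANON$half, CANON$epoch_len_s) + 1
  p10 <- evoked_power(sine_epochs(10, CANON$half, noise_sd = 2, seed = 3))$power[1, b]
  p160 <- evoked_power(sine_epochs(160, CANON$half, noise_sd = 2, seed = 3))$power[1, b]
  expect_lt(abs(p160 - 0.25), abs(p10 - 0.25)) # converges to the clean value
  expect_equal(unname(p160), 0.25, tolerance = 0.05)

  # random phase: evoked power at the bin scales as 1/n
  pr <- vapply(c(10, 200), function(n) {
    mean(evoked_power(sine_epochs(n, CANON$half, n_channels = 30, seed = 5,
                                  random_phase = FALSE))$power[, b])
  }, numeric(1))
  expect_equal(pr[1], pr[2], tolerance = 1e-6) # fixed phase: n-invariant
  set.seed(99)
  prand <- vapply(c(10, 200), function(n) {
    # average over independent channels-as-replicates to stabilize
    arr <- array(0, c(n, 30, CANON$n_samp))
    t <- (seq_len(CANON$n_samp) - 1) / CANON$srate
    for (e in seq_len(n)) for (c in 1:30)
      arr[e, c, ] <- cos(2 * pi * CANON$half * t + runif(1, 0, 2 * pi))
    mean(evoked_power(epoch_set(arr, CANON$srate, paste0("c", 1:30)))$power[, b])
  }, numeric(1))
  expect_equal(prand[1] / prand[2], 20, tolerance = 0.6) # 200/10 = 20x drop
  expect_equal(prand[2], 0.25 / 200, tolerance = 0.5)    # absolute 1/n level
})

test_that("the transform conserves energy (Parseval)", {
  es <- sine_epochs(4, CANON$half, amp = 2, noise_sd = 1, seed = 8)
  spec <- evoked_power(es)
  erp <- colMeans(es$data)[1, ] # channel 1 trial average
  pw <- spec$power[1, ]
  nb <- length(pw)
  # reassemble the two-sided sum from the one-sided spectrum (even n)
  total <- pw[1] + pw[nb] + 2 * sum(pw[2:(nb - 1)])
  expect_equal(total, mean(erp^2), tolerance = 1e-9)
})

test_that("neighbor-bin SNR matches hand-computed values", {
  nb <- 60
  pw <- matrix(1, 1, nb)
  pw[1, 23] <- 15 # 0-based bin 22
  spec <- spectrum_set(pw, (0:(nb - 1)) / 14.08, 14.08)
  snr <- snr_normalize(spec)$snr[1, ]
  expect_equal(snr[23], 15)
  expect_equal(snr[22], 1 / ((13 + 15) / 14)) # 0.5: peak leaks into the mean
  flat <- snr_normalize(spectrum_set(matrix(1, 1, nb), (0:(nb - 1)) / 14.08, 14.08))
  expect_true(all(abs(flat$snr[1, 1:(nb - 7)] - 1) < 1e-12)) # interior + DC side
  expect_true(all(is.na(flat$snr[1, (nb - 6):nb]))) # Nyquist edge undefined
  expect_error(snr_normalize(spectrum_set(matrix(1, 1, 14), (0:13) / 14.08, 14.08)),
               "fewer than 15")
  # zero neighborhood is flagged, not a crash
  z <- snr_normalize(spectrum_set(matrix(0, 1, nb), (0:(nb - 1)) / 14.08, 14.08))
  expect_true(all(is.na(z$snr[1, ])))
})

test_that("SNR and D are scale invariant and D is zero for flat spectra", {
  es <- sine_epochs(6, CANON$half, amp = 1, noise_sd = 1, seed = 10)
  es2 <- es
  es2$data <- es2$data * 37
  p1 <- peak_measures(snr_normalize(evoked_power(es)), c(0.78125, 1.5625))
  p2 <- peak_measures(snr_normalize(evoked_power(es2)), c(0.78125, 1.5625))
  expect_equal(p1$snr, p2$snr, tolerance = 1e-12)
  expect_equal(p1$d, p2$d, tolerance = 1e-12)

  flat <- spectrum_set(matrix(1, 2, 100), (0:99) / 14.08, 14.08)
  pf <- peak_measures(snr_normalize(flat), c(0.78125, 1.5625, 3.125))
  expect_true(all(abs(pf$d) < 1e-12))
  expect_true(all(abs(pf$snr - 1) < 1e-12))
  expect_error(peak_measures(snr_normalize(flat), 1.0), "off the")
})

test_that("target-bin SNR grows monotonically with component amplitude", {
  b <- target_bin(CANON$half, CANON$epoch_len_s) + 1
  snrs <- vapply(c(0.5, 1, 2, 4), function(a) {
    es <- sine_epochs(5, CANON$half, amp = a, noise_sd = 1.5, seed = 77)
    snr_normalize(evoked_power(es))$snr[1, b]
  }, numeric(1))
  expect_true(all(diff(snrs) > 0))
})

test_that("spectrum_average pools rows of power and SNR", {
  pw <- rbind(rep(1, 40), rep(3, 40))
  sp <- snr_normalize(spectrum_set(pw, (0:39) / 14.08, 14.08))
  avg <- spectrum_average(sp)
  expect_equal(nrow(avg$power), 1)
  expect_true(all(avg$power == 2))
  expect_true(all(abs(avg$snr[1, 1:30] - 1) < 1e-12))
})
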