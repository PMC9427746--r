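test_that("Kaiser FIR designs meet their passband/stopband contract", {
  lp <- fir_kaiser(152, 20, 250, "low")
  expect_length(lp, 153)
  expect_equal(sum(lp), 1) # exact unity DC gain
  expect_equal(fir_response(lp, 20, 250), 0.5, tolerance = 0.02) # -6 dB point
  expect_gt(fir_response(lp, 2, 250), 10^(-1 / 20)) # within 1 dB in passband
  expect_lt(abs(fir_response(lp, 30, 250)), 10^(-6 / 20)) # >= 6 dB down

  hp <- fir_kaiser(2266, 0.2, 250, "high")
  expect_lt(abs(fir_response(hp, 0, 250)), 1e-12) # DC blocked
  expect_gt(fir_response(hp, 0.78125, 250), 10^(-1 / 20))
  expect_error(fir_kaiser(151, 20, 250), "even")
  expect_error(fir_kaiser(152, 200, 250), "cutoff")
})

test_that("preprocessing halves the rate and applies the band limits", {
  rec <- toy_recording(20, 500, list(
    dc = function(t) rep(7, length(t)),
    slow = function(t) sin(2 * pi * 2 * t),
    fast = function(t) sin(2 * pi * 30 * t),
    M1 = function(t) numeric(length(t)),
    M2 = function(t) numeric(length(t))
  ))
  out <- preprocess_continuous(rec)
  expect_equal(out$srate, 250)
  expect_equal(nrow(out$data), round(20 * 250))
  mid <- 1500:3500 # away from edge transients
  expect_lt(max(abs(out$data[mid, 1])), 0.05) # DC removed by the high-pass
  amp2 <- max(abs(out$data[mid, 2]))
  expect_gt(amp2, 10^(-1 / 20))
  expect_lt(amp2, 10^(1 / 20))
  expect_lt(max(abs(out$data[mid, 3])), 0.5) # 30 Hz beyond cutoff
})

test_that("re-referencing is idempotent and preserves channel differences", {
  set.seed(42)
  n <- 4000
  mk <- function() rnorm(n, sd = 3)
  rec <- toy_recording(8, 500, list(a = function(t) mk(), b = function(t) mk(),
                                    M1 = function(t) mk(), M2 = function(t) mk()))
  # pre-referenced copy: subtracting the mastoid mean up front must not
  # change anything downstream
  ref <- 0.5 * (rec$data[, "M1"] + rec$data[, "M2"])
  rec_pre <- eeg_recording(rec$data - ref, 500, rec$channel_labels, rec$events)
  o1 <- preprocess_continuous(rec)
  o2 <- preprocess_continuous(rec_pre)
  expect_equal(o1$data, o2$data, tolerance = 1e-10)
  expect_equal(o1$data[, 1] - o1$data[, 2], o2$data[, 1] - o2$data[, 2],
               tolerance = 1e-10)
  # output is referenced: mastoid mean is (numerically) zero
  expect_lt(max(abs(0.5 * (o1$data[, 3] + o1$data[, 4]))), 1e-10)
})

test_that("preprocessing validates its inputs", {
  rec <- toy_recording(2, 500, list(a = function(t) t, M1 = function(t) t,
                                    M2 = function(t) t))
  bad <- rec; bad$channel_labels[2] <- "TP9"
  expect_error(preprocess_continuous(bad), "mastoid")
  bad2 <- rec; bad2$srate <- 441
  expect_error(preprocess_continuous(bad2), "multiple")
})

test_that("epochs are cut at onset + 1.28 s with zero mean per channel", {
  # synthetic already-preprocessed recording at 250 Hz
  n <- 5000
  set.seed(7)
  data <- matrix(rnorm(n * 3), n, 3)
  ev <- data.frame(sample = 1L, trial = 1L, condition = "x", is_outlier = FALSE)
  rec <- eeg_recording(data, 250, c("a", "b", "M1"), ev)
  es <- extract_epochs(rec)
  expect_equal(dim(es$data), c(1, 3, 3520))
  # covers samples 321..3840 (0-based 320..3839)
  seg <- data[321:3840, 1]
  expect_equal(as.vector(es$data[1, 1, ]), seg - mean(seg))
  expect_lt(max(abs(rowMeans(es$data[1, , ]))), 1e-9)

  # truncated second trial is skipped with a warning
  ev2 <- rbind(ev, data.frame(sample = 2000L, trial = 2L, condition = "x",
                              is_outlier = FALSE))
  rec2 <- eeg_recording(data, 250, c("a", "b", "M1"), ev2)
  expect_warning(es2 <- extract_epochs(rec2), "truncated")
  expect_equal(dim(es2$data)[1], 1)
  # outlier trials are dropped before epoching
  ev3 <- ev; ev3$is_outlier <- TRUE
  rec3 <- eeg_recording(data, 250, c("a", "b", "M1"), ev3)
  expect_error(extract_epochs(rec3), "no trial events")
  expect_equal(dim(extract_epochs(rec3, exclude_outlier_trials = FALSE)$data)[1], 1)
})

test_that("dummy-epoch amplitude rules fire as specified", {
  t <- (0:3519) / 250
  base <- 50 * sin(2 * pi * 2 * t)
  arr <- array(0, c(6, 2, 3520))
  set.seed(11)
  for (e in 1:6) for (c in 1:2) arr[e, c, ] <- base + rnorm(3520)
  es <- epoch_set(arr, 250, c("a", "b"))
  clean <- reject_epochs(es, rule_set = "ica_dummy")
  expect_equal(dim(clean$data)[1], 6) # sinusoid + mild noise: none rejected

  # a +/- 500 uV pulse trips the absolute rule
  arr2 <- arr
  arr2[3, 1, 100:149] <- arr2[3, 1, 100:149] + 500
  es2 <- epoch_set(arr2, 250, c("a", "b"))
  rej <- reject_epochs(es2, rule_set = "ica_dummy")
  expect_equal(dim(rej$data)[1], 5)
  expect_true("abs_400uV" %in% rej$rejection_log$rule)
  expect_true(3 %in% rej$rejection_log$epoch_index)

  # a smaller excursion is caught by the pooled-SD rules instead
  arr3 <- arr
  arr3[2, 2, 200:210] <- arr3[2, 2, 200:210] + 300
  rej3 <- reject_epochs(epoch_set(arr3, 250, c("a", "b")), rule_set = "ica_dummy")
  expect_equal(dim(rej3$data)[1], 5)
  expect_false("abs_400uV" %in% rej3$rejection_log$rule)
})

test_that("the 40 dB spectral rule removes low-frequency outlier epochs", {
  t <- (0:3519) / 250
  set.seed(13)
  arr <- array(rnorm(8 * 2 * 3520, sd = 1), c(8, 2, 3520))
  # epoch 5 carries a ~1 Hz (exact-bin) component with ~1e5 times the
  # others' power at that bin: 10 log10(1e5) = 50 dB > 40 dB
  f14 <- 14 / 14.08
  per_bin_noise <- 1 / 3520 # E|X/n|^2 for unit-variance white noise
  amp <- sqrt(4 * 1e5 * per_bin_noise)
  arr[5, 1, ] <- arr[5, 1, ] + amp * sin(2 * pi * f14 * t)
  es <- epoch_set(arr, 250, c("a", "b"))
  rej <- reject_epochs(es, rule_set = "final")
  expect_equal(dim(rej$data)[1], 7)
  expect_equal(rej$rejection_log$epoch_index, 5)
  expect_identical(unique(rej$rejection_log$rule), "spectral_40dB")
  # mutually dominating epochs: everything rejected is an explicit error
  two <- array(rnorm(2 * 1 * 3520, sd = 0.01), c(2, 1, 3520))
  two[1, 1, ] <- two[1, 1, ] + amp * sin(2 * pi * f14 * t)
  two[2, 1, ] <- two[2, 1, ] + amp * sin(2 * pi * 28 / 14.08 * t)
  expect_error(reject_epochs(epoch_set(two, 250, "a"), rule_set = "final"),
               "all epochs rejected")
  expect_error(reject_epochs(epoch_set(array(0, c(0, 2, 10)), 250, c("a", "b"))),
               "empty")
})

test_that("the ICA copy is strongly high-pass filtered", {
  rec <- toy_recording(20, 250, list(
    slow = function(t) sin(2 * pi * 0.3 * t),
    keep = function(t) sin(2 * pi * 5 * t),
    M1 = function(t) numeric(length(t)),
    M2 = function(t) numeric(length(t))
  ))
  out <- make_ica_copy(rec)
  mid <- 1500:3500
  h <- fir_kaiser(454, 1, 250, "high")
  gain_03 <- abs(fir_response(h, 0.3, 250))
  expect_equal(max(abs(out$data[mid, 1])), gain_03, tolerance = 0.05)
  expect_lt(gain_03, 0.5) # genuinely suppressed relative to the passband
  expect_equal(max(abs(out$data[mid, 2])), abs(fir_response(h, 5, 250)),
               tolerance = 0.01)
  expect_equal(out$srate, 250)
})
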