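test_that("rendered envelopes have the contracted length and are nonnegative", {
  d <- quick_design()
  env <- render_trial_envelope(d, 1, env_rate = 1000)
  expect_length(env$samples, 15360) # 15.36 s x 1000 Hz
  expect_true(all(env$samples >= 0))
  expect_length(render_trial_envelope(d, 1, env_rate = 250)$samples, 3840)
  expect_error(render_trial_envelope(d, 1, env_rate = 1), "env_rate")
  expect_error(render_trial_envelope(d, 3, env_rate = 250), "out of range")
})

test_that("W24 maxima sit on words 2 and 4 of every sentence", {
  d <- build_design("S22", "OvP", n_trials = 1, outlier_fraction = 0, seed = 3,
                    word_gain_jitter_sd = 0)
  env <- render_trial_envelope(d, 1, env_rate = 1000)
  at <- function(t) env$samples[round(t * 1000) + 1]
  for (s in 0:11) {
    t0 <- s * 1.28
    expect_gt(at(t0 + 0.48), at(t0 + 0.16)) # word 2 > word 1 center
    expect_gt(at(t0 + 1.12), at(t0 + 0.80)) # word 4 > word 3 center
  }
})

test_that("flat envelopes carry no sentence- or phrase-rate component", {
  d <- build_design("S22", "ImplP", n_trials = 1, outlier_fraction = 0,
                    seed = 1, word_gain_jitter_sd = 0)
  env <- render_trial_envelope(d, 1, env_rate = 250)
  amp <- Mod(stats::fft(env$samples)) / length(env$samples)
  # full-trial grid: df = 1/15.36 Hz; word rate at bin 48, sentence 12, half 24
  expect_gt(amp[48 + 1], 1e-3)
  expect_lt(amp[12 + 1], 1e-12 * amp[48 + 1])
  expect_lt(amp[24 + 1], 1e-12 * amp[48 + 1])
})

test_that("W24 spectral amplitude at the modulation rate matches the closed form", {
  dflat <- build_design("S22", "ImplP", n_trials = 1, outlier_fraction = 0,
                        seed = 1, word_gain_jitter_sd = 0)
  dw <- build_design("S22", "OvP", n_trials = 1, outlier_fraction = 0,
                     seed = 1, word_gain_jitter_sd = 0)
  rate <- 500
  f <- render_trial_envelope(dflat, 1, rate)$samples
  w <- render_trial_envelope(dw, 1, rate)$samples
  n <- length(f)
  Ff <- stats::fft(f) / n
  Fw <- stats::fft(w) / n
  m <- dw$contour$modulation_index
  nu_bin <- 24 # 1.5625 Hz x 15.36 s
  theta <- 2 * pi * 1.5625 * dw$contour$phase_anchor_s
  # modulation theorem: X_w(k) = X_f(k) + m/2 (e^{-i theta} X_f(k - k_nu)
  #                                          + e^{+i theta} X_f(k + k_nu))
  predicted <- Ff[nu_bin + 1] +
    (m / 2) * (exp(-1i * theta) * Ff[1] + exp(1i * theta) * Ff[2 * nu_bin + 1])
  expect_equal(Mod(Fw[nu_bin + 1]), Mod(predicted), tolerance = 1e-8)
  expect_gt(Mod(Fw[nu_bin + 1]), 0.1 * m) # a real, order-m peak
})

test_that("per-word jitter is reproducible from the design seed", {
  d <- build_design("S22", "ImplP", n_trials = 2, outlier_fraction = 0, seed = 4)
  e1 <- render_trial_envelope(d, 1, 250)
  e1b <- render_trial_envelope(d, 1, 250)
  e2 <- render_trial_envelope(d, 2, 250)
  expect_identical(e1$samples, e1b$samples)
  expect_false(identical(e1$samples, e2$samples))
})

test_that("envelope spectra expose word-rate peaks and honor the window", {
  d <- build_design("S22", "ImplP", n_trials = 8, outlier_fraction = 0, seed = 2)
  trials <- lapply(1:8, function(i) render_trial_envelope(d, i, 250))
  sp <- envelope_spectrum(trials)
  expect_s3_class(sp, "spectrum_set")
  expect_equal(nrow(sp$power), 8)
  expect_equal(sp$freqs[2] - sp$freqs[1], 1 / 14.08)
  avg <- snr_normalize(spectrum_average(sp))
  expect_gt(avg$snr[1, target_bin(3.125, 14.08) + 1], 20)
  expect_lt(avg$snr[1, target_bin(1.5625, 14.08) + 1], 3)
  expect_lt(avg$snr[1, target_bin(0.78125, 14.08) + 1], 3)

  # mixed sampling rates are rejected
  bad <- c(trials, list(render_trial_envelope(d, 1, 500)))
  expect_error(envelope_spectrum(bad), "env_rate")
  expect_error(envelope_spectrum(trials, analysis_window = 20), "window")
})

test_that("a constant envelope transforms to DC only", {
  d <- build_design("S22", "ImplP", n_trials = 1, outlier_fraction = 0,
                    seed = 1, word_gain_jitter_sd = 0)
  env <- render_trial_envelope(d, 1, 250, ramp_s = 0) # exactly constant 1
  expect_true(all(abs(env$samples - 1) < 1e-12))
  sp <- envelope_spectrum(list(env))
  expect_lt(max(sp$power[1, -1]), 1e-20)
  expect_equal(unname(sqrt(sp$power[1, 1])), 1, tolerance = 1e-9)
})

test_that("envelope WAV and CSV export round-trip basic properties", {
  d <- quick_design()
  env <- render_trial_envelope(d, 1, 250)
  wav <- withr::local_tempfile(fileext = ".wav")
  write_envelope_wav(env, wav)
  expect_true(file.exists(wav))
  expect_equal(file.size(wav), 44 + 2 * length(env$samples))
  csv <- withr::local_tempfile(fileext = ".csv")
  sp <- envelope_spectrum(lapply(1:2, function(i) render_trial_envelope(d, i, 250)))
  write_envelope_spectrum_csv(sp, csv)
  df <- read.csv(csv)
  expect_named(df, c("freq_hz", "trial", "amplitude"))
  expect_equal(nrow(df), 2 * ncol(sp$power))
})
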