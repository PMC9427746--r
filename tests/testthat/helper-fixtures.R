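# Shared fixture builders. Everything is generated in code; no files.

CANON <- list(epoch_len_s = 14.08, srate = 250, n_samp = 3520,
              sent = 0.78125, half = 1.5625, word = 3.125)

# epoch_set of sinusoids built directly at the analysis rate
sine_epochs <- function(n_epochs, freq, amp = 1, noise_sd = 0,
                        n_channels = 4, phase = 0, seed = 1,
                        random_phase = FALSE, srate = CANON$srate,
                        n_samp = CANON$n_samp) {
  t <- (seq_len(n_samp) - 1) / srate
  arr <- array(0, c(n_epochs, n_channels, n_samp))
  withr::with_seed(seed, {
    for (e in seq_len(n_epochs)) {
      ph <- if (random_phase) runif(1, 0, 2 * pi) else phase
      base <- amp * cos(2 * pi * freq * t + ph)
      for (c in seq_len(n_channels)) {
        x <- base
        if (noise_sd > 0) x <- x + rnorm(n_samp, 0, noise_sd)
        arr[e, c, ] <- x - mean(x)
      }
    }
  })
  epoch_set(arr, srate, paste0("ch", seq_len(n_channels)))
}

# small continuous recording with chosen per-channel generators
toy_recording <- function(dur_s = 20, srate = 500, channels, events = NULL) {
  n <- round(dur_s * srate)
  t <- (seq_len(n) - 1) / srate
  data <- vapply(channels, function(f) f(t), numeric(n))
  labels <- names(channels)
  if (is.null(events))
    events <- data.frame(sample = integer(0), trial = integer(0),
                         condition = character(0), is_outlier = logical(0))
  eeg_recording(data, srate, labels, events)
}

quick_design <- function(syntax = "S22", prosody = "ImplP", n_trials = 2,
                         seed = 1, ...) {
  build_design(syntax, prosody, n_trials = n_trials, outlier_fraction = 0,
               seed = seed, ...)
}

# effect table with all amplitudes zeroed except the named component rows
effects_only <- function(component, amplitude = 1, topography = "uniform",
                         fixed_phase = TRUE) {
  et <- default_effect_table()
  et$amplitude <- 0
  sel <- et$component == component
  et$amplitude[sel] <- amplitude
  et$topography[sel] <- topography
  et$fixed_phase[sel] <- fixed_phase
  et
}
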