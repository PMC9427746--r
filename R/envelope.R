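#' Render the intensity envelope of one trial
#'
#' Produces the stimulus intensity envelope (arbitrary linear units, all
#' values >= 0) of one trial of the design. Each word contributes a
#' stylized pulse: unit amplitude with raised-cosine onset/offset ramps,
#' identical for every word, so the flat-prosody envelope is exactly
#' periodic at the word rate and carries no energy at the sentence or
#' half-sentence rates. A W24 contour multiplies the flat envelope by
#' `1 + m cos(2 pi f t)` with `f` the half-sentence rate and maxima at the
#' midpoints of words 2 and 4 of every sentence (t = 0.48 s and 1.12 s
#' within each 1.28-s sentence).
#'
#' Per-word multiplicative intensity jitter (lognormal, sd set in the
#' design) emulates natural word-to-word loudness differences and gives
#' the single-trial spectra a broadband floor; it is reproducible from the
#' design seed and the trial index.
#'
#' @param design A [build_design()] object.
#' @param trial_index Trial number, 1-based.
#' @param env_rate Envelope sampling rate in Hz; must be at least four
#'   times the word rate.
#' @param ramp_s Raised-cosine ramp duration in seconds (default 10 ms).
#'
#' @return An object of class `trial_envelope`: list with `samples`,
#'   `env_rate`, `trial_index`.
#' @examples
#' d <- build_design("S22", "OvP", n_trials = 2, outlier_fraction = 0, seed = 1)
#' env <- render_trial_envelope(d, 1, env_rate = 250)
#' length(env$samples) # 3840 = 15.36 s x 250 Hz
#' @export
render_trial_envelope <- function(design, trial_index, env_rate = 250,
                                  ramp_s = 0.010) {
  stopifnot(inherits(design, "stimulus_design"))
  dc <- design$constants
  if (env_rate < 4 * dc$word_rate)
    stop("env_rate too low: need at least 4 x word rate (",
         4 * dc$word_rate, " Hz)")
  trial_index <- as.integer(trial_index)
  if (is.na(trial_index) || trial_index < 1 || trial_index > design$n_trials)
    stop("trial_index out of range [1, ", design$n_trials, "]")
  if (ramp_s < 0 || 2 * ramp_s > dc$word_duration)
    stop("ramp_s must lie in [0, word_duration / 2]")

  n <- .n_samples(dc$trial_duration, env_rate)
  t <- (seq_len(n) - 1) / env_rate
  word_idx <- pmin(floor(t / dc$word_duration), dc$words_per_trial - 1)
  u <- t - word_idx * dc$word_duration # position within word

  pulse <- rep(1, n)
  if (ramp_s > 0) {
    on <- u < ramp_s
    off <- u > dc$word_duration - ramp_s
    pulse[on] <- 0.5 - 0.5 * cos(pi * u[on] / ramp_s)
    pulse[off] <- 0.5 - 0.5 * cos(pi * (dc$word_duration - u[off]) / ramp_s)
  }

  gains <- rep(1, dc$words_per_trial)
  if (design$word_gain_jitter_sd > 0) {
    gains <- with_seed(
      child_seed(design$seed, "wordgain", design$syntax, design$prosody, trial_index),
      exp(stats::rnorm(dc$words_per_trial, 0, design$word_gain_jitter_sd))
    )
  }
  env <- pulse * gains[word_idx + 1]

  if (design$contour$kind == "W24") {
    m <- design$contour$modulation_index
    f <- design$contour$modulation_rate
    env <- env * (1 + m * cos(2 * pi * f * (t - design$contour$phase_anchor_s)))
  }

  structure(list(samples = env, env_rate = env_rate,
                 trial_index = trial_index),
            class = "trial_envelope")
}

#' Modulation spectra of trial envelopes
#'
#' Computes per-trial amplitude spectra of the intensity envelopes over the
#' analysis window used by the EEG path (by default the final 14.08 s of
#' the 15.36-s trial, i.e. from the start of the second sentence), plus the
#' across-trial average spectrum. The result shares the `spectrum_set`
#' container with the EEG path, so the same neighbor-bin SNR normalization
#' applies downstream.
#'
#' @param trials List of [render_trial_envelope()] objects with a common
#'   sampling rate.
#' @param analysis_window Window length in seconds; grid spacing is its
#'   reciprocal.
#' @param offset Window start within the trial, seconds.
#' @return A [spectrum_set()] with one row per trial (row names `trial<i>`).
#' @export
envelope_spectrum <- function(trials, analysis_window = 14.08, offset = 1.28) {
  if (length(trials) < 1) stop("need at least one trial envelope")
  rates <- vapply(trials, function(x) x$env_rate, numeric(1))
  if (length(unique(rates)) != 1)
    stop("all trials must share the same env_rate")
  rate <- rates[1]
  n_have <- length(trials[[1]]$samples)
  if (offset < 0 || (offset + analysis_window) * rate > n_have + 0.5)
    stop("analysis window exceeds trial duration")
  i0 <- .n_samples(offset, rate)
  n <- .n_samples(analysis_window, rate)
  amp <- t(vapply(trials, function(tr) {
    x <- tr$samples[(i0 + 1):(i0 + n)]
    Mod(stats::fft(x)) / n
  }, numeric(n)))
  nb <- floor(n / 2) + 1
  amp <- amp[, seq_len(nb), drop = FALSE]
  rownames(amp) <- paste0("trial", vapply(trials, function(x) x$trial_index, integer(1)))
  spectrum_set(power = amp^2,
               freqs = (seq_len(nb) - 1) / analysis_window,
               epoch_length = analysis_window,
               n_epochs_averaged = 1L,
               amplitude = amp)
}

#' Write trial envelopes as WAV audio
#'
#' Mono 16-bit PCM WAV with the envelope rate as sample rate; intended for
#' inspection, not playback fidelity. Samples are rescaled to peak 0.9.
#'
#' @param env A `trial_envelope`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_envelope_wav <- function(env, path) {
  stopifnot(inherits(env, "trial_envelope"))
  x <- env$samples
  if (max(abs(x)) > 0) x <- 0.9 * x / max(abs(x))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_data <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_data), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")      # PCM
  writeBin(1L, con, size = 2, endian = "little")      # mono
  writeBin(as.integer(env$env_rate), con, size = 4, endian = "little")
  writeBin(as.integer(env$env_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_data, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Export envelope spectra to CSV
#'
#' Long-format table with columns `freq_hz`, `trial`, `amplitude`.
#'
#' @param spec A `spectrum_set` from [envelope_spectrum()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_envelope_spectrum_csv <- function(spec, path) {
  amp <- attr(spec, "amplitude")
  if (is.null(amp)) amp <- sqrt(spec$power)
  df <- data.frame(
    freq_hz = rep(spec$freqs, each = nrow(amp)),
    trial = rep(rownames(amp), times = ncol(amp)),
    amplitude = as.vector(amp)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
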