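#' EEG recording container
#'
#' @param data Numeric matrix, samples x channels (column-major time
#'   series; channel order matches `channel_labels`).
#' @param srate Sampling rate, Hz.
#' @param channel_labels Channel names (montage labels; mastoids `M1`,
#'   `M2`).
#' @param events data.frame with columns `sample` (1-based trial-onset
#'   index), `trial`, `condition`, `is_outlier`.
#' @param meta Optional list of provenance fields.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, srate, channel_labels, events,
                          meta = list()) {
  data <- as.matrix(data)
  stopifnot(ncol(data) == length(channel_labels))
  if (nrow(events) > 0) {
    if (is.unsorted(events$sample, strictly = TRUE))
      stop("events must be strictly increasing")
    if (max(events$sample) - 1 + any_trial_span(meta, srate) > nrow(data))
      stop("every event must leave a full trial of signal after it")
  }
  structure(list(data = data, srate = srate,
                 channel_labels = channel_labels,
                 events = events, meta = meta),
            class = "eeg_recording")
}

# trial span in samples for the event-coverage invariant (0 if unknown)
any_trial_span <- function(meta, srate) {
  if (!is.null(meta$trial_duration)) round(meta$trial_duration * srate) else 0
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("eeg_recording: %d channels x %d samples @ %g Hz, %d events\n",
              ncol(x$data), nrow(x$data), x$srate, nrow(x$events)))
  invisible(x)
}

#' Simulate a multichannel EEG recording for one condition cell
#'
#' Builds a continuous 500-Hz recording: per trial, each channel receives
#' the sum over evoked components of
#' `amplitude x topography_weight x cos(2 pi f (t - trial_onset))` —
#' phase fixed relative to trial onset and identical across trials, so the
#' components survive trial averaging — plus `1/f^alpha` background noise
#' drawn fresh per trial and independently per channel. Trials are
#' contiguous; zero-padding of `pad_s` seconds flanks the trial block.
#' Optionally, a fraction of trials receives a square-pulse artifact
#' (default +/- 500 uV, 200 ms, one random channel) to exercise the
#' amplitude rejection rules.
#'
#' Components flagged `fixed_phase = FALSE` in the effect table get a new
#' uniform random phase on every trial: they are "induced" activity and
#' must cancel from the evoked spectrum as the trial count grows.
#'
#' @param design A [build_design()] object selecting the condition cell.
#' @param effects An effect table ([default_effect_table()]); rows are
#'   subset to the design's (syntax, prosody) cell.
#' @param noise_alpha Spectral exponent of the background noise.
#' @param noise_scale Noise standard deviation per channel, microvolts.
#' @param artifact_rate Fraction of trials receiving an artifact pulse.
#' @param seed Integer seed; the recording is bitwise reproducible.
#' @param srate Sampling rate (Hz).
#' @param montage Montage table ([default_montage()]).
#' @param component_gains Optional named multipliers on component
#'   amplitudes (names = component labels), e.g. per-participant gains.
#' @param artifact_amp,artifact_dur_s Artifact pulse amplitude (uV) and
#'   duration (s).
#' @param pad_s Zero-padding before and after the trial block, seconds.
#' @return An [eeg_recording()].
#' @export
simulate_recording <- function(design, effects = default_effect_table(),
                               noise_alpha = 1, noise_scale = 5,
                               artifact_rate = 0, seed = 1, srate = 500,
                               montage = default_montage(),
                               component_gains = NULL,
                               artifact_amp = 500, artifact_dur_s = 0.2,
                               pad_s = 2) {
  stopifnot(inherits(design, "stimulus_design"))
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  if (artifact_rate < 0 || artifact_rate > 1)
    stop("artifact_rate must lie in [0, 1]")
  validate_effect_table(effects)
  eff <- effects[effects$syntax == design$syntax &
                   effects$prosody == design$prosody &
                   effects$amplitude > 0, , drop = FALSE]
  if (!is.null(component_gains)) {
    m <- match(eff$component, names(component_gains))
    gain <- ifelse(is.na(m), 1, component_gains[m])
    eff$amplitude <- eff$amplitude * gain
  }

  labels <- montage$channel
  n_ch <- length(labels)
  dc <- design$constants
  ns_trial <- .n_samples(dc$trial_duration, srate)
  ns_pad <- .n_samples(pad_s, srate)
  n_trials <- design$n_trials
  n_total <- ns_pad * 2L + ns_trial * n_trials

  # topography weight matrix: channels x components
  W <- vapply(seq_len(nrow(eff)), function(i) {
    topography_profile(eff$topography[i], montage)
  }, numeric(n_ch))

  tt <- (seq_len(ns_trial) - 1) / srate
  fixed_templates <- NULL
  if (nrow(eff) > 0 && any(eff$fixed_phase)) {
    idx <- which(eff$fixed_phase)
    S <- vapply(idx, function(i) eff$amplitude[i] * cos(2 * pi * eff$freq[i] * tt),
                numeric(ns_trial))
    fixed_templates <- S %*% t(W[, idx, drop = FALSE]) # ns_trial x channels
  }
  rand_idx <- which(!eff$fixed_phase)

  data <- matrix(0, n_total, n_ch)
  events <- data.frame(sample = integer(n_trials), trial = seq_len(n_trials),
                       condition = paste(design$syntax, design$prosody, sep = "_"),
                       is_outlier = design$trial_outlier_flags)

  artifact_trials <- integer(0)
  if (artifact_rate > 0) {
    n_art <- round(artifact_rate * n_trials)
    if (n_art > 0)
      artifact_trials <- with_seed(child_seed(seed, "arttrials"),
                                   sample.int(n_trials, n_art))
  }

  for (tr in seq_len(n_trials)) {
    i0 <- ns_pad + (tr - 1L) * ns_trial
    sel <- (i0 + 1L):(i0 + ns_trial)
    block <- make_pink_noise(ns_trial, n_ch, alpha = noise_alpha,
                             seed = child_seed(seed, "noise", tr),
                             scale = noise_scale)
    if (!is.null(fixed_templates)) block <- block + fixed_templates
    if (length(rand_idx)) {
      ph <- with_seed(child_seed(seed, "phase", tr),
                      stats::runif(length(rand_idx), 0, 2 * pi))
      S <- vapply(seq_along(rand_idx), function(j) {
        i <- rand_idx[j]
        eff$amplitude[i] * cos(2 * pi * eff$freq[i] * tt + ph[j])
      }, numeric(ns_trial))
      block <- block + S %*% t(W[, rand_idx, drop = FALSE])
    }
    if (tr %in% artifact_trials) {
      art <- with_seed(child_seed(seed, "artifact", tr), {
        list(ch = sample.int(n_ch, 1),
             at = sample.int(ns_trial - .n_samples(artifact_dur_s, srate), 1),
             sign = sample(c(-1, 1), 1))
      })
      span <- art$at:(art$at + .n_samples(artifact_dur_s, srate) - 1L)
      block[span, art$ch] <- block[span, art$ch] + art$sign * artifact_amp
    }
    data[sel, ] <- block
    events$sample[tr] <- i0 + 1L
  }

  eeg_recording(data, srate, labels, events,
                meta = list(syntax = design$syntax, prosody = design$prosody,
                            trial_duration = dc$trial_duration,
                            seed = seed, noise_alpha = noise_alpha,
                            noise_scale = noise_scale,
                            artifact_trials = artifact_trials))
}

#' Simulate behavioral outlier-detection responses
#'
#' One button-press response per trial: outlier trials are reported as
#' containing an implausible sentence with probability `p_hit`, clean
#' trials with probability `p_fa`. Defaults match the overall accuracy
#' level the paradigm produces in listeners (roughly 72% correct).
#'
#' @param design A [build_design()] object (its outlier flags define the
#'   signal trials).
#' @param p_hit,p_fa Hit and false-alarm probabilities.
#' @param seed Integer seed.
#' @return data.frame with columns `trial`, `condition`, `has_outlier`,
#'   `response_outlier`.
#' @export
simulate_behavior <- function(design, p_hit = 0.722, p_fa = 0.278, seed = 1) {
  stopifnot(inherits(design, "stimulus_design"))
  if (any(c(p_hit, p_fa) < 0) || any(c(p_hit, p_fa) > 1))
    stop("p_hit and p_fa must lie in [0, 1]")
  has <- design$trial_outlier_flags
  resp <- with_seed(child_seed(seed, "behavior"), {
    u <- stats::runif(length(has))
    ifelse(has, u < p_hit, u < p_fa)
  })
  data.frame(trial = seq_along(has),
             condition = paste(design$syntax, design$prosody, sep = "_"),
             has_outlier = has, response_outlier = resp)
}

#' Tally signal-detection counts from behavioral responses
#'
#' @param responses Output of [simulate_behavior()] (rows may be pooled
#'   across conditions).
#' @return Named integer vector: `n_hit`, `n_miss`, `n_fa`, `n_cr`.
#' @export
behavior_counts <- function(responses) {
  c(n_hit = sum(responses$has_outlier & responses$response_outlier),
    n_miss = sum(responses$has_outlier & !responses$response_outlier),
    n_fa = sum(!responses$has_outlier & responses$response_outlier),
    n_cr = sum(!responses$has_outlier & !responses$response_outlier))
}
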