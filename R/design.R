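#' Design constants of the frequency-tagging paradigm
#'
#' Timing constants of the isochronous speech design: monosyllabic words of
#' fixed duration are concatenated without pauses into four-word sentences,
#' and twelve sentences form one trial. All tagged rates follow from the
#' word duration alone, so the constants are computed, not stored.
#'
#' @param word_duration Duration of one spoken word in seconds.
#' @param words_per_sentence Number of words per sentence.
#' @param sentences_per_trial Number of sentences per trial.
#' @param n_clean_trials Trials without a semantic outlier sentence
#'   (the trials entering EEG analysis).
#' @param n_outlier_trials Additional trials containing one semantically
#'   implausible sentence each; used only for the behavioral task.
#'
#' @return An object of class `design_constants`: a list with the timing
#'   fields plus the derived rates `word_rate`, `sentence_rate`,
#'   `half_sentence_rate` (Hz) and `trial_duration` (s).
#' @examples
#' dc <- design_constants()
#' dc$trial_duration     # 15.36 s
#' dc$half_sentence_rate # 1.5625 Hz
#' @export
design_constants <- function(word_duration = 0.320,
                             words_per_sentence = 4L,
                             sentences_per_trial = 12L,
                             n_clean_trials = 22L,
                             n_outlier_trials = 8L) {
  stopifnot(word_duration > 0, words_per_sentence >= 1, sentences_per_trial >= 1)
  sentence_duration <- word_duration * words_per_sentence
  dc <- list(
    word_duration = word_duration,
    words_per_sentence = as.integer(words_per_sentence),
    sentences_per_trial = as.integer(sentences_per_trial),
    sentence_duration = sentence_duration,
    trial_duration = sentence_duration * sentences_per_trial,
    word_rate = 1 / word_duration,
    sentence_rate = 1 / sentence_duration,
    half_sentence_rate = 2 / sentence_duration,
    words_per_trial = as.integer(words_per_sentence * sentences_per_trial),
    n_clean_trials = as.integer(n_clean_trials),
    n_outlier_trials = as.integer(n_outlier_trials)
  )
  class(dc) <- "design_constants"
  dc
}

#' @export
print.design_constants <- function(x, ...) {
  cat("Design constants:\n")
  cat(sprintf("  word       %.3f s  (%.5g Hz)\n", x$word_duration, x$word_rate))
  cat(sprintf("  sentence   %.3f s  (%.5g Hz, 1/2-sentence %.5g Hz)\n",
              x$sentence_duration, x$sentence_rate, x$half_sentence_rate))
  cat(sprintf("  trial      %.2f s  (%d words)\n", x$trial_duration, x$words_per_trial))
  invisible(x)
}

#' Prosodic contour specification
#'
#' A contour is either `flat` (prosodically neutralized speech: constant
#' intensity, flattened pitch) or `W24`: a sinusoidal modulation at the
#' half-sentence rate whose intensity and pitch maxima fall on the temporal
#' centers of words 2 and 4 of every sentence.
#'
#' @param kind `"flat"` or `"W24"`.
#' @param intensity_depth_db Peak-to-trough intensity modulation depth in dB
#'   (W24 only). The depth is a free parameter of the design; 6 dB is the
#'   package default.
#' @param pitch_depth_semitones Peak-to-trough pitch excursion in semitones.
#'   Pitch is carried as metadata only; the analysis path uses intensity.
#' @param constants A [design_constants()] object supplying the modulation
#'   rate and word timing.
#'
#' @return An object of class `prosody_contour`.
#' @export
prosody_contour <- function(kind = c("flat", "W24"),
                            intensity_depth_db = 6,
                            pitch_depth_semitones = 4,
                            constants = design_constants()) {
  kind <- match.arg(kind)
  if (kind == "flat") {
    intensity_depth_db <- 0
    pitch_depth_semitones <- 0
  }
  if (intensity_depth_db < 0) stop("intensity_depth_db must be >= 0")
  r <- 10^(intensity_depth_db / 20)
  contour <- list(
    kind = kind,
    modulation_rate = if (kind == "W24") constants$half_sentence_rate else 0,
    intensity_depth_db = intensity_depth_db,
    # modulation index m of (1 + m cos): (1+m)/(1-m) = peak/trough ratio
    modulation_index = (r - 1) / (r + 1),
    pitch_depth_semitones = pitch_depth_semitones,
    # maxima at word-2 and word-4 midpoints within each sentence
    phase_anchor_s = 1.5 * constants$word_duration
  )
  class(contour) <- "prosody_contour"
  contour
}

.SYNTAX_LEVELS <- c("S22", "S13")
.PROSODY_LEVELS <- c("ImplP", "OvP", "InstrP")

#' Build a stimulus design for one condition cell
#'
#' Assembles the full description of a trial sequence for one cell of the
#' syntax-by-prosody crossing. Only the overt-prosody condition (`OvP`)
#' carries an acoustic W24 contour: implicit (`ImplP`) and instructed
#' (`InstrP`) stimuli are acoustically identical flat-prosody speech.
#'
#' @param syntax `"S22"` (2 + 2 phrase structure) or `"S13"` (1 + 3).
#' @param prosody `"ImplP"`, `"OvP"` or `"InstrP"`.
#' @param n_trials Total number of trials (clean + outlier).
#' @param outlier_fraction Fraction of trials carrying one semantically
#'   implausible sentence (behavioral targets, excluded from EEG analysis).
#' @param seed Integer seed; outlier positions and per-trial word-level
#'   amplitude jitter are reproducible from it.
#' @param constants A [design_constants()] object.
#' @param contour Optional [prosody_contour()] override; by default chosen
#'   from `prosody` (W24 for OvP, flat otherwise).
#' @param word_gain_jitter_sd Standard deviation of the multiplicative
#'   per-word intensity jitter (natural words differ in loudness; this puts
#'   a broadband floor under the envelope spectrum). Set 0 for an exactly
#'   periodic envelope.
#'
#' @return An object of class `stimulus_design`.
#' @examples
#' d <- build_design("S22", "OvP", n_trials = 30, outlier_fraction = 8 / 30, seed = 1)
#' d$constants$trial_duration
#' @export
build_design <- function(syntax, prosody, n_trials = 30L,
                         outlier_fraction = 8 / 30, seed = 1L,
                         constants = design_constants(),
                         contour = NULL,
                         word_gain_jitter_sd = 0.05) {
  if (!is.character(syntax) || length(syntax) != 1 || !(syntax %in% .SYNTAX_LEVELS))
    stop("unknown syntax label: must be one of ", paste(.SYNTAX_LEVELS, collapse = ", "))
  if (!is.character(prosody) || length(prosody) != 1 || !(prosody %in% .PROSODY_LEVELS))
    stop("unknown prosody label: must be one of ", paste(.PROSODY_LEVELS, collapse = ", "))
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1) stop("n_trials must be >= 1")
  if (outlier_fraction < 0 || outlier_fraction > 1)
    stop("outlier_fraction must lie in [0, 1]")
  if (is.null(contour)) {
    contour <- prosody_contour(if (prosody == "OvP") "W24" else "flat",
                               constants = constants)
  }
  if (prosody %in% c("ImplP", "InstrP") && contour$kind != "flat")
    stop("ImplP/InstrP stimuli are acoustically flat; contour must be 'flat'")

  n_outlier <- round(outlier_fraction * n_trials)
  flags <- rep(FALSE, n_trials)
  if (n_outlier > 0) {
    idx <- with_seed(child_seed(seed, "design", syntax, prosody),
                     sample.int(n_trials, n_outlier))
    flags[idx] <- TRUE
  }

  design <- list(
    constants = constants,
    syntax = syntax,
    prosody = prosody,
    contour = contour,
    n_trials = n_trials,
    trial_outlier_flags = flags,
    word_gain_jitter_sd = word_gain_jitter_sd,
    seed = as.integer(seed)
  )
  class(design) <- "stimulus_design"
  design
}

#' @export
print.stimulus_design <- function(x, ...) {
  cat(sprintf("Stimulus design: %s / %s, %d trials (%d outlier), contour %s\n",
              x$syntax, x$prosody, x$n_trials, sum(x$trial_outlier_flags),
              x$contour$kind))
  invisible(x)
}
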