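#' Default effect table for the synthetic cohort
#'
#' One row per (syntax, prosody, component): the amplitude (arbitrary
#' units, treated as microvolts) and scalp topography of each evoked
#' sinusoidal component the simulator injects. The default amplitudes
#' encode the qualitative group findings the generator is meant to
#' emulate:
#'
#' * half-sentence amplitude: OvP/S22 > InstrP/S22 > ImplP/S22 (alignment
#'   of overt or imagined prosody with 2 + 2 phrasing boosts the phrase-
#'   rate response);
#' * half-sentence amplitude: ImplP/S13 > ImplP/S22 (a covert prosodic
#'   boundary mid-sentence drives a phrase-rate response that no acoustic
#'   or isochronous-syntactic cue explains);
#' * sentence amplitude: OvP/S13 and InstrP/S13 < ImplP/S13 (misaligned
#'   prosody suppresses the sentence-rate response), with the instructed
#'   effect the same sign as, and no larger than, the overt one;
#' * topography: sentence-rate responses centro-posterior everywhere;
#'   half-sentence responses posterior for 2 + 2 phrasing but broadly
#'   frontal for 1 + 3.
#'
#' Absolute values are free parameters (the empirical spectra are in
#' scaled arbitrary units); only orderings and ratios are meaningful.
#' An optional third harmonic of the sentence rate (3/1.28 Hz) is included
#' with amplitude 0; set `harmonic3_amplitude` to activate it.
#'
#' @param constants [design_constants()] supplying the component rates.
#' @param harmonic3_amplitude Amplitude of the sentence-rate third
#'   harmonic (2.34375 Hz), default 0 (off).
#' @return A data.frame of class `effect_table` with columns `syntax`,
#'   `prosody`, `component`, `freq`, `amplitude`, `topography`,
#'   `fixed_phase`.
#' @export
default_effect_table <- function(constants = design_constants(),
                                 harmonic3_amplitude = 0) {
  amp <- rbind(
    # sentence, half_sentence, word
    ImplP_S22  = c(0.80, 0.50, 1.0),
    OvP_S22    = c(1.00, 1.10, 1.0),
    InstrP_S22 = c(0.90, 0.75, 1.0),
    ImplP_S13  = c(0.80, 0.70, 1.0),
    OvP_S13    = c(0.45, 0.45, 1.0),
    InstrP_S13 = c(0.50, 0.45, 1.0)
  )
  cells <- do.call(rbind, strsplit(rownames(amp), "_"))
  comp_freq <- c(sentence = constants$sentence_rate,
                 half_sentence = constants$half_sentence_rate,
                 word = constants$word_rate,
                 harmonic3 = 3 * constants$sentence_rate)
  rows <- list()
  for (i in seq_len(nrow(amp))) {
    syntax <- cells[i, 2]; prosody <- cells[i, 1]
    half_topo <- if (syntax == "S22") "posterior" else "frontal_broad"
    rows[[i]] <- data.frame(
      syntax = syntax, prosody = prosody,
      component = c("sentence", "half_sentence", "word", "harmonic3"),
      freq = unname(comp_freq),
      amplitude = c(amp[i, ], harmonic3_amplitude),
      topography = c("centro_posterior", half_topo, "centro_posterior",
                     "centro_posterior"),
      fixed_phase = TRUE,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("effect_table", "data.frame")
  validate_effect_table(out)
  out
}

#' Validate an effect table
#'
#' Checks amplitudes are nonnegative, topography labels are known, and
#' every (syntax, prosody) cell of the full crossing is present.
#'
#' @param effects An `effect_table` data.frame.
#' @return The table, invisibly; errors on violation.
#' @export
validate_effect_table <- function(effects) {
  need <- c("syntax", "prosody", "component", "freq", "amplitude",
            "topography", "fixed_phase")
  if (!all(need %in% names(effects)))
    stop("effect table must have columns: ", paste(need, collapse = ", "))
  if (any(effects$amplitude < 0)) stop("effect amplitudes must be >= 0")
  bad <- setdiff(unique(effects$topography), .TOPOGRAPHY_LABELS)
  if (length(bad))
    stop("unknown topography label(s): ", paste(bad, collapse = ", "))
  cells <- unique(paste(effects$syntax, effects$prosody))
  want <- as.vector(outer(.SYNTAX_LEVELS, .PROSODY_LEVELS, paste))
  if (!all(want %in% cells))
    stop("effect table missing condition cell(s): ",
         paste(setdiff(want, cells), collapse = ", "))
  invisible(effects)
}
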