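#' Configuration of an end-to-end synthetic-cohort run
#'
#' Defines the cohort (26 participants by default), the condition cells
#' (full syntax x prosody crossing), the effect table, noise and artifact
#' parameters, preprocessing settings, and the master seed from which all
#' per-participant, per-condition child seeds are derived.
#'
#' The EEG stream simulates the analysis trials (the outlier-free
#' trials; 22 per condition by default): trials containing a semantic
#' outlier never enter the spectral analysis, so they are simulated only
#' in the behavioral stream (30 trials, 8 with an outlier). Participants
#' vary by lognormal gains on the component amplitudes; the half-sentence
#' gain is drawn independently for the two syntax types (the two
#' phrase-rate responses are modeled as distinct processes), while the
#' sentence and word gains are shared across conditions.
#'
#' @param n_participants Cohort size.
#' @param master_seed Master integer seed.
#' @param effects Effect table ([default_effect_table()]).
#' @param preprocess [preprocess_config()] overrides.
#' @param noise_alpha,noise_scale Background-noise exponent and SD (uV).
#' @param artifact_rate Fraction of EEG trials receiving an artifact.
#' @param n_trials_eeg Analysis trials per condition run.
#' @param n_trials_behavior Behavioral trials per condition.
#' @param outlier_fraction_behavior Outlier fraction in the behavioral
#'   stream.
#' @param participant_gain_sd SD of the lognormal participant gains.
#' @param p_hit,p_fa Behavioral hit / false-alarm probabilities.
#' @param n_boot Bootstrap resamples for the group tests.
#' @param targets Target frequencies tested at group level, Hz.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_participants = 26L, master_seed = 1L,
                       effects = default_effect_table(),
                       preprocess = preprocess_config(),
                       noise_alpha = 1, noise_scale = 5,
                       artifact_rate = 0,
                       n_trials_eeg = 22L, n_trials_behavior = 30L,
                       outlier_fraction_behavior = 8 / 30,
                       participant_gain_sd = 0.25,
                       p_hit = 0.722, p_fa = 0.278,
                       n_boot = 2000L,
                       targets = c(0.78125, 1.5625)) {
  stopifnot(n_participants >= 1)
  validate_effect_table(effects)
  cfg <- as.list(environment())
  cfg$cells <- expand.grid(syntax = .SYNTAX_LEVELS, prosody = .PROSODY_LEVELS,
                           stringsAsFactors = FALSE)
  class(cfg) <- "run_config"
  cfg
}

# lognormal participant gains; half-sentence gain independent per syntax
participant_gains <- function(config, p) {
  sd <- config$participant_gain_sd
  g <- with_seed(child_seed(config$master_seed, "gains", p),
                 exp(stats::rnorm(5, 0, sd)))
  list(
    S22 = c(sentence = g[1], half_sentence = g[2], word = g[3], harmonic3 = g[1]),
    S13 = c(sentence = g[1], half_sentence = g[4], word = g[3], harmonic3 = g[1]),
    attention = g[5]
  )
}

# simulate + preprocess + epoch + reject one run of one condition cell
simulate_and_epoch <- function(config, p, syntax, prosody, run) {
  seed_d <- child_seed(config$master_seed, "design", p, syntax, prosody, run)
  seed_r <- child_seed(config$master_seed, "eeg", p, syntax, prosody, run)
  design <- build_design(syntax, prosody, n_trials = config$n_trials_eeg,
                         outlier_fraction = 0, seed = seed_d)
  gains <- participant_gains(config, p)[[syntax]]
  rec <- simulate_recording(design, config$effects,
                            noise_alpha = config$noise_alpha,
                            noise_scale = config$noise_scale,
                            artifact_rate = config$artifact_rate,
                            seed = seed_r,
                            component_gains = gains)
  rec$meta$participant_id <- p
  rec <- preprocess_continuous(rec, config$preprocess)
  es <- extract_epochs(rec, config$preprocess)
  reject_epochs(es, config$preprocess, "final")
}

#' Run the full synthetic-cohort pipeline
#'
#' For every participant and condition cell: simulate the recording
#' (implicit prosody twice — an early and a late run whose epochs are
#' pooled before averaging, mirroring the averaging of the two
#' implicit-prosody recordings), preprocess, epoch, reject, compute the
#' evoked SNR spectrum and channel-level peak measures. At group level:
#' BCa bootstrap tests of the peak-minus-noise measure D per cell and
#' target frequency with Bonferroni correction over the whole family,
#' ROI topography tables, cross-condition peak correlations, and
#' behavioral d-prime per participant.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return An object of class `run_report` (see Details in the package
#'   vignette): per-condition group SNR spectra, channel-level and
#'   participant-level peak tables, bootstrap tests, ROI maps,
#'   correlation table, behavioral summary, and a provenance block.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  layout <- default_roi_layout()
  scalp <- layout$channel
  cells <- config$cells
  say <- function(...) if (!quiet) message(sprintf(...))

  peak_rows <- list()
  spec_sum <- list() # per cell: running sum of participant SNR spectra
  freqs <- NULL
  behavior_rows <- list()
  stage_log <- list()

  for (p in seq_len(config$n_participants)) {
    say("participant %d/%d", p, config$n_participants)
    for (ci in seq_len(nrow(cells))) {
      syntax <- cells$syntax[ci]; prosody <- cells$prosody[ci]
      runs <- if (prosody == "ImplP") 1:2 else 1L
      esets <- lapply(runs, function(r)
        simulate_and_epoch(config, p, syntax, prosody, r))
      es <- do.call(epochs_bind, esets)
      spec <- snr_normalize(evoked_power(es))
      freqs <- spec$freqs
      pk <- peak_measures(spec, c(config$targets, 3.125), layout = layout)
      pk <- pk[pk$channel %in% scalp, ]
      pk$participant <- p; pk$syntax <- syntax; pk$prosody <- prosody
      peak_rows[[length(peak_rows) + 1L]] <- pk

      key <- paste(syntax, prosody, sep = "_")
      chan_mean_snr <- colMeans(spec$snr[scalp, , drop = FALSE])
      spec_sum[[key]] <- (spec_sum[[key]] %||% 0) + chan_mean_snr
      stage_log[[length(stage_log) + 1L]] <- data.frame(
        participant = p, syntax = syntax, prosody = prosody,
        n_epochs = dim(es$data)[1], n_rejected = nrow(es$rejection_log))

      beh_design <- build_design(syntax, prosody,
                                 n_trials = config$n_trials_behavior,
                                 outlier_fraction = config$outlier_fraction_behavior,
                                 seed = child_seed(config$master_seed, "behdesign",
                                                   p, syntax, prosody))
      behavior_rows[[length(behavior_rows) + 1L]] <- cbind(
        participant = p,
        simulate_behavior(beh_design, config$p_hit, config$p_fa,
                          seed = child_seed(config$master_seed, "beh",
                                            p, syntax, prosody)))
    }
  }

  peaks <- do.call(rbind, peak_rows)
  behavior <- do.call(rbind, behavior_rows)

  # participant-level D (mean over scalp channels)
  part <- stats::aggregate(cbind(d, snr) ~ participant + syntax + prosody + target_freq,
                           data = peaks, FUN = mean)

  say("group statistics")
  tests <- list()
  for (ci in seq_len(nrow(cells))) for (f in config$targets) {
    syntax <- cells$syntax[ci]; prosody <- cells$prosody[ci]
    vals <- part$d[part$syntax == syntax & part$prosody == prosody &
                     part$target_freq == f]
    bt <- bca_bootstrap_test(vals, n_boot = config$n_boot,
                             seed = child_seed(config$master_seed, "boot",
                                               syntax, prosody, round(f * 64)))
    tests[[paste(syntax, prosody, f, sep = "_")]] <- bt
  }
  p_raw <- vapply(tests, function(t) t$p_value, numeric(1))
  p_adj <- bonferroni_adjust(p_raw, family = length(p_raw))
  test_table <- data.frame(
    test = names(tests),
    syntax = rep(cells$syntax, each = length(config$targets)),
    prosody = rep(cells$prosody, each = length(config$targets)),
    target_freq = rep(config$targets, times = nrow(cells)),
    mean_d = vapply(tests, function(t) t$observed_stat, numeric(1)),
    ci_low = vapply(tests, function(t) t$ci_low, numeric(1)),
    ci_high = vapply(tests, function(t) t$ci_high, numeric(1)),
    p = p_raw, p_bonferroni = p_adj, row.names = NULL)

  # ROI topography per cell x target (mean over participants)
  roi <- stats::aggregate(cbind(d, snr) ~ syntax + prosody + target_freq +
                            anteriority + laterality,
                          data = peaks, FUN = mean)

  # cross-condition correlations of participant-level measures
  pick <- function(syntax, prosody, f) {
    v <- part[part$syntax == syntax & part$prosody == prosody &
                part$target_freq == f, ]
    v$d[order(v$participant)]
  }
  half <- 1.5625; sent <- 0.78125
  corr_specs <- list(
    half_S22_vs_S13_ImplP = list(pick("S22", "ImplP", half), pick("S13", "ImplP", half)),
    sent_S22_vs_S13_ImplP = list(pick("S22", "ImplP", sent), pick("S13", "ImplP", sent)),
    half_S22_OvP_vs_InstrP_effect = list(
      pick("S22", "OvP", half) - pick("S22", "ImplP", half),
      pick("S22", "InstrP", half) - pick("S22", "ImplP", half)),
    sent_S13_OvP_vs_InstrP_effect = list(
      pick("S13", "OvP", sent) - pick("S13", "ImplP", sent),
      pick("S13", "InstrP", sent) - pick("S13", "ImplP", sent))
  )
  correlations <- do.call(rbind, lapply(names(corr_specs), function(nm) {
    cr <- peak_correlation(corr_specs[[nm]][[1]], corr_specs[[nm]][[2]])
    data.frame(pair = nm, r = cr$r, r_squared = cr$r_squared, p = cr$p)
  }))

  # behavioral d-prime per participant (pooled over conditions)
  dp <- do.call(rbind, lapply(seq_len(config$n_participants), function(p) {
    cnt <- behavior_counts(behavior[behavior$participant == p, ])
    d <- dprime(cnt["n_hit"], cnt["n_miss"], cnt["n_fa"], cnt["n_cr"])
    acc <- (cnt["n_hit"] + cnt["n_cr"]) / sum(cnt)
    data.frame(participant = p, dprime = d$dprime, accuracy = as.numeric(acc),
               t(cnt))
  }))

  group_snr <- do.call(rbind, lapply(names(spec_sum), function(k)
    spec_sum[[k]] / config$n_participants))
  rownames(group_snr) <- names(spec_sum)

  report <- list(
    group_snr = group_snr, freqs = freqs,
    peaks = peaks, participant_peaks = part,
    tests = tests, test_table = test_table,
    roi = roi, correlations = correlations,
    behavior = behavior, dprime = dp,
    stage_log = do.call(rbind, stage_log),
    provenance = list(master_seed = config$master_seed,
                      n_participants = config$n_participants,
                      n_trials_eeg = config$n_trials_eeg,
                      noise_alpha = config$noise_alpha,
                      noise_scale = config$noise_scale,
                      n_boot = config$n_boot,
                      package_version = as.character(utils::packageVersion("prosotag")))
  )
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d participants, %d group tests\n",
              x$provenance$n_participants, nrow(x$test_table)))
  print(x$test_table[, c("syntax", "prosody", "target_freq", "mean_d",
                         "p_bonferroni")], digits = 3)
  invisible(x)
}

#' Write report artifacts
#'
#' CSV tables (`spectra.csv`, `peaks.csv`, `roi.csv`, `behavior.csv`,
#' `correlations.csv`) plus a JSON summary (`tests.json`) of the test
#' objects and provenance. Re-writing the same report yields identical
#' files.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  if (is.null(report$test_table) || nrow(report$test_table) == 0)
    stop("empty report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wcsv <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  spectra <- data.frame(
    condition = rep(rownames(report$group_snr), times = ncol(report$group_snr)),
    freq_hz = rep(report$freqs, each = nrow(report$group_snr)),
    snr = as.vector(report$group_snr))
  wcsv(spectra, "spectra.csv")
  wcsv(report$peaks, "peaks.csv")
  wcsv(report$roi, "roi.csv")
  wcsv(report$behavior, "behavior.csv")
  wcsv(report$correlations, "correlations.csv")
  tests_json <- list(
    tests = lapply(report$tests, unclass),
    test_table = report$test_table,
    provenance = report$provenance)
  f <- file.path(dir, "tests.json")
  jsonlite::write_json(tests_json, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}
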