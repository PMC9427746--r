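#' Preprocessing configuration
#'
#' All continuous-data conditioning parameters. Defaults follow the
#' canonical pipeline: resample to 250 Hz, then zero-phase FIR filtering
#' with Kaiser windows (low-pass 20 Hz cut-off, order 152; high-pass
#' 0.2 Hz, order 2266; beta = 5.65326; orders interpreted at the 250-Hz
#' rate), linked-mastoid re-reference, 14.08-s epochs starting one
#' sentence (1.28 s) after trial onset, and the three dummy-epoch
#' rejection rules used to prepare ICA plus the final 40-dB spectral
#' rule in the 0-4 Hz band.
#'
#' @param resample_rate Target rate, Hz.
#' @param lowpass_cutoff,lowpass_order Low-pass -6 dB cut-off (Hz) and FIR
#'   order (taps = order + 1).
#' @param highpass_cutoff,highpass_order High-pass cut-off and order.
#' @param kaiser_beta Kaiser window shape parameter.
#' @param ica_copy_highpass,ica_copy_order High-pass used for the
#'   ICA-decomposition copy of the data.
#' @param reject_abs Absolute amplitude threshold, microvolts.
#' @param reject_chan_sd Per-electrode deviation threshold, SD units.
#' @param reject_global_sd All-electrode deviation threshold, SD units.
#' @param reject_spectral_db Spectral rejection threshold, dB.
#' @param reject_spectral_band Band (Hz) for the spectral rule.
#' @param epoch_length Epoch length, s (11 sentences = 14.08 s).
#' @param epoch_offset Epoch start relative to trial onset, s (one
#'   sentence, so the first sentence's onset transient is skipped).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(resample_rate = 250,
                              lowpass_cutoff = 20, lowpass_order = 152,
                              highpass_cutoff = 0.2, highpass_order = 2266,
                              kaiser_beta = 5.65326,
                              ica_copy_highpass = 1.0, ica_copy_order = 454,
                              reject_abs = 400,
                              reject_chan_sd = 2, reject_global_sd = 6,
                              reject_spectral_db = 40,
                              reject_spectral_band = c(0, 4),
                              epoch_length = 14.08, epoch_offset = 1.28) {
  cfg <- as.list(environment())
  stopifnot(lowpass_order %% 2 == 0, highpass_order %% 2 == 0,
            ica_copy_order %% 2 == 0)
  class(cfg) <- "preprocess_config"
  cfg
}

#' Design a windowed-sinc FIR filter with a Kaiser window
#'
#' Linear-phase type-I FIR (even order, odd tap count). The cut-off is
#' the -6 dB point. High-pass filters are obtained by spectral inversion
#' of the complementary low-pass.
#'
#' @param order Filter order (even); the filter has `order + 1` taps.
#' @param cutoff -6 dB cut-off frequency, Hz.
#' @param srate Sampling rate the filter operates at, Hz.
#' @param type `"low"` or `"high"`.
#' @param beta Kaiser window beta.
#' @return Numeric vector of `order + 1` coefficients.
#' @export
fir_kaiser <- function(order, cutoff, srate, type = c("low", "high"),
                       beta = 5.65326) {
  type <- match.arg(type)
  if (order %% 2 != 0) stop("order must be even (type-I linear phase)")
  if (cutoff <= 0 || cutoff >= srate / 2)
    stop("cutoff must lie in (0, srate/2)")
  M <- order
  n <- 0:M
  x <- n - M / 2
  fc <- cutoff / srate # normalized (cycles/sample)
  h <- ifelse(x == 0, 2 * fc, sin(2 * pi * fc * x) / (pi * x))
  arg <- 1 - (2 * n / M - 1)^2
  arg[arg < 0] <- 0
  w <- besselI(beta * sqrt(arg), 0) / besselI(beta, 0)
  h <- h * w
  h <- h / sum(h) # exact unity DC gain
  if (type == "high") {
    h <- -h
    h[M / 2 + 1] <- h[M / 2 + 1] + 1
  }
  h
}

#' Real amplitude response of a linear-phase FIR filter
#'
#' Evaluates `sum h[n] cos(2 pi f (n - M/2) / srate)` — the zero-phase
#' (delay-compensated) gain, which can be negative in the stopband.
#'
#' @param h FIR coefficients (odd count, symmetric).
#' @param freqs Frequencies, Hz.
#' @param srate Sampling rate, Hz.
#' @return Numeric vector of gains.
#' @export
fir_response <- function(h, freqs, srate) {
  M <- length(h) - 1
  vapply(freqs, function(f) {
    sum(h * cos(2 * pi * f / srate * ((0:M) - M / 2)))
  }, numeric(1))
}

# next integer >= n whose prime factors are all in {2, 3, 5}
next_5smooth <- function(n) {
  n <- as.integer(ceiling(n))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# Zero-phase application of a symmetric FIR + integer-factor decimation,
# fused in the frequency domain. x: samples x channels; h is defined at
# the OUTPUT rate. Linear (not circular) convolution is guaranteed by
# padding to a 5-smooth length with room for the kernel span.
fir_resample_apply <- function(x, decim, h) {
  N <- nrow(x); C <- ncol(x)
  taps <- length(h); M <- taps - 1L
  L <- next_5smooth(N + (taps + 2) * decim)
  while (L %% decim != 0L) L <- next_5smooth(L + 1L)
  Lo <- L %/% decim
  n_out <- N %/% decim

  # zero-phase real response on the output grid (shift theorem removes
  # the linear phase of the symmetric kernel)
  Hf <- stats::fft(c(h, rep(0, Lo - taps)))
  A <- Re(Hf * exp(2i * pi * (0:(Lo - 1)) * (M / 2) / Lo))

  half <- Lo %/% 2
  pos <- seq_len(half)                 # 0-based bins 0..half-1
  neg_out <- (Lo - half + 2):Lo        # 0-based bins half+1..Lo-1
  neg_in <- (L - half + 2):L

  out <- matrix(0, n_out, C)
  for (p in seq_len(ceiling(C / 2))) {
    c1 <- 2L * p - 1L; c2 <- min(2L * p, C)
    z <- complex(real = c(x[, c1], rep(0, L - N)),
                 imaginary = c(x[, c2], rep(0, L - N)))
    Z <- stats::fft(z)
    Y <- complex(length.out = Lo)
    Y[pos] <- Z[pos] * A[pos]
    Y[neg_out] <- Z[neg_in] * A[neg_out]
    y <- stats::fft(Y, inverse = TRUE) / L
    out[, c1] <- Re(y)[seq_len(n_out)]
    if (c2 > c1) out[, c2] <- Im(y)[seq_len(n_out)]
  }
  out
}

#' Condition a continuous recording
#'
#' Re-references to linked mastoids (mean of `M1` and `M2` subtracted
#' from every channel), resamples to the target rate, and applies the
#' low- and high-pass Kaiser FIR filters in a zero-phase manner
#' (delay-compensated single pass; the two symmetric kernels are combined
#' by convolution and applied in the frequency domain fused with the
#' rate conversion). Events are re-indexed to the new rate.
#'
#' @param rec An [eeg_recording()].
#' @param cfg A [preprocess_config()].
#' @return A filtered, resampled [eeg_recording()].
#' @export
preprocess_continuous <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(cfg, "preprocess_config"))
  if (rec$srate < 2 * cfg$lowpass_cutoff)
    stop("input rate too low for the requested low-pass cutoff")
  m1 <- match("M1", rec$channel_labels)
  m2 <- match("M2", rec$channel_labels)
  if (is.na(m1) || is.na(m2))
    stop("missing mastoid channel (M1/M2) required for re-referencing")
  if (rec$srate %% cfg$resample_rate != 0)
    stop("srate must be an integer multiple of resample_rate")
  decim <- rec$srate %/% cfg$resample_rate

  data <- rec$data - 0.5 * (rec$data[, m1] + rec$data[, m2])

  h_lp <- fir_kaiser(cfg$lowpass_order, cfg$lowpass_cutoff,
                     cfg$resample_rate, "low", cfg$kaiser_beta)
  h_hp <- fir_kaiser(cfg$highpass_order, cfg$highpass_cutoff,
                     cfg$resample_rate, "high", cfg$kaiser_beta)
  h <- stats::convolve(h_lp, rev(h_hp), type = "open")

  out <- fir_resample_apply(data, decim, h)

  ev <- rec$events
  if (nrow(ev) > 0) ev$sample <- (ev$sample - 1L) %/% decim + 1L
  meta <- rec$meta
  meta$preprocessed <- TRUE
  eeg_recording(out, cfg$resample_rate, rec$channel_labels, ev, meta)
}

#' High-pass filtered copy for ICA decomposition
#'
#' Returns the recording filtered with the strong (1 Hz) high-pass used
#' only to compute an ICA decomposition; the unmixing itself is delegated
#' to external tools. The copy is neither resampled nor re-referenced
#' beyond what `rec` already carries.
#'
#' @param rec An [eeg_recording()] (typically already preprocessed).
#' @param cfg A [preprocess_config()].
#' @return An [eeg_recording()].
#' @export
make_ica_copy <- function(rec, cfg = preprocess_config()) {
  h <- fir_kaiser(cfg$ica_copy_order, cfg$ica_copy_highpass, rec$srate,
                  "high", cfg$kaiser_beta)
  out <- fir_resample_apply(rec$data, 1L, h)
  meta <- rec$meta
  meta$ica_copy <- TRUE
  eeg_recording(out, rec$srate, rec$channel_labels, rec$events, meta)
}

#' Epoch container
#'
#' @param data Numeric array, epochs x channels x samples, microvolts.
#' @param srate Sampling rate, Hz.
#' @param channel_labels Channel names.
#' @param condition Named list or string describing the condition cell.
#' @param participant_id Participant identifier.
#' @param trials Original trial indices of the epochs.
#' @param rejection_log data.frame `(epoch_index, rule)` accumulated by
#'   [reject_epochs()].
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, srate, channel_labels, condition = NULL,
                      participant_id = NA, trials = NULL,
                      rejection_log = NULL) {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == length(channel_labels))
  if (is.null(trials)) trials <- seq_len(dim(data)[1])
  if (is.null(rejection_log))
    rejection_log <- data.frame(epoch_index = integer(0), rule = character(0))
  structure(list(data = data, srate = srate,
                 channel_labels = channel_labels, condition = condition,
                 participant_id = participant_id, trials = trials,
                 rejection_log = rejection_log),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoch_set: %d epochs x %d channels x %d samples @ %g Hz (%d rejected)\n",
              d[1], d[2], d[3], x$srate, nrow(x$rejection_log)))
  invisible(x)
}

#' Extract fixed-length epochs time-locked to trial onsets
#'
#' One epoch per trial event, starting `epoch_offset` seconds (one
#' sentence) after the onset so the trial-initial transient is excluded,
#' lasting `epoch_length` seconds (3520 samples at 250 Hz). Each epoch is
#' demeaned per channel. Events without a full epoch of signal are
#' skipped with a warning.
#'
#' @param rec A preprocessed [eeg_recording()].
#' @param cfg A [preprocess_config()].
#' @param exclude_outlier_trials Drop trials flagged as containing a
#'   semantic outlier (these never enter the spectral analysis).
#' @return An [epoch_set()].
#' @export
extract_epochs <- function(rec, cfg = preprocess_config(),
                           exclude_outlier_trials = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  ev <- rec$events
  if (exclude_outlier_trials && nrow(ev) > 0) ev <- ev[!ev$is_outlier, ]
  if (nrow(ev) == 0) stop("no trial events to epoch")
  offs <- .n_samples(cfg$epoch_offset, rec$srate)
  len <- .n_samples(cfg$epoch_length, rec$srate)
  n_ch <- ncol(rec$data)
  starts <- ev$sample + offs
  ok <- starts + len - 1L <= nrow(rec$data)
  if (any(!ok))
    warning(sum(!ok), " truncated trial(s) skipped during epoching")
  starts <- starts[ok]
  trials <- ev$trial[ok]
  if (length(starts) == 0) stop("no complete epochs available")
  # gather all epochs in one indexing pass: big is (len * nE) x channels
  nE <- length(starts)
  rows <- as.vector(vapply(starts, function(s) s:(s + len - 1L),
                           integer(len)))
  big <- array(rec$data[rows, , drop = FALSE], c(len, nE, n_ch))
  means <- colMeans(big) # nE x channels epoch/channel means
  big <- big - rep(means, each = len)
  arr <- aperm(big, c(2, 3, 1))
  epoch_set(arr, rec$srate, rec$channel_labels,
            condition = list(syntax = rec$meta$syntax,
                             prosody = rec$meta$prosody),
            participant_id = rec$meta$participant_id %||% NA,
            trials = trials)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reject artifact epochs
#'
#' Two rule sets:
#' * `"final"` — the spectral rule applied before spectral analysis: an
#'   epoch is removed when, at any channel and any frequency bin inside
#'   `reject_spectral_band`, its power exceeds the mean power of the
#'   remaining epochs at that channel/bin by more than
#'   `reject_spectral_db` dB.
#' * `"ica_dummy"` — the three amplitude rules used on dummy epochs
#'   before ICA: (1) any sample beyond `reject_abs` microvolts; (2) any
#'   sample deviating from its electrode's mean by more than
#'   `reject_chan_sd` standard deviations of that electrode's pooled
#'   signal; (3) any sample deviating from the pooled all-electrode mean
#'   by more than `reject_global_sd` pooled standard deviations.
#'
#' Rules fired per epoch are appended to the rejection log.
#'
#' @param epochs An [epoch_set()].
#' @param cfg A [preprocess_config()].
#' @param rule_set `"final"` or `"ica_dummy"`.
#' @return The [epoch_set()] with offending epochs removed.
#' @export
reject_epochs <- function(epochs, cfg = preprocess_config(),
                          rule_set = c("final", "ica_dummy")) {
  stopifnot(inherits(epochs, "epoch_set"))
  rule_set <- match.arg(rule_set)
  d <- dim(epochs$data)
  if (d[1] == 0) stop("epoch set is empty")
  log_add <- data.frame(epoch_index = integer(0), rule = character(0))

  if (rule_set == "ica_dummy") {
    bad_abs <- bad_chan <- bad_glob <- logical(d[1])
    ch_mean <- ch_sd <- numeric(d[2])
    for (c in seq_len(d[2])) {
      v <- as.vector(epochs$data[, c, ])
      ch_mean[c] <- mean(v); ch_sd[c] <- stats::sd(v)
    }
    g_mean <- mean(epochs$data); g_sd <- stats::sd(as.vector(epochs$data))
    for (e in seq_len(d[1])) {
      seg <- matrix(epochs$data[e, , ], d[2], d[3])
      bad_abs[e] <- any(abs(seg) > cfg$reject_abs)
      dev <- abs(seg - ch_mean)
      bad_chan[e] <- any(dev > cfg$reject_chan_sd * ch_sd)
      bad_glob[e] <- any(abs(seg - g_mean) > cfg$reject_global_sd * g_sd)
    }
    for (rule in list(c("abs_400uV", "bad_abs"), c("chan_2sd", "bad_chan"),
                      c("global_6sd", "bad_glob"))) {
      hits <- which(get(rule[2]))
      if (length(hits))
        log_add <- rbind(log_add,
                         data.frame(epoch_index = epochs$trials[hits],
                                    rule = rule[1]))
    }
    drop <- bad_abs | bad_chan | bad_glob
  } else {
    nfft <- d[3]
    df <- epochs$srate / nfft
    band <- which((seq_len(nfft) - 1) * df >= cfg$reject_spectral_band[1] &
                    (seq_len(nfft) - 1) * df <= cfg$reject_spectral_band[2])
    pw <- array(0, c(d[1], d[2], length(band)))
    for (e in seq_len(d[1])) {
      X <- stats::mvfft(t(matrix(epochs$data[e, , ], d[2], d[3])))
      pw[e, , ] <- t(Mod(X[band, , drop = FALSE])^2)
    }
    # reference = mean power of the REMAINING epochs (leave-one-out);
    # an include-self mean could never exceed the threshold once one
    # epoch dominates it
    thr <- 10^(cfg$reject_spectral_db / 10)
    if (d[1] == 1) {
      drop <- FALSE
    } else {
      total <- colSums(pw)
      drop <- vapply(seq_len(d[1]), function(e) {
        ref <- (total - pw[e, , ]) / (d[1] - 1)
        any(pw[e, , ] > thr * ref)
      }, logical(1))
    }
    if (any(drop))
      log_add <- rbind(log_add,
                       data.frame(epoch_index = epochs$trials[which(drop)],
                                  rule = "spectral_40dB"))
  }

  if (all(drop)) stop("all epochs rejected by rule set '", rule_set, "'")
  keep <- which(!drop)
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$trials <- epochs$trials[keep]
  epochs$rejection_log <- rbind(epochs$rejection_log, log_add)
  epochs
}

#' Concatenate epoch sets
#'
#' Pools epochs from several sets with identical channels and rates —
#' used to average the two runs of the implicit-prosody condition.
#'
#' @param ... `epoch_set` objects.
#' @return A pooled [epoch_set()].
#' @export
epochs_bind <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1)
  if (length(sets) == 1) return(sets[[1]])
  base <- sets[[1]]
  for (s in sets[-1]) {
    stopifnot(identical(s$channel_labels, base$channel_labels),
              s$srate == base$srate, dim(s$data)[3] == dim(base$data)[3])
  }
  datas <- lapply(sets, function(s) s$data)
  n <- sum(vapply(datas, function(a) dim(a)[1], integer(1)))
  arr <- array(0, c(n, dim(base$data)[2], dim(base$data)[3]))
  i <- 0L
  for (a in datas) {
    k <- dim(a)[1]
    if (k > 0) arr[(i + 1):(i + k), , ] <- a
    i <- i + k
  }
  epoch_set(arr, base$srate, base$channel_labels, base$condition,
            base$participant_id,
            trials = unlist(lapply(sets, function(s) s$trials)),
            rejection_log = do.call(rbind, lapply(sets, function(s) s$rejection_log)))
}
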