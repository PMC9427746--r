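#' Spectrum container
#'
#' Holds power (and, once normalized, SNR) over a shared frequency grid for
#' a set of rows — EEG channels, envelope trials, or participants,
#' depending on the producing stage. Grid spacing is `1 / epoch_length`
#' (0.0710 Hz for the canonical 14.08-s epoch), so the tagged rates
#' 0.78125, 1.5625 and 3.125 Hz fall exactly on bins 11, 22 and 44
#' (0-based).
#'
#' @param power Numeric matrix, rows x frequency bins.
#' @param freqs Frequency grid in Hz, one value per column.
#' @param epoch_length Analysis window length in seconds.
#' @param n_epochs_averaged Number of epochs averaged before the transform.
#' @param snr Optional SNR matrix of the same shape (see [snr_normalize()]).
#' @param amplitude Optional amplitude matrix (envelope path).
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(power, freqs, epoch_length, n_epochs_averaged = 1L,
                         snr = NULL, amplitude = NULL) {
  power <- as.matrix(power)
  stopifnot(length(freqs) == ncol(power))
  if (abs(freqs[2] - freqs[1] - 1 / epoch_length) > 1e-9)
    stop("frequency grid spacing must equal 1 / epoch_length")
  out <- structure(
    list(power = power, freqs = as.numeric(freqs),
         epoch_length = epoch_length,
         n_epochs_averaged = as.integer(n_epochs_averaged),
         snr = snr),
    class = "spectrum_set")
  attr(out, "amplitude") <- amplitude
  out
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("spectrum_set: %d row(s) x %d bins, df = %.4f Hz, %s\n",
              nrow(x$power), ncol(x$power), 1 / x$epoch_length,
              if (is.null(x$snr)) "power only" else "power + SNR"))
  invisible(x)
}

#' Map a target frequency to its 0-based spectral bin
#'
#' The analysis requires every target to lie exactly on the grid: frequency
#' times epoch length must be an integer (tolerance 1e-6). Off-grid
#' requests are rejected with a message naming the nearest bin.
#'
#' @param freq Target frequency, Hz.
#' @param epoch_length Window length, seconds.
#' @return Integer 0-based bin index.
#' @examples
#' target_bin(0.78125, 14.08) # 11
#' target_bin(1.5625, 14.08)  # 22
#' @export
target_bin <- function(freq, epoch_length) {
  k <- freq * epoch_length
  if (abs(k - round(k)) > 1e-6)
    stop(sprintf(
      "target %g Hz is off the %.4g-Hz grid; nearest bin is %d (%.5g Hz)",
      freq, 1 / epoch_length, round(k), round(k) / epoch_length))
  as.integer(round(k))
}

#' Evoked power spectrum of an epoch set
#'
#' Averages the epochs across trials per channel (the ERP) and takes the
#' squared magnitude of its discrete Fourier transform — the evoked power,
#' which retains only activity phase-locked to trial onset. No taper is
#' applied: the tagged frequencies are exact multiples of the 1/14.08-s
#' grid, so the rectangular window is leakage-free there, and tapering
#' would smear the single-bin peaks.
#'
#' Power convention: `power_k = |X_k|^2 / N^2`, so a sinusoid of amplitude
#' `A` with an integer number of cycles contributes `A^2/4` at its bin on
#' the two-sided grid. Only bins up to the Nyquist frequency are kept.
#'
#' @param epochs An `epoch_set` (see [extract_epochs()]).
#' @return A [spectrum_set()], rows = channels.
#' @export
evoked_power <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  dims <- dim(epochs$data)
  if (is.null(dims) || dims[1] < 1) stop("empty epoch set: no surviving epochs")
  n_ep <- dims[1]; n_ch <- dims[2]; n <- dims[3]
  erp <- if (n_ep == 1) {
    matrix(epochs$data[1, , ], n_ch, n)
  } else {
    colMeans(epochs$data) # averages over the epoch dimension
  }
  X <- t(stats::mvfft(t(erp))) / n # channels x bins, full grid
  pw <- Mod(X)^2
  nb <- floor(n / 2) + 1
  pw <- pw[, seq_len(nb), drop = FALSE]
  rownames(pw) <- epochs$channel_labels
  epoch_len <- n / epochs$srate
  spectrum_set(power = pw,
               freqs = (seq_len(nb) - 1) / epoch_len,
               epoch_length = epoch_len,
               n_epochs_averaged = n_ep)
}

#' Neighbor-bin SNR normalization
#'
#' Divides the power at every frequency bin by the mean power at its
#' `2 * n_side` neighbors (`n_side` bins on each side, 0.5 Hz for the
#' default 7 bins of 0.071 Hz), flattening the 1/f noise floor so that a
#' bin carrying only background noise has SNR near 1. Near the DC edge
#' the neighborhood is completed by mirroring (bin `-j` carries the same
#' power as bin `+j` for a real signal); bins within `n_side` of the
#' Nyquist edge have no full neighborhood and are returned as `NA`, as is
#' any bin whose neighbor mean is zero.
#'
#' @param spec A [spectrum_set()].
#' @param n_side Number of neighbor bins on each side (default 7, i.e. 14
#'   neighbors in total).
#' @return The input with its `snr` field filled.
#' @export
snr_normalize <- function(spec, n_side = 7L) {
  stopifnot(inherits(spec, "spectrum_set"))
  n_side <- as.integer(n_side)
  nb <- ncol(spec$power)
  if (nb < 2L * n_side + 1L)
    stop("spectrum has fewer than ", 2 * n_side + 1, " bins")
  pw <- spec$power
  k <- 2L * n_side + 1L
  # Running mean of the (2*n_side+1)-bin window minus the center bin.
  # The spectrum is mirrored at DC (bin -j equals bin +j for real
  # signals), so bins near 0 Hz keep a full neighborhood; bins within
  # n_side of the Nyquist edge remain undefined.
  win <- rep(1, k)
  neigh <- t(apply(pw, 1, function(row) {
    ext <- c(row[(n_side + 1):2], row)
    s <- as.numeric(stats::filter(ext, win, sides = 2))
    (s[(n_side + 1):(n_side + length(row))] - row) / (k - 1)
  }))
  snr <- pw / neigh
  snr[!is.finite(snr)] <- NA_real_
  snr[which(neigh == 0)] <- NA_real_
  spec$snr <- snr
  spec$n_side <- n_side
  spec
}

#' Peak measures at target frequencies
#'
#' For each target frequency and each row (channel), returns the SNR at
#' the target bin and the peak-minus-noise measure
#' `D = SNR(target) - mean(SNR of the 2 * n_side neighbor bins)` — the
#' dependent measure of the analysis. A spectrally flat input gives D = 0.
#'
#' @param spec A [spectrum_set()]; normalized with [snr_normalize()] first
#'   if its `snr` field is empty.
#' @param targets Target frequencies in Hz; each must lie on the bin grid.
#' @param layout Optional ROI layout ([default_roi_layout()]); adds
#'   anteriority/laterality columns for mapped channels.
#' @param n_side Neighborhood half-width (must match the normalization).
#' @return A data.frame with columns `channel`, `target_freq`, `snr`, `d`
#'   (+ `anteriority`, `laterality` when a layout is given).
#' @export
peak_measures <- function(spec, targets, layout = NULL, n_side = 7L) {
  stopifnot(inherits(spec, "spectrum_set"))
  if (is.null(spec$snr)) spec <- snr_normalize(spec, n_side = n_side)
  n_side <- spec$n_side
  chans <- rownames(spec$power)
  if (is.null(chans)) chans <- paste0("row", seq_len(nrow(spec$power)))
  out <- do.call(rbind, lapply(targets, function(f) {
    b0 <- target_bin(f, spec$epoch_length) # 0-based
    col <- b0 + 1L
    if (col - n_side < 1L || col + n_side > ncol(spec$snr))
      stop("target ", f, " Hz too close to the spectrum edge")
    neigh_cols <- c((col - n_side):(col - 1L), (col + 1L):(col + n_side))
    snr_t <- spec$snr[, col]
    d <- snr_t - rowMeans(spec$snr[, neigh_cols, drop = FALSE])
    data.frame(channel = chans, target_freq = f, snr = snr_t, d = d,
               row.names = NULL)
  }))
  if (!is.null(layout)) {
    m <- match(out$channel, layout$channel)
    out$anteriority <- layout$anteriority[m]
    out$laterality <- layout$laterality[m]
  }
  out
}

#' Average a spectrum set across its rows
#'
#' Means of power (and of SNR, when present) across rows — used for
#' across-trial envelope spectra and for group averages of participant
#' SNR spectra.
#'
#' @param spec A [spectrum_set()].
#' @param label Row name for the result.
#' @return A single-row [spectrum_set()].
#' @export
spectrum_average <- function(spec, label = "average") {
  stopifnot(inherits(spec, "spectrum_set"))
  pw <- matrix(colMeans(spec$power), 1, ncol(spec$power),
               dimnames = list(label, NULL))
  snr <- if (!is.null(spec$snr))
    matrix(colMeans(spec$snr), 1, ncol(spec$snr), dimnames = list(label, NULL))
  out <- spectrum_set(pw, spec$freqs, spec$epoch_length,
                      n_epochs_averaged = spec$n_epochs_averaged, snr = snr)
  out$n_side <- spec$n_side
  out
}
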