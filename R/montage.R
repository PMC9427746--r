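#' Default 64-channel 10-20 montage
#'
#' The scalp channel set used throughout the package: 64 extended 10-20
#' labels arranged in nine sagittal rows, plus the two mastoid reference
#' channels `M1`/`M2`. Each scalp channel carries an anterior-posterior
#' row coordinate (1 = frontal pole, 10 = inion) used by the topography
#' profiles, and a left/medial/right side tag from the 10-20 numbering
#' (odd = left, even = right, z = midline).
#'
#' @return A data.frame with columns `channel`, `row` (numeric AP
#'   coordinate; `NA` for mastoids), `side`, `is_reference`.
#' @export
default_montage <- function() {
  rows <- list(
    `1` = c("Fp1", "Fpz", "Fp2"),
    `2` = c("AF7", "AF3", "AFz", "AF4", "AF8"),
    `3` = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
    `4` = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
    `5` = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
    `6` = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
    `7` = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
    `8` = c("PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8"),
    `9` = c("O1", "Oz", "O2"),
    `10` = c("Iz")
  )
  ch <- unlist(rows, use.names = FALSE)
  row_coord <- rep(as.numeric(names(rows)), lengths(rows))
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", ch)))
  side <- ifelse(grepl("z$", ch), "medial",
                 ifelse(num %% 2 == 1, "left", "right"))
  out <- data.frame(
    channel = c(ch, "M1", "M2"),
    row = c(row_coord, NA, NA),
    side = c(side, "left", "right"),
    is_reference = c(rep(FALSE, length(ch)), TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  stopifnot(sum(!out$is_reference) == 64L)
  out
}

#' Default anteriority x laterality ROI layout
#'
#' Maps every scalp channel of [default_montage()] to one cell of the
#' 3 x 3 topographic grid used for region contrasts: anteriority
#' frontal (rows Fp/AF/F) / central (FT-FC/T-C/TP-CP) / posterior
#' (P/PO/O/Iz), crossed with laterality left / medial / right. Mastoids
#' are not mapped. All nine cells are nonempty.
#'
#' @return An object of class `roi_layout`: data.frame with columns
#'   `channel`, `anteriority`, `laterality`.
#' @export
default_roi_layout <- function() {
  mont <- default_montage()
  mont <- mont[!mont$is_reference, ]
  ant <- cut(mont$row, breaks = c(0, 3.5, 6.5, 10.5),
             labels = c("frontal", "central", "posterior"))
  out <- data.frame(channel = mont$channel,
                    anteriority = as.character(ant),
                    laterality = mont$side,
                    stringsAsFactors = FALSE)
  class(out) <- c("roi_layout", "data.frame")
  out
}

.TOPOGRAPHY_LABELS <- c("centro_posterior", "posterior", "frontal_broad", "uniform")

#' Per-channel topography weights
#'
#' Smooth anterior-posterior weight profiles in [0, 1] (maximum 1) over
#' the scalp channels, used by the simulator to give each evoked component
#' a scalp distribution: `centro_posterior` peaks over centro-parietal
#' rows (the distribution of the sentence-rate response),
#' `posterior` peaks over parieto-occipital rows (half-sentence response
#' for 2 + 2 phrasing), `frontal_broad` is an anteriorly weighted, shallow
#' gradient (half-sentence response for 1 + 3 phrasing), and `uniform` is
#' flat. Gaussian profiles over the montage row coordinate; mastoids get
#' weight 0.
#'
#' @param label One of `"centro_posterior"`, `"posterior"`,
#'   `"frontal_broad"`, `"uniform"`.
#' @param montage Montage table from [default_montage()].
#' @return Named numeric vector of weights over all montage channels.
#' @export
topography_profile <- function(label = .TOPOGRAPHY_LABELS,
                               montage = default_montage()) {
  label <- match.arg(label)
  r <- montage$row
  w <- switch(label,
    centro_posterior = exp(-((r - 6.5)^2) / (2 * 2.2^2)),
    posterior = exp(-((r - 8.5)^2) / (2 * 1.8^2)),
    frontal_broad = exp(-((r - 2.5)^2) / (2 * 4.5^2)),
    uniform = rep(1, length(r))
  )
  w[is.na(w)] <- 0
  w[montage$is_reference] <- 0
  if (max(w) > 0) w <- w / max(w)
  names(w) <- montage$channel
  w
}
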