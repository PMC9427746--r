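# Minimal European Data Format (EDF) I/O: 16-bit integer records with
# per-channel physical scaling. Trial events and condition labels travel
# in a JSON sidecar (<path>.events.json) because plain EDF has no
# annotation channel.

.edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

.edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 6, width = 1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4, width = 1)
  .edf_field(s, width)
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with one-second data records; physical units are
#' microvolts. The final record is zero-padded when the recording length
#' is not a whole number of seconds. Events are written to a JSON
#' sidecar `<path>.events.json`.
#'
#' @param rec An [eeg_recording()]; `srate` must be a positive integer.
#' @param path Output file path (conventionally `.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  srate <- rec$srate
  if (srate != round(srate) || srate < 1)
    stop("EDF export requires an integer sampling rate")
  data <- rec$data
  n <- nrow(data); nc <- ncol(data)
  n_rec <- ceiling(n / srate)
  pm <- apply(abs(data), 2, max)
  pm <- ifelse(pm == 0, 1, pm * 1.0001) # avoid clipping at the extreme
  dig <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_field("0", 8),
    .edf_field("synthetic recording", 80),
    .edf_field(paste("condition", rec$meta$syntax %||% "", rec$meta$prosody %||% ""), 80),
    .edf_field("01.01.26", 8), .edf_field("00.00.00", 8),
    .edf_field(256 * (1 + nc), 8),
    .edf_field("", 44),
    .edf_field(n_rec, 8),
    .edf_field(1, 8),
    .edf_field(nc, 4)
  )
  sig <- paste0(
    paste(vapply(rec$channel_labels, .edf_field, "", width = 16), collapse = ""),
    paste(rep(.edf_field("", 80), nc), collapse = ""),
    paste(rep(.edf_field("uV", 8), nc), collapse = ""),
    paste(vapply(-pm, .edf_num, ""), collapse = ""),
    paste(vapply(pm, .edf_num, ""), collapse = ""),
    paste(rep(.edf_field(-dig, 8), nc), collapse = ""),
    paste(rep(.edf_field(dig, 8), nc), collapse = ""),
    paste(rep(.edf_field("", 80), nc), collapse = ""),
    paste(rep(.edf_field(srate, 8), nc), collapse = ""),
    paste(rep(.edf_field("", 32), nc), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)

  scaled <- matrix(0L, n, nc)
  for (c in seq_len(nc))
    scaled[, c] <- as.integer(round(data[, c] / pm[c] * dig))
  for (r in seq_len(n_rec)) {
    i0 <- (r - 1L) * srate
    take <- min(srate, n - i0)
    block <- matrix(0L, srate, nc)
    if (take > 0) block[seq_len(take), ] <- scaled[(i0 + 1):(i0 + take), ]
    writeBin(as.vector(block), con, size = 2, endian = "little")
  }

  sidecar <- list(srate = srate, n_samples = n,
                  channel_labels = rec$channel_labels,
                  events = rec$events, meta = rec$meta)
  jsonlite::write_json(sidecar, paste0(path, ".events.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Restores physical units from the per-channel scaling and, when the
#' JSON sidecar is present, the events table and metadata (including the
#' true sample count, trimming the zero-padded tail of the last record).
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  labels <- vapply(seq_len(nc), function(i) rd(16), "")
  for (i in seq_len(nc)) rd(80)
  for (i in seq_len(nc)) rd(8)
  phys_min <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nc)) rd(80)
  spr <- vapply(seq_len(nc), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(nc)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-channel sampling rates are not supported")
  srate <- spr[1] / rec_dur

  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                 endian = "little")
  data <- matrix(0, n_rec * spr[1], nc)
  for (r in seq_len(n_rec)) {
    off <- (r - 1L) * sum(spr)
    block <- matrix(raw[(off + 1):(off + sum(spr))], spr[1], nc)
    data[((r - 1L) * spr[1] + 1):(r * spr[1]), ] <- block
  }
  for (c in seq_len(nc)) {
    g <- (phys_max[c] - phys_min[c]) / (dig_max[c] - dig_min[c])
    data[, c] <- (data[, c] - dig_min[c]) * g + phys_min[c]
  }

  events <- data.frame(sample = integer(0), trial = integer(0),
                       condition = character(0), is_outlier = logical(0))
  meta <- list()
  sidecar_path <- paste0(path, ".events.json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (!is.null(sc$events) && length(sc$events)) events <- as.data.frame(sc$events)
    if (!is.null(sc$meta)) meta <- sc$meta
    if (!is.null(sc$n_samples)) data <- data[seq_len(sc$n_samples), , drop = FALSE]
    if (!is.null(sc$channel_labels)) labels <- sc$channel_labels
  }
  eeg_recording(data, srate, labels, events, meta)
}
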