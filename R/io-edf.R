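# Minimal European Data Format (EDF) writer/reader for continuous
# recordings. One data record per second; samples are stored as 16-bit
# little-endian integers scaled per channel to the physical (microvolt)
# range. Stimulus annotations travel in a companion tab-separated events
# file (see write_events), not inside the EDF.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' @param rec an `eeg_recording`. The sampling rate must be an integer
#'   (samples per 1-s data record); the signal is zero-padded to a whole
#'   number of records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  rate <- rec$rate_hz
  if (abs(rate - round(rate)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  rate <- as.integer(round(rate))
  X <- rec$samples
  n_ch <- nrow(X)
  n_rec <- ceiling(ncol(X) / rate)
  if (ncol(X) < n_rec * rate)
    X <- cbind(X, matrix(0, n_ch, n_rec * rate - ncol(X)))
  pmax_ <- apply(abs(X), 1, max)
  pmax_ <- ifelse(pmax_ <= 0, 1, ceiling(pmax_))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(ifelse(is.na(rec$subject_id), "X", rec$subject_id), 80),
    .edf_pad("synthetic EEG", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (1 + n_ch), 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad(1, 8), .edf_pad(n_ch, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(rec$channel_labels, .edf_pad, "", width = 16),
    rep(.edf_pad("AgAgCl electrode", 80), n_ch),
    rep(.edf_pad("uV", 8), n_ch),
    vapply(-pmax_, .edf_pad, "", width = 8),
    vapply(pmax_, .edf_pad, "", width = 8),
    rep(.edf_pad(-32768, 8), n_ch),
    rep(.edf_pad(32767, 8), n_ch),
    rep(.edf_pad("", 80), n_ch),
    rep(.edf_pad(rate, 8), n_ch),
    rep(.edf_pad("", 32), n_ch))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)

  # the same affine map the reader inverts: [-pmax, pmax] <-> [-32768, 32767]
  step <- 2 * pmax_ / 65535
  D <- round((X + pmax_) / step) - 32768
  D[D > 32767] <- 32767; D[D < -32768] <- -32768
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * rate + 1L):(r * rate)
    writeBin(as.integer(t(D[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Supports the subset written by [write_edf()]: identical sampling rate on
#' every signal, no EDF+ annotation signals.
#'
#' @param path EDF file path.
#' @param events_path optional companion events TSV (see [read_events()]);
#'   its rows become the recording's annotations.
#' @param subject_id optional identifier (defaults to the EDF patient field).
#' @return an `eeg_recording`.
#' @export
read_edf <- function(path, events_path = NULL, subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  invisible(rd(8))
  patient <- rd(80); invisible(rd(80)); invisible(rd(8)); invisible(rd(8))
  invisible(rd(8)); invisible(rd(44))
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  labels <- vapply(seq_len(n_ch), function(i) rd(16), "")
  invisible(replicate(n_ch, rd(80))); invisible(replicate(n_ch, rd(8)))
  pmin_ <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  invisible(replicate(n_ch, rd(80)))
  spr <- as.integer(vapply(seq_len(n_ch), function(i) rd(8), ""))
  invisible(replicate(n_ch, rd(32)))
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  rate <- spr[1] / dur
  X <- matrix(0, n_ch, n_rec * spr[1])
  scale_ <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    d <- readBin(con, "integer", n = n_ch * spr[1], size = 2L, signed = TRUE,
                 endian = "little")
    M <- matrix(d, nrow = spr[1])
    cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    X[, cols] <- t(M * rep(scale_, each = spr[1]) +
                     rep(pmin_ - dmin * scale_, each = spr[1]))
  }
  ann <- if (!is.null(events_path)) read_events(events_path)
         else empty_annotations()
  eeg_recording(X, rate, labels, ann,
                subject_id = if (is.null(subject_id)) patient else subject_id)
}

#' Write a stimulus events table
#'
#' Tab-separated columns `onset_s`, `duration_s`, `class_id`, `class_name`.
#'
#' @param annotations annotation data.frame (as on an `eeg_recording`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(annotations, path) {
  ann <- as.data.frame(annotations)
  if (!"class_name" %in% names(ann))
    ann$class_name <- landscape_classes()[ann$class_id]
  write.table(ann[, c("onset_s", "duration_s", "class_id", "class_name")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stimulus events table
#' @param path events TSV written by [write_events()].
#' @return annotation data.frame.
#' @export
read_events <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "class_id")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("events file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  ev
}
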