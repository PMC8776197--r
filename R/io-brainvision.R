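# BrainVision Core reader (header .vhdr + binary data + .vmrk markers) for
# the acquisition format of the recording hardware family, plus a writer
# used to produce round-trip fixtures. Supports multiplexed binary data in
# IEEE_FLOAT_32 or INT_16 (with per-channel resolution scaling).

.bv_parse_ini <- function(lines) {
  sec <- NULL
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- character()
    } else if (grepl("=", ln) && !is.null(sec)) {
      kv <- sub("=", "\r", ln)
      kv <- strsplit(kv, "\r", fixed = TRUE)[[1]]
      out[[sec]][trimws(kv[1])] <- trimws(ifelse(length(kv) > 1, kv[2], ""))
    }
  }
  out
}

#' Read a BrainVision Core recording
#'
#' @param vhdr_path path to the `.vhdr` header; the data and marker files it
#'   names are resolved relative to the header's directory.
#' @param block_duration_s duration assigned to stimulus markers whose
#'   marker length is 1 point (BrainVision stimulus markers are typically
#'   instantaneous; block designs need a duration to epoch against).
#' @return an `eeg_recording`; stimulus markers `S<n>` become annotations
#'   with `class_id = n`.
#' @export
read_brainvision <- function(vhdr_path, block_duration_s = 40) {
  ini <- .bv_parse_ini(readLines(vhdr_path, warn = FALSE))
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  chs <- ini[["Channel Infos"]]
  if (is.null(ci)) stop("not a BrainVision header: ", vhdr_path)
  if (!identical(toupper(ci[["DataFormat"]]), "BINARY"))
    stop("only BINARY DataFormat is supported")
  if (!identical(toupper(ci[["DataOrientation"]]), "MULTIPLEXED"))
    stop("only MULTIPLEXED orientation is supported")
  n_ch <- as.integer(ci[["NumberOfChannels"]])
  rate <- 1e6 / as.numeric(ci[["SamplingInterval"]])
  dir <- dirname(vhdr_path)
  data_path <- file.path(dir, ci[["DataFile"]])

  labels <- character(n_ch); resol <- rep(1, n_ch)
  for (i in seq_len(n_ch)) {
    parts <- strsplit(chs[[paste0("Ch", i)]], ",", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3]))
      resol[i] <- as.numeric(parts[3])
  }

  fmt <- toupper(bi[["BinaryFormat"]])
  sz <- file.info(data_path)$size
  con <- file(data_path, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    raw_ <- readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    raw_ <- readBin(con, "integer", n = sz / 2, size = 2, signed = TRUE,
                    endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  n_t <- length(raw_) %/% n_ch
  X <- matrix(raw_[seq_len(n_ch * n_t)], nrow = n_ch) * resol

  ann <- empty_annotations()
  mf <- if ("MarkerFile" %in% names(ci)) ci[["MarkerFile"]] else NULL
  if (!is.null(mf) && file.exists(file.path(dir, mf))) {
    mk <- .bv_parse_ini(readLines(file.path(dir, mf), warn = FALSE))
    mks <- mk[["Marker Infos"]]
    rows <- list()
    for (key in names(mks)) {
      parts <- strsplit(mks[[key]], ",", fixed = TRUE)[[1]]
      if (length(parts) < 4 || !identical(parts[1], "Stimulus")) next
      m <- regmatches(parts[2], regexec("^S\\s*([0-9]+)$", parts[2]))[[1]]
      if (length(m) < 2) next
      pos <- as.numeric(parts[3]); len <- as.numeric(parts[4])
      rows[[length(rows) + 1L]] <- data.frame(
        onset_s = (pos - 1) / rate,
        duration_s = if (len > 1) len / rate else block_duration_s,
        class_id = as.integer(m[2]),
        class_name = landscape_classes()[as.integer(m[2])],
        stringsAsFactors = FALSE)
    }
    if (length(rows)) ann <- do.call(rbind, rows)
  }
  eeg_recording(X, rate, labels, ann)
}

#' Write a recording in BrainVision Core format
#'
#' Writes `<base>.vhdr`, `<base>.eeg` (multiplexed IEEE float 32) and
#' `<base>.vmrk` with one stimulus marker per annotation.
#'
#' @param rec an `eeg_recording`.
#' @param base output path without extension.
#' @return the `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, base) {
  vhdr <- paste0(base, ".vhdr")
  stem <- basename(base)
  n_ch <- nrow(rec$samples)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    paste0("SamplingInterval=", format(1e6 / rec$rate_hz, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_ch), rec$channel_labels))
  writeLines(hdr, vhdr)
  con <- file(paste0(base, ".eeg"), "wb")
  writeBin(as.numeric(rec$samples), con, size = 4, endian = "little")
  close(con)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Common Infos]", paste0("DataFile=", stem, ".eeg"),
          "[Marker Infos]")
  ann <- rec$annotations
  if (nrow(ann))
    mk <- c(mk, sprintf("Mk%d=Stimulus,S%d,%d,%d,0", seq_len(nrow(ann)),
                        ann$class_id, round(ann$onset_s * rec$rate_hz) + 1,
                        round(ann$duration_s * rec$rate_hz)))
  writeLines(mk, paste0(base, ".vmrk"))
  invisible(vhdr)
}
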