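# Continuous multichannel EEG container and the stimulus annotation table.

#' Construct an EEG recording
#'
#' @param samples channels x time numeric matrix, microvolts.
#' @param rate_hz sampling rate, Hz.
#' @param channel_labels character vector, one label per row of `samples`.
#' @param annotations data.frame with columns `onset_s`, `duration_s`,
#'   `class_id` (and optionally `class_name`); may be empty.
#' @param subject_id optional identifier carried through the pipeline.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, rate_hz, channel_labels,
                          annotations = empty_annotations(),
                          subject_id = NA_character_) {
  samples <- as.matrix(samples)
  if (nrow(samples) != length(channel_labels))
    stop("samples has ", nrow(samples), " rows but ",
         length(channel_labels), " channel labels")
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be positive")
  annotations <- as.data.frame(annotations)
  if (nrow(annotations)) {
    need <- c("onset_s", "duration_s", "class_id")
    miss <- setdiff(need, names(annotations))
    if (length(miss))
      stop("annotations missing column(s): ", paste(miss, collapse = ", "))
    span <- ncol(samples) / rate_hz
    if (any(annotations$onset_s < 0 |
            annotations$onset_s + annotations$duration_s > span + 1e-9))
      stop("annotations extend beyond the recorded span")
  }
  rownames(samples) <- channel_labels
  structure(list(samples = samples, rate_hz = rate_hz,
                 channel_labels = channel_labels,
                 annotations = annotations, subject_id = subject_id),
            class = "eeg_recording")
}

#' Empty annotation table
#' @return zero-row annotation data.frame.
#' @export
empty_annotations <- function() {
  data.frame(onset_s = numeric(), duration_s = numeric(),
             class_id = integer(), class_name = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %.1f s @ %g Hz, %d annotations%s\n",
              nrow(x$samples), ncol(x$samples) / x$rate_hz, x$rate_hz,
              nrow(x$annotations),
              if (is.na(x$subject_id)) "" else paste0(" [", x$subject_id, "]")))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$rate_hz
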