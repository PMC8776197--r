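# Preprocessing: linked-mastoid re-referencing, linear detrending,
# anti-aliased downsampling to 250 Hz, zero-phase 0.5-70 Hz band-pass,
# artifact removal (ICA / blink regression / none) and segmentation into
# labelled 2-s epochs with amplitude-based rejection.
#
# Canonical stage order: rereference -> detrend -> resample -> bandpass ->
# artifact removal -> segment.

#' Re-reference to the average of the mastoids
#'
#' Subtracts 0.5 x (left + right mastoid) from every channel and drops the
#' two reference channels from the output.
#'
#' @param rec an `eeg_recording`.
#' @param montage an `eeg_montage` naming the reference labels.
#' @return re-referenced `eeg_recording` without the reference channels.
#' @export
rereference_mastoid <- function(rec, montage = default_montage()) {
  refs <- montage$reference_labels
  miss <- setdiff(refs, rec$channel_labels)
  if (length(miss))
    stop("reference channel(s) missing from recording: ",
         paste(miss, collapse = ", "))
  ridx <- channel_index(refs, rec$channel_labels)
  refsig <- colMeans(rec$samples[ridx, , drop = FALSE])
  keep <- setdiff(seq_len(nrow(rec$samples)), ridx)
  X <- rec$samples[keep, , drop = FALSE] -
    matrix(refsig, length(keep), ncol(rec$samples), byrow = TRUE)
  out <- rec
  out$samples <- X
  out$channel_labels <- rec$channel_labels[keep]
  rownames(out$samples) <- out$channel_labels
  out
}

#' Remove per-channel linear trends
#'
#' Least-squares line (intercept + slope) removed from every channel.
#'
#' @param rec an `eeg_recording`.
#' @return detrended `eeg_recording`.
#' @export
detrend_channels <- function(rec) {
  X <- rec$samples
  n <- ncol(X)
  tc <- seq_len(n) - (n + 1) / 2
  slope <- as.numeric(X %*% tc) / sum(tc^2)
  X <- X - rowMeans(X) - slope %o% tc
  out <- rec
  out$samples <- X
  out
}

#' Downsample with FIR anti-aliasing
#'
#' Integer-factor polyphase decimation: a linear-phase low-pass FIR
#' (Hamming-windowed, cutoff 90% of the target Nyquist) is applied with its
#' group delay compensated, then every q-th sample is kept. Annotations are
#' in seconds and carry over unchanged.
#'
#' @param rec an `eeg_recording`.
#' @param target_hz target rate (must divide `rec$rate_hz`).
#' @param taps FIR length (odd).
#' @return resampled `eeg_recording`.
#' @export
resample_to <- function(rec, target_hz = 250, taps = 65L) {
  if (target_hz > rec$rate_hz)
    stop("upsampling (", rec$rate_hz, " -> ", target_hz,
         " Hz) is not supported")
  if (abs(target_hz - rec$rate_hz) < 1e-9) return(rec)
  q <- rec$rate_hz / target_hz
  if (abs(q - round(q)) > 1e-9)
    stop("only integer decimation factors are supported (got ",
         rec$rate_hz, " -> ", target_hz, " Hz)")
  q <- as.integer(round(q))
  h <- signal::fir1(taps - 1L, 0.9 / q, type = "low")
  Y <- .fir_filter_cols(h, t(rec$samples), stride = q)
  out <- rec
  out$samples <- t(Y)
  rownames(out$samples) <- out$channel_labels
  out$rate_hz <- target_hz
  out
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (zero phase, squared
#' magnitude response) across all channels.
#'
#' @param rec an `eeg_recording`.
#' @param lo,hi band edges, Hz; `hi` must be below Nyquist.
#' @param order filter order per pass.
#' @return filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, lo = 0.5, hi = 70, order = 4L) {
  if (hi >= rec$rate_hz / 2)
    stop("upper edge ", hi, " Hz is at or above Nyquist (",
         rec$rate_hz / 2, " Hz)")
  out <- rec
  out$samples <- t(.bandpass_cols(t(rec$samples), rec$rate_hz, lo, hi,
                                  order = order))
  rownames(out$samples) <- out$channel_labels
  out
}

# symmetric FastICA (logcosh nonlinearity) on whitened data
.fastica <- function(Xc, maxit = 100L, tol = 1e-4, seed = 1L) {
  n <- ncol(Xc)
  C <- tcrossprod(Xc) / n
  eg <- eigen(C, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-10
  K <- diag(1 / sqrt(eg$values[keep]), sum(keep)) %*%
    t(eg$vectors[, keep, drop = FALSE])
  Z <- K %*% Xc
  k <- nrow(Z)
  set.seed(seed)
  W <- matrix(rnorm(k * k), k, k)
  sym_decorr <- function(W) {
    s <- eigen(tcrossprod(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values), k) %*% t(s$vectors) %*% W
  }
  W <- sym_decorr(W)
  for (it in seq_len(maxit)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    W1 <- G %*% t(Z) / n - diag(rowMeans(1 - G^2), k) %*% W
    W1 <- sym_decorr(W1)
    delta <- max(abs(1 - abs(rowSums(W1 * W))))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% Z
  A <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eg$values[keep]), sum(keep)) %*% t(W)
  list(S = S, A = A)
}

.kurtosis <- function(x) {
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2 - 3
}

#' Remove ocular artifacts
#'
#' For `method = "ica"`, a FastICA decomposition is computed and components
#' whose scalp loading concentrates on the frontopolar channels and whose
#' sub-4 Hz content has high kurtosis (spiky blink transients) are dropped
#' before reconstruction. For `method = "regression"`, a blink reference
#' (low-passed mean of the frontopolar channels) is regressed out of every
#' channel. `method = "none"` is the identity.
#'
#' @param rec an `eeg_recording` (band-passed).
#' @param method one of "ica", "regression", "none".
#' @param fp_labels frontopolar channel labels used to identify blinks.
#' @param conc_threshold minimal fraction of absolute mixing weight on the
#'   frontopolar channels for a component to count as ocular.
#' @param kurt_threshold minimal excess kurtosis of the component's sub-4 Hz
#'   signal.
#' @param maxit,tol FastICA iteration controls.
#' @param seed seed for the FastICA initialisation.
#' @return cleaned `eeg_recording`; attribute `removed_components` gives the
#'   number of dropped components (ICA) or regressed references.
#' @export
remove_artifacts <- function(rec, method = c("ica", "regression", "none"),
                             fp_labels = c("Fp1", "Fp2"),
                             conc_threshold = 0.25, kurt_threshold = 5,
                             maxit = 100L, tol = 1e-4, seed = 1L) {
  method <- match.arg(method)
  if (method == "none") {
    attr(rec, "removed_components") <- 0L
    return(rec)
  }
  fp <- intersect(fp_labels, rec$channel_labels)
  if (!length(fp))
    stop("no frontopolar channel among: ",
         paste(fp_labels, collapse = ", "))
  fpi <- channel_index(fp, rec$channel_labels)
  out <- rec
  if (method == "regression") {
    ref <- colMeans(rec$samples[fpi, , drop = FALSE])
    flt <- .butter_design(4L, 4 / (rec$rate_hz / 2), "low")
    ref <- .filtfilt_cols(flt, matrix(ref, ncol = 1))[, 1]
    ref <- ref - mean(ref)
    beta <- as.numeric(rec$samples %*% ref) / sum(ref^2)
    out$samples <- rec$samples - beta %o% ref
    attr(out, "removed_components") <- 1L
  } else {
    mu <- rowMeans(rec$samples)
    dec <- .fastica(rec$samples - mu, maxit = maxit, tol = tol, seed = seed)
    conc <- colSums(abs(dec$A[fpi, , drop = FALSE])) / colSums(abs(dec$A))
    flt <- .butter_design(4L, 4 / (rec$rate_hz / 2), "low")
    Slp <- t(.filtfilt_cols(flt, t(dec$S)))
    kur <- apply(Slp, 1, .kurtosis)
    drop_ <- which(conc > conc_threshold & kur > kurt_threshold)
    keep <- setdiff(seq_len(nrow(dec$S)), drop_)
    out$samples <- dec$A[, keep, drop = FALSE] %*%
      dec$S[keep, , drop = FALSE] + mu
    rownames(out$samples) <- out$channel_labels
    attr(out, "removed_components") <- length(drop_)
  }
  out
}

#' Segment a recording into labelled 2-s epochs
#'
#' Non-overlapping contiguous windows are cut from within each annotated
#' stimulus block (from block onset forward; a trailing partial window is
#' discarded). Windows containing any sample exceeding `reject_uv` in
#' magnitude on a feature channel are rejected. Only the montage's feature
#' channels are retained.
#'
#' @param rec an `eeg_recording` at the analysis rate (250 Hz by default
#'   upstream).
#' @param montage an `eeg_montage`.
#' @param window_s epoch length, seconds.
#' @param reject_uv peak-amplitude rejection threshold, microvolts.
#' @return object of class `epoch_set`: list with `data` (channels x samples
#'   x epochs array), `info` (data.frame epoch_index / block_index /
#'   class_id / video_instance / subject_id), `rate_hz`, `channel_labels`,
#'   `n_rejected`.
#' @export
segment_epochs <- function(rec, montage = default_montage(), window_s = 2,
                           reject_uv = 100) {
  ann <- rec$annotations
  if (!nrow(ann)) stop("recording has no stimulus annotations")
  chi <- channel_index(montage$feature_channels, rec$channel_labels)
  wlen <- round(window_s * rec$rate_hz)
  ord <- order(ann$onset_s)
  ann <- ann[ord, , drop = FALSE]
  inst <- stats::ave(ann$class_id, ann$class_id, FUN = seq_along)

  datas <- list(); rows <- list(); n_rej <- 0L
  for (b in seq_len(nrow(ann))) {
    n_win <- floor(ann$duration_s[b] / window_s)
    if (n_win < 1L) {
      warning("block ", b, " shorter than the epoch window; skipped")
      next
    }
    i0 <- floor(ann$onset_s[b] * rec$rate_hz) + 1L
    for (w in seq_len(n_win)) {
      idx <- (i0 + (w - 1L) * wlen):(i0 + w * wlen - 1L)
      if (idx[length(idx)] > ncol(rec$samples)) break
      seg <- rec$samples[chi, idx, drop = FALSE]
      if (max(abs(seg)) > reject_uv) { n_rej <- n_rej + 1L; next }
      datas[[length(datas) + 1L]] <- seg
      rows[[length(rows) + 1L]] <- data.frame(
        block_index = b, class_id = ann$class_id[b],
        video_instance = inst[b], stringsAsFactors = FALSE)
    }
  }
  n_ep <- length(datas)
  data <- array(0, dim = c(length(chi), wlen, n_ep),
                dimnames = list(montage$feature_channels, NULL, NULL))
  for (i in seq_len(n_ep)) data[, , i] <- datas[[i]]
  info <- if (n_ep) {
    cbind(data.frame(epoch_index = seq_len(n_ep)), do.call(rbind, rows))
  } else {
    data.frame(epoch_index = integer(), block_index = integer(),
               class_id = integer(), video_instance = integer())
  }
  info$subject_id <- rep(rec$subject_id, nrow(info))
  structure(list(data = data, info = info, rate_hz = rec$rate_hz,
                 channel_labels = montage$feature_channels,
                 window_s = window_s, n_rejected = n_rej),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d ch x %d samples @ %g Hz (%d rejected)\n",
              dim(x$data)[3], dim(x$data)[1], dim(x$data)[2], x$rate_hz,
              x$n_rejected))
  invisible(x)
}

#' Full preprocessing pipeline
#'
#' Applies the canonical stage order (re-reference, detrend, resample,
#' band-pass, artifact removal, segmentation) and returns labelled epochs.
#'
#' @param rec raw `eeg_recording`.
#' @param montage an `eeg_montage`.
#' @param target_hz analysis sampling rate.
#' @param lo,hi band-pass edges, Hz.
#' @param artifact_method passed to [remove_artifacts()].
#' @param window_s,reject_uv passed to [segment_epochs()].
#' @param ... further arguments for [remove_artifacts()].
#' @return an `epoch_set`.
#' @export
preprocess_recording <- function(rec, montage = default_montage(),
                                 target_hz = 250, lo = 0.5, hi = 70,
                                 artifact_method = "ica", window_s = 2,
                                 reject_uv = 100, ...) {
  rec <- rereference_mastoid(rec, montage)
  rec <- detrend_channels(rec)
  rec <- resample_to(rec, target_hz)
  rec <- bandpass_filter(rec, lo, hi)
  rec <- remove_artifacts(rec, method = artifact_method, ...)
  segment_epochs(rec, montage, window_s = window_s, reject_uv = reject_uv)
}
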