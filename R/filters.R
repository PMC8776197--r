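# Internal filtering utilities shared by the generator, preprocessing and the
# differential-entropy estimator. Filters are designed with signal::butter and
# applied zero-phase (forward-backward) by a compiled kernel across many
# signals at once.

.filter_cache <- new.env(parent = emptyenv())

#' Butterworth design with caching
#' @noRd
.butter_design <- function(order, W, type) {
  key <- paste(type, order, paste(signif(W, 10), collapse = "-"), sep = "|")
  hit <- .filter_cache[[key]]
  if (!is.null(hit)) return(hit)
  flt <- signal::butter(order, W, type = type)
  m <- max(length(flt$a), length(flt$b)) - 1L
  b <- c(flt$b, rep(0, m + 1L - length(flt$b)))
  a <- c(flt$a, rep(0, m + 1L - length(flt$a)))
  # steady-state initial filter state for a unit step input, so that the
  # forward and backward passes start without a start-up transient
  comp <- matrix(0, m, m)
  comp[1, ] <- -a[2:(m + 1L)] / a[1]
  if (m > 1) comp[cbind(2:m, 1:(m - 1L))] <- 1
  rhs <- b[2:(m + 1L)] - b[1] * a[2:(m + 1L)]
  # narrow bands make this system nearly singular; fall back to zero state
  # (the reflection padding then absorbs the start-up transient)
  zi <- tryCatch(solve(diag(m) - t(comp), rhs),
                 error = function(e) tryCatch(qr.solve(diag(m) - t(comp),
                                                       rhs),
                                              error = function(e) rep(0, m)))
  if (any(!is.finite(zi)) || max(abs(zi)) > 1e6) zi <- rep(0, m)
  out <- list(b = b, a = a, zi = zi)
  .filter_cache[[key]] <- out
  out
}

#' Zero-phase IIR filtering of matrix columns with odd-reflection padding
#'
#' @param X numeric matrix, time in rows, one signal per column.
#' @param pad number of reflected samples prepended/appended per end.
#' @noRd
.filtfilt_cols <- function(flt, X, pad = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(pad)) pad <- 3L * length(flt$zi)
  pad <- min(pad, n - 1L)
  if (pad > 0L) {
    top <- 2 * matrix(X[1L, ], pad, ncol(X), byrow = TRUE) -
      X[(pad + 1L):2L, , drop = FALSE]
    bot <- 2 * matrix(X[n, ], pad, ncol(X), byrow = TRUE) -
      X[(n - 1L):(n - pad), , drop = FALSE]
    Xp <- rbind(top, X, bot)
  } else {
    Xp <- X
  }
  Y <- .iir_filtfilt_cols(flt$b, flt$a, Xp, flt$zi)
  Y[(pad + 1L):(pad + n), , drop = FALSE]
}

#' Band-pass filter matrix columns (time in rows), zero phase
#' @noRd
.bandpass_cols <- function(X, rate_hz, lo, hi, order = 4L, pad = NULL) {
  flt <- .butter_design(order, c(lo, hi) / (rate_hz / 2), "pass")
  .filtfilt_cols(flt, X, pad = pad)
}

#' Welch power spectral density estimate (Hann window, 50% overlap)
#'
#' One-sided density in units of signal^2 per Hz; used by tests and the
#' synthetic-signal power checks rather than the per-epoch feature estimator.
#'
#' @param x numeric vector.
#' @param rate_hz sampling rate in Hz.
#' @param seg_s segment length in seconds.
#' @return list with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, rate_hz, seg_s = 2) {
  nseg <- round(seg_s * rate_hz)
  step <- max(1L, nseg %/% 2L)
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / nseg) # periodic Hann
  u <- sum(w^2)
  acc <- numeric(nseg %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- abs(fft(seg))^2 / (rate_hz * u)
    half <- P[1:(nseg %/% 2L + 1L)]
    half[2:(nseg %/% 2L)] <- 2 * half[2:(nseg %/% 2L)]
    acc <- acc + half
  }
  list(freq = (0:(nseg %/% 2L)) * rate_hz / nseg, psd = acc / length(starts))
}

#' Band power from a Welch estimate
#' @param x numeric vector.
#' @param rate_hz sampling rate in Hz.
#' @param lo,hi band edges in Hz (lo inclusive, hi exclusive unless
#'   `hi_inclusive`).
#' @param hi_inclusive include the upper edge bin.
#' @return band power (signal^2).
#' @export
band_power <- function(x, rate_hz, lo, hi, hi_inclusive = FALSE) {
  w <- welch_psd(x, rate_hz)
  sel <- w$freq >= lo & (if (hi_inclusive) w$freq <= hi else w$freq < hi)
  df <- w$freq[2] - w$freq[1]
  sum(w$psd[sel]) * df
}
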