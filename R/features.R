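# Six feature families per epoch per frequency band. Frequency-domain
# families (29 values per band): MAS, the log mean one-sided amplitude
# spectrum over the band; PSD, the log mean periodogram density; DE, the
# Gaussian differential entropy 0.5 * ln(2*pi*e*var) of the band-filtered
# signal. Spatial-domain families derived from DE: DASM (left - right,
# 13 pairs), RASM (left / right, 13 pairs), DCAU (frontal - posterior,
# 11 pairs). The "total" band is the concatenation of the five bands.

#' The five-band frequency scheme
#'
#' delta 1-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-70 Hz. Band bins
#' are taken lo-inclusive / hi-exclusive so the shared edges are not double
#' counted; the gamma upper edge (70 Hz, the analysis band limit) is
#' inclusive.
#'
#' @return data.frame with columns `band`, `lo_hz`, `hi_hz`, `hi_inclusive`.
#' @export
band_scheme <- function() {
  e <- .band_edges()
  data.frame(band = rownames(e), lo_hz = e[, "lo"], hi_hz = e[, "hi"],
             hi_inclusive = rownames(e) == "gamma",
             row.names = NULL, stringsAsFactors = FALSE)
}

.feature_families <- c("MAS", "PSD", "DE", "DASM", "RASM", "DCAU")

.band_bins <- function(freq, lo, hi, hi_inclusive) {
  sel <- which(freq >= lo & (if (hi_inclusive) freq <= hi else freq < hi))
  if (!length(sel)) stop("no frequency bins in band [", lo, ", ", hi, ")")
  sel
}

#' One-sided amplitude and power spectra of an epoch
#'
#' Single Hann-tapered periodogram on the full epoch (0.5 Hz grid for the
#' default 2-s epoch at 250 Hz). The amplitude spectrum is taper-gain
#' corrected so a unit sine at a bin centre reads 1.0; the power spectrum is
#' a one-sided density (signal^2 per Hz) satisfying Parseval against the
#' Hann-weighted signal variance.
#'
#' @param epoch channels x samples numeric matrix.
#' @param rate_hz sampling rate, Hz.
#' @return list with `freq` and channels x bins matrices `amplitude`,
#'   `power`.
#' @export
epoch_spectrum <- function(epoch, rate_hz) {
  epoch <- as.matrix(epoch)
  n <- ncol(epoch)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)
  FT <- mvfft(t(epoch * matrix(w, nrow(epoch), n, byrow = TRUE)))
  nb <- n %/% 2L + 1L
  mag <- Mod(FT[seq_len(nb), , drop = FALSE])
  amp <- 2 * mag / sum(w)
  pow <- 2 * mag^2 / (rate_hz * sum(w^2))
  edge <- c(1L, if (n %% 2L == 0L) nb)
  amp[edge, ] <- amp[edge, , drop = FALSE] / 2
  pow[edge, ] <- pow[edge, , drop = FALSE] / 2
  list(freq = (seq_len(nb) - 1L) * rate_hz / n,
       amplitude = t(amp), power = t(pow))
}

.band_row <- function(scheme, band) {
  i <- match(band, scheme$band)
  if (is.na(i)) stop("unknown band: ", band)
  scheme[i, ]
}

#' Mean amplitude spectrum feature (log scale)
#'
#' @param epoch channels x samples matrix.
#' @param rate_hz sampling rate, Hz.
#' @param band band name from [band_scheme()].
#' @param scheme band scheme table.
#' @param spec optional precomputed [epoch_spectrum()] result.
#' @return named numeric vector, one value per channel (natural log of the
#'   band-mean amplitude).
#' @export
feat_mas <- function(epoch, rate_hz, band, scheme = band_scheme(),
                     spec = NULL) {
  if (is.null(spec)) spec <- epoch_spectrum(epoch, rate_hz)
  b <- .band_row(scheme, band)
  sel <- .band_bins(spec$freq, b$lo_hz, b$hi_hz, b$hi_inclusive)
  log(rowMeans(spec$amplitude[, sel, drop = FALSE]))
}

#' Power spectral density feature (log scale)
#'
#' @inheritParams feat_mas
#' @return named numeric vector (natural log of the band-mean periodogram
#'   density).
#' @export
feat_psd <- function(epoch, rate_hz, band, scheme = band_scheme(),
                     spec = NULL) {
  if (is.null(spec)) spec <- epoch_spectrum(epoch, rate_hz)
  b <- .band_row(scheme, band)
  sel <- .band_bins(spec$freq, b$lo_hz, b$hi_hz, b$hi_inclusive)
  log(rowMeans(spec$power[, sel, drop = FALSE]))
}

#' Differential entropy feature
#'
#' Gaussian closed form 0.5 * ln(2*pi*e*sigma^2) where sigma^2 is the
#' variance of the band-pass-filtered channel signal within the epoch
#' (4th-order zero-phase Butterworth, odd-reflection padding). Zero
#' variance yields `-Inf`, which downstream design construction treats as a
#' flagged sentinel.
#'
#' @inheritParams feat_mas
#' @param pad reflection padding, samples per end.
#' @return named numeric vector, one DE value per channel (nats).
#' @export
feat_de <- function(epoch, rate_hz, band, scheme = band_scheme(),
                    pad = 250L) {
  b <- .band_row(scheme, band)
  Xf <- .bandpass_cols(t(as.matrix(epoch)), rate_hz, b$lo_hz, b$hi_hz,
                       pad = pad)
  v <- apply(Xf, 2, var)
  names(v) <- rownames(epoch)
  ifelse(v > 0, 0.5 * log(2 * pi * exp(1) * v), -Inf)
}

.pair_values <- function(de_full, pairs, what) {
  miss <- setdiff(c(pairs), names(de_full))
  if (length(miss))
    stop(what, " pair member(s) missing from DE vector: ",
         paste(miss, collapse = ", "))
  NULL
}

#' Differential asymmetry (left minus right DE)
#'
#' @param de_full named per-channel DE vector covering all feature channels.
#' @param montage an `eeg_montage` providing the 13 left-right pairs.
#' @return numeric vector of length 13, named "left-right".
#' @export
feat_dasm <- function(de_full, montage = default_montage()) {
  p <- montage$lr_pairs
  .pair_values(de_full, p, "DASM")
  out <- de_full[p[, 1]] - de_full[p[, 2]]
  names(out) <- paste(p[, 1], p[, 2], sep = "-")
  out
}

#' Rational asymmetry (left over right DE)
#'
#' DE values of microvolt-scale signals can cross zero; ratios whose
#' denominator magnitude is below `eps` are returned as `NA` sentinels.
#'
#' @inheritParams feat_dasm
#' @param eps minimal denominator magnitude.
#' @return numeric vector of length 13, named "left/right".
#' @export
feat_rasm <- function(de_full, montage = default_montage(), eps = 1e-6) {
  p <- montage$lr_pairs
  .pair_values(de_full, p, "RASM")
  den <- de_full[p[, 2]]
  out <- ifelse(abs(den) < eps, NA_real_, de_full[p[, 1]] / den)
  names(out) <- paste(p[, 1], p[, 2], sep = "/")
  out
}

#' Differential caudality (frontal minus posterior DE)
#'
#' @inheritParams feat_dasm
#' @return numeric vector of length 11, named "frontal-posterior".
#' @export
feat_dcau <- function(de_full, montage = default_montage()) {
  p <- montage$fp_pairs
  .pair_values(de_full, p, "DCAU")
  out <- de_full[p[, 1]] - de_full[p[, 2]]
  names(out) <- paste(p[, 1], p[, 2], sep = "-")
  out
}

.expected_dims <- function(montage) {
  n_ch <- length(montage$feature_channels)
  c(MAS = n_ch, PSD = n_ch, DE = n_ch,
    DASM = nrow(montage$lr_pairs), RASM = nrow(montage$lr_pairs),
    DCAU = nrow(montage$fp_pairs))
}

#' Extract all feature families for one subject's epochs
#'
#' Computes the six families over the five bands, plus the "total" band as
#' the concatenation of the per-band vectors in band order. Feature
#' dimensions are checked against the montage at construction time.
#'
#' @param epochs an `epoch_set` from one subject.
#' @param montage an `eeg_montage`.
#' @param scheme band scheme table.
#' @param de_pad reflection padding for the DE band filters, samples.
#' @return object of class `feature_tensor`: list with `features`
#'   (`features[[family]][[band]]` = epochs x dim matrix), `info` (epoch
#'   labels), `subject_id`, `bands`, `meta` (estimator provenance).
#' @export
extract_features <- function(epochs, montage = default_montage(),
                             scheme = band_scheme(), de_pad = 250L) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  n_ch <- d[1]; n_s <- d[2]; n_ep <- d[3]
  rate <- epochs$rate_hz
  labels <- epochs$channel_labels
  # time x (channels*epochs) layout so every epoch is filtered/transformed
  # in one pass
  flat <- matrix(aperm(epochs$data, c(2, 1, 3)), nrow = n_s)

  # spectra for MAS/PSD
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_s) / n_s)
  FT <- mvfft(flat * w)
  nb <- n_s %/% 2L + 1L
  mag <- Mod(FT[seq_len(nb), , drop = FALSE])
  amp <- 2 * mag / sum(w)
  pow <- 2 * mag^2 / (rate * sum(w^2))
  edge <- c(1L, if (n_s %% 2L == 0L) nb)
  amp[edge, ] <- amp[edge, , drop = FALSE] / 2
  pow[edge, ] <- pow[edge, , drop = FALSE] / 2
  freq <- (seq_len(nb) - 1L) * rate / n_s

  fam <- lapply(.feature_families, function(f) list())
  names(fam) <- .feature_families
  for (bi in seq_len(nrow(scheme))) {
    b <- scheme[bi, ]
    sel <- .band_bins(freq, b$lo_hz, b$hi_hz, b$hi_inclusive)
    # column means over band bins -> (channels*epochs), then epochs x ch
    mas <- matrix(log(colMeans(amp[sel, , drop = FALSE])), nrow = n_ch)
    psd <- matrix(log(colMeans(pow[sel, , drop = FALSE])), nrow = n_ch)
    Xf <- .bandpass_cols(flat, rate, b$lo_hz, b$hi_hz, pad = de_pad)
    v <- colMeans(Xf^2) - colMeans(Xf)^2
    v <- v * n_s / (n_s - 1)
    de <- matrix(ifelse(v > 0, 0.5 * log(2 * pi * exp(1) * v), -Inf),
                 nrow = n_ch)
    rownames(mas) <- rownames(psd) <- rownames(de) <- labels
    fam$MAS[[b$band]] <- t(mas)
    fam$PSD[[b$band]] <- t(psd)
    fam$DE[[b$band]] <- t(de)
    lr <- montage$lr_pairs; fp <- montage$fp_pairs
    dasm <- t(de[lr[, 1], , drop = FALSE] - de[lr[, 2], , drop = FALSE])
    den <- de[lr[, 2], , drop = FALSE]
    rasm <- t(ifelse(abs(den) < 1e-6, NA_real_,
                     de[lr[, 1], , drop = FALSE] / den))
    dcau <- t(de[fp[, 1], , drop = FALSE] - de[fp[, 2], , drop = FALSE])
    colnames(dasm) <- paste(lr[, 1], lr[, 2], sep = "-")
    colnames(rasm) <- paste(lr[, 1], lr[, 2], sep = "/")
    colnames(dcau) <- paste(fp[, 1], fp[, 2], sep = "-")
    fam$DASM[[b$band]] <- dasm
    fam$RASM[[b$band]] <- rasm
    fam$DCAU[[b$band]] <- dcau
  }
  want <- .expected_dims(montage)
  for (f in .feature_families) {
    for (bn in scheme$band) {
      if (ncol(fam[[f]][[bn]]) != want[[f]])
        stop("feature dimension violation: ", f, "/", bn, " has ",
             ncol(fam[[f]][[bn]]), " columns, expected ", want[[f]])
    }
    tot <- do.call(cbind, fam[[f]][scheme$band])
    colnames(tot) <- unlist(lapply(scheme$band, function(bn)
      paste(bn, colnames(fam[[f]][[bn]]), sep = ".")))
    fam[[f]][["total"]] <- tot
  }
  structure(list(features = fam, info = epochs$info,
                 subject_id = epochs$info$subject_id[1] %||% NA_character_,
                 bands = scheme,
                 meta = list(log_base = "natural",
                             spectral_estimator = "single Hann periodogram",
                             de_filter = "butterworth order 4, zero phase",
                             de_pad = de_pad)),
            class = "feature_tensor")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Retrieve one (family, band) feature matrix
#'
#' @param tensor a `feature_tensor`.
#' @param family one of MAS, PSD, DE, DASM, RASM, DCAU.
#' @param band a band name or "total".
#' @return epochs x dim numeric matrix.
#' @export
feature_matrix <- function(tensor, family, band) {
  m <- tensor$features[[family]][[band]]
  if (is.null(m)) stop("no feature slice for ", family, "/", band)
  m
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat(sprintf("<feature_tensor> subject %s: %d epochs, %d families x %d bands\n",
              x$subject_id, nrow(x$info), length(x$features),
              length(x$features[[1]])))
  invisible(x)
}

#' Write a feature tensor as a tab-separated table
#'
#' Long format, one row per (epoch, family, band): columns `subject_id`,
#' `epoch_index`, `class_id`, `video_instance`, `family`, `band`,
#' `v1..vD` (D = widest family; narrower rows are NA-padded). A sidecar
#' `<path>.meta.yaml` records the estimator provenance.
#'
#' @param tensor a `feature_tensor`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_tensor <- function(tensor, path) {
  bands <- c(tensor$bands$band, "total")
  dmax <- max(vapply(tensor$features,
                     function(f) max(vapply(f, ncol, 0L)), 0L))
  rows <- list()
  for (f in names(tensor$features)) {
    for (bn in bands) {
      m <- tensor$features[[f]][[bn]]
      vals <- matrix(NA_real_, nrow(m), dmax)
      vals[, seq_len(ncol(m))] <- m
      rows[[paste(f, bn)]] <- data.frame(
        subject_id = tensor$info$subject_id,
        epoch_index = tensor$info$epoch_index,
        class_id = tensor$info$class_id,
        video_instance = tensor$info$video_instance,
        family = f, band = bn, vals, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[-(1:6)] <- paste0("v", seq_len(dmax))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(tensor$meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a feature tensor written by [write_feature_tensor()]
#'
#' @param path TSV path.
#' @return a `feature_tensor` (feature matrices and epoch labels; metadata
#'   restored from the sidecar if present).
#' @export
read_feature_tensor <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  vcols <- grep("^v[0-9]+$", names(d))
  fams <- unique(d$family)
  bands <- unique(d$band)
  feats <- lapply(fams, function(f) {
    out <- lapply(bands, function(bn) {
      sub <- d[d$family == f & d$band == bn, , drop = FALSE]
      sub <- sub[order(sub$epoch_index), , drop = FALSE]
      m <- as.matrix(sub[, vcols, drop = FALSE])
      m[, colSums(is.na(m)) < nrow(m), drop = FALSE]
    })
    names(out) <- bands
    out
  })
  names(feats) <- fams
  first <- d[d$family == fams[1] & d$band == bands[1], , drop = FALSE]
  first <- first[order(first$epoch_index), , drop = FALSE]
  info <- first[, c("epoch_index", "class_id", "video_instance",
                    "subject_id")]
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  structure(list(features = feats, info = info,
                 subject_id = info$subject_id[1], bands = band_scheme(),
                 meta = meta),
            class = "feature_tensor")
}
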