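# Synthetic stimulus-locked EEG with the study's block design: 7 landscape
# classes x 2 repeats of ~40 s video blocks separated by 60 s rests, recorded
# on a 32-channel 10-20 cap. Signals are a sum of 1/f background noise,
# per-band narrowband oscillations whose power carries the class signal, and
# eye-blink / 50 Hz line artifacts.

.BANDS <- c("delta", "theta", "alpha", "beta", "gamma")

#' Build a randomized stimulus schedule
#'
#' Fourteen stimulus blocks (each of the 7 classes exactly twice) in seeded
#' random order, separated by rest periods, with a few seconds of lead-in and
#' lead-out so filter edge effects land outside the blocks.
#'
#' @param seed integer seed for the block order permutation.
#' @param block_s stimulus block duration, seconds.
#' @param rest_s rest duration between blocks, seconds.
#' @param lead_s lead-in/lead-out silence, seconds.
#' @param n_classes,n_repeats class count and repeats per class.
#' @return object of class `stimulus_schedule`: list with `blocks`
#'   (data.frame class_id/onset_s/duration_s), `rest_s`, `lead_s`, `seed`,
#'   `total_s`.
#' @export
make_schedule <- function(seed = 0L, block_s = 40, rest_s = 60, lead_s = 5,
                          n_classes = 7L, n_repeats = 2L) {
  set.seed(seed)
  classes <- sample(rep(seq_len(n_classes), n_repeats))
  n_blocks <- length(classes)
  onsets <- lead_s + (seq_len(n_blocks) - 1L) * (block_s + rest_s)
  total <- lead_s + n_blocks * block_s + (n_blocks - 1L) * rest_s + lead_s
  blocks <- data.frame(class_id = classes, onset_s = onsets,
                       duration_s = block_s)
  structure(list(blocks = blocks, rest_s = rest_s, lead_s = lead_s,
                 seed = seed, total_s = total),
            class = "stimulus_schedule")
}

#' Class-discriminative band-power signatures
#'
#' Each class scales per-band oscillatory power by a multiplicative gain.
#' By default classes differ only in the gamma and beta bands (log-spaced
#' gains across the 7 classes, mirroring the finding that the high-frequency
#' bands carry the discriminative signal) plus a small left-right gamma gain
#' differential. `effect_size = 0` collapses all signatures to the identical
#' null model.
#'
#' @param montage an `eeg_montage`; supplies channel labels and laterality.
#' @param effect_size dimensionless scalar multiplying all log-gains and the
#'   asymmetry differential; 1 is the default study condition, 0 the null.
#' @param gamma_gain_max,beta_gain_max power gain of the last class relative
#'   to the first in the gamma / beta band.
#' @param asym_max maximal left-minus-right relative gamma gain differential.
#' @param n_classes number of stimulus classes.
#' @return object of class `class_signatures`: list of per-class lists with
#'   `class_id` and `gain` (5 bands x n channels matrix of power gains),
#'   plus attributes `effect_size`, `asym_max`.
#' @export
class_signatures <- function(montage = default_montage(), effect_size = 1,
                             gamma_gain_max = 4, beta_gain_max = 2.5,
                             asym_max = 0.1, n_classes = 7L) {
  labels <- montage$electrodes$label
  side <- sign(montage$electrodes$x) # -1 left, +1 right, 0 midline
  sigs <- vector("list", n_classes)
  for (k in seq_len(n_classes)) {
    frac <- (k - 1) / (n_classes - 1)
    g <- matrix(1, length(.BANDS), length(labels),
                dimnames = list(.BANDS, labels))
    g["gamma", ] <- exp(effect_size * frac * log(gamma_gain_max))
    g["beta", ] <- exp(effect_size * frac * log(beta_gain_max))
    a <- effect_size * asym_max * (2 * frac - 1)
    g["gamma", ] <- g["gamma", ] * (1 - a * side) # left boosted when a > 0
    stopifnot(all(g > 0))
    sigs[[k]] <- list(class_id = k, gain = g)
  }
  structure(sigs, effect_size = effect_size, asym_max = asym_max,
            class = "class_signatures")
}

#' Noise and artifact model for the generator
#'
#' @param montage an `eeg_montage` (for the blink scalp topography).
#' @param alpha 1/f^alpha background spectral exponent.
#' @param background_rms_uv background noise RMS per channel, microvolts.
#' @param osc_rms_uv named per-band baseline oscillation RMS, microvolts.
#' @param line_hz,line_amp_uv mains interference frequency and amplitude.
#' @param blink_rate_per_min,blink_amp_uv,blink_duration_s eye-blink Poisson
#'   rate, peak amplitude at the frontopolar sites and raised-cosine
#'   transient duration.
#' @return object of class `eeg_noise_model`.
#' @export
noise_model <- function(montage = default_montage(), alpha = 1,
                        background_rms_uv = 10,
                        osc_rms_uv = c(delta = 4, theta = 3, alpha = 4,
                                       beta = 2.5, gamma = 3),
                        line_hz = 50, line_amp_uv = 2,
                        blink_rate_per_min = 12, blink_amp_uv = 80,
                        blink_duration_s = 0.4) {
  stopifnot(all(osc_rms_uv >= 0), background_rms_uv >= 0, line_amp_uv >= 0,
            blink_amp_uv >= 0, blink_rate_per_min >= 0)
  y <- montage$electrodes$y
  # frontopolar-weighted loading, ~1 at Fp1/Fp2 and near zero behind Cz
  loading <- 0.05 + 0.95 * pmax(0, (y - 0.3) / 0.65)^2
  names(loading) <- montage$electrodes$label
  structure(list(alpha = alpha, background_rms_uv = background_rms_uv,
                 osc_rms_uv = osc_rms_uv[.BANDS], line_hz = line_hz,
                 line_amp_uv = line_amp_uv,
                 blink_rate_per_min = blink_rate_per_min,
                 blink_amp_uv = blink_amp_uv,
                 blink_duration_s = blink_duration_s,
                 blink_loading = loading),
            class = "eeg_noise_model")
}

# 1/f^alpha Gaussian noise by spectral shaping; the spectrum is flattened
# below 0.5 Hz so session-length drifts do not dominate the variance budget.
# The shaping filter is real and symmetric in frequency, so two real
# channels are filtered per complex FFT (one in the real part, one in the
# imaginary part).
.one_over_f_mat <- function(n, rate_hz, alpha, rms, ncols) {
  if (rms == 0) return(matrix(0, n, ncols))
  if (alpha == 0) return(matrix(rnorm(n * ncols, sd = rms), n, ncols))
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * rate_hz / n
  shape <- pmax(f, 0.5)^(-alpha / 2)
  shape[1] <- 0
  out <- matrix(0, n, ncols)
  for (p in seq_len(ceiling(ncols / 2))) {
    zc <- complex(real = rnorm(n), imaginary = rnorm(n))
    y <- fft(fft(zc) * shape, inverse = TRUE) / n
    c1 <- 2L * p - 1L
    x1 <- Re(y)
    out[, c1] <- x1 * (rms / sd(x1))
    if (2L * p <= ncols) {
      x2 <- Im(y)
      out[, 2L * p] <- x2 * (rms / sd(x2))
    }
  }
  out
}

# raised-cosine blink transient train; returns the clean train plus onsets
.blink_train <- function(n, rate_hz, rate_per_min, amp, dur_s, total_s) {
  s <- numeric(n)
  if (rate_per_min <= 0 || amp <= 0)
    return(list(train = s, onsets_s = numeric()))
  n_ev <- rpois(1L, rate_per_min / 60 * total_s)
  onsets <- sort(runif(n_ev, 0, total_s - dur_s))
  len <- round(dur_s * rate_hz)
  tpl <- amp * 0.5 * (1 - cos(2 * pi * seq_len(len) / len))
  for (o in onsets) {
    i0 <- floor(o * rate_hz) + 1L
    idx <- i0:(i0 + len - 1L)
    s[idx] <- s[idx] + tpl
  }
  list(train = s, onsets_s = onsets)
}

#' Generate one subject's recording
#'
#' Per channel the signal is 1/f^alpha background plus, for every band, a
#' band-limited (4th-order Butterworth-filtered white noise) oscillation
#' whose amplitude envelope equals the baseline RMS during rest and
#' `baseline * sqrt(gain)` inside stimulus blocks, so that expected band
#' power inside a class-k block is `gain` times the rest baseline. Blink
#' transients (frontally weighted) and a 50 Hz sinusoid are then mixed in.
#' Reference (mastoid) channels carry background noise only.
#'
#' @param schedule a `stimulus_schedule`.
#' @param signatures a `class_signatures` covering every scheduled class.
#' @param noise an `eeg_noise_model`.
#' @param montage an `eeg_montage`.
#' @param rate_hz generation sampling rate (>= 250); the default 500 Hz
#'   leaves the 250 Hz downsampling stage non-trivial.
#' @param seed integer seed; identical (seed, config) gives identical samples.
#' @param gain_jitter per-subject multiplicative jitter (+-fraction) applied
#'   to baseline band amplitudes per channel and, as one scalar, to the
#'   class log-gains; it never differs between classes, so the null model
#'   stays null.
#' @param subject_id identifier stored on the recording.
#' @return an `eeg_recording` with stimulus annotations; the list element
#'   `artifacts` records the injected blink onsets for oracle checks.
#' @export
generate_subject <- function(schedule, signatures, noise,
                             montage = default_montage(), rate_hz = 500,
                             seed = 1L, gain_jitter = 0.1,
                             subject_id = NA_character_) {
  stopifnot(inherits(schedule, "stimulus_schedule"),
            inherits(noise, "eeg_noise_model"), rate_hz >= 250)
  need <- sort(unique(schedule$blocks$class_id))
  have <- vapply(signatures, function(s) s$class_id, 0L)
  if (!all(need %in% have))
    stop("missing class signature(s) for class id(s): ",
         paste(setdiff(need, have), collapse = ", "))
  set.seed(seed)
  labels <- montage$electrodes$label
  n_ch <- length(labels)
  total_s <- schedule$total_s
  n <- round(total_s * rate_hz)
  is_ref <- labels %in% montage$reference_labels

  # time x channels layout during synthesis (column operations are cheap);
  # transposed once at the end
  Xt <- .one_over_f_mat(n, rate_hz, noise$alpha, noise$background_rms_uv,
                        n_ch)

  # per-block sample index ranges
  blocks <- schedule$blocks
  block_idx <- lapply(seq_len(nrow(blocks)), function(i) {
    i0 <- floor(blocks$onset_s[i] * rate_hz) + 1L
    i0:min(n, i0 + round(blocks$duration_s[i] * rate_hz) - 1L)
  })

  eff_jit <- if (gain_jitter > 0) runif(1, 1 - gain_jitter, 1 + gain_jitter) else 1
  osc_ch <- which(!is_ref)
  # one white-noise process per channel, split into the five disjoint bands
  # by the per-band filters; disjoint pass bands make the band components
  # mutually uncorrelated
  W <- matrix(rnorm(n * length(osc_ch)), n)
  for (b in seq_along(.BANDS)) {
    band <- .BANDS[b]
    base <- noise$osc_rms_uv[[band]]
    if (base <= 0) next
    edges <- .band_edges()[band, ]
    U <- .bandpass_cols(W, rate_hz, edges[1], edges[2], pad = 0L)
    sds <- sqrt(colMeans(U^2) - colMeans(U)^2)
    for (j in seq_along(osc_ch)) {
      c <- osc_ch[j]
      amp <- base * (if (gain_jitter > 0)
        runif(1, 1 - gain_jitter, 1 + gain_jitter) else 1)
      env <- rep(amp, n)
      for (i in seq_len(nrow(blocks))) {
        g <- signatures[[blocks$class_id[i]]]$gain[band, labels[c]]
        env[block_idx[[i]]] <- amp * exp(eff_jit * log(g) / 2)
      }
      Xt[, c] <- Xt[, c] + (U[, j] / sds[j]) * env
    }
  }

  if (noise$line_amp_uv > 0) {
    tt <- (seq_len(n) - 1) / rate_hz
    phi <- runif(1, 0, 2 * pi)
    line <- sin(2 * pi * noise$line_hz * tt + phi)
    coup <- runif(n_ch, 0.8, 1.2) * noise$line_amp_uv
    for (c in seq_len(n_ch)) Xt[, c] <- Xt[, c] + coup[c] * line
  }

  bl <- .blink_train(n, rate_hz, noise$blink_rate_per_min,
                     noise$blink_amp_uv, noise$blink_duration_s, total_s)
  if (length(bl$onsets_s)) {
    for (c in which(noise$blink_loading > 1e-3))
      Xt[, c] <- Xt[, c] + noise$blink_loading[c] * bl$train
  }
  X <- t(Xt)
  dimnames(X) <- list(labels, NULL)

  ann <- data.frame(onset_s = blocks$onset_s, duration_s = blocks$duration_s,
                    class_id = blocks$class_id,
                    class_name = landscape_classes()[blocks$class_id],
                    stringsAsFactors = FALSE)
  rec <- eeg_recording(X, rate_hz, labels, ann, subject_id = subject_id)
  rec$artifacts <- list(blink_onsets_s = bl$onsets_s,
                        line_hz = noise$line_hz)
  rec
}

#' Generate a multi-subject dataset
#'
#' One recording per subject with independently randomized schedules;
#' subject i uses seed `base_seed + i - 1` for both its schedule and its
#' signal, so a fixed `base_seed` reproduces the dataset bit-identically.
#'
#' @param n_subjects number of subjects (study default 20).
#' @param base_seed integer base seed.
#' @param montage,signatures,noise,rate_hz,gain_jitter passed to
#'   [generate_subject()].
#' @param schedule_args list of extra arguments for [make_schedule()].
#' @param callback optional `function(recording, subject_index)`; when given,
#'   each recording is handed to it right after generation and only the
#'   callback results are kept (constant-memory streaming over subjects).
#' @return list of `eeg_recording` (or of callback results).
#' @export
generate_dataset <- function(n_subjects = 20L, base_seed = 1L,
                             montage = default_montage(),
                             signatures = class_signatures(montage),
                             noise = noise_model(montage), rate_hz = 500,
                             gain_jitter = 0.1, schedule_args = list(),
                             callback = NULL) {
  stopifnot(n_subjects >= 1)
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    seed_i <- base_seed + i - 1L
    sch <- do.call(make_schedule, c(list(seed = seed_i), schedule_args))
    rec <- generate_subject(sch, signatures, noise, montage, rate_hz,
                            seed = seed_i, gain_jitter = gain_jitter,
                            subject_id = sprintf("S%02d", i))
    out[[i]] <- if (is.null(callback)) rec else callback(rec, i)
  }
  out
}

# band edge lookup shared with the feature module
.band_edges <- function() {
  m <- rbind(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
             beta = c(13, 30), gamma = c(30, 70))
  colnames(m) <- c("lo", "hi")
  m
}
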