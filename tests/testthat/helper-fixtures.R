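# Shared fixtures, built in code: short schedules and recordings so unit
# tests stay fast; the full-scale study design is exercised in the
# acceptance tests.

# compressed session: same 14-block structure, shorter blocks/rests
short_schedule <- function(seed = 0, block_s = 10, rest_s = 2, lead_s = 2) {
  make_schedule(seed, block_s = block_s, rest_s = rest_s, lead_s = lead_s)
}

# clean noise model: no artifacts, light background
quiet_noise <- function(montage = default_montage(), ...) {
  noise_model(montage, blink_rate_per_min = 0, line_amp_uv = 0, ...)
}

# one fast subject at 250 Hz with clean noise
quick_subject <- function(seed = 1, effect_size = 1, rate_hz = 250,
                          schedule = short_schedule(seed),
                          montage = default_montage(),
                          noise = quiet_noise(montage), gain_jitter = 0) {
  generate_subject(schedule, class_signatures(montage, effect_size), noise,
                   montage, rate_hz = rate_hz, seed = seed,
                   gain_jitter = gain_jitter,
                   subject_id = sprintf("S%02d", seed))
}

# sine-wave test recording on the default montage channel set
sine_recording <- function(freq_hz, rate_hz = 250, dur_s = 4, amp = 1,
                           n_ch = 32) {
  m <- default_montage()
  tt <- seq_len(dur_s * rate_hz) / rate_hz
  X <- matrix(rep(amp * sin(2 * pi * freq_hz * tt), each = n_ch), n_ch)
  eeg_recording(X, rate_hz, m$electrodes$label[seq_len(n_ch)])
}

# epoch matrix (29 x n) of one sinusoid on every channel
sine_epoch <- function(freq_hz, rate_hz = 250, n = 500, amp = 1) {
  m <- default_montage()
  tt <- seq_len(n) / rate_hz
  x <- amp * sin(2 * pi * freq_hz * tt)
  matrix(rep(x, each = 29), 29,
         dimnames = list(m$feature_channels, NULL))
}

# band-limited Gaussian epochs with exactly known variance: a sum of
# integer-bin sinusoids with iid N(0, s^2) quadrature amplitudes has
# pointwise variance n_bins * s^2 and is confined to the chosen bins
bandlimited_gaussian_epoch <- function(freqs_hz, sigma2, rate_hz = 250,
                                       n = 500, n_ch = 29) {
  s <- sqrt(sigma2 / length(freqs_hz))
  tt <- seq_len(n) / rate_hz
  X <- matrix(0, n_ch, n)
  for (c in seq_len(n_ch)) {
    x <- numeric(n)
    for (f in freqs_hz)
      x <- x + rnorm(1, 0, s) * sqrt(2) * cos(2 * pi * f * tt) +
        rnorm(1, 0, s) * sqrt(2) * sin(2 * pi * f * tt)
    X[c, ] <- x / sqrt(2)
  }
  rownames(X) <- default_montage()$feature_channels
  X
}

# minimal epoch_set wrapper around an array of epochs
as_epoch_set <- function(data, class_id, rate_hz = 250,
                         subject_id = "S01") {
  n <- dim(data)[3]
  structure(list(
    data = data,
    info = data.frame(epoch_index = seq_len(n), block_index = 1L,
                      class_id = class_id,
                      video_instance = 1L, subject_id = subject_id),
    rate_hz = rate_hz,
    channel_labels = dimnames(data)[[1]] %||%
      default_montage()$feature_channels,
    window_s = dim(data)[2] / rate_hz, n_rejected = 0L),
    class = "epoch_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
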