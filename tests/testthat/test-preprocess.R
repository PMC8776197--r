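mont <- default_montage()

test_that("mastoid re-referencing subtracts the exact mastoid mean", {
  set.seed(6)
  labels <- mont$electrodes$label
  n <- 500
  X <- matrix(rnorm(32 * n), 32, dimnames = list(labels, NULL))
  o <- sin(2 * pi * 3 * seq_len(n) / 250)
  X["TP9", ] <- o
  X["TP10", ] <- o
  rec <- eeg_recording(X, 250, labels)
  out <- rereference_mastoid(rec, mont)
  expect_equal(nrow(out$samples), 30)
  expect_false(any(c("TP9", "TP10") %in% out$channel_labels))
  expect_equal(out$samples["Cz", ], X["Cz", ] - o, ignore_attr = TRUE)

  # zero mastoids leave the signal unchanged
  X0 <- X; X0["TP9", ] <- 0; X0["TP10", ] <- 0
  out0 <- rereference_mastoid(eeg_recording(X0, 250, labels), mont)
  expect_equal(out0$samples["Fz", ], X0["Fz", ], ignore_attr = TRUE)

  # all channels equal to the mastoids -> all-zero output
  Xe <- matrix(rep(o, each = 32), 32, dimnames = list(labels, NULL))
  oute <- rereference_mastoid(eeg_recording(Xe, 250, labels), mont)
  expect_equal(max(abs(oute$samples)), 0)

  expect_error(rereference_mastoid(
    eeg_recording(X[1:5, ], 250, labels[1:5]), mont), "TP9")
})

test_that("detrending removes ramps and preserves oscillations", {
  n <- 1000
  tt <- seq_len(n)
  ramp <- 0.02 * tt + 3
  s <- sin(2 * pi * 7 * tt / 250)
  X <- rbind(ramp, s + ramp)
  rec <- eeg_recording(X, 250, c("Fp1", "Fp2"))
  out <- detrend_channels(rec)
  expect_lt(max(abs(out$samples[1, ])), 1e-9)
  expect_lt(max(abs(out$samples[2, ] - (s - mean(s)))), 0.05)
})

test_that("re-referencing and detrending commute (both linear)", {
  set.seed(7)
  labels <- mont$electrodes$label
  X <- matrix(rnorm(32 * 400), 32, dimnames = list(labels, NULL))
  rec <- eeg_recording(X, 250, labels)
  a <- detrend_channels(rereference_mastoid(rec, mont))
  b <- rereference_mastoid(detrend_channels(rec), mont)
  expect_equal(a$samples, b$samples, tolerance = 1e-12)
})

test_that("downsampling halves the samples and preserves in-band sinusoids", {
  rate <- 500; n <- rate * 4
  tt <- seq_len(n) / rate
  x <- sin(2 * pi * 10 * tt)
  rec <- eeg_recording(rbind(x, x), rate, c("Fp1", "Fp2"))
  out <- resample_to(rec, 250)
  expect_equal(out$rate_hz, 250)
  expect_equal(ncol(out$samples), n / 2)
  mid <- 200:800 # away from the zero-padded edges
  ref <- sin(2 * pi * 10 * seq(1, n, by = 2)[mid] / rate)
  expect_lt(max(abs(out$samples[1, mid] - ref)), 0.01)

  expect_identical(resample_to(rec, 500), rec)
  expect_error(resample_to(rec, 1000), "upsampling")
})

test_that("band-pass keeps 10 Hz within 1 dB and kills 100 Hz by 20 dB", {
  rate <- 250; n <- rate * 8
  tt <- seq_len(n) / rate
  mk <- function(f) eeg_recording(matrix(sin(2 * pi * f * tt), 1), rate, "Cz")
  amp <- function(rec) {
    x <- rec$samples[1, (rate):(n - rate)]
    sqrt(2 * mean(x^2))
  }
  keep <- bandpass_filter(mk(10))
  expect_gt(amp(keep), 10^(-1 / 20))
  kill <- bandpass_filter(mk(100))
  expect_lt(amp(kill), 10^(-20 / 20))
  dc <- bandpass_filter(eeg_recording(matrix(5, 1, n), rate, "Cz"))
  expect_lt(max(abs(dc$samples[1, (rate):(n - rate)])), 0.05)
  expect_error(bandpass_filter(mk(10), hi = 130), "Nyquist")
})

test_that("ICA removes injected blinks and spares blink-free data", {
  m <- default_montage()
  sch <- short_schedule(8, block_s = 6, rest_s = 2)
  mk <- function(blinks) {
    nz <- noise_model(m, blink_rate_per_min = blinks, line_amp_uv = 0)
    rec <- generate_subject(sch, class_signatures(m, 0), nz, m,
                            rate_hz = 250, seed = 9, gain_jitter = 0)
    rec <- rereference_mastoid(rec, m)
    rec <- detrend_channels(rec)
    bandpass_filter(rec)
  }
  with_bl <- mk(20)
  no_bl <- mk(0)
  delta_power <- function(rec)
    band_power(rec$samples["Fp1", ], 250, 1, 4)
  excess_before <- delta_power(with_bl) - delta_power(no_bl)
  expect_gt(excess_before, 0)
  cleaned <- remove_artifacts(with_bl, "ica", seed = 2)
  expect_gte(attr(cleaned, "removed_components"), 1)
  excess_after <- delta_power(cleaned) - delta_power(no_bl)
  expect_lt(excess_after, 0.3 * excess_before)

  # blink-free input: band powers preserved within 10%
  spared <- remove_artifacts(no_bl, "ica", seed = 2)
  for (ch in c("Fp1", "Cz", "O1")) {
    for (band in list(c(8, 13), c(30, 70))) {
      p0 <- band_power(no_bl$samples[ch, ], 250, band[1], band[2])
      p1 <- band_power(spared$samples[ch, ], 250, band[1], band[2])
      expect_lt(abs(p1 / p0 - 1), 0.10)
    }
  }

  # method none is the identity
  same <- remove_artifacts(with_bl, "none")
  expect_identical(same$samples, with_bl$samples)

  # regression also reduces frontal blink power
  regr <- remove_artifacts(with_bl, "regression")
  expect_lt(delta_power(regr) - delta_power(no_bl), 0.5 * excess_before)
})

test_that("segmentation cuts 20 epochs per clean 40-s block and rejects spikes", {
  m <- default_montage()
  labels <- m$electrodes$label
  rate <- 250
  n <- 100 * rate
  set.seed(10)
  X <- matrix(rnorm(32 * n, sd = 5), 32, dimnames = list(labels, NULL))
  ann <- data.frame(onset_s = c(5, 55), duration_s = c(40, 40),
                    class_id = c(2L, 5L))
  rec <- eeg_recording(X, rate, labels, ann)
  ep <- segment_epochs(rec, m)
  expect_equal(dim(ep$data), c(29, 500, 40))
  expect_equal(as.vector(table(ep$info$class_id)), c(20L, 20L))

  # a 150 uV spike inside the third window of block 1 kills that epoch
  Xs <- X
  Xs["Cz", 5 * rate + 2.5 * rate] <- 150
  eps <- segment_epochs(eeg_recording(Xs, rate, labels, ann), m)
  expect_equal(dim(eps$data)[3], 39)
  expect_equal(eps$n_rejected, 1)
  expect_equal(sum(eps$info$class_id == 2), 19)

  # a block shorter than the window contributes nothing, with a warning
  ann2 <- data.frame(onset_s = c(5, 55), duration_s = c(1, 40),
                     class_id = c(2L, 5L))
  expect_warning(ep2 <- segment_epochs(eeg_recording(X, rate, labels, ann2), m),
                 "shorter")
  expect_equal(dim(ep2$data)[3], 20)

  # lowering the threshold never increases the epoch count
  counts <- vapply(c(Inf, 100, 20, 10, 5), function(th)
    dim(segment_epochs(rec, m, reject_uv = th)$data)[3], 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("video instances are numbered by onset within class", {
  m <- default_montage()
  rec <- quick_subject(4, schedule = short_schedule(4, block_s = 4, rest_s = 1))
  ep <- preprocess_recording(rec, m, artifact_method = "none")
  inst <- unique(ep$info[, c("class_id", "block_index", "video_instance")])
  expect_equal(as.vector(table(inst$class_id)), rep(2L, 7))
  expect_true(all(tapply(inst$video_instance, inst$class_id,
                         function(v) identical(sort(v), c(1L, 2L)))))
})
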