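mont <- default_montage()

test_that("spectrum recovers a unit sine's amplitude at its bin", {
  ep <- sine_epoch(10, amp = 1)
  sp <- epoch_spectrum(ep, 250)
  peak <- which(sp$freq == 10)
  expect_lt(abs(sp$amplitude[1, peak] - 1), 0.02)
  # all-zero epoch -> all-zero spectra
  z <- epoch_spectrum(matrix(0, 29, 500), 250)
  expect_equal(max(abs(z$amplitude)), 0)
  expect_equal(max(abs(z$power)), 0)
})

test_that("one-sided power integrates to the signal variance (Parseval)", {
  tt <- seq_len(500) / 250
  x <- 2 * sin(2 * pi * 10 * tt) + 1.2 * sin(2 * pi * 23.5 * tt) +
    0.5 * cos(2 * pi * 41 * tt)
  v <- 2^2 / 2 + 1.2^2 / 2 + 0.5^2 / 2
  sp <- epoch_spectrum(matrix(x, 1), 250)
  tot <- sum(sp$power) * (sp$freq[2] - sp$freq[1])
  expect_lt(abs(tot / v - 1), 0.01)
})

test_that("MAS matches the closed-form Hann line spectrum of a sine", {
  A <- 3
  ep <- sine_epoch(10, amp = A)
  got <- feat_mas(ep, 250, "alpha")
  # integer-bin sine under a periodic Hann taper occupies exactly 3 bins:
  # A at 10 Hz, A/2 at 9.5 and 10.5 Hz; alpha covers 8 <= f < 13 (10 bins)
  expected <- log((A + A / 2 + A / 2) / 10)
  expect_equal(unname(got), rep(expected, 29), tolerance = 1e-6)
})

test_that("log-scale features obey their scaling identities", {
  set.seed(11)
  ep <- matrix(rnorm(29 * 500), 29,
               dimnames = list(mont$feature_channels, NULL))
  c_ <- 2.7
  for (band in c("theta", "gamma")) {
    expect_equal(feat_mas(ep * c_, 250, band),
                 feat_mas(ep, 250, band) + log(c_), tolerance = 1e-9)
    expect_equal(feat_psd(ep * c_, 250, band),
                 feat_psd(ep, 250, band) + 2 * log(c_), tolerance = 1e-9)
    expect_equal(feat_de(ep * c_, 250, band),
                 feat_de(ep, 250, band) + log(c_), tolerance = 1e-6)
  }
})

test_that("PSD of white noise estimates the flat density level", {
  set.seed(12)
  sigma2 <- 4
  vals <- replicate(300, {
    ep <- matrix(rnorm(500, sd = sqrt(sigma2)), 1)
    feat_psd(ep, 250, "beta")
  })
  # log density of white noise: log(sigma^2 / (rate/2)), Jensen bias is
  # small after band-averaging 34 bins
  expect_lt(abs(mean(vals) - log(sigma2 / 125)), 0.05)
})

test_that("DE matches the Gaussian closed form on band-limited signals", {
  set.seed(13)
  sigma2 <- 9
  freqs <- seq(9, 12, by = 0.5) # interior of the alpha band
  n_rep <- 100
  des <- replicate(n_rep, {
    ep <- bandlimited_gaussian_epoch(freqs, sigma2)
    mean(feat_de(ep, 250, "alpha"))
  })
  # expected DE of the estimator: Gaussian closed form, plus the exact
  # chi-square log bias of an m-component variance estimate
  # (E[ln(chi2_2m / 2m)] = digamma(m) - ln(m)), plus the zero-phase
  # Butterworth power response |H|^4 at the component frequencies
  m <- length(freqs)
  flt <- signal::butter(4, c(8, 13) / 125, type = "pass")
  Hmag <- vapply(freqs, function(f) {
    z <- exp(-1i * 2 * pi * f / 250 * seq(0, length(flt$b) - 1))
    Mod(sum(flt$b * z) / sum(flt$a * z))
  }, 0)
  theory <- 0.5 * log(2 * pi * exp(1) * sigma2) +
    0.5 * (digamma(m) - log(m)) + 0.5 * log(mean(Hmag^4))
  se <- sd(des) / sqrt(n_rep)
  expect_lt(abs(mean(des) - theory), 3 * se)
  # zero-variance channel flags the -Inf sentinel
  z <- feat_de(matrix(0, 29, 500), 250, "alpha")
  expect_true(all(z == -Inf))
})

test_that("asymmetry features respect their exact symmetries", {
  de <- rnorm(29)
  names(de) <- mont$feature_channels
  # symmetric DE (right = left) -> DASM zero, RASM one
  de_sym <- de
  de_sym[mont$lr_pairs[, 2]] <- de_sym[mont$lr_pairs[, 1]]
  expect_equal(unname(feat_dasm(de_sym, mont)), rep(0, 13))
  expect_equal(unname(feat_rasm(de_sym, mont)), rep(1, 13))
  # swapping pair members negates DASM and inverts RASM
  de_swap <- de
  de_swap[mont$lr_pairs[, 1]] <- de[mont$lr_pairs[, 2]]
  de_swap[mont$lr_pairs[, 2]] <- de[mont$lr_pairs[, 1]]
  expect_equal(feat_dasm(de_swap, mont), -feat_dasm(de, mont),
               ignore_attr = TRUE)
  expect_equal(feat_rasm(de_swap, mont), 1 / feat_rasm(de, mont),
               ignore_attr = TRUE)
  # near-zero denominator flags NA
  de_z <- de
  de_z[mont$lr_pairs[1, 2]] <- 1e-9
  expect_true(is.na(feat_rasm(de_z, mont)[1]))
  expect_error(feat_dasm(de[1:5], mont), "missing")
})

test_that("DCAU vanishes on uniform epochs and shifts by ln c", {
  set.seed(14)
  x <- rnorm(500)
  ep <- matrix(rep(x, each = 29), 29,
               dimnames = list(mont$feature_channels, NULL))
  de <- feat_de(ep, 250, "beta")
  expect_equal(unname(feat_dcau(de, mont)), rep(0, 11))
  ep2 <- ep
  ep2[mont$fp_pairs[, 1], ] <- 2 * ep2[mont$fp_pairs[, 1], ]
  de2 <- feat_de(ep2, 250, "beta")
  expect_equal(unname(feat_dcau(de2, mont)), rep(log(2), 11),
               tolerance = 1e-9)
})

test_that("extracted tensors have the published dimensions and totals", {
  set.seed(15)
  data <- array(rnorm(29 * 500 * 21), c(29, 500, 21),
                dimnames = list(mont$feature_channels, NULL, NULL))
  ep <- as_epoch_set(data, class_id = rep(1:7, 3))
  fx <- extract_features(ep, mont)
  dims <- sapply(fx$features, function(f) sapply(f, ncol))
  expect_equal(unname(dims["delta", ]), c(29, 29, 29, 13, 13, 11))
  expect_equal(unname(dims["total", ]), c(145, 145, 145, 65, 65, 55))
  # total rows are the per-band rows concatenated in band order
  for (f in names(fx$features)) {
    joined <- do.call(cbind, fx$features[[f]][band_scheme()$band])
    expect_equal(unname(fx$features[[f]]$total), unname(joined))
  }
  expect_equal(nrow(fx$features$DE$gamma), 21)
})

test_that("per-epoch feature extraction agrees with the batched path", {
  set.seed(16)
  data <- array(rnorm(29 * 500 * 3), c(29, 500, 3),
                dimnames = list(mont$feature_channels, NULL, NULL))
  ep <- as_epoch_set(data, class_id = c(1L, 2L, 3L))
  fx <- extract_features(ep, mont)
  for (i in 1:3) {
    expect_equal(fx$features$MAS$alpha[i, ],
                 feat_mas(data[, , i], 250, "alpha"), tolerance = 1e-10)
    expect_equal(fx$features$PSD$gamma[i, ],
                 feat_psd(data[, , i], 250, "gamma"), tolerance = 1e-10)
    expect_equal(fx$features$DE$delta[i, ],
                 feat_de(data[, , i], 250, "delta"), tolerance = 1e-8)
    de <- feat_de(data[, , i], 250, "beta")
    expect_equal(fx$features$DASM$beta[i, ], feat_dasm(de, mont),
                 tolerance = 1e-8)
    expect_equal(fx$features$DCAU$beta[i, ], feat_dcau(de, mont),
                 tolerance = 1e-8)
  }
})

test_that("DE and log band power are affinely related for Gaussian signals", {
  set.seed(17)
  n_ep <- 200
  des <- numeric(n_ep); psds <- numeric(n_ep)
  for (i in seq_len(n_ep)) {
    amp <- exp(runif(1, -2, 2))
    ep <- matrix(amp * rnorm(500), 1)
    des[i] <- feat_de(ep, 250, "gamma")
    psds[i] <- feat_psd(ep, 250, "gamma")
  }
  expect_gt(cor(des, psds), 0.99)
})

test_that("the five bands tile the 1-70 Hz analysis range without overlap", {
  sc <- band_scheme()
  sp <- epoch_spectrum(matrix(rnorm(500), 1), 250)
  sel_all <- sp$freq >= 1 & sp$freq <= 70
  sel_union <- rep(FALSE, length(sp$freq))
  n_hits <- rep(0, length(sp$freq))
  for (i in seq_len(nrow(sc))) {
    s <- sp$freq >= sc$lo_hz[i] &
      (if (sc$hi_inclusive[i]) sp$freq <= sc$hi_hz[i]
       else sp$freq < sc$hi_hz[i])
    sel_union <- sel_union | s
    n_hits <- n_hits + s
  }
  expect_equal(sel_union, sel_all)
  expect_true(all(n_hits <= 1))
  # hence band powers add exactly to the 1-70 Hz total
  tot <- sum(sp$power[1, sel_all])
  expect_equal(sum(sp$power[1, sel_union]), tot)
})

test_that("feature tensors round-trip through the TSV store", {
  set.seed(18)
  data <- array(rnorm(29 * 500 * 7), c(29, 500, 7),
                dimnames = list(mont$feature_channels, NULL, NULL))
  ep <- as_epoch_set(data, class_id = 1:7)
  fx <- extract_features(ep, mont)
  p <- tempfile(fileext = ".tsv")
  write_feature_tensor(fx, p)
  expect_true(file.exists(paste0(p, ".meta.yaml")))
  back <- read_feature_tensor(p)
  for (f in names(fx$features)) for (b in c("delta", "gamma", "total"))
    expect_equal(unname(back$features[[f]][[b]]),
                 unname(fx$features[[f]][[b]]), tolerance = 1e-10)
  expect_equal(back$info$class_id, fx$info$class_id)
  expect_equal(back$meta$log_base, "natural")
})
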