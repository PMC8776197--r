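test_that("schedules have 14 non-overlapping blocks, each class twice", {
  for (seed in 0:3) {
    sch <- make_schedule(seed)
    expect_equal(nrow(sch$blocks), 14)
    expect_equal(as.vector(table(sch$blocks$class_id)), rep(2L, 7))
    ends <- sch$blocks$onset_s + sch$blocks$duration_s
    expect_true(all(diff(sch$blocks$onset_s) >= sch$blocks$duration_s[-14] +
                      sch$rest_s - 1e-9))
    expect_true(all(ends[-14] <= sch$blocks$onset_s[-1]))
  }
})

test_that("schedule order is a seeded permutation: reproducible, seed-dependent", {
  a <- make_schedule(0); b <- make_schedule(0); c <- make_schedule(1)
  expect_identical(a$blocks, b$blocks)
  expect_false(identical(a$blocks$class_id, c$blocks$class_id))
  expect_equal(sort(a$blocks$class_id), sort(c$blocks$class_id))
})

test_that("null signatures are identical across classes; gains positive", {
  m <- default_montage()
  s0 <- class_signatures(m, effect_size = 0)
  for (k in 2:7) expect_equal(s0[[k]]$gain, s0[[1]]$gain)
  s1 <- class_signatures(m)
  expect_true(all(vapply(s1, function(s) all(s$gain > 0), TRUE)))
  # classes differ only in beta/gamma
  expect_equal(s1[[1]]$gain["delta", ], s1[[7]]$gain["delta", ])
  expect_gt(mean(s1[[7]]$gain["gamma", ]), mean(s1[[1]]$gain["gamma", ]))
})

test_that("generation is bit-identical under a fixed seed", {
  sch <- short_schedule(2)
  a <- quick_subject(2, schedule = sch)
  b <- quick_subject(2, schedule = sch)
  expect_identical(a$samples, b$samples)
  expect_identical(a$annotations, b$annotations)
})

test_that("class band-power gain is realized in the generated signal", {
  m <- default_montage()
  # gain 2.0 in gamma for class 3 only, no background, no artifacts
  sig <- class_signatures(m, effect_size = 0)
  for (k in 1:7) sig[[k]]$gain[] <- 1
  sig[[3]]$gain["gamma", ] <- 2
  nz <- quiet_noise(m, background_rms_uv = 0)
  sch <- make_schedule(5) # full-length blocks: 80 s of class-3 signal
  rec <- generate_subject(sch, sig, nz, m, rate_hz = 250, seed = 7,
                          gain_jitter = 0)
  x <- rec$samples["Cz", ]
  blocks <- rec$annotations
  in3 <- blocks[blocks$class_id == 3, ]
  base <- blocks[blocks$class_id == 1, ]
  seg <- function(b) {
    idx <- unlist(lapply(seq_len(nrow(b)), function(i)
      (floor(b$onset_s[i] * 250) + 1):floor((b$onset_s[i] + b$duration_s[i]) * 250)))
    x[idx]
  }
  p3 <- band_power(seg(in3), 250, 30, 70, hi_inclusive = TRUE)
  p1 <- band_power(seg(base), 250, 30, 70, hi_inclusive = TRUE)
  expect_gt(p3 / p1, 2 * 0.85)
  expect_lt(p3 / p1, 2 * 1.15)
})

test_that("blink transients land on frontopolar channels at the injected times", {
  m <- default_montage()
  nz <- noise_model(m, blink_rate_per_min = 12, line_amp_uv = 0,
                    background_rms_uv = 5)
  sch <- short_schedule(3)
  rec <- generate_subject(sch, class_signatures(m, 0), nz, m,
                          rate_hz = 250, seed = 3)
  on <- rec$artifacts$blink_onsets_s
  expect_gte(length(on), qpois(0.005, 12 / 60 * sch$total_s))
  fp1 <- rec$samples["Fp1", ]
  bg_sd <- sd(rec$samples["Pz", ]) # posterior channel: background only
  hits <- vapply(on, function(o) {
    idx <- (floor(o * 250) + 1):min(length(fp1), floor((o + 0.4) * 250))
    max(fp1[idx]) > 3 * bg_sd
  }, TRUE)
  expect_true(all(hits))
})

test_that("generate_dataset yields per-subject randomized, reproducible recordings", {
  m <- default_montage()
  args <- list(n_subjects = 2, base_seed = 11, montage = m,
               signatures = class_signatures(m), noise = quiet_noise(m),
               rate_hz = 250, gain_jitter = 0,
               schedule_args = list(block_s = 4, rest_s = 2, lead_s = 1))
  d1 <- do.call(generate_dataset, args)
  d2 <- do.call(generate_dataset, args)
  expect_length(d1, 2)
  expect_identical(d1[[1]]$samples, d2[[1]]$samples)
  expect_identical(d1[[2]]$samples, d2[[2]]$samples)
  expect_false(identical(d1[[1]]$annotations$class_id,
                         d1[[2]]$annotations$class_id))
  # callback streaming returns the callback results
  ids <- do.call(generate_dataset,
                 c(args, list(callback = function(rec, i) rec$subject_id)))
  expect_equal(unlist(ids), c("S01", "S02"))
})
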