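test_that("gap interpolation recovers linear structure and respects edges", {
  expect_equal(interpolate_missing(c(0, NA, 2)), c(0, 1, 2))

  ramp <- as.numeric(0:186)
  gap <- ramp; gap[60:80] <- NA
  expect_equal(interpolate_missing(gap), ramp)

  edge <- c(NA, NA, 5, 6, 7, NA)
  expect_equal(interpolate_missing(edge), c(5, 5, 5, 6, 7, 7))
  expect_equal(interpolate_missing(edge, kind = "cubic")[1:2], c(5, 5))

  expect_error(interpolate_missing(rep(NA_real_, 10)), "unrecoverable")
})

test_that("baseline removal suppresses drift but preserves beat shape", {
  fs <- 125
  t <- (0:1249) / fs
  drift <- 0.5 * sin(2 * pi * 0.3 * t)
  resid <- remove_baseline_drift(drift, fs)
  expect_lt(sqrt(mean(resid^2)), 0.1 * sqrt(mean(drift^2)))

  expect_equal(remove_baseline_drift(numeric(187), fs), numeric(187))

  beat <- generate_beat(0, 187, seed = 3)
  drift187 <- 0.3 * sin(2 * pi * 0.3 * (0:186) / fs + 1)
  cleaned <- remove_baseline_drift(beat + drift187, fs)
  expect_gte(cor(cleaned, beat), 0.95)

  expect_error(remove_baseline_drift(numeric(10), fs, window_long = 2),
               "exceeds beat length")
})

test_that("the notch filter rejects its target and passes DC and mid-band", {
  fs <- 250
  t <- (0:2499) / fs
  target <- sin(2 * pi * 50 * t)
  out <- notch_filter(target, fs, 50, 30)
  expect_lte(sqrt(mean(out^2)), 0.1 * sqrt(mean(target^2)))

  dc <- rep(2.5, 400)
  expect_lt(max(abs(notch_filter(dc, fs, 50, 30) - dc)), 1e-6)

  half <- sin(2 * pi * 25 * t)
  atten_db <- -20 * log10(sd(notch_filter(half, fs, 50, 30)) / sd(half))
  expect_lt(atten_db, 3)

  expect_error(notch_filter(c(1, NA, 2), fs), "finite")
  expect_error(notch_filter(numeric(100), 125, notch_freq = 70), "Nyquist")
})

test_that("wavelet transform reconstructs perfectly at zero threshold", {
  set.seed(2)
  for (len in c(187, 256, 200)) {
    x <- rnorm(len)
    expect_lt(max(abs(wavelet_denoise(x, threshold = 0) - x)), 1e-8)
  }
  expect_equal(wavelet_denoise(numeric(64)), numeric(64))
  expect_error(wavelet_denoise(numeric(8), levels = 4), "levels")
})

test_that("wavelet shrinkage reduces error on a noisy smooth signal", {
  set.seed(4)
  clean <- sin(2 * pi * 3 * (0:255) / 256)
  noisy <- clean + rnorm(256, 0, 0.2)
  denoised <- wavelet_denoise(noisy)
  expect_lt(mean((denoised - clean)^2), mean((noisy - clean)^2))
})

test_that("z-normalisation matches hand arithmetic and is idempotent", {
  z <- znormalize_beat(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  expect_equal(round(z, 4), c(-1.2247, 0, 1.2247))
  expect_equal(znormalize_beat(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(znormalize_beat(z), z, tolerance = 1e-9)
  b <- znormalize_beat(generate_beat(2, seed = 1))
  expect_lt(abs(mean(b)), 1e-9)
  expect_lt(abs(sqrt(mean((b - mean(b))^2)) - 1), 1e-9)
})

test_that("disabled stages make the pipeline an identity and errors name the beat", {
  d <- clean_beat_set(2, seed = 6)
  cfg_off <- denoise_config(stages = c(interpolate = FALSE, baseline = FALSE,
                                       notch = FALSE, wavelet = FALSE),
                            znormalize = FALSE)
  expect_identical(denoise_beats(d$beats, d$masks, cfg_off), d$beats)

  bad <- d$beats
  bad[3, 5] <- NA
  expect_error(denoise_beats(bad, config = cfg_off), "beat 3")
})

test_that("full denoising barely distorts clean beats", {
  d <- clean_beat_set(4, seed = 8)
  out <- denoise_beats(d$beats, d$masks,
                       denoise_config(znormalize = FALSE))
  for (i in seq_len(nrow(out)))
    expect_gte(cor(out[i, ], d$beats[i, ]), 0.99)
  expect_true(all(is.finite(out)))
  expect_identical(dim(out), dim(d$beats))
})

test_that("denoising strictly reduces error on fully contaminated data", {
  spec <- noise_spec(gaussian_sigma = 0.15, baseline_amplitude = 0.4,
                     baseline_freq = 0.3, powerline_amplitude = 0.2,
                     powerline_freq = 50, motion_burst_rate = 0.3,
                     motion_amplitude = 0.3, contact_loss_prob = 0.2,
                     gap_length = 10)
  n <- 50
  clean <- t(sapply(1:n, function(i) generate_beat((i - 1) %% 5, seed = i)))
  noisy <- clean
  masks <- matrix(FALSE, n, 187)
  for (i in 1:n) {
    nz <- apply_noise(clean[i, ], spec, 125, seed = 500 + i)
    noisy[i, ] <- nz$beat
    masks[i, ] <- nz$mask
  }
  out <- denoise_beats(noisy, masks, denoise_config(znormalize = FALSE))
  zero_filled <- noisy; zero_filled[is.na(zero_filled)] <- 0
  mse_before <- mean((zero_filled - clean)^2)
  mse_after <- mean((out - clean)^2)
  expect_lt(mse_after, mse_before)
})
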