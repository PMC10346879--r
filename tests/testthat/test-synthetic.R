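test_that("generated clips are seed-deterministic and respect the DC/AC model", {
  spec <- synthetic_spec(hr_bpm = 72, seed = 11L)
  a <- generate_clip(spec)
  b <- generate_clip(spec)
  expect_identical(a$series$values, b$series$values)
  expect_identical(a$truth, rep(72, 600))

  # channel means sit at the configured DC within the noise allowance
  T <- n_frames(a$series)
  for (ch in spec$channels) {
    tol <- 3 * spec$noise_sd * spec$dc[ch] / sqrt(T) +
      spec$dc[ch] * (spec$drift_amp + spec$n_spikes * spec$spike_amp * 2 / T)
    expect_lt(abs(mean(a$series$values[ch, ]) - spec$dc[ch]), tol)
  }
  expect_identical(rownames(a$series$values), c("R", "G", "B", "NIR"))
})

test_that("the clean pulsatile part peaks exactly at the heart-rate bin", {
  # 72 bpm = 1.2 Hz is a bin centre for a 20 s window at 30 Hz
  spec <- synthetic_spec(hr_bpm = 72, n_spikes = 0, drift_amp = 0,
                         noise_sd = 0, seed = 1L)
  clip <- generate_clip(spec)
  S <- compute_psd(clip$series)
  for (ch in spec$channels) {
    pk <- which.max(S$psd[ch, ])
    expect_equal(S$freqs[pk], 1.2)
    # DC-normalised cosine of amplitude a gives a bin of height ~a/2
    expect_equal(unname(S$psd[ch, pk]), spec$rel_amp[[ch]] / 2, tolerance = 1e-6)
  }
})

test_that("spec validation rejects non-physiological settings", {
  expect_error(synthetic_spec(hr_bpm = 200), "hr_bpm")
  expect_error(synthetic_spec(hr_bpm = 100, fs = 3), "fs")
})

test_that("dark mode halves DC and raises only the RGB noise floor", {
  base <- synthetic_spec(hr_bpm = 80, n_spikes = 0, drift_amp = 0, seed = 5L)
  dark <- synthetic_spec(hr_bpm = 80, n_spikes = 0, drift_amp = 0, seed = 5L,
                         dark = TRUE)
  a <- generate_clip(base)$series
  b <- generate_clip(dark)$series
  expect_equal(mean(b$values["G", ]) / mean(a$values["G", ]), 0.5,
               tolerance = 0.02)
  rel_noise <- function(x) stats::sd(x) / mean(x)
  expect_gt(rel_noise(b$values["B", ]), 5 * rel_noise(a$values["B", ]))
  # NIR noise unchanged relative to its (halved) DC
  expect_equal(rel_noise(b$values["NIR", ]), rel_noise(a$values["NIR", ]),
               tolerance = 0.5)
})

test_that("interference tones appear at the requested frequencies and channels", {
  tones <- list(list(hz = 3.0, amp = c(NIR = 0.01)))
  spec <- synthetic_spec(hr_bpm = 72, n_spikes = 0, drift_amp = 0,
                         noise_sd = 0, interf = tones, seed = 2L)
  S <- compute_psd(generate_clip(spec)$series)
  bin3 <- which.min(abs(S$freqs - 3.0))
  expect_equal(unname(S$psd["NIR", bin3]), 0.005, tolerance = 1e-6)
  expect_lt(S$psd["G", bin3], 1e-8)
})

test_that("toy frames reproduce the clip series under the face-disk mask", {
  spec <- synthetic_spec(hr_bpm = 72, duration_s = 1, seed = 3L)
  fr <- generate_frames(spec, size = c(32, 32), nir_size = c(24, 24))
  # background is static over time
  bg <- sapply(fr$rgb$frames, function(f) f[1, 1, 1])
  expect_true(all(bg == bg[1]))
  # disk mean equals the generated channel value
  f1 <- fr$rgb$frames[[5]]
  disk <- f1[, , 2] != f1[1, 1, 2]
  expect_equal(mean(f1[, , 2][disk]), unname(fr$clip$series$values["G", 5]),
               tolerance = 1e-9)
  nir5 <- fr$nir$frames[[5]]
  diskn <- nir5 != nir5[1, 1]
  expect_equal(mean(nir5[diskn]), unname(fr$clip$series$values["NIR", 5]),
               tolerance = 1e-9)
})
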