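test_that("the DC-normalised amplitude spectrum has the closed-form tone height", {
  fs <- 30; T <- 600
  tt <- (seq_len(T) - 1) / fs
  vals <- rbind(100 * (1 + 0.001 * cos(2 * pi * 1.2 * tt)),
                matrix(50, 2, T))   # constant G and B rows
  C <- channel_series(vals, fs = fs)
  S <- compute_psd(C)
  pk <- which.max(S$psd["R", ])
  expect_equal(S$freqs[pk], 1.2)
  expect_equal(unname(S$psd["R", pk]), 0.0005, tolerance = 1e-9)  # a/2
  expect_lt(max(S$psd["R", -pk]), 1e-12)
  # constant channels have an all-zero AC spectrum
  expect_lt(max(S$psd["G", ]), 1e-12)
  expect_equal(S$psd[, 1], c(R = 0, G = 0, B = 0))  # DC bin zeroed
})

test_that("the amplitude spectrum is invariant to channel gain and errors on zero mean", {
  C <- clean_clip()
  S1 <- compute_psd(C)
  C2 <- channel_series(C$values * c(2, 1, 1, 1), fs = C$fs, labels = C$labels)
  S2 <- compute_psd(C2)
  expect_equal(S1$psd, S2$psd, tolerance = 1e-12)

  vals <- C$values
  vals[2, ] <- vals[2, ] - mean(vals[2, ])
  expect_error(compute_psd(channel_series(vals, fs = 30, labels = C$labels)),
               "G")
})

test_that("the blue-restriction inequality gates bins as specified", {
  # P_B = 3 > 1.25 * (P_R + P_G) = 2.5 at one bin: that bin is suppressed
  fs <- 30; T <- 300
  tt <- (seq_len(T) - 1) / fs
  tone <- function(a) 100 * (1 + a * sin(2 * pi * 1.5 * tt))
  C <- channel_series(rbind(tone(2e-3), tone(2e-3), tone(6e-3)), fs = fs)
  S <- compute_psd(C)
  w <- 1e-4
  Chat <- masf_filter(S, masf_config(suppression_weight = w), "rgb_only")
  expect_equal(attr(Chat, "n_suppressed"), 1L)
  Shat <- compute_psd(Chat)
  bin <- which.min(abs(S$freqs - 1.5))
  for (ch in 1:3)
    expect_equal(unname(Shat$psd[ch, bin] / S$psd[ch, bin]), w, tolerance = 1e-3)
})

test_that("a clean clip passes the gate untouched", {
  C <- clean_clip()          # NIR peak 3e-4 <= alpha, blue <= 1.25 (R + G)
  S <- compute_psd(C)
  Chat <- masf_filter(S, masf_config(), "dual")
  expect_equal(attr(Chat, "n_suppressed"), 0L)
  expect_equal(Chat$values, C$values, tolerance = 1e-9)
})

test_that("an NIR spike above alpha suppresses that bin in every channel", {
  spec <- synthetic_spec(hr_bpm = 72, n_spikes = 0, drift_amp = 0,
                         noise_sd = 0, seed = 1L,
                         interf = list(list(hz = 3.0, amp = c(NIR = 0.01))))
  C <- generate_clip(spec)$series
  S <- compute_psd(C)
  w <- 1e-4
  Chat <- masf_filter(S, masf_config(suppression_weight = w), "dual")
  Shat <- compute_psd(Chat)
  bin <- which.min(abs(S$freqs - 3.0))
  expect_equal(unname(Shat$psd["NIR", bin] / S$psd["NIR", bin]), w, tolerance = 1e-3)
  # the heart-rate bin survives unchanged
  hrbin <- which.min(abs(S$freqs - 1.2))
  expect_equal(unname(Shat$psd["G", hrbin]), unname(S$psd["G", hrbin]), tolerance = 1e-9)
  # rgb_only mode ignores the NIR ceiling entirely
  Cr <- masf_filter(S, masf_config(suppression_weight = w), "rgb_only")
  expect_equal(attr(Cr, "n_suppressed"), 0L)
  expect_equal(Cr$values, C$values, tolerance = 1e-9)
})

test_that("filter output is real, never amplified, and identity at weight 1", {
  spec <- synthetic_spec(hr_bpm = 90, seed = 9L, dark = TRUE,
                         interf = list(list(hz = 2.2, amp = c(NIR = 0.02)))
                         )
  C <- generate_clip(spec)$series
  S <- compute_psd(C)
  Chat <- masf_filter(S, masf_config(), "dual")
  expect_true(all(is.finite(Chat$values)))
  Shat <- compute_psd(Chat)
  expect_true(all(Shat$psd <= compute_psd(C)$psd * (1 + 1e-9) + 1e-15))
  # weight -> 1 is the identity up to transform round-off
  Cid <- masf_filter(S, masf_config(suppression_weight = 1 - 1e-12), "dual")
  expect_equal(Cid$values, C$values, tolerance = 1e-8)
})

test_that("alpha defaults follow the window-length rule and ASF gates on the R channel", {
  cfg <- masf_config()
  expect_equal(dmhre:::resolve_alpha(cfg, 10), 0.004)
  expect_equal(dmhre:::resolve_alpha(cfg, 20), 0.003)
  # R-channel tone above the ASF ceiling is suppressed by the baseline filter
  spec <- synthetic_spec(hr_bpm = 72, n_spikes = 0, drift_amp = 0,
                         noise_sd = 0, seed = 1L,
                         interf = list(list(hz = 2.5, amp = c(R = 0.006))))
  S <- compute_psd(generate_clip(spec)$series)
  Chat <- asf_filter(S, masf_config(suppression_weight = 1e-4))
  bin <- which.min(abs(S$freqs - 2.5))
  expect_equal(unname(compute_psd(Chat)$psd["R", bin] / S$psd["R", bin]), 1e-4,
               tolerance = 1e-3)
  # but an NIR-only tone is invisible to ASF
  spec2 <- synthetic_spec(hr_bpm = 72, n_spikes = 0, drift_amp = 0,
                          noise_sd = 0, seed = 1L,
                          interf = list(list(hz = 2.5, amp = c(NIR = 0.01))))
  S2 <- compute_psd(generate_clip(spec2)$series)
  expect_equal(attr(asf_filter(S2, masf_config()), "n_suppressed"), 0L)
})
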