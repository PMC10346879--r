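# Shared fixture builders for the test suite.

# A clean 4-channel cosine clip: every channel carries the same pure tone at
# hr_bpm with per-channel AC/DC amplitude, no noise/spikes/drift.
clean_clip <- function(hr_bpm = 72, fs = 30, duration_s = 20,
                       rel_amp = c(R = 5e-4, G = 1e-3, B = 7e-4, NIR = 6e-4),
                       dc = c(R = 120, G = 140, B = 110, NIR = 100)) {
  tt <- (seq_len(round(duration_s * fs)) - 1) / fs
  tone <- cos(2 * pi * hr_bpm / 60 * tt)
  vals <- sapply(names(dc), function(ch) dc[ch] * (1 + rel_amp[ch] * tone))
  channel_series(t(vals), fs = fs, labels = names(dc))
}

# Uniform-colour RGB frame stack.
uniform_rgb_frames <- function(rgb, n = 3, h = 16, w = 16, fps = 30) {
  fr <- array(0, c(h, w, 3))
  for (p in 1:3) fr[, , p] <- rgb[p]
  frame_sequence(replicate(n, fr, simplify = FALSE), fps = fps,
                 modality = "RGB")
}
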