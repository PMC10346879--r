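test_that("the brightness detector recovers a planted square exactly", {
  fr <- matrix(5, 64, 64)
  fr[11:50, 11:50] <- 200          # 40x40 square with top-left (10,10) 0-based
  seq <- frame_sequence(replicate(4, fr, simplify = FALSE), fps = 30,
                        modality = "NIR")
  boxes <- locate_roi(seq, detector_brightness())
  # brute-force oracle: extent of thresholded pixels
  on <- which(fr > (5 + 200) / 2, arr.ind = TRUE)
  expect_equal(boxes[[1]]$x, min(on[, 2]) - 1L)
  expect_equal(boxes[[1]]$y, min(on[, 1]) - 1L)
  expect_equal(boxes[[1]]$H, diff(range(on[, 1])) + 1L)
  expect_equal(boxes[[1]]$W, diff(range(on[, 2])) + 1L)
  # identity carry-forward: every frame gets the frame-1 box
  expect_true(all(vapply(boxes, identical, logical(1), boxes[[1]])))
})

test_that("a detector that finds no face in frame 1 is a hard error", {
  blank <- frame_sequence(list(matrix(0, 8, 8), matrix(0, 8, 8)), fps = 30,
                          modality = "NIR")
  expect_error(locate_roi(blank, function(f) NULL), "NIR")
})

test_that("tracker failures carry the previous box forward with a warning", {
  fr <- matrix(0, 16, 16); fr[5:8, 5:8] <- 250
  seq <- frame_sequence(replicate(3, fr, simplify = FALSE), fps = 30,
                        modality = "NIR")
  flaky <- function(prev, frame) NULL
  expect_warning(boxes <- locate_roi(seq, detector_brightness(), flaky),
                 "carried forward")
  expect_identical(boxes[[3]], boxes[[1]])
})

test_that("skin rules classify chroma and brightness as published", {
  # a skin-tone uniform patch satisfies the YCbCr box everywhere
  skin <- uniform_rgb_frames(c(150, 100, 80))$frames[[1]]
  expect_equal(skin_mask(skin, "rgb_rule")$coverage, 1.0)
  # pure blue: Cb = 255 far outside [77, 127]
  blue <- uniform_rgb_frames(c(0, 0, 255))$frames[[1]]
  expect_warning(m <- skin_mask(blue, "rgb_rule"), "zero coverage")
  expect_equal(m$coverage, 0.0)
  # Otsu on a half-bright/half-dark patch keeps the brighter half
  gray <- cbind(matrix(40, 8, 4), matrix(200, 8, 4))
  expect_equal(skin_mask(gray, "gray_rule")$coverage, 0.5)
})

test_that("masked channel means match a per-pixel loop oracle", {
  set.seed(42)
  T <- 5
  frames <- replicate(T, array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3)),
                      simplify = FALSE)
  rgb <- frame_sequence(frames, fps = 30, modality = "RGB")
  rois <- list(rgb = replicate(T, roi_box(1, 2, 5, 6), simplify = FALSE))
  masks <- list(rgb = lapply(1:T, function(t)
    skin_mask(array(0, c(5, 6, 3)), "external",
              fn = function(r) matrix(runif(30) > 0.5, 5, 6))))
  cs <- extract_channel_series(rgb, rois = rois, masks = masks)
  for (t in 1:T) {
    roi <- frames[[t]][3:7, 2:7, , drop = FALSE]
    mk <- masks$rgb[[t]]$mask
    for (p in 1:3) {
      acc <- 0; cnt <- 0
      for (i in 1:5) for (j in 1:6) if (mk[i, j]) {
        acc <- acc + roi[i, j, p]; cnt <- cnt + 1
      }
      expect_equal(unname(cs$values[p, t]), acc / cnt, tolerance = 1e-12)
    }
  }
  # pixels outside the mask (or outside the ROI) are irrelevant
  frames2 <- frames
  frames2[[1]][3:7, 2:7, ][!array(masks$rgb[[1]]$mask, c(5, 6, 3))] <- 0
  frames2[[2]][1, , ] <- 0               # outside the ROI entirely
  cs2 <- extract_channel_series(
    frame_sequence(frames2, fps = 30, modality = "RGB"),
    rois = rois, masks = masks)
  expect_equal(cs2$values[, 1], cs$values[, 1])
  expect_equal(cs2$values[, 2], cs$values[, 2])
})

test_that("uniform frames with full masks give constant channel rows", {
  rgb <- uniform_rgb_frames(c(100, 150, 200), n = 3)
  rois <- list(rgb = replicate(3, roi_box(0, 0, 16, 16), simplify = FALSE))
  cs <- extract_channel_series(rgb, rois = rois)
  expect_equal(unname(cs$values),
               matrix(rep(c(100, 150, 200), 3), 3), tolerance = 1e-12)
})

test_that("modality mismatches in frame count are hard errors", {
  rgb <- uniform_rgb_frames(c(100, 100, 100), n = 3)
  nir <- frame_sequence(replicate(2, matrix(90, 16, 16), simplify = FALSE),
                        fps = 30, modality = "NIR")
  rois <- list(rgb = replicate(3, roi_box(0, 0, 16, 16), simplify = FALSE),
               nir = replicate(2, roi_box(0, 0, 16, 16), simplify = FALSE))
  expect_error(extract_channel_series(rgb, nir, rois), "frame count")
})

test_that("frames in, heart rate out: the frontend feeds the full pipeline", {
  spec <- synthetic_spec(hr_bpm = 72, n_spikes = 0, drift_amp = 0,
                         noise_sd = 1e-4, seed = 31L)
  fr <- generate_frames(spec, size = c(32, 32), nir_size = c(24, 24))
  cs <- frontend_series(fr$rgb, fr$nir, skin_mode = "gray_rule")
  expect_equal(n_frames(cs), 600)
  est <- run_window(cs)
  expect_lte(abs(est$bpm - 72), 3)
})
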