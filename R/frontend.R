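#' Frame sequence container
#'
#' @param frames list of frames: `h x w` matrices for NIR, `h x w x 3` arrays
#'   for RGB, 8-bit intensity range `[0, 255]`.
#' @param fps frames per second, Hz.
#' @param modality `"RGB"` or `"NIR"`.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps, modality = c("RGB", "NIR")) {
  modality <- match.arg(modality)
  if (!length(frames)) stop("frame sequence is empty")
  if (fps <= 0) stop("fps must be positive")
  dims <- dim(frames[[1L]])
  for (f in frames) {
    if (!identical(dim(f)[1:2], dims[1:2]))
      stop("all frames must share one height/width")
    if (min(f) < 0 || max(f) > 255)
      stop("pixel values must lie within [0, 255]")
  }
  if (modality == "RGB" && (length(dims) != 3L || dims[3L] != 3L))
    stop("RGB frames must be h x w x 3 arrays")
  if (modality == "NIR" && length(dims) != 2L)
    stop("NIR frames must be h x w matrices")
  structure(list(frames = frames, fps = fps, modality = modality),
            class = "frame_sequence")
}

#' Region-of-interest box
#'
#' 0-based, row-major, half-open: pixels `[y, y+H) x [x, x+W)`.
#'
#' @param x,y top-left pixel (0-based column/row).
#' @param H,W box height and width in pixels, `> 0`.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(x, y, H, W) {
  if (H <= 0 || W <= 0) stop("roi_box needs H > 0 and W > 0")
  if (x < 0 || y < 0) stop("roi_box coordinates are 0-based and nonnegative")
  structure(list(x = as.integer(x), y = as.integer(y),
                 H = as.integer(H), W = as.integer(W)), class = "roi_box")
}

frame_gray <- function(frame) {
  if (length(dim(frame)) == 3L) (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3
  else frame
}

crop_roi <- function(frame, box) {
  rows <- (box$y + 1L):(box$y + box$H)
  cols <- (box$x + 1L):(box$x + box$W)
  if (max(rows) > dim(frame)[1L] || max(cols) > dim(frame)[2L])
    stop("roi_box extends outside the frame")
  if (length(dim(frame)) == 3L) frame[rows, cols, , drop = FALSE]
  else frame[rows, cols, drop = FALSE]
}

#' Brightness-blob face detector
#'
#' A trained-model-free detector for synthetic or controlled footage: it
#' thresholds the gray frame and returns the bounding box of the
#' above-threshold pixels. Real deployments plug in an external face
#' detector/tracker behind the same function contract
#' (`function(frame) -> roi_box or NULL`).
#'
#' @param threshold gray-level threshold; default halfway between the frame
#'   minimum and maximum.
#' @return A detector function.
#' @export
detector_brightness <- function(threshold = NULL) {
  function(frame) {
    g <- frame_gray(frame)
    thr <- if (is.null(threshold)) (min(g) + max(g)) / 2 else threshold
    on <- which(g > thr, arr.ind = TRUE)
    if (!nrow(on)) return(NULL)
    y0 <- min(on[, 1]) - 1L; y1 <- max(on[, 1])
    x0 <- min(on[, 2]) - 1L; x1 <- max(on[, 2])
    roi_box(x = x0, y = y0, H = y1 - y0, W = x1 - x0)
  }
}

#' Locate the face ROI on every frame
#'
#' The detector runs on frame 1 only; subsequent frames are handed to the
#' tracker (`function(prev_box, frame) -> roi_box or NULL`). A `NULL`
#' tracker — and any frame where the tracker fails — carries the previous
#' box forward (with one warning per sequence on failure).
#'
#' @param seq a [frame_sequence()].
#' @param detector detector function for frame 1.
#' @param tracker optional tracker function.
#' @return List of [roi_box()], one per frame.
#' @export
locate_roi <- function(seq, detector, tracker = NULL) {
  stopifnot(inherits(seq, "frame_sequence"))
  box <- detector(seq$frames[[1L]])
  if (is.null(box))
    stop("no face found in frame 1 of the ", seq$modality, " stream")
  boxes <- vector("list", length(seq$frames))
  boxes[[1L]] <- box
  failed <- FALSE
  for (t in seq_along(seq$frames)[-1L]) {
    nxt <- if (is.null(tracker)) NULL else tracker(box, seq$frames[[t]])
    if (is.null(nxt)) {
      if (!is.null(tracker)) failed <- TRUE
      nxt <- box                        # carry the previous box forward
    }
    box <- nxt
    boxes[[t]] <- box
  }
  if (failed)
    warning("tracker failed on some ", seq$modality,
            " frames; previous ROI carried forward")
  boxes
}

#' Skin mask for a ROI crop
#'
#' `rgb_rule` applies the published YCbCr skin-chroma box
#' (Cb in \[77, 127\], Cr in \[133, 173\], BT.601 from 8-bit RGB);
#' `gray_rule` thresholds at the Otsu level and keeps the brighter class;
#' `external` accepts any user-supplied mask function
#' (`function(roi) -> logical matrix`). Zero coverage triggers a warning;
#' callers fall back to the full-ROI mask.
#'
#' @param frame_roi a cropped ROI (`h x w` matrix or `h x w x 3` array).
#' @param mode masking rule.
#' @param fn mask function for `mode = "external"`.
#' @return An object of class `skin_mask`: list with logical `mask` and
#'   scalar `coverage` in `[0, 1]`.
#' @export
skin_mask <- function(frame_roi, mode = c("rgb_rule", "gray_rule", "external"),
                      fn = NULL) {
  mode <- match.arg(mode)
  if (!length(frame_roi)) stop("empty ROI")
  mask <- switch(mode,
    rgb_rule = {
      if (length(dim(frame_roi)) != 3L)
        stop("rgb_rule needs an RGB ROI")
      R <- frame_roi[, , 1]; G <- frame_roi[, , 2]; B <- frame_roi[, , 3]
      Cb <- 128 - 0.168736 * R - 0.331264 * G + 0.5 * B
      Cr <- 128 + 0.5 * R - 0.418688 * G - 0.081312 * B
      Cb >= 77 & Cb <= 127 & Cr >= 133 & Cr <= 173
    },
    gray_rule = {
      g <- frame_gray(frame_roi)
      if (max(g) - min(g) < sqrt(.Machine$double.eps)) {
        matrix(TRUE, nrow(g), ncol(g))   # flat ROI: nothing to split
      } else {
        thr <- EBImage::otsu(EBImage::as.Image(g / 255)) * 255
        g > thr
      }
    },
    external = {
      if (!is.function(fn)) stop("external mode needs a mask function fn")
      m <- fn(frame_roi)
      storage.mode(m) <- "logical"
      m
    })
  cov <- mean(mask)
  if (cov == 0)
    warning("skin mask has zero coverage; callers should fall back to the full ROI")
  structure(list(mask = mask, coverage = cov), class = "skin_mask")
}

masked_mean <- function(roi, mask) {
  if (is.null(mask) || !any(mask)) mask <- array(TRUE, dim(roi)[1:2])
  if (length(dim(roi)) == 3L)
    vapply(1:3, function(p) mean(roi[, , p][mask]), numeric(1))
  else
    mean(roi[mask])
}

#' Spatially average ROIs into a channel time series
#'
#' Each frame's ROI is cropped, the skin mask applied, and the surviving
#' pixels averaged per channel, yielding the `k x T` matrix of channel means
#' (rows ordered R, G, B, then NIR when present). RGB and NIR streams are
#' processed independently; no spatial registration is attempted.
#'
#' @param rgb RGB [frame_sequence()].
#' @param nir optional NIR [frame_sequence()]; must match `rgb` in frame
#'   count and fps (temporal sync is assumed).
#' @param rois list with `rgb` (and `nir`) elements: per-frame [roi_box()]
#'   lists as returned by [locate_roi()].
#' @param masks optional list with `rgb`/`nir` per-frame [skin_mask()]
#'   lists; `NULL` means full-ROI masks.
#' @return A [channel_series()].
#' @export
extract_channel_series <- function(rgb, nir = NULL, rois, masks = NULL) {
  stopifnot(inherits(rgb, "frame_sequence"))
  T <- length(rgb$frames)
  if (!is.null(nir)) {
    if (length(nir$frames) != T)
      stop("RGB and NIR streams differ in frame count (",
           T, " vs ", length(nir$frames), ")")
    if (nir$fps != rgb$fps)
      stop("RGB and NIR streams differ in fps")
  }
  get_mask <- function(ms, t) if (is.null(ms)) NULL else ms[[t]]$mask
  vals <- matrix(0, if (is.null(nir)) 3L else 4L, T)
  for (t in seq_len(T)) {
    roi <- crop_roi(rgb$frames[[t]], rois$rgb[[t]])
    vals[1:3, t] <- masked_mean(roi, get_mask(masks$rgb, t))
    if (!is.null(nir)) {
      roin <- crop_roi(nir$frames[[t]], rois$nir[[t]])
      vals[4L, t] <- masked_mean(roin, get_mask(masks$nir, t))
    }
  }
  channel_series(vals, fs = rgb$fps)
}

#' One-call frontend: frames in, channel series out
#'
#' Chains [locate_roi()], [skin_mask()] and [extract_channel_series()] on
#' the RGB (and optional NIR) streams.
#'
#' @inheritParams extract_channel_series
#' @param detector face detector, see [locate_roi()].
#' @param tracker optional tracker.
#' @param skin_mode masking rule per stream, see [skin_mask()]; NIR streams
#'   always use gray-level rules.
#' @return A [channel_series()].
#' @export
frontend_series <- function(rgb, nir = NULL, detector = detector_brightness(),
                            tracker = NULL, skin_mode = "gray_rule") {
  rois <- list(rgb = locate_roi(rgb, detector, tracker))
  masks <- list(rgb = lapply(seq_along(rgb$frames), function(t)
    skin_mask(crop_roi(rgb$frames[[t]], rois$rgb[[t]]), skin_mode)))
  if (!is.null(nir)) {
    rois$nir <- locate_roi(nir, detector, tracker)
    masks$nir <- lapply(seq_along(nir$frames), function(t)
      skin_mask(crop_roi(nir$frames[[t]], rois$nir[[t]]), "gray_rule"))
  }
  extract_channel_series(rgb, nir, rois, masks)
}
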