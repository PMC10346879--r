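#' Assemble the fusion matrix M from a filtered channel series
#'
#' In the default `ab_nir` mode the filtered R/G/B rows are converted
#' per-sample to CIELab (sRGB companding, D65 white, 8-bit values scaled to
#' `[0, 1]`), the luminance `L*` is discarded, and the `(a*, b*)` chroma
#' rows are stacked with the NIR row to form the `3 x T` matrix `M`.
#' Chroma carries the haemoglobin pulse while dropping the
#' illumination-dominated luminance; working with three rows instead of
#' four also trims the downstream cost. The NIR row is DC-normalised and
#' mean-removed before stacking so the three rows live on comparable
#' scales. `rgb_nir` and `rgb` modes pass the rows through unchanged
#' (4 x T and 3 x T respectively).
#'
#' @param Chat filtered [channel_series()] (output of [masf_filter()]).
#' @param mode fusion mode.
#' @return A [channel_series()] with labels `(a, b, NIR)`, `(R,G,B,NIR)`,
#'   or `(R,G,B)` by mode.
#' @export
assemble_M <- function(Chat, mode = c("ab_nir", "rgb_nir", "rgb")) {
  mode <- match.arg(mode)
  stopifnot(inherits(Chat, "channel_series"))
  k <- nrow(Chat$values)
  if (mode %in% c("ab_nir", "rgb_nir") && k != 4L)
    stop("mode '", mode, "' requires 4 input channels (R,G,B,NIR)")
  if (mode == "rgb_nir")
    return(Chat)
  if (mode == "rgb")
    return(channel_series(Chat$values[1:3, , drop = FALSE], fs = Chat$fs,
                          labels = Chat$labels[1:3]))

  rgb <- Chat$values[1:3, , drop = FALSE]
  eps <- 0.5                       # tolerated spectral-filter ringing
  if (min(rgb) < -eps || max(rgb) > 255 + eps)
    warning("RGB values outside [0, 255]; clipping before Lab conversion")
  rgb <- pmin(pmax(rgb, 0), 255)
  lab <- grDevices::convertColor(t(rgb) / 255, from = "sRGB", to = "Lab")
  nir <- Chat$values[4L, ]
  nir <- nir / mean(nir) - 1
  channel_series(rbind(a = lab[, "a"], b = lab[, "b"], NIR = nir),
                 fs = Chat$fs, labels = c("a", "b", "NIR"))
}
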