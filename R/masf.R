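#' MASF configuration
#'
#' Parameters of the amplitude-selective spectral gate. The NIR amplitude
#' ceiling `alpha` lives on the DC-normalised (AC/DC) amplitude scale: the
#' pulsatile band of facial video sits in roughly `[1e-4, 2e-3]`, so the
#' default ceiling is just above it — 0.004 for windows of 10 s or shorter
#' and 0.003 for longer windows (shorter signals concentrate transient noise
#' into taller low-frequency peaks and need the larger ceiling). `beta`
#' restricts the blue amplitude relative to red plus green. Rejected bins
#' are multiplied by `suppression_weight` rather than zeroed, because exact
#' zeros can make the downstream ICA covariance (near-)singular.
#'
#' @param alpha NIR amplitude threshold; `NULL` picks 0.004/0.003 by window
#'   length at filter time.
#' @param beta blue restriction factor.
#' @param suppression_weight multiplier applied to rejected bins, in (0, 1).
#' @param band frequency interval (Hz) inside which the conditions are
#'   evaluated; bins outside are left untouched.
#' @param asf_alpha_r R-channel amplitude ceiling used by the original ASF
#'   baseline ([asf_filter()]); defaults to the upper edge of the pulsatile
#'   band.
#' @return An object of class `masf_config`.
#' @export
masf_config <- function(alpha = NULL, beta = 1.25, suppression_weight = 1e-4,
                        band = c(0.5, 4.0), asf_alpha_r = 0.002) {
  if (!is.null(alpha) && alpha <= 0) stop("alpha must be positive")
  if (beta <= 0) stop("beta must be positive")
  if (suppression_weight <= 0 || suppression_weight >= 1)
    stop("suppression_weight must lie in (0, 1)")
  if (band[1] <= 0 || band[2] <= band[1]) stop("band must be 0 < lo < hi")
  structure(list(alpha = alpha, beta = beta,
                 suppression_weight = suppression_weight,
                 band = band, asf_alpha_r = asf_alpha_r),
            class = "masf_config")
}

resolve_alpha <- function(cfg, duration_s) {
  if (!is.null(cfg$alpha)) return(cfg$alpha)
  if (duration_s <= 10) 0.004 else 0.003
}

#' Per-channel amplitude spectra of a channel series
#'
#' Each channel is divided by its temporal mean (AC/DC normalisation),
#' mean-removed, and Fourier transformed. `psd` holds the one-sided
#' amplitude `|X(w)|/T`, so a pure cosine of AC/DC amplitude `a` shows a
#' peak of height `a/2`; the DC bin is set to 0. The full complex
#' coefficient matrix and the channel means are retained so the filter can
#' reconstruct the time domain exactly.
#'
#' @param C a [channel_series()].
#' @return An object of class `spectrum_set`: `freqs` (one-sided Hz axis),
#'   `coeffs` (k x T complex), `psd` (k x n_freq amplitudes), `dc` (channel
#'   means), `fs`, `labels`, `T`.
#' @export
compute_psd <- function(C) {
  stopifnot(inherits(C, "channel_series"))
  T <- n_frames(C)
  dc <- rowMeans(C$values)
  zero <- which(abs(dc) < 1e-9 * pmax(apply(abs(C$values), 1L, max), 1e-300))
  if (length(zero))
    stop("channel ", C$labels[zero[1L]],
         " has zero temporal mean; AC/DC normalisation undefined")
  norm <- sweep(C$values, 1L, dc, "/") - 1
  coeffs <- t(apply(norm, 1L, stats::fft))
  nf <- floor(T / 2) + 1L
  freqs <- (seq_len(nf) - 1L) * C$fs / T
  psd <- Mod(coeffs[, seq_len(nf), drop = FALSE]) / T
  psd[, 1L] <- 0
  dimnames(psd) <- list(C$labels, NULL)
  structure(list(freqs = freqs, coeffs = coeffs, psd = psd, dc = dc,
                 fs = C$fs, labels = C$labels, T = T),
            class = "spectrum_set")
}

# Multiply bin j (1-based one-sided index) and its conjugate partner by w
# across all channels, keeping the inverse transform real.
suppress_bins <- function(coeffs, bins, T, w) {
  for (j in bins) {
    coeffs[, j] <- coeffs[, j] * w
    partner <- T - j + 2L
    if (j > 1L && partner != j && partner <= T)
      coeffs[, partner] <- coeffs[, partner] * w
  }
  coeffs
}

spectrum_to_series <- function(S, coeffs) {
  rec <- t(apply(coeffs, 1L, function(z) Re(stats::fft(z, inverse = TRUE)) / S$T))
  vals <- sweep(rec + 1, 1L, S$dc, "*")   # restore each channel's DC
  channel_series(vals, fs = S$fs, labels = S$labels)
}

masf_selection <- function(S, cfg, mode) {
  in_band <- S$freqs > cfg$band[1] & S$freqs < cfg$band[2]
  alpha <- resolve_alpha(cfg, S$T / S$fs)
  # bins whose total amplitude is numerical dust carry no evidence either way
  content <- colSums(S$psd) > 1e-10 * max(S$psd, 1e-300)
  sel <- rep(TRUE, length(S$freqs))
  if (mode == "dual")
    sel <- sel & S$psd["NIR", ] <= alpha
  sel <- sel & S$psd["B", ] <= cfg$beta * (S$psd["R", ] + S$psd["G", ])
  which(in_band & content & !sel)
}

#' Modified amplitude-selective filter (MASF)
#'
#' Gates spectral bins inside the evaluation band: a bin survives iff the
#' NIR amplitude does not exceed `alpha` (skipped in `rgb_only` mode) and
#' the blue amplitude does not exceed `beta * (P_R + P_G)`. Rejected bins
#' have the complex coefficients of *all* channels (and their conjugate
#' partners) multiplied by `suppression_weight`; the inverse transform then
#' returns the filtered series with each channel's original DC restored.
#'
#' @param S a [compute_psd()] spectrum set.
#' @param cfg a [masf_config()].
#' @param mode `"dual"` (needs an NIR channel) or `"rgb_only"` (the NIR
#'   ceiling is ignored, as for RGB-only footage).
#' @return The filtered [channel_series()]; the number of suppressed bins is
#'   attached as attribute `n_suppressed`.
#' @export
masf_filter <- function(S, cfg = masf_config(), mode = c("dual", "rgb_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(S, "spectrum_set"))
  if (mode == "dual" && !"NIR" %in% S$labels)
    stop("mode = 'dual' requires an NIR channel; use mode = 'rgb_only'")
  if (cfg$band[2] >= S$fs / 2)
    stop("evaluation band must lie within (0, fs/2)")
  bad <- masf_selection(S, cfg, mode)
  out <- spectrum_to_series(
    S, suppress_bins(S$coeffs, bad, S$T, cfg$suppression_weight))
  attr(out, "n_suppressed") <- length(bad)
  out
}

#' Original amplitude-selective filter (ASF) baseline
#'
#' The ablation baseline: bins whose R-channel AC/DC amplitude exceeds
#' `asf_alpha_r` are suppressed. Provided for comparison only; its ceiling
#' is the nominal upper edge of the pulsatile amplitude band, not tuned.
#'
#' @inheritParams masf_filter
#' @return The filtered [channel_series()] with attribute `n_suppressed`.
#' @export
asf_filter <- function(S, cfg = masf_config()) {
  stopifnot(inherits(S, "spectrum_set"))
  in_band <- S$freqs > cfg$band[1] & S$freqs < cfg$band[2]
  bad <- which(in_band & S$psd["R", ] > cfg$asf_alpha_r)
  out <- spectrum_to_series(
    S, suppress_bins(S$coeffs, bad, S$T, cfg$suppression_weight))
  attr(out, "n_suppressed") <- length(bad)
  out
}
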