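# Orthogonal wavelet filter banks. Coefficients are the standard
# (sum = sqrt(2)) decomposition filters; the transform normalises them to
# unit DC gain so approximation coefficients preserve constants.
wavelet_filters <- function(name) {
  switch(name,
    sym4 = list(
      dec_lo = c(-0.07576571478927333, -0.02963552764599851,
                  0.49761866763201545,  0.80373875180591614,
                  0.29785779560527736, -0.09921954357684722,
                 -0.01260396726203783,  0.03222310060404270),
      dec_hi = c(-0.03222310060404270, -0.01260396726203783,
                  0.09921954357684722,  0.29785779560527736,
                 -0.80373875180591614,  0.49761866763201545,
                  0.02963552764599851, -0.07576571478927333)),
    haar = list(dec_lo = c(1, 1) / sqrt(2), dec_hi = c(1, -1) / sqrt(2)),
    stop("unsupported wavelet '", name, "' (available: sym4, haar)")
  )
}

# Frequency response of a filter upsampled by `stride` (zeros inserted),
# zero-padded to length n: the level-j a-trous filter.
atrous_response <- function(h, stride, n) {
  up <- numeric(n)
  idx <- seq(1L, by = stride, length.out = length(h))
  if (max(idx) > n) stop("signal too short for this decomposition level")
  up[idx] <- h
  stats::fft(up)
}

#' Stationary wavelet decomposition of a single row
#'
#' Undecimated (a-trous) dyadic decomposition with periodic boundary
#' handling; filters are normalised to unit DC gain. Returns all
#' approximation/detail bands so the inverse transform can be checked.
#'
#' @param x numeric vector, length at least `2^levels * filter length / 2`.
#' @param wavelet filter-bank name (`"sym4"` or `"haar"`).
#' @param levels decomposition depth.
#' @return List of bands `A1, D1, A2, D2, ...` (each `length(x)` long).
#' @export
swt_decompose <- function(x, wavelet = "sym4", levels = 2L) {
  fb <- wavelet_filters(wavelet)
  h <- fb$dec_lo / sqrt(2)              # unit DC gain
  g <- fb$dec_hi / sqrt(2)
  n <- length(x)
  out <- list()
  A <- stats::fft(x)
  for (j in seq_len(levels)) {
    stride <- 2^(j - 1L)
    H <- atrous_response(h, stride, n)
    G <- atrous_response(g, stride, n)
    D <- A * G
    A <- A * H
    out[[paste0("A", j)]] <- Re(stats::fft(A, inverse = TRUE)) / n
    out[[paste0("D", j)]] <- Re(stats::fft(D, inverse = TRUE)) / n
  }
  out
}

#' Inverse stationary wavelet transform
#'
#' Reconstructs the signal from the deepest approximation band plus all
#' detail bands, using the adjoint filters. With the orthogonal banks used
#' here the round trip is exact to floating-point precision.
#'
#' @param bands list as returned by [swt_decompose()].
#' @param wavelet filter-bank name.
#' @return Numeric vector of the reconstructed signal.
#' @export
swt_reconstruct <- function(bands, wavelet = "sym4") {
  fb <- wavelet_filters(wavelet)
  h <- fb$dec_lo / sqrt(2)
  g <- fb$dec_hi / sqrt(2)
  levels <- sum(grepl("^A", names(bands)))
  n <- length(bands[[1L]])
  A <- stats::fft(bands[[paste0("A", levels)]])
  for (j in rev(seq_len(levels))) {
    stride <- 2^(j - 1L)
    H <- atrous_response(h, stride, n)
    G <- atrous_response(g, stride, n)
    D <- stats::fft(bands[[paste0("D", j)]])
    A <- Conj(H) * A + Conj(G) * D      # power complementarity: |H|^2+|G|^2 = 1
  }
  Re(stats::fft(A, inverse = TRUE)) / n
}

#' Wavelet denoising: keep the level-2 approximation band
#'
#' Each row of `M` is decomposed independently by a 2-level stationary
#' wavelet transform (sym4 by default) and replaced by its level-2
#' approximation `AC2`, i.e. the smooth band that retains the heart-rate
#' range while shedding high-frequency noise; shape is preserved. For
#' subjects expected above ~130 bpm the level-2 detail band can be kept
#' instead (`keep = "DC2"`). If `T` is not a multiple of `2^levels` the rows
#' are symmetric-padded to the next multiple and the output cropped back.
#'
#' @param M a [channel_series()] (typically the fusion matrix from
#'   [assemble_M()]).
#' @param wavelet filter-bank name.
#' @param levels decomposition depth.
#' @param keep `"AC2"` (approximation, default) or `"DC2"` (detail) — more
#'   generally the approximation/detail at `levels`.
#' @return A [channel_series()] of the same shape as `M`.
#' @export
swt_ac2 <- function(M, wavelet = "sym4", levels = 2L,
                    keep = c("AC2", "DC2")) {
  keep <- match.arg(keep)
  stopifnot(inherits(M, "channel_series"))
  T <- n_frames(M)
  if (T < 8L) stop("need at least 8 samples for a 2-level decomposition")
  block <- 2L^levels
  pad <- (block - T %% block) %% block
  target <- if (keep == "AC2") paste0("A", levels) else paste0("D", levels)
  out <- t(apply(M$values, 1L, function(row) {
    if (pad > 0L) row <- c(row, row[seq(T, by = -1L, length.out = pad)])
    swt_decompose(row, wavelet, levels)[[target]][seq_len(T)]
  }))
  channel_series(out, fs = M$fs, labels = M$labels)
}
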