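#' JADE independent component analysis
#'
#' Blind source separation by Joint Approximate Diagonalization of
#' Eigen-matrices: the rows of `X` are zero-meaned and whitened through the
#' eigen-decomposition of their covariance, the full set of fourth-order
#' cumulant matrices is estimated, and an orthogonal transform jointly
#' diagonalising them is found by Jacobi rotations. Components come out
#' with (empirical) unit variance and identity covariance; ICA's usual
#' sign/permutation indeterminacy applies.
#'
#' @param X numeric `n x T` matrix of mixed signals (rows = channels).
#' @param rotation_tol Jacobi rotation threshold on `|sin(theta)|`;
#'   defaults to `1e-8 / sqrt(T)`.
#' @param max_sweeps cap on Jacobi sweeps.
#' @return An object of class `ica_result`: `components` (`n x T`),
#'   `unmixing` (`n x n`, so `components = unmixing %*% centred X`).
#' @export
jade <- function(X, rotation_tol = NULL, max_sweeps = 100L) {
  X <- as.matrix(X)
  n <- nrow(X); T <- ncol(X)
  if (T < 30L) stop("jade needs at least 30 samples")
  if (is.null(rotation_tol)) rotation_tol <- 1e-8 / sqrt(T)
  X <- X - rowMeans(X)

  ## whitening
  R <- tcrossprod(X) / T
  eg <- eigen(R, symmetric = TRUE)
  if (min(eg$values) < 1e-12 * max(eg$values))
    stop("rank-deficient covariance: the low-rank stage collapsed the ",
         "channels; rerun with the RPCA step disabled to diagnose")
  W <- diag(1 / sqrt(eg$values), n) %*% t(eg$vectors)
  Z <- W %*% X

  ## fourth-order cumulant matrices, n(n+1)/2 of them, side by side
  nbcm <- n * (n + 1L) / 2L
  CM <- matrix(0, n, n * nbcm)
  I_n <- diag(n)
  k <- 0L
  for (i in seq_len(n)) {
    g <- Z[i, ] * Z[i, ]
    Q <- tcrossprod(Z * rep(g, each = n), Z) / T - I_n
    Q[i, i] <- Q[i, i] - 2
    CM[, k * n + seq_len(n)] <- Q
    k <- k + 1L
    for (j in seq_len(i - 1L)) {
      g <- Z[i, ] * Z[j, ]
      Q <- tcrossprod(Z * rep(g, each = n), Z) / T
      Q[i, j] <- Q[i, j] - 1
      Q[j, i] <- Q[j, i] - 1
      CM[, k * n + seq_len(n)] <- sqrt(2) * Q
      k <- k + 1L
    }
  }

  ## joint diagonalisation by Jacobi rotations
  V <- diag(n)
  for (sweep in seq_len(max_sweeps)) {
    rotated <- FALSE
    for (p in seq_len(n - 1L)) {
      for (q in seq((p + 1L), n)) {
        colp <- seq(p, n * nbcm, by = n)
        colq <- seq(q, n * nbcm, by = n)
        g1 <- CM[p, colp] - CM[q, colq]
        g2 <- CM[p, colq] + CM[q, colp]
        ton <- sum(g1 * g1) - sum(g2 * g2)
        toff <- 2 * sum(g1 * g2)
        theta <- 0.5 * atan2(toff, ton + sqrt(ton * ton + toff * toff))
        s <- sin(theta)
        if (abs(s) > rotation_tol) {
          rotated <- TRUE
          cth <- cos(theta)
          # Givens rotation [[c, -s], [s, c]] (column-major fill)
          G <- matrix(c(cth, s, -s, cth), 2L)
          pq <- c(p, q)
          CM[pq, ] <- t(G) %*% CM[pq, ]
          old_p <- CM[, colp]; old_q <- CM[, colq]
          CM[, colp] <- cth * old_p + s * old_q
          CM[, colq] <- -s * old_p + cth * old_q
          V[, pq] <- V[, pq] %*% G
        }
      }
    }
    if (!rotated) break
  }

  B <- t(V) %*% W
  structure(list(components = B %*% X, unmixing = B),
            class = "ica_result")
}

#' Amari separation index
#'
#' Permutation- and scale-invariant distance between an estimated unmixing
#' matrix and the true mixing: 0 for perfect separation, larger values for
#' residual mixing. Computed on `P = unmixing %*% mixing`.
#'
#' @param unmixing estimated unmixing matrix.
#' @param mixing true mixing matrix.
#' @return Scalar index in `[0, 1]`.
#' @export
amari_index <- function(unmixing, mixing) {
  P <- abs(unmixing %*% mixing)
  n <- nrow(P)
  rows <- sum(rowSums(P / apply(P, 1L, max)) - 1)
  cols <- sum(colSums(P / rep(apply(P, 2L, max), each = n)) - 1)
  (rows + cols) / (2 * n * (n - 1))
}

## Local maxima with topographic prominence and a minimum-separation rule.
## Returns sorted sample indices.
find_peaks <- function(x, min_dist = 1L, min_prom = 0) {
  n <- length(x)
  if (n < 3L) return(integer())
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                x[2:(n - 1L)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer())
  prom <- vapply(cand, function(i) {
    lm <- x[i]; j <- i
    while (j > 1L && x[j - 1L] <= x[i]) { j <- j - 1L; lm <- min(lm, x[j]) }
    rm <- x[i]; j <- i
    while (j < n && x[j + 1L] <= x[i]) { j <- j + 1L; rm <- min(rm, x[j]) }
    x[i] - max(lm, rm)
  }, numeric(1))
  cand <- cand[prom >= min_prom]
  if (!length(cand)) return(integer())
  keep <- integer()
  for (i in cand[order(x[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Select the rPPG component by peak-interval regularity
#'
#' For each unmixed component and each polarity (ICA leaves the sign
#' undetermined), local maxima are detected with a minimum separation of
#' one shortest physiologic beat interval (`fs * 60 / hr_high` samples) and
#' a prominence of at least `prominence_frac` of the component's SD. The
#' score of a component is the smaller, over the two polarities, of the
#' standard deviation of successive peak-to-peak distances (in samples);
#' the most regular — most periodic — component is selected, ties broken by
#' the lower index. Components with fewer than 3 peaks score `Inf`.
#'
#' @param components `3 x T` matrix from [jade()] (or an `ica_result`).
#' @param fs sampling rate, Hz.
#' @param hr_band_bpm plausible heart-rate band in bpm; only the upper edge
#'   enters the minimum peak separation.
#' @param prominence_frac prominence threshold as a fraction of the raw
#'   component's SD.
#' @param detrend_band_hz optional band (Hz): peaks are then detected on a
#'   band-limited copy of each component, so slow drift and out-of-band
#'   noise cannot scramble the beat-interval statistics. The prominence
#'   threshold stays tied to the raw SD, which keeps aperiodic components
#'   (whose band-limited residue is tiny) out of the running.
#' @return List with `selected` (component index) and `peak_sd` (scores).
#' @export
select_rppg <- function(components, fs, hr_band_bpm = c(50, 144),
                        prominence_frac = 0.25, detrend_band_hz = NULL) {
  if (inherits(components, "ica_result")) components <- components$components
  stopifnot(nrow(components) == 3L, fs > 0)
  min_dist <- floor(fs * 60 / hr_band_bpm[2L])
  score_one <- function(x) {
    prom <- prominence_frac * stats::sd(x)
    xs <- if (is.null(detrend_band_hz)) x
          else bandpass(x, fs, band_hz = detrend_band_hz)
    best <- Inf
    for (sgn in c(1, -1)) {
      pk <- find_peaks(sgn * xs, min_dist = min_dist, min_prom = prom)
      if (length(pk) >= 3L)
        best <- min(best, stats::sd(diff(pk)))
    }
    best
  }
  peak_sd <- apply(components, 1L, score_one)
  if (all(!is.finite(peak_sd)))
    stop("no periodic component found")
  list(selected = which.min(peak_sd), peak_sd = peak_sd)
}
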