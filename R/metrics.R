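#' Evaluate heart-rate estimates against ground truth
#'
#' Signed errors `e_i = est_i - gt_i` are summarised as MAE, RMSE, the SD
#' of the signed errors (population SD by default), and the accuracy
#' `Acc = DS / DT`, where `DS` counts estimates with `|e| <` the success
#' threshold (5 bpm by default, following the ANSI/AAMI EC13 tolerance for
#' physiological rate meters) and `DT` is the total count.
#'
#' @param est estimated bpm values.
#' @param gt ground-truth bpm values, same length.
#' @param success_thresh success threshold in bpm (strict inequality).
#' @param sd_type `"population"` (default) or `"sample"` SD of the errors.
#' @param exclude_gt_above optionally drop pairs whose ground truth exceeds
#'   this bpm (e.g. 100 to ignore high-rate cases).
#' @return An object of class `eval_report`: `mae`, `rmse`, `sd`, `acc`,
#'   `ds`, `dt`.
#' @export
#' @examples
#' evaluate_hr(c(72, 77, 74), c(70, 70, 70))
evaluate_hr <- function(est, gt, success_thresh = 5,
                        sd_type = c("population", "sample"),
                        exclude_gt_above = NULL) {
  sd_type <- match.arg(sd_type)
  if (length(est) != length(gt))
    stop("est and gt must have equal length")
  if (!length(est)) stop("need at least one estimate")
  if (!is.null(exclude_gt_above)) {
    keep <- gt <= exclude_gt_above
    est <- est[keep]; gt <- gt[keep]
    if (!length(est)) stop("all pairs excluded by the ground-truth ceiling")
  }
  e <- est - gt
  n <- length(e)
  ds <- sum(abs(e) < success_thresh)
  sdv <- if (sd_type == "population") sqrt(mean((e - mean(e))^2))
         else stats::sd(e)
  structure(list(mae = mean(abs(e)), rmse = sqrt(mean(e^2)),
                 sd = sdv, acc = ds / n, ds = ds, dt = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n=%d  MAE=%.2f  RMSE=%.2f  SD=%.2f  Acc(5bpm)=%.3f (%d/%d)\n",
    x$dt, x$mae, x$rmse, x$sd, x$acc, x$ds, x$dt))
  invisible(x)
}

#' FFT bin width in bpm for a window length
#'
#' A window of `Ls` seconds resolves heart rate to `b = 60 / Ls` bpm — the
#' theoretical floor of spectral-peak readout accuracy (6 bpm at 10 s,
#' 3 bpm at 20 s, 1 bpm at 60 s).
#'
#' @param Ls window length in seconds, `> 0`.
#' @return Bin width in bpm.
#' @export
frequency_resolution <- function(Ls) {
  if (any(Ls <= 0)) stop("window length must be positive")
  60 / Ls
}

#' Convert frequency in Hz to beats per minute
#'
#' @param f frequency in Hz.
#' @return `60 * f` bpm.
#' @export
hz_to_bpm <- function(f) 60 * f
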