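valid_config_keys <- list(
  top = c("input", "synth", "gt", "out", "seed", "variant", "fusion",
          "fps", "window_sec", "step", "exclude_hgt",
          "masf", "wd", "rpca", "ica", "select", "hr", "eval"),
  synth = c("hr_bpm", "fs", "duration_s", "harmonic2_frac", "n_spikes",
            "spike_amp", "drift_amp", "drift_hz", "noise_sd", "dark",
            "channels", "seed"),
  masf = c("alpha", "beta", "suppression_weight", "band", "asf_alpha_r"),
  wd = c("wavelet", "levels", "keep"),
  rpca = c("lambda", "tol", "max_iter"),
  ica = c("rotation_tol"),
  select = c("prominence_frac"),
  hr = c("band_hz", "order"),
  eval = c("success_thresh")
)

check_keys <- function(x, section) {
  valid <- valid_config_keys[[section]]
  bad <- setdiff(names(x), valid)
  if (length(bad))
    stop("unknown key(s) in config section '", section, "': ",
         paste(bad, collapse = ", "), "; valid keys: ",
         paste(valid, collapse = ", "))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full estimate + evaluate job from a config file
#'
#' Reads a YAML config with sections `masf`, `wd`, `rpca`, `ica`, `select`,
#' `hr` and `eval` plus top-level run keys, executes the sliding-window
#' estimation (on a CSV series given by `input`, or a generated clip
#' described by a `synth` section), evaluates against ground truth when
#' available, logs each stage, and optionally writes a JSON report.
#' Unknown keys raise an error listing the valid ones. All randomness flows
#' from the single `seed` key.
#'
#' @param path YAML config path.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `estimates` (data frame) and `report`
#'   (an [evaluate_hr()] report, or `NULL` without ground truth).
#' @export
run_config <- function(path, quiet = FALSE) {
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, "top")
  for (sec in intersect(names(cfg), c("synth", "masf", "wd", "rpca",
                                      "ica", "select", "hr", "eval")))
    check_keys(cfg[[sec]], sec)
  say <- function(...) if (!quiet) message(sprintf(...))

  seed <- cfg$seed %||% 1L
  gt <- NULL
  if (!is.null(cfg$input)) {
    series <- read_series(cfg$input, fps = cfg$fps)
    say("read %d-channel series of %d frames from %s",
        nrow(series$values), n_frames(series), cfg$input)
    if (!is.null(cfg$gt)) {
      gdf <- utils::read.csv(cfg$gt)
      if (!"bpm" %in% names(gdf)) stop("gt file needs a 'bpm' column")
      gt <- gdf$bpm
    }
  } else if (!is.null(cfg$synth)) {
    sargs <- cfg$synth
    sargs$seed <- sargs$seed %||% seed
    clip <- generate_clip(do.call(synthetic_spec, sargs))
    series <- clip$series
    gt <- clip$truth
    say("generated synthetic clip: %d frames @ %g Hz", n_frames(series),
        series$fs)
  } else stop("config needs either 'input' (CSV path) or a 'synth' section")

  masf_args <- cfg$masf %||% list()
  if (!is.null(masf_args$band)) masf_args$band <- as.numeric(masf_args$band)
  pcfg <- pipeline_config(
    variant = cfg$variant %||% "p3",
    fusion = cfg$fusion,
    masf = do.call(masf_config, masf_args),
    wd_wavelet = cfg$wd$wavelet %||% "sym4",
    wd_levels = cfg$wd$levels %||% 2L,
    wd_keep = cfg$wd$keep %||% "AC2",
    rpca_lambda = cfg$rpca$lambda,
    rpca_tol = cfg$rpca$tol %||% 1e-7,
    rpca_max_iter = cfg$rpca$max_iter %||% 500L,
    band_hz = as.numeric(cfg$hr$band_hz %||% c(0.83, 2.4)),
    filter_order = cfg$hr$order %||% 10L,
    prominence_frac = cfg$select$prominence_frac %||% 0.25,
    ica_rotation_tol = cfg$ica$rotation_tol)

  window_len <- round((cfg$window_sec %||% (n_frames(series) / series$fs)) *
                        series$fs)
  t0 <- proc.time()["elapsed"]
  est <- sliding_estimate(series, window_len = window_len,
                          step = cfg$step %||% 6L, gt = gt, cfg = pcfg)
  say("estimated %d windows (variant %s) in %.1f s", nrow(est),
      pcfg$variant, proc.time()["elapsed"] - t0)

  report <- NULL
  if (!is.null(gt)) {
    report <- evaluate_hr(est$bpm, est$gt_bpm,
                          success_thresh = cfg$eval$success_thresh %||% 5,
                          exclude_gt_above = cfg$exclude_hgt)
    say("MAE %.2f  RMSE %.2f  Acc %.3f", report$mae, report$rmse, report$acc)
  }
  if (!is.null(cfg$out)) {
    payload <- list(estimates = est,
                    report = if (is.null(report)) NULL else unclass(report),
                    variant = pcfg$variant, seed = seed)
    jsonlite::write_json(payload, cfg$out, auto_unbox = TRUE, digits = NA,
                         null = "null")
    say("wrote report to %s", cfg$out)
  }
  invisible(list(estimates = est, report = report))
}
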