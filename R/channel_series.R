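#' Multi-channel mean-intensity time series
#'
#' The basic container of the pipeline: a `k x T` matrix of per-frame,
#' spatially averaged channel intensities (`k = 3` for R/G/B, `k = 4` with a
#' near-infrared channel) together with the sampling rate.
#'
#' @param values numeric matrix, channels in rows, frames in columns.
#' @param fs sampling rate in Hz (frames per second), `> 0`.
#' @param labels character vector of channel names; defaults to
#'   `c("R","G","B")` or `c("R","G","B","NIR")` by row count.
#'
#' @return An object of class `channel_series` (a list with elements
#'   `values`, `fs`, `labels`).
#' @export
#' @examples
#' cs <- channel_series(matrix(rnorm(3 * 90, 100), 3), fs = 30)
#' n_frames(cs)
channel_series <- function(values, fs, labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("channel series values must be finite numerics")
  k <- nrow(values)
  if (!k %in% c(3L, 4L))
    stop("expected 3 (R,G,B) or 4 (R,G,B,NIR) channel rows, got ", k)
  if (ncol(values) < 2L)
    stop("a channel series needs at least 2 samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  if (is.null(labels))
    labels <- if (k == 4L) c("R", "G", "B", "NIR") else c("R", "G", "B")
  if (length(labels) != k)
    stop("labels length must match the number of channel rows")
  rownames(values) <- labels
  structure(list(values = values, fs = fs, labels = labels),
            class = "channel_series")
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("<channel_series> %d channels (%s) x %d frames @ %g Hz (%.1f s)\n",
              nrow(x$values), paste(x$labels, collapse = ","),
              ncol(x$values), x$fs, ncol(x$values) / x$fs))
  invisible(x)
}

#' Number of frames in a channel series
#' @param x a [channel_series()].
#' @return integer frame count `T`.
#' @export
n_frames <- function(x) ncol(x$values)

has_nir <- function(x) "NIR" %in% x$labels

#' Write a channel series to CSV
#'
#' Writes a header `t,R,G,B[,NIR]` preceded by a `# fps: <value>` sidecar
#' comment line so the sampling rate travels with the file.
#'
#' @param x a [channel_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(x, path) {
  stopifnot(inherits(x, "channel_series"))
  df <- data.frame(t = seq_len(n_frames(x)) - 1L,
                   t(x$values), check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fps: %.10g", x$fs), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a channel series from CSV
#'
#' Expects the format written by [write_series()]: optional `# fps:` comment,
#' header `t,R,G,B` with an optional `NIR` column. A file without the NIR
#' column yields a 3-channel series.
#'
#' @param path CSV file path.
#' @param fps sampling rate override in Hz; required when the file carries no
#'   `# fps:` sidecar line.
#' @return A [channel_series()].
#' @export
read_series <- function(path, fps = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("series file too short: ", path)
  is_comment <- grepl("^\\s*#", lines)
  fps_line <- grep("^\\s*#\\s*fps\\s*:", lines, value = TRUE)
  if (length(fps_line)) {
    file_fps <- as.numeric(sub("^\\s*#\\s*fps\\s*:\\s*", "", fps_line[1L]))
    if (is.null(fps)) fps <- file_fps
  }
  if (is.null(fps))
    stop("no '# fps:' sidecar line in ", path, "; pass fps explicitly")
  body <- lines[!is_comment]
  line_no <- which(!is_comment)           # original line numbers for messages
  nf <- utils::count.fields(textConnection(body), sep = ",")
  if (any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged row in %s at line %d (%d fields, expected %d)",
                 path, line_no[bad], nf[bad], nf[1L]))
  }
  df <- utils::read.csv(textConnection(body), check.names = FALSE)
  want <- c("R", "G", "B")
  if ("NIR" %in% names(df)) want <- c(want, "NIR")
  if (!all(want %in% names(df)))
    stop("series file must have columns t,R,G,B[,NIR]; got: ",
         paste(names(df), collapse = ","))
  for (cn in want) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1L]
      stop(sprintf("non-numeric value in column %s of %s at line %d",
                   cn, path, line_no[bad + 1L]))
    }
  }
  channel_series(t(as.matrix(df[want])), fs = fps, labels = want)
}
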