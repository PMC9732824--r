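#' Epoched EEG container
#'
#' Lightweight container for stimulus-locked epochs: a numeric array of shape
#' trials x channels x samples plus sampling rate, epoch start time and a
#' tibble of per-trial labels.
#'
#' @param data Array `[trials, channels, samples]`.
#' @param fs_hz Sampling rate in Hz.
#' @param t0 Time of the first sample relative to stimulus onset, in seconds
#'   (default -0.1).
#' @param labels Tibble with one row per trial (difficulty, context, choice,
#'   RT, ...).
#' @return Object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, fs_hz, t0 = -0.1, labels = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (is.null(labels)) labels <- tibble(.rows = dim(data)[1])
  labels <- as_tibble(labels)
  if (nrow(labels) != dim(data)[1]) {
    abort("`labels` must have one row per trial.")
  }
  if (anyNA(data)) abort("Epoch data must not contain NAs.")
  structure(list(data = data, fs_hz = fs_hz, t0 = t0, labels = labels),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, t0 = %g s\n",
              d[1], d[2], d[3], x$fs_hz, x$t0))
  invisible(x)
}

#' Sample times of an epochs object
#' @param x An `eeg_epochs` object.
#' @return Numeric vector of sample times (s) relative to stimulus onset.
#' @export
epoch_times <- function(x) {
  stopifnot(inherits(x, "eeg_epochs"))
  x$t0 + (seq_len(dim(x$data)[3]) - 1) / x$fs_hz
}

#' Continuous EEG container
#'
#' @param data Matrix channels x samples.
#' @param fs_hz Sampling rate in Hz.
#' @param channels Channel names (default "ch01"...).
#' @param triggers Named list of integer sample indices (e.g. `volume`,
#'   `stimulus`, `response`, `blink`).
#' @return Object of class `raw_eeg`.
#' @export
raw_eeg <- function(data, fs_hz, channels = NULL, triggers = list()) {
  stopifnot(is.matrix(data))
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(nrow(data)))
  n <- ncol(data)
  for (nm in names(triggers)) {
    tr <- triggers[[nm]]
    if (length(tr) && (min(tr) < 1 || max(tr) > n)) {
      abort(sprintf("Trigger list '%s' extends past the record.", nm))
    }
  }
  structure(list(data = data, fs_hz = fs_hz, channels = channels,
                 triggers = triggers),
            class = "raw_eeg")
}

#' @export
print.raw_eeg <- function(x, ...) {
  cat(sprintf("<raw_eeg> %d channels x %d samples @ %g Hz; triggers: %s\n",
              nrow(x$data), ncol(x$data), x$fs_hz,
              paste(names(x$triggers), collapse = ", ")))
  invisible(x)
}

#' 4D BOLD volume series container
#'
#' @param data Array `[x, y, z, t]`.
#' @param tr_s Repetition time in seconds.
#' @return Object of class `volume_series`.
#' @export
volume_series <- function(data, tr_s) {
  stopifnot(is.array(data), length(dim(data)) == 4, tr_s > 0)
  structure(list(data = data, tr_s = tr_s), class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %d x %d x %d voxels, %d scans, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}
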