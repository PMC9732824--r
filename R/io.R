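#' Read and write behavioral trial tables
#'
#' Tab-separated trial tables with columns `trial`, `subject`, `context`,
#' `p_level`, `evidence`, `choice` (+1/-1), `rt_s` (extra columns pass
#' through).
#'
#' @param trials Trial tibble.
#' @param path File path.
#' @return `read_behavior_tsv()` returns a tibble; the writer returns `path`
#'   invisibly.
#' @export
write_behavior_tsv <- function(trials, path) {
  utils::write.table(as.data.frame(trials), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_behavior_tsv
#' @export
read_behavior_tsv <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Read and write epoched EEG as a flat binary container
#'
#' The array is stored as little-endian doubles in trial-major order next to
#' a JSON sidecar holding the dimensions, sampling rate, epoch start and the
#' label table.
#'
#' @param epochs An [eeg_epochs()].
#' @param path Path without extension; `<path>.dat` and `<path>.json` are
#'   written.
#' @return The reader returns an [eeg_epochs()]; the writer returns `path`
#'   invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(epochs$data), con, size = 8, endian = "little")
  meta <- list(dims = dim(epochs$data), fs_hz = epochs$fs_hz, t0 = epochs$t0,
               labels = epochs$labels)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dims)
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  eeg_epochs(array(vals, dim = meta$dims), fs_hz = meta$fs_hz, t0 = meta$t0,
             labels = as_tibble(meta$labels))
}

#' Read and write FSL-style 3-column event files
#'
#' Plain text with onset, duration and amplitude columns.
#'
#' @param events Tibble with `onset`, `duration`, `amplitude`.
#' @param path File path.
#' @return The reader returns an event tibble.
#' @export
write_events_fsl <- function(events, path) {
  utils::write.table(events[, c("onset", "duration", "amplitude")], path,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events_fsl
#' @export
read_events_fsl <- function(path) {
  d <- utils::read.table(path, col.names = c("onset", "duration", "amplitude"))
  as_tibble(d)
}

#' Read and write 4D BOLD series as NIfTI-1 plus a JSON sidecar
#'
#' @param volumes A [volume_series()].
#' @param path Path of the `.nii.gz` file; a `.json` sidecar with the TR is
#'   written alongside.
#' @return The reader returns a [volume_series()].
#' @export
write_bold_nifti <- function(volumes, path) {
  stopifnot(inherits(volumes, "volume_series"))
  RNifti::writeNifti(RNifti::asNifti(volumes$data), path)
  jsonlite::write_json(list(RepetitionTime = volumes$tr_s),
                       sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  tr <- if (file.exists(side)) {
    jsonlite::read_json(side)$RepetitionTime
  } else {
    RNifti::pixdim(img)[4]
  }
  volume_series(array(as.numeric(img), dim = dim(img)), tr_s = tr)
}
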