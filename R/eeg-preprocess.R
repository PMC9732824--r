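#' Gradient artifact removal by sliding template subtraction
#'
#' For each MR volume, the average of the volume-locked segments from up to
#' `template_halfwidth` volumes on either side (70 consecutive volumes at the
#' default, centered on the volume of interest) is subtracted channel-wise.
#' The window shrinks symmetrically near the record edges; if fewer volumes
#' than a full window exist at all, a message flags it.
#'
#' @param raw A [raw_eeg()] record.
#' @param volume_triggers Volume onset samples (default
#'   `raw$triggers$volume`).
#' @param template_halfwidth Half-width of the template window in volumes
#'   (default 35).
#' @param spacing_tol Allowed deviation of trigger spacing from its median,
#'   in samples (default 1); irregular spacing is an error.
#' @return Cleaned [raw_eeg()].
#' @export
remove_gradient_artifact <- function(raw, volume_triggers = NULL,
                                     template_halfwidth = 35,
                                     spacing_tol = 1) {
  stopifnot(inherits(raw, "raw_eeg"))
  trig <- volume_triggers %||% raw$triggers$volume
  if (is.null(trig) || length(trig) < 2) {
    abort("At least two volume triggers are required.")
  }
  sp <- diff(trig)
  vol_len <- round(median(sp))
  if (any(abs(sp - vol_len) > spacing_tol)) {
    abort("Irregular volume trigger spacing beyond tolerance.")
  }
  n_vol <- length(trig)
  if (n_vol < 2 * template_halfwidth) {
    inform(sprintf("Only %d volumes available; template window shrinks below %d volumes.",
                   n_vol, 2 * template_halfwidth))
  }
  vol_len <- min(vol_len, ncol(raw$data) - trig[n_vol] + 1)
  n_ch <- nrow(raw$data)
  # segment stack and its cumulative sum over volumes for O(1) window means
  segs <- array(0, dim = c(n_ch, vol_len, n_vol))
  for (j in seq_len(n_vol)) {
    segs[, , j] <- raw$data[, trig[j] + seq_len(vol_len) - 1]
  }
  csum <- array(0, dim = c(n_ch, vol_len, n_vol + 1))
  for (j in seq_len(n_vol)) csum[, , j + 1] <- csum[, , j] + segs[, , j]
  out <- raw$data
  width <- min(2 * template_halfwidth + 1, n_vol)
  for (j in seq_len(n_vol)) {
    # centered window, clipped at the record edges but kept at full width so
    # edge volumes never degenerate toward subtracting themselves
    a <- min(max(1, j - template_halfwidth), n_vol - width + 1)
    b <- a + width - 1
    templ <- (csum[, , b + 1] - csum[, , a]) / width
    idx <- trig[j] + seq_len(vol_len) - 1
    out[, idx] <- out[, idx] - templ
  }
  raw_eeg(out, fs_hz = raw$fs_hz, channels = raw$channels,
          triggers = raw$triggers)
}

#' Median-filter despiking
#'
#' Running median per channel with a window of `width_ms` milliseconds
#' (rounded up to an odd sample count), removing residual spike artifacts
#' while leaving locally monotone signal unchanged.
#'
#' @param raw A [raw_eeg()].
#' @param width_ms Window width in ms (default 12).
#' @return Filtered [raw_eeg()].
#' @export
despike_median <- function(raw, width_ms = 12) {
  stopifnot(inherits(raw, "raw_eeg"))
  k <- max(3, round(width_ms * raw$fs_hz / 1000))
  if (k %% 2 == 0) k <- k + 1
  out <- t(apply(raw$data, 1, function(x) stats::runmed(x, k)))
  raw_eeg(out, fs_hz = raw$fs_hz, channels = raw$channels,
          triggers = raw$triggers)
}

# zero-phase frequency-domain filter with raised-cosine band edges; immune
# to the numerical instability of high-order IIR designs at band ratios like
# 0.5 Hz on a multi-kHz record
fft_filter <- function(x, fs, low = NULL, high = NULL, trans_frac = 0.5) {
  n <- length(x)
  f <- abs(seq(0, fs, length.out = n + 1)[seq_len(n)])
  f <- pmin(f, fs - f)
  gain <- rep(1, n)
  if (!is.null(low) && low > 0) {
    lo0 <- low * (1 - trans_frac)
    ramp <- f > lo0 & f < low
    gain[f <= lo0] <- 0
    gain[ramp] <- 0.5 - 0.5 * cos(pi * (f[ramp] - lo0) / (low - lo0))
  }
  if (!is.null(high)) {
    hi1 <- high * (1 + trans_frac)
    ramp <- f > high & f < hi1
    gain[f >= hi1] <- 0
    gain[ramp] <- 0.5 + 0.5 * cos(pi * (f[ramp] - high) / (hi1 - high))
  }
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

#' Bandpass filter and downsample
#'
#' Zero-phase frequency-domain bandpass (raised-cosine transition bands),
#' default 0.5-20 Hz, then integer-factor downsampling to `target_fs` (the
#' sub-Nyquist passband doubles as the anti-alias filter). Trigger samples
#' are re-indexed by the exact decimation ratio.
#'
#' @param raw A [raw_eeg()].
#' @param low,high Passband edges in Hz (defaults 0.5 and 20).
#' @param target_fs Output sampling rate; must divide `raw$fs_hz` exactly.
#' @return Filtered, downsampled [raw_eeg()].
#' @export
bandpass_and_downsample <- function(raw, low = 0.5, high = 20,
                                    target_fs = 1000) {
  stopifnot(inherits(raw, "raw_eeg"))
  out <- t(apply(raw$data, 1, fft_filter, fs = raw$fs_hz, low = low,
                 high = high))
  fac <- raw$fs_hz / target_fs
  if (fac != round(fac)) abort("`target_fs` must divide the sampling rate exactly.")
  fac <- as.integer(fac)
  triggers <- raw$triggers
  if (fac > 1) {
    out <- out[, seq(1, ncol(out), by = fac), drop = FALSE]
    triggers <- lapply(triggers, function(tr) pmax(1L, as.integer((tr - 1) %/% fac + 1)))
  }
  raw_eeg(out, fs_hz = target_fs, channels = raw$channels,
          triggers = triggers)
}

# orthonormal basis of the top spatial principal components of a segment set
spatial_pcs <- function(X) {
  # X: channels x samples; rows centered
  Xc <- X - rowMeans(X)
  e <- eigen(tcrossprod(Xc) / (ncol(Xc) - 1), symmetric = TRUE)
  list(U = e$vectors, var_frac = e$values / sum(e$values))
}

#' Blink component removal
#'
#' Fits spatial principal components on calibration-blink segments and
#' projects out of the whole record every component whose calibration-segment
#' variance fraction exceeds `var_threshold`.
#'
#' @param raw A [raw_eeg()].
#' @param calibration_triggers Blink onset samples (default
#'   `raw$triggers$blink`). With no calibration blinks the record is returned
#'   unchanged with a warning.
#' @param var_threshold Variance fraction above which a component is deemed
#'   blink-related (default 0.2).
#' @param window_s Segment length after each trigger (default 0.3 s).
#' @return Cleaned [raw_eeg()]; removed spatial components are in
#'   `attr(x, "removed_components")`.
#' @export
remove_blink_components <- function(raw, calibration_triggers = NULL,
                                    var_threshold = 0.2, window_s = 0.3) {
  stopifnot(inherits(raw, "raw_eeg"))
  trig <- calibration_triggers %||% raw$triggers$blink
  if (is.null(trig) || length(trig) == 0) {
    warn("No calibration blinks; record returned unchanged.")
    return(raw)
  }
  len <- round(window_s * raw$fs_hz)
  trig <- trig[trig + len - 1 <= ncol(raw$data)]
  seg <- do.call(cbind, lapply(trig, function(b)
    raw$data[, b + seq_len(len) - 1]))
  pcs <- spatial_pcs(seg)
  keep <- which(pcs$var_frac > var_threshold)
  if (!length(keep)) {
    warn("No component exceeded the blink variance threshold; record unchanged.")
    return(raw)
  }
  U <- pcs$U[, keep, drop = FALSE]
  cleaned <- raw$data - U %*% crossprod(U, raw$data)
  out <- raw_eeg(cleaned, fs_hz = raw$fs_hz, channels = raw$channels,
                 triggers = raw$triggers)
  attr(out, "removed_components") <- U
  out
}

#' Az-guided ballistocardiogram component selection
#'
#' Estimates spatial principal components on a copy of the record low-passed
#' at `lp_hz` (the band where BCG power concentrates), builds candidate
#' datasets with the top `k = 0..k_max` component weightings projected onto
#' the broadband data and subtracted, scores each candidate with the supplied
#' classification scorer, and keeps the dataset with peak performance (ties
#' toward fewer components).
#'
#' @param raw A [raw_eeg()].
#' @param scorer Function `raw_eeg -> Az` (typically epochs + LOO Az of the
#'   decoding stage).
#' @param k_max Maximum number of components to try (default 5).
#' @param lp_hz Low-pass edge for component estimation (default 4).
#' @return List with `k` (selected count), `cleaned` ([raw_eeg()]),
#'   `scores` (tibble of k, az, skipped).
#' @export
select_bcg_components <- function(raw, scorer, k_max = 5, lp_hz = 4) {
  stopifnot(inherits(raw, "raw_eeg"), is.function(scorer))
  if (k_max == 0) {
    return(list(k = 0L, cleaned = raw,
                scores = tibble(k = 0L, az = NA_real_, skipped = FALSE)))
  }
  lp <- t(apply(raw$data, 1, fft_filter, fs = raw$fs_hz, high = lp_hz))
  pcs <- spatial_pcs(lp)
  candidates <- vector("list", k_max + 1)
  scores <- rep(NA_real_, k_max + 1)
  skipped <- rep(FALSE, k_max + 1)
  for (k in 0:k_max) {
    cand <- if (k == 0) raw$data else {
      U <- pcs$U[, seq_len(k), drop = FALSE]
      raw$data - U %*% crossprod(U, raw$data)
    }
    cand_raw <- raw_eeg(cand, fs_hz = raw$fs_hz, channels = raw$channels,
                        triggers = raw$triggers)
    candidates[[k + 1]] <- cand_raw
    sc <- tryCatch(scorer(cand_raw), error = function(e) NA_real_)
    if (is.na(sc)) {
      skipped[k + 1] <- TRUE
      warn(sprintf("Scorer failed at k = %d; candidate skipped.", k))
    } else {
      scores[k + 1] <- sc
    }
  }
  if (all(is.na(scores))) abort("Scorer failed for every candidate.")
  k_star <- which.max(scores) - 1L  # which.max takes the first (smallest k) tie
  list(k = k_star, cleaned = candidates[[k_star + 1]],
       scores = tibble(k = 0:k_max, az = scores, skipped = skipped))
}

#' Cut stimulus-locked epochs from a continuous record
#'
#' @param raw A [raw_eeg()].
#' @param stimulus_triggers Stimulus onset samples.
#' @param t_start,t_end Epoch window relative to each trigger (s).
#' @param labels Optional tibble of per-trial labels.
#' @return An [eeg_epochs()].
#' @export
epoch_raw <- function(raw, stimulus_triggers = NULL, t_start = -0.1,
                      t_end = 0.8, labels = NULL) {
  stopifnot(inherits(raw, "raw_eeg"))
  trig <- stimulus_triggers %||% raw$triggers$stimulus
  if (is.null(trig) || !length(trig)) abort("No stimulus triggers.")
  pre <- round(-t_start * raw$fs_hz)
  post <- round(t_end * raw$fs_hz)
  ok <- trig - pre >= 1 & trig + post <= ncol(raw$data)
  if (!all(ok)) {
    warn(sprintf("%d trigger(s) too close to the record edge dropped.", sum(!ok)))
    trig <- trig[ok]
    if (!is.null(labels)) labels <- labels[ok, ]
  }
  n_samp <- pre + post + 1
  data <- array(0, dim = c(length(trig), nrow(raw$data), n_samp))
  for (i in seq_along(trig)) {
    data[i, , ] <- raw$data[, (trig[i] - pre):(trig[i] + post)]
  }
  eeg_epochs(data, fs_hz = raw$fs_hz, t0 = t_start, labels = labels)
}
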