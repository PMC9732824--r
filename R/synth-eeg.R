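#' Specification for synthetic epoched EEG
#'
#' Describes 64-channel, 1000-Hz stimulus-locked epochs containing a
#' difficulty-modulated linear build-up (the planted accumulation component)
#' mixed into channel space through a fixed unit-norm topography, an evoked
#' response, and white sensor noise. The component waveform per trial is an
#' early evoked deflection (peak then dip) followed by a ramp that starts at
#' a trial-specific onset and is truncated (held) at the response time.
#'
#' @param n_channels Number of channels (default 64).
#' @param fs_hz Sampling rate (default 1000).
#' @param t_start,t_end Epoch window relative to stimulus onset, seconds
#'   (defaults -0.1 and 0.8).
#' @param topography Unit-norm mixing vector of length `n_channels`; default
#'   a smooth centroparietal-like bump.
#' @param slope_by_difficulty Named ramp slopes (component units/s) for
#'   `easy`, `medium`, `hard`; must satisfy easy > medium > hard > 0.
#' @param slope_sd_frac Per-trial SD of the slope as a fraction of its
#'   condition mean (default 0.3).
#' @param onset_mean_s,onset_sd_s Per-trial ramp onset distribution (normal,
#'   defaults 0.363 and 0.097 s), clipped to `onset_clip`.
#' @param onset_clip Onset clipping range (default `c(0.2, 0.6)` s).
#' @param evoked_amp Amplitude of the evoked waveform (component units).
#' @param noise_sd Per-channel white noise SD.
#' @param seed Integer seed.
#' @return Object of class `synth_eeg_spec`.
#' @export
synth_eeg_spec <- function(n_channels = 64, fs_hz = 1000,
                           t_start = -0.1, t_end = 0.8,
                           topography = NULL,
                           slope_by_difficulty = c(easy = 3, medium = 2,
                                                   hard = 1),
                           slope_sd_frac = 0.3,
                           onset_mean_s = 0.363, onset_sd_s = 0.097,
                           onset_clip = c(0.2, 0.6),
                           evoked_amp = 1, noise_sd = 4, seed = 1L) {
  if (is.null(topography)) topography <- default_topography(n_channels)
  if (length(topography) != n_channels) {
    abort("`topography` must have length `n_channels`.")
  }
  if (abs(sum(topography^2) - 1) > 1e-8) {
    abort("`topography` must have unit norm.")
  }
  s <- slope_by_difficulty
  if (!(s[["easy"]] > s[["medium"]] && s[["medium"]] > s[["hard"]] &&
        s[["hard"]] > 0)) {
    abort("Slopes must satisfy easy > medium > hard > 0.")
  }
  structure(list(n_channels = n_channels, fs_hz = fs_hz, t_start = t_start,
                 t_end = t_end, topography = topography,
                 slope_by_difficulty = s, slope_sd_frac = slope_sd_frac,
                 onset_mean_s = onset_mean_s, onset_sd_s = onset_sd_s,
                 onset_clip = onset_clip, evoked_amp = evoked_amp,
                 noise_sd = noise_sd, seed = seed),
            class = "synth_eeg_spec")
}

#' Default smooth unit-norm topography
#' @param n_channels Number of channels.
#' @param center Relative position of the bump (0..1, default 0.7).
#' @return Unit-norm numeric vector.
#' @export
default_topography <- function(n_channels, center = 0.7) {
  x <- seq(0, 1, length.out = n_channels)
  w <- exp(-0.5 * ((x - center) / 0.12)^2)
  w / sqrt(sum(w^2))
}

# Early evoked peak of the component waveform; the dip preceding the ramp is
# built per trial so that its trough coincides with the accumulation onset.
evoked_wave <- function(t) {
  dnorm(t, 0.12, 0.03) / dnorm(0.12, 0.12, 0.03)
}

# per-trial component: evoked peak, half-cosine descent into a trough at the
# onset, then a linear build-up truncated (held) at the response
component_wave <- function(t, onset, slope, rt, evoked_amp, dip_amp = 0.5,
                           dip_start = 0.18) {
  y <- evoked_amp * evoked_wave(t)
  dip <- numeric(length(t))
  o <- max(onset, dip_start + 0.02)
  pre <- t > dip_start & t <= o
  dip[pre] <- -dip_amp * (1 - cos(pi * (t[pre] - dip_start) /
                                    (o - dip_start))) / 2
  post <- t > o
  t_stop <- max(o, rt)
  dip[post] <- -dip_amp + slope * pmin(t[post] - o, max(t_stop - o, 0))
  y + dip
}

difficulty_label <- function(code) c("easy", "medium", "hard")[code]

#' Generate synthetic EEG epochs from a behavioral table
#'
#' Builds one epoch per behavioral trial. The planted component has an early
#' evoked peak, a half-cosine descent into a trough exactly at the
#' trial-specific accumulation onset, and a linear build-up from the trough
#' whose slope is the difficulty-condition mean perturbed by
#' `slope_sd_frac`; the build-up is held constant after the response time.
#' Channel data are the component mixed through the spec topography, plus an
#' orthogonal visual-evoked distractor and white noise. Ground-truth onsets
#' and slopes are carried in the label table (`true_onset_s`, `true_slope`).
#'
#' @param behavior Trial table from [synth_behavior()] (needs `difficulty`
#'   or `p_level`, `choice`, `rt_s`).
#' @param spec A [synth_eeg_spec()].
#' @return An [eeg_epochs()] object; the mixing topography is in
#'   `attr(x, "topography")`. Trials whose RT precedes the drawn onset get a
#'   zero-length ramp and are flagged in `labels$ramp_flagged`.
#' @export
synth_eeg_epochs <- function(behavior, spec = synth_eeg_spec()) {
  behavior <- as_tibble(behavior)
  if (!"difficulty" %in% names(behavior) || anyNA(behavior$difficulty)) {
    if (!"p_level" %in% names(behavior)) {
      abort("`behavior` needs a `difficulty` or `p_level` column.")
    }
    behavior$difficulty <- level_to_difficulty(behavior$p_level)
  }
  stopifnot(all(c("choice", "rt_s") %in% names(behavior)))
  set.seed(spec$seed)
  n_trials <- nrow(behavior)
  t <- seq(spec$t_start, spec$t_end, by = 1 / spec$fs_hz)
  n_samples <- length(t)
  # orthogonal distractor: early visual response through a frontal-occipital
  # pattern orthogonalized against the component topography
  d_raw <- default_topography(spec$n_channels, center = 0.25)
  d_topo <- d_raw - sum(d_raw * spec$topography) * spec$topography
  d_topo <- d_topo / sqrt(sum(d_topo^2))
  d_wave <- spec$evoked_amp * dnorm(t, 0.15, 0.04) / dnorm(0.15, 0.15, 0.04)

  slopes_cond <- spec$slope_by_difficulty[difficulty_label(behavior$difficulty)]
  onset <- pmin(pmax(rnorm(n_trials, spec$onset_mean_s, spec$onset_sd_s),
                     spec$onset_clip[1]), spec$onset_clip[2])
  slope <- slopes_cond * pmax(1 + spec$slope_sd_frac * rnorm(n_trials), 0.05)
  ramp_flagged <- behavior$rt_s < onset
  if (any(ramp_flagged)) {
    warn(sprintf("%d trial(s) responded before the drawn onset; zero-length ramp planted.",
                 sum(ramp_flagged)))
  }
  data <- array(rnorm(n_trials * spec$n_channels * n_samples,
                      sd = spec$noise_sd),
                dim = c(n_trials, spec$n_channels, n_samples))
  for (i in seq_len(n_trials)) {
    y <- component_wave(t, onset[i], slope[i],
                        min(behavior$rt_s[i], spec$t_end), spec$evoked_amp)
    data[i, , ] <- data[i, , ] + outer(spec$topography, y) +
      outer(d_topo, d_wave)
  }
  labels <- behavior
  labels$difficulty_label <- difficulty_label(labels$difficulty)
  labels$true_onset_s <- onset
  labels$true_slope <- unname(slope)
  labels$ramp_flagged <- ramp_flagged
  out <- eeg_epochs(data, fs_hz = spec$fs_hz, t0 = spec$t_start,
                    labels = labels)
  attr(out, "topography") <- spec$topography
  out
}

#' Clean continuous EEG background record
#'
#' White-noise multichannel record used as the substrate for the artifact
#' generator; carries an empty trigger set.
#'
#' @param n_channels,n_seconds,fs_hz Record geometry.
#' @param sd Noise SD.
#' @param seed Integer seed.
#' @return A [raw_eeg()] object.
#' @export
synth_raw_eeg <- function(n_channels = 8, n_seconds = 60, fs_hz = 1000,
                          sd = 1, seed = 1L) {
  set.seed(seed)
  n <- round(n_seconds * fs_hz)
  raw_eeg(matrix(rnorm(n_channels * n, sd = sd), nrow = n_channels),
          fs_hz = fs_hz)
}

#' Specification for synthetic EEG artifacts
#'
#' @param gradient_period_s MR volume repetition period (s).
#' @param gradient_amp Gradient artifact amplitude.
#' @param gradient_drift Linear scaling drift of the gradient template across
#'   the record (0 = identical template every volume).
#' @param bcg_period_s,bcg_jitter_s Ballistocardiogram period and timing
#'   jitter SD (s).
#' @param bcg_amp BCG amplitude.
#' @param bcg_topography Optional unit-norm BCG spatial pattern.
#' @param blink_rate_hz Mean blink rate.
#' @param blink_amp Blink amplitude.
#' @param seed Integer seed.
#' @return Object of class `synth_artifact_spec`.
#' @export
synth_artifact_spec <- function(gradient_period_s = 2, gradient_amp = 50,
                                gradient_drift = 0,
                                bcg_period_s = 1.0, bcg_jitter_s = 0.08,
                                bcg_amp = 10, bcg_topography = NULL,
                                blink_rate_hz = 0.2, blink_amp = 30,
                                seed = 1L) {
  if (gradient_period_s <= 0 || bcg_period_s <= 0) {
    abort("All artifact periods must be > 0.")
  }
  structure(list(gradient_period_s = gradient_period_s,
                 gradient_amp = gradient_amp,
                 gradient_drift = gradient_drift,
                 bcg_period_s = bcg_period_s, bcg_jitter_s = bcg_jitter_s,
                 bcg_amp = bcg_amp, bcg_topography = bcg_topography,
                 blink_rate_hz = blink_rate_hz, blink_amp = blink_amp,
                 seed = seed),
            class = "synth_artifact_spec")
}

#' Contaminate a clean record with scanner artifacts
#'
#' Adds (1) a gradient artifact: a fixed high-frequency template repeated at
#' each volume trigger, optionally drifting linearly in amplitude; (2) a
#' quasi-periodic ballistocardiogram with a fixed spatial pattern; and (3)
#' stereotyped frontal blinks. Ground-truth artifact-only signals are kept in
#' `attr(x, "ground_truth")` for testing; volume and blink triggers are
#' recorded on the returned object.
#'
#' @param clean A [raw_eeg()] record.
#' @param spec A [synth_artifact_spec()].
#' @param volume_triggers Optional explicit volume trigger samples; default
#'   one per `gradient_period_s` from sample 1. Triggers beyond the record
#'   are rejected.
#' @param blink_times Optional explicit blink sample indices (e.g.
#'   calibration blinks); default Poisson at `blink_rate_hz`.
#' @return A [raw_eeg()] with artifacts added.
#' @export
synth_raw_eeg_with_artifacts <- function(clean, spec = synth_artifact_spec(),
                                         volume_triggers = NULL,
                                         blink_times = NULL) {
  stopifnot(inherits(clean, "raw_eeg"), inherits(spec, "synth_artifact_spec"))
  set.seed(spec$seed)
  n_ch <- nrow(clean$data)
  n <- ncol(clean$data)
  fs <- clean$fs_hz
  vol_len <- round(spec$gradient_period_s * fs)
  if (is.null(volume_triggers)) {
    volume_triggers <- seq(1, n - vol_len + 1, by = vol_len)
  }
  if (max(volume_triggers) + vol_len - 1 > n || min(volume_triggers) < 1) {
    abort("Volume trigger list extends past the record.")
  }
  # gradient template: deterministic broadband sawtooth-like burst, identical
  # across channels up to a per-channel gain
  tt <- seq_len(vol_len) / fs
  template <- spec$gradient_amp *
    (sin(2 * pi * 120 * tt) + 0.5 * sin(2 * pi * 300 * tt + 1) +
       0.25 * sign(sin(2 * pi * 60 * tt)))
  ch_gain <- seq(0.8, 1.2, length.out = n_ch)
  gradient <- matrix(0, n_ch, n)
  for (j in seq_along(volume_triggers)) {
    idx <- volume_triggers[j] + seq_len(vol_len) - 1
    scale_j <- 1 + spec$gradient_drift * (j - 1) / max(1, length(volume_triggers) - 1)
    gradient[, idx] <- gradient[, idx] + scale_j * (ch_gain %o% template)
  }
  # BCG: biphasic pulse at quasi-periodic times through a fixed pattern
  bcg_topo <- spec$bcg_topography
  if (is.null(bcg_topo)) {
    v <- rnorm(n_ch)
    bcg_topo <- v / sqrt(sum(v^2))
  }
  pulse_t <- seq(0, 0.4, by = 1 / fs)
  pulse <- sin(2 * pi * pulse_t / 0.4) * exp(-((pulse_t - 0.1) / 0.12)^2)
  beats <- cumsum(pmax(spec$bcg_period_s +
                         rnorm(ceiling(n / fs / spec$bcg_period_s) + 5,
                               0, spec$bcg_jitter_s), 0.3))
  beat_samp <- round(beats * fs)
  beat_samp <- beat_samp[beat_samp + length(pulse) <= n & beat_samp >= 1]
  bcg <- matrix(0, n_ch, n)
  for (b in beat_samp) {
    idx <- b + seq_along(pulse) - 1
    bcg[, idx] <- bcg[, idx] + spec$bcg_amp * (bcg_topo %o% pulse)
  }
  # blinks: gaussian bump through a frontal pattern
  if (is.null(blink_times)) {
    n_blinks <- stats::rpois(1, spec$blink_rate_hz * n / fs)
    blink_times <- sort(sample.int(n - round(0.4 * fs), max(n_blinks, 0)))
  }
  if (length(blink_times) && (max(blink_times) + round(0.3 * fs) > n ||
                              min(blink_times) < 1)) {
    abort("Blink time list extends past the record.")
  }
  blink_topo <- exp(-(seq_len(n_ch) - 1) / 2)
  blink_topo <- blink_topo / sqrt(sum(blink_topo^2))
  bw_t <- seq(0, 0.3, by = 1 / fs)
  bw <- dnorm(bw_t, 0.15, 0.05) / dnorm(0.15, 0.15, 0.05)
  blink <- matrix(0, n_ch, n)
  for (b in blink_times) {
    idx <- b + seq_along(bw) - 1
    blink[, idx] <- blink[, idx] + spec$blink_amp * (blink_topo %o% bw)
  }
  out <- raw_eeg(clean$data + gradient + bcg + blink, fs_hz = fs,
                 channels = clean$channels,
                 triggers = utils::modifyList(clean$triggers,
                                              list(volume = volume_triggers,
                                                   blink = blink_times)))
  attr(out, "ground_truth") <- list(gradient = gradient, bcg = bcg,
                                    blink = blink, bcg_topography = bcg_topo,
                                    blink_topography = blink_topo)
  out
}
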