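test_that("gradient template subtraction cancels a volume-locked artifact", {
  clean <- synth_raw_eeg(n_channels = 4, n_seconds = 30, fs_hz = 500,
                         sd = 0, seed = 91)
  clean$data <- clean$data + outer(rep(1, 4), sin(2 * pi * 9.7 *
                                                    seq_len(ncol(clean$data)) / 500))
  spec <- synth_artifact_spec(gradient_period_s = 1, gradient_amp = 50,
                              bcg_amp = 0, blink_amp = 0, blink_rate_hz = 0,
                              seed = 92)
  dirty <- synth_raw_eeg_with_artifacts(clean, spec)
  out <- suppressMessages(remove_gradient_artifact(dirty))
  gt <- attr(dirty, "ground_truth")
  # artifact gone
  expect_lt(sum((out$data - clean$data)[, 1:14500]^2) / sum(gt$gradient^2),
            1e-3)
  # the non-volume-locked 10 Hz carrier survives within 5% amplitude
  seg <- out$data[1, 2000:10000]
  ref <- clean$data[1, 2000:10000]
  expect_gt(cor(seg, ref), 0.99)
  expect_lt(abs(sd(seg) - sd(ref)) / sd(ref), 0.05)
  expect_error(remove_gradient_artifact(dirty,
                                        volume_triggers = c(1, 400, 1200)),
               "Irregular")
})

test_that("a sliding template tracks slow artifact drift better than a global one", {
  clean <- synth_raw_eeg(n_channels = 2, n_seconds = 80, fs_hz = 250,
                         sd = 0.5, seed = 93)
  spec <- synth_artifact_spec(gradient_period_s = 1, gradient_amp = 30,
                              gradient_drift = 0.5, bcg_amp = 0,
                              blink_amp = 0, blink_rate_hz = 0, seed = 94)
  dirty <- synth_raw_eeg_with_artifacts(clean, spec)
  sliding <- suppressMessages(remove_gradient_artifact(dirty,
                                                       template_halfwidth = 10))
  global <- suppressMessages(remove_gradient_artifact(dirty,
                                                      template_halfwidth = 1000))
  res_s <- sum((sliding$data - clean$data)^2)
  res_g <- sum((global$data - clean$data)^2)
  expect_lt(res_s, res_g)
})

test_that("median despiking removes isolated spikes and leaves ramps alone", {
  fs <- 1000
  x <- seq(0, 1, length.out = fs)          # monotone ramp
  raw <- raw_eeg(rbind(x, x), fs_hz = fs)
  raw$data[1, 500] <- 50                    # isolated one-sample spike
  out <- despike_median(raw, width_ms = 12)
  # spike replaced by the local running median (within one sample of the ramp)
  expect_lt(abs(out$data[1, 500] - x[500]), 1.5 / fs)
  inner <- 20:(fs - 20)
  expect_equal(out$data[2, inner], x[inner], tolerance = 1e-12)
  # white-noise variance shrinks roughly like the variance of a sample median
  set.seed(95)
  noise <- raw_eeg(matrix(rnorm(2 * 4000), 2), fs_hz = fs)
  sm <- despike_median(noise, width_ms = 12)
  k <- 13
  oracle <- var(replicate(3000, median(rnorm(k))))
  expect_equal(var(as.numeric(sm$data[, 50:3950])), oracle,
               tolerance = 0.25 * oracle)
})

test_that("bandpass keeps 10 Hz, rejects 40 Hz and DC, and re-indexes triggers", {
  fs <- 4000
  t <- seq_len(8 * fs) / fs
  sig <- 2 + sin(2 * pi * 10 * t) + sin(2 * pi * 40 * t)
  raw <- raw_eeg(rbind(sig), fs_hz = fs,
                 triggers = list(stimulus = c(4000L, 16000L)))
  out <- bandpass_and_downsample(raw, 0.5, 20, target_fs = 1000)
  expect_identical(out$fs_hz, 1000)
  expect_identical(out$triggers$stimulus, c(1000L, 4000L))
  inner <- 1500:6500
  tt <- inner / 1000
  amp10 <- 2 * abs(mean(out$data[1, inner] * exp(-2i * pi * 10 * tt)))
  amp40 <- 2 * abs(mean(out$data[1, inner] * exp(-2i * pi * 40 * tt)))
  expect_gt(amp10, 10^(-1 / 20))          # within 1 dB of unit amplitude
  expect_lt(amp40, 10^(-20 / 20))         # at least 20 dB down
  expect_lt(abs(mean(out$data[1, inner])), 0.02)  # DC removed
  expect_error(bandpass_and_downsample(raw, target_fs = 900), "divide")
})

test_that("blink components are identified on calibration segments and projected out", {
  set.seed(96)
  fs <- 500
  n <- 40 * fs
  n_ch <- 32
  base <- matrix(rnorm(n_ch * n, sd = 0.5), n_ch)
  blink_topo <- exp(-(seq_len(n_ch) - 1) / 2)
  blink_topo <- blink_topo / sqrt(sum(blink_topo^2))
  bw <- dnorm(seq(0, 0.3, by = 1 / fs), 0.15, 0.05) * 3
  times <- seq(2 * fs, n - fs, by = 4 * fs)
  blinks <- matrix(0, n_ch, n)
  for (b in times) blinks[, b + seq_along(bw) - 1] <- blink_topo %o% bw
  raw <- raw_eeg(base + blinks, fs_hz = fs, triggers = list(blink = times))
  out <- remove_blink_components(raw)
  U <- attr(out, "removed_components")
  expect_gt(abs(cor(U[, 1], blink_topo)), 0.95)
  # blink energy removed, non-blink signal preserved
  expect_lt(sum((out$data - base)^2), 0.1 * sum(blinks^2))
  expect_gt(sum(out$data * base) / sum(base^2), 0.95)
  # no calibration blinks: identity with a warning
  raw2 <- raw_eeg(base, fs_hz = fs)
  expect_warning(same <- remove_blink_components(raw2), "No calibration")
  expect_identical(same$data, base)
})

test_that("Az-guided BCG selection finds the planted component count", {
  set.seed(97)
  fs <- 250
  clean <- synth_raw_eeg(n_channels = 8, n_seconds = 120, fs_hz = fs,
                         sd = 1, seed = 98)
  # plant a discriminable low-frequency signal: two trial types differing in
  # a slow component mixed through a fixed topography
  topo <- default_topography(8, 0.6)
  stim <- as.integer(seq(2 * fs, ncol(clean$data) - 2 * fs, by = 2 * fs))
  labels <- rep(c(FALSE, TRUE), length.out = length(stim))
  sig <- dnorm(seq(0, 0.8, by = 1 / fs), 0.4, 0.15)
  sig <- 4 * sig / max(sig)
  for (i in seq_along(stim)) {
    idx <- stim[i] + seq_along(sig) - 1
    amp <- ifelse(labels[i], 2, 1)
    clean$data[, idx] <- clean$data[, idx] + amp * (topo %o% sig)
  }
  clean$triggers$stimulus <- stim
  ortho <- rnorm(8); ortho <- ortho - sum(ortho * topo) * topo
  ortho <- ortho / sqrt(sum(ortho^2))
  bcg_topo <- 0.9 * topo + sqrt(1 - 0.81) * ortho
  spec <- synth_artifact_spec(gradient_amp = 0, bcg_amp = 40,
                              bcg_period_s = 1, bcg_topography = bcg_topo,
                              blink_amp = 0,
                              blink_rate_hz = 0, seed = 99)
  dirty <- synth_raw_eeg_with_artifacts(clean, spec)
  scorer <- function(r) {
    ep <- epoch_raw(r, r$triggers$stimulus, t_start = 0, t_end = 0.8)
    loo_az(ep, labels, center_s = 0.4, gamma = 0.08, window_len_ms = 200)
  }
  sel <- suppressWarnings(select_bcg_components(dirty, scorer, k_max = 3,
                                                lp_hz = 4))
  expect_gte(sel$k, 1)
  az0 <- sel$scores$az[sel$scores$k == 0]
  expect_gte(sel$scores$az[sel$scores$k == sel$k], az0)
  # the selected components capture most of the planted BCG variance
  gt <- attr(dirty, "ground_truth")
  removed <- dirty$data - sel$cleaned$data
  expect_gt(sum(removed * gt$bcg) / sum(gt$bcg^2), 0.7)
  # k_max = 0 is the identity
  sel0 <- select_bcg_components(dirty, scorer, k_max = 0)
  expect_identical(sel0$cleaned$data, dirty$data)
})
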