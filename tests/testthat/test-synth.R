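test_that("behavioral generator is reproducible and validates its spec", {
  b1 <- synth_behavior(ref_params, n_trials_per_level = 15, seed = 71)
  b2 <- synth_behavior(ref_params, n_trials_per_level = 15, seed = 71)
  expect_identical(b1, b2)
  expect_setequal(unique(b1$context), c("social", "nonsocial"))
  expect_true(all(b1$choice %in% c(-1, 1)))
  expect_true(all(b1$rt_s >= 0.3))
  expect_error(synth_behavior(ref_params, evidence_levels = c(-1, 0, 0.5)),
               "symmetric|increasing")
  expect_error(synth_behavior(ref_params, n_trials_per_level = 0), ">= 1")
})

test_that("noiseless epochs reconstruct the planted component exactly", {
  beh <- fix_behavior[1:12, ]
  spec <- synth_eeg_spec(n_channels = 16, noise_sd = 0, seed = 72,
                         slope_sd_frac = 0)
  ep <- suppressWarnings(synth_eeg_epochs(beh, spec))
  t <- epoch_times(ep)
  topo <- attr(ep, "topography")
  for (i in c(1, 5, 12)) {
    y_rec <- as.numeric(topo %*% ep$data[i, , ])
    y_true <- neuroaccum:::component_wave(
      t, ep$labels$true_onset_s[i], ep$labels$true_slope[i],
      min(ep$labels$rt_s[i], spec$t_end), spec$evoked_amp)
    # the distractor is orthogonal to the component topography
    expect_equal(y_rec, y_true, tolerance = 1e-10)
  }
})

test_that("condition-mean ramps preserve the planted slope ordering", {
  beh <- synth_behavior(ref_params, n_trials_per_level = 25, seed = 73)
  spec <- synth_eeg_spec(n_channels = 16, noise_sd = 0, seed = 74,
                         slope_sd_frac = 0,
                         slope_by_difficulty = c(easy = 3, medium = 2,
                                                 hard = 1))
  ep <- suppressWarnings(synth_eeg_epochs(beh, spec))
  sl <- ep$labels$true_slope
  d <- ep$labels$difficulty
  expect_gt(min(sl[d == 1]), max(sl[d == 2]) - 1e-12)
  expect_gt(min(sl[d == 2]), max(sl[d == 3]) - 1e-12)
  expect_error(synth_eeg_spec(slope_by_difficulty = c(easy = 1, medium = 2,
                                                      hard = 3)),
               "easy > medium > hard")
})

test_that("responses earlier than the onset are flagged with zero-length ramps", {
  beh <- fix_behavior[1:10, ]
  beh$rt_s <- 0.15   # before any clipped onset
  spec <- synth_eeg_spec(n_channels = 8, noise_sd = 0, seed = 75)
  expect_warning(ep <- synth_eeg_epochs(beh, spec), "before the drawn onset")
  expect_true(all(ep$labels$ramp_flagged))
})

test_that("artifact generator: zero amplitudes are the identity, templates cancel", {
  clean <- synth_raw_eeg(n_channels = 6, n_seconds = 24, fs_hz = 500,
                         sd = 0, seed = 76)
  spec0 <- synth_artifact_spec(gradient_amp = 0, bcg_amp = 0, blink_amp = 0,
                               blink_rate_hz = 0, seed = 77)
  out0 <- synth_raw_eeg_with_artifacts(clean, spec0)
  expect_equal(out0$data, clean$data, tolerance = 1e-12)
  # zero-amplitude identity also on a noisy record
  noisy <- synth_raw_eeg(n_channels = 3, n_seconds = 10, fs_hz = 500,
                         seed = 761)
  expect_equal(synth_raw_eeg_with_artifacts(noisy, spec0)$data, noisy$data,
               tolerance = 1e-12)
  # identical gradient template at every volume: subtraction nearly exact
  spec1 <- synth_artifact_spec(gradient_amp = 40, bcg_amp = 0, blink_amp = 0,
                               blink_rate_hz = 0, gradient_drift = 0,
                               seed = 78)
  dirty <- synth_raw_eeg_with_artifacts(clean, spec1)
  gt <- attr(dirty, "ground_truth")
  cleaned <- suppressMessages(remove_gradient_artifact(dirty))
  resid <- cleaned$data - clean$data
  expect_lt(sum(resid^2) / sum(gt$gradient^2), 1e-10)
  # triggers past the record are rejected
  expect_error(synth_raw_eeg_with_artifacts(clean, spec1,
                                            volume_triggers = c(1, 1e7)),
               "past the record")
})

test_that("zero-noise BOLD volumes return the planted betas exactly", {
  trials <- make_trials_for_glm(30, seed = 79)
  n_scans <- scans_for(trials)
  des <- build_task_design(trials, tr_s = 2, n_scans = n_scans)
  mask <- blob_mask(c(10, 10, 6), c(5, 5, 3), 1)
  spec <- synth_bold_spec(grid = c(10, 10, 6), noise_sd = 1e-12, ar1 = 0,
                          effects = list(list(regressor = "social_slope",
                                              mask = mask, beta = -2)),
                          seed = 80)
  vol <- synth_bold(des, spec)
  fit <- fit_glm(vol, des)
  beta <- stat_volume(fit, "social_slope", "beta")
  expect_equal(beta[mask], rep(-2, sum(mask)), tolerance = 1e-6)
  expect_equal(beta[!mask], rep(0, sum(!mask)), tolerance = 1e-6)
  # mask dimension mismatches are rejected
  bad <- synth_bold_spec(grid = c(10, 10, 6),
                         effects = list(list(regressor = "social_slope",
                                             mask = blob_mask(c(4, 4, 4),
                                                              c(2, 2, 2), 1),
                                             beta = 1)))
  expect_error(synth_bold(des, bad), "mask")
})

test_that("generators are bit-identical under fixed seeds", {
  s <- synth_eeg_spec(n_channels = 8, seed = 81)
  e1 <- suppressWarnings(synth_eeg_epochs(fix_behavior[1:8, ], s))
  e2 <- suppressWarnings(synth_eeg_epochs(fix_behavior[1:8, ], s))
  expect_identical(e1$data, e2$data)
  clean <- synth_raw_eeg(4, 10, 500, seed = 82)
  a <- synth_artifact_spec(seed = 83)
  expect_identical(synth_raw_eeg_with_artifacts(clean, a)$data,
                   synth_raw_eeg_with_artifacts(clean, a)$data)
})
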