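test_that("double-gamma HRF has the canonical shape", {
  t <- seq(0, 32, by = 0.01)
  h <- hrf_double_gamma(t)
  expect_equal(t[which.max(h)], 5, tolerance = 0.3)   # peak near 5-6 s
  expect_true(all(hrf_double_gamma(seq(-5, -0.01, by = 0.1)) == 0))
  expect_lt(min(h), 0)                                 # undershoot present
  expect_equal(sum(h) * 0.01, 1 - 1 / 6, tolerance = 0.01)
})

test_that("design columns are impulse responses and superpose linearly", {
  tr_s <- 2; n_scans <- 60
  one <- glm_design(list(a = tibble::tibble(onset = 10, duration = 0.1,
                                            amplitude = 1)),
                    tr_s, n_scans)
  scan_t <- (seq_len(n_scans) - 1) * tr_s
  # boxcar width smoothing: the column integrates the HRF over 100 ms,
  # i.e. the midpoint-sampled HRF to second order
  ref <- 0.1 * hrf_double_gamma(scan_t - 10 - 0.05)
  expect_equal(one$X[, "a"], ref, tolerance = 0.02)
  two <- glm_design(list(a = tibble::tibble(onset = c(10, 40),
                                            duration = 0.1,
                                            amplitude = c(1, 2))),
                    tr_s, n_scans)
  shifted <- glm_design(list(a = tibble::tibble(onset = 40, duration = 0.1,
                                                amplitude = 2)),
                        tr_s, n_scans)
  expect_equal(two$X[, "a"], one$X[, "a"] + shifted$X[, "a"],
               tolerance = 1e-10)
  expect_error(glm_design(list(a = tibble::tibble(onset = 500, duration = 1,
                                                  amplitude = 1)),
                          tr_s, n_scans), "outside")
})

test_that("modulated amplitudes are mean-centered and shuffles preserve onsets", {
  trials <- make_trials_for_glm(30, seed = 121)
  des <- build_task_design(trials, tr_s = 2, n_scans = scans_for(trials))
  for (nm in des$modulated) {
    expect_equal(mean(des$events[[nm]]$amplitude), 0, tolerance = 1e-10)
  }
  set.seed(122)
  sh <- neuroaccum:::shuffle_design_amplitudes(des)
  nm <- "social_slope"
  expect_identical(sh$events[[nm]]$onset, des$events[[nm]]$onset)
  expect_setequal(sh$events[[nm]]$amplitude, des$events[[nm]]$amplitude)
  expect_false(identical(sh$X[, nm], des$X[, nm]))
  # rebuilding from the cached basis equals a fresh convolution
  ref <- neuroaccum:::convolve_events(sh$events[[nm]], des$tr_s, des$n_scans)
  expect_equal(sh$X[, nm], ref, tolerance = 1e-10)
})

test_that("GLM residuals are orthogonal to the design and z maps are finite", {
  trials <- make_trials_for_glm(30, seed = 123)
  des <- build_task_design(trials, tr_s = 2, n_scans = scans_for(trials))
  spec <- synth_bold_spec(grid = c(8, 8, 4), seed = 124)
  vol <- synth_bold(des, spec)
  fit <- fit_glm(vol, des)
  Y <- t(matrix(vol$data, ncol = dim(vol$data)[4]))
  res <- Y - des$X %*% fit$beta
  expect_lt(max(abs(crossprod(des$X, res))), 1e-6)
  expect_true(all(is.finite(fit$z)))
  # rank-deficient designs are rejected with the offending column named
  des_bad <- des
  des_bad$X <- cbind(des$X, social_slope_copy = des$X[, "social_slope"])
  des_bad$names <- colnames(des_bad$X)
  expect_error(fit_glm(vol, des_bad), "social_slope")
})

test_that("t-to-z conversion matches tail probabilities", {
  tv <- c(-6, -1.2, 0, 0.8, 4.5)
  z <- t_to_z(tv, df = 40)
  expect_equal(pnorm(z), pt(tv, 40), tolerance = 1e-10)
  expect_true(all(sign(z) == sign(tv)))
})

test_that("cluster labeling uses 26-connectivity on both signs", {
  z <- array(0, c(6, 6, 4))
  z[2, 2, 2] <- 3; z[3, 3, 3] <- 3.5   # diagonal neighbors: one cluster
  z[6, 6, 4] <- -4                      # separate negative cluster
  ct <- cluster_table(z, z_thr = 2.57)
  expect_identical(nrow(ct), 2L)
  pos <- ct[ct$sign == 1, ]
  expect_identical(pos$size, 2L)
  expect_equal(pos$max_abs_z, 3.5)
  expect_identical(ct$size[ct$sign == -1], 1L)
})

test_that("resampling threshold flags a planted effect but not pure noise", {
  trials <- make_trials_for_glm(40, seed = 125)
  n_scans <- scans_for(trials)
  des <- build_task_design(trials, tr_s = 2, n_scans = n_scans)
  grid <- c(14, 14, 8)
  mask <- blob_mask(grid, c(7, 7, 4), 2)
  spec <- synth_bold_spec(grid = grid,
                          effects = list(list(regressor = "social_slope",
                                              mask = mask, beta = -30)),
                          seed = 126)
  vol <- synth_bold(des, spec)
  fit <- fit_glm(vol, des)
  thr <- resample_cluster_threshold(vol, des, "social_slope", n_iter = 40,
                                    seed = 127)
  ct <- cluster_table(stat_volume(fit, "social_slope"), thr$z_thr,
                      min_size = thr$size_thr)
  expect_gte(nrow(ct), 1)
  expect_identical(ct$sign[which.max(ct$size)], -1)
  expect_warning(resample_cluster_threshold(vol, des, "social_slope",
                                            n_iter = 5, seed = 1),
                 "unstable")
})

test_that("PPI design recovers planted coupling and rejects degenerate inputs", {
  trials <- make_trials_for_glm(40, seed = 128)
  n_scans <- scans_for(trials)
  des <- build_task_design(trials, tr_s = 2, n_scans = n_scans)
  grid <- c(12, 12, 6)
  seed_mask <- blob_mask(grid, c(4, 4, 3), 1)
  target <- blob_mask(grid, c(9, 9, 3), 1)
  psych0 <- build_ppi_design(rnorm(n_scans), trials, 2, n_scans)$X[, "psych"]
  spec <- synth_bold_spec(grid = grid,
                          ppi = list(seed_mask = seed_mask,
                                     target_mask = target,
                                     coupling = -0.5, psych = psych0),
                          seed = 129)
  vol <- synth_bold(des, spec)
  seed_ts <- extract_seed_timeseries(vol, seed_mask)
  ppi <- build_ppi_design(seed_ts, trials, 2, n_scans)
  fit <- fit_glm(vol, ppi)
  b <- stat_volume(fit, "interaction", "beta")
  expect_equal(mean(b[target]), -0.5, tolerance = 0.1)
  # zero coupling: interaction beta centered on zero elsewhere
  expect_lt(abs(mean(b[!target & !seed_mask])), 0.05)
  # constant difficulty makes the psychological factor degenerate
  const <- trials; const$difficulty <- 2
  expect_error(build_ppi_design(seed_ts, const, 2, n_scans), "collinear")
  # seed extraction identities
  expect_error(extract_seed_timeseries(vol, array(FALSE, grid)), "empty")
  one <- array(FALSE, grid); one[3, 3, 3] <- TRUE
  expect_equal(extract_seed_timeseries(vol, one), vol$data[3, 3, 3, ])
})

test_that("slope and RT regressors are only moderately correlated on synthetic behavior", {
  beh <- synth_behavior(ref_params, n_trials_per_level = 40, seed = 130)
  set.seed(131)
  beh$onset_s <- seq(8, by = 7, length.out = nrow(beh))
  # slopes fall with difficulty plus endogenous variability, as planted
  cond_slope <- c(3, 2, 1)[beh$difficulty]
  beh$slope <- cond_slope * (1 + 0.3 * rnorm(nrow(beh)))
  r <- cor(beh$slope, beh$rt_s)
  expect_lt(r, 0)          # shallower build-up, longer RT
  expect_lt(abs(r), 0.5)
})

test_that("file round trips preserve behavioral tables, events, epochs and volumes", {
  tmp <- withr::local_tempdir()
  b <- fix_behavior[1:10, ]
  write_behavior_tsv(b, file.path(tmp, "beh.tsv"))
  b2 <- read_behavior_tsv(file.path(tmp, "beh.tsv"))
  expect_equal(as.data.frame(b2), as.data.frame(b), tolerance = 1e-12)
  ev <- tibble::tibble(onset = c(1.5, 9), duration = 0.1,
                       amplitude = c(-0.3, 2))
  write_events_fsl(ev, file.path(tmp, "ev.txt"))
  expect_equal(read_events_fsl(file.path(tmp, "ev.txt")), ev,
               tolerance = 1e-12)
  ep <- eeg_epochs(array(rnorm(4 * 3 * 10), c(4, 3, 10)), fs_hz = 100,
                   t0 = -0.02,
                   labels = tibble::tibble(difficulty = c(1, 2, 3, 1)))
  write_epochs(ep, file.path(tmp, "ep"))
  ep2 <- read_epochs(file.path(tmp, "ep"))
  expect_equal(ep2$data, ep$data, tolerance = 1e-12)
  expect_equal(ep2$labels$difficulty, ep$labels$difficulty)
  vol <- volume_series(array(rnorm(4 * 4 * 2 * 6), c(4, 4, 2, 6)), tr_s = 2)
  write_bold_nifti(vol, file.path(tmp, "bold.nii.gz"))
  vol2 <- read_bold_nifti(file.path(tmp, "bold.nii.gz"))
  expect_equal(vol2$data, vol$data, tolerance = 1e-6)
  expect_equal(vol2$tr_s, 2)
})
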