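test_that("Fisher direction recovers an axis-aligned mean difference", {
  set.seed(111)
  n <- 1500; d <- 8
  X1 <- matrix(rnorm(n * d), n)
  X2 <- matrix(rnorm(n * d), n)
  X2[, 3] <- X2[, 3] + 2
  fit <- fda_train(X1, X2, gamma = 0.02)
  cosine <- abs(fit$w[3]) / sqrt(sum(fit$w^2))
  expect_gte(cosine, 0.99)
  # identical class means: projections separate no better than chance
  X2b <- matrix(rnorm(n * d), n)
  fitb <- fda_train(X1, X2b, gamma = 0.02)
  proj <- c(X1 %*% fitb$w, X2b %*% fitb$w)
  az <- neuroaccum:::az_auc(proj, rep(c(FALSE, TRUE), each = n))
  expect_lt(abs(az - 0.5), 0.06)
  # full shrinkage reduces to the mean difference direction
  fit1 <- fda_train(X1, X2, gamma = 1)
  diffm <- colMeans(X2) - colMeans(X1)
  expect_equal(fit1$w / sqrt(sum(fit1$w^2)), diffm / sqrt(sum(diffm^2)),
               tolerance = 1e-10)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(112)
  proj <- rnorm(120)
  lab <- runif(120) < plogis(proj)
  az_pkg <- neuroaccum:::az_auc(proj, lab)
  az_ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(lab, proj,
                                                            quiet = TRUE))))
  expect_equal(az_pkg, az_ref, tolerance = 1e-12)
})

test_that("leave-one-out projections equal brute-force refits", {
  set.seed(113)
  n <- 14; d <- 5
  X <- matrix(rnorm(2 * n * d), 2 * n)
  X[(n + 1):(2 * n), 2] <- X[(n + 1):(2 * n), 2] + 1
  is2 <- rep(c(FALSE, TRUE), each = n)
  proj <- neuroaccum:::loo_projections(X, is2, gamma = 0.04)
  for (j in c(1, 7, 20, 28)) {
    fit <- fda_train(X[-j, , drop = FALSE][!is2[-j], , drop = FALSE],
                     X[-j, , drop = FALSE][is2[-j], , drop = FALSE],
                     gamma = 0.04)
    expect_equal(proj[j], sum(X[j, ] * fit$w), tolerance = 1e-8)
  }
})

test_that("sliding discrimination finds the late window on planted ramps", {
  lab <- fix_epochs$labels
  keep <- lab$difficulty %in% c(1, 3)
  ep <- eeg_epochs(fix_epochs$data[keep, , ], fix_epochs$fs_hz,
                   fix_epochs$t0, lab[keep, ])
  m <- sliding_loo_az(ep, ep$labels$difficulty == 3)
  expect_true(all(m$az$az >= 0 & m$az$az <= 1))
  expect_gt(m$peak_time, 0.35)
  expect_gt(m$peak_az, 0.6)
  # pre-stimulus windows carry no information
  pre <- m$az$az[m$az$time < 0]
  expect_lt(mean(pre), 0.58)
})

test_that("bootstrap Az threshold is above chance, reproducible, and tightens with n", {
  lab <- fix_epochs$labels
  keep <- lab$difficulty %in% c(1, 3)
  ep <- eeg_epochs(fix_epochs$data[keep, , ], fix_epochs$fs_hz,
                   fix_epochs$t0, lab[keep, ])
  is2 <- ep$labels$difficulty == 3
  b1 <- bootstrap_az_threshold(ep, is2, center_s = 0.6, gamma = 0.04,
                               n_iter = 120, seed = 5)
  b2 <- bootstrap_az_threshold(ep, is2, center_s = 0.6, gamma = 0.04,
                               n_iter = 120, seed = 5)
  expect_identical(b1$threshold, b2$threshold)
  expect_gt(b1$threshold, 0.5)
  # halving the trial count inflates the null Az spread and the threshold
  half <- seq_len(nrow(ep$labels)) %% 2 == 0
  ep_half <- eeg_epochs(ep$data[half, , ], ep$fs_hz, ep$t0,
                        ep$labels[half, ])
  b_half <- bootstrap_az_threshold(ep_half, is2[half], center_s = 0.6,
                                   gamma = 0.04, n_iter = 120, seed = 6)
  expect_gt(b_half$threshold, b1$threshold)
})

test_that("forward model obeys its algebraic identities and recovers a plant", {
  set.seed(115)
  a0 <- default_topography(12, 0.4)
  y <- rnorm(400)
  X_exact <- outer(y, a0)           # trials x channels, exactly rank one
  expect_equal(forward_model(X_exact, y), a0, tolerance = 1e-12)
  # scaling law: a(c*y) = a(y)/c
  expect_equal(forward_model(X_exact, 2 * y),
               forward_model(X_exact, y) / 2, tolerance = 1e-12)
  # consistency under independent noise
  X_noisy <- X_exact + matrix(rnorm(400 * 12, sd = 0.5), 400)
  a_hat <- forward_model(X_noisy, y)
  expect_gte(sum(a_hat * a0) / sqrt(sum(a_hat^2)), 0.95)
})

test_that("component time courses are z-scored per context", {
  ctx <- fix_epochs$labels$context
  comp <- component_timecourses(fix_epochs, attr(fix_epochs, "topography"),
                                context = ctx)
  for (cx in unique(ctx)) {
    y <- comp$y[ctx == cx, ]
    expect_equal(mean(y), 0, tolerance = 1e-10)
    expect_equal(sd(y), 1, tolerance = 1e-10)
  }
})

test_that("onset detection recovers a planted onset at low noise and flags pure noise", {
  beh <- synth_behavior(list(a = ref_params$social), n_trials_per_level = 15,
                        seed = 116)
  beh$rt_s <- pmax(beh$rt_s, 0.75)
  spec <- synth_eeg_spec(n_channels = 8, noise_sd = 0.1, onset_sd_s = 0.001,
                         seed = 117)
  ep <- suppressWarnings(synth_eeg_epochs(beh, spec))
  comp <- component_timecourses(ep, attr(ep, "topography"))
  cm <- condition_means(comp)
  for (cond in c("easy", "medium")) {
    tr <- cm[cm$condition == cond, ]
    on <- detect_onset(tr$mean_y, tr$time)
    expect_false(on$flagged)
    expect_lt(abs(on$onset_s - 0.363), 0.02)
  }
  # a monotone trace has no dip: the sustained-rise fallback is flagged
  on0 <- detect_onset(seq(0, 1, length.out = 901),
                      seq(-0.1, 0.8, by = 1e-3))
  expect_true(on0$flagged)
})

test_that("trial slopes are exact on lines and flipping is an involution", {
  times <- seq(-0.1, 0.8, by = 1e-3)
  slopes_true <- c(-1.5, 0.3, 2.2)
  y <- vapply(slopes_true, function(s) 0.2 + s * times, numeric(length(times)))
  sl <- trial_slopes(t(y), onset_s = 0.3, peak_s = 0.7, times = times)
  expect_equal(sl, slopes_true, tolerance = 1e-10)
  p_level <- c(1, 2, 5)
  expect_identical(flip_slopes(flip_slopes(sl, p_level), p_level), sl)
  expect_equal(flip_slopes(sl, p_level)[1:2], -sl[1:2])
  expect_error(trial_slopes(t(y), 0.7, 0.3, times = times), "exceed")
})

test_that("onset realignment sharpens jittered traces and flags truncation", {
  times <- seq(-0.1, 0.8, by = 1e-3)
  onsets <- c(0.25, 0.35, 0.45)
  traces <- t(vapply(onsets, function(o) pmax(times - o, 0) * 2,
                     numeric(length(times))))
  # identical onsets: realignment is a pure shift of every row equally
  same <- realign_to_onset(traces[c(1, 1), ], c(0.25, 0.25), times)
  expect_equal(same$y[1, ], same$y[2, ])
  re <- realign_to_onset(traces, onsets, times)
  ok <- colSums(is.na(re$y)) == 0
  realigned_mean <- colMeans(re$y[, ok])
  unaligned_mean <- colMeans(traces[, ok])
  n_ok <- sum(ok)
  late <- seq_len(n_ok) > n_ok / 2
  slope_of <- function(v) {
    tt <- seq_along(v); unname(coef(lm(v ~ tt))[2])
  }
  expect_gt(slope_of(realigned_mean[late]), slope_of(unaligned_mean[late]))
  # out-of-range onset: full truncation flagged
  expect_warning(tr <- realign_to_onset(traces, c(0.25, 0.35, 5), times),
                 "truncated")
  expect_true(tr$truncated[3])
})
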