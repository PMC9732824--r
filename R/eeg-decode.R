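#' Sliding-window discriminant analysis settings
#'
#' @param window_len_ms Window length in ms (default 60); channel data are
#'   averaged across the window before discrimination.
#' @param step_ms Spacing of window centers (default 20).
#' @param t_min,t_max Range of window centers relative to stimulus onset (s).
#' @param shrinkage_grid Candidate covariance shrinkage values (the
#'   regularization weight toward a spherical covariance), each in `[0, 1]`.
#' @return Object of class `fda_config`.
#' @export
fda_config <- function(window_len_ms = 60, step_ms = 20, t_min = -0.1,
                       t_max = 0.8,
                       shrinkage_grid = c(0, 0.01, 0.02, 0.04, 0.08, 0.16)) {
  if (any(shrinkage_grid < 0 | shrinkage_grid > 1)) {
    abort("Shrinkage values must lie in [0, 1].")
  }
  structure(list(window_len_ms = window_len_ms, step_ms = step_ms,
                 t_min = t_min, t_max = t_max,
                 shrinkage_grid = shrinkage_grid),
            class = "fda_config")
}

#' Average channel data over a time window
#'
#' @param epochs An [eeg_epochs()].
#' @param center_s Window center relative to stimulus onset (s).
#' @param window_len_ms Window length (ms).
#' @return Matrix trials x channels.
#' @export
window_average <- function(epochs, center_s, window_len_ms = 60) {
  t <- epoch_times(epochs)
  half <- window_len_ms / 2000
  idx <- which(t >= center_s - half - 1e-9 & t <= center_s + half + 1e-9)
  if (!length(idx)) abort("Window lies outside the epoch.")
  if (length(idx) == 1) return(epochs$data[, , idx])
  apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
}

regularize_cov <- function(S, gamma) {
  nu <- mean(diag(S))
  (1 - gamma) * S + gamma * nu * diag(nrow(S))
}

#' Train a regularized Fisher discriminant on window data
#'
#' Class means are taken over window-averaged channel data; the common
#' covariance is the average of the shrinkage-regularized class covariances
#' `(1-gamma)*S_i + gamma*nu*I` (`nu` = average eigenvalue of `S_i`), and the
#' weight vector solves `S_common w = m2 - m1`. At `gamma = 0` a singular
#' covariance falls back to a pseudo-inverse with a warning.
#'
#' @param X1,X2 Matrices trials x channels for class 1 and class 2.
#' @param gamma Shrinkage in `[0, 1]`.
#' @return List with `w`, `m1`, `m2`.
#' @export
fda_train <- function(X1, X2, gamma = 0.02) {
  if (nrow(X1) < 2 || nrow(X2) < 2) abort("Both classes need >= 2 trials.")
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  S1 <- regularize_cov(cov(X1), gamma)
  S2 <- regularize_cov(cov(X2), gamma)
  Sc <- (S1 + S2) / 2
  diffm <- m2 - m1
  w <- tryCatch(solve(Sc, diffm), error = function(e) {
    warn("Singular common covariance; pseudo-inverse used.")
    sv <- svd(Sc)
    pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], diffm)) / sv$d[pos])
  })
  list(w = as.numeric(w), m1 = m1, m2 = m2)
}

# rank-based area under the ROC curve: probability that a class-1 projection
# exceeds a class-0 projection (ties at 1/2)
az_auc <- function(proj, is_class2) {
  n1 <- sum(is_class2); n0 <- sum(!is_class2)
  r <- rank(proj)
  (sum(r[is_class2]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# leave-one-trial-out projections at one window via class-wise scatter
# downdates; X: trials x channels, is2: logical class membership
loo_projections <- function(X, is2, gamma) {
  D <- ncol(X)
  I_D <- diag(D)
  proj <- numeric(nrow(X))
  stats_for <- function(M) {
    list(n = nrow(M), s = colSums(M), A = crossprod(M))
  }
  st <- list(stats_for(X[!is2, , drop = FALSE]),
             stats_for(X[is2, , drop = FALSE]))
  if (st[[1]]$n < 3 || st[[2]]$n < 3) abort("Both classes need >= 3 trials for LOO.")
  cov_from <- function(n, s, A) {
    m <- s / n
    (A - n * tcrossprod(m)) / (n - 1)
  }
  for (j in seq_len(nrow(X))) {
    cls <- if (is2[j]) 2L else 1L
    x <- X[j, ]
    held <- st
    held[[cls]]$n <- st[[cls]]$n - 1L
    held[[cls]]$s <- st[[cls]]$s - x
    held[[cls]]$A <- st[[cls]]$A - tcrossprod(x)
    m1 <- held[[1]]$s / held[[1]]$n
    m2 <- held[[2]]$s / held[[2]]$n
    S1 <- cov_from(held[[1]]$n, held[[1]]$s, held[[1]]$A)
    S2 <- cov_from(held[[2]]$n, held[[2]]$s, held[[2]]$A)
    Sc <- ((1 - gamma) * (S1 + S2) +
             gamma * (mean(diag(S1)) + mean(diag(S2))) * I_D) / 2
    w <- tryCatch(solve(Sc, m2 - m1), error = function(e) {
      qr.solve(Sc + 1e-10 * mean(diag(Sc)) * I_D, m2 - m1)
    })
    proj[j] <- sum(x * w)
  }
  proj
}

#' Leave-one-out Az at a single window
#'
#' @param epochs An [eeg_epochs()].
#' @param is_class2 Logical per-trial class membership (e.g. hard = TRUE).
#' @param center_s Window center (s).
#' @param gamma Covariance shrinkage.
#' @param window_len_ms Window length (ms).
#' @return Scalar Az in `[0, 1]`.
#' @export
loo_az <- function(epochs, is_class2, center_s, gamma = 0.02,
                   window_len_ms = 60) {
  X <- window_average(epochs, center_s, window_len_ms)
  az_auc(loo_projections(X, is_class2, gamma), is_class2)
}

#' Sliding-window leave-one-out discrimination performance
#'
#' For every window center and every shrinkage value in the grid, computes
#' the leave-one-trial-out Az between the two classes; the shrinkage is then
#' chosen by peak LOO Az and the peak window is the argmax of the winning Az
#' time course (ties toward the earlier window). The returned model carries
#' the discriminant weights refit on all trials at the peak window.
#'
#' @param epochs An [eeg_epochs()].
#' @param is_class2 Logical per-trial class labels (TRUE = class 2, e.g.
#'   hard trials).
#' @param cfg An [fda_config()].
#' @return Object of class `fda_model`: list with `az` (tibble of `time`,
#'   `az` for the selected shrinkage), `az_by_gamma` (matrix), `gamma`,
#'   `peak_time`, `peak_az`, `w` (weights at the peak window), `config`.
#' @export
sliding_loo_az <- function(epochs, is_class2, cfg = fda_config()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  is_class2 <- as.logical(is_class2)
  n1 <- sum(!is_class2); n2 <- sum(is_class2)
  if (max(n1, n2) / min(n1, n2) > 10) warn("Class imbalance exceeds 10:1.")
  if (min(n1, n2) < 20) inform("Fewer than 20 trials per class; Az estimates will be noisy.")
  t <- epoch_times(epochs)
  half <- cfg$window_len_ms / 2000
  centers <- seq(cfg$t_min, cfg$t_max, by = cfg$step_ms / 1000)
  centers <- centers[centers - half >= t[1] - 1e-9 &
                       centers + half <= t[length(t)] + 1e-9]
  Xw <- lapply(centers, function(cc)
    window_average(epochs, cc, cfg$window_len_ms))
  az <- matrix(NA_real_, length(centers), length(cfg$shrinkage_grid),
               dimnames = list(NULL, paste0("g", cfg$shrinkage_grid)))
  for (gi in seq_along(cfg$shrinkage_grid)) {
    g <- cfg$shrinkage_grid[gi]
    for (wi in seq_along(centers)) {
      az[wi, gi] <- az_auc(loo_projections(Xw[[wi]], is_class2, g), is_class2)
    }
  }
  best_gi <- which.max(apply(az, 2, max))
  az_best <- az[, best_gi]
  peak_wi <- which.max(az_best)  # first index on ties = earlier window
  gamma <- cfg$shrinkage_grid[best_gi]
  fit <- fda_train(Xw[[peak_wi]][!is_class2, , drop = FALSE],
                   Xw[[peak_wi]][is_class2, , drop = FALSE], gamma)
  # the discriminant's sign is arbitrary; orient the weights so the
  # grand-average projection rises toward the peak window (build-up
  # convention), leaving Az unchanged
  xbar <- apply(epochs$data, c(2, 3), mean)
  ybar <- as.numeric(crossprod(xbar, fit$w))
  late <- t >= 0.3 * t[length(t)]
  tc <- t[late] - mean(t[late])
  if (sum(tc * ybar[late]) < 0) fit$w <- -fit$w
  structure(list(az = tibble(time = centers, az = az_best),
                 az_by_gamma = az, gamma = gamma,
                 peak_time = centers[peak_wi], peak_az = az_best[peak_wi],
                 w = fit$w, config = cfg),
            class = "fda_model")
}

#' @export
print.fda_model <- function(x, ...) {
  cat(sprintf("<fda_model> peak Az = %.3f at %g ms (shrinkage %g)\n",
              x$peak_az, 1000 * x$peak_time, x$gamma))
  invisible(x)
}

#' Bootstrap Az significance threshold
#'
#' Null distribution of the leave-one-out Az at one window obtained by
#' permuting trial labels; the threshold is the `1 - alpha` quantile, a
#' participant-specific alternative to assuming Az = 0.5 chance level.
#'
#' @param epochs An [eeg_epochs()].
#' @param is_class2 Logical trial labels.
#' @param center_s Window at which to compute the null (typically the peak
#'   window).
#' @param gamma Covariance shrinkage.
#' @param n_iter Permutations (default 500).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @param window_len_ms Window length (ms).
#' @return List with `threshold`, `null_az` (vector), `alpha`.
#' @export
bootstrap_az_threshold <- function(epochs, is_class2, center_s, gamma = 0.02,
                                   n_iter = 500, alpha = 0.05, seed = 1L,
                                   window_len_ms = 60) {
  X <- window_average(epochs, center_s, window_len_ms)
  set.seed(seed)
  null_az <- vapply(seq_len(n_iter), function(i) {
    lab <- sample(is_class2)
    az_auc(loo_projections(X, lab, gamma), lab)
  }, numeric(1))
  list(threshold = as.numeric(quantile(null_az, 1 - alpha)),
       null_az = null_az, alpha = alpha)
}

#' Forward model of a discriminant component
#'
#' The channel-space coupling `a = X y / (y' y)`: the pattern whose rank-1
#' combination with the component best explains the data. Scaling the
#' weights by `c` scales `y` by `c` and `a` by `1/c`.
#'
#' @param X Window data, trials x channels.
#' @param y Component amplitudes per trial.
#' @return Numeric channel vector.
#' @export
forward_model <- function(X, y) {
  stopifnot(nrow(X) == length(y))
  as.numeric(crossprod(X, y) / sum(y^2))
}

#' Component time courses from a spatial filter
#'
#' Applies the discriminant weights of the peak window across the entire
#' stimulus-locked epoch, `y(trial, t) = w' x(trial, t)`, then z-scores the
#' matrix separately per context (over all trials and samples of that
#' context).
#'
#' @param epochs An [eeg_epochs()].
#' @param w Channel weight vector.
#' @param context Optional per-trial context labels for the z-scoring
#'   (default: one shared context).
#' @return Object of class `component_timecourse`: list with `y`
#'   (trials x samples, z-scored), `times`, `labels`.
#' @export
component_timecourses <- function(epochs, w, context = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  stopifnot(length(w) == d[2])
  flat <- matrix(aperm(epochs$data, c(2, 1, 3)), nrow = d[2])
  y <- matrix(crossprod(flat, w), nrow = d[1])
  if (is.null(context)) context <- rep("all", d[1])
  for (cx in unique(context)) {
    i <- context == cx
    y[i, ] <- (y[i, ] - mean(y[i, ])) / sd(y[i, ])
  }
  structure(list(y = y, times = epoch_times(epochs), labels = epochs$labels,
                 context = context),
            class = "component_timecourse")
}

#' @export
print.component_timecourse <- function(x, ...) {
  cat(sprintf("<component_timecourse> %d trials x %d samples\n",
              nrow(x$y), ncol(x$y)))
  invisible(x)
}

#' Condition-mean component traces
#'
#' @param comp A [component_timecourses()] result.
#' @param by Label column to average by (default `difficulty_label`).
#' @return Tibble with `condition`, `time`, `mean_y`.
#' @export
condition_means <- function(comp, by = "difficulty_label") {
  stopifnot(inherits(comp, "component_timecourse"),
            by %in% names(comp$labels))
  g <- comp$labels[[by]]
  purrr::map_dfr(unique(g), function(cond) {
    tibble(condition = cond, time = comp$times,
           mean_y = colMeans(comp$y[g == cond, , drop = FALSE]))
  })
}

#' Detect the accumulation onset in a mean component trace
#'
#' Smooths the trace with a moving average, then finds the last local
#' minimum (the post-evoked dip) preceding the pre-peak rise within the
#' search window; its time is the onset. With no dip, the first time of a
#' sustained positive derivative is used and the result is flagged.
#'
#' @param mean_y Condition-mean component trace.
#' @param times Sample times (s).
#' @param search Search window (default `c(0.15, 0.6)` s).
#' @param smooth_ms Moving-average width (default 50 ms).
#' @return List with `onset_s`, `peak_s` (global maximum after onset) and
#'   `flagged`.
#' @export
detect_onset <- function(mean_y, times, search = c(0.15, 0.6),
                         smooth_ms = 50) {
  fs <- 1 / median(diff(times))
  k <- max(3, round(smooth_ms * fs / 1000))
  sm <- as.numeric(stats::filter(mean_y, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- mean_y[is.na(sm)]
  # the build-up peak lies beyond the onset search window; restricting the
  # peak search there keeps early evoked deflections out of the way
  in_post <- times >= search[2]
  peak_i <- which(in_post)[which.max(sm[in_post])]
  peak_s <- times[peak_i]
  win <- which(times >= search[1] & times <= min(search[2], peak_s))
  onset_i <- NA_integer_
  if (length(win) > 2) {
    # the dip: deepest point of the smoothed trace between the early evoked
    # response and the pre-peak rise; accept only a true interior minimum
    cand <- win[which.min(sm[win])]
    interior <- cand > win[1] && cand < peak_i &&
      cand > 1 && cand < length(sm) &&
      sm[cand] <= sm[cand - 1] && sm[cand] <= sm[cand + 1]
    if (interior) onset_i <- cand
  }
  flagged <- is.na(onset_i)
  if (flagged) {
    dy <- diff(sm)
    run <- max(3, round(0.05 * fs))
    cand <- which(times[-length(times)] >= search[1] &
                    times[-length(times)] <= search[2])
    onset_i <- NA_integer_
    for (i in cand) {
      if (i + run - 1 <= length(dy) && all(dy[i:(i + run - 1)] > 0)) {
        onset_i <- i
        break
      }
    }
    if (is.na(onset_i)) onset_i <- win[1]
  }
  list(onset_s = times[onset_i], peak_s = peak_s, flagged = flagged)
}

#' Per-trial build-up slopes of the component
#'
#' Ordinary least-squares slope of `y(t)` on `t` between onset and peak,
#' separately per trial.
#'
#' @param comp A [component_timecourses()] result (or a trials x samples
#'   matrix with a `times` argument).
#' @param onset_s,peak_s Regression interval bounds (s).
#' @param times Required when `comp` is a bare matrix.
#' @return Numeric vector of slopes (component units per second).
#' @export
trial_slopes <- function(comp, onset_s, peak_s, times = NULL) {
  if (inherits(comp, "component_timecourse")) {
    y <- comp$y; times <- comp$times
  } else {
    y <- comp
    if (is.null(times)) abort("`times` required for a bare matrix.")
  }
  if (peak_s <= onset_s) abort("`peak_s` must exceed `onset_s`.")
  idx <- which(times >= onset_s & times <= peak_s)
  if (length(idx) < 2) abort("Fewer than two samples between onset and peak.")
  tc <- times[idx] - mean(times[idx])
  yc <- y[, idx, drop = FALSE]
  yc <- yc - rowMeans(yc)
  as.numeric(yc %*% tc) / sum(tc^2)
}

#' Flip slope signs for keep-favoring reward levels
#'
#' Aligns EEG build-up rates with the accumulator's signed-drift convention:
#' levels 1 and 2 (reward probabilities 0-0.2 and 0.2-0.4) favor keep
#' choices, so their slopes change sign. Flipping twice is the identity.
#'
#' @param slopes Numeric slopes.
#' @param p_level Reward-probability level per trial (1..5).
#' @return Signed slopes.
#' @export
flip_slopes <- function(slopes, p_level) {
  stopifnot(length(slopes) == length(p_level), all(p_level %in% 1:5))
  slopes * ifelse(p_level %in% c(1, 2), -1, 1)
}

#' Re-align traces to per-subject onsets
#'
#' Shifts each row of a subjects x samples matrix of condition means so that
#' its own onset lands at time zero, truncating shifted-out samples (flagged
#' as NA).
#'
#' @param traces Matrix subjects x samples.
#' @param onsets_s Per-subject onset times (s).
#' @param times Sample times (s).
#' @return List with `y` (realigned matrix, NA-padded), `times`
#'   (onset-relative), `truncated` (logical per subject).
#' @export
realign_to_onset <- function(traces, onsets_s, times) {
  stopifnot(nrow(traces) == length(onsets_s))
  fs <- 1 / median(diff(times))
  out <- matrix(NA_real_, nrow(traces), ncol(traces))
  truncated <- rep(FALSE, nrow(traces))
  for (i in seq_len(nrow(traces))) {
    start <- round((onsets_s[i] - times[1]) * fs) + 1
    if (start > ncol(traces)) {
      truncated[i] <- TRUE
      warn(sprintf("Subject %d: onset beyond epoch end; trace truncated entirely.", i))
      next
    }
    start <- max(start, 1)
    src <- start:ncol(traces)
    out[i, seq_along(src)] <- traces[i, src]
    truncated[i] <- start > 1
  }
  list(y = out, times = (seq_len(ncol(traces)) - 1) / fs,
       truncated = truncated)
}
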