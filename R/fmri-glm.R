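#' Canonical double-gamma hemodynamic response function
#'
#' `h(t) = g(t; peak) - g(t; undershoot)/ratio` with gamma-density lobes.
#' Positive lobe peaks near `peak_delay` seconds; the kernel integrates to a
#' finite value and is 0 for `t < 0`.
#'
#' @param t Time grid in seconds.
#' @param peak_delay,peak_disp Delay and dispersion of the positive lobe
#'   (defaults 6 and 1 s).
#' @param under_delay,under_disp Delay and dispersion of the undershoot
#'   (defaults 16 and 1 s).
#' @param ratio Peak-to-undershoot amplitude ratio (default 6).
#' @return Numeric vector of HRF values.
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, under_delay = 16,
                             peak_disp = 1, under_disp = 1, ratio = 6) {
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    stats::dgamma(t, shape = under_delay / under_disp, scale = under_disp) / ratio
  h[t < 0] <- 0
  h
}

# Unit responses of boxcar events under the HRF, evaluated analytically: the
# convolution of a boxcar [onset, onset+dur) with h equals
# H(t - onset) - H(t - onset - dur), where H is the running integral of h on
# a 10-ms grid. Returns a scans x events matrix so a design column is
# `basis %*% amplitudes` and amplitude shuffles need no re-convolution.
event_basis <- function(events, tr_s, n_scans, dt = 0.01,
                        hrf_params = list()) {
  hrf_t <- seq(0, 32, by = dt)
  hrf <- do.call(hrf_double_gamma, c(list(t = hrf_t), hrf_params))
  H <- cumsum(hrf) * dt
  Hfun <- function(t) {
    out <- approx(hrf_t, H, xout = t, rule = 2)$y
    out[t < 0] <- 0
    out
  }
  scan_t <- (seq_len(n_scans) - 1) * tr_s
  vapply(seq_len(nrow(events)), function(i) {
    dur <- max(events$duration[i], dt)
    Hfun(scan_t - events$onset[i]) - Hfun(scan_t - events$onset[i] - dur)
  }, numeric(n_scans))
}

# render an event stream as its HRF-convolved regressor at the scan times
convolve_events <- function(events, tr_s, n_scans, dt = 0.01,
                            hrf_params = list()) {
  as.numeric(event_basis(events, tr_s, n_scans, dt, hrf_params) %*%
               events$amplitude)
}

#' Build a GLM design matrix from event streams
#'
#' Each regressor is a list of events (`onset`, `duration`, `amplitude`)
#' rendered as 100-ms-scale boxcars on a 10-ms grid, convolved with the
#' canonical double-gamma HRF and sampled at the TR. Amplitudes of regressors
#' named in `modulated` are mean-centered across events first, so the
#' corresponding unmodulated regressors absorb the mean response.
#'
#' @param event_list Named list of event tibbles with columns `onset`,
#'   `duration`, `amplitude` (seconds / seconds / arbitrary units).
#' @param tr_s Repetition time (s).
#' @param n_scans Number of volumes.
#' @param modulated Character vector of regressor names whose amplitudes are
#'   mean-centered.
#' @param nuisance Optional matrix of nuisance columns (e.g. motion), added
#'   unconvolved.
#' @param hrf_params Optional list of [hrf_double_gamma()] parameter
#'   overrides.
#' @param dt High-resolution grid step (s, default 0.01).
#' @return Object of class `glm_design`: list with `X` (T x N, including
#'   intercept), `names`, `events`, `modulated`, `tr_s`, `n_scans`.
#' @export
glm_design <- function(event_list, tr_s, n_scans, modulated = character(),
                       nuisance = NULL, hrf_params = list(), dt = 0.01) {
  stopifnot(is.list(event_list), !is.null(names(event_list)))
  t_end <- tr_s * n_scans
  events_store <- list()
  bases <- list()
  cols <- lapply(names(event_list), function(nm) {
    ev <- as_tibble(event_list[[nm]])
    stopifnot(all(c("onset", "duration", "amplitude") %in% names(ev)))
    if (any(ev$onset < 0 | ev$onset + ev$duration > t_end)) {
      abort(sprintf("Events of regressor '%s' fall outside the scan window.", nm))
    }
    if (nm %in% modulated) ev$amplitude <- ev$amplitude - mean(ev$amplitude)
    events_store[[nm]] <<- ev
    B <- event_basis(ev, tr_s, n_scans, dt = dt, hrf_params = hrf_params)
    bases[[nm]] <<- B
    as.numeric(B %*% ev$amplitude)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- names(event_list)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    colnames(nuisance) <- colnames(nuisance) %||%
      paste0("nuisance", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  X <- cbind(intercept = 1, X)
  structure(list(X = X, names = colnames(X), events = events_store,
                 bases = bases, modulated = modulated, tr_s = tr_s,
                 n_scans = n_scans, hrf_params = hrf_params, dt = dt),
            class = "glm_design")
}

#' @export
print.glm_design <- function(x, ...) {
  cat(sprintf("<glm_design> %d scans x %d regressors (TR %g s): %s\n",
              nrow(x$X), ncol(x$X), x$tr_s, paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Build the eight-regressor task design from a trial table
#'
#' Per context the design carries: an EEG-informed regressor parametrically
#' modulated by the trial-wise build-up slope (response-locked), an
#' RT-modulated regressor (response-locked), a difficulty-modulated regressor
#' coded -1 hard / 0 medium / +1 easy (stimulus-locked), and an unmodulated
#' stimulus-locked regressor. All events are 100-ms boxcars. Six synthetic
#' AR(1) motion nuisance columns are appended. Trials with a missing slope
#' enter only the unmodulated regressor and are flagged with a warning.
#'
#' @param trials Trial table with `context`, `onset_s` (stimulus onset in
#'   scan time), `rt_s`, `difficulty` (1 easy / 2 medium / 3 hard) and
#'   `slope` (signed build-up rate; may contain NAs).
#' @param tr_s,n_scans Scan geometry.
#' @param motion_seed Seed for the synthetic motion columns (`NULL` to omit
#'   them).
#' @inheritParams glm_design
#' @return A [glm_design()] with regressors named
#'   `<context>_{slope,rt,difficulty,unmod}`.
#' @export
build_task_design <- function(trials, tr_s, n_scans, hrf_params = list(),
                              motion_seed = 1L) {
  trials <- as_tibble(trials)
  stopifnot(all(c("context", "onset_s", "rt_s", "difficulty") %in%
                  names(trials)))
  if (!"slope" %in% names(trials)) trials$slope <- NA_real_
  if (anyNA(trials$slope)) {
    warn(sprintf("%d trial(s) lack a slope; they enter only the unmodulated regressor.",
                 sum(is.na(trials$slope))))
  }
  dur <- 0.1
  ev_list <- list()
  modulated <- character()
  for (cx in unique(trials$context)) {
    d <- trials[trials$context == cx, ]
    ds <- d[!is.na(d$slope), ]
    resp <- d$onset_s + d$rt_s
    ev_list[[paste0(cx, "_slope")]] <-
      tibble(onset = ds$onset_s + ds$rt_s, duration = dur,
             amplitude = ds$slope)
    ev_list[[paste0(cx, "_rt")]] <-
      tibble(onset = resp, duration = dur, amplitude = d$rt_s)
    ev_list[[paste0(cx, "_difficulty")]] <-
      tibble(onset = d$onset_s, duration = dur,
             amplitude = 2 - d$difficulty)  # 1 easy -> +1, 3 hard -> -1
    ev_list[[paste0(cx, "_unmod")]] <-
      tibble(onset = d$onset_s, duration = dur, amplitude = 1)
    modulated <- c(modulated, paste0(cx, c("_slope", "_rt", "_difficulty")))
  }
  nuis <- NULL
  if (!is.null(motion_seed)) {
    nuis <- with_fixed_seed(motion_seed, {
      m <- replicate(6, as.numeric(stats::filter(rnorm(n_scans), 0.95,
                                                 method = "recursive")))
      colnames(m) <- paste0("motion", 1:6)
      m
    })
  }
  glm_design(ev_list, tr_s = tr_s, n_scans = n_scans, modulated = modulated,
             nuisance = nuis, hrf_params = hrf_params)
}

#' Voxelwise GLM fit
#'
#' Ordinary least squares of every voxel's time series on the design,
#' with per-regressor t statistics and z-scores (t-to-z by matching tail
#' probabilities at the residual degrees of freedom).
#'
#' @param volumes A [volume_series()].
#' @param design A [glm_design()].
#' @return Object of class `stat_map`: list with `beta`, `t`, `z` (matrices
#'   regressors x voxels), `dims`, `df`, `design`.
#' @export
fit_glm <- function(volumes, design) {
  stopifnot(inherits(volumes, "volume_series"), inherits(design, "glm_design"))
  d <- dim(volumes$data)
  Tn <- d[4]
  X <- design$X
  if (nrow(X) != Tn) abort("Design rows and scan count differ.")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- design$names[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("Design is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  Y <- matrix(volumes$data, nrow = prod(d[1:3]), ncol = Tn)
  Y <- t(Y)  # T x V
  XtXi <- chol2inv(chol(crossprod(X)))
  beta <- XtXi %*% crossprod(X, Y)         # N x V
  res <- Y - X %*% beta
  df <- Tn - ncol(X)
  sigma2 <- colSums(res^2) / df
  se <- sqrt(outer(diag(XtXi), sigma2))
  tval <- beta / se
  zval <- t_to_z(tval, df)
  rownames(beta) <- rownames(tval) <- rownames(zval) <- design$names
  structure(list(beta = beta, t = tval, z = zval, dims = d[1:3], df = df,
                 design = design),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s voxels, %d regressors, df = %d\n",
              paste(x$dims, collapse = "x"), nrow(x$beta), x$df))
  invisible(x)
}

#' Convert t statistics to z-scores
#'
#' Matches upper- (or lower-) tail probabilities between the t distribution
#' at `df` and the standard normal, in log space for numerical stability.
#'
#' @param t Numeric vector/matrix of t statistics.
#' @param df Residual degrees of freedom.
#' @return z-scores with the same shape as `t`.
#' @export
t_to_z <- function(t, df) {
  z <- t
  neg <- t < 0
  z[neg] <- qnorm(pt(t[neg], df, log.p = TRUE), log.p = TRUE)
  z[!neg] <- -qnorm(pt(t[!neg], df, lower.tail = FALSE, log.p = TRUE),
                    log.p = TRUE)
  z
}

#' Extract a 3D statistical volume from a fit
#'
#' @param fit A `stat_map` from [fit_glm()].
#' @param regressor Regressor name.
#' @param what One of `"z"`, `"t"`, `"beta"`.
#' @return 3D array.
#' @export
stat_volume <- function(fit, regressor, what = c("z", "t", "beta")) {
  what <- match.arg(what)
  stopifnot(regressor %in% rownames(fit[[what]]))
  array(fit[[what]][regressor, ], dim = fit$dims)
}

#' Group-level z-map from subject-level fits
#'
#' One-sample t test across subjects' voxelwise betas for one regressor,
#' converted to z (the desk-scale stand-in for a mixed-effects group level).
#'
#' @param fits List of `stat_map` objects with identical dims.
#' @param regressor Regressor name.
#' @return 3D z array.
#' @export
glm_group_z <- function(fits, regressor) {
  B <- vapply(fits, function(f) f$beta[regressor, ],
              numeric(prod(fits[[1]]$dims)))
  n <- length(fits)
  m <- rowMeans(B)
  s <- sqrt(pmax(rowSums((B - m)^2) / (n - 1), 1e-300))
  tval <- m / (s / sqrt(n))
  array(t_to_z(tval, n - 1), dim = fits[[1]]$dims)
}

# 26-connectivity neighbor offsets
neighbor_offsets_26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

label_clusters <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  offs <- neighbor_offsets_26()
  idx <- which(mask)
  if (!length(idx)) return(lab)
  coords <- arrayInd(idx, dims)
  current <- 0L
  for (s in seq_along(idx)) {
    if (lab[idx[s]] != 0L) next
    current <- current + 1L
    stack <- idx[s]
    lab[idx[s]] <- current
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      cv <- arrayInd(v, dims)
      nb <- sweep(offs, 2, as.integer(cv), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      ni <- nb[, 1] + (nb[, 2] - 1L) * dims[1] +
        (nb[, 3] - 1L) * dims[1] * dims[2]
      ni <- ni[mask[ni] & lab[ni] == 0L]
      if (length(ni)) {
        lab[ni] <- current
        stack <- c(stack, ni)
      }
    }
  }
  lab
}

#' Suprathreshold clusters of a z volume
#'
#' Labels 26-connected clusters of voxels with `|z| > z_thr` (positive and
#' negative tails separately) and tabulates their size and peak.
#'
#' @param z 3D z array.
#' @param z_thr Voxel threshold (default 2.57).
#' @param min_size Minimum cluster extent to report.
#' @return Tibble with `cluster`, `sign`, `size`, `max_abs_z`, `peak_x/y/z`.
#' @export
cluster_table <- function(z, z_thr = 2.57, min_size = 1) {
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- (sgn * z) > z_thr
    lab <- label_clusters(mask)
    if (!any(lab > 0)) next
    for (cl in seq_len(max(lab))) {
      vox <- which(lab == cl)
      if (length(vox) < min_size) next
      zi <- abs(z[vox])
      pk <- arrayInd(vox[which.max(zi)], dim(z))
      out[[length(out) + 1]] <-
        tibble(sign = sgn, size = length(vox), max_abs_z = max(zi),
               peak_x = pk[1], peak_y = pk[2], peak_z = pk[3])
    }
  }
  if (!length(out)) {
    return(tibble(sign = integer(), size = integer(), max_abs_z = numeric(),
                  peak_x = integer(), peak_y = integer(), peak_z = integer()))
  }
  res <- dplyr::bind_rows(out)
  res$cluster <- seq_len(nrow(res))
  dplyr::relocate(res, "cluster")
}

shuffle_design_amplitudes <- function(design) {
  # onsets and durations stay fixed; only the parametric amplitudes permute,
  # so shuffled columns are re-assembled from the cached unit-event bases
  out <- design
  for (nm in design$modulated) {
    if (nm %in% names(design$events) && nrow(design$events[[nm]]) > 1) {
      amp <- sample(design$events[[nm]]$amplitude)
      out$events[[nm]]$amplitude <- amp
      out$X[, nm] <- as.numeric(design$bases[[nm]] %*% amp)
    }
  }
  out
}

#' Resampling-based joint cluster threshold
#'
#' Builds a null distribution of cluster sizes by holding every regressor's
#' onsets and durations fixed while shuffling the parametric amplitudes
#' across trials, re-running the analysis, and collecting all clusters with
#' `|z| > z_keep` and size above `min_size_keep`. The returned cluster-extent
#' threshold is the `1 - alpha` quantile of the null sizes (at the fixed
#' voxel threshold `z_keep`), the joint threshold used to correct the
#' observed maps.
#'
#' @param volumes A [volume_series()] or list of them (one per subject).
#' @param design Matching [glm_design()] or list of designs.
#' @param regressor Regressor whose z-map is thresholded.
#' @param n_iter Shuffle iterations (default 100; < 20 warns).
#' @param z_keep Voxel z threshold (default 2.57, two-tailed).
#' @param min_size_keep Minimum null cluster size entering the distribution.
#' @param alpha Family-wise rate (default 0.05).
#' @param seed Integer seed for the shuffles.
#' @return List with `size_thr` (cluster-extent threshold), `z_thr`,
#'   `null_sizes`.
#' @export
resample_cluster_threshold <- function(volumes, design, regressor,
                                       n_iter = 100, z_keep = 2.57,
                                       min_size_keep = 10, alpha = 0.05,
                                       seed = 1L) {
  if (n_iter < 20) warn("Fewer than 20 resampling iterations: unstable quantile.")
  single <- inherits(volumes, "volume_series")
  vol_list <- if (single) list(volumes) else volumes
  des_list <- if (single) list(design) else design
  set.seed(seed)
  # family-wise control: the null statistic is the largest surviving cluster
  # per shuffled analysis (0 when none survives); its upper quantile bounds
  # the chance of any cluster that size appearing anywhere in a null map
  null_sizes <- vapply(seq_len(n_iter), function(it) {
    z <- if (length(vol_list) == 1) {
      fit <- fit_glm(vol_list[[1]], shuffle_design_amplitudes(des_list[[1]]))
      stat_volume(fit, regressor, "z")
    } else {
      fits <- purrr::map2(vol_list, des_list, function(v, d)
        fit_glm(v, shuffle_design_amplitudes(d)))
      glm_group_z(fits, regressor)
    }
    ct <- cluster_table(z, z_thr = z_keep, min_size = min_size_keep + 1)
    if (nrow(ct)) max(ct$size) else 0
  }, numeric(1))
  size_thr <- max(as.numeric(quantile(null_sizes, 1 - alpha, type = 1)),
                  min_size_keep)
  list(size_thr = size_thr, z_thr = z_keep, null_sizes = null_sizes)
}

#' Mean time series of a seed mask
#'
#' @param volumes A [volume_series()].
#' @param mask Logical 3D array matching the volume grid.
#' @return Numeric vector of length `n_scans`.
#' @export
extract_seed_timeseries <- function(volumes, mask) {
  stopifnot(inherits(volumes, "volume_series"))
  d <- dim(volumes$data)
  if (!identical(dim(mask), d[1:3])) abort("Mask dims do not match the volume grid.")
  if (!any(mask)) abort("Seed mask is empty.")
  Y <- matrix(volumes$data, nrow = prod(d[1:3]))
  colMeans(Y[which(mask), , drop = FALSE])
}

#' Psychophysiological interaction design
#'
#' Builds the three PPI columns: the psychological regressor (a parametric
#' boxcar whose amplitude encodes task difficulty, 1 = difficult to 3 = easy,
#' and whose duration is the trial RT, HRF-convolved then centered), the
#' physiological regressor (centered seed time series) and their product,
#' formed at the BOLD signal level.
#'
#' @param seed_ts Seed region time series (length `n_scans`).
#' @param trials Trial table with `onset_s`, `rt_s` and `difficulty`
#'   (1 easy / 2 medium / 3 hard coding as elsewhere in the package; the
#'   psychological amplitude used is `4 - difficulty`).
#' @param tr_s,n_scans Scan geometry.
#' @param nuisance Optional nuisance matrix.
#' @inheritParams glm_design
#' @return A [glm_design()] with columns `psych`, `physio`, `interaction`.
#' @export
build_ppi_design <- function(seed_ts, trials, tr_s, n_scans,
                             nuisance = NULL, hrf_params = list()) {
  trials <- as_tibble(trials)
  stopifnot(all(c("onset_s", "rt_s", "difficulty") %in% names(trials)),
            length(seed_ts) == n_scans)
  amp <- 4 - trials$difficulty   # 1 = difficult ... 3 = easy
  if (sd(amp) == 0) {
    abort("Constant difficulty: the interaction would be collinear with the physiological regressor.")
  }
  psych <- convolve_events(tibble(onset = trials$onset_s,
                                  duration = pmax(trials$rt_s, 0.01),
                                  amplitude = amp),
                           tr_s, n_scans, hrf_params = hrf_params)
  # both factors centered and scaled to unit SD before the product, so the
  # interaction coefficient is a coupling per SD of each factor
  psych_c <- as.numeric(scale(psych))
  physio_c <- as.numeric(scale(seed_ts))
  inter <- psych_c * physio_c
  X <- cbind(intercept = 1, psych = psych_c, physio = physio_c,
             interaction = inter)
  if (!is.null(nuisance)) X <- cbind(X, as.matrix(nuisance))
  if (qr(X)$rank < ncol(X)) {
    abort("PPI design is rank deficient (degenerate psychological factor).")
  }
  structure(list(X = X, names = colnames(X), events = list(),
                 modulated = character(), tr_s = tr_s, n_scans = n_scans,
                 hrf_params = hrf_params, dt = 0.01),
            class = "glm_design")
}
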