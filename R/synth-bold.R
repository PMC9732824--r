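#' Rectangular blob mask helper
#'
#' @param grid 3D grid dimensions.
#' @param center Voxel center (length 3).
#' @param radius Half-width in voxels (scalar or length 3).
#' @return Logical 3D array.
#' @export
blob_mask <- function(grid, center, radius) {
  radius <- rep(radius, length.out = 3)
  m <- array(FALSE, grid)
  ix <- pmax(1, center[1] - radius[1]):pmin(grid[1], center[1] + radius[1])
  iy <- pmax(1, center[2] - radius[2]):pmin(grid[2], center[2] + radius[2])
  iz <- pmax(1, center[3] - radius[3]):pmin(grid[3], center[3] + radius[3])
  m[ix, iy, iz] <- TRUE
  m
}

#' Specification for synthetic BOLD volumes
#'
#' Declares a small 3D grid, AR(1) voxel noise, planted regressor effects
#' (per-blob betas) and an optional planted psychophysiological coupling: the
#' target blob receives `coupling * psych_c * seed_ts_c` on top of its noise,
#' where the seed time series is the mean signal of the seed blob.
#'
#' @param grid Grid dimensions (default `c(20, 20, 10)`).
#' @param tr_s Repetition time (default 2 s).
#' @param noise_sd Marginal SD of the AR(1) voxel noise.
#' @param ar1 AR(1) coefficient (default 0.3).
#' @param effects List of `list(regressor =, mask =, beta =)` entries; each
#'   adds `beta * X[, regressor]` inside `mask`.
#' @param ppi Optional `list(seed_mask =, target_mask =, coupling =, psych =)`
#'   where `psych` is a length-`n_scans` psychological time course (centered
#'   internally).
#' @param seed Integer seed.
#' @return Object of class `synth_bold_spec`.
#' @export
synth_bold_spec <- function(grid = c(20, 20, 10), tr_s = 2, noise_sd = 1,
                            ar1 = 0.3, effects = list(), ppi = NULL,
                            seed = 1L) {
  structure(list(grid = grid, tr_s = tr_s, noise_sd = noise_sd, ar1 = ar1,
                 effects = effects, ppi = ppi, seed = seed),
            class = "synth_bold_spec")
}

#' Generate synthetic BOLD volumes for a design
#'
#' Voxel time series are planted effects (`design X %*% beta` inside each
#' effect mask) plus AR(1) noise with the spec's marginal SD. When a PPI
#' coupling is declared, the target blob additionally receives the centered
#' psychological time course multiplied by the centered seed-blob mean
#' signal, scaled by the coupling coefficient.
#'
#' @param design A [glm_design()] whose scan count sets the time axis.
#' @param spec A [synth_bold_spec()].
#' @return A [volume_series()]; planted truth is stored in
#'   `attr(x, "ground_truth")`.
#' @export
synth_bold <- function(design, spec = synth_bold_spec()) {
  stopifnot(inherits(design, "glm_design"), inherits(spec, "synth_bold_spec"))
  set.seed(spec$seed)
  V <- prod(spec$grid)
  Tn <- design$n_scans
  innov_sd <- spec$noise_sd * sqrt(1 - spec$ar1^2)
  noise <- matrix(rnorm(V * Tn, sd = innov_sd), nrow = Tn)
  if (spec$ar1 != 0) {
    noise <- apply(noise, 2, function(e)
      as.numeric(stats::filter(e, spec$ar1, method = "recursive")))
  }
  Y <- t(noise)  # V x T
  for (ef in spec$effects) {
    if (!identical(dim(ef$mask), as.integer(spec$grid)) &&
        !identical(dim(ef$mask), spec$grid)) {
      abort("Effect mask dims do not match the grid.")
    }
    if (!ef$regressor %in% colnames(design$X)) {
      abort(sprintf("Effect regressor '%s' not in the design.", ef$regressor))
    }
    vox <- which(ef$mask)
    Y[vox, ] <- Y[vox, ] +
      matrix(ef$beta * design$X[, ef$regressor], nrow = length(vox),
             ncol = Tn, byrow = TRUE)
  }
  if (!is.null(spec$ppi)) {
    p <- spec$ppi
    if (!any(p$seed_mask) || !any(p$target_mask)) {
      abort("PPI seed/target masks must be non-empty.")
    }
    seed_ts <- colMeans(Y[which(p$seed_mask), , drop = FALSE])
    # factors standardized exactly as in the PPI design, so the planted
    # coupling coefficient is recovered on the same scale
    inter <- as.numeric(scale(p$psych)) * as.numeric(scale(seed_ts))
    vox <- which(p$target_mask)
    Y[vox, ] <- Y[vox, ] +
      matrix(p$coupling * inter, nrow = length(vox), ncol = Tn, byrow = TRUE)
  }
  out <- volume_series(array(Y, dim = c(spec$grid, Tn)), tr_s = spec$tr_s)
  attr(out, "ground_truth") <- list(effects = spec$effects, ppi = spec$ppi)
  out
}
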