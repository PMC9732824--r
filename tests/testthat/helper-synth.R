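# Shared fixtures, built once when the helpers are sourced. Kept small so
# unit tests stay fast; the acceptance tests build their own larger inputs.

# representative fitted accumulator parameters for the two task contexts
ref_params <- list(
  social = ou_params(leak = 5.774, k = 3.206, sigma = 0.02, ndt = 0.336),
  nonsocial = ou_params(leak = 5.277, k = 2.611, sigma = 0.011, ndt = 0.304)
)

# small two-context behavioral table (20 trials/level/context)
fix_behavior <- synth_behavior(ref_params, n_trials_per_level = 20,
                               seed = 101)

# reduced-scale epochs: 16 channels keep the FDA tests quick
fix_eeg_spec <- synth_eeg_spec(n_channels = 16, seed = 202, noise_sd = 3)
fix_epochs <- suppressWarnings(synth_eeg_epochs(fix_behavior, fix_eeg_spec))

# fast fit settings for unit tests (not the acceptance-scale settings)
fix_fit_cfg <- ou_fit_config(n_restarts = 1, maxit = 40, n_traces = 300,
                             n_traces_final = 1000, n_traces_select = 4000,
                             grid_points = 3, coarse_n = 0)

make_trials_for_glm <- function(n_tr = 40, seed = 7) {
  set.seed(seed)
  tibble::tibble(
    context = rep(c("social", "nonsocial"), length.out = n_tr),
    onset_s = seq(8, by = 7.5, length.out = n_tr),
    rt_s = stats::runif(n_tr, 0.4, 1.1),
    difficulty = sample(1:3, n_tr, TRUE),
    slope = stats::rnorm(n_tr, 2, 1)
  )
}

scans_for <- function(trials, tr_s = 2) ceiling((max(trials$onset_s) + 20) / tr_s)

# independent reference for the asymptotic two-sample KS p-value, written
# from scratch (ecdf evaluation on the pooled support + Kolmogorov series)
ref_ks_p <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  d <- max(abs(ecdf(x)(pts) - ecdf(y)(pts)))
  ne <- length(x) * length(y) / (length(x) + length(y))
  lambda <- sqrt(ne) * d
  if (lambda < 0.1) return(1)
  j <- 1:200
  min(max(2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2)), 0), 1)
}
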