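#' Ornstein-Uhlenbeck accumulator parameters
#'
#' Bundles the five free parameters of the leaky (here: self-exciting)
#' accumulator used to model two-alternative economic choices. Evidence is
#' integrated from 0 toward absorbing bounds at `+boundary` ("play") and
#' `-boundary` ("keep"); the Euler update per time step `dt` is
#' `EA <- EA + leak*EA*dt + k*evidence*dt + N(0, sigma)`, with `bias` added
#' each step on zero-evidence trials only.
#'
#' @param leak Self-coupling ("acceleration to threshold"), in 1/s. Positive
#'   values accelerate the state toward the nearer bound.
#' @param k Drift gain: mean integration rate per unit evidence per second.
#' @param sigma Per-step noise SD, in accumulator units. Tied to the step
#'   `dt = 0.001` s (it is not rescaled if `dt` changes; a warning is emitted
#'   for non-default `dt`).
#' @param bias Additive per-step increment applied only when evidence is
#'   exactly 0, capturing idiosyncratic play/keep tendencies at indecision.
#' @param ndt Non-decision time in seconds (encoding + motor), added to the
#'   first-passage time to form the RT.
#' @param boundary Absorbing bound magnitude; fixed at 1 in the reference
#'   model, free in the variable-boundary variant.
#' @return An object of class `ou_params` (named list).
#' @export
#' @examples
#' ou_params(leak = 5, k = 3, sigma = 0.015, ndt = 0.33)
ou_params <- function(leak, k, sigma, bias = 0, ndt, boundary = 1) {
  vals <- c(leak = leak, k = k, sigma = sigma, bias = bias,
            ndt = ndt, boundary = boundary)
  if (any(!is.finite(vals))) {
    abort("All accumulator parameters must be finite.")
  }
  if (sigma <= 0) abort("`sigma` must be > 0.")
  if (ndt < 0) abort("`ndt` must be >= 0.")
  if (boundary <= 0) abort("`boundary` must be > 0.")
  structure(as.list(vals), class = "ou_params")
}

#' @export
print.ou_params <- function(x, ...) {
  cat("<ou_params>  leak:", format(x$leak), " k:", format(x$k),
      " sigma:", format(x$sigma), " bias:", format(x$bias),
      " ndt:", format(x$ndt), "s  boundary:", format(x$boundary), "\n")
  invisible(x)
}

#' Simulation settings for the accumulator
#'
#' @param dt_s Euler step in seconds. The model's noise term is defined at
#'   `dt_s = 0.001`; changing it changes the effective diffusion and triggers
#'   a warning.
#' @param n_traces Simulated decision traces per evidence level.
#' @param max_decision_time_s Cap on the first-passage time; non-terminating
#'   traces are redrawn (an error is raised if more than 1% of draws needed a
#'   redraw).
#' @param seed Optional integer seed applied before simulation for
#'   reproducibility.
#' @return An object of class `ou_sim_config`.
#' @export
ou_sim_config <- function(dt_s = 0.001, n_traces = 5000,
                          max_decision_time_s = 3.0, seed = NULL) {
  if (dt_s <= 0) abort("`dt_s` must be > 0.")
  if (n_traces < 1) abort("`n_traces` must be >= 1.")
  if (dt_s != 0.001) {
    warn("`dt_s` differs from 0.001 s; sigma is a per-step SD, so the effective diffusion changes with dt.")
  }
  structure(list(dt_s = dt_s, n_traces = as.integer(n_traces),
                 max_decision_time_s = max_decision_time_s,
                 seed = seed),
            class = "ou_sim_config")
}

#' Default transformed evidence levels
#'
#' The five reward-probability bins, recentered so that evidence is symmetric
#' about the indecision point.
#' @return Numeric vector `c(-0.5, -0.25, 0, 0.25, 0.5)`.
#' @export
ou_evidence_levels <- function() c(-0.5, -0.25, 0, 0.25, 0.5)

#' Simulate accumulator trials at one evidence level
#'
#' Euler-simulates first passages of the accumulator and returns one row per
#' trial. Choice is the sign of the state at bound crossing (`+1` play,
#' `-1` keep); RT is the crossing time plus non-decision time.
#'
#' @param params An [ou_params()] object.
#' @param evidence Scalar evidence (conventionally in `[-0.5, 0.5]`).
#' @param cfg An [ou_sim_config()].
#' @return A tibble with columns `choice` (+1/-1) and `rt_s`.
#' @export
ou_simulate_trials <- function(params, evidence, cfg = ou_sim_config()) {
  stopifnot(inherits(params, "ou_params"), inherits(cfg, "ou_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  budget <- as.integer(ceiling(0.01 * cfg$n_traces))
  res <- ou_simulate_level(params$leak, params$k, params$sigma, params$bias,
                           params$ndt, params$boundary, evidence,
                           cfg$n_traces, cfg$dt_s, cfg$max_decision_time_s,
                           budget)
  if (isTRUE(res$aborted)) {
    abort(sprintf(
      "More than 1%% of traces failed to reach a bound within %.1f s; check parameters.",
      cfg$max_decision_time_s), class = "neuroaccum_redraw_error")
  }
  tibble(choice = res$choice, rt_s = res$rt)
}

#' Simulate the accumulator across evidence levels
#'
#' Runs [ou_simulate_trials()] at each level and assembles the quantities the
#' pseudo-likelihood needs: the per-level fraction of play choices and the
#' pooled signed-RT distribution in which keep-trial RTs carry a negative
#' sign.
#'
#' @inheritParams ou_simulate_trials
#' @param evidence_levels Ordered evidence levels; defaults to
#'   [ou_evidence_levels()].
#' @return An object of class `ou_sim`: list with `trials` (tibble of
#'   `evidence`, `choice`, `rt_s`, `signed_rt`) and `summary` (tibble of
#'   `evidence`, `n`, `p_play`, `mean_rt`).
#' @export
ou_simulate <- function(params, evidence_levels = ou_evidence_levels(),
                        cfg = ou_sim_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cfg_inner <- cfg
  cfg_inner$seed <- NULL
  trials <- purrr::map_dfr(evidence_levels, function(ev) {
    tr <- ou_simulate_trials(params, ev, cfg_inner)
    tr$evidence <- ev
    tr
  })
  trials$signed_rt <- trials$rt_s * trials$choice
  summ <- trials |>
    dplyr::group_by(.data$evidence) |>
    dplyr::summarise(n = dplyr::n(),
                     p_play = mean(.data$choice == 1),
                     mean_rt = mean(.data$rt_s),
                     .groups = "drop")
  structure(list(trials = trials, summary = summ,
                 params = params, cfg = cfg),
            class = "ou_sim")
}

#' @export
print.ou_sim <- function(x, ...) {
  cat("<ou_sim> ", nrow(x$trials), "trials across",
      nrow(x$summary), "evidence levels\n")
  print(x$summary)
  invisible(x)
}

#' Closed-form absorption probability of the driftless-leak special case
#'
#' For zero leak and zero bias the accumulator is a discrete random walk with
#' drift `k*evidence*dt` and per-step SD `sigma` between bounds at
#' `+/-boundary`; the probability of absorption at the upper bound is
#' `1 / (1 + exp(-2*k*evidence*dt*boundary/sigma^2))`. Used as an independent
#' check of the simulator.
#'
#' @inheritParams ou_simulate_trials
#' @param dt_s Euler step the per-step noise is defined at.
#' @return Scalar probability of a play (`+1`) choice.
#' @export
ou_p_play_closed_form <- function(params, evidence, dt_s = 0.001) {
  stopifnot(inherits(params, "ou_params"))
  if (params$leak != 0 || params$bias != 0) {
    abort("Closed form requires leak = 0 and bias = 0.")
  }
  drift <- params$k * evidence * dt_s
  1 / (1 + exp(-2 * drift * params$boundary / params$sigma^2))
}
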