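#' Generate a synthetic behavioral dataset from the accumulator
#'
#' Simulates a trial table for one or more contexts using the same
#' Ornstein-Uhlenbeck simulator the model fit uses (shared code path), so
#' planted parameters are exactly recoverable in expectation. Trials are laid
#' out per context and evidence level and then shuffled into a random
#' presentation order.
#'
#' @param params_by_context Named list of [ou_params()] (e.g.
#'   `list(social = ..., nonsocial = ...)`).
#' @param n_trials_per_level Trials per evidence level per context.
#' @param evidence_levels Strictly increasing vector, symmetric about 0;
#'   default [ou_evidence_levels()].
#' @param seed Integer seed; fixed seeds give bit-identical tables.
#' @param dt_s,max_decision_time_s Simulator settings (see [ou_sim_config()]).
#' @return Tibble with columns `trial`, `subject` (= "s01"), `context`,
#'   `p_level` (1..5 when the default levels are used), `evidence`,
#'   `difficulty`, `choice` (+1 play / -1 keep) and `rt_s`.
#' @export
synth_behavior <- function(params_by_context, n_trials_per_level = 50,
                           evidence_levels = ou_evidence_levels(),
                           seed = 1L, dt_s = 0.001,
                           max_decision_time_s = 3.0) {
  stopifnot(is.list(params_by_context), length(params_by_context) >= 1,
            !is.null(names(params_by_context)))
  if (n_trials_per_level < 1) abort("`n_trials_per_level` must be >= 1.")
  if (any(diff(evidence_levels) <= 0)) {
    abort("`evidence_levels` must be strictly increasing.")
  }
  if (max(abs(evidence_levels + rev(evidence_levels))) > 1e-12) {
    abort("`evidence_levels` must be symmetric about 0.")
  }
  set.seed(seed)
  cfg <- ou_sim_config(dt_s = dt_s, n_traces = n_trials_per_level,
                       max_decision_time_s = max_decision_time_s)
  out <- purrr::imap_dfr(params_by_context, function(p, ctx) {
    purrr::map_dfr(seq_along(evidence_levels), function(i) {
      tr <- ou_simulate_trials(p, evidence_levels[i], cfg)
      tr$context <- ctx
      tr$p_level <- i
      tr$evidence <- evidence_levels[i]
      tr
    })
  })
  out <- out[sample.int(nrow(out)), ]
  out$trial <- seq_len(nrow(out))
  out$subject <- "s01"
  out$difficulty <- if (length(evidence_levels) == 5) {
    level_to_difficulty(out$p_level)
  } else {
    NA_integer_
  }
  dplyr::select(out, "trial", "subject", "context", "p_level", "evidence",
                "difficulty", "choice", "rt_s")
}
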