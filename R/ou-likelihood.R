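# two-sample KS statistic evaluated at the jump points of both samples
# (inputs must be sorted); identical to the classical D with ties handled by
# comparing the empirical CDFs at every observed value
ks2_stat <- function(x_sorted, y_sorted) {
  n1 <- length(x_sorted); n2 <- length(y_sorted)
  # with tied values the ECDFs are evaluated at the end of each tied run
  kx <- c(x_sorted[-1] != x_sorted[-n1], TRUE)
  ky <- c(y_sorted[-1] != y_sorted[-n2], TRUE)
  fy_at_x <- findInterval(x_sorted[kx], y_sorted) / n2
  fx_at_y <- findInterval(y_sorted[ky], x_sorted) / n1
  max(abs(seq_len(n1)[kx] / n1 - fy_at_x),
      abs(seq_len(n2)[ky] / n2 - fx_at_y))
}

# asymptotic p-value of the two-sample KS test: survival of the Kolmogorov
# distribution at sqrt(n1*n2/(n1+n2)) * D, by the alternating series
# 2*sum_j (-1)^(j-1) exp(-2 j^2 lambda^2)
kolmogorov_p <- function(lambda) {
  if (lambda < 0.1) return(1)
  j <- seq_len(ceiling(6 / lambda) + 3)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

ks2_pvalue <- function(x_sorted, y_sorted) {
  n1 <- length(x_sorted); n2 <- length(y_sorted)
  ne <- n1 * n2 / (n1 + n2)
  kolmogorov_p(sqrt(ne) * ks2_stat(x_sorted, y_sorted))
}

#' Kolmogorov-Smirnov pseudo-log-likelihood of choice/RT data
#'
#' Scores a simulated accumulator against observed trials. Per evidence level
#' the score has two parts: the log of the two-sample Kolmogorov-Smirnov
#' p-value between the signed-RT distributions (keep-trial RTs carry a
#' negative sign), plus a Gaussian penalty on the mismatch in play fraction,
#' `-((p_data - p_model) / 0.01)^2`. The total is the sum over levels; it is
#' at most 0 and equals 0 only when both distributions and play fractions
#' agree (up to the resolution of the KS p-value).
#'
#' @param data Behavioral trials for one context: a data frame with columns
#'   `evidence`, `choice` (+1 play / -1 keep) and `rt_s`.
#' @param sim An [ou_simulate()] result sharing the data's evidence levels.
#' @param p_floor Floor applied to KS p-values before taking logs (the score
#'   is undefined at p = 0).
#' @return Scalar pseudo-log-likelihood (<= 0).
#' @export
ou_pseudo_loglik <- function(data, sim, p_floor = 1e-300) {
  stopifnot(inherits(sim, "ou_sim"))
  data <- check_behavior(data)
  levels_model <- sort(unique(sim$trials$evidence))
  levels_data <- sort(unique(data$evidence))
  if (!all(levels_data %in% levels_model)) {
    abort("Data contain evidence levels absent from the simulation.")
  }
  ll <- 0
  for (ev in levels_model) {
    d <- data[data$evidence == ev, ]
    if (nrow(d) == 0L) {
      warn(sprintf("No data trials at evidence %.3g; level skipped.", ev))
      next
    }
    m <- sim$trials[sim$trials$evidence == ev, ]
    signed_d <- d$rt_s * d$choice
    p_ks <- ks2_pvalue(sort(signed_d), sort(m$signed_rt))
    p_play_d <- mean(d$choice == 1)
    p_play_m <- mean(m$choice == 1)
    ll <- ll + log(max(p_ks, p_floor)) - ((p_play_d - p_play_m) / 0.01)^2
  }
  ll
}

check_behavior <- function(data) {
  data <- as_tibble(data)
  need <- c("evidence", "choice", "rt_s")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("Behavioral data lack column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!all(data$choice %in% c(-1, 1))) {
    abort("`choice` must be coded +1 (play) / -1 (keep).")
  }
  data
}
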