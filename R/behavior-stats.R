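#' Map reward-probability level to evidence and difficulty
#'
#' The five reward-probability bins (level 1 = 0-0.2 ... level 5 = 0.8-1) map
#' to signed evidence `(-0.5, -0.25, 0, 0.25, 0.5)` and to three difficulty
#' grades: levels 1 and 5 are easy, 2 and 4 medium, 3 hard.
#'
#' @param p_level Integer vector of levels in 1..5.
#' @return `level_to_evidence()`: numeric evidence; `level_to_difficulty()`:
#'   integer difficulty code (1 easy, 2 medium, 3 hard).
#' @export
level_to_evidence <- function(p_level) {
  stopifnot(all(p_level %in% 1:5))
  (p_level - 3) * 0.25
}

#' @rdname level_to_evidence
#' @export
level_to_difficulty <- function(p_level) {
  stopifnot(all(p_level %in% 1:5))
  c(1L, 2L, 3L, 2L, 1L)[p_level]
}

# Weibull psychometric function over the level index:
# P(play | x) = guess + (1 - guess - lapse) * (1 - exp(-(x/alpha)^beta))
weibull_prob <- function(x, alpha, beta, guess, lapse) {
  p <- guess + (1 - guess - lapse) * (1 - exp(-(x / alpha)^beta))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

weibull_negll <- function(par, counts_list) {
  alpha <- exp(par[1]); beta <- exp(par[2])
  guess <- 0.05 * stats::plogis(par[3]); lapse <- 0.05 * stats::plogis(par[4])
  nll <- 0
  for (cc in counts_list) {
    p <- weibull_prob(cc$level, alpha, beta, guess, lapse)
    nll <- nll - sum(cc$n_play * log(p) + (cc$n - cc$n_play) * log(1 - p))
  }
  nll
}

# Binomial-likelihood Weibull psychometric fit. counts_list: list of tibbles
# (level, n_play, n) sharing one curve. Returns log-likelihood and parameters.
fit_weibull_counts <- function(counts_list) {
  best <- tryCatch(optim(c(log(3), log(2), 0, 0), weibull_negll,
                         counts_list = counts_list, method = "BFGS",
                         control = list(maxit = 150)),
                   error = function(e) NULL)
  if (!is.null(best) && is.finite(best$value)) {
    # simplex polish: quasi-Newton can stall short of the optimum, which
    # would bias likelihood-ratio statistics built on this fit
    pol <- tryCatch(optim(best$par, weibull_negll, counts_list = counts_list,
                          method = "Nelder-Mead",
                          control = list(maxit = 200)),
                    error = function(e) NULL)
    if (!is.null(pol) && is.finite(pol$value) && pol$value < best$value) {
      best <- pol
    }
  }
  if (is.null(best) || !is.finite(best$value)) {
    # quasi-Newton can fail on flat/degenerate count patterns; fall back to
    # multistart Nelder-Mead
    for (s in list(c(log(3), log(2), 0, 0), c(log(2.5), log(1), 0, 0),
                   c(log(4), log(3), -2, -2))) {
      opt <- tryCatch(optim(s, weibull_negll, counts_list = counts_list,
                            method = "Nelder-Mead",
                            control = list(maxit = 500)),
                      error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$value) &&
          (is.null(best) || opt$value < best$value)) best <- opt
    }
  }
  if (is.null(best)) abort("Weibull fit failed.")
  par <- best$par
  degenerate <- abs(par[1]) > 12 || abs(par[2]) > 12
  list(loglik = -best$value, par = par,
       alpha = exp(par[1]), beta = exp(par[2]),
       guess = 0.05 * stats::plogis(par[3]),
       lapse = 0.05 * stats::plogis(par[4]),
       degenerate = degenerate)
}

# separate-curves model with exactly two extra parameters: context-specific
# shape and scale, shared guess and lapse (so the statistic has 2 df)
weibull_negll_sep <- function(par, counts_list) {
  guess <- 0.05 * stats::plogis(par[5]); lapse <- 0.05 * stats::plogis(par[6])
  nll <- 0
  for (i in 1:2) {
    cc <- counts_list[[i]]
    p <- weibull_prob(cc$level, exp(par[2 * i - 1]), exp(par[2 * i]),
                      guess, lapse)
    nll <- nll - sum(cc$n_play * log(p) + (cc$n - cc$n_play) * log(1 - p))
  }
  nll
}

fit_weibull_separate <- function(counts_list, joint_par = NULL) {
  start <- if (is.null(joint_par)) c(log(3), log(2), log(3), log(2), 0, 0)
           else c(joint_par[1:2], joint_par[1:2], joint_par[3:4])
  best <- tryCatch(optim(start, weibull_negll_sep,
                         counts_list = counts_list, method = "BFGS",
                         control = list(maxit = 200)),
                   error = function(e) NULL)
  if (!is.null(best) && is.finite(best$value)) {
    pol <- tryCatch(optim(best$par, weibull_negll_sep,
                          counts_list = counts_list,
                          method = "Nelder-Mead",
                          control = list(maxit = 250)),
                    error = function(e) NULL)
    if (!is.null(pol) && is.finite(pol$value) && pol$value < best$value) {
      best <- pol
    }
  }
  if (is.null(best) || !is.finite(best$value)) {
    best <- optim(c(log(3), log(2), log(3), log(2), 0, 0),
                  weibull_negll_sep, counts_list = counts_list,
                  method = "Nelder-Mead", control = list(maxit = 1000))
  }
  degenerate <- any(abs(best$par[1:4]) > 12)
  list(loglik = -best$value, degenerate = degenerate)
}

aggregate_counts <- function(trials) {
  lev <- sort(unique(trials$p_level))
  list(level = lev,
       n_play = vapply(lev, function(l)
         sum(trials$choice[trials$p_level == l] == 1), numeric(1)),
       n = vapply(lev, function(l) sum(trials$p_level == l), numeric(1)))
}

#' Likelihood-ratio test: one psychometric curve versus two
#'
#' Tests whether a single Weibull choice function fits the play fractions of
#' both contexts as well as context-specific curves. Per subject, a joint
#' Weibull (shared shape/scale) and separate curves (context-specific shape
#' and scale, shared guess/lapse so exactly 2 parameters differ) are fitted
#' by binomial maximum likelihood. The statistic is
#' `lambda = -2 * log(mean_i L_i(joint) / mean_i L_i(separate))`
#' with subject likelihoods averaged on the likelihood scale (computed via
#' log-sum-exp), referred to a chi-square with 2 df. Small lambda (large p)
#' means a single curve suffices.
#'
#' @param trials Trial table with columns `subject`, `context`, `p_level`
#'   (1..5) and `choice` (+1 play / -1 keep).
#' @return An object of class `lrt_result`: list with `lambda`, `df`,
#'   `p_value`, and `per_subject` (tibble of joint/separate log-likelihoods
#'   and degenerate-fit flags).
#' @export
lrt_single_vs_separate <- function(trials) {
  trials <- as_tibble(trials)
  stopifnot(all(c("subject", "context", "p_level", "choice") %in% names(trials)))
  ctxs <- unique(trials$context)
  if (length(ctxs) != 2) abort("Exactly two contexts are required.")
  per_subject <- trials |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_map(function(d, key) {
      counts <- lapply(ctxs, function(cx)
        aggregate_counts(d[d$context == cx, ]))
      joint <- fit_weibull_counts(counts)
      sep <- fit_weibull_separate(counts, joint_par = joint$par)
      tibble(subject = key$subject,
             ll_joint = joint$loglik,
             ll_separate = max(sep$loglik, joint$loglik),
             degenerate = joint$degenerate || sep$degenerate)
    }) |>
    dplyr::bind_rows()
  if (any(per_subject$degenerate)) {
    warn("Degenerate Weibull fit(s) detected (asymptote bounds applied); see `per_subject$degenerate`.")
  }
  lse <- function(ll) max(ll) + log(mean(exp(ll - max(ll))))
  lambda <- -2 * (lse(per_subject$ll_joint) - lse(per_subject$ll_separate))
  structure(list(lambda = lambda, df = 2L,
                 p_value = pchisq(lambda, df = 2, lower.tail = FALSE),
                 n_subjects = nrow(per_subject),
                 per_subject = per_subject),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("<lrt_result> lambda(%d) = %.3f, df = %d, p = %.3f\n",
              x$n_subjects - 1, x$lambda, x$df, x$p_value))
  invisible(x)
}

#' @rdname lrt_single_vs_separate
#' @param x An `lrt_result`.
#' @param ... Unused.
#' @method glance lrt_result
#' @export
glance.lrt_result <- function(x, ...) {
  tibble(lambda = x$lambda, df = x$df, p_value = x$p_value,
         n_subjects = x$n_subjects)
}

#' Chi-square p-value for a likelihood-ratio statistic
#'
#' Survival probability of a chi-square distribution at the observed
#' statistic; with `df = 2` this is `exp(-lambda/2)`.
#'
#' @param lambda Observed statistic.
#' @param df Degrees of freedom (default 2).
#' @return Scalar p-value.
#' @export
lrt_p_value <- function(lambda, df = 2) {
  pchisq(lambda, df = df, lower.tail = FALSE)
}

group_regression <- function(per_subject, predictor) {
  ok <- per_subject[!per_subject$flagged, ]
  tt <- if (nrow(ok) >= 2) t.test(ok$beta1) else NULL
  structure(list(per_subject = per_subject, predictor = predictor,
                 group_t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                 group_p = if (is.null(tt)) NA_real_ else tt$p.value,
                 group_df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
                 mean_beta1 = mean(ok$beta1)),
            class = "group_regression")
}

#' @export
print.group_regression <- function(x, ...) {
  cat(sprintf("<group_regression> predictor: %s | mean beta1 = %.4f, t(%g) = %.3f, p = %.3g\n",
              x$predictor, x$mean_beta1, x$group_df, x$group_t, x$group_p))
  invisible(x)
}

#' @method tidy group_regression
#' @export
tidy.group_regression <- function(x, ...) x$per_subject

#' @method glance group_regression
#' @export
glance.group_regression <- function(x, ...) {
  tibble(predictor = x$predictor, mean_beta1 = x$mean_beta1,
         group_t = x$group_t, group_df = x$group_df, group_p = x$group_p,
         n_subjects = sum(!x$per_subject$flagged))
}

#' Single-trial logistic regressions of choice
#'
#' Per subject, fits a logistic regression of the probability of a play
#' choice on (a) the reward-probability level, (b) the signed EEG build-up
#' slope, or (c) both, then tests the per-subject slope coefficients against
#' zero with a two-tailed one-sample t test. Slopes must already carry the
#' sign convention of the accumulator (flip the sign for the two
#' keep-favoring levels first; see [flip_slopes()]).
#'
#' @param trials Trial table with `subject`, `choice` (+1/-1), `p_level`, and
#'   (for slope models) a `slope` column of signed build-up rates.
#' @param predictor One of `"reward_probability"`, `"slope"`, `"both"`.
#' @return A `group_regression` object; `tidy()` gives per-subject
#'   coefficients and deviances, `glance()` the group test. Subjects with
#'   separated fits are flagged and excluded from the group test.
#' @export
fit_choice_logistic <- function(trials,
                                predictor = c("reward_probability", "slope",
                                              "both")) {
  predictor <- match.arg(predictor)
  trials <- as_tibble(trials)
  stopifnot(all(c("subject", "choice", "p_level") %in% names(trials)))
  if (predictor != "reward_probability" && !"slope" %in% names(trials)) {
    abort("Slope-based models need a `slope` column of signed build-up rates.")
  }
  form <- switch(predictor,
                 reward_probability = play ~ p_level,
                 slope = play ~ slope,
                 both = play ~ slope + p_level)
  per_subject <- trials |>
    dplyr::mutate(play = as.integer(.data$choice == 1)) |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_map(function(d, key) {
      sep <- FALSE
      fit <- withCallingHandlers(
        glm(form, family = binomial(), data = d),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
            sep <<- TRUE
          invokeRestart("muffleWarning")
        })
      cf <- coef(fit)
      flagged <- sep || any(abs(cf[-1]) > 20)
      tibble(subject = key$subject, beta0 = unname(cf[1]),
             beta1 = unname(cf[2]),
             beta2 = if (length(cf) > 2) unname(cf[3]) else NA_real_,
             deviance = deviance(fit),
             null_deviance = fit$null.deviance,
             flagged = flagged)
    }) |>
    dplyr::bind_rows()
  if (any(per_subject$flagged)) {
    warn("Separated logistic fit(s) flagged and excluded from the group test.")
  }
  group_regression(per_subject, predictor)
}

#' Reaction time as a function of task difficulty
#'
#' Per-subject ordinary least squares of RT on the three-grade difficulty
#' code (1 easy, 2 medium, 3 hard, derived from `p_level`), followed by a
#' group one-sample t test on the slopes. A positive group slope means slower
#' responses on harder trials.
#'
#' @param trials Trial table with `subject`, `p_level`, `rt_s`.
#' @return A `group_regression` object.
#' @export
rt_difficulty_regression <- function(trials) {
  trials <- as_tibble(trials)
  stopifnot(all(c("subject", "p_level", "rt_s") %in% names(trials)))
  trials$difficulty <- level_to_difficulty(trials$p_level)
  if (length(unique(trials$difficulty)) < 2) {
    abort("At least two distinct difficulty levels are required.")
  }
  per_subject <- trials |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_map(function(d, key) {
      fit <- lm(rt_s ~ difficulty, data = d)
      cf <- coef(fit)
      tibble(subject = key$subject, beta0 = unname(cf[1]),
             beta1 = unname(cf[2]),
             beta2 = NA_real_,
             deviance = sum(residuals(fit)^2),
             null_deviance = sum((d$rt_s - mean(d$rt_s))^2),
             flagged = FALSE)
    }) |>
    dplyr::bind_rows()
  group_regression(per_subject, "difficulty")
}

#' Serial autoregression of per-trial build-up slopes
#'
#' Regresses each trial's slope on the previous `n_lags` trials' slopes
#' (per subject, trial order preserved) and reports the variance explained.
#' Low R-squared indicates the absence of slow attentional drifts in the
#' slopes.
#'
#' @param slopes Tibble with `subject` and `slope` in trial order (optionally
#'   a `trial` column used to sort).
#' @param n_lags Number of lags (default 4).
#' @return Tibble with one row per subject (`subject`, `r_squared`,
#'   `degenerate`) plus attribute-free mean available via `mean(res$r_squared)`.
#' @export
slope_autoregression <- function(slopes, n_lags = 4) {
  slopes <- as_tibble(slopes)
  stopifnot(all(c("subject", "slope") %in% names(slopes)))
  slopes |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_map(function(d, key) {
      if ("trial" %in% names(d)) d <- d[order(d$trial), ]
      s <- d$slope
      if (length(s) <= n_lags + 1 || sd(s) == 0) {
        warn(sprintf("Subject %s: degenerate slope series; R^2 set to NA.",
                     key$subject))
        return(tibble(subject = key$subject, r_squared = NA_real_,
                      degenerate = TRUE))
      }
      emb <- stats::embed(s, n_lags + 1)
      fit <- lm.fit(cbind(1, emb[, -1, drop = FALSE]), emb[, 1])
      r2 <- 1 - sum(fit$residuals^2) / sum((emb[, 1] - mean(emb[, 1]))^2)
      tibble(subject = key$subject, r_squared = r2, degenerate = FALSE)
    }) |>
    dplyr::bind_rows()
}

#' Minimum sample size for a one-sample t test
#'
#' Smallest `n` at which a one-sample t test with effect size `d` (Cohen's d,
#' noncentrality `d * sqrt(n)`) reaches the requested power, evaluated with
#' the noncentral t distribution.
#'
#' @param effect_d Standardized effect size (> 0).
#' @param alpha Significance level.
#' @param power Target power.
#' @param tails 1 or 2.
#' @param n_max Search cap.
#' @return Integer minimum sample size.
#' @export
#' @examples
#' min_sample_size(0.847, alpha = 0.05, power = 0.95)  # 21
min_sample_size <- function(effect_d, alpha = 0.05, power = 0.95, tails = 2,
                            n_max = 1e6) {
  stopifnot(effect_d > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            tails %in% c(1, 2))
  pow_at <- function(n) {
    df <- n - 1
    ncp <- effect_d * sqrt(n)
    if (tails == 2) {
      crit <- qt(1 - alpha / 2, df)
      pt(crit, df, ncp = ncp, lower.tail = FALSE) + pt(-crit, df, ncp = ncp)
    } else {
      crit <- qt(1 - alpha, df)
      pt(crit, df, ncp = ncp, lower.tail = FALSE)
    }
  }
  for (n in 2:n_max) {
    if (pow_at(n) >= power) return(as.integer(n))
  }
  abort("Requested power not reachable within `n_max`.")
}
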