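#' Estimate the stop-signal reaction time (mean method)
#'
#' For staircase-tracked designs that converge to ~50% stop success, the
#' latent stopping latency is estimated as
#' `SSRT = mean RT on correct go trials - mean SSD over stop trials`.
#' The integration method (RT-distribution quantile at the observed
#' stop-failure rate minus mean SSD) is available via `method`.
#'
#' @param log A stop-trial log as produced by [simulate_stop_signal()]:
#'   columns `trial_type`, `ssd`, `responded`, `rt`, `correct_cue`.
#' @param method `"mean"` (default) or `"integration"`.
#' @return data.frame (`sst_result`): `ssrt` (ms), `mean_go_rt`, `mean_ssd`,
#'   `go_error_rate` (wrong-cue or omitted go trials), `stop_success_rate`.
#' @export
estimate_ssrt <- function(log, method = c("mean", "integration")) {
  method <- match.arg(method)
  go <- log[log$trial_type == "go", , drop = FALSE]
  stop_t <- log[log$trial_type == "stop", , drop = FALSE]
  if (nrow(stop_t) == 0) stop("no stop trials in log: SSRT undefined")
  resp_go <- go[go$responded, , drop = FALSE]
  if (nrow(resp_go) == 0) stop("no responded go trials in log: SSRT undefined")
  correct_go <- resp_go[resp_go$correct_cue, , drop = FALSE]
  if (nrow(correct_go) == 0) stop("no correct go trials in log: SSRT undefined")
  mean_go_rt <- mean(correct_go$rt)
  mean_ssd <- mean(stop_t$ssd)
  p_respond <- mean(stop_t$responded)
  ssrt <- if (method == "mean") {
    mean_go_rt - mean_ssd
  } else {
    stats::quantile(correct_go$rt, probs = min(1, p_respond), names = FALSE) -
      mean_ssd
  }
  res <- data.frame(ssrt = ssrt, mean_go_rt = mean_go_rt, mean_ssd = mean_ssd,
                    go_error_rate = mean(!go$responded |
                                           (go$responded & !go$correct_cue)),
                    stop_success_rate = 1 - p_respond)
  class(res) <- c("sst_result", "data.frame")
  res
}

#' Hyperbolic discounted value
#'
#' Mazur's hyperbola `V = A / (1 + K * D)`: the subjective present value of an
#' amount `A` delivered after a delay of `D` days under discount rate `K`
#' (1/day). Larger K means steeper devaluation of delayed rewards.
#'
#' @param amount Reward amount (> 0), vectorised.
#' @param delay Delay in days (>= 0), vectorised.
#' @param k Discount rate in 1/day (>= 0).
#' @return Discounted value, same units as `amount`.
#' @export
discounted_value <- function(amount, delay, k) {
  stopifnot(all(amount > 0), all(delay >= 0), all(k >= 0))
  amount / (1 + k * delay)
}

#' Fit the hyperbolic discount rate K by maximum likelihood
#'
#' Logistic-choice likelihood: `P(choose delayed) =
#' plogis(beta * (V_delayed - V_immediate))` with hyperbolic values from
#' [discounted_value()]. K is searched on a log-spaced grid over
#' `k_bounds` (with beta profiled by 1-D optimisation at each grid point) and
#' the best grid point is polished by bounded Nelder-Mead on
#' `(log K, log beta)`. Degenerate choice patterns (all delayed / all
#' immediate, or a fit pinned at a K bound) are flagged `converged = FALSE`.
#'
#' @param log A choice log: columns `immediate_amount`, `delayed_amount`,
#'   `delay_days` (or `delay`), `chose_delayed`.
#' @param k_bounds Search bounds for K (1/day).
#' @param beta_bounds Search bounds for the choice slope.
#' @param n_grid Number of log-spaced K grid points.
#' @return data.frame (`discounting_fit`): `k`, `beta`, `log_likelihood`,
#'   `converged`.
#' @export
fit_hyperbolic_k <- function(log, k_bounds = c(1e-5, 1),
                             beta_bounds = c(1e-3, 100), n_grid = 41) {
  if (nrow(log) == 0) stop("empty choice log")
  delay <- if ("delay_days" %in% names(log)) log$delay_days else log$delay
  a_i <- log$immediate_amount
  a_d <- log$delayed_amount
  y <- as.logical(log$chose_delayed)

  nll <- function(logk, logbeta) {
    v_d <- discounted_value(a_d, delay, exp(logk))
    p <- stats::plogis(exp(logbeta) * (v_d - a_i))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(ifelse(y, base::log(p), log1p(-p)))
  }
  grid <- seq(base::log(k_bounds[1]), base::log(k_bounds[2]), length.out = n_grid)
  prof <- vapply(grid, function(lk) {
    opt <- stats::optimize(function(lb) nll(lk, lb),
                           base::log(beta_bounds))
    c(opt$objective, opt$minimum)
  }, numeric(2))
  best <- which.min(prof[1, ])
  fit <- stats::optim(c(grid[best], prof[2, best]),
                      function(p) nll(p[1], p[2]),
                      method = "L-BFGS-B",
                      lower = base::log(c(k_bounds[1], beta_bounds[1])),
                      upper = base::log(c(k_bounds[2], beta_bounds[2])))
  k_hat <- exp(fit$par[1])
  one_sided <- all(y) || !any(y)
  at_bound <- k_hat <= k_bounds[1] * 1.01 || k_hat >= k_bounds[2] * 0.99
  res <- data.frame(k = k_hat, beta = exp(fit$par[2]),
                    log_likelihood = -fit$value,
                    converged = fit$convergence == 0 && !one_sided && !at_bound)
  class(res) <- c("discounting_fit", "data.frame")
  res
}

#' Score a speeded-arithmetic session
#'
#' A trial is *timely* if it was responded to with RT at or below the
#' deadline, and *accurate* if the timely response matched the correct side.
#' By default accuracy is `n(accurate & timely) / n(all trials)` — late or
#' omitted responses count as failures, matching a speeded-deadline design;
#' `denominator = "timely"` divides by timely trials only. Subjects with
#' fewer than `min_valid` accurate-and-timely trials are flagged `discarded`.
#'
#' @param log data.frame with `correct_answer_side`, `response_side` (`NA` if
#'   omitted), `rt`.
#' @param deadline_ms Response deadline in ms.
#' @param min_valid Minimum accurate-and-timely trials to keep the subject.
#' @param denominator `"all"` (default) or `"timely"`.
#' @return data.frame (`arith_result`): `accuracy`, `mean_rt` (timely correct
#'   trials), `n_valid` (accurate & timely count), `discarded`.
#' @export
score_arithmetic <- function(log, deadline_ms = 2000, min_valid = 3,
                             denominator = c("all", "timely")) {
  denominator <- match.arg(denominator)
  if (nrow(log) == 0) stop("empty arithmetic log")
  timely <- !is.na(log$response_side) & !is.na(log$rt) & log$rt <= deadline_ms
  accurate <- timely & log$response_side == log$correct_answer_side
  n_valid <- sum(accurate)
  denom <- if (denominator == "all") nrow(log) else sum(timely)
  accuracy <- if (denom == 0) 0 else n_valid / denom
  data.frame(accuracy = accuracy,
             mean_rt = if (n_valid > 0) mean(log$rt[accurate]) else NA_real_,
             n_valid = n_valid,
             discarded = n_valid < min_valid)
}

#' Score a recognition-memory session
#'
#' Proportion of trials where the chosen alternative matches the studied one;
#' chance level is 0.25 under four alternatives.
#'
#' @param log data.frame with `chosen_alternative`, `correct_alternative`,
#'   optionally `rt`.
#' @return data.frame (`memory_result`): `accuracy`, `mean_rt` (`NA` if no RT
#'   column), `n_valid`.
#' @export
score_memory <- function(log) {
  if (nrow(log) == 0) stop("empty memory log")
  correct <- log$chosen_alternative == log$correct_alternative
  data.frame(accuracy = mean(correct),
             mean_rt = if ("rt" %in% names(log)) mean(log$rt) else NA_real_,
             n_valid = nrow(log))
}
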