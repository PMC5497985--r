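#' Simulate a stop-signal session from a race-model agent
#'
#' Go reaction times are drawn from a normal distribution (`go_rt_mean`,
#' `go_rt_sd`, truncated at 50 ms). On stop trials a response is emitted iff
#' the sampled go RT is below `SSD + ssrt_true` (horse-race model). The
#' stop-signal delay follows a one-up/one-down staircase: a successful stop
#' raises the next stop trial's SSD by `ssd_step`, a failed stop lowers it,
#' floored at 0 — so the stop-success rate tracks 50%.
#'
#' Stop trials are deterministically interleaved: trials are laid out in
#' blocks of `round(1/stop_fraction)` with exactly one stop trial per block at
#' a seeded random position, so the nominal stop fraction is exact whenever
#' `n_trials` is a multiple of the block length.
#'
#' @param truth A [subject_truth()] (fields used: `ssrt_true`, `go_rt_mean`,
#'   `go_rt_sd`).
#' @param n_trials Total number of trials.
#' @param stop_fraction Fraction of stop trials (default 0.25).
#' @param ssd_initial,ssd_step Staircase start and step, ms.
#' @param p_go_error Probability of a wrong-cue press on a responded go trial.
#' @param seed Integer seed.
#' @return data.frame (`stop_trial_log`): `trial_index`, `trial_type`
#'   (`"go"`/`"stop"`), `cue` (`"x"`/`"o"`), `ssd` (ms, `NA` on go trials),
#'   `responded`, `rt` (ms, `NA` if no response), `correct_cue`.
#' @export
simulate_stop_signal <- function(truth, n_trials = 400, stop_fraction = 0.25,
                                 ssd_initial = 250, ssd_step = 50,
                                 p_go_error = 0.02, seed = 1L) {
  stopifnot(stop_fraction > 0, stop_fraction < 1, ssd_step > 0, n_trials >= 1)
  set.seed(seed)
  block <- max(2L, as.integer(round(1 / stop_fraction)))
  is_stop <- logical(n_trials)
  for (start in seq(1L, n_trials, by = block)) {
    len <- min(block, n_trials - start + 1L)
    if (len == block) is_stop[start + sample.int(block, 1L) - 1L] <- TRUE
  }
  cue <- sample(c("x", "o"), n_trials, replace = TRUE)
  go_rt <- pmax(50, stats::rnorm(n_trials, truth$go_rt_mean, truth$go_rt_sd))

  ssd <- rep(NA_real_, n_trials)
  responded <- logical(n_trials)
  rt <- rep(NA_real_, n_trials)
  correct_cue <- rep(NA, n_trials)
  cur_ssd <- ssd_initial
  for (i in seq_len(n_trials)) {
    if (is_stop[i]) {
      ssd[i] <- cur_ssd
      if (go_rt[i] < cur_ssd + truth$ssrt_true) {   # go process wins: failed stop
        responded[i] <- TRUE
        rt[i] <- go_rt[i]
        correct_cue[i] <- stats::runif(1) > p_go_error
        cur_ssd <- max(0, cur_ssd - ssd_step)
      } else {                                      # successful stop
        cur_ssd <- cur_ssd + ssd_step
      }
    } else {
      responded[i] <- TRUE
      rt[i] <- go_rt[i]
      correct_cue[i] <- stats::runif(1) > p_go_error
    }
  }
  log <- data.frame(trial_index = seq_len(n_trials),
                    trial_type = ifelse(is_stop, "stop", "go"),
                    cue = cue, ssd = ssd, responded = responded, rt = rt,
                    correct_cue = correct_cue, stringsAsFactors = FALSE)
  class(log) <- c("stop_trial_log", "data.frame")
  log
}

#' The default 27-item monetary-choice question set
#'
#' The standard Kirby-style grid of immediate-versus-delayed money choices
#' (immediate amounts 11-80, delayed amounts 25-85, delays 7-186 days), the
#' common instrument for estimating the hyperbolic discount rate K.
#'
#' @return data.frame: `immediate_amount`, `delayed_amount`, `delay_days`.
#' @export
kirby_choice_set <- function() {
  data.frame(
    immediate_amount = c(54, 55, 19, 31, 14, 47, 15, 25, 78, 40, 11, 67, 34,
                         27, 69, 49, 80, 24, 33, 28, 34, 25, 41, 54, 54, 22, 20),
    delayed_amount   = c(55, 75, 25, 85, 25, 50, 35, 60, 80, 55, 30, 75, 35,
                         50, 85, 60, 85, 35, 80, 30, 50, 30, 75, 60, 80, 25, 55),
    delay_days       = c(117, 61, 53, 7, 19, 160, 13, 14, 162, 62, 7, 119, 186,
                         21, 91, 89, 157, 29, 14, 179, 30, 80, 20, 111, 30, 136, 7)
  )
}

#' Simulate delay-discounting choices
#'
#' For each item the agent discounts hyperbolically with its true K
#' ([discounted_value()]) and chooses the delayed option with probability
#' `plogis(choice_beta * (V_delayed - V_immediate))`; `choice_beta = Inf`
#' gives a deterministic value-maximiser.
#'
#' @param truth A [subject_truth()] (fields used: `k_true`, `choice_beta`).
#' @param choice_set data.frame with `immediate_amount`, `delayed_amount`,
#'   `delay_days`; defaults to [kirby_choice_set()].
#' @param repeats Number of passes through the item set.
#' @param seed Integer seed.
#' @return data.frame (`choice_log`): the item columns plus `chose_delayed`.
#' @export
simulate_discounting <- function(truth, choice_set = kirby_choice_set(),
                                 repeats = 1, seed = 1L) {
  if (nrow(choice_set) == 0) stop("empty choice set")
  stopifnot(all(choice_set$immediate_amount > 0),
            all(choice_set$delayed_amount > 0),
            all(choice_set$delay_days >= 0))
  set.seed(seed)
  items <- choice_set[rep(seq_len(nrow(choice_set)), repeats), , drop = FALSE]
  v_i <- items$immediate_amount
  v_d <- discounted_value(items$delayed_amount, items$delay_days, truth$k_true)
  p_d <- stats::plogis(truth$choice_beta * (v_d - v_i))
  p_d[is.nan(p_d)] <- 0.5                    # Inf * 0 when values tie exactly
  items$chose_delayed <- stats::runif(nrow(items)) < p_d
  rownames(items) <- NULL
  class(items) <- c("choice_log", "data.frame")
  items
}

#' Simulate a speeded-arithmetic session
#'
#' Bernoulli accuracy with the subject's `p_arith`; responses are timely
#' (RT below the deadline) with probability `p_timely`, RTs drawn lognormal.
#'
#' @param truth A [subject_truth()] (field used: `p_arith`).
#' @param n_trials Trials per session.
#' @param p_timely Probability a response lands before the deadline.
#' @param deadline_ms Response deadline, ms.
#' @param seed Integer seed.
#' @return data.frame (`arith_log`): `trial_index`, `correct_answer_side`,
#'   `response_side` (`NA` if omitted), `rt` (ms, `NA` if omitted).
#' @export
simulate_arithmetic <- function(truth, n_trials = 40, p_timely = 0.95,
                                deadline_ms = 2000, seed = 1L) {
  set.seed(seed)
  correct_side <- sample(c("greater", "smaller"), n_trials, replace = TRUE)
  is_correct <- stats::runif(n_trials) < truth$p_arith
  timely <- stats::runif(n_trials) < p_timely
  rt <- ifelse(timely,
               pmin(deadline_ms - 1, stats::rlnorm(n_trials, log(900), 0.3)),
               deadline_ms + stats::rexp(n_trials, 1 / 300))
  response <- ifelse(is_correct, correct_side,
                     ifelse(correct_side == "greater", "smaller", "greater"))
  data.frame(trial_index = seq_len(n_trials),
             correct_answer_side = correct_side,
             response_side = response, rt = rt, stringsAsFactors = FALSE)
}

#' Simulate a pattern-recognition memory session
#'
#' Four-alternative forced choice: the subject retrieves the studied
#' orientation with probability `p_mem`, otherwise guesses uniformly over the
#' four alternatives (so expected accuracy is `p_mem + (1 - p_mem)/4`; chance
#' is 0.25).
#'
#' @param truth A [subject_truth()] (field used: `p_mem`).
#' @param n_trials Trials per session.
#' @param seed Integer seed.
#' @return data.frame (`memory_log`): `trial_index`, `correct_alternative`,
#'   `chosen_alternative`.
#' @export
simulate_memory <- function(truth, n_trials = 24, seed = 1L) {
  set.seed(seed)
  correct <- sample.int(4, n_trials, replace = TRUE)
  knows <- stats::runif(n_trials) < truth$p_mem
  chosen <- ifelse(knows, correct, sample.int(4, n_trials, replace = TRUE))
  data.frame(trial_index = seq_len(n_trials),
             correct_alternative = correct, chosen_alternative = chosen)
}
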