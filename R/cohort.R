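#' Ground-truth parameters for one simulated subject
#'
#' Houses everything the downstream estimators are supposed to recover:
#' the TEP amplitude scale and true inhibition level, race-model stop-signal
#' parameters, the hyperbolic discount rate and decision noise, task accuracy
#' probabilities, and questionnaire-scale means.
#'
#' @param subject_id Identifier.
#' @param group Group label (e.g. `"SU"`, `"NU"`).
#' @param tep_amplitude_scale Multiplier on the canonical TEP template.
#' @param lici_true True inhibition in percent (negative = facilitation).
#' @param noise_sd Per-sample EEG noise sd, microvolts.
#' @param ssrt_true Stop-signal reaction time, ms.
#' @param go_rt_mean,go_rt_sd Go RT distribution, ms.
#' @param k_true Hyperbolic discount rate, 1/day.
#' @param choice_beta Logistic decision-noise slope (per value unit).
#' @param p_arith,p_mem Accuracy probabilities for the arithmetic and memory
#'   tasks.
#' @param score_means Named list of questionnaire-scale means.
#' @return An object of class `subject_truth`.
#' @export
subject_truth <- function(subject_id = "s01", group = "NU",
                          tep_amplitude_scale = 1, lici_true = 27,
                          noise_sd = 5, ssrt_true = 240, go_rt_mean = 600,
                          go_rt_sd = 100, k_true = 0.01, choice_beta = 0.5,
                          p_arith = 0.8, p_mem = 0.6, score_means = list()) {
  stopifnot(noise_sd >= 0, go_rt_sd >= 0, k_true >= 0,
            p_arith >= 0, p_arith <= 1, p_mem >= 0, p_mem <= 1)
  structure(list(subject_id = subject_id, group = group,
                 tep_amplitude_scale = tep_amplitude_scale,
                 lici_true = lici_true, noise_sd = noise_sd,
                 ssrt_true = ssrt_true, go_rt_mean = go_rt_mean,
                 go_rt_sd = go_rt_sd, k_true = k_true,
                 choice_beta = choice_beta, p_arith = p_arith, p_mem = p_mem,
                 score_means = score_means),
            class = "subject_truth")
}

#' Default per-group parameter distributions
#'
#' Study-condition defaults for a two-group cohort of heavy smartphone users
#' (SU, n = 16) versus nonusers (NU, n = 35). Group means follow the
#' published group summaries where available (SSRT 239/241 ms, go RT 583/601
#' ms, inhibition 29/26 percent) and otherwise encode the reported effect
#' directions at their reported effect sizes (lower TEP amplitude, higher K,
#' lower arithmetic accuracy and higher ADHD-scale scores in SU).
#'
#' @return Named list of group definitions, each with `label`, `n`, `mean`
#'   and `sd` lists over subject-truth parameters, and `score_mean`/`score_sd`
#'   lists over questionnaire scales.
#' @export
default_group_params <- function() {
  scales_sd <- list(inattention = 10, hyperactivity = 10, impulsivity = 10,
                    adhd_index = 10, cas = 10, bdi = 5, rsms = 10,
                    usage_freq = 110)
  list(
    SU = list(
      label = "SU", n = 16,
      mean = list(tep_amplitude_scale = 0.8, lici_true = 29, noise_sd = 5,
                  ssrt_true = 239, go_rt_mean = 583, go_rt_sd = 80,
                  log_k = log(0.025), choice_beta = 0.5,
                  p_arith = 0.70, p_mem = 0.60),
      sd = list(tep_amplitude_scale = 0.3, lici_true = 5, noise_sd = 0,
                ssrt_true = 32, go_rt_mean = 75, go_rt_sd = 0,
                log_k = 0.8, choice_beta = 0, p_arith = 0.12, p_mem = 0.15),
      score_mean = list(inattention = 52, hyperactivity = 52, impulsivity = 52.5,
                        adhd_index = 55, cas = 56, bdi = 8, rsms = 50,
                        usage_freq = 1068),
      score_sd = scales_sd
    ),
    NU = list(
      label = "NU", n = 35,
      mean = list(tep_amplitude_scale = 1.0, lici_true = 26, noise_sd = 5,
                  ssrt_true = 241, go_rt_mean = 601, go_rt_sd = 80,
                  log_k = log(0.010), choice_beta = 0.5,
                  p_arith = 0.80, p_mem = 0.60),
      sd = list(tep_amplitude_scale = 0.3, lici_true = 6, noise_sd = 0,
                ssrt_true = 41, go_rt_mean = 114, go_rt_sd = 0,
                log_k = 0.8, choice_beta = 0, p_arith = 0.12, p_mem = 0.15),
      score_mean = list(inattention = 46, hyperactivity = 45, impulsivity = 45,
                        adhd_index = 47, cas = 50, bdi = 8, rsms = 50,
                        usage_freq = 200),
      score_sd = scales_sd
    )
  )
}

#' Cohort simulation specification
#'
#' @param groups Group definitions as in [default_group_params()].
#' @param correlation_targets List of length-3 lists/vectors
#'   `(scale_a, scale_b, rho)` imposed on the questionnaire-score covariance
#'   within every group. Default: usage frequency correlates 0.5 with
#'   inattention.
#' @param protocol [protocol_config()] used when EEG epochs are generated.
#' @param tasks Simulate behavioral task logs (stop-signal, discounting,
#'   arithmetic, memory)? Disable for fast score-only cohorts.
#' @param seed Master seed; everything downstream is deterministic given it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = default_group_params(),
                        correlation_targets = list(list("usage_freq",
                                                        "inattention", 0.5)),
                        protocol = protocol_config(),
                        tasks = TRUE, seed = 1L) {
  for (g in groups) stopifnot(g$n >= 1)
  for (ct in correlation_targets) {
    if (abs(as.numeric(ct[[3]])) > 1) stop("|rho| must be <= 1")
  }
  structure(list(groups = groups, correlation_targets = correlation_targets,
                 protocol = protocol, tasks = tasks, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Correlation matrix over score scales implied by the targets; identity off
# the targeted pairs. Errors if not positive semi-definite.
score_correlation_matrix <- function(scales, targets) {
  R <- diag(length(scales))
  dimnames(R) <- list(scales, scales)
  for (ct in targets) {
    a <- ct[[1]]; b <- ct[[2]]; rho <- as.numeric(ct[[3]])
    if (!(a %in% scales) || !(b %in% scales)) {
      stop("correlation target names unknown scale: ", a, " / ", b)
    }
    R[a, b] <- R[b, a] <- rho
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("correlation targets imply a non-positive-semi-definite matrix ",
         sprintf("(min eigenvalue %.3g)", min(ev)))
  }
  R
}

#' Simulate a cohort with known ground truth
#'
#' Draws per-subject ground-truth parameters from the group distributions
#' (normal, truncated where the parameter has a hard bound; K is lognormal
#' via `log_k`), questionnaire score tables from a multivariate normal whose
#' correlation structure honours `correlation_targets`, and (optionally) the
#' behavioral task logs. EEG epochs are not materialised here — they can be
#' large — but every subject carries an `eeg_seed`, and
#' [subject_epochs()] regenerates that subject's epoch sets on demand,
#' deterministically.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `cohort_dataset`: `spec`, `subjects` (one row
#'   per subject: group, ground truth, per-task seeds, score columns) and
#'   `logs` (per-subject list of task logs, if `spec$tasks`).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  scales <- names(spec$groups[[1]]$score_mean)
  R <- score_correlation_matrix(scales, spec$correlation_targets)

  subjects <- list()
  idx <- 0
  for (g in spec$groups) {
    sd_vec <- unlist(g$score_sd[scales])
    Sigma <- diag(sd_vec) %*% R %*% diag(sd_vec)
    scores <- MASS::mvrnorm(g$n, mu = unlist(g$score_mean[scales]),
                            Sigma = Sigma)
    scores <- matrix(scores, nrow = g$n,
                     dimnames = list(NULL, scales))
    draw <- function(p, lower = -Inf, upper = Inf) {
      x <- stats::rnorm(g$n, g$mean[[p]], g$sd[[p]])
      pmin(pmax(x, lower), upper)
    }
    df <- data.frame(
      subject_id = sprintf("%s%02d", g$label, seq_len(g$n)),
      group = g$label,
      tep_amplitude_scale = draw("tep_amplitude_scale", lower = 0.05),
      lici_true = draw("lici_true"),
      noise_sd = draw("noise_sd", lower = 0),
      ssrt_true = draw("ssrt_true", lower = 80),
      go_rt_mean = draw("go_rt_mean", lower = 200),
      go_rt_sd = draw("go_rt_sd", lower = 10),
      k_true = exp(draw("log_k")),
      choice_beta = draw("choice_beta", lower = 0.01),
      p_arith = draw("p_arith", lower = 0.05, upper = 1),
      p_mem = draw("p_mem", lower = 0, upper = 1),
      stringsAsFactors = FALSE
    )
    df <- cbind(df, as.data.frame(scores))
    subjects[[g$label]] <- df
    idx <- idx + g$n
  }
  subjects <- do.call(rbind, subjects)
  rownames(subjects) <- NULL
  n_total <- nrow(subjects)
  subjects$eeg_seed <- sample.int(.Machine$integer.max - 1, n_total)
  subjects$task_seed <- sample.int(.Machine$integer.max - 1, n_total)

  logs <- NULL
  if (spec$tasks) {
    logs <- lapply(seq_len(n_total), function(i) {
      truth <- truth_from_row(subjects[i, ])
      s <- subjects$task_seed[i]
      list(stop = simulate_stop_signal(truth, seed = s),
           choice = simulate_discounting(truth, repeats = 5, seed = s + 1L),
           arithmetic = simulate_arithmetic(truth, seed = s + 2L),
           memory = simulate_memory(truth, seed = s + 3L))
    })
    names(logs) <- subjects$subject_id
  }
  structure(list(spec = spec, subjects = subjects, logs = logs),
            class = "cohort_dataset")
}

truth_from_row <- function(row) {
  subject_truth(subject_id = row$subject_id, group = row$group,
                tep_amplitude_scale = row$tep_amplitude_scale,
                lici_true = row$lici_true, noise_sd = row$noise_sd,
                ssrt_true = row$ssrt_true, go_rt_mean = row$go_rt_mean,
                go_rt_sd = row$go_rt_sd, k_true = row$k_true,
                choice_beta = row$choice_beta, p_arith = row$p_arith,
                p_mem = row$p_mem)
}

#' Regenerate one subject's TEP epoch sets
#'
#' Deterministic given the cohort's master seed: uses the per-subject
#' `eeg_seed` drawn at cohort creation.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param subject_id Subject to generate.
#' @return List with `single` and `paired` [epoch_set()]s.
#' @export
subject_epochs <- function(cohort, subject_id) {
  i <- match(subject_id, cohort$subjects$subject_id)
  if (is.na(i)) stop("unknown subject: ", subject_id)
  simulate_tep_epochs(truth_from_row(cohort$subjects[i, ]),
                      cohort$spec$protocol,
                      seed = cohort$subjects$eeg_seed[i])
}

#' @export
print.cohort_dataset <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat("cohort_dataset:", nrow(x$subjects), "subjects (",
      paste(sprintf("%s n=%d", names(tab), as.integer(tab)), collapse = ", "),
      "), seed", x$spec$seed, "\n")
  invisible(x)
}

#' Score a cohort: per-subject outcome measures
#'
#' Runs the full measurement pipeline over a simulated cohort and returns the
#' per-subject measure table the statistics layer consumes: early TEP and
#' LICI (if `eeg = TRUE`; regenerates each subject's epochs, which dominates
#' run time), SSRT and go-task summaries, the fitted discount rate, and
#' arithmetic/memory accuracies, alongside the questionnaire scores.
#' Arithmetic scores follow the discard rule (fewer than `min_valid`
#' accurate-and-timely trials gives `NA` accuracy with `arith_discarded`
#' set).
#'
#' @param cohort A [simulate_cohort()] result (with `tasks = TRUE` for the
#'   behavioral columns).
#' @param eeg Compute TEP/LICI measures from regenerated epochs?
#' @param min_valid Arithmetic discard threshold.
#' @return data.frame, one row per subject.
#' @export
analyze_cohort <- function(cohort, eeg = TRUE, min_valid = 3) {
  subj <- cohort$subjects
  out <- data.frame(subject_id = subj$subject_id, group = subj$group,
                    stringsAsFactors = FALSE)
  if (eeg) {
    tep <- lapply(subj$subject_id, function(id) {
      ep <- subject_epochs(cohort, id)
      compute_subject_tep_metrics(ep$single, ep$paired)
    })
    tep <- do.call(rbind, tep)
    out$early_tep_mean <- tep$early_tep_mean
    out$early_tep_auc <- tep$early_tep_auc
    out$lici_percent <- tep$lici_percent
  }
  if (!is.null(cohort$logs)) {
    beh <- lapply(cohort$logs, function(lg) {
      sst <- estimate_ssrt(lg$stop)
      fit <- fit_hyperbolic_k(lg$choice)
      ar <- score_arithmetic(lg$arithmetic, min_valid = min_valid)
      mem <- score_memory(lg$memory)
      data.frame(ssrt = sst$ssrt, mean_go_rt = sst$mean_go_rt,
                 go_error_rate = sst$go_error_rate,
                 stop_success_rate = sst$stop_success_rate,
                 k = fit$k,
                 arith_accuracy = ifelse(ar$discarded, NA_real_, ar$accuracy),
                 arith_discarded = ar$discarded,
                 memory_accuracy = mem$accuracy)
    })
    out <- cbind(out, do.call(rbind, beh))
    rownames(out) <- NULL
  }
  score_cols <- names(cohort$spec$groups[[1]]$score_mean)
  out <- cbind(out, subj[, score_cols, drop = FALSE])
  out
}
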