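#' Simulate single- and paired-pulse TEP epochs for one subject
#'
#' Generates epoched EEG around TMS pulses with a known ground truth. The
#' noise-free single-pulse response on each channel is the canonical template
#' ([tep_template()]) scaled by the subject's `tep_amplitude_scale` and the
#' channel's spatial gain. A paired-pulse epoch is the conditioning-pulse (CS)
#' response placed at `-cs_ts_interval_ms` plus a test-pulse (TS) response
#' whose post-TS waveform is multiplied by `1 - lici_true/100`; with
#' `lici_true = 100` the TS response is fully suppressed, with 0 it equals the
#' single-pulse response. White Gaussian noise with per-sample standard
#' deviation `noise_sd` (microvolts) is added independently to every sample;
#' `noise_color = "pink"` instead adds 1/f-shaped noise of the same marginal
#' standard deviation, for robustness experiments.
#'
#' @param truth A [subject_truth()] (fields used: `tep_amplitude_scale`,
#'   `lici_true`, `noise_sd`, `subject_id`).
#' @param protocol A [protocol_config()].
#' @param seed Integer seed; the simulation is fully deterministic given it.
#' @param noise_color `"white"` (default) or `"pink"`.
#' @return List with elements `single` and `paired`, each an [epoch_set()].
#' @export
simulate_tep_epochs <- function(truth, protocol = protocol_config(),
                                seed = 1L, noise_color = c("white", "pink")) {
  noise_color <- match.arg(noise_color)
  stopifnot(inherits(protocol, "protocol_config"))
  set.seed(seed)
  t_ms <- protocol_time_axis(protocol)
  ch <- protocol$channel_names
  gains <- channel_gains(ch, protocol$coil_channels)
  # CS placed at an integer number of samples before the TS so the
  # shift-subtract correction (integer-sample shift) can remove it exactly;
  # at 2048 Hz a nominal 100 ms interval becomes 205 samples (100.098 ms).
  dt <- 1000 / protocol$sampling_rate
  cs_time <- -round(protocol$cs_ts_interval_ms / dt) * dt
  base <- tep_template(t_ms, scale = truth$tep_amplitude_scale)
  cs <- tep_template(t_ms - cs_time, scale = truth$tep_amplitude_scale)
  ts_factor <- 1 - truth$lici_true / 100

  single_clean <- outer(gains, base)                # channel x time
  paired_clean <- outer(gains, cs + ts_factor * base)

  make <- function(clean, n_trials) {
    arr <- array(rep(clean, n_trials), dim = c(length(ch), length(t_ms), n_trials))
    if (truth$noise_sd > 0) {
      arr <- arr + gen_noise(dim(arr), truth$noise_sd, noise_color)
    }
    arr
  }
  single <- epoch_set(make(single_clean, protocol$n_single), t_ms, ch,
                      protocol$sampling_rate, "single", truth$subject_id)
  paired <- epoch_set(make(paired_clean, protocol$n_paired), t_ms, ch,
                      protocol$sampling_rate, "paired", truth$subject_id,
                      cs_time_ms = cs_time)
  list(single = single, paired = paired)
}

# White or 1/f ("pink") Gaussian noise with marginal sd `sd` per sample,
# independent across channels and trials.
gen_noise <- function(dims, sd, color) {
  n <- prod(dims)
  if (color == "white") {
    return(array(stats::rnorm(n, sd = sd), dim = dims))
  }
  nt <- dims[2]
  # shape white noise in the frequency domain by 1/sqrt(f), renormalise to sd
  f <- c(1, seq_len(nt - 1))
  f <- pmin(f, nt - f + 1)
  shape <- 1 / sqrt(f)
  out <- array(0, dim = dims)
  for (tr in seq_len(dims[3])) {
    for (c_i in seq_len(dims[1])) {
      w <- stats::rnorm(nt)
      x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / nt
      out[c_i, , tr] <- x / stats::sd(x) * sd
    }
  }
  out
}
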