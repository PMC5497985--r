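#' Average epochs into an evoked potential
#'
#' Per-channel mean over trials, followed by per-channel subtraction of the
#' mean over the baseline window. The baseline must lie inside the epoch and,
#' for paired-pulse epochs, end before the conditioning pulse; the default
#' (-400 to -110 ms) ends 10 ms before a CS at -100 ms.
#'
#' @param epochs An [epoch_set()].
#' @param baseline_window Length-2 numeric (ms), inclusive endpoints; `NULL`
#'   skips baseline correction.
#' @return An [erp()].
#' @export
epochs_to_erp <- function(epochs, baseline_window = c(-400, -110)) {
  stopifnot(inherits(epochs, "epoch_set"))
  avg <- apply(epochs$data, c(1, 2), mean)
  if (!is.null(baseline_window)) {
    stopifnot(length(baseline_window) == 2)
    if (baseline_window[1] < min(epochs$time_ms) - 1e-9 ||
        baseline_window[2] > max(epochs$time_ms) + 1e-9) {
      stop("baseline window outside the epoch time axis")
    }
    pulse_times <- c(0, if (is.finite(epochs$cs_time_ms)) epochs$cs_time_ms)
    if (any(pulse_times >= baseline_window[1] & pulse_times <= baseline_window[2])) {
      stop("baseline window overlaps a pulse; it must end before the first pulse")
    }
    if (epochs$condition == "paired" && baseline_window[2] >= epochs$cs_time_ms) {
      stop("baseline window must end before the conditioning pulse at ",
           epochs$cs_time_ms, " ms")
    }
    idx <- which(epochs$time_ms >= baseline_window[1] - 1e-9 &
                   epochs$time_ms <= baseline_window[2] + 1e-9)
    if (length(idx) == 0) stop("baseline window contains no samples")
    avg <- avg - rowMeans(avg[, idx, drop = FALSE])
  }
  erp(avg, epochs$time_ms, epochs$channel_names, epochs$sampling_rate,
      epochs$condition, epochs$subject_id, epochs$cs_time_ms,
      n_trials_averaged = dim(epochs$data)[3])
}

#' Shift-and-subtract correction of the conditioning-pulse response
#'
#' Removes the lingering conditioning-pulse (CS) activity from a paired-pulse
#' evoked potential: the single-pulse ERP is repositioned so its pulse onset
#' aligns with the CS time (`-shift_ms`) and subtracted,
#' `corrected(c, t) = paired(c, t) - single(c, t + shift_ms)`.
#' Samples beyond the grid edge, where the shifted single ERP is undefined,
#' are carried through unmodified and flagged `FALSE` in the result's
#' `defined` mask; downstream window statistics exclude them.
#'
#' The shift is realised as an integer number of samples. A `shift_ms` that
#' is not an exact multiple of the sample period is snapped to the nearest
#' sample count when within half a sample (e.g. a nominal 100 ms at 2048 Hz
#' becomes 205 samples, matching the simulator's CS placement); larger
#' discrepancies are rejected.
#'
#' @param single_erp,paired_erp [erp()]s on an identical grid with identical
#'   channels.
#' @param shift_ms CS-TS interval in ms.
#' @return Corrected paired-pulse [erp()] with a `defined` mask.
#' @export
shift_subtract <- function(single_erp, paired_erp, shift_ms = 100) {
  stopifnot(inherits(single_erp, "erp"), inherits(paired_erp, "erp"))
  if (!same_grid(single_erp, paired_erp)) {
    stop("single and paired ERPs must share time grid and channels")
  }
  dt <- 1000 / single_erp$sampling_rate
  k <- as.integer(round(shift_ms / dt))
  if (k < 1) stop("shift_ms must be at least one sample period")
  nt <- length(paired_erp$time_ms)
  corrected <- paired_erp$data
  defined <- rep(FALSE, nt)
  src <- seq_len(nt) + k                      # sample feeding each target
  ok <- src >= 1 & src <= nt
  corrected[, ok] <- paired_erp$data[, ok, drop = FALSE] -
    single_erp$data[, src[ok], drop = FALSE]
  defined[ok] <- TRUE
  erp(corrected, paired_erp$time_ms, paired_erp$channel_names,
      paired_erp$sampling_rate, "paired", paired_erp$subject_id,
      paired_erp$cs_time_ms, paired_erp$n_trials_averaged, defined = defined)
}
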