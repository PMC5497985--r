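#' @keywords internal
window_index <- function(erp, window, use_defined = TRUE) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  idx <- which(erp$time_ms >= window[1] - 1e-9 & erp$time_ms <= window[2] + 1e-9)
  if (use_defined) idx <- idx[erp$defined[idx]]
  if (length(idx) == 0) {
    stop(sprintf("window [%g, %g] ms contains no (defined) samples",
                 window[1], window[2]))
  }
  idx
}

check_channels <- function(erp, channels) {
  missing <- setdiff(channels, erp$channel_names)
  if (length(missing)) {
    stop("channels not present in ERP: ", paste(missing, collapse = ", "))
  }
  channels
}

#' Rectified mean amplitude over a time window
#'
#' Per channel, the mean absolute voltage over all samples with
#' `window[1] <= t <= window[2]` (inclusive endpoints), then the unweighted
#' mean over the requested channels. This is the early-TEP statistic when
#' applied to the single-pulse ERP with the 15-40 ms window and the coil
#' electrodes.
#'
#' @param erp An [erp()].
#' @param window Length-2 numeric window in ms.
#' @param channels Channels to pool (unweighted mean).
#' @return Rectified mean amplitude in microvolts (non-negative scalar).
#' @export
rectified_window_mean <- function(erp, window = c(15, 40),
                                  channels = c("FC4", "F4", "FC6", "F6")) {
  stopifnot(inherits(erp, "erp"))
  channels <- check_channels(erp, channels)
  idx <- window_index(erp, window)
  per_channel <- rowMeans(abs(erp$data[channels, idx, drop = FALSE]))
  mean(per_channel)
}

#' Rectified area under the curve over a time window
#'
#' Per channel, the composite-trapezoid integral of the absolute voltage over
#' the window, then the unweighted mean over channels. Undefined samples
#' (flagged by [shift_subtract()]) are excluded; the integral runs over the
#' remaining contiguous grid.
#'
#' @inheritParams rectified_window_mean
#' @return Rectified AUC in microvolt-milliseconds (non-negative scalar).
#' @export
rectified_auc <- function(erp, window = c(50, 150),
                          channels = c("FC4", "F4", "FC6", "F6")) {
  stopifnot(inherits(erp, "erp"))
  channels <- check_channels(erp, channels)
  idx <- window_index(erp, window)
  if (length(idx) < 2) stop("need at least two samples for a trapezoid integral")
  tt <- erp$time_ms[idx]
  vals <- apply(abs(erp$data[channels, idx, drop = FALSE]), 1,
                function(v) pracma::trapz(tt, v))
  mean(vals)
}

#' Long-interval cortical inhibition from single- and paired-pulse ERPs
#'
#' Applies the shift-and-subtract correction to remove the conditioning-pulse
#' response from the paired-pulse ERP, then computes
#' `LICI = (1 - AUC_rect(corrected paired) / AUC_rect(single)) * 100`
#' with both rectified AUCs taken over the same post-test-pulse window
#' (default 50-150 ms) on the coil channels. 100 means full suppression of
#' the test-pulse response, 0 no inhibition, negative values facilitation.
#'
#' Samples where the corrected ERP is undefined (grid edge after shifting)
#' are excluded from the window for *both* AUCs, so the ratio compares like
#' with like.
#'
#' @param single_erp,paired_erp Single-pulse and (uncorrected) paired-pulse
#'   [erp()]s on the same grid.
#' @param window Post-TS analysis window in ms.
#' @param channels Coil channel set.
#' @param shift_ms CS-TS interval used for the correction.
#' @return LICI in percent.
#' @export
compute_lici <- function(single_erp, paired_erp, window = c(50, 150),
                         channels = c("FC4", "F4", "FC6", "F6"),
                         shift_ms = 100) {
  corrected <- shift_subtract(single_erp, paired_erp, shift_ms)
  lici_from_corrected(single_erp, corrected, window, channels)
}

# Eq-1 ratio from an already corrected paired ERP; both AUCs restricted to
# the corrected ERP's defined samples within the window.
lici_from_corrected <- function(single_erp, corrected_erp, window, channels) {
  idx <- window_index(corrected_erp, window)
  sub_window <- range(corrected_erp$time_ms[idx])
  single_use <- single_erp
  single_use$defined <- corrected_erp$defined
  auc_single <- rectified_auc(single_use, sub_window, channels)
  auc_paired <- rectified_auc(corrected_erp, sub_window, channels)
  if (auc_single <= 0) {
    stop("rectified AUC of the single-pulse ERP is zero: LICI ratio undefined")
  }
  (1 - auc_paired / auc_single) * 100
}

#' Per-subject TEP metrics
#'
#' Orchestrates the full electrophysiological pipeline for one subject:
#' trial-averaging with baseline correction, the early-TEP statistic from the
#' single-pulse ERP (both the rectified window mean and the rectified AUC over
#' the same window are reported; they are proportional for a fixed window),
#' and LICI from the single/paired pair.
#'
#' @param single,paired [epoch_set()]s for the two conditions.
#' @param early_window Early-TEP window in ms.
#' @param lici_window Post-TS LICI window in ms.
#' @param baseline_window Baseline window passed to [epochs_to_erp()].
#' @param channels Coil channel set.
#' @param shift_ms CS-TS interval for the shift-subtract correction.
#' @return A one-row data.frame of class `tep_result`: `subject_id`,
#'   `early_tep_mean` (uV), `early_tep_auc` (uV ms), `lici_percent`, plus the
#'   windows/channels used as attributes.
#' @export
compute_subject_tep_metrics <- function(single, paired,
                                        early_window = c(15, 40),
                                        lici_window = c(50, 150),
                                        baseline_window = c(-400, -110),
                                        channels = c("FC4", "F4", "FC6", "F6"),
                                        shift_ms = 100) {
  stopifnot(inherits(single, "epoch_set"), inherits(paired, "epoch_set"),
            single$condition == "single", paired$condition == "paired")
  serp <- epochs_to_erp(single, baseline_window)
  perp <- epochs_to_erp(paired, baseline_window)
  res <- data.frame(
    subject_id = single$subject_id,
    early_tep_mean = rectified_window_mean(serp, early_window, channels),
    early_tep_auc = rectified_auc(serp, early_window, channels),
    lici_percent = compute_lici(serp, perp, lici_window, channels, shift_ms),
    stringsAsFactors = FALSE
  )
  attr(res, "early_window") <- early_window
  attr(res, "lici_window") <- lici_window
  attr(res, "baseline_window") <- baseline_window
  attr(res, "channels") <- channels
  attr(res, "shift_ms") <- shift_ms
  class(res) <- c("tep_result", "data.frame")
  res
}
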