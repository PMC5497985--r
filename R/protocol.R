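#' Default scalp montage used by the simulator
#'
#' A small frontal-weighted montage containing the four electrodes under the
#' TMS coil (FC4, FC6, F4, F6) plus surrounding sites.
#'
#' @return Character vector of channel names.
#' @export
default_channels <- function() {
  c("F3", "Fz", "F4", "F6", "FC4", "FC6", "C4", "Cz", "Pz", "Oz")
}

#' TMS-EEG protocol configuration
#'
#' Bundles the acquisition and stimulation parameters of a single/paired-pulse
#' TMS-EEG session. Defaults follow a standard LICI protocol over the right
#' prefrontal cortex: 2048 Hz sampling, 50 single and 50 paired pulses, a
#' 100 ms conditioning-to-test interval, and the four electrodes under the
#' coil (FC4, FC6, F4, F6) as the analysis set.
#'
#' Times are in milliseconds relative to the test-pulse onset at t = 0; in
#' paired-pulse epochs the conditioning pulse (CS) sits at
#' `-cs_ts_interval_ms`. The epoch window must span both the CS time and the
#' end of the LICI analysis window, with enough tail for the shift-subtract
#' correction (which reads the single-pulse response up to
#' `window end + cs_ts_interval_ms`).
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param epoch_window Length-2 numeric, epoch start/end in ms relative to the
#'   test pulse.
#' @param n_single,n_paired Number of single-pulse and paired-pulse trials.
#' @param cs_ts_interval_ms Conditioning-to-test pulse interval in ms.
#' @param channel_names Channels recorded.
#' @param coil_channels Channels under the coil centre, used for TEP/LICI.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(sampling_rate = 2048,
                            epoch_window = c(-400, 350),
                            n_single = 50,
                            n_paired = 50,
                            cs_ts_interval_ms = 100,
                            channel_names = default_channels(),
                            coil_channels = c("FC4", "F4", "FC6", "F6")) {
  stopifnot(is.numeric(sampling_rate), length(sampling_rate) == 1,
            length(epoch_window) == 2, is.numeric(epoch_window),
            n_single >= 1, n_paired >= 1, cs_ts_interval_ms > 0)
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (epoch_window[1] >= epoch_window[2]) stop("epoch_window must be increasing")
  if (!all(coil_channels %in% channel_names)) {
    stop("coil_channels must be a subset of channel_names")
  }
  if (epoch_window[1] > -cs_ts_interval_ms) {
    stop("epoch window too short: must start at or before the CS time (-",
         cs_ts_interval_ms, " ms)")
  }
  if (epoch_window[2] < 150) {
    stop("epoch window too short: must extend to the end of the LICI window (150 ms)")
  }
  structure(list(sampling_rate = sampling_rate,
                 epoch_window = as.numeric(epoch_window),
                 n_single = as.integer(n_single),
                 n_paired = as.integer(n_paired),
                 cs_ts_interval_ms = cs_ts_interval_ms,
                 channel_names = channel_names,
                 coil_channels = coil_channels),
            class = "protocol_config")
}

#' Time axis of a protocol's epochs
#'
#' Uniform grid in ms with step 1000/sampling_rate, constructed so that t = 0
#' (the test-pulse onset) lies exactly on the grid and the CS time is an
#' integer number of samples away (the shift-subtract correction needs an
#' integer-sample shift).
#'
#' @param protocol A [protocol_config()].
#' @return Numeric vector of sample times in ms.
#' @export
protocol_time_axis <- function(protocol) {
  dt <- 1000 / protocol$sampling_rate
  i0 <- floor(protocol$epoch_window[1] / dt)
  i1 <- ceiling(protocol$epoch_window[2] / dt)
  seq(i0, i1) * dt
}

#' @export
print.protocol_config <- function(x, ...) {
  cat("TMS-EEG protocol:", x$sampling_rate, "Hz, epoch",
      sprintf("[%g, %g] ms", x$epoch_window[1], x$epoch_window[2]), "\n")
  cat("  trials:", x$n_single, "single +", x$n_paired,
      "paired (CS-TS", x$cs_ts_interval_ms, "ms)\n")
  cat("  channels:", length(x$channel_names), "| coil set:",
      paste(x$coil_channels, collapse = ", "), "\n")
  invisible(x)
}
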