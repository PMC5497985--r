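#' Canonical TEP component table
#'
#' The simulator's ground-truth TMS-evoked potential is a sum of
#' Gaussian-windowed damped sinusoids at fixed post-pulse latencies, loosely
#' patterned on the stereotyped TEP deflection sequence (P20-N30-P45-N60-
#' N100-P180). The dominant early component sits inside the 15-40 ms
#' early-TEP window so that the early-TEP statistic measures something real,
#' and the N100 is the largest late deflection, as in published TEP
#' waveforms — it carries most of the signal in the 50-150 ms window where
#' paired-pulse inhibition is quantified.
#'
#' @return data.frame with columns `latency_ms`, `amplitude_uv`, `freq_hz`,
#'   `width_ms`.
#' @export
tep_components <- function() {
  data.frame(
    latency_ms   = c(20,  30,  45,  60,  100,  180),
    amplitude_uv = c(6,  -4,   4,  -3,   -6,    3),
    freq_hz      = c(35,  28,  18,  12,    9,    5),
    width_ms     = c(8,    9,  12,  15,   25,   40)
  )
}

#' Evaluate the canonical TEP template
#'
#' Causal waveform: zero before the pulse (t < 0), afterwards the sum of the
#' [tep_components()] each evaluated as
#' `amp * exp(-((t - lat)^2) / (2 width^2)) * cos(2 pi f (t - lat) / 1000)`.
#'
#' @param t_ms Numeric vector of times in ms relative to pulse onset.
#' @param scale Dimensionless amplitude multiplier.
#' @param components Component table, defaults to [tep_components()].
#' @return Numeric vector of voltages (microvolts), same length as `t_ms`.
#' @export
tep_template <- function(t_ms, scale = 1, components = tep_components()) {
  v <- numeric(length(t_ms))
  for (i in seq_len(nrow(components))) {
    cmp <- components[i, ]
    v <- v + cmp$amplitude_uv *
      exp(-((t_ms - cmp$latency_ms)^2) / (2 * cmp$width_ms^2)) *
      cos(2 * pi * cmp$freq_hz * (t_ms - cmp$latency_ms) / 1000)
  }
  v[t_ms < 0] <- 0
  scale * v
}

#' Per-channel spatial gains relative to the coil position
#'
#' Channels under the coil respond at full amplitude; the response falls off
#' with (crudely binned) scalp distance. Channels without an entry in the
#' built-in map get the `default_gain`.
#'
#' @param channel_names Channels to return gains for.
#' @param coil_channels Channels treated as directly under the coil (gain 1).
#' @param default_gain Gain for channels not in the built-in map.
#' @return Named numeric vector of gains in `[0, 1]`.
#' @export
channel_gains <- function(channel_names,
                          coil_channels = c("FC4", "F4", "FC6", "F6"),
                          default_gain = 0.2) {
  map <- c(F3 = 0.25, Fz = 0.5, C4 = 0.55, Cz = 0.35, Pz = 0.15, Oz = 0.08)
  g <- rep(default_gain, length(channel_names))
  names(g) <- channel_names
  hit <- channel_names %in% names(map)
  g[hit] <- map[channel_names[hit]]
  g[channel_names %in% coil_channels] <- 1
  g
}
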