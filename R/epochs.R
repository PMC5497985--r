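#' Epoched TMS-EEG data
#'
#' Container for voltage epochs time-locked to a TMS test pulse: a 3-D array
#' indexed (channel, time, trial) on a uniform time grid in ms, with the test
#' pulse at t = 0. For paired-pulse epochs the conditioning pulse sits at
#' `-cs_time_ms`.
#'
#' @param data Numeric array `[n_channels, n_times, n_trials]`.
#' @param time_ms Numeric vector of sample times (ms), strictly increasing and
#'   uniform.
#' @param channel_names Character vector, one per array row.
#' @param sampling_rate Hz.
#' @param condition `"single"` or `"paired"`.
#' @param subject_id Subject identifier.
#' @param cs_time_ms CS onset in ms (negative) for paired epochs, `NA` for
#'   single.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, time_ms, channel_names, sampling_rate,
                      condition = c("single", "paired"),
                      subject_id = "s01", cs_time_ms = NA_real_) {
  condition <- match.arg(condition)
  if (length(dim(data)) != 3) stop("data must be a 3-D array (channel, time, trial)")
  if (dim(data)[1] != length(channel_names)) stop("channel dimension mismatch")
  if (dim(data)[2] != length(time_ms)) stop("time dimension mismatch")
  if (dim(data)[3] < 1) stop("need at least one trial")
  if (!all(is.finite(data))) stop("data must be finite")
  dt <- diff(time_ms)
  if (any(dt <= 0) || max(abs(dt - 1000 / sampling_rate)) > 1e-6) {
    stop("time_ms must be strictly increasing with step 1000/sampling_rate")
  }
  if (condition == "paired" && !is.finite(cs_time_ms)) {
    stop("paired epochs need cs_time_ms")
  }
  dimnames(data) <- list(channel_names, NULL, NULL)
  structure(list(subject_id = subject_id, condition = condition,
                 channel_names = channel_names, sampling_rate = sampling_rate,
                 time_ms = as.numeric(time_ms), cs_time_ms = cs_time_ms,
                 data = data),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set: subject %s, %s, %d channels x %d samples x %d trials\n",
              x$subject_id, x$condition, dim(x$data)[1], dim(x$data)[2],
              dim(x$data)[3]))
  cat(sprintf("  %g Hz, t in [%g, %g] ms%s\n", x$sampling_rate,
              min(x$time_ms), max(x$time_ms),
              if (is.finite(x$cs_time_ms)) sprintf(", CS at %g ms", x$cs_time_ms) else ""))
  invisible(x)
}

#' Trial-averaged evoked potential
#'
#' Per-channel waveform on the same grid as its source epochs, with the number
#' of averaged trials retained. Optionally carries a logical `defined` mask
#' (used after shift-subtract correction, where grid-edge samples have no
#' shifted counterpart).
#'
#' @param data Numeric matrix `[n_channels, n_times]`.
#' @inheritParams epoch_set
#' @param n_trials_averaged Number of trials the average was taken over.
#' @param defined Logical vector per sample; `FALSE` marks samples carried
#'   through unmodified by a correction step.
#' @return An object of class `erp`.
#' @export
erp <- function(data, time_ms, channel_names, sampling_rate,
                condition = c("single", "paired"), subject_id = "s01",
                cs_time_ms = NA_real_, n_trials_averaged = 1L,
                defined = NULL) {
  condition <- match.arg(condition)
  if (!is.matrix(data)) stop("data must be a matrix (channel x time)")
  if (nrow(data) != length(channel_names)) stop("channel dimension mismatch")
  if (ncol(data) != length(time_ms)) stop("time dimension mismatch")
  if (is.null(defined)) defined <- rep(TRUE, length(time_ms))
  if (length(defined) != length(time_ms)) stop("defined mask length mismatch")
  rownames(data) <- channel_names
  structure(list(subject_id = subject_id, condition = condition,
                 channel_names = channel_names, sampling_rate = sampling_rate,
                 time_ms = as.numeric(time_ms), cs_time_ms = cs_time_ms,
                 data = data, n_trials_averaged = as.integer(n_trials_averaged),
                 defined = defined),
            class = "erp")
}

#' @export
print.erp <- function(x, ...) {
  cat(sprintf("erp: subject %s, %s, %d channels x %d samples (avg of %d trials)\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data),
              x$n_trials_averaged))
  invisible(x)
}

same_grid <- function(a, b) {
  length(a$time_ms) == length(b$time_ms) &&
    max(abs(a$time_ms - b$time_ms)) < 1e-9 &&
    identical(a$channel_names, b$channel_names)
}
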