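# Toy builders used across test files.

# ERP on a uniform grid from hand-given per-channel rows.
toy_erp <- function(rows, time_ms, channels = paste0("ch", seq_along(rows)),
                    condition = "single", cs_time_ms = NA_real_) {
  data <- do.call(rbind, rows)
  sr <- 1000 / diff(time_ms[1:2])
  erp(data, time_ms, channels, sr, condition, cs_time_ms = cs_time_ms)
}

# Single/paired ERP pair constructed noise-free from an arbitrary single
# template `s` (channel x time) and TS response `r`: paired = s placed at the
# CS + r. `k` is the CS-TS shift in samples.
paired_from_single <- function(s, r, time_ms, k) {
  nt <- ncol(s)
  cs_part <- matrix(0, nrow(s), nt)
  idx <- seq_len(nt - k)
  cs_part[, idx] <- s[, idx + k]
  list(single = s, paired = cs_part + r)
}

# Small coil-channel ERP grid helper: 4 coil channels, 256 Hz unless given.
coil_grid <- function(t_start = -200, t_end = 260, sr = 256) {
  dt <- 1000 / sr
  seq(floor(t_start / dt), ceiling(t_end / dt)) * dt
}

coil_channels <- c("FC4", "F4", "FC6", "F6")

# Truth with quiet defaults for fast tests.
quiet_truth <- function(...) subject_truth(noise_sd = 0, ...)
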