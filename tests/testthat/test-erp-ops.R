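test_that("averaging identical trials returns the waveform itself", {
  t_ms <- coil_grid(-200, 260, 256)
  w <- rbind(tep_template(t_ms), 0.5 * tep_template(t_ms))
  arr <- array(rep(w, 5), dim = c(2, length(t_ms), 5))
  ep <- epoch_set(arr, t_ms, c("FC4", "F4"), 256, "single")
  out <- epochs_to_erp(ep, baseline_window = NULL)
  expect_equal(out$data, w, ignore_attr = TRUE)
  expect_equal(out$n_trials_averaged, 5L)
})

test_that("trials alternating +v and -v average to zero", {
  t_ms <- coil_grid(-100, 200, 256)
  v <- rbind(sin(t_ms / 10))
  arr <- array(c(v, -v, v, -v), dim = c(1, length(t_ms), 4))
  ep <- epoch_set(arr, t_ms, "FC4", 256, "single")
  out <- epochs_to_erp(ep, baseline_window = NULL)
  expect_lt(max(abs(out$data)), 1e-12)
})

test_that("trial averaging matches a brute-force loop to 1e-12", {
  set.seed(7)
  t_ms <- coil_grid(-150, 200, 128)
  arr <- array(rnorm(3 * length(t_ms) * 10), dim = c(3, length(t_ms), 10))
  ep <- epoch_set(arr, t_ms, c("FC4", "F4", "Cz"), 128, "single")
  out <- epochs_to_erp(ep, baseline_window = c(-150, -110))
  # independent oracle: naive loops over channels/samples, then baseline
  oracle <- matrix(0, 3, length(t_ms))
  for (c_i in 1:3) for (s_i in seq_along(t_ms)) {
    oracle[c_i, s_i] <- sum(arr[c_i, s_i, ]) / 10
  }
  bl <- which(t_ms >= -150 & t_ms <= -110)
  for (c_i in 1:3) oracle[c_i, ] <- oracle[c_i, ] - mean(oracle[c_i, bl])
  expect_equal(out$data, oracle, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("baseline windows overlapping a pulse are rejected", {
  t_ms <- coil_grid(-200, 260, 256)
  arr <- array(0, dim = c(1, length(t_ms), 2))
  single <- epoch_set(arr, t_ms, "FC4", 256, "single")
  expect_error(epochs_to_erp(single, c(-50, 50)), "pulse")
  paired <- epoch_set(arr, t_ms, "FC4", 256, "paired", cs_time_ms = -100)
  expect_error(epochs_to_erp(paired, c(-150, -50)), "pulse")
  expect_error(epochs_to_erp(single, c(-500, -110)), "outside")
})

test_that("shift-subtract removes an exactly repositioned single response", {
  t_ms <- coil_grid(-200, 260, 256)
  k <- round(100 / (1000 / 256))
  s <- rbind(tep_template(t_ms), 0.7 * tep_template(t_ms))
  pr <- paired_from_single(s, 0 * s, t_ms, k)
  se <- toy_erp(list(s[1, ], s[2, ]), t_ms, c("FC4", "F4"))
  pe <- toy_erp(list(pr$paired[1, ], pr$paired[2, ]), t_ms, c("FC4", "F4"),
                condition = "paired", cs_time_ms = -k * 1000 / 256)
  corr <- shift_subtract(se, pe, shift_ms = k * 1000 / 256)
  expect_lt(max(abs(corr$data[, corr$defined])), 1e-12)
  expect_false(all(corr$defined))           # tail has no shifted counterpart
  # undefined samples carried through unmodified
  expect_equal(corr$data[, !corr$defined], pe$data[, !corr$defined])
})

test_that("subtracting a zero single ERP leaves the paired ERP unchanged", {
  t_ms <- coil_grid(-100, 200, 128)
  pe_dat <- rbind(cos(t_ms / 20))
  se <- toy_erp(list(0 * t_ms), t_ms, "FC4")
  pe <- toy_erp(list(pe_dat[1, ]), t_ms, "FC4", "paired", cs_time_ms = -100)
  corr <- shift_subtract(se, pe, 100)
  expect_equal(corr$data, pe$data, ignore_attr = TRUE)
})

test_that("shift-subtract equals an index-by-index brute-force oracle", {
  t_ms <- seq(0, 9) * 10          # 100 Hz toy grid
  s_val <- c(5, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  p_val <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 4)
  se <- toy_erp(list(s_val), t_ms, "FC4")
  pe <- toy_erp(list(p_val), t_ms, "FC4", "paired", cs_time_ms = -30)
  corr <- shift_subtract(se, pe, shift_ms = 30)
  k <- 3
  for (i in seq_along(t_ms)) {
    if (i + k <= length(t_ms)) {
      expect_equal(unname(corr$data[1, i]), p_val[i] - s_val[i + k])
      expect_true(corr$defined[i])
    } else {
      expect_equal(unname(corr$data[1, i]), p_val[i])
      expect_false(corr$defined[i])
    }
  }
})

test_that("grid or channel mismatches are rejected", {
  t_ms <- seq(0, 9) * 10
  se <- toy_erp(list(rnorm(10)), t_ms, "FC4")
  pe <- toy_erp(list(rnorm(10)), t_ms + 5, "FC4", "paired", cs_time_ms = -30)
  expect_error(shift_subtract(se, pe, 30), "grid")
  pe2 <- toy_erp(list(rnorm(10)), t_ms, "F4", "paired", cs_time_ms = -30)
  expect_error(shift_subtract(se, pe2, 30), "grid|channel")
  pe3 <- toy_erp(list(rnorm(10)), t_ms, "FC4", "paired", cs_time_ms = -30)
  expect_error(shift_subtract(se, pe3, 2), "sample period")
})
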