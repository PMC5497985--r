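test_that("rectified window mean handles zero, constant and hand cases", {
  t_ms <- seq(0, 50, by = 5)
  z <- toy_erp(list(rep(0, 11), rep(0, 11), rep(0, 11), rep(0, 11)),
               t_ms, coil_channels)
  expect_equal(rectified_window_mean(z, c(15, 40)), 0)
  k <- toy_erp(rep(list(rep(-3, 11)), 4), t_ms, coil_channels)
  expect_equal(rectified_window_mean(k, c(15, 40)), 3)
  # two channels, window covering exactly samples [1,-2,3] / [-4,0,2]
  h <- toy_erp(list(c(9, 1, -2, 3, 9, 9, 9, 9, 9, 9, 9),
                    c(9, -4, 0, 2, 9, 9, 9, 9, 9, 9, 9)),
               t_ms, c("FC4", "F4"))
  expect_equal(rectified_window_mean(h, c(5, 15), c("FC4", "F4")), 2.0)
})

test_that("rectified AUC matches rectangle, zero and hand-trapezoid cases", {
  t_ms <- seq(-10, 110, by = 10)
  one <- toy_erp(rep(list(rep(1, 13)), 4), t_ms, coil_channels)
  expect_equal(rectified_auc(one, c(0, 100)), 100)
  z <- toy_erp(rep(list(rep(0, 13)), 4), t_ms, coil_channels)
  expect_equal(rectified_auc(z, c(0, 100)), 0)
  # 5-sample ramp on one channel: composite trapezoid by hand
  t5 <- seq(0, 40, by = 10)
  ramp <- c(0, -1, 2, 3, 4)
  r <- toy_erp(list(ramp), t5, "FC4")
  hand <- sum(diff(t5) * (abs(ramp)[-5] + abs(ramp)[-1]) / 2)
  expect_equal(rectified_auc(r, c(0, 40), "FC4"), hand, tolerance = 1e-12)
})

test_that("window statistics reject empty windows and missing channels", {
  t_ms <- seq(0, 50, by = 5)
  e <- toy_erp(list(rep(1, 11)), t_ms, "FC4")
  expect_error(rectified_window_mean(e, c(200, 250), "FC4"), "no")
  expect_error(rectified_window_mean(e, c(0, 50), "F4"), "not present")
})

test_that("AUC / windowed mean equals the window span up to quadrature error", {
  set.seed(11)
  t_ms <- coil_grid(-100, 200, 512)
  for (i in 1:5) {
    v <- tep_template(t_ms, scale = runif(1, 0.5, 2)) + rnorm(length(t_ms), sd = 0.2)
    e <- toy_erp(list(v), t_ms, "FC4")
    m <- rectified_window_mean(e, c(15, 40), "FC4")
    a <- rectified_auc(e, c(15, 40), "FC4")
    idx <- which(t_ms >= 15 - 1e-9 & t_ms <= 40 + 1e-9)
    span <- diff(range(t_ms[idx]))
    expect_equal(a / m, span, tolerance = 0.05)
  }
})

test_that("Eq-1 identities hold for constructed AUC ratios", {
  t_ms <- coil_grid(-200, 260, 256)
  dt <- 1000 / 256
  k <- round(100 / dt)
  s <- do.call(rbind, rep(list(tep_template(t_ms)), 4))
  se <- toy_erp(asplit(s, 1), t_ms, coil_channels)
  for (case in list(c(1, 0), c(0, 100), c(0.73, 27))) {
    pr <- paired_from_single(s, case[1] * s, t_ms, k)
    pe <- toy_erp(asplit(pr$paired, 1), t_ms, coil_channels, "paired",
                  cs_time_ms = -k * dt)
    expect_equal(compute_lici(se, pe, shift_ms = k * dt), case[2],
                 tolerance = 1e-9)
  }
})

test_that("LICI errors on a degenerate single-pulse response", {
  t_ms <- coil_grid(-200, 260, 256)
  z <- rep(list(rep(0, length(t_ms))), 4)
  se <- toy_erp(z, t_ms, coil_channels)
  pe <- toy_erp(z, t_ms, coil_channels, "paired", cs_time_ms = -100)
  expect_error(compute_lici(se, pe, shift_ms = 100), "undefined|zero")
})

test_that("voltage rescaling scales amplitudes but leaves LICI unchanged", {
  tr <- quiet_truth(lici_true = 35)
  p <- protocol_config(sampling_rate = 256, n_single = 2, n_paired = 2)
  ep <- simulate_tep_epochs(tr, p, seed = 3)
  m1 <- compute_subject_tep_metrics(ep$single, ep$paired)
  ep$single$data <- ep$single$data * 3.7
  ep$paired$data <- ep$paired$data * 3.7
  m2 <- compute_subject_tep_metrics(ep$single, ep$paired)
  expect_equal(m2$early_tep_mean, 3.7 * m1$early_tep_mean, tolerance = 1e-10)
  expect_equal(m2$early_tep_auc, 3.7 * m1$early_tep_auc, tolerance = 1e-10)
  expect_equal(m2$lici_percent, m1$lici_percent, tolerance = 1e-10)
})

test_that("LICI is monotone decreasing in the corrected-paired AUC", {
  t_ms <- coil_grid(-200, 260, 256)
  dt <- 1000 / 256
  k <- round(100 / dt)
  s <- do.call(rbind, rep(list(tep_template(t_ms)), 4))
  se <- toy_erp(asplit(s, 1), t_ms, coil_channels)
  ratios <- seq(0, 1.4, by = 0.2)
  lici <- vapply(ratios, function(rt) {
    pr <- paired_from_single(s, rt * s, t_ms, k)
    pe <- toy_erp(asplit(pr$paired, 1), t_ms, coil_channels, "paired",
                  cs_time_ms = -k * dt)
    compute_lici(se, pe, shift_ms = k * dt)
  }, numeric(1))
  expect_true(all(diff(lici) < 0))
  expect_true(lici[length(lici)] < 0)       # facilitation goes negative
})
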