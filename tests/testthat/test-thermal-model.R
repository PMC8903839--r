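test_that("saturating-exponential model evaluates its closed form", {
  m <- temperature_model()             # A = 31.62, B = 7.99, c = 0.023/min
  expect_equal(predict_temperature(m, 0), 31.62)
  expect_equal(temperature_rise(m, 0), 0)
  # asymptote
  expect_equal(predict_temperature(m, 1e9), 31.62 + 7.99, tolerance = 1e-10)
  # 1 h with per-minute rate: consistent with the ~38 degC in vivo rise
  expect_equal(predict_temperature(m, 3600), 31.62 + 7.99 * (1 - exp(-0.023 * 60)))
  expect_gt(predict_temperature(m, 3600), 37)
  expect_lt(predict_temperature(m, 3600), 38.5)
  # identity predict = A + rise, on a grid
  tt <- seq(0, 7200, by = 60)
  expect_equal(predict_temperature(m, tt), m$A + temperature_rise(m, tt))
  # strict monotonicity of the rise
  expect_true(all(diff(temperature_rise(m, tt)) > 0))
  # per-second reading remains selectable and saturates within minutes
  ms <- temperature_model(c_unit = "per_second")
  expect_equal(temperature_rise(ms, 7200), 7.99, tolerance = 1e-10)
  expect_error(predict_temperature(m, -1), ">= 0")
})

test_that("model fit recovers generator parameters exactly on noiseless data", {
  m <- temperature_model(31.62, 7.99, 0.023, "per_minute")
  s <- gen_temperature_series(m, duration = 7200, dt = 60, noise = noise_spec(0))
  fit <- fit_temperature_model(s)
  expect_equal(fit$model$A, 31.62, tolerance = 1e-4)
  expect_equal(fit$model$B, 7.99, tolerance = 1e-4)
  expect_equal(fit$model$c, 0.023, tolerance = 1e-4)
  expect_equal(fit$R, 1, tolerance = 1e-9)
  expect_false(fit$degenerate)
})

test_that("fit is invariant to the reporting unit of the rate constant", {
  m <- temperature_model()
  s <- gen_temperature_series(m, 7200, 60, noise_spec(0.1, seed = 11))
  f_min <- fit_temperature_model(s, c_unit = "per_minute")
  f_sec <- fit_temperature_model(s, c_unit = "per_second")
  expect_equal(f_min$model$c, f_sec$model$c * 60, tolerance = 1e-8)
  expect_equal(f_min$model$A, f_sec$model$A)
  expect_equal(f_min$rss, f_sec$rss)
})

test_that("noisy-series fit recovers the baseline within 0.2 degC (median over seeds)", {
  m <- temperature_model()
  errs <- vapply(1:100, function(seed) {
    s <- gen_temperature_series(m, 7200, 60, noise_spec(0.2, seed = seed))
    abs(fit_temperature_model(s)$model$A - m$A)
  }, numeric(1))
  expect_lte(median(errs), 0.2)
})

test_that("constant series gives a flagged degenerate fit", {
  s <- timeseries(seq(0, 600, by = 60), rep(33, 11), "degC")
  expect_warning(fit <- fit_temperature_model(s), "degenerate")
  expect_true(fit$degenerate)
  expect_equal(fit$model$B, 0)
})

test_that("ramp schedule tracks the model and hits the protocol endpoint", {
  m <- temperature_model()
  # 90 min protocol from 32.5 degC ends near 39 degC
  sch <- build_ramp_schedule(m, duration = 5400, n_segments = 6,
                             start_setpoint = 32.5)
  expect_equal(sch$t_s[1], 0)
  expect_equal(sch$setpoint_degC[1], 32.5)
  expect_equal(sch$setpoint_degC[nrow(sch)], 39, tolerance = 1 / 39)
  # single segment = one linear ramp
  s1 <- build_ramp_schedule(m, 5400, 1, 32.5)
  expect_equal(nrow(s1), 2)
  mid <- ramp_setpoint(s1, 2700)
  expect_equal(mid, mean(s1$setpoint_degC))
  # 6 segments over 2 h stay within 0.2 degC of the smooth model
  s6 <- build_ramp_schedule(m, 7200, 6, m$A)
  expect_lt(attr(s6, "max_deviation"), 0.2)
  # interpolation error decreases toward zero with refinement
  devs <- vapply(c(1, 2, 4, 8, 16), function(n) {
    attr(build_ramp_schedule(m, 7200, n, m$A), "max_deviation")
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[length(devs)], 0.05)
  expect_error(build_ramp_schedule(m, -5, 3), "duration")
})
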