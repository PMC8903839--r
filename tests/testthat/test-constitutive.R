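test_that("relaxation modulus evaluates the Prony sum and is completely monotone", {
  pr <- mat_table1$prony
  # t = 0: g_inf plus the 473 kPa branch sum
  expect_equal(relaxation_modulus(pr, 0), pr$g_inf + 473e3)
  expect_equal(relaxation_modulus(pr, 1e9), pr$g_inf, tolerance = 1e-12)
  # single branch at t = tau: g_inf + G/e
  expect_equal(relaxation_modulus(prony_1b, 2), 1e5 + 5e4 / exp(1))
  # complete monotonicity on a sampled grid
  tt <- seq(0, 5000, length.out = 400)
  g <- relaxation_modulus(pr, tt)
  expect_true(all(g > 0))
  expect_true(all(diff(g) <= 0))
  expect_true(all(diff(diff(g)) >= -1e-9 * g[1]))   # convex
  expect_error(relaxation_modulus(pr, -1), ">= 0")
})

test_that("dynamic moduli have the correct limits and stay physical", {
  pr <- mat_table1$prony
  d0 <- dynamic_moduli(pr, 0)
  expect_equal(d0$storage, pr$g_inf)
  expect_equal(d0$loss, 0)
  dinf <- dynamic_moduli(pr, 1e9)
  expect_equal(dinf$storage, pr$g_inf + sum(pr$G), tolerance = 1e-6)
  expect_equal(dinf$loss, 0, tolerance = 1e-3)
  # loss peaks at G/2 for a single branch at omega*tau = 1
  d1 <- dynamic_moduli(prony_1b, 1 / prony_1b$tau)
  expect_equal(d1$loss, prony_1b$G / 2)
  # loss non-negative across the spectrum, vanishing at both extremes
  w <- 10^seq(-6, 6, length.out = 100)
  expect_true(all(dynamic_moduli(pr, w)$loss >= 0))
})

test_that("stress response matches its relaxation and dynamic oracles", {
  pr <- mat_table1$prony
  # step strain -> stress = eps0 * G(t), dt <= tau_min/20
  dt <- min(pr$tau) / 40
  tt <- seq(0, 30, by = dt)
  sr <- stress_response(pr, timeseries(tt, rep(0.05, length(tt)), "strain"))
  oracle <- 0.05 * relaxation_modulus(pr, tt)
  expect_lt(max(abs(sr$value - oracle) / oracle), 0.005)
  # zero strain -> zero stress
  s0 <- stress_response(pr, timeseries(tt, numeric(length(tt)), "strain"))
  expect_equal(s0$value, numeric(length(tt)))
  # steady sinusoid: amplitude eps0*|G*| and phase tan(delta) = loss/storage
  f <- 1; dtc <- 1 / 200
  tc <- seq(0, 60, by = dtc)
  eps0 <- 0.03
  sg <- stress_response(pr, timeseries(tc, eps0 * sin(2 * pi * f * tc), "strain"))$value
  dm <- dynamic_moduli(pr, 2 * pi * f)
  last <- tc >= 59 - 1e-9
  amp <- (max(sg[last]) - min(sg[last])) / 2
  expect_equal(amp, eps0 * sqrt(dm$storage^2 + dm$loss^2), tolerance = 0.01)
  # non-uniform sampling rejected
  expect_error(stress_response(pr, timeseries(c(0, 1, 3), c(0, 0, 0), "strain")),
               "uniform")
})

test_that("closed-form hysteresis area agrees with measured steady loops", {
  # elastic material dissipates nothing
  el <- prony_series(2e5)
  expect_equal(hysteresis_closed_form(el, 0.05, 2 * pi), 0)
  # single branch at omega*tau = 1: pi eps0^2 G/2
  w1 <- 1 / prony_1b$tau
  expect_equal(hysteresis_closed_form(prony_1b, 0.1, w1),
               pi * 0.01 * prony_1b$G / 2)
  # packaged branches: generated steady loop area within 2 % by cycle 100
  pr <- mat_table1$prony
  loops <- gen_hysteresis_loops(pr, loading_protocol(0.10, 0.05), n_cycles = 100,
                                waveform = "sin")
  a <- hysteresis_area(loops, cycle = 100)
  expect_equal(as.numeric(a), hysteresis_closed_form(pr, 0.05, 2 * pi),
               tolerance = 0.02)
})

test_that("energy dissipated per steady cycle is never negative", {
  pr <- mat_table1$prony
  for (f in c(0.1, 1, 5)) {
    loops <- gen_hysteresis_loops(pr, loading_protocol(0.05, 0.04, frequency = f),
                                  n_cycles = 12, waveform = "sin")
    expect_gte(as.numeric(hysteresis_area(loops, cycle = 12)), 0)
  }
})

test_that("material container validates physics and loads the packaged preset", {
  m <- table1_material()
  expect_equal(m$E_eq, 500e3)
  expect_equal(m$nu, 0.23)
  expect_equal(m$porosity, 0.68)
  expect_equal(m$permeability, 2.1e-14)
  expect_equal(m$biot_alpha, 1)
  expect_equal(m$Q_dis, 9000)
  expect_equal(m$prony$G, c(200e3, 58e3, 215e3))
  expect_equal(m$prony$tau, c(0.42, 5.82, 1600))
  # long-term shear modulus consistent with drained E_eq
  expect_equal(m$prony$g_inf, 500e3 / (2 * 1.23))
  expect_error(material_properties(5e5, 0.6, 0.68, 1e-14, C_solid = 1, K_solid = 1,
                                   C_fluid = 1, K_fluid = 1), "nu")
  expect_error(material_properties(5e5, 0.23, 1.2, 1e-14, C_solid = 1, K_solid = 1,
                                   C_fluid = 1, K_fluid = 1), "porosity")
})

test_that("material config round trip and preset override work", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("preset = table1", "Q_dis = 4500  # halved source"), path)
  m <- read_material_config(path)
  expect_equal(m$Q_dis, 4500)
  expect_equal(m$E_eq, 500e3)
  writeLines(c("preset = table1", "bogus_key = 3"), path)
  expect_error(read_material_config(path), "unknown material config keys")
})
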