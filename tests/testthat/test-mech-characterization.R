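test_that("hysteresis area matches the elliptic closed form", {
  th <- seq(0, 2 * pi, length.out = 201)
  eps0 <- 0.05; sig0 <- 2e4; delta <- 0.35
  lp <- hysteresis_loop(1, eps0 * sin(th), sig0 * sin(th + delta), 1)
  expect_equal(as.numeric(hysteresis_area(lp)),
               pi * sig0 * eps0 * sin(delta), tolerance = 0.005)
  # elastic (in-phase) loop has zero area
  lp0 <- hysteresis_loop(1, eps0 * sin(th), sig0 * sin(th), 1)
  expect_equal(as.numeric(hysteresis_area(lp0)), 0, tolerance = 1e-12)
})

test_that("loop area is invariant to rotation and stress offset, rejects open loops", {
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  eps <- 0.04 * sin(th); sig <- 1e4 * sin(th + 0.4)
  base <- as.numeric(hysteresis_area(hysteresis_loop(1, eps, sig, 1)))
  # cyclic rotation of the sample order
  rot <- c(41:128, 1:40)
  expect_equal(as.numeric(hysteresis_area(hysteresis_loop(1, eps[rot], sig[rot], 1))),
               base, tolerance = 1e-9)
  # constant stress offset
  expect_equal(as.numeric(hysteresis_area(hysteresis_loop(1, eps, sig + 5e4, 1))),
               base, tolerance = 1e-9)
  # open loop rejected with the gap size
  bad <- hysteresis_loop(1, seq(0, 0.05, length.out = 64),
                         seq(0, 1e4, length.out = 64), 1)
  expect_error(hysteresis_area(bad), "open loop")
})

test_that("dissipative power is area times frequency", {
  expect_equal(dissipative_power(9000, 1), 9000)
  expect_equal(dissipative_power(9000, 0.5), 4500)
  expect_equal(dissipative_power(0, 3), 0)
  expect_error(dissipative_power(-1, 1), "area")
})

test_that("steady-loop area measured on generated data matches the Prony oracle", {
  pr <- mat_table1$prony
  loops <- gen_hysteresis_loops(pr, loading_protocol(0.10, 0.05), n_cycles = 100,
                                waveform = "sin")
  a <- hysteresis_area(loops, cycle = 100)
  expect_equal(as.numeric(a), hysteresis_closed_form(pr, 0.05, 2 * pi),
               tolerance = 0.02)
})

test_that("equilibrium modulus is recovered from relaxation sequences", {
  pr <- prony_series(0, c(8e4, 4e4), c(0.3, 1.5))
  s <- gen_relaxation_sequence(500e3, pr, c(0.05, 0.10, 0.15, 0.20), hold = 60,
                               dt = 0.05, noise = noise_spec(0))
  E <- equilibrium_modulus(s)
  expect_equal(as.numeric(E), 500e3, tolerance = 0.01)
  # only the 10-20% window is used
  rel <- attr(E, "relaxed")
  expect_equal(rel$used, c(FALSE, TRUE, TRUE, TRUE))
  # linear elastic data give the exact slope
  sel <- gen_relaxation_sequence(350e3, prony_series(0), c(0.10, 0.15, 0.20),
                                 hold = 5, dt = 0.05)
  expect_equal(as.numeric(equilibrium_modulus(sel)), 350e3, tolerance = 1e-9)
  # stress offset invariance and linear scaling
  s2 <- s
  for (i in seq_along(s2$steps)) {
    st <- s2$steps[[i]]$stress
    s2$steps[[i]]$stress <- timeseries(st$t_s, 2 * st$value + 1e4, "Pa")
  }
  expect_equal(as.numeric(equilibrium_modulus(s2)), 2 * as.numeric(E),
               tolerance = 1e-9)
  expect_error(equilibrium_modulus(
    gen_relaxation_sequence(1e5, prony_series(0), c(0.01, 0.05), hold = 5, dt = 0.1)),
    "inside")
})

test_that("noisy relaxation sequences still recover E_eq within 3% (median)", {
  pr <- prony_series(0, 5e4, 0.5)
  errs <- vapply(1:100, function(seed) {
    s <- gen_relaxation_sequence(500e3, pr, c(0.10, 0.125, 0.15, 0.175, 0.20),
                                 hold = 20, dt = 0.05,
                                 noise = noise_spec(2e3, seed = seed))
    abs(as.numeric(equilibrium_modulus(s)) - 500e3) / 500e3
  }, numeric(1))
  expect_lte(median(errs), 0.03)
})
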