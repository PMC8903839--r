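test_that("temperature generator equals the analytic model at sd = 0", {
  m <- temperature_model()
  s <- gen_temperature_series(m, duration = 3600, dt = 10, noise = noise_spec(0))
  expect_equal(nrow(s), floor(3600 / 10) + 1)
  expect_identical(ts_unit <- attr(s, "unit"), "degC")
  expect_equal(s$value, predict_temperature(m, s$t_s))
  expect_equal(s$value[1], 31.62)
  # c -> infinity limit: A + B everywhere beyond t = 0
  mfast <- temperature_model(c = 1e6, c_unit = "per_second")
  sf <- gen_temperature_series(mfast, 100, 10, noise_spec(0))
  expect_equal(sf$value[-1], rep(31.62 + 7.99, nrow(sf) - 1))
  expect_error(gen_temperature_series(m, -10, 1), "duration")
  expect_error(gen_temperature_series(m, 10, 0), "dt")
})

test_that("generators are pure functions of (parameters, seed)", {
  m <- temperature_model()
  a <- gen_temperature_series(m, 600, 10, noise_spec(0.1, seed = 42))
  b <- gen_temperature_series(m, 600, 10, noise_spec(0.1, seed = 42))
  expect_identical(a, b)
  # and do not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(gen_temperature_series(m, 600, 10, noise_spec(0.1, seed = 1)))
  expect_identical(rnorm(1), before)
  l1 <- gen_hysteresis_loops(prony_1b, loading_protocol(0.1, 0.05), 2,
                             noise_spec(50, seed = 3))
  l2 <- gen_hysteresis_loops(prony_1b, loading_protocol(0.1, 0.05), 2,
                             noise_spec(50, seed = 3))
  expect_identical(l1, l2)
  fc <- matrix(c(1, 2), 2, 1, dimnames = list(NULL, "g"))
  t1 <- gen_ct_table("g", c("a", "b"), fc, replicates = 3,
                     noise = noise_spec(0.3, seed = 5))
  t2 <- gen_ct_table("g", c("a", "b"), fc, replicates = 3,
                     noise = noise_spec(0.3, seed = 5))
  expect_identical(t1, t2)
})

test_that("hysteresis-loop generator: elastic loops close with zero area", {
  el <- prony_series(3e5)
  loops <- gen_hysteresis_loops(el, loading_protocol(0.1, 0.05), n_cycles = 3)
  expect_length(loops, 3)
  expect_equal(vapply(loops, `[[`, integer(1), "cycle_index"), 1:3)
  # zero up to shoelace roundoff on ~1e4 Pa stresses
  expect_lt(as.numeric(hysteresis_area(loops, 2)), 1e-8)
  expect_error(gen_hysteresis_loops(el, loading_protocol(0.1, -0.1), 1),
               "amplitude")
})

test_that("raised-cosine waveform is compression-only and spans pre to pre+amp", {
  el <- prony_series(3e5)
  loops <- gen_hysteresis_loops(el, loading_protocol(0.10, 0.10), 2,
                                waveform = "raised_cosine")
  eps <- loops[[1]]$strain
  expect_equal(min(eps), 0.10, tolerance = 1e-12)
  expect_equal(max(eps), 0.20, tolerance = 1e-3)
})

test_that("relaxation sequence decays to E_eq * strain at each level", {
  pr <- prony_series(0, 1e5, 0.5)
  s <- gen_relaxation_sequence(500e3, pr, c(0.10, 0.15, 0.20), hold = 20,
                               dt = 0.02, noise = noise_spec(0))
  relaxed <- vapply(s$steps, function(st) {
    v <- st$stress$value; mean(tail(v, 10))
  }, numeric(1))
  expect_equal(relaxed, 500e3 * c(0.10, 0.15, 0.20), tolerance = 1e-6)
  # zero-strain step gives zero stress
  s0 <- gen_relaxation_sequence(500e3, pr, c(0, 0.1), hold = 20, dt = 0.02)
  expect_equal(s0$steps[[1]]$stress$value, rep(0, length(s0$steps[[1]]$stress$value)))
  # short hold warns
  expect_warning(gen_relaxation_sequence(500e3, pr, c(0.1, 0.2), hold = 1, dt = 0.01),
                 "not fully relaxed")
  expect_error(gen_relaxation_sequence(500e3, pr, numeric(0), 10, 0.1), "non-empty")
})

test_that("Ct generator encodes fold changes exactly and rejects bad designs", {
  genes <- c("Sox9", "Twist")
  groups <- c("ctrl", "tm")
  fc <- matrix(c(1, 1, 2, 0.5), 2, 2, byrow = TRUE,
               dimnames = list(groups, genes))
  tab <- gen_ct_table(genes, groups, fc, ref_gene = "RPL13a", replicates = 3,
                      noise = noise_spec(0))
  expect_s3_class(tab, "ct_table")
  # balanced design: every gene x group x replicate present once
  expect_equal(nrow(tab), 3 * 2 * 3)
  # fold 2 means the target Ct is exactly one cycle earlier
  sox_tm <- tab$ct[tab$gene == "Sox9" & tab$group == "tm"]
  sox_c <- tab$ct[tab$gene == "Sox9" & tab$group == "ctrl"]
  expect_equal(unique(sox_c - sox_tm), 1)
  # fold 1 everywhere -> all ddCt are zero downstream
  fc1 <- matrix(1, 2, 2, dimnames = list(groups, genes))
  tab1 <- gen_ct_table(genes, groups, fc1, replicates = 3)
  r <- delta_delta_ct(tab1, "RPL13a", "ctrl")
  expect_equal(r$per_replicate$ddct, rep(0, nrow(r$per_replicate)))
  expect_error(gen_ct_table(genes, groups, -fc, replicates = 3), "> 0")
  fc_bad <- fc; fc_bad[1, 1] <- 1.5
  expect_error(gen_ct_table(genes, groups, fc_bad, replicates = 3), "control")
  expect_error(gen_ct_table(genes, groups, fc, replicates = 1), "replicates")
})

test_that("noisy Ct tables recover true folds within 15% over resimulations", {
  genes <- "Sox9"; groups <- c("ctrl", "tm")
  fc <- matrix(c(1, 2), 2, 1, dimnames = list(groups, genes))
  est <- vapply(1:200, function(seed) {
    tab <- gen_ct_table(genes, groups, fc, replicates = 4,
                        noise = noise_spec(0.3, seed = seed))
    r <- delta_delta_ct(tab, "RPL13a", "ctrl")
    r$summary$mean_fold[r$summary$group == "tm"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 2) / 2, 0.15)
})
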