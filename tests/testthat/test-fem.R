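test_that("mesh construction honors geometry, tags, and refinement", {
  geo <- well_geometry()
  # derived well height reproduces the medium volume
  v_med <- pi * geo$well_radius^2 * geo$well_height -
    pi * geo$sample_radius^2 * geo$sample_thickness
  expect_equal(v_med, 2e-6, tolerance = 0.05)
  m1 <- build_mesh(geo, 0.8e-3)
  m2 <- build_mesh(geo, 0.4e-3)
  # halving h at least quadruples the element count in 2D
  expect_gte(nrow(m2$tri), 4 * nrow(m1$tri))
  # meridian sample area = radius x thickness (pi-collapsed geometry check)
  g <- tri_geometry_for_test(m2)
  expect_equal(sum(g$area[m2$domain == "sample"]),
               geo$sample_radius * geo$sample_thickness, tolerance = 1e-12)
  # every boundary tag present; edges tagged once each
  expect_setequal(unique(m2$edges$tag),
                  c("axis", "base", "wall", "top", "interface"))
  key <- paste(pmin(m2$edges$n1, m2$edges$n2), pmax(m2$edges$n1, m2$edges$n2))
  expect_equal(anyDuplicated(key), 0)
  # sample-only mesh has the piston/side tags
  ms <- build_mesh(geo, 0.4e-3, include_medium = FALSE)
  expect_setequal(unique(ms$edges$tag), c("axis", "base", "side", "piston"))
  expect_error(build_mesh(geo, -1), "target_h")
})

test_that("adiabatic uniform source heats the domain at Q/(rhoC)_eff", {
  msh <- build_mesh(well_geometry(), 0.4e-3, include_medium = FALSE)
  hr <- solve_heat(msh, mat_table1, thermal_bc("adiabatic"), source_Q = 9000,
                   duration = 600, dt = 10, T0 = 32)
  rate_oracle <- 9000 / sample_rhoC(mat_table1)
  dT <- hr$T_final - 32
  expect_equal(max(dT), rate_oracle * 600, tolerance = 0.005)
  # spatially uniform
  expect_lt(diff(range(dT)), 1e-9)
})

test_that("no source + isothermal walls keeps the well at T0 and obeys the maximum principle", {
  msh <- build_mesh(well_geometry(), 0.8e-3)
  hr <- solve_heat(msh, mat_table1, thermal_bc("isothermal", 32), source_Q = 0,
                   duration = 600, dt = 20, T0 = 32)
  expect_equal(max(abs(hr$T_final - 32)), 0, tolerance = 1e-10)
  # maximum principle: cooling from a hot start stays within [wall, T0]
  hr2 <- solve_heat(msh, mat_table1, thermal_bc("isothermal", 32), source_Q = 0,
                    duration = 600, dt = 20, T0 = 40)
  expect_gte(min(hr2$T_final), 32 - 1e-9)
  expect_lte(max(hr2$T_final), 40 + 1e-9)
})

test_that("1D slab conduction matches the Fourier-series solution within 1%", {
  geo <- well_geometry()
  msh <- build_mesh(geo, 0.1e-3, include_medium = FALSE)
  L <- geo$sample_thickness
  alpha <- sample_K(mat_table1) / sample_rhoC(mat_table1)
  tstar <- 0.1 * L^2 / alpha
  hr <- solve_heat(msh, mat_table1, thermal_bc("isothermal", 0), source_Q = 0,
                   duration = tstar, dt = tstar / 400, T0 = 1,
                   dirichlet_tags = c("base", "piston"))
  z <- msh$nodes[, 2]
  oracle <- vapply(z, function(zz) {
    s <- 0
    for (n in seq(1, 199, by = 2)) {
      s <- s + 4 / (n * pi) * sin(n * pi * zz / L) * exp(-(n * pi / L)^2 * alpha * tstar)
    }
    s
  }, numeric(1))
  l2 <- sqrt(sum((hr$T_final - oracle)^2) / sum(oracle^2))
  expect_lte(l2, 0.01)
})

test_that("poroelastic solve: drained slow ramp recovers E_eq; zero loading gives zero fields", {
  msh <- build_mesh(well_geometry(), 0.4e-3, include_medium = FALSE)
  # high permeability + slow ramp = drained elastic response
  mat <- mat_elastic(permeability = 1e-8)
  res <- solve_poroviscoelastic(msh, mat, loading = NULL,
                                piston_strain = function(t) 0.1 * pmin(t / 100, 1),
                                duration = 100, dt = 2, viscoelastic = FALSE)
  area <- pi * well_geometry()$sample_radius^2
  E_est <- abs(res$reaction_N[length(res$reaction_N)]) / area / 0.1
  expect_equal(E_est, 500e3, tolerance = 0.02)
  # zero loading -> identically zero fields
  res0 <- solve_poroviscoelastic(msh, mat, loading = NULL,
                                 piston_strain = function(t) 0 * t,
                                 duration = 10, dt = 2, viscoelastic = FALSE)
  expect_equal(max(abs(res0$u)), 0)
  expect_equal(max(abs(res0$p)), 0)
})

test_that("confined column consolidation matches the Terzaghi series within 1%", {
  geo <- well_geometry()
  msh <- build_mesh(geo, 0.2e-3, include_medium = FALSE)
  mat <- mat_elastic()
  L <- geo$sample_thickness
  Kb <- mat$E_eq / (3 * (1 - 2 * mat$nu))
  G <- mat$E_eq / (2 * (1 + mat$nu))
  cv <- mat$permeability * (Kb + 4 * G / 3) / mat$mu_f
  sigma0 <- 50e3
  tstar <- 0.2 * L^2 / cv
  res <- solve_poroviscoelastic(msh, mat, loading = NULL, mode = "column",
                                load = "traction", sigma0 = sigma0,
                                duration = tstar, dt = tstar / 200,
                                viscoelastic = FALSE, store_history = TRUE)
  z <- msh$nodes[, 2]
  oracle <- vapply(z, function(zz) {
    s <- 0
    for (m in 0:200) {
      M <- (2 * m + 1) * pi / 2
      s <- s + (2 / M) * sin(M * (L - zz) / L) * exp(-M^2 * cv * tstar / L^2)
    }
    sigma0 * s
  }, numeric(1))
  p_num <- res$p_history[, ncol(res$p_history)]
  l2 <- sqrt(sum((p_num - oracle)^2) / sum(oracle^2))
  expect_lte(l2, 0.01)
  # fluid mass bookkeeping closes
  expect_lt(res$fluid_ledger$rel, 0.01)
})

test_that("isothermal scenario keeps the medium change under 0.5 degC with a closed energy ledger", {
  res <- run_scenario(scenario_config("isothermal_32C", minutes = 90,
                                      target_h = 0.4e-3))
  expect_lt(res$max_medium_dT, 0.5)
  expect_lt(res$heat$ledger$closure_rel, 0.01)
  # Darcy speeds exist and are small (mostly undrained gel)
  expect_gt(mean(res$poro$v_f$speed), 0)
  expect_lt(max(res$poro$v_f$speed), 1e-2)
})

test_that("adiabatic scenario rises monotonically and exceeds the isothermal case", {
  iso <- run_scenario(scenario_config("isothermal_32C", minutes = 30,
                                      target_h = 0.6e-3, mech = FALSE))
  adi <- run_scenario(scenario_config("adiabatic", minutes = 30,
                                      target_h = 0.6e-3, mech = FALSE))
  hist <- adi$heat$medium_max_history
  expect_true(all(diff(hist) > -1e-12))
  expect_gt(mean(adi$heat$T_final), mean(iso$heat$T_final))
  # no source: nothing changes in either scenario
  iso0 <- run_scenario(scenario_config("isothermal_32C", minutes = 10,
                                       target_h = 0.8e-3, Q_dis = 0, mech = FALSE))
  expect_equal(iso0$max_medium_dT, 0, tolerance = 1e-12)
})

test_that("medium warming is non-decreasing in the dissipative source", {
  dts <- vapply(c(3000, 9000, 18000), function(q) {
    run_scenario(scenario_config("isothermal_32C", minutes = 15,
                                 target_h = 0.8e-3, Q_dis = q,
                                 mech = FALSE))$max_medium_dT
  }, numeric(1))
  expect_true(all(diff(dts) > 0))
})

test_that("mesh convergence reports first-order-or-better behavior", {
  cfg <- scenario_config("isothermal_32C", minutes = 90, mech = FALSE)
  tab <- mesh_convergence(cfg, c(0.8e-3, 0.4e-3, 0.2e-3))
  expect_equal(nrow(tab), 3)
  expect_gte(attr(tab, "order"), 1)
  expect_lte(attr(tab, "final_rel_change"), 0.02)
  # identical level run twice is deterministic
  t2 <- mesh_convergence(cfg, c(0.8e-3, 0.4e-3, 0.2e-3))
  expect_identical(tab$max_medium_dT, t2$max_medium_dT)
  expect_warning(mesh_convergence(cfg, c(0.8e-3, 0.6e-3)), "unassessed")
})
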