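#' Configure a well heat-transfer scenario
#'
#' Bundles everything [run_scenario()] needs: the thermal boundary
#' condition (`"isothermal_32C"` holds all outer well boundaries at 32 degC;
#' `"adiabatic"` insulates them), the material set, geometry, loading
#' protocol, horizon, and discretization. The dissipative source defaults
#' to the material's `Q_dis` applied uniformly over the sample subdomain.
#'
#' @param scenario `"isothermal_32C"` or `"adiabatic"`.
#' @param material A [material_properties()] (default [table1_material()]).
#' @param geometry A [well_geometry()].
#' @param loading A [loading_protocol()].
#' @param minutes Thermal horizon in minutes (default 90).
#' @param target_h Mesh size, m (default 0.5 mm, ~1-2k elements).
#' @param dt_heat Heat-equation time step, s (default 10).
#' @param T0 Initial temperature, degC (default 32).
#' @param Q_dis Override of the volumetric source, W/m^3 (default
#'   `material$Q_dis`).
#' @param mech Run the poro-viscoelastic stage to get the advection field?
#'   (default TRUE; the Darcy speeds are tiny, so FALSE gives a
#'   conduction-only approximation)
#' @param n_cycles,dt_mech Mechanical stage controls (see
#'   [solve_poroviscoelastic()]).
#' @return A `"scenario_config"` list.
#' @export
scenario_config <- function(scenario = c("isothermal_32C", "adiabatic"),
                            material = table1_material(),
                            geometry = well_geometry(),
                            loading = loading_protocol(),
                            minutes = 90, target_h = 0.5e-3, dt_heat = 10,
                            T0 = 32, Q_dis = NULL, mech = TRUE,
                            n_cycles = 5, dt_mech = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(material, "material_properties"),
            inherits(geometry, "well_geometry"),
            inherits(loading, "loading_protocol"))
  stop_if_not_scalar(minutes, "minutes", positive = TRUE)
  stop_if_not_scalar(target_h, "target_h", positive = TRUE)
  stop_if_not_scalar(dt_heat, "dt_heat", positive = TRUE)
  if (!is.null(Q_dis)) stop_if_not_scalar(Q_dis, "Q_dis", nonneg = TRUE)
  structure(list(scenario = scenario, material = material, geometry = geometry,
                 loading = loading, minutes = minutes, target_h = target_h,
                 dt_heat = dt_heat, T0 = T0,
                 Q_dis = if (is.null(Q_dis)) material$Q_dis else Q_dis,
                 mech = isTRUE(mech), n_cycles = n_cycles, dt_mech = dt_mech),
            class = "scenario_config")
}

#' Run a coupled well heat-transfer scenario
#'
#' Chains the two physics stages with multirate coupling: the 1 Hz
#' mechanical problem is solved to its periodic cycle on the sample
#' subdomain ([solve_poroviscoelastic()], default 5 cycles), its
#' cycle-averaged Darcy velocity field is handed to the long-horizon heat
#' solve ([solve_heat()]) together with the constant volumetric dissipative
#' source (default 9000 W/m^3 in the sample). Resolving every one of the
#' thousands of mechanical cycles over the thermal horizon is unnecessary
#' because the per-cycle dissipated energy is constant in the periodic
#' regime.
#'
#' @param config A [scenario_config()].
#' @return A `"scenario_result"`: the `heat` result (with `max_medium_dT`,
#'   `max_sample_T`, energy ledger, snapshots), the mechanical stage
#'   result (`poro`, or NULL), the mesh, and the config.
#' @examples
#' \donttest{
#' res <- run_scenario(scenario_config("isothermal_32C", minutes = 10,
#'                                     target_h = 1e-3, mech = FALSE))
#' res$heat$max_medium_dT   # well below 0.5 degC
#' }
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  mesh <- build_mesh(config$geometry, config$target_h)
  poro <- NULL
  advection <- NULL
  if (config$mech && config$Q_dis > 0) {
    sm <- sample_submesh(mesh)
    poro <- solve_poroviscoelastic(sm, config$material, config$loading,
                                   n_cycles = config$n_cycles,
                                   dt = config$dt_mech)
    # map element-averaged Darcy velocities back onto the full mesh
    nt <- nrow(mesh$tri)
    vr <- numeric(nt); vz <- numeric(nt)
    vr[mesh$domain == "sample"] <- poro$v_f$vr
    vz[mesh$domain == "sample"] <- poro$v_f$vz
    advection <- list(vr = vr, vz = vz)
  }
  bc <- if (config$scenario == "isothermal_32C") {
    thermal_bc("isothermal", wall_temperature = 32)
  } else {
    thermal_bc("adiabatic")
  }
  heat <- solve_heat(mesh, config$material, bc, source_Q = config$Q_dis,
                     advection = advection, duration = config$minutes * 60,
                     dt = config$dt_heat, T0 = config$T0)
  structure(list(heat = heat, poro = poro, mesh = mesh, config = config,
                 max_medium_dT = heat$max_medium_dT,
                 max_sample_T = heat$max_sample_T),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%g min, h = %g mm, Q = %g W/m^3):\n",
              x$config$scenario, x$config$minutes, x$config$target_h * 1e3,
              x$config$Q_dis))
  cat(sprintf("  max medium dT = %.4g degC; max sample T = %.4g degC\n",
              x$max_medium_dT, x$max_sample_T))
  invisible(x)
}

#' Mesh-convergence study of a scenario
#'
#' Reruns [run_scenario()] at each mesh size in `h_levels` and tabulates
#' the maximum culture-medium temperature change. With at least three
#' levels, a Richardson-type observed convergence order is estimated from
#' the last three levels; the final two levels should differ by no more
#' than 2 % for the result to count as mesh-converged.
#'
#' @param config A [scenario_config()] (its `target_h` is overridden).
#' @param h_levels Decreasing vector of mesh sizes, m. Fewer than 3 levels
#'   triggers a warning that convergence is unassessed.
#' @return A data frame `(h, n_elements, max_medium_dT)` with attributes
#'   `"order"` (estimated convergence order, NA if not computable) and
#'   `"final_rel_change"`.
#' @export
mesh_convergence <- function(config, h_levels) {
  stopifnot(inherits(config, "scenario_config"))
  if (length(h_levels) < 3) {
    warning("fewer than 3 mesh levels: convergence unassessed")
  }
  rows <- lapply(h_levels, function(h) {
    cfg <- config; cfg$target_h <- h
    res <- run_scenario(cfg)
    data.frame(h = h, n_elements = nrow(res$mesh$tri),
               max_medium_dT = res$max_medium_dT)
  })
  out <- do.call(rbind, rows)
  ord <- NA_real_; final_rel <- NA_real_
  n <- nrow(out)
  if (n >= 2) {
    final_rel <- abs(out$max_medium_dT[n] - out$max_medium_dT[n - 1]) /
      max(abs(out$max_medium_dT[n]), 1e-300)
  }
  if (n >= 3) {
    d1 <- out$max_medium_dT[n - 1] - out$max_medium_dT[n - 2]
    d2 <- out$max_medium_dT[n] - out$max_medium_dT[n - 1]
    r1 <- out$h[n - 2] / out$h[n - 1]
    if (d2 != 0 && d1 / d2 > 0) ord <- log(abs(d1 / d2)) / log(r1)
    if (!is.na(ord) && (d1 * d2 < 0) && abs(d2) > abs(d1)) {
      warning("non-monotone divergence across mesh levels")
    }
  }
  attr(out, "order") <- ord
  attr(out, "final_rel_change") <- final_rel
  out
}
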