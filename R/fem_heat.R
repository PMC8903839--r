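# --- axisymmetric P1 assembly helpers -------------------------------------
# Quadrature: 3 edge-midpoint points, weight area/3 (exact to degree 2).
# Shape-function values at the midpoints (rows = points, cols = nodes):
.midpt_N <- matrix(c(0.5, 0.5, 0,
                     0,   0.5, 0.5,
                     0.5, 0,   0.5), nrow = 3, byrow = TRUE)

# r coordinate at the three quadrature points, nt x 3
.quad_r <- function(geo) {
  cbind((geo$p1[, 1] + geo$p2[, 1]) / 2,
        (geo$p2[, 1] + geo$p3[, 1]) / 2,
        (geo$p1[, 1] + geo$p3[, 1]) / 2)
}

# weighted mass-type integrals: returns nt x 3 x 3 entries as list of columns
# M^e_ab = coef_e * 2*pi * sum_q (A/3) N_a(q) N_b(q) r_q
assemble_mass <- function(mesh, geo, coef) {
  rq <- .quad_r(geo)
  nt <- nrow(mesh$tri)
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    w <- numeric(nt)
    for (q in 1:3) w <- w + .midpt_N[q, a] * .midpt_N[q, b] * rq[, q]
    ii[[k]] <- mesh$tri[, a]; jj[[k]] <- mesh$tri[, b]
    xx[[k]] <- coef * 2 * pi * (geo$area / 3) * w
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = rep(nrow(mesh$nodes), 2))
}

# stiffness: K^e_ab = coef_e * (b_a b_b + c_a c_b) * 2*pi*r_cent * A
assemble_stiffness <- function(mesh, geo, coef) {
  nt <- nrow(mesh$tri)
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  fac <- coef * 2 * pi * geo$r_cent * geo$area
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    ii[[k]] <- mesh$tri[, a]; jj[[k]] <- mesh$tri[, b]
    xx[[k]] <- fac * (geo$b[, a] * geo$b[, b] + geo$c[, a] * geo$c[, b])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = rep(nrow(mesh$nodes), 2))
}

# advection: C^e_ab = coef_e * (vr b_b + vz c_b) * 2*pi * int N_a r dA
assemble_advection <- function(mesh, geo, coef, vr, vz) {
  rq <- .quad_r(geo)
  nt <- nrow(mesh$tri)
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) {
    wa <- numeric(nt)
    for (q in 1:3) wa <- wa + .midpt_N[q, a] * rq[, q]
    inta <- 2 * pi * (geo$area / 3) * wa
    for (b in 1:3) {
      k <- k + 1L
      ii[[k]] <- mesh$tri[, a]; jj[[k]] <- mesh$tri[, b]
      xx[[k]] <- coef * inta * (vr * geo$b[, b] + vz * geo$c[, b])
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = rep(nrow(mesh$nodes), 2))
}

# load vector: F^e_a = coef_e * 2*pi * sum_q (A/3) N_a(q) r_q
assemble_load <- function(mesh, geo, coef) {
  rq <- .quad_r(geo)
  F <- numeric(nrow(mesh$nodes))
  for (a in 1:3) {
    w <- numeric(nrow(mesh$tri))
    for (q in 1:3) w <- w + .midpt_N[q, a] * rq[, q]
    F <- F + as.vector(tapply_add(mesh$tri[, a],
                                  coef * 2 * pi * (geo$area / 3) * w,
                                  nrow(mesh$nodes)))
  }
  F
}

tapply_add <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# effective volumetric heat capacity / conductivity per element
heat_coefficients <- function(mesh, material) {
  phi <- material$porosity
  rc_sample <- phi * material$rho_fluid * material$C_fluid +
    (1 - phi) * material$rho_solid * material$C_solid
  k_sample <- phi * material$K_fluid + (1 - phi) * material$K_solid
  rc_medium <- material$rho_fluid * material$C_fluid
  k_medium <- material$K_fluid
  is_sample <- mesh$domain == "sample"
  list(rhoC = ifelse(is_sample, rc_sample, rc_medium),
       K = ifelse(is_sample, k_sample, k_medium),
       rhoC_sample = rc_sample)
}

#' Transient conjugate heat transfer in the culture well
#'
#' Solves the axisymmetric heat equation
#' `(rho C)_eff dT/dt + rho_f C_f v . grad T = div(K_eff grad T) + Q`
#' with P1 elements and backward-Euler time stepping. In the sample
#' subdomain the effective properties are porosity-weighted mixtures of the
#' solid and fluid phases and the volumetric source `source_Q` is active;
#' the culture medium is a conductive, non-flowing water domain with no
#' source. The optional `advection` field (cycle-averaged Darcy velocity
#' per element from [solve_poroviscoelastic()]) adds convective transport
#' inside the sample.
#'
#' Boundary conditions: `isothermal` fixes all outer well boundaries (wall,
#' base, top) at the wall temperature; `adiabatic` imposes zero flux
#' everywhere. The axis is always a symmetry (zero-flux) boundary.
#'
#' @param mesh A `"ct_mesh"` from [build_mesh()].
#' @param material A [material_properties()].
#' @param bc A [thermal_bc()].
#' @param source_Q Volumetric heat source in the sample, W/m^3.
#' @param advection Optional list with per-element `vr`, `vz` Darcy
#'   velocities, m/s (as in the `v_f` field of a poro-viscoelastic result).
#' @param duration Simulated time, s, `> 0`.
#' @param dt Time step, s, `> 0`.
#' @param T0 Initial temperature, degC (uniform).
#' @param n_snapshots Number of stored field snapshots (default 6).
#' @param source_domain `"sample"` (default) or `"all"`.
#' @param dirichlet_tags Optional override of the boundary tags held at the
#'   wall temperature in isothermal mode (e.g. `c("base", "piston")` to
#'   leave the lateral face insulated in a slab benchmark).
#' @return A `"heat_result"`: times, running summaries (`max_medium_dT`,
#'   `max_sample_T`), history of the medium maximum temperature, final
#'   field `T_final`, snapshots, and the energy `ledger` (source input,
#'   boundary outflux, stored change, relative closure error).
#' @export
solve_heat <- function(mesh, material, bc, source_Q = 0, advection = NULL,
                       duration, dt, T0, n_snapshots = 6,
                       source_domain = c("sample", "all"),
                       dirichlet_tags = NULL) {
  stopifnot(inherits(mesh, "ct_mesh"), inherits(material, "material_properties"),
            inherits(bc, "thermal_bc"))
  source_domain <- match.arg(source_domain)
  stop_if_not_scalar(duration, "duration", positive = TRUE)
  stop_if_not_scalar(dt, "dt", positive = TRUE)
  stop_if_not_scalar(T0, "T0")

  geo <- tri_geometry(mesh)
  hc <- heat_coefficients(mesh, material)
  nn <- nrow(mesh$nodes)
  is_sample_el <- mesh$domain == "sample"

  M <- assemble_mass(mesh, geo, hc$rhoC)
  A <- assemble_stiffness(mesh, geo, hc$K)
  q_el <- if (source_domain == "all") rep(source_Q, nrow(mesh$tri)) else
    ifelse(is_sample_el, source_Q, 0)
  F <- assemble_load(mesh, geo, q_el)

  C <- NULL
  if (!is.null(advection)) {
    vr <- advection$vr; vz <- advection$vz
    if (length(vr) != nrow(mesh$tri) || length(vz) != nrow(mesh$tri)) {
      stop("'advection' must give per-element vr, vz", call. = FALSE)
    }
    coef_adv <- ifelse(is_sample_el, material$rho_fluid * material$C_fluid, 0)
    speed <- sqrt(vr^2 + vz^2)
    h_el <- sqrt(2 * geo$area)
    pe <- material$rho_fluid * material$C_fluid * speed * h_el / (2 * hc$K)
    if (any(pe > 2)) {
      warning(sprintf("advection under-resolved: max element Peclet = %.2g", max(pe)))
    }
    C <- assemble_advection(mesh, geo, coef_adv, vr, vz)
  }

  dir_nodes <- integer(0)
  dir_value <- NULL
  if (bc$kind == "isothermal") {
    tags <- if (is.null(dirichlet_tags)) {
      intersect(c("wall", "base", "top", "side", "piston"),
                unique(mesh$edges$tag))
    } else dirichlet_tags
    dir_nodes <- boundary_nodes(mesh, tags)
    dir_value <- rep(bc$wall_temperature, length(dir_nodes))
  }

  Araw <- A
  if (!is.null(C)) Araw <- Araw + C
  LHS <- M / dt + Araw
  if (length(dir_nodes)) {
    # row replacement for Dirichlet nodes
    LHS[dir_nodes, ] <- 0
    LHS[cbind(dir_nodes, dir_nodes)] <- 1
  }
  fac <- Matrix::lu(LHS)

  nsteps <- max(1L, ceiling(duration / dt))
  snap_at <- unique(pmax(1L, round(seq(1L, nsteps, length.out = max(1, n_snapshots)))))
  Tn <- rep(T0, nn)
  med_nodes <- setdiff(sort(unique(as.vector(mesh$tri[!is_sample_el, ]))), integer(0))
  samp_nodes <- sort(unique(as.vector(mesh$tri[is_sample_el, ])))

  max_medium_dT <- 0
  max_sample_T <- T0
  med_max_hist <- numeric(nsteps)
  times <- numeric(nsteps)
  snapshots <- list()
  flux_out_int <- 0
  source_int <- 0
  T0vec <- rep(T0, nn)

  for (n in seq_len(nsteps)) {
    rhs <- as.numeric(M %*% Tn) / dt + F
    if (length(dir_nodes)) rhs[dir_nodes] <- dir_value
    Tnp <- as.numeric(Matrix::solve(fac, rhs))
    if (any(!is.finite(Tnp))) stop("heat solver produced non-finite temperatures")
    # consistent boundary flux from the unconstrained residual at Dirichlet rows
    if (length(dir_nodes)) {
      # unconstrained residual at Dirichlet rows = boundary influx; negate
      res <- as.numeric(M %*% (Tnp - Tn)) / dt + as.numeric(Araw %*% Tnp) - F
      flux_out_int <- flux_out_int - dt * sum(res[dir_nodes])
    }
    source_int <- source_int + dt * sum(F)
    Tn <- Tnp
    times[n] <- n * dt
    if (length(med_nodes)) {
      dTmed <- max(abs(Tn[med_nodes] - T0))
      med_max_hist[n] <- max(Tn[med_nodes])
      max_medium_dT <- max(max_medium_dT, dTmed)
    }
    max_sample_T <- max(max_sample_T, max(Tn[samp_nodes]))
    if (n %in% snap_at) {
      snapshots[[length(snapshots) + 1L]] <- list(time = n * dt, T = Tn)
    }
  }

  stored <- sum(as.numeric(M %*% (Tn - T0vec)))
  closure <- if (source_int != 0) {
    abs(source_int - stored - flux_out_int) / abs(source_int)
  } else if (stored != 0 || flux_out_int != 0) {
    abs(stored + flux_out_int) / max(abs(stored), abs(flux_out_int))
  } else 0

  structure(list(
    times = times, T_final = Tn,
    max_medium_dT = max_medium_dT, max_sample_T = max_sample_T,
    medium_max_history = med_max_hist,
    snapshots = snapshots,
    ledger = list(source_in_J = source_int, boundary_out_J = flux_out_int,
                  stored_J = stored, closure_rel = closure),
    mesh = mesh, T0 = T0, bc = bc
  ), class = "heat_result")
}

#' @export
print.heat_result <- function(x, ...) {
  cat(sprintf("Heat transfer run (%s): %g s, max medium dT = %.4g degC, max sample T = %.4g degC\n",
              x$bc$kind, x$times[length(x$times)], x$max_medium_dT, x$max_sample_T))
  cat(sprintf("  energy ledger: in %.4g J, out %.4g J, stored %.4g J (closure %.2g)\n",
              x$ledger$source_in_J, x$ledger$boundary_out_J, x$ledger$stored_J,
              x$ledger$closure_rel))
  invisible(x)
}
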