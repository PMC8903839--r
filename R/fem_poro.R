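# --- axisymmetric Biot poro-viscoelasticity --------------------------------
# Quadrature for the u-p problem: 3 interior Gauss points (degree 2), which
# keep r > 0 on elements touching the symmetry axis (the hoop strain term
# N_a / r is singular at r = 0).
.int_N <- matrix(c(2/3, 1/6, 1/6,
                   1/6, 2/3, 1/6,
                   1/6, 1/6, 2/3), nrow = 3, byrow = TRUE)

# Voigt order: (eps_rr, eps_zz, eps_theta, gamma_rz)
.voigt_m <- c(1, 1, 1, 0)
.voigt_Pdev <- matrix(c( 2/3, -1/3, -1/3, 0,
                        -1/3,  2/3, -1/3, 0,
                        -1/3, -1/3,  2/3, 0,
                         0,    0,    0,   0.5), nrow = 4, byrow = TRUE)

# Build the global strain-displacement operator: sparse (4*nqp x 2*nn)
# matrix mapping nodal (u_r, u_z) to Voigt strain at each quadrature point,
# plus quadrature weights w_q = (A/3) * 2*pi*r_q and the qp shape values.
build_strain_operator <- function(mesh, geo) {
  nt <- nrow(mesh$tri)
  nqp <- 3L * nt
  rq <- cbind(.int_N[1, 1] * geo$p1[, 1] + .int_N[1, 2] * geo$p2[, 1] + .int_N[1, 3] * geo$p3[, 1],
              .int_N[2, 1] * geo$p1[, 1] + .int_N[2, 2] * geo$p2[, 1] + .int_N[2, 3] * geo$p3[, 1],
              .int_N[3, 1] * geo$p1[, 1] + .int_N[3, 2] * geo$p2[, 1] + .int_N[3, 3] * geo$p3[, 1])
  ii <- jj <- xx <- list(); k <- 0L
  add <- function(i, j, x) {
    k <<- k + 1L; ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x
  }
  el <- seq_len(nt)
  for (q in 1:3) {
    qrow0 <- (el - 1L) * 12L + (q - 1L) * 4L   # start of this qp's 4 rows - 1
    for (a in 1:3) {
      na <- mesh$tri[, a]
      dr <- 2L * na - 1L; dz <- 2L * na
      # eps_rr = b_a u_r
      add(qrow0 + 1L, dr, geo$b[, a])
      # eps_zz = c_a u_z
      add(qrow0 + 2L, dz, geo$c[, a])
      # eps_theta = N_a/r u_r
      add(qrow0 + 3L, dr, .int_N[q, a] / rq[, q])
      # gamma_rz = c_a u_r + b_a u_z
      add(qrow0 + 4L, dr, geo$c[, a])
      add(qrow0 + 4L, dz, geo$b[, a])
    }
  }
  Bop <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                              dims = c(4L * nqp, 2L * nrow(mesh$nodes)))
  # qp-major ordering: (el1 q1, el1 q2, el1 q3, el2 q1, ...)
  w_qp <- as.vector(t(2 * pi * rq * (geo$area / 3)))
  list(B = Bop, w = w_qp, rq = rq, nqp = nqp)
}

# shape-value matrix at the interior qps: (nqp x nn)
build_qp_shapes <- function(mesh) {
  nt <- nrow(mesh$tri)
  el <- seq_len(nt)
  ii <- jj <- xx <- list(); k <- 0L
  for (q in 1:3) for (a in 1:3) {
    k <- k + 1L
    ii[[k]] <- (el - 1L) * 3L + q
    jj[[k]] <- mesh$tri[, a]
    xx[[k]] <- rep(.int_N[q, a], nt)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(3L * nt, nrow(mesh$nodes)))
}

# nodal force from a uniform normal traction sigma (Pa, acting in -z) on a
# set of horizontal boundary edges
traction_load_z <- function(mesh, tag, sigma) {
  e <- mesh$edges[mesh$edges$tag == tag, , drop = FALSE]
  f <- numeric(2L * nrow(mesh$nodes))
  for (i in seq_len(nrow(e))) {
    r1 <- mesh$nodes[e$n1[i], 1]; r2 <- mesh$nodes[e$n2[i], 1]
    L <- abs(r2 - r1)
    f[2L * e$n1[i]] <- f[2L * e$n1[i]] - sigma * 2 * pi * L * (2 * r1 + r2) / 6
    f[2L * e$n2[i]] <- f[2L * e$n2[i]] - sigma * 2 * pi * L * (r1 + 2 * r2) / 6
  }
  f
}

# strain waveform of a displacement-controlled protocol
protocol_strain <- function(loading, t, waveform = "raised_cosine") {
  ph <- 2 * pi * loading$frequency * t
  switch(waveform,
         raised_cosine = loading$pre_strain + (loading$amplitude / 2) * (1 - cos(ph)),
         sin = loading$pre_strain + loading$amplitude * sin(ph),
         stop("unknown waveform"))
}

#' Quasi-static axisymmetric poro-viscoelastic solve
#'
#' Solves Biot consolidation with a Prony deviatoric viscoelastic solid on
#' the sample mesh: momentum balance `div(sigma_eff - alpha p I) = 0` with
#' `sigma_eff = K_b tr(eps) I + 2 G(t) * dev(eps)` (hereditary, handled by
#' exact-exponential internal variables per quadrature point), and mass
#' balance `alpha d(div u)/dt + div v_f = 0`, `v_f = -(k/mu_f) grad p`.
#' Equal-order P1 displacement/pressure elements with Brezzi-Pitkaranta
#' pressure stabilization; backward-Euler time stepping; direct sparse
#' factorization reused across steps.
#'
#' Two configurations:
#' \describe{
#'   \item{`mode = "piston"`}{the culture-well sample: symmetry axis
#'     (`u_r = 0`), frictionless base (`u_z = 0`), rigid impermeable piston
#'     prescribing the axial strain on the top face, lateral surface
#'     traction-free and drained (`p = 0`).}
#'   \item{`mode = "column"`}{laterally confined column (`u_r = 0`
#'     everywhere): step traction `sigma0` (Pa) or prescribed displacement
#'     on the top face, drained at the top, impermeable elsewhere — the
#'     classical consolidation configuration.}
#' }
#'
#' @param mesh A sample-only `"ct_mesh"` (from
#'   [build_mesh()]`(include_medium = FALSE)` or [sample_submesh()]).
#' @param material A [material_properties()].
#' @param loading A [loading_protocol()] (ignored when `piston_strain` or a
#'   traction load is given).
#' @param n_cycles Number of cycles to simulate in cyclic mode (default 5,
#'   enough to reach the periodic regime of the fast branches).
#' @param dt Time step, s; default `1/(100 f)` in cyclic mode. Must satisfy
#'   `dt <= 1/(50 f)` for cyclic loading.
#' @param waveform `"raised_cosine"` (compression-only, default) or
#'   `"sin"` (centered).
#' @param mode `"piston"` or `"column"`.
#' @param load `"displacement"` or `"traction"` (column mode).
#' @param sigma0 Traction magnitude, Pa (compressive, for
#'   `load = "traction"`).
#' @param piston_strain Optional `function(t)` returning the prescribed
#'   axial strain (overrides `loading`).
#' @param duration Total simulated time, s (required when not cyclic).
#' @param viscoelastic Use the Prony branches? `FALSE` freezes the solid at
#'   its long-term (drained equilibrium) stiffness.
#' @param store_history Keep the full pressure history matrix? (column
#'   benchmarks)
#' @return A `"poro_result"` with final fields (`u`, `p`), per-element
#'   cycle-averaged Darcy velocity (`v_f$vr`, `v_f$vz`, `v_f$speed`),
#'   per-element cycle-averaged dissipation density (W/m^3, viscoelastic +
#'   Darcy), the piston reaction-force history (N), the fluid mass-balance
#'   ledger, and solver metadata.
#' @export
solve_poroviscoelastic <- function(mesh, material, loading = loading_protocol(),
                                   n_cycles = 5, dt = NULL,
                                   waveform = c("raised_cosine", "sin"),
                                   mode = c("piston", "column"),
                                   load = c("displacement", "traction"),
                                   sigma0 = NULL, piston_strain = NULL,
                                   duration = NULL, viscoelastic = TRUE,
                                   store_history = FALSE) {
  stopifnot(inherits(mesh, "ct_mesh"), inherits(material, "material_properties"))
  if (mesh$include_medium) {
    stop("poro-viscoelastic solve expects the sample-only mesh; use sample_submesh()",
         call. = FALSE)
  }
  waveform <- match.arg(waveform)
  mode <- match.arg(mode)
  load <- match.arg(load)

  cyclic <- is.null(piston_strain) && load == "displacement"
  f <- if (!is.null(loading)) loading$frequency else NA_real_
  if (cyclic) {
    if (is.null(dt)) dt <- 1 / (100 * f)
    if (dt > 1 / (50 * f) + 1e-12) {
      stop(sprintf("dt = %g s too coarse: need dt <= 1/(50 f) = %g s", dt, 1 / (50 * f)),
           call. = FALSE)
    }
    duration <- n_cycles / f
  } else {
    if (is.null(duration)) stop("'duration' required for non-cyclic loading", call. = FALSE)
    if (is.null(dt)) stop("'dt' required for non-cyclic loading", call. = FALSE)
  }
  nsteps <- max(1L, round(duration / dt))

  geo <- tri_geometry(mesh)
  nn <- nrow(mesh$nodes)
  nt <- nrow(mesh$tri)
  nu_dof <- 2L * nn
  so <- build_strain_operator(mesh, geo)
  Nqp <- build_qp_shapes(mesh)
  nqp <- 3L * nt
  w4 <- rep(so$w, each = 4L)

  # material operators
  pr <- material$prony
  E <- material$E_eq; nu_p <- material$nu
  Kb <- E / (3 * (1 - 2 * nu_p))
  g_inf <- pr$g_inf
  nb <- if (viscoelastic) length(pr$G) else 0L
  ef <- gf <- numeric(0)
  if (nb) {
    ef <- exp(-dt / pr$tau)
    gf <- pr$G * (pr$tau / dt) * (1 - ef)
  }
  Ghat <- g_inf + if (nb) sum(gf) else 0
  G0 <- g_inf + if (nb) sum(pr$G) else 0
  Dhat <- Kb * (.voigt_m %o% .voigt_m) + 2 * Ghat * .voigt_Pdev

  Dbig <- Matrix::kronecker(Matrix::Diagonal(nqp), Matrix::Matrix(Dhat, sparse = TRUE))
  Wd <- Matrix::Diagonal(x = w4)
  Kuu <- Matrix::t(so$B) %*% Wd %*% Dbig %*% so$B

  # coupling alpha * int N_a div(u) dV
  mrow <- Matrix::kronecker(Matrix::Diagonal(nqp),
                            Matrix::Matrix(matrix(.voigt_m, nrow = 1), sparse = TRUE))
  div_op <- mrow %*% so$B                       # nqp x nu_dof
  Qc <- material$biot_alpha * Matrix::t(Nqp) %*% Matrix::Diagonal(x = so$w) %*% div_op

  Hp <- assemble_stiffness(mesh, geo, rep(material$permeability / material$mu_f, nt))
  beta_e <- (2 * geo$area) / (4 * (Kb + 4 * G0 / 3))   # h_e^2 / (4 M)
  Sp <- assemble_stiffness(mesh, geo, beta_e)

  # boundary conditions
  axis_n <- boundary_nodes(mesh, "axis")
  base_n <- boundary_nodes(mesh, "base")
  pist_n <- boundary_nodes(mesh, c("piston", "top"))
  side_n <- boundary_nodes(mesh, c("side", "wall"))
  thick <- mesh$geometry$sample_thickness

  fix_u <- integer(0)
  if (mode == "piston") {
    fix_u <- c(2L * axis_n - 1L, 2L * base_n)
    drained <- side_n
  } else {
    fix_u <- c(seq(1L, nu_dof, by = 2L), 2L * base_n)   # all u_r, base u_z
    drained <- pist_n
  }
  presc_dof <- integer(0)
  if (load == "displacement") presc_dof <- 2L * pist_n
  fix_u <- setdiff(unique(fix_u), presc_dof)

  strain_fun <- if (!is.null(piston_strain)) {
    piston_strain
  } else if (load == "displacement") {
    function(t) protocol_strain(loading, t, waveform)
  } else NULL

  f_ext <- numeric(nu_dof)
  if (load == "traction") {
    if (is.null(sigma0)) stop("'sigma0' required for traction loading", call. = FALSE)
    f_ext <- traction_load_z(mesh, if (mesh$include_medium) "top" else "piston", sigma0)
  }

  ndof <- nu_dof + nn
  A_raw <- rbind(cbind(Kuu, -Matrix::t(Qc)),
                 cbind(Qc, dt * Hp + Sp))
  con_dofs <- c(fix_u, presc_dof, nu_dof + drained)
  A_con <- A_raw
  A_con[con_dofs, ] <- 0
  A_con[cbind(con_dofs, con_dofs)] <- 1
  # symmetric diagonal equilibration: the stiffness and permeability blocks
  # differ by ~13 orders of magnitude, enough to trip the LU conditioning check
  At <- as(abs(A_con), "TsparseMatrix")
  rmax <- numeric(ndof)
  agg <- tapply(At@x, At@i, max)
  rmax[as.integer(names(agg)) + 1L] <- agg
  dscale <- 1 / sqrt(pmax(rmax, 1e-300))
  Dsc <- Matrix::Diagonal(x = dscale)
  fac <- Matrix::lu(Dsc %*% A_con %*% Dsc)
  solve_scaled <- function(rhs) dscale * as.numeric(Matrix::solve(fac, dscale * rhs))

  # state
  u <- numeric(nu_dof); p <- numeric(nn)
  edev <- matrix(0, nqp, 4L)
  hbr <- if (nb) lapply(seq_len(nb), function(i) matrix(0, nqp, 4L)) else list()
  sum_gf <- if (nb) sum(gf) else 0

  last_cycle_start <- if (cyclic) nsteps - round(1 / (f * dt)) + 1L else 1L
  vr_acc <- vz_acc <- sp_acc <- numeric(nt)
  diss_acc <- numeric(nt)        # J/m^3 accumulated over averaging window
  n_avg <- 0L
  reaction <- numeric(nsteps)
  times <- numeric(nsteps)
  p_hist <- if (store_history) matrix(0, nn, nsteps) else NULL
  vol_strain_int <- 0; outflux_int <- 0

  # per-element qp index blocks for dissipation bookkeeping
  qp_of_el <- matrix(seq_len(nqp), nrow = 3L)

  sig_prev <- matrix(0, nqp, 4L)
  for (n in seq_len(nsteps)) {
    t_np <- n * dt
    # history stress at qps
    if (nb) {
      s_hist <- -2 * sum_gf * edev
      for (i in seq_len(nb)) s_hist <- s_hist + ef[i] * hbr[[i]]
    } else {
      s_hist <- matrix(0, nqp, 4L)
    }
    f_hist <- -as.numeric(Matrix::t(so$B) %*% (w4 * as.vector(t(s_hist))))
    rhs <- c(f_ext + f_hist,
             as.numeric(Qc %*% u) + as.numeric(Sp %*% p))
    rhs_raw <- rhs
    if (length(fix_u)) rhs[fix_u] <- 0
    if (length(presc_dof)) rhs[presc_dof] <- -strain_fun(t_np) * thick
    if (length(drained)) rhs[nu_dof + drained] <- 0
    x <- solve_scaled(rhs)
    if (any(!is.finite(x))) {
      stop(sprintf("poro-viscoelastic solver diverged at step %d (t = %g s)", n, t_np))
    }
    u_new <- x[seq_len(nu_dof)]; p_new <- x[nu_dof + seq_len(nn)]

    # strain + internal-variable update
    e_vec <- as.numeric(so$B %*% u_new)
    e_new <- matrix(e_vec, ncol = 4L, byrow = TRUE)
    edev_new <- e_new %*% t(.voigt_Pdev)
    if (nb) {
      dedev <- edev_new - edev
      for (i in seq_len(nb)) hbr[[i]] <- ef[i] * hbr[[i]] + 2 * gf[i] * dedev
    }
    # total solid stress at qps (effective stress, Voigt)
    sig <- e_new %*% t(Kb * (.voigt_m %o% .voigt_m) + 2 * g_inf * .voigt_Pdev)
    if (nb) for (i in seq_len(nb)) sig <- sig + hbr[[i]]

    # reaction force on the prescribed/loaded face (momentum residual)
    res <- as.numeric(A_raw %*% x - rhs_raw)
    if (length(presc_dof)) reaction[n] <- sum(res[presc_dof])

    # fluid mass ledger (mass rows are dt-scaled): the summed mass equations
    # state that the volumetric-strain increment equals the drained-boundary
    # residual; accumulated mismatch must vanish relative to the traffic.
    vol_step <- sum(Qc %*% (u_new - u))          # alpha * d int(div u) this step
    outflux_step <- if (length(drained)) sum(res[nu_dof + drained]) else 0
    vol_strain_int <- vol_strain_int + abs(vol_step)
    outflux_int <- outflux_int + abs(outflux_step)
    if (n == 1L) fluid_closure_num <- 0
    fluid_closure_num <- fluid_closure_num + (vol_step - outflux_step)

    # averaging window accumulators
    if (n >= last_cycle_start) {
      gp <- -(material$permeability / material$mu_f)
      # element pressure gradients
      pr1 <- p_new[mesh$tri[, 1]]; pr2 <- p_new[mesh$tri[, 2]]; pr3 <- p_new[mesh$tri[, 3]]
      vr_e <- gp * (geo$b[, 1] * pr1 + geo$b[, 2] * pr2 + geo$b[, 3] * pr3)
      vz_e <- gp * (geo$c[, 1] * pr1 + geo$c[, 2] * pr2 + geo$c[, 3] * pr3)
      vr_acc <- vr_acc + vr_e; vz_acc <- vz_acc + vz_e
      sp_acc <- sp_acc + sqrt(vr_e^2 + vz_e^2)
      # solid work increment per element (qp-mean), plus Darcy dissipation
      if (n > last_cycle_start) {
        dW_qp <- rowSums(0.5 * (sig + sig_prev) * (e_new - e_prev))
        dW_el <- (dW_qp[qp_of_el[1, ]] + dW_qp[qp_of_el[2, ]] + dW_qp[qp_of_el[3, ]]) / 3
        darcy_el <- (material$mu_f / material$permeability) * (vr_e^2 + vz_e^2) * dt
        diss_acc <- diss_acc + dW_el + darcy_el
      }
      n_avg <- n_avg + 1L
      e_prev <- e_new
    }
    sig_prev <- sig
    if (!exists("e_prev", inherits = FALSE)) e_prev <- e_new
    u <- u_new; p <- p_new
    edev <- edev_new
    times[n] <- t_np
    if (store_history) p_hist[, n] <- p_new
  }

  window_T <- n_avg * dt
  fluid_scale <- max(vol_strain_int, outflux_int, 1e-300)
  structure(list(
    times = times,
    u = matrix(u, ncol = 2L, byrow = TRUE),
    p = p,
    v_f = list(vr = vr_acc / max(1L, n_avg), vz = vz_acc / max(1L, n_avg),
               speed = sp_acc / max(1L, n_avg)),
    dissipation_Wm3 = if (window_T > 0) diss_acc / window_T else diss_acc,
    reaction_N = reaction,
    p_history = p_hist,
    fluid_ledger = list(closure_abs = fluid_closure_num,
                        rel = abs(fluid_closure_num) / fluid_scale),
    mesh = mesh, dt = dt, mode = mode, cyclic = cyclic,
    strain_fun = strain_fun
  ), class = "poro_result")
}

#' @export
print.poro_result <- function(x, ...) {
  cat(sprintf("Poro-viscoelastic solve (%s): %d steps, dt = %g s\n",
              x$mode, length(x$times), x$dt))
  cat(sprintf("  max |p| = %.4g Pa, mean cycle-avg |v_f| = %.3g m/s, mean dissipation = %.4g W/m^3\n",
              max(abs(x$p)), mean(x$v_f$speed), mean(x$dissipation_Wm3)))
  invisible(x)
}
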