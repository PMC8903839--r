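#' Prony-series relaxation modulus
#'
#' Sum-of-exponentials representation of a linear viscoelastic relaxation
#' modulus, `G(t) = g_inf + sum_i G_i exp(-t / tau_i)`. Moduli are in Pa
#' throughout the package (SI); relaxation times in seconds.
#'
#' @param g_inf Long-term (equilibrium) modulus, Pa, `>= 0`.
#' @param G Branch moduli `G_i`, Pa, all `> 0` (may be empty for a purely
#'   elastic material).
#' @param tau Branch relaxation times `tau_i`, s, all `> 0`, strictly
#'   increasing; same length as `G`.
#' @return An object of class `"prony_series"`.
#' @examples
#' pr <- prony_series(g_inf = 2e5, G = c(2e5, 5.8e4, 2.15e5),
#'                    tau = c(0.42, 5.82, 1600))
#' relaxation_modulus(pr, 0)      # instantaneous modulus
#' @export
prony_series <- function(g_inf, G = numeric(0), tau = numeric(0)) {
  stop_if_not_scalar(g_inf, "g_inf", nonneg = TRUE)
  if (length(G) != length(tau)) stop("'G' and 'tau' must match in length", call. = FALSE)
  if (length(G)) {
    if (any(G <= 0)) stop("all branch moduli G_i must be > 0", call. = FALSE)
    if (any(tau <= 0)) stop("all relaxation times tau_i must be > 0", call. = FALSE)
    if (length(tau) > 1 && any(diff(tau) <= 0)) {
      stop("'tau' must be strictly increasing", call. = FALSE)
    }
  }
  structure(list(g_inf = g_inf, G = as.numeric(G), tau = as.numeric(tau)),
            class = "prony_series")
}

#' @export
print.prony_series <- function(x, ...) {
  cat(sprintf("Prony series: g_inf = %.4g kPa, %d branch(es)\n",
              x$g_inf / 1e3, length(x$G)))
  if (length(x$G)) {
    print(data.frame(G_kPa = x$G / 1e3, tau_s = x$tau))
  }
  invisible(x)
}

#' Relaxation modulus G(t)
#'
#' @param prony A [prony_series()].
#' @param t Times, s, `>= 0` (vectorized).
#' @return Modulus values, Pa; monotone non-increasing in `t`.
#' @export
relaxation_modulus <- function(prony, t) {
  stopifnot(inherits(prony, "prony_series"))
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  out <- rep(prony$g_inf, length(t))
  for (i in seq_along(prony$G)) {
    out <- out + prony$G[i] * exp(-t / prony$tau[i])
  }
  out
}

#' Storage and loss moduli of a Prony material
#'
#' Standard transform of the relaxation kernel to the frequency domain:
#' `storage = g_inf + sum G_i w^2 tau_i^2 / (1 + w^2 tau_i^2)`,
#' `loss = sum G_i w tau_i / (1 + w^2 tau_i^2)`.
#'
#' @param prony A [prony_series()].
#' @param omega Angular frequency rad/s, `>= 0` (vectorized).
#' @return A list with numeric vectors `storage` and `loss` (Pa).
#' @export
dynamic_moduli <- function(prony, omega) {
  stopifnot(inherits(prony, "prony_series"))
  if (any(omega < 0)) stop("'omega' must be >= 0", call. = FALSE)
  storage <- rep(prony$g_inf, length(omega))
  loss <- numeric(length(omega))
  for (i in seq_along(prony$G)) {
    wt <- omega * prony$tau[i]
    storage <- storage + prony$G[i] * wt^2 / (1 + wt^2)
    loss <- loss + prony$G[i] * wt / (1 + wt^2)
  }
  list(storage = storage, loss = loss)
}

#' Stress response to an arbitrary strain history
#'
#' Hereditary-integral viscoelastic stress for a uniformly sampled strain
#' history, computed with the exact-exponential recursive-convolution
#' scheme (one internal variable per Prony branch, O(N) in samples). The
#' material is assumed at rest before the first sample: a non-zero first
#' strain value is treated as an instantaneous step, loading every branch
#' with its glassy contribution.
#'
#' @param prony A [prony_series()].
#' @param strain_history A [timeseries()] of dimensionless strain sampled at
#'   uniform `dt`.
#' @param dt Optional expected sampling interval, s; checked against the
#'   series if given.
#' @return A [timeseries()] of stress in Pa on the same time grid.
#' @export
stress_response <- function(prony, strain_history, dt = NULL) {
  stopifnot(inherits(prony, "prony_series"),
            inherits(strain_history, "ct_timeseries"))
  t <- strain_history$t_s
  eps <- strain_history$value
  n <- length(t)
  if (n < 1) stop("empty strain history", call. = FALSE)
  if (n > 1) {
    steps <- diff(t)
    h <- steps[1]
    if (any(abs(steps - h) > 1e-8 * max(h, 1e-30))) {
      stop("strain history must be uniformly sampled", call. = FALSE)
    }
    if (!is.null(dt) && abs(dt - h) > 1e-8 * h) {
      stop(sprintf("sampling interval %.6g s does not match requested dt %.6g s",
                   h, dt), call. = FALSE)
    }
  } else h <- if (is.null(dt)) 1 else dt

  nb <- length(prony$G)
  sig <- prony$g_inf * eps
  if (nb) {
    # branch states after the initial step from rest to eps[1]
    hvar <- prony$G * eps[1]
    sig[1] <- sig[1] + sum(hvar)
    if (n > 1) {
      ef <- exp(-h / prony$tau)
      gf <- prony$G * (prony$tau / h) * (1 - ef)   # exact for linear strain
      for (k in 2:n) {
        d <- eps[k] - eps[k - 1]
        hvar <- ef * hvar + gf * d
        sig[k] <- sig[k] + sum(hvar)
      }
    }
  }
  timeseries(t, sig, "Pa")
}

#' Closed-form hysteresis area of a steady sinusoidal cycle
#'
#' For strain `eps0 sin(w t)` in the steady state of a linear viscoelastic
#' material, the energy dissipated per cycle per unit volume is
#' `pi * eps0^2 * loss(w)` (J/m^3). Serves as the analytic oracle for
#' loop-integration measurements.
#'
#' @param prony A [prony_series()].
#' @param eps0 Strain amplitude, `> 0`.
#' @param omega Angular frequency, rad/s.
#' @return Dissipated energy density per cycle, J/m^3.
#' @export
hysteresis_closed_form <- function(prony, eps0, omega) {
  stopifnot(inherits(prony, "prony_series"))
  stop_if_not_scalar(eps0, "eps0", positive = TRUE)
  stop_if_not_scalar(omega, "omega", nonneg = TRUE)
  pi * eps0^2 * dynamic_moduli(prony, omega)$loss
}

#' Poro-viscoelastic and thermal material parameter set
#'
#' Container for every parameter of the coupled hydrogel model: drained
#' equilibrium modulus and Poisson ratio, porosity, permeability,
#' Biot-Willis coefficient, volumetric dissipative power, solid/fluid heat
#' capacities and conductivities, the Prony shear branches, and fluid
#' viscosity and phase densities. The Prony branch moduli are interpreted
#' as shear-relaxation branches acting on the deviatoric response, with the
#' volumetric response elastic from `(E_eq, nu)`; the long-term shear
#' modulus is `g_inf = E_eq / (2 (1 + nu))` so the drained equilibrium
#' response matches `E_eq`.
#'
#' @param E_eq Drained equilibrium Young's modulus, Pa.
#' @param nu Drained Poisson ratio, `0 <= nu < 0.5`.
#' @param porosity Fluid volume fraction `phi`, in (0, 1).
#' @param permeability Intrinsic permeability `k`, m^2, `> 0`.
#' @param biot_alpha Biot-Willis coefficient, in (0, 1].
#' @param Q_dis Volumetric dissipative heat source under the reference
#'   cyclic loading, W/m^3, `>= 0`.
#' @param C_solid,C_fluid Specific heat capacities, J/(kg K), `> 0`.
#' @param K_solid,K_fluid Thermal conductivities, W/(m K), `> 0`.
#' @param prony_G,prony_tau Shear Prony branch moduli (Pa) and times (s).
#' @param mu_f Pore fluid dynamic viscosity, Pa s (default water).
#' @param rho_solid,rho_fluid Phase densities, kg/m^3 (defaults: pHEMA
#'   polymer and water).
#' @return An object of class `"material_properties"`, with a
#'   [prony_series()] in `$prony` whose `g_inf` is the drained long-term
#'   shear modulus.
#' @seealso [table1_material()] for the packaged hydrogel preset.
#' @export
material_properties <- function(E_eq, nu, porosity, permeability,
                                biot_alpha = 1, Q_dis = 0,
                                C_solid, K_solid, C_fluid, K_fluid,
                                prony_G = numeric(0), prony_tau = numeric(0),
                                mu_f = 1.0e-3, rho_solid = 1150,
                                rho_fluid = 1000) {
  stop_if_not_scalar(E_eq, "E_eq", positive = TRUE)
  stop_if_not_scalar(nu, "nu", nonneg = TRUE)
  if (nu >= 0.5) stop("'nu' must be < 0.5", call. = FALSE)
  stop_if_not_scalar(porosity, "porosity", positive = TRUE)
  if (porosity >= 1) stop("'porosity' must be < 1", call. = FALSE)
  stop_if_not_scalar(permeability, "permeability", positive = TRUE)
  stop_if_not_scalar(biot_alpha, "biot_alpha", positive = TRUE)
  if (biot_alpha > 1) stop("'biot_alpha' must be <= 1", call. = FALSE)
  stop_if_not_scalar(Q_dis, "Q_dis", nonneg = TRUE)
  for (nm in c("C_solid", "K_solid", "C_fluid", "K_fluid", "mu_f",
               "rho_solid", "rho_fluid")) {
    stop_if_not_scalar(get(nm), nm, positive = TRUE)
  }
  g_inf <- E_eq / (2 * (1 + nu))
  structure(list(
    E_eq = E_eq, nu = nu, porosity = porosity, permeability = permeability,
    biot_alpha = biot_alpha, Q_dis = Q_dis,
    C_solid = C_solid, K_solid = K_solid,
    C_fluid = C_fluid, K_fluid = K_fluid,
    prony = prony_series(g_inf, prony_G, prony_tau),
    mu_f = mu_f, rho_solid = rho_solid, rho_fluid = rho_fluid
  ), class = "material_properties")
}

#' Dissipative hydrogel material preset
#'
#' The packaged parameter set of the cartilage-mimetic pHEMA hydrogel used
#' throughout the well heat-transfer scenarios: equilibrium modulus 500 kPa,
#' Poisson ratio 0.23, porosity 68 %, permeability 2.1e-14 m^2, Biot-Willis
#' coefficient 1, volumetric dissipative power 9000 W/m^3 (from the 1 Hz
#' hysteresis-loop area), pHEMA heat capacity 1308 J/(kg K) and conductivity
#' 0.25 W/(m K), water heat capacity 4200 J/(kg K) and conductivity
#' 0.6 W/(m K), and three shear Prony branches (200, 58, 215) kPa with
#' relaxation times (0.42, 5.82, 1600) s. Fluid viscosity and phase
#' densities are package defaults (water at 1e-3 Pa s and 1000 kg/m^3,
#' pHEMA at 1150 kg/m^3), and the storage coefficient is taken as zero
#' (incompressible constituents).
#'
#' @return A [material_properties()] object.
#' @examples
#' m <- table1_material()
#' relaxation_modulus(m$prony, 0) / 1e3   # instantaneous shear modulus, kPa
#' @export
table1_material <- function() {
  material_properties(
    E_eq = 500e3, nu = 0.23, porosity = 0.68, permeability = 2.1e-14,
    biot_alpha = 1, Q_dis = 9000,
    C_solid = 1308, K_solid = 0.25, C_fluid = 4200, K_fluid = 0.6,
    prony_G = c(200e3, 58e3, 215e3), prony_tau = c(0.42, 5.82, 1600)
  )
}

#' @export
print.material_properties <- function(x, ...) {
  cat("Poro-viscoelastic material:\n")
  cat(sprintf("  E_eq = %g kPa, nu = %g, porosity = %g, k = %g m^2, alpha = %g\n",
              x$E_eq / 1e3, x$nu, x$porosity, x$permeability, x$biot_alpha))
  cat(sprintf("  Q_dis = %g W/m^3; C_s = %g, C_f = %g J/(kg K); K_s = %g, K_f = %g W/(m K)\n",
              x$Q_dis, x$C_solid, x$C_fluid, x$K_solid, x$K_fluid))
  print(x$prony)
  invisible(x)
}

#' Load material properties from a plain-text config file
#'
#' Reads a `key = value` text file (one pair per line, `#` comments) with
#' keys matching the arguments of [material_properties()]; `prony_G` and
#' `prony_tau` take comma-separated lists. The special line
#' `preset = table1` loads [table1_material()] with any further keys
#' overriding the preset.
#'
#' @param path Path to the config file.
#' @return A [material_properties()] object.
#' @export
read_material_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
    kv[[trimws(parts[1])]] <- trimws(parts[2])
  }
  base <- NULL
  if (!is.null(kv$preset)) {
    if (kv$preset != "table1") stop("unknown material preset: ", kv$preset, call. = FALSE)
    base <- table1_material()
    kv$preset <- NULL
  }
  parse_num <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  args <- lapply(kv, parse_num)
  if (any(vapply(args, function(v) anyNA(v), logical(1)))) {
    stop("non-numeric value in material config", call. = FALSE)
  }
  if (!is.null(base)) {
    full <- list(E_eq = base$E_eq, nu = base$nu, porosity = base$porosity,
                 permeability = base$permeability, biot_alpha = base$biot_alpha,
                 Q_dis = base$Q_dis, C_solid = base$C_solid, K_solid = base$K_solid,
                 C_fluid = base$C_fluid, K_fluid = base$K_fluid,
                 prony_G = base$prony$G, prony_tau = base$prony$tau,
                 mu_f = base$mu_f, rho_solid = base$rho_solid,
                 rho_fluid = base$rho_fluid)
    full[names(args)] <- args
    args <- full
  }
  bad <- setdiff(names(args), names(formals(material_properties)))
  if (length(bad)) stop("unknown material config keys: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  do.call(material_properties, args)
}
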