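#' First-order-plus-dead-time thermal plant
#'
#' Lumped surrogate of the heater-well thermal path (thermo-foil heater
#' under an aluminium conductive disc carrying the culture wells):
#' `tau dT/dt = gain * P(t - L) - (T - ambient)`. The default numbers are
#' fabricated plant surrogates for simulation studies — no hardware
#' identification data exists — chosen so a 100 W heater can span the
#' 32.5-39 degC biomimetic protocol from a pre-warmed 32 degC chamber.
#'
#' @param gain Steady-state gain, degC/W, `> 0`.
#' @param time_constant Plant time constant `tau`, s, `> 0`.
#' @param dead_time Transport delay `L`, s, `>= 0`.
#' @param ambient Zero-power equilibrium temperature, degC.
#' @param P_max Heater power limit, W.
#' @return An object of class `"thermal_plant"`.
#' @export
thermal_plant <- function(gain = 0.08, time_constant = 240, dead_time = 8,
                          ambient = 32, P_max = 100) {
  stop_if_not_scalar(gain, "gain", positive = TRUE)
  stop_if_not_scalar(time_constant, "time_constant", positive = TRUE)
  stop_if_not_scalar(dead_time, "dead_time", nonneg = TRUE)
  stop_if_not_scalar(ambient, "ambient")
  stop_if_not_scalar(P_max, "P_max", positive = TRUE)
  structure(list(gain = gain, time_constant = time_constant,
                 dead_time = dead_time, ambient = ambient, P_max = P_max),
            class = "thermal_plant")
}

#' PID gains (standard/ISA form)
#'
#' `P(t) = Kp (e + (1/Ti) int e dt + Td de/dt)`.
#'
#' @param Kp Proportional gain, W/degC, `> 0`.
#' @param Ti Integral time, s, `> 0`.
#' @param Td Derivative time, s, `>= 0`.
#' @return An object of class `"pid_gains"`.
#' @export
pid_gains <- function(Kp, Ti, Td = 0) {
  stop_if_not_scalar(Kp, "Kp", positive = TRUE)
  stop_if_not_scalar(Ti, "Ti", positive = TRUE)
  stop_if_not_scalar(Td, "Td", nonneg = TRUE)
  structure(list(Kp = Kp, Ti = Ti, Td = Td), class = "pid_gains")
}

#' Simulate the open-loop thermal plant
#'
#' Integrates the first-order-plus-dead-time model with the exact
#' exponential update per step (exact for piecewise-constant power), so a
#' step response reproduces `1 - exp(-t/tau)` to within discretization of
#' the delay only.
#'
#' @param plant A [thermal_plant()].
#' @param power A [timeseries()] of heater power (W) on a uniform grid, or
#'   a function of time.
#' @param dt Time step, s; must satisfy `dt <= time_constant / 20`.
#' @param duration Duration, s (required when `power` is a function).
#' @param T0 Initial temperature (default ambient).
#' @return A [timeseries()] of plant temperature, degC.
#' @export
simulate_plant <- function(plant, power, dt, duration = NULL,
                           T0 = plant$ambient) {
  stopifnot(inherits(plant, "thermal_plant"))
  stop_if_not_scalar(dt, "dt", positive = TRUE)
  if (dt > plant$time_constant / 20) {
    stop(sprintf("dt = %g s too coarse: need dt <= tau/20 = %g s",
                 dt, plant$time_constant / 20), call. = FALSE)
  }
  if (inherits(power, "ct_timeseries")) {
    duration <- power$t_s[nrow(power)]
    pfun <- function(t) stats::approx(power$t_s, power$value, xout = t,
                                      rule = 2)$y
  } else if (is.function(power)) {
    if (is.null(duration)) stop("'duration' required with a power function", call. = FALSE)
    pfun <- power
  } else stop("'power' must be a timeseries or a function", call. = FALSE)

  n <- floor(duration / dt) + 1L
  t <- (seq_len(n) - 1L) * dt
  Tv <- numeric(n); Tv[1] <- T0
  ex <- exp(-dt / plant$time_constant)
  for (k in 2:n) {
    td <- t[k - 1] - plant$dead_time
    P <- if (td < 0) 0 else pfun(td)
    Teq <- plant$ambient + plant$gain * P
    Tv[k] <- Teq + (Tv[k - 1] - Teq) * ex
  }
  timeseries(t, Tv, "degC")
}

#' Ziegler-Nichols PID tuning from the plant reaction curve
#'
#' Open-loop (reaction-curve) Ziegler-Nichols rules for a
#' first-order-plus-dead-time plant: `Kp = 1.2 tau / (gain L)`,
#' `Ti = 2 L`, `Td = 0.5 L`. Requires a non-zero dead time — the rules
#' divide by the lag; for a delay-free plant choose gains directly or add
#' a small artificial delay.
#'
#' @param plant A [thermal_plant()] with `dead_time > 0`.
#' @return A [pid_gains()] object.
#' @examples
#' tune_ziegler_nichols(thermal_plant(gain = 0.1, time_constant = 300,
#'                                    dead_time = 10))
#' @export
tune_ziegler_nichols <- function(plant) {
  stopifnot(inherits(plant, "thermal_plant"))
  if (plant$dead_time <= 0) {
    stop("reaction-curve Ziegler-Nichols needs dead_time > 0; ",
         "set a small delay or pick gains manually", call. = FALSE)
  }
  pid_gains(Kp = 1.2 * plant$time_constant / (plant$gain * plant$dead_time),
            Ti = 2 * plant$dead_time,
            Td = 0.5 * plant$dead_time)
}

#' Closed-loop tracking of a heater ramp schedule
#'
#' Simulates the PID-controlled plant following a piecewise-linear setpoint
#' schedule. Positional PID with: first-order filtered derivative
#' (filter coefficient `N`, default 10), heater power clamped to
#' `[0, P_max]`, and conditional-integration anti-windup (the integrator
#' freezes while the actuator is saturated in the direction of the error).
#' The reported tracking error is the maximum `|T - setpoint|` after an
#' initial settling window.
#'
#' @param plant A [thermal_plant()].
#' @param gains A [pid_gains()].
#' @param schedule A ramp schedule from [build_ramp_schedule()].
#' @param dt Controller/integration step, s (default 1).
#' @param settling Settling window excluded from the error metric, s
#'   (default 300).
#' @param N Derivative filter coefficient (default 10).
#' @param T0 Initial plant temperature (default the first setpoint).
#' @return A list: `trace` (temperature [timeseries()]), `setpoint`
#'   ([timeseries()]), `power` ([timeseries()], W), `max_abs_error` (degC,
#'   after settling), `unstable` flag.
#' @export
track_schedule <- function(plant, gains, schedule, dt = 1, settling = 300,
                           N = 10, T0 = ramp_setpoint(schedule, 0)) {
  stopifnot(inherits(plant, "thermal_plant"), inherits(gains, "pid_gains"))
  duration <- schedule$t_s[nrow(schedule)]
  if (duration <= 0) stop("schedule duration must be > 0", call. = FALSE)
  n <- floor(duration / dt) + 1L
  t <- (seq_len(n) - 1L) * dt
  sp <- ramp_setpoint(schedule, t)
  Tv <- numeric(n); Tv[1] <- T0
  Pv <- numeric(n)
  ex <- exp(-dt / plant$time_constant)
  nd <- max(0L, round(plant$dead_time / dt))
  buf <- numeric(nd)            # power delay line
  integ <- 0; e_prev <- sp[1] - Tv[1]; d_state <- 0
  a_d <- if (gains$Td > 0) gains$Td / (gains$Td + N * dt) else 0
  unstable <- FALSE
  for (k in seq_len(n - 1L)) {
    e <- sp[k] - Tv[k]
    d_state <- if (gains$Td > 0) a_d * d_state + a_d * N * (e - e_prev) else 0
    u_raw <- gains$Kp * (e + integ / gains$Ti + d_state)
    u <- min(max(u_raw, 0), plant$P_max)
    # conditional integration: only integrate when not pushing into a limit
    if (!((u_raw > plant$P_max && e > 0) || (u_raw < 0 && e < 0))) {
      integ <- integ + e * dt
    }
    Pv[k] <- u
    Pd <- if (nd == 0L) u else buf[1]
    if (nd > 0L) buf <- c(buf[-1], u)
    Teq <- plant$ambient + plant$gain * Pd
    Tv[k + 1] <- Teq + (Tv[k] - Teq) * ex
    if (!is.finite(Tv[k + 1]) || abs(Tv[k + 1]) > 1e3) {
      unstable <- TRUE
      Tv[(k + 1):n] <- Tv[k + 1]
      break
    }
    e_prev <- e
  }
  Pv[n] <- Pv[n - 1L]
  err <- abs(Tv - sp)
  max_abs_error <- max(err[t >= settling])
  if (unstable) warning("closed loop unstable: temperature diverged")
  list(trace = timeseries(t, Tv, "degC"),
       setpoint = timeseries(t, sp, "degC"),
       power = timeseries(t, Pv, "W"),
       max_abs_error = max_abs_error,
       unstable = unstable)
}
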