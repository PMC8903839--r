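#' One cycle of a stress-strain hysteresis loop
#'
#' @param cycle_index Cycle number (counted from 1).
#' @param strain Dimensionless strain samples over one period; first and
#'   last samples must close the loop (their gap is checked against
#'   `closure_tol` times the strain amplitude in [hysteresis_area()]).
#' @param stress Stress samples, Pa; same length as `strain`.
#' @param frequency Loading frequency, Hz.
#' @return An object of class `"hysteresis_loop"`.
#' @export
hysteresis_loop <- function(cycle_index, strain, stress, frequency) {
  if (length(strain) != length(stress)) {
    stop("'strain' and 'stress' must match in length", call. = FALSE)
  }
  if (length(strain) < 32) stop("a loop needs at least 32 samples", call. = FALSE)
  stop_if_not_scalar(frequency, "frequency", positive = TRUE)
  if (anyNA(strain) || anyNA(stress)) stop("NA samples not allowed", call. = FALSE)
  structure(list(cycle_index = as.integer(cycle_index),
                 strain = as.numeric(strain), stress = as.numeric(stress),
                 frequency = frequency),
            class = "hysteresis_loop")
}

#' @export
print.hysteresis_loop <- function(x, ...) {
  cat(sprintf("Hysteresis loop: cycle %d, %d samples at %g Hz, strain %.3g..%.3g\n",
              x$cycle_index, length(x$strain), min(x$strain), max(x$strain)))
  invisible(x)
}

#' Hysteresis-loop area (energy dissipated per cycle)
#'
#' Signed area of the closed stress-strain polygon by the shoelace rule on
#' the ordered samples, returned as its absolute value in J/m^3 (Pa x
#' strain); the traversal orientation is recorded as attribute
#' `"orientation"` (+1 counter-clockwise, -1 clockwise). The loop must
#' close: an endpoint strain gap larger than `closure_tol` times the strain
#' amplitude is rejected with the measured gap. The measure is invariant to
#' cyclic rotation of the samples and to any constant stress offset.
#'
#' @param loops A single [hysteresis_loop()] or a list of them (as produced
#'   by [gen_hysteresis_loops()]).
#' @param cycle Which cycle index to measure (default 100, the
#'   standard preconditioned-cycle choice); ignored when a single loop is
#'   given.
#' @param closure_tol Allowed endpoint strain gap as a fraction of strain
#'   amplitude (default 0.01).
#' @return Loop area, J/m^3 per cycle.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 201)
#' lp <- hysteresis_loop(1, 0.05 * sin(th), 1e4 * sin(th + 0.3), 1)
#' hysteresis_area(lp)                      # ~ pi * 1e4 * 0.05 * sin(0.3)
#' @export
hysteresis_area <- function(loops, cycle = 100, closure_tol = 0.01) {
  loop <- if (inherits(loops, "hysteresis_loop")) {
    loops
  } else {
    idx <- vapply(loops, `[[`, integer(1), "cycle_index")
    hit <- which(idx == cycle)
    if (length(hit) != 1) {
      stop(sprintf("requested cycle %d not present (have %d..%d)",
                   cycle, min(idx), max(idx)), call. = FALSE)
    }
    loops[[hit]]
  }
  eps <- loop$strain
  sig <- loop$stress
  amp <- (max(eps) - min(eps)) / 2
  gap <- abs(eps[length(eps)] - eps[1])
  # the seam of a cyclically rotated loop legitimately spans one sampling
  # step; anything beyond max(tolerance band, one step) indicates drift
  allowed <- max(closure_tol * 2 * amp, 1.05 * max(abs(diff(eps))))
  if (amp > 0 && gap > allowed) {
    stop(sprintf("open loop: endpoint strain gap %.3g exceeds %.3g (%.0f%% of amplitude)",
                 gap, closure_tol * 2 * amp, 100 * closure_tol), call. = FALSE)
  }
  # drop duplicated closing point if present; shoelace wraps implicitly
  n <- length(eps)
  if (eps[n] == eps[1] && sig[n] == sig[1]) {
    eps <- eps[-n]; sig <- sig[-n]; n <- n - 1L
  }
  j <- c(2:n, 1L)
  signed <- 0.5 * sum(eps * sig[j] - eps[j] * sig)
  structure(abs(signed), orientation = sign(signed))
}

#' Volumetric dissipative power from loop area
#'
#' Under steady cyclic loading the heat generated per unit volume per unit
#' time is the per-cycle hysteresis area times the loading frequency; at
#' 1 Hz a 9000 J/m^3 loop area yields the 9000 W/m^3 source used in the
#' well heat-transfer scenarios.
#'
#' @param area Loop area, J/m^3 per cycle, `>= 0`.
#' @param frequency Loading frequency, Hz, `> 0`.
#' @return Power density, W/m^3.
#' @export
dissipative_power <- function(area, frequency) {
  stop_if_not_scalar(as.numeric(area), "area", nonneg = TRUE)
  stop_if_not_scalar(frequency, "frequency", positive = TRUE)
  as.numeric(area) * frequency
}

#' Equilibrium modulus from a sequential relaxation record
#'
#' The relaxed stress of each step is the mean over the final
#' `tail_fraction` of its hold; the equilibrium modulus is the
#' least-squares slope of relaxed stress versus strain over the steps whose
#' strain lies inside `strain_window` (default the 10-20 % range). The
#' estimate is invariant to a constant stress offset and scales linearly
#' with stress.
#'
#' @param seq A `"relaxation_sequence"` from [gen_relaxation_sequence()] (or
#'   the same structure from measured data).
#' @param strain_window Inclusive `(lo, hi)` strain window (default
#'   `c(0.10, 0.20)`).
#' @param tail_fraction Fraction of each hold used as the relaxed plateau
#'   (default 0.1).
#' @return Equilibrium modulus, Pa, with attribute `"relaxed"`: the
#'   per-step (strain, relaxed stress) table used for the fit.
#' @export
equilibrium_modulus <- function(seq, strain_window = c(0.10, 0.20),
                                tail_fraction = 0.1) {
  stopifnot(inherits(seq, "relaxation_sequence"))
  if (tail_fraction <= 0 || tail_fraction > 1) {
    stop("'tail_fraction' must be in (0, 1]", call. = FALSE)
  }
  lv <- vapply(seq$steps, `[[`, numeric(1), "strain_level")
  relaxed <- vapply(seq$steps, function(st) {
    v <- st$stress$value
    n <- length(v)
    k <- max(1L, ceiling(tail_fraction * n))
    mean(v[(n - k + 1L):n])
  }, numeric(1))
  tol <- 1e-9
  use <- lv >= strain_window[1] - tol & lv <= strain_window[2] + tol
  if (sum(use) < 2) {
    stop(sprintf("need >= 2 steps with strain inside [%g, %g]; found %d",
                 strain_window[1], strain_window[2], sum(use)), call. = FALSE)
  }
  fit <- stats::lm(relaxed[use] ~ lv[use])
  structure(unname(stats::coef(fit)[2]),
            relaxed = data.frame(strain = lv, stress_Pa = relaxed,
                                 used = use))
}
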