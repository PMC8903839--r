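#' @keywords internal
#' @importFrom stats rnorm runif sd var
"_PACKAGE"

# Run expr with a private RNG stream so generators are pure functions of
# (parameters, seed) and never disturb the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_if_not_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0 (got %g)", name, x), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("'%s' must be >= 0 (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

#' Specify additive Gaussian measurement noise
#'
#' All synthetic-data generators in the package share this noise model:
#' independent additive Gaussian perturbations with standard deviation `sd`
#' in the units of the series being generated, drawn from a private RNG
#' stream seeded with `seed`. Identical `(parameters, seed)` give
#' bitwise-identical output.
#'
#' @param sd Standard deviation of the additive noise (series units); `>= 0`.
#' @param seed Integer RNG seed, or `NULL` to use (and advance) the global
#'   RNG stream.
#' @return An object of class `"noise_spec"`.
#' @examples
#' noise_spec(0.1, seed = 42)
#' @export
noise_spec <- function(sd = 0, seed = NULL) {
  stop_if_not_scalar(sd, "sd", nonneg = TRUE)
  if (!is.null(seed)) stop_if_not_scalar(seed, "seed")
  structure(list(sd = sd, seed = seed), class = "noise_spec")
}

as_noise_spec <- function(noise) {
  if (is.null(noise)) return(noise_spec(0))
  if (inherits(noise, "noise_spec")) return(noise)
  if (is.numeric(noise) && length(noise) == 1L) return(noise_spec(noise))
  stop("'noise' must be a noise_spec(), a single sd value, or NULL",
       call. = FALSE)
}

#' Construct a tagged time series
#'
#' A minimal container for sampled measurements: a data frame with columns
#' `t_s` (seconds, strictly increasing, `t_s[1] >= 0`), `value`, and a unit
#' tag recorded once as an attribute (and in the CSV round trip as a third
#' column).
#'
#' @param t_s Sampling times in seconds.
#' @param value Measured values (same length as `t_s`).
#' @param unit Unit tag, e.g. `"degC"`, `"Pa"`, `"strain"`.
#' @return A `data.frame` of class `"ct_timeseries"`.
#' @export
timeseries <- function(t_s, value, unit) {
  if (length(t_s) != length(value)) {
    stop("'t_s' and 'value' must have equal length", call. = FALSE)
  }
  if (anyNA(t_s) || anyNA(value)) stop("NA values are not allowed", call. = FALSE)
  if (length(t_s) > 0) {
    if (t_s[1] < 0) stop("t_s[1] must be >= 0", call. = FALSE)
    if (length(t_s) > 1 && any(diff(t_s) <= 0)) {
      stop("'t_s' must be strictly increasing", call. = FALSE)
    }
  }
  if (!is.character(unit) || length(unit) != 1L || !nzchar(unit)) {
    stop("'unit' must be a non-empty string", call. = FALSE)
  }
  structure(data.frame(t_s = as.numeric(t_s), value = as.numeric(value)),
            unit = unit, class = c("ct_timeseries", "data.frame"))
}

ts_unit <- function(x) attr(x, "unit", exact = TRUE)

#' @export
print.ct_timeseries <- function(x, ...) {
  cat(sprintf("Time series [%s]: %d samples, t = %g..%g s\n",
              ts_unit(x), nrow(x), x$t_s[1], x$t_s[nrow(x)]))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}
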