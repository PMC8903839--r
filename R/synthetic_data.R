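#' Generate a noisy intra-articular temperature series
#'
#' Samples the saturating-exponential model on a uniform grid and adds
#' independent Gaussian measurement noise, emulating an in vivo
#' intra-articular temperature trace recorded during activity. With
#' `sd = 0` the output equals the analytic model to machine precision.
#'
#' @param model A [temperature_model()].
#' @param duration Total duration, s, `> 0`.
#' @param dt Sampling interval, s, `> 0` (default 10 s).
#' @param noise A [noise_spec()] (sd in degC).
#' @return A [timeseries()] with unit `"degC"` and
#'   `floor(duration/dt) + 1` samples.
#' @examples
#' s <- gen_temperature_series(temperature_model(), 7200, dt = 60,
#'                             noise = noise_spec(0.2, seed = 1))
#' @export
gen_temperature_series <- function(model, duration, dt = 10,
                                   noise = noise_spec(0)) {
  stopifnot(inherits(model, "temperature_model"))
  stop_if_not_scalar(duration, "duration", positive = TRUE)
  stop_if_not_scalar(dt, "dt", positive = TRUE)
  noise <- as_noise_spec(noise)
  t <- seq(0, by = dt, length.out = floor(duration / dt) + 1L)
  v <- predict_temperature(model, t)
  if (noise$sd > 0) {
    v <- v + with_seed(noise$seed, rnorm(length(t), 0, noise$sd))
  }
  timeseries(t, v, "degC")
}

#' Generate cyclic stress-strain hysteresis loops
#'
#' Stands in for load-frame records of displacement-controlled cyclic
#' compression. The strain waveform is either `pre_strain +
#' amplitude*sin(2*pi*f*t)` (`waveform = "sin"`, centered) or the
#' compression-only raised cosine `pre_strain +
#' (amplitude/2)*(1 - cos(2*pi*f*t))` (`waveform = "raised_cosine"`,
#' ramping from the pre-strain to `pre_strain + amplitude` each cycle).
#' Stress follows the linear viscoelastic [stress_response()] of `prony`
#' plus additive Gaussian noise. Cycles are indexed from 1; each returned
#' loop carries one full period with coincident first/last strain samples.
#'
#' @param prony A [prony_series()] (uniaxial kernel for the recorded
#'   stress channel).
#' @param loading A [loading_protocol()].
#' @param n_cycles Number of cycles to generate, `>= 1`.
#' @param noise A [noise_spec()] (sd in Pa, applied to stress).
#' @param samples_per_cycle Samples per period, `>= 100` (default 200).
#' @param waveform `"sin"` or `"raised_cosine"`.
#' @return A list of [hysteresis_loop()] objects, length `n_cycles`.
#' @export
gen_hysteresis_loops <- function(prony, loading, n_cycles,
                                 noise = noise_spec(0),
                                 samples_per_cycle = 200,
                                 waveform = c("sin", "raised_cosine")) {
  stopifnot(inherits(prony, "prony_series"), inherits(loading, "loading_protocol"))
  waveform <- match.arg(waveform)
  if (!is.numeric(n_cycles) || n_cycles < 1) stop("'n_cycles' must be >= 1", call. = FALSE)
  n_cycles <- as.integer(n_cycles)
  if (samples_per_cycle < 100) stop("'samples_per_cycle' must be >= 100", call. = FALSE)
  if (loading$amplitude <= 0) stop("'amplitude' must be > 0", call. = FALSE)
  noise <- as_noise_spec(noise)

  f <- loading$frequency
  N <- as.integer(samples_per_cycle)
  dt <- 1 / (f * N)
  n <- n_cycles * N + 1L
  t <- (seq_len(n) - 1L) * dt
  phase <- 2 * pi * f * t
  eps <- switch(waveform,
    sin = loading$pre_strain + loading$amplitude * sin(phase),
    raised_cosine = loading$pre_strain +
      (loading$amplitude / 2) * (1 - cos(phase)))
  sig <- stress_response(prony, timeseries(t, eps, "strain"))$value
  if (noise$sd > 0) {
    sig <- sig + with_seed(noise$seed, rnorm(n, 0, noise$sd))
  }
  lapply(seq_len(n_cycles), function(j) {
    idx <- ((j - 1L) * N + 1L):(j * N + 1L)
    hysteresis_loop(cycle_index = j, strain = eps[idx], stress = sig[idx],
                    frequency = f)
  })
}

#' Generate a sequential stress-relaxation record
#'
#' Emulates the equilibrium-modulus measurement: the strain is stepped
#' through `strain_steps` (each step applied instantaneously and held for
#' `hold` seconds) and the uniaxial stress decays toward
#' `E_eq * strain` at each level. The transient follows the Prony branches
#' of `prony` (its `g_inf` is ignored: the long-term uniaxial modulus is
#' `E_eq`).
#'
#' @param E_eq Long-term (equilibrium) uniaxial modulus, Pa.
#' @param prony A [prony_series()] supplying the transient branches.
#' @param strain_steps Strictly increasing strain levels, non-empty.
#' @param hold Hold time per step, s; a warning is emitted when
#'   `hold < 10 * max(tau)` since the final stress is then still relaxing.
#' @param dt Sampling interval, s.
#' @param noise A [noise_spec()] (sd in Pa).
#' @return A `"relaxation_sequence"`: list with element `steps`, each step a
#'   list of `strain_level` and a stress [timeseries()] (time measured from
#'   the step's own start).
#' @export
gen_relaxation_sequence <- function(E_eq, prony, strain_steps, hold, dt,
                                    noise = noise_spec(0)) {
  stop_if_not_scalar(E_eq, "E_eq", nonneg = TRUE)
  stopifnot(inherits(prony, "prony_series"))
  if (length(strain_steps) == 0) stop("'strain_steps' must be non-empty", call. = FALSE)
  if (length(strain_steps) > 1 && any(diff(strain_steps) <= 0)) {
    stop("'strain_steps' must be strictly increasing", call. = FALSE)
  }
  stop_if_not_scalar(hold, "hold", positive = TRUE)
  stop_if_not_scalar(dt, "dt", positive = TRUE)
  noise <- as_noise_spec(noise)
  if (length(prony$tau) && hold < 10 * max(prony$tau)) {
    warning(sprintf(
      "hold = %g s is below 10*max(tau) = %g s: final stresses not fully relaxed",
      hold, 10 * max(prony$tau)))
  }
  kernel <- prony_series(E_eq, prony$G, prony$tau)
  n_per <- floor(hold / dt) + 1L
  n_steps <- length(strain_steps)
  # full staircase strain history so each step carries the previous history
  eps_full <- rep(strain_steps, each = n_per)
  t_full <- (seq_along(eps_full) - 1L) * dt
  sig_full <- stress_response(kernel, timeseries(t_full, eps_full, "strain"))$value
  if (noise$sd > 0) {
    sig_full <- sig_full + with_seed(noise$seed,
                                     rnorm(length(sig_full), 0, noise$sd))
  }
  steps <- lapply(seq_len(n_steps), function(j) {
    idx <- ((j - 1L) * n_per + 1L):(j * n_per)
    list(strain_level = strain_steps[j],
         stress = timeseries((seq_len(n_per) - 1L) * dt, sig_full[idx], "Pa"))
  })
  structure(list(steps = steps, hold = hold, dt = dt),
            class = "relaxation_sequence")
}

#' @export
print.relaxation_sequence <- function(x, ...) {
  lv <- vapply(x$steps, `[[`, numeric(1), "strain_level")
  cat(sprintf("Sequential stress relaxation: %d steps at strain {%s}, hold %g s\n",
              length(x$steps), paste(format(lv), collapse = ", "), x$hold))
  invisible(x)
}

#' Generate a replicate qPCR Ct table with known fold changes
#'
#' Builds a balanced synthetic Ct table for the comparative delta-delta-Ct
#' pipeline. For a target gene with true fold change `F` in a group
#' (relative to the first group, the control), the generated
#' `Ct = base_ct - log2(F) + noise`; the reference gene has constant
#' `Ct = base_ct + noise` in every sample. The control group must have fold
#' 1 for every gene, and the reference gene fold must be 1 everywhere.
#'
#' @param genes Character vector of target gene names (excluding
#'   `ref_gene`).
#' @param groups Character vector of group labels; the first is the control.
#' @param fold_changes Numeric matrix `length(groups) x length(genes)`
#'   (dimnames optional) of true fold changes, all `> 0`; control row all 1.
#' @param ref_gene Reference (housekeeping) gene name.
#' @param base_ct Baseline Ct in cycles (default 20).
#' @param replicates Replicates per group, `>= 2`.
#' @param noise A [noise_spec()] (sd in Ct cycles).
#' @return A `"ct_table"`: data frame with columns `sample`, `group`,
#'   `gene`, `ct`, `replicate`.
#' @examples
#' fc <- matrix(c(1, 1, 2, 0.5), nrow = 2, byrow = TRUE,
#'              dimnames = list(c("control", "loaded"), c("Sox9", "Twist1")))
#' tab <- gen_ct_table(c("Sox9", "Twist1"), c("control", "loaded"), fc,
#'                     ref_gene = "RPL13a", replicates = 4,
#'                     noise = noise_spec(0.3, seed = 7))
#' @export
gen_ct_table <- function(genes, groups, fold_changes, ref_gene = "RPL13a",
                         base_ct = 20, replicates = 4,
                         noise = noise_spec(0)) {
  stopifnot(is.character(genes), is.character(groups),
            length(genes) >= 1, length(groups) >= 1)
  if (ref_gene %in% genes) {
    stop("'genes' must not contain the reference gene", call. = FALSE)
  }
  if (!is.matrix(fold_changes) ||
      nrow(fold_changes) != length(groups) ||
      ncol(fold_changes) != length(genes)) {
    stop("'fold_changes' must be a groups x genes matrix", call. = FALSE)
  }
  if (any(fold_changes <= 0)) stop("fold changes must be > 0", call. = FALSE)
  if (any(abs(fold_changes[1, ] - 1) > 1e-12)) {
    stop("control group (first row) must have fold 1 for every gene", call. = FALSE)
  }
  if (replicates < 2) stop("'replicates' must be >= 2", call. = FALSE)
  stop_if_not_scalar(base_ct, "base_ct", positive = TRUE)
  noise <- as_noise_spec(noise)

  all_genes <- c(ref_gene, genes)
  grid <- expand.grid(replicate = seq_len(replicates), group = groups,
                      gene = all_genes, stringsAsFactors = FALSE)
  grid$sample <- sprintf("%s_r%d", grid$group, grid$replicate)
  gi <- match(grid$gene, genes)        # NA for the reference gene
  ri <- match(grid$group, groups)
  fold <- ifelse(is.na(gi), 1, fold_changes[cbind(ri, ifelse(is.na(gi), 1L, gi))])
  ct <- base_ct - log2(fold)
  if (noise$sd > 0) {
    ct <- ct + with_seed(noise$seed, rnorm(nrow(grid), 0, noise$sd))
  }
  out <- data.frame(sample = grid$sample, group = grid$group,
                    gene = grid$gene, ct = ct, replicate = grid$replicate,
                    stringsAsFactors = FALSE)
  structure(out, ref_gene = ref_gene, class = c("ct_table", "data.frame"))
}
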