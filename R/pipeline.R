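#' Configure an end-to-end in silico stimulation study
#'
#' Assembles the configuration of the full pipeline: temperature-model
#' parameters (or a CSV path to fit from), heater schedule and control
#' plant, the well scenario, and the Ct-table design for the gene-
#' expression stage. Unknown keys are rejected; the configuration is fully
#' serializable to JSON and a run is reproducible from its manifest alone.
#'
#' @param seed Global integer seed; per-stage child seeds are derived by a
#'   fixed rule (`seed * 8 + stage index`, kept below 2^31).
#' @param thermal Either a [temperature_model()] or a path to a
#'   `t_s,value,unit` CSV to fit.
#' @param schedule_minutes Ramp-schedule horizon, minutes (default 90).
#' @param n_segments Schedule segments (default 6).
#' @param start_setpoint First setpoint, degC (default 32.5).
#' @param plant A [thermal_plant()].
#' @param scenario `"isothermal_32C"` or `"adiabatic"`.
#' @param scenario_minutes Heat-transfer horizon, minutes (default 90).
#' @param target_h Mesh size, m (default 0.5 mm).
#' @param Q_dis Dissipative source override, W/m^3 (NULL = material preset).
#' @param ct_design List with `genes`, `groups`, `fold_changes` (matrix),
#'   `ref_gene`, `replicates`, `ct_sd` for [gen_ct_table()].
#' @return A `"study_config"` list.
#' @export
study_config <- function(seed = 1,
                         thermal = temperature_model(),
                         schedule_minutes = 90, n_segments = 6,
                         start_setpoint = 32.5,
                         plant = thermal_plant(),
                         scenario = "isothermal_32C",
                         scenario_minutes = 90, target_h = 0.5e-3,
                         Q_dis = NULL,
                         ct_design = NULL) {
  stop_if_not_scalar(seed, "seed")
  if (!(inherits(thermal, "temperature_model") ||
        (is.character(thermal) && length(thermal) == 1L))) {
    stop("'thermal' must be a temperature_model or a CSV path", call. = FALSE)
  }
  if (!scenario %in% c("isothermal_32C", "adiabatic")) {
    stop("unknown scenario: ", scenario, call. = FALSE)
  }
  if (is.null(ct_design)) {
    fc <- matrix(c(1, 1, 1, 1, 1, 1,
                   3.5, 2.0, 1.8, 2.5, 0.5, 1.1),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("FS32.5", "ThermoMech"),
                                 c("Sox9", "Col2a", "Agc", "Comp", "Twist", "Col1a")))
    ct_design <- list(genes = colnames(fc), groups = rownames(fc),
                      fold_changes = fc, ref_gene = "RPL13a",
                      replicates = 5, ct_sd = 0.3)
  }
  need <- c("genes", "groups", "fold_changes", "ref_gene", "replicates", "ct_sd")
  if (!all(need %in% names(ct_design))) {
    stop("ct_design needs fields: ", paste(need, collapse = ", "), call. = FALSE)
  }
  structure(list(seed = as.integer(seed), thermal = thermal,
                 schedule_minutes = schedule_minutes, n_segments = n_segments,
                 start_setpoint = start_setpoint, plant = plant,
                 scenario = scenario, scenario_minutes = scenario_minutes,
                 target_h = target_h, Q_dis = Q_dis, ct_design = ct_design),
            class = "study_config")
}

stage_seed <- function(seed, stage) {
  (as.integer(seed) * 8L + as.integer(stage)) %% .Machine$integer.max
}

#' Run the full in silico thermo-mechanobiology study
#'
#' Chains every stage on synthetic inputs: (1) generate a noisy biomimetic
#' temperature series and re-fit the saturating-exponential model; (2)
#' build the piecewise-ramp heater schedule; (3) simulate Ziegler-Nichols
#' tuned PID tracking of the schedule on the heater plant; (4) run the
#' coupled poro-viscoelastic/heat-transfer well scenario; (5) generate a
#' replicate Ct table from the configured fold-change design and run the
#' delta-delta-Ct analysis with Welch group comparisons. All artifacts
#' (CSV series, schedule knots, VTK snapshots, results tables), a JSON
#' provenance manifest (config, seed, package version) and a plain-text
#' summary are written to `out_dir`. A stage failure halts the run with a
#' stage-tagged error.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created; must be empty or absent unless
#'   `overwrite = TRUE`).
#' @param overwrite Allow writing into an existing directory?
#' @return Invisibly, a list with all stage results (`fit`, `schedule`,
#'   `tracking`, `scenario`, `expression`) and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "study_config"))
  if (dir.exists(out_dir) && !overwrite &&
      length(list.files(out_dir, all.files = TRUE, no.. = TRUE))) {
    stop("output directory exists and is not empty: ", out_dir, call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  # 1. thermal model: synthetic series (or CSV) -> fit
  fit <- stage("thermal_fit", {
    series <- if (inherits(config$thermal, "temperature_model")) {
      gen_temperature_series(config$thermal, duration = 7200, dt = 60,
                             noise = noise_spec(0.2, seed = stage_seed(config$seed, 1L)))
    } else {
      read_timeseries_csv(config$thermal)
    }
    write_timeseries_csv(series, file.path(out_dir, "temperature_series.csv"))
    fit_temperature_model(series)
  })

  # 2. ramp schedule
  schedule <- stage("schedule", {
    sch <- build_ramp_schedule(fit$model, duration = config$schedule_minutes * 60,
                               n_segments = config$n_segments,
                               start_setpoint = config$start_setpoint)
    write_schedule_csv(sch, file.path(out_dir, "ramp_schedule.csv"))
    sch
  })

  # 3. PID tracking
  tracking <- stage("control", {
    gains <- tune_ziegler_nichols(config$plant)
    tr <- track_schedule(config$plant, gains, schedule)
    write_timeseries_csv(tr$trace, file.path(out_dir, "tracked_temperature.csv"))
    tr
  })

  # 4. FEM scenario
  scenario <- stage("fem_scenario", {
    cfg <- scenario_config(config$scenario, minutes = config$scenario_minutes,
                           target_h = config$target_h, Q_dis = config$Q_dis)
    res <- run_scenario(cfg)
    for (i in seq_along(res$heat$snapshots)) {
      sn <- res$heat$snapshots[[i]]
      write_vtk(res$mesh,
                file.path(out_dir, sprintf("temperature_%04.0fs.vtk", sn$time)),
                point_data = list(temperature_degC = sn$T))
    }
    utils::write.csv(
      data.frame(time_s = res$heat$times,
                 max_medium_T_degC = res$heat$medium_max_history),
      file.path(out_dir, "medium_temperature.csv"), row.names = FALSE)
    res
  })

  # 5. expression analysis on a synthetic Ct table
  expression <- stage("expression", {
    d <- config$ct_design
    tab <- gen_ct_table(d$genes, d$groups, d$fold_changes, ref_gene = d$ref_gene,
                        replicates = d$replicates,
                        noise = noise_spec(d$ct_sd, seed = stage_seed(config$seed, 5L)))
    write_ct_csv(tab, file.path(out_dir, "ct_table.csv"))
    fc <- delta_delta_ct(tab, d$ref_gene, d$groups[1])
    utils::write.csv(fc$summary, file.path(out_dir, "fold_changes.csv"),
                     row.names = FALSE)
    cmp <- NULL
    if (length(d$groups) >= 2) {
      cmp <- compare_groups(fc, d$groups[1], d$groups[2])
      utils::write.csv(cmp, file.path(out_dir, "group_comparison.csv"),
                       row.names = FALSE)
    }
    list(table = tab, folds = fc, comparison = cmp)
  })

  manifest <- list(
    package = "chondrotherm",
    version = as.character(utils::packageVersion("chondrotherm")),
    seed = config$seed,
    config = serialize_config(config),
    created = "see summary.txt"
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  summary_lines <- c(
    sprintf("fitted model: A=%.4f B=%.4f c=%.6f %s (R=%.4f)",
            fit$model$A, fit$model$B, fit$model$c, fit$model$c_unit, fit$R),
    sprintf("schedule: %g min, %d segments, %.2f -> %.2f degC",
            config$schedule_minutes, config$n_segments,
            schedule$setpoint_degC[1], schedule$setpoint_degC[nrow(schedule)]),
    sprintf("tracking max |error| after settling: %.4f degC", tracking$max_abs_error),
    sprintf("scenario %s: max medium dT = %.6f degC, max sample T = %.4f degC",
            config$scenario, scenario$max_medium_dT, scenario$max_sample_T),
    sprintf("energy ledger closure: %.3g", scenario$heat$ledger$closure_rel)
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(list(fit = fit, schedule = schedule, tracking = tracking,
                 scenario = scenario, expression = expression,
                 out_dir = out_dir))
}

# flatten a study_config into JSON-serializable primitives
serialize_config <- function(config) {
  list(
    seed = config$seed,
    thermal = if (inherits(config$thermal, "temperature_model")) {
      unclass(config$thermal)
    } else config$thermal,
    schedule_minutes = config$schedule_minutes,
    n_segments = config$n_segments,
    start_setpoint = config$start_setpoint,
    plant = unclass(config$plant),
    scenario = config$scenario,
    scenario_minutes = config$scenario_minutes,
    target_h = config$target_h,
    Q_dis = config$Q_dis,
    ct_design = list(
      genes = config$ct_design$genes,
      groups = config$ct_design$groups,
      fold_changes = as.vector(config$ct_design$fold_changes),
      ref_gene = config$ct_design$ref_gene,
      replicates = config$ct_design$replicates,
      ct_sd = config$ct_design$ct_sd
    )
  )
}
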