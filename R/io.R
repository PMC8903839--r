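#' Read and write tagged time-series CSV
#'
#' Fixed three-column format with a one-line header `t_s,value,unit`; the
#' unit tag is repeated on every row and must be consistent. The round trip
#' `read_timeseries_csv(write_timeseries_csv(x))` reproduces `x` to float
#' precision. Malformed headers or non-numeric fields are rejected with the
#' offending line number.
#'
#' @param x A [timeseries()].
#' @param path File path.
#' @return `read_timeseries_csv` returns a [timeseries()];
#'   `write_timeseries_csv` returns `path` invisibly.
#' @export
write_timeseries_csv <- function(x, path) {
  stopifnot(inherits(x, "ct_timeseries"))
  df <- data.frame(t_s = format(x$t_s, digits = 17, trim = TRUE, scientific = NA),
                   value = format(x$value, digits = 17, trim = TRUE, scientific = NA),
                   unit = ts_unit(x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_csv
#' @export
read_timeseries_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  header <- strsplit(trimws(lines[1]), ",", fixed = TRUE)[[1]]
  if (!identical(header, c("t_s", "value", "unit"))) {
    stop(sprintf("line 1: expected header 't_s,value,unit', got '%s'", lines[1]),
         call. = FALSE)
  }
  if (length(lines) < 2) stop("line 2: no data rows", call. = FALSE)
  t_s <- value <- numeric(length(lines) - 1L)
  unit <- character(length(lines) - 1L)
  for (i in 2:length(lines)) {
    f <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(f) != 3) {
      stop(sprintf("line %d: expected 3 fields, got %d", i, length(f)), call. = FALSE)
    }
    tv <- suppressWarnings(as.numeric(f[1:2]))
    if (anyNA(tv)) stop(sprintf("line %d: non-numeric t_s/value", i), call. = FALSE)
    if (!nzchar(trimws(f[3]))) stop(sprintf("line %d: missing unit tag", i), call. = FALSE)
    t_s[i - 1L] <- tv[1]; value[i - 1L] <- tv[2]; unit[i - 1L] <- trimws(f[3])
  }
  if (length(unique(unit)) != 1) {
    stop("inconsistent unit tags in ", path, call. = FALSE)
  }
  timeseries(t_s, value, unit[1])
}

#' Read and write hysteresis loops as CSV
#'
#' Format `cycle,strain,stress_Pa` with one row per sample; loops are
#' reassembled by cycle index. The loop frequency is carried in a comment
#' line `# frequency_hz=<f>` after the header.
#'
#' @param loops A list of [hysteresis_loop()] objects.
#' @param path File path.
#' @return `read_loops_csv` returns a list of [hysteresis_loop()].
#' @export
write_loops_csv <- function(loops, path) {
  if (inherits(loops, "hysteresis_loop")) loops <- list(loops)
  f <- loops[[1]]$frequency
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("cycle,strain,stress_Pa", sprintf("# frequency_hz=%.17g", f)), con)
  for (lp in loops) {
    writeLines(sprintf("%d,%.17g,%.17g", lp$cycle_index, lp$strain, lp$stress), con)
  }
  invisible(path)
}

#' @rdname write_loops_csv
#' @export
read_loops_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !identical(trimws(lines[1]), "cycle,strain,stress_Pa")) {
    stop("line 1: expected header 'cycle,strain,stress_Pa'", call. = FALSE)
  }
  fline <- grep("^# frequency_hz=", lines)
  if (!length(fline)) stop("missing '# frequency_hz=' comment line", call. = FALSE)
  freq <- as.numeric(sub("^# frequency_hz=", "", lines[fline[1]]))
  data_lines <- lines[-c(1L, fline)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad)) stop(sprintf("malformed loop row near line %d", bad[1] + 2L), call. = FALSE)
  mat <- matrix(as.numeric(unlist(parts)), ncol = 3, byrow = TRUE)
  if (anyNA(mat)) stop("non-numeric loop data in ", path, call. = FALSE)
  lapply(sort(unique(mat[, 1])), function(cy) {
    sel <- mat[, 1] == cy
    hysteresis_loop(cy, mat[sel, 2], mat[sel, 3], freq)
  })
}

#' Read and write Ct tables as CSV
#'
#' Format `sample,group,gene,ct` (a `replicate` column is accepted and
#' preserved when present).
#'
#' @param table A `"ct_table"` or compatible data frame.
#' @param path File path.
#' @return `read_ct_csv` returns a data frame of class `"ct_table"`.
#' @export
write_ct_csv <- function(table, path) {
  stopifnot(is.data.frame(table),
            all(c("sample", "group", "gene", "ct") %in% names(table)))
  cols <- intersect(c("sample", "group", "gene", "ct", "replicate"), names(table))
  utils::write.csv(table[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ct_csv
#' @export
read_ct_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% names(df))) {
    stop("line 1: Ct CSV needs header columns sample,group,gene,ct", call. = FALSE)
  }
  if (!is.numeric(df$ct)) stop("non-numeric 'ct' column in ", path, call. = FALSE)
  structure(df, class = c("ct_table", "data.frame"))
}

#' Export mesh fields as a legacy-ASCII VTK unstructured grid
#'
#' Writes the axisymmetric meridian mesh (r as x, z as y) with any number
#' of nodal scalar fields as POINT_DATA and element scalar fields as
#' CELL_DATA, readable by standard VTK tools.
#'
#' @param mesh A `"ct_mesh"`.
#' @param path Output `.vtk` path.
#' @param point_data Named list of per-node numeric vectors.
#' @param cell_data Named list of per-element numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list()) {
  stopifnot(inherits(mesh, "ct_mesh"))
  nn <- nrow(mesh$nodes); nt <- nrow(mesh$tri)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "axisymmetric well fields", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  writeLines(sprintf("%.10g %.10g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", nt, 4L * nt), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                     mesh$tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(rep("5", nt), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nn), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      stopifnot(length(v) == nn)
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.10g", v), con)
    }
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", nt), con)
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      stopifnot(length(v) == nt)
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.10g", v), con)
    }
  }
  invisible(path)
}

#' Write a ramp schedule as CSV of knots
#'
#' @param schedule A `"ramp_schedule"`.
#' @param path File path.
#' @return `read_schedule_csv` returns a `"ramp_schedule"`.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "ramp_schedule"))
  utils::write.csv(as.data.frame(schedule)[, c("t_s", "setpoint_degC")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t_s", "setpoint_degC") %in% names(df))) {
    stop("schedule CSV needs columns t_s,setpoint_degC", call. = FALSE)
  }
  structure(df[, c("t_s", "setpoint_degC")],
            class = c("ramp_schedule", "data.frame"))
}
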