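# File formats: legacy ASCII VTK structured points for fields, CSV for
# tables, JSON for configuration and timings.  Numbers are written with
# 17 significant digits so velocity frames round-trip bit-exactly.

.fmt <- function(x) sprintf("%.17g", x)

#' Write a velocity field as legacy VTK structured points
#'
#' ASCII `STRUCTURED_POINTS` dataset with a 3-component point field
#' named `velocity` (m/s), an optional integer point field `mask`, and
#' the frame time in a `TimeValue` field-data array.  Units are recorded
#' in the header line and asserted by [read_field_vtk()].
#'
#' @param field a [grid_velocity_field()].
#' @param path output file path (conventional extension `.vtk`).
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(field, path) {
  stopifnot(inherits(field, "grid_velocity_field"))
  d <- field$dims
  n <- prod(d)
  v <- matrix(field$velocity, n, 3)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("triflow velocity frame; length_unit=m velocity_unit=m/s")
  wl("ASCII")
  wl("DATASET STRUCTURED_POINTS")
  wl("DIMENSIONS ", paste(d, collapse = " "))
  wl("ORIGIN ", paste(.fmt(field$origin), collapse = " "))
  wl("SPACING ", paste(.fmt(field$spacing), collapse = " "))
  wl("FIELD FieldData 1")
  wl("TimeValue 1 1 double")
  wl(.fmt(field$time))
  wl("POINT_DATA ", n)
  wl("VECTORS velocity double")
  writeLines(paste(.fmt(v[, 1]), .fmt(v[, 2]), .fmt(v[, 3])), con)
  if (!is.null(field$mask)) {
    wl("SCALARS mask int 1")
    wl("LOOKUP_TABLE default")
    writeLines(as.character(as.integer(field$mask)), con)
  }
  invisible(path)
}

#' Write modality fields as legacy VTK structured points
#'
#' Point scalar fields `rotation`, `shear`, `strain`, `sss` (1/s);
#' undefined nodes are written as `nan`.
#'
#' @param m a `"modality_fields"` object from [decompose_field()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_modalities_vtk <- function(m, path) {
  stopifnot(inherits(m, "modality_fields"))
  d <- m$dims
  n <- prod(d)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("triflow modality fields; length_unit=m value_unit=1/s connectivity=26")
  wl("ASCII")
  wl("DATASET STRUCTURED_POINTS")
  wl("DIMENSIONS ", paste(d, collapse = " "))
  wl("ORIGIN ", paste(.fmt(m$origin), collapse = " "))
  wl("SPACING ", paste(.fmt(m$spacing), collapse = " "))
  wl("FIELD FieldData 1")
  wl("TimeValue 1 1 double")
  wl(.fmt(m$time))
  wl("POINT_DATA ", n)
  for (nm in c("rotation", "shear", "strain", "sss")) {
    wl("SCALARS ", nm, " double 1")
    wl("LOOKUP_TABLE default")
    vals <- .fmt(m[[nm]])
    vals[is.na(m[[nm]])] <- "nan"
    writeLines(vals, con)
  }
  invisible(path)
}

#' Read a velocity field from a legacy VTK structured-points file
#'
#' Counterpart of [write_field_vtk()].  The file must be ASCII
#' `STRUCTURED_POINTS` with a 3-component `velocity` point field;
#' a `mask` point field and a `TimeValue` field-data entry are optional
#' (time defaults to 0).  Velocities must be declared in m/s in the
#' header line; no silent unit conversion is performed.
#'
#' @param path file path.
#' @return A [grid_velocity_field()].
#' @export
read_field_vtk <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  fail <- function(msg) stop(msg, " in ", path, call. = FALSE)
  if (length(lines) < 10 || !grepl("^# vtk DataFile", lines[1])) {
    fail("not a legacy VTK file")
  }
  title <- lines[2]
  if (grepl("velocity_unit=", title) &&
      !grepl("velocity_unit=m/s", title, fixed = TRUE)) {
    fail("velocity unit is not m/s")
  }
  if (toupper(trimws(lines[3])) != "ASCII") fail("only ASCII VTK supported")
  grab <- function(key) {
    i <- grep(paste0("^", key, " "), lines)
    if (length(i) != 1) fail(paste("missing", key))
    as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]][-1])
  }
  if (!any(grepl("^DATASET STRUCTURED_POINTS", lines))) {
    fail("dataset is not STRUCTURED_POINTS")
  }
  d <- as.integer(grab("DIMENSIONS"))
  origin <- grab("ORIGIN")
  spacing <- grab("SPACING")
  n <- prod(d)

  time <- 0
  it <- grep("^TimeValue ", lines)
  if (length(it) == 1) time <- as.numeric(lines[it + 1])

  iv <- grep("^VECTORS velocity ", lines)
  if (length(iv) != 1) fail("missing point field 'velocity'")
  vec_lines <- lines[(iv + 1):(iv + n)]
  v <- matrix(scan(text = vec_lines, quiet = TRUE), ncol = 3, byrow = TRUE)
  if (nrow(v) != n) fail("velocity field has wrong length")
  vel <- array(0, c(d, 3L))
  for (k in 1:3) vel[, , , k] <- array(v[, k], d)

  mask <- NULL
  im <- grep("^SCALARS mask ", lines)
  if (length(im) == 1) {
    mask_vals <- scan(text = lines[(im + 2):(im + 1 + n)], quiet = TRUE)
    mask <- array(mask_vals != 0, d)
  }
  grid_velocity_field(vel, spacing, origin, mask = mask, time = time)
}

#' Read a sequence of velocity frames
#'
#' Reads each file with [read_field_vtk()], checks that all frames share
#' the same grid geometry, and returns them sorted by their embedded
#' time values (which must be distinct).
#'
#' @param paths character vector of VTK file paths.
#' @return A list of [grid_velocity_field()] objects in time order.
#' @export
read_velocity_frames <- function(paths) {
  if (length(paths) == 0) stop("no input frames given", call. = FALSE)
  frames <- lapply(paths, read_field_vtk)
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (anyDuplicated(times)) {
    stop("frames do not have distinct time values", call. = FALSE)
  }
  frames <- frames[order(times)]
  ref <- frames[[1]]
  for (i in seq_along(frames)[-1]) {
    f <- frames[[i]]
    if (!identical(f$dims, ref$dims) ||
        !isTRUE(all.equal(f$spacing, ref$spacing)) ||
        !isTRUE(all.equal(f$origin, ref$origin))) {
      stop("geometry mismatch in ", paths[order(times)][i], call. = FALSE)
    }
  }
  frames
}

#' Write a modality time series as CSV
#'
#' RFC-4180 CSV with header
#' `time,mean_rotation,mean_shear,mean_strain,mean_sss`.
#'
#' @param series data frame from [time_series()] or [spatial_average()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_time_series_csv <- function(series, path) {
  need <- c("time", "mean_rotation", "mean_shear", "mean_strain", "mean_sss")
  if (!all(need %in% names(series))) {
    stop("series lacks required columns", call. = FALSE)
  }
  utils::write.table(series[, need], path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a structure-component table as CSV
#'
#' Header `label,voxels,centroid_x,centroid_y,centroid_z`; an empty
#' component list yields a header-only file.
#'
#' @param components data frame from [extract_structures()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_components_csv <- function(components, path) {
  need <- c("label", "voxels", "centroid_x", "centroid_y", "centroid_z")
  if (!all(need %in% names(components))) {
    stop("components lack required columns", call. = FALSE)
  }
  utils::write.table(components[, need], path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an LV volume curve from CSV
#'
#' Expects columns `time_s` and `volume_ml`.
#'
#' @param path CSV file path.
#' @return A [volume_curve()].
#' @export
read_volume_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "volume_ml") %in% names(df))) {
    stop("volume CSV must have columns time_s,volume_ml: ", path,
         call. = FALSE)
  }
  volume_curve(df$time_s, df$volume_ml)
}

#' Write an LV volume curve as CSV
#'
#' @param curve a [volume_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume_csv <- function(curve, path) {
  stopifnot(inherits(curve, "volume_curve"))
  utils::write.table(data.frame(time_s = .fmt(curve$times),
                                volume_ml = .fmt(curve$volumes)),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write phase timings (and optional volumetric indices) as JSON
#'
#' @param timings a `"phase_timings"` object from [detect_phases()].
#' @param path output file path.
#' @param ef optional list from [ejection_fraction()] to embed.
#' @return `path`, invisibly.
#' @export
write_timings_json <- function(timings, path, ef = NULL) {
  stopifnot(inherits(timings, "phase_timings"))
  out <- unclass(timings)
  if (!is.null(ef)) out <- c(out, ef)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a valve configuration from JSON
#'
#' Blocks: `axes {l, saa, sap}` (mm), `schedule {knots: [[t, saa_scale,
#' sap_scale], ...]}`, optional `clip {s, width_mm}` and
#' `fluid {density, viscosity}`.  Omitted blocks fall back to the
#' package defaults.
#'
#' @param path JSON file path.
#' @return A list with elements `model` (a [valve_model()]) and `fluid`
#'   (a [fluid_properties()]).
#' @export
read_valve_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  axes <- if (is.null(cfg$axes)) valve_axes() else
    valve_axes(cfg$axes$l, cfg$axes$saa, cfg$axes$sap)
  sched <- if (is.null(cfg$schedule)) scaling_schedule() else {
    k <- cfg$schedule$knots
    if (is.list(k)) k <- do.call(rbind, k)
    scaling_schedule(k[, 1], k[, 2], k[, 3])
  }
  clip <- if (is.null(cfg$clip)) NULL else
    clip_spec(cfg$clip$s,
              if (is.null(cfg$clip$width_mm)) 5 else cfg$clip$width_mm)
  fluid <- if (is.null(cfg$fluid)) fluid_properties() else
    fluid_properties(cfg$fluid$density, cfg$fluid$viscosity)
  list(model = valve_model(axes, sched, clip), fluid = fluid)
}

#' Write a run manifest
#'
#' Records the configuration, seed and package/R versions of a run so it
#' can be replayed deterministically.
#'
#' @param config named list describing the run (echoed verbatim).
#' @param seed the seed used (or `NULL`).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, seed, path) {
  jsonlite::write_json(
    list(config = config, seed = seed,
         versions = list(triflow = as.character(utils::packageVersion("triflow")),
                         R = paste(R.version$major, R.version$minor, sep = "."))),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
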