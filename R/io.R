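#' Dataset manifest describing a recording on disk
#'
#' Recordings are consumed as delimited text plus a column-mapping manifest,
#' so the reader adapts to a file layout instead of hard-coding one. Paths
#' are interpreted relative to the manifest's own directory once written.
#'
#' @param iq_file CSV with the radar channels, or `NULL` if absent.
#' @param reference_file CSV with the displacement reference, or `NULL`.
#' @param columns Named list mapping roles to column names; recognized roles:
#'   `time`, `i`, `q`, `displacement`.
#' @param sampling_rate Declared sampling rate in Hz.
#' @param time_unit `"s"` if the time column holds seconds, `"index"` if it
#'   holds sample indices (converted to seconds via `sampling_rate`).
#' @param subject Free-text subject identifier.
#' @param schedule Optional data frame with `duration` (s) and `level`
#'   columns describing the protocol segments.
#' @return Object of class `dataset_manifest`.
#' @export
dataset_manifest <- function(iq_file = NULL, reference_file = NULL,
                             columns = list(time = "time_s", i = "i", q = "q",
                                            displacement = "displacement_m"),
                             sampling_rate = 1092,
                             time_unit = c("s", "index"),
                             subject = "synthetic",
                             schedule = NULL) {
  time_unit <- match.arg(time_unit)
  assert_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  if (is.null(iq_file) && is.null(reference_file))
    stop_respiradar("manifest needs at least one of iq_file, reference_file")
  if (is.null(columns$time)) stop_respiradar("column map must name a 'time' column")
  if (!is.null(schedule)) {
    schedule <- as.data.frame(schedule)
    if (!all(c("duration", "level") %in% names(schedule)))
      stop_respiradar("schedule needs 'duration' and 'level' columns")
    if (any(schedule$duration <= 0)) stop_respiradar("schedule durations must be > 0")
  }
  structure(list(iq_file = iq_file, reference_file = reference_file,
                 columns = columns, sampling_rate = sampling_rate,
                 time_unit = time_unit, subject = subject,
                 schedule = schedule),
            class = "dataset_manifest")
}

#' Write a manifest to YAML
#' @param manifest A [dataset_manifest()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  x <- unclass(manifest)
  if (!is.null(x$schedule))
    x$schedule <- lapply(seq_len(nrow(x$schedule)), function(i)
      list(duration = x$schedule$duration[i],
           level = as.character(x$schedule$level[i])))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a manifest from YAML
#' @param path YAML file written by [write_manifest()] or authored by hand.
#' @return A [dataset_manifest()]; relative file paths are resolved against
#'   the manifest's directory.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_respiradar("manifest not found: %s", path)
  x <- yaml::read_yaml(path)
  sched <- if (!is.null(x$schedule))
    do.call(rbind, lapply(x$schedule, function(s)
      data.frame(duration = s$duration, level = as.character(s$level))))
  resolve <- function(f) {
    if (is.null(f)) return(NULL)
    if (file.exists(f)) f else file.path(dirname(path), f)
  }
  dataset_manifest(iq_file = resolve(x$iq_file),
                   reference_file = resolve(x$reference_file),
                   columns = x$columns,
                   sampling_rate = x$sampling_rate,
                   time_unit = x$time_unit %||% "s",
                   subject = x$subject %||% "unknown",
                   schedule = sched)
}

# fixed float format for round-trip stability
fmt_num <- function(x) sprintf("%.9g", x)

write_trace_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_num), stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated recording and its manifest to a directory
#'
#' Emits `iq.csv` (`time_s, i, q`), `reference.csv`
#' (`time_s, displacement_m`) and `manifest.yaml`; numbers use a fixed
#' 9-significant-digit format so identical inputs give byte-identical files.
#'
#' @param recording List with `iq` and/or `reference`, as from
#'   [simulate_recording()].
#' @param dir Output directory (created if needed).
#' @param subject Subject label stored in the manifest.
#' @param schedule Optional protocol schedule (`duration`, `level`).
#' @return Path of the written manifest, invisibly.
#' @export
write_recording <- function(recording, dir, subject = "synthetic",
                            schedule = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iq_file <- ref_file <- NULL
  fs <- NULL
  if (!is.null(recording$iq)) {
    iq_file <- "iq.csv"
    write_trace_csv(data.frame(time_s = recording$iq$times,
                               i = recording$iq$i, q = recording$iq$q),
                    file.path(dir, iq_file))
    fs <- attr(recording$iq, "sampling_rate")
  }
  if (!is.null(recording$reference)) {
    ref_file <- "reference.csv"
    write_trace_csv(data.frame(time_s = recording$reference$times,
                               displacement_m = recording$reference$displacement),
                    file.path(dir, ref_file))
    fs <- fs %||% attr(recording$reference, "sampling_rate")
  }
  man <- dataset_manifest(iq_file = iq_file, reference_file = ref_file,
                          sampling_rate = fs, subject = subject,
                          schedule = schedule)
  write_manifest(man, file.path(dir, "manifest.yaml"))
  invisible(file.path(dir, "manifest.yaml"))
}

read_mapped_csv <- function(path, columns, roles, sampling_rate, time_unit) {
  if (!file.exists(path)) stop_respiradar("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- unlist(columns[c("time", roles)], use.names = FALSE)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_respiradar("missing columns in %s: %s", path,
                    paste(missing_cols, collapse = ", "))
  for (cl in need) {
    vals <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(!is.finite(vals))
    if (length(bad))
      stop_respiradar("unparseable or non-finite values in %s column '%s' (rows %s)",
                      path, cl, paste(utils::head(bad, 5), collapse = ", "))
    df[[cl]] <- vals
  }
  t <- df[[columns$time]]
  if (time_unit == "index") t <- t / sampling_rate
  if (any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1] + 1L
    stop_respiradar("non-monotone time in %s (row %d)", path, bad)
  }
  vals <- lapply(roles, function(r) df[[columns[[r]]]])
  names(vals) <- roles
  # validate the grid against the declared rate; snap small jitter (e.g.
  # limited float formatting) to the canonical grid, resample otherwise
  dt <- diff(t)
  declared_dt <- 1 / sampling_rate
  canonical <- t[1] + (seq_along(t) - 1) * declared_dt
  if (all(abs(t - canonical) <= 0.01 * declared_dt)) {
    t <- canonical
  } else {
    warning(sprintf("%s: time grid deviates from declared %g Hz; resampling",
                    basename(path), sampling_rate), call. = FALSE)
    grid <- seq(t[1], t[length(t)], by = declared_dt)
    vals <- lapply(vals, function(v) stats::approx(t, v, xout = grid)$y)
    t <- grid
  }
  c(list(time = t), vals)
}

#' Read a recording described by a manifest
#'
#' Loads the mapped columns, validates monotone time, converts index-based
#' time to seconds, and resamples (with a warning) onto the declared rate if
#' the file's grid deviates by more than 1%.
#'
#' @param manifest A [dataset_manifest()] or the path of a manifest YAML.
#' @return List with `iq` (`iq_trace` or `NULL`), `reference` (`ref_trace`
#'   or `NULL`), and `schedule` (data frame with `start`, `end`, `level`, or
#'   `NULL`).
#' @export
read_recording <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "dataset_manifest"))
  iq <- ref <- NULL
  if (!is.null(manifest$iq_file)) {
    d <- read_mapped_csv(manifest$iq_file, manifest$columns, c("i", "q"),
                         manifest$sampling_rate, manifest$time_unit)
    iq <- structure(list(times = d$time, i = d$i, q = d$q),
                    sampling_rate = manifest$sampling_rate,
                    class = "iq_trace")
  }
  if (!is.null(manifest$reference_file)) {
    d <- read_mapped_csv(manifest$reference_file, manifest$columns,
                         "displacement",
                         manifest$sampling_rate, manifest$time_unit)
    ref <- structure(list(times = d$time, displacement = d$displacement),
                     sampling_rate = manifest$sampling_rate,
                     class = "ref_trace")
  }
  sched <- if (!is.null(manifest$schedule))
    level_schedule(manifest$schedule$duration, manifest$schedule$level)
  list(iq = iq, reference = ref, schedule = sched)
}

#' Write a complete synthetic recording fixture to disk
#'
#' Simulates a preset scenario and writes everything a downstream command
#' needs: I/Q trace, reference trace, protocol schedule and manifest.
#' Deterministic per (preset, seed): identical calls give byte-identical
#' files.
#'
#' @param name Preset id, see [scenario_presets()].
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param config A [radar_config()]; its `noise_sd` and `adc_bits` govern
#'   the realism of the radar channels.
#' @return Path of the written manifest, invisibly.
#' @export
make_fixture <- function(name, seed = 1L, dir,
                         config = radar_config(noise_sd = 0.05)) {
  sc <- scenario_preset(name, seed = seed)   # errors on unknown preset
  rec <- simulate_recording(sc, config)
  levels <- attr(sc, "levels") %||% rep("single", nrow(sc$segments))
  schedule <- data.frame(duration = sc$segments[, "duration"], level = levels)
  write_recording(rec, dir, subject = paste0("synthetic-", name),
                  schedule = schedule)
}

#' Write an instantaneous-rate series as CSV
#'
#' Columns `time_s`, `bpm`, `quality` on the uniform grid.
#'
#' @param series An `inst_rate`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rate_series <- function(series, path) {
  stopifnot(inherits(series, "inst_rate"))
  write_trace_csv(data.frame(time_s = series$grid_times, bpm = series$bpm,
                             quality = series$quality_interp), path)
}
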