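#' Write a response trace to CSV with a JSON sidecar
#'
#' The CSV holds columns `time_s` and `value`; the sidecar `<path>.json`
#' carries `dt_s`, `baseline_value`, `label` and any extra metadata (e.g. the
#' detector parameters that produced the trace).
#'
#' @param trace a [response_trace()].
#' @param path output CSV path.
#' @param meta named list of extra metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, meta = list()) {
  utils::write.csv(data.frame(time_s = trace_time(trace), value = trace$values),
                   path, row.names = FALSE)
  write_json_file(c(list(dt_s = trace$dt_s, baseline_value = trace$baseline_value,
                         label = trace$label), meta),
                  paste0(path, ".json"))
  invisible(path)
}

#' Read a response trace written by [write_trace_csv()]
#'
#' @param path CSV path (sidecar `<path>.json` must exist).
#' @return A [response_trace()].
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  response_trace(d$value, dt_s = meta$dt_s,
                 baseline_value = meta$baseline_value, label = meta$label)
}

#' Write column traces to CSV (time column plus one column per visual column)
#'
#' @param traces a `column_traces` object.
#' @param path output CSV path.
#' @param meta extra sidecar metadata.
#' @return `path`, invisibly.
#' @export
write_column_traces_csv <- function(traces, path, meta = list()) {
  d <- as.data.frame(traces$values)
  names(d) <- sprintf("col_%02d", seq_len(ncol(d)))
  d <- cbind(time_s = (seq_len(nrow(d)) - 1) * traces$dt_s, d)
  utils::write.csv(d, path, row.names = FALSE)
  write_json_file(c(list(dt_s = traces$dt_s, centers_deg = traces$centers_deg),
                    meta), paste0(path, ".json"))
  invisible(path)
}

#' Write a tuning curve in long format
#'
#' Long CSV with columns `parameter`, `condition`, `amplitude` (and `sem`
#' where present), plus a JSON sidecar with the curve's metadata.
#'
#' @param curve a `tuning_curve` data frame from [temporal_tuning()],
#'   [direction_tuning()] or [delay_tuning()].
#' @param path output CSV path.
#' @param meta extra sidecar metadata.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path, meta = list()) {
  par_col <- intersect(c("frequency", "direction", "delay"), names(curve))[1]
  value_cols <- setdiff(names(curve), par_col)
  long <- do.call(rbind, lapply(value_cols, function(cc)
    data.frame(parameter = curve[[par_col]], condition = cc,
               amplitude = curve[[cc]])))
  utils::write.csv(long, path, row.names = FALSE)
  write_json_file(c(list(parameter = par_col, stage = attr(curve, "stage"),
                         pair = attr(curve, "pair")), meta),
                  paste0(path, ".json"))
  invisible(path)
}

#' Write a receptive-field map to CSV
#'
#' @param map an [rf_map()] (or any data frame with hex coordinates).
#' @param path output CSV path.
#' @param meta extra sidecar metadata.
#' @return `path`, invisibly.
#' @export
write_rf_map_csv <- function(map, path, meta = list()) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  raster <- attr(map, "raster")
  write_json_file(c(list(n_rings = if (!is.null(raster)) raster$n_rings),
                    meta), paste0(path, ".json"))
  invisible(path)
}

#' Write a synthetic recording to a directory
#'
#' One CSV per condition (time column plus one column per repetition) and a
#' `manifest.json` holding the full generator provenance — enough to
#' regenerate the recording bit-identically with
#' [regenerate_recording()].
#'
#' @param recording a [simulate_recording()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "synthetic_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(recording$conditions)) {
    cond <- recording$conditions[[nm]]
    d <- as.data.frame(t(cond$traces))
    names(d) <- sprintf("rep_%d", seq_len(ncol(d)))
    d <- cbind(time_s = (seq_len(nrow(d)) - 1) * recording$dt_s, d)
    utils::write.csv(d, file.path(dir, paste0(gsub("[^0-9A-Za-z_-]", "_", nm),
                                              ".csv")), row.names = FALSE)
  }
  manifest <- recording$provenance
  manifest$conditions <- lapply(recording$conditions, function(cond)
    as.data.frame(cond$protocol))
  write_json_file(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Regenerate a synthetic recording from its manifest
#'
#' Rebuilds the generator inputs recorded in a `manifest.json` written by
#' [write_recording()] and reruns [simulate_recording()]; by construction the
#' result is bit-identical to the recording that produced the manifest.
#'
#' @param manifest_path path to a `manifest.json`.
#' @return A [simulate_recording()] result.
#' @export
regenerate_recording <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  raster <- make_hex_raster(m$n_rings)
  rf <- synth_rf(raster, ring_amplitudes = m$rf_spec$ring_amplitudes,
                 gaussian_fwhm = m$rf_spec$gaussian_fwhm)
  conditions <- lapply(m$conditions, function(p)
    hex_protocol(p$q, p$r, onset_s = p$onset_s, duration_s = p$duration_s,
                 amplitude = p$amplitude))
  params <- do.call(detector_params, m$detector)
  simulate_recording(conditions, rf, cell_model = m$cell_model,
                     kernel = calcium_kernel(m$tau_ca_s),
                     noise_sd = m$noise_sd, n_reps = m$n_reps, seed = m$seed,
                     dt_s = m$dt_s, pre_s = m$pre_s, post_s = m$post_s,
                     params = params)
}

# deterministic JSON writer shared by all outputs
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
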